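test_that("anchor-based cluster naming recovers a pure bijection", {
  truth <- rep(c("unripe", "ripe", "overripe"), each = 10)
  assignments <- rep(c(2L, 3L, 1L), each = 10)  # pure but permuted
  mp <- map_clusters_to_stages(assignments, truth = truth)
  expect_equal(mp$agreement, 1)
  expect_equal(mp$map, c("overripe", "unripe", "ripe"))
  # permuting cluster ids permutes the map but names every image identically
  relabel <- c(3L, 1L, 2L)[assignments]
  mp2 <- map_clusters_to_stages(relabel, truth = truth)
  expect_equal(mp2$map[relabel], mp$map[assignments])
  # partial anchors work
  truth_part <- truth; truth_part[seq(1, 30, 2)] <- NA
  expect_equal(map_clusters_to_stages(assignments, truth = truth_part)$map, mp$map)
})

test_that("proxy-based naming ranks clusters by maturity evidence", {
  assignments <- rep(1:3, each = 20)
  crack <- rep(c(0.15, 0.0, 0.06), each = 20) +
    withr::with_seed(1, runif(60, 0, 0.01))
  mp <- map_clusters_to_stages(assignments, proxy = crack, proxy_type = "crack")
  expect_equal(mp$map, c("overripe", "unripe", "ripe"))
  oil <- rep(c(39, 46, 44.4), each = 20)
  mo <- map_clusters_to_stages(assignments, proxy = oil, proxy_type = "oil")
  expect_equal(mo$map, c("unripe", "ripe", "overripe"))
  expect_match(mo$note, "non-monotone")
  expect_error(map_clusters_to_stages(rep(1:2, 10), proxy = rnorm(20)), "3 clusters")
  expect_error(map_clusters_to_stages(assignments), "anchor|proxy")
})

test_that("crack-proxy naming agrees with truth-anchor naming on a synthetic run", {
  imgs <- generate_dataset(12, size = 64, rng_seed = 50, separation = 1)
  truth <- truth_stages(imgs)
  bb <- build_backbone(backbone_config("tiny", init_seed = 51))
  f <- extract_features(bb, imgs)
  cl <- kmeans_fit(l2_normalize(apply_reduction(fit_reduction(f, 16), f)), 3,
                   rng_seed = 52)
  crack_frac <- vapply(imgs, function(im) {
    if (is.null(im$crack_bbox)) 0 else {
      b <- im$crack_bbox
      (b[["x1"]] - b[["x0"]] + 1) * (b[["y1"]] - b[["y0"]] + 1) / (64 * 64)
    }
  }, numeric(1))
  by_truth <- map_clusters_to_stages(cl$assignments, truth = truth)
  by_proxy <- map_clusters_to_stages(cl$assignments, proxy = crack_frac,
                                     proxy_type = "crack")
  expect_gte(by_truth$agreement, 0.9)
  expect_equal(by_proxy$map, by_truth$map)
})

test_that("confusion matrices count true-by-predicted pairs", {
  stages <- c("unripe", "ripe", "overripe")
  perfect <- build_confusion(rep(stages, each = 4), rep(stages, each = 4))
  expect_equal(unname(diag(unclass(perfect))), rep(4L, 3))
  expect_equal(sum(unclass(perfect)) - sum(diag(unclass(perfect))), 0L)
  cm <- testing_set_confusion()
  expect_equal(sum(unclass(cm)), 160L)
  expect_equal(sum(diag(unclass(cm))), 146L)
  expect_equal(unname(rowSums(unclass(cm))), c(50, 60, 50))
  # random labelings conserve row sums
  tr <- withr::with_seed(2, sample(stages, 100, TRUE))
  pr <- withr::with_seed(3, sample(stages, 100, TRUE))
  rcm <- build_confusion(tr, pr)
  expect_equal(unname(rowSums(unclass(rcm))), unname(table(factor(tr, stages))),
               ignore_attr = TRUE)
  expect_error(build_confusion(c("unripe", "rotten"), c("ripe", "ripe"),
                               stage_names = stages), "unknown label")
})

test_that("metrics follow the one-vs-rest definitions", {
  diagm <- build_confusion(rep(c("a", "b"), each = 5), rep(c("a", "b"), each = 5),
                           stage_names = c("a", "b"))
  md <- compute_metrics(diagm)
  expect_equal(md$per_stage$precision, c(100, 100))
  expect_equal(md$per_stage$f1, c(100, 100))
  expect_equal(md$overall_accuracy, 100)
  # micro-averaged recall == overall accuracy on random matrices
  for (s in 1:10) {
    cm <- withr::with_seed(400 + s,
                           matrix(rpois(9, 20) + 1, 3, 3,
                                  dimnames = list(true = letters[1:3],
                                                  predicted = letters[1:3])))
    m <- compute_metrics(cm)
    micro_recall <- 100 * sum(diag(cm)) / sum(cm)
    expect_equal(m$overall_accuracy, micro_recall, tolerance = 1e-12)
    # F1 lies between precision and recall when defined
    ok <- !is.na(m$per_stage$f1)
    expect_true(all(m$per_stage$f1[ok] <=
                      pmax(m$per_stage$precision, m$per_stage$recall)[ok] + 1e-9))
    expect_true(all(m$per_stage$f1[ok] >=
                      pmin(m$per_stage$precision, m$per_stage$recall)[ok] - 1e-9))
  }
})

test_that("metrics are invariant to simultaneous class permutation", {
  cm <- unclass(testing_set_confusion())
  perm <- c(3, 1, 2)
  cmp <- cm[perm, perm]
  m1 <- compute_metrics(cm)
  m2 <- compute_metrics(cmp)
  expect_equal(m1$overall_accuracy, m2$overall_accuracy)
  expect_equal(m1$per_stage$f1[perm], m2$per_stage$f1)
})

test_that("never-predicted classes get flagged undefined precision", {
  cm <- matrix(c(3, 1, 2, 2, 4, 3, 0, 0, 0), 3, 3,  # class c never predicted
               dimnames = list(true = letters[1:3], predicted = letters[1:3]))
  m <- compute_metrics(cm)
  expect_true("c" %in% m$undefined_precision)
  expect_error(compute_metrics(matrix(0, 2, 2)), "empty")
})

test_that("moisture content implements the drying weight fraction", {
  expect_equal(moisture_content(10, 10), 0)
  expect_equal(moisture_content(10, 4), 60)
  expect_equal(moisture_content(c(10, 8), c(4, 2)), c(60, 75))
  expect_error(moisture_content(4, 10), "exceed")
  expect_error(moisture_content(0, 0), "positive")
})
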