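test_that("one-way ANOVA matches a hand-computed decomposition", {
  # small fixed dataset, sums of squares worked by hand:
  # groups: a = (1, 2, 3), b = (4, 5, 6), c = (8, 9, 10)
  # grand mean = 48/9 = 16/3; group means 2, 5, 9
  # SSB = 3[(2-16/3)^2 + (5-16/3)^2 + (9-16/3)^2] = 3*(100/9 + 1/9 + 121/9) = 74
  # SSW = 2 + 2 + 2 = 6; MSB = 37, MSE = 1, F = 37
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(8, 9, 10))
  an <- one_way_anova(g)
  expect_equal(an$F, 37, tolerance = 1e-12)
  expect_equal(an$MSE, 1, tolerance = 1e-12)
  expect_equal(an$df_between, 2)
  expect_equal(an$df_error, 6)
  expect_equal(an$p, pf(37, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # relabeling the groups leaves F unchanged
  an2 <- one_way_anova(g[c(3, 1, 2)])
  expect_equal(an2$F, an$F)
})

test_that("huge offsets are detected and degenerate inputs rejected", {
  base <- withr::with_seed(1, rnorm(10))
  g <- list(a = base, b = base + 1000, c = base + 2000)
  expect_lt(one_way_anova(g)$p, 1e-10)
  expect_error(one_way_anova(list(a = rep(1, 3), b = rep(1, 3))), "degenerate")
  expect_error(one_way_anova(list(a = 1:3)), "two groups")
  expect_error(one_way_anova(list(a = 1, b = 1:3)), "two values")
})

test_that("Duncan ranges and separations match a hand-worked oracle", {
  # worked example prepared by hand before coding:
  # 4 groups, n = 5 each, means 9.8, 15.4, 17.6, 21.6, MSE = 8.06 on df = 16
  # se = sqrt(8.06/5) = 1.2696
  # R2 = q(.95, 2, 16)*se = 2.9980*1.2696 = 3.806
  # R3 = q(.9025, 3, 16)*se = 3.1441*1.2696 = 3.992
  # R4 = q(.857375, 4, 16)*se = 3.2353*1.2696 = 4.108
  # sorted desc: 21.6, 17.6, 15.4, 9.8
  # 21.6-17.6 = 4.0 > R2 sig; 17.6-15.4 = 2.2 < R2 ns; 15.4-9.8 = 5.6 > R2 sig
  # 21.6-15.4 = 6.2 > R3 sig; 17.6-9.8 = 7.8 > R3 sig; 21.6-9.8 = 11.8 > R4 sig
  # letters (desc): a, b, b, c
  means <- c(g1 = 9.8, g2 = 15.4, g3 = 17.6, g4 = 21.6)
  grp <- rep(names(means), each = 5)
  # symmetric residuals scaled so the error mean square is exactly 8.06
  resid <- rep(c(-2, -1, 0, 1, 2), 4)
  scale <- sqrt(8.06 / (sum(resid^2) / 16))
  vals <- rep(means, each = 5) + resid * scale
  d <- duncan_mrt(vals, grp)
  se <- sqrt(8.06 / 5)
  expect_equal(unname(d$ranges), qtukey(c(0.95, 0.95^2, 0.95^3), 2:4, 16) * se,
               tolerance = 1e-9)
  expect_equal(unname(d$letters[c("g4", "g3", "g2", "g1")]), c("a", "b", "b", "c"))
  expect_equal(unname(d$means), c(21.6, 17.6, 15.4, 9.8), tolerance = 1e-9)
})

test_that("degenerate stage means reproduce the published letter ordering", {
  # dry seed weight means by stage with vanishing SD: ripe > overripe > unripe
  withr::with_seed(2, {
    g <- list(unripe = 8.06 + rnorm(3, 0, 1e-9),
              ripe = 12.44 + rnorm(3, 0, 1e-9),
              overripe = 11.05 + rnorm(3, 0, 1e-9))
    d <- suppressWarnings(duncan_mrt(g))
    expect_equal(unname(d$letters[c("ripe", "overripe", "unripe")]),
                 c("a", "b", "c"))
  })
})

test_that("identical groups share one letter; distinct tight groups all differ", {
  base <- withr::with_seed(3, rnorm(8, sd = 1))
  g <- list(a = base, b = base + 0.001, c = base - 0.001)
  expect_equal(unname(duncan_mrt(g)$letters), rep("a", 3))
  tight <- withr::with_seed(4, list(a = rnorm(8, 0, 0.01), b = rnorm(8, 5, 0.01),
                                    c = rnorm(8, 10, 0.01)))
  expect_equal(sort(unname(duncan_mrt(tight)$letters)), c("a", "b", "c"))
})

test_that("least significant ranges grow with span and letters are transitive", {
  for (s in 1:8) {
    g <- withr::with_seed(500 + s, split(rnorm(40, rep(c(0, 0.5, 1, 3), each = 10)),
                                         rep(letters[1:4], each = 10)))
    d <- duncan_mrt(g)
    expect_true(all(diff(d$ranges) > 0))
    # transitivity: any letter's carriers are contiguous in the sorted order
    lab <- d$letters[names(d$means)]
    for (ch in unique(unlist(strsplit(lab, "")))) {
      carriers <- which(grepl(ch, lab))
      expect_equal(carriers, seq(min(carriers), max(carriers)))
    }
  }
})

test_that("n_eff overrides the replication used for the ranges", {
  g <- withr::with_seed(6, split(rnorm(90, rep(c(0, 1, 2), each = 30)),
                                 rep(letters[1:3], each = 30)))
  d_full <- duncan_mrt(g)
  d3 <- duncan_mrt(g, n_eff = 3)
  expect_equal(d_full$n_h, 30)
  expect_equal(d3$n_h, 3)
  expect_equal(d3$df, 6)
  expect_true(all(d3$ranges > d_full$ranges))
})

test_that("conjoint_report mirrors the stage-by-property table layout", {
  tab <- generate_property_table(12, rng_seed = 7)
  rep1 <- conjoint_report(tab)
  expect_s3_class(rep1, "rc_conjoint")
  expect_setequal(unique(rep1$table$property),
                  c("transverse_diameter_mm", "vertical_diameter_mm",
                    "dry_seed_weight_g", "moisture_pct", "oil_pct",
                    "soluble_protein_pct", "soluble_sugar_pct", "starch_pct"))
  expect_equal(nrow(rep1$table), 8 * 3)
  expect_true(all(grepl("±", rep1$table$label)))
  # record order does not matter
  perm <- withr::with_seed(8, sample.int(nrow(tab)))
  rep2 <- conjoint_report(tab[perm, ])
  expect_equal(rep1$table, rep2$table)
  # moisture is derived from the weights when absent
  tab_nomc <- tab[, setdiff(names(tab), "moisture_pct")]
  rep3 <- conjoint_report(tab_nomc)
  expect_equal(rep3$table[rep3$table$property == "moisture_pct", "mean"],
               rep1$table[rep1$table$property == "moisture_pct", "mean"],
               tolerance = 1e-9)
})

test_that("properties with missing stage coverage are flagged, not computed", {
  tab <- generate_property_table(5, rng_seed = 9)
  tab$oil_pct[tab$stage == "ripe"] <- NA
  rep <- conjoint_report(tab)
  expect_true("oil_pct" %in% rep$flagged)
  expect_false("oil_pct" %in% names(rep$results))
})
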