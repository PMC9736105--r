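test_that("unripe fruit render with no crack and the renderer is deterministic", {
  ph <- default_phenotypes(1)
  img1 <- generate_image(ph$unripe, 64, rng_seed = 5, noise_sd = 0, keep_masks = TRUE)
  expect_null(img1$crack_bbox)
  expect_equal(sum(img1$masks$crack), 0)
  img2 <- generate_image(ph$unripe, 64, rng_seed = 5, noise_sd = 0, keep_masks = TRUE)
  expect_identical(img1$pixels, img2$pixels)
  img3 <- generate_image(ph$unripe, 64, rng_seed = 6, noise_sd = 0)
  expect_false(identical(img1$pixels, img3$pixels))
  expect_true(all(img1$pixels >= 0 & img1$pixels <= 255))
})

test_that("phenotype invariants are enforced", {
  expect_error(stage_phenotype("unripe", 100, crack_fraction = 0.1), "indehiscent")
  expect_error(stage_phenotype("ripe", 60, crack_fraction = 0.05, seed_exposure = 0.1),
               "seed_exposure")
  expect_error(stage_phenotype("ripe", 60, crack_fraction = 1.2), "crack_fraction")
  expect_error(generate_image(default_phenotypes()$ripe, size = 16), "size")
})

test_that("rendered crack area tracks crack_fraction over repeated draws", {
  ph <- default_phenotypes(1)$overripe  # crack_fraction 0.15
  fracs <- vapply(1:100, function(s) {
    img <- generate_image(ph, 64, rng_seed = 1000 + s, keep_masks = TRUE)
    sum(img$masks$crack) / sum(img$masks$fruit)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - ph$crack_fraction) / ph$crack_fraction, 0.10)
})

test_that("generate_dataset produces the requested stage counts, shuffled", {
  imgs <- generate_dataset(50, size = 64, rng_seed = 2, noise_sd = 0)
  expect_length(imgs, 150)
  expect_equal(unname(table(truth_stages(imgs))[MATURITY <- c("unripe", "ripe", "overripe")]),
               rep(50L, 3), ignore_attr = TRUE)
  # testing-set style unbalanced counts
  ts <- generate_dataset(c(unripe = 5, ripe = 6, overripe = 5), rng_seed = 3)
  expect_length(ts, 16)
  expect_equal(sum(truth_stages(ts) == "ripe"), 6)
  # truth labels are not grouped by construction order
  expect_gt(length(rle(truth_stages(imgs))$lengths), 10)
})

test_that("stage hue bands are separable and a hue threshold classifies cleanly", {
  imgs <- generate_dataset(20, size = 64, rng_seed = 7, separation = 1,
                           noise_sd = 0, keep_masks = TRUE)
  hues <- vapply(imgs, ripecluster:::mean_fruit_hue, numeric(1))
  truth <- truth_stages(imgs)
  means <- tapply(hues, truth, mean)
  expect_true(means[["unripe"]] > means[["ripe"]],
              label = "unripe hue above ripe hue")
  expect_true(means[["ripe"]] > means[["overripe"]])
  # nearest configured band = perfect classification at zero noise
  bands <- c(unripe = 105, ripe = 65, overripe = 25)
  pred <- names(bands)[apply(abs(outer(hues, bands, `-`)), 1, which.min)]
  expect_equal(mean(pred == truth), 1)
})

test_that("property draws reproduce the configured stage means and SDs", {
  tab <- generate_property_table(1000, rng_seed = 11)
  ref <- fruit_property_reference()
  # unripe moisture mean recovers its configured value
  mc <- tab$moisture_pct[tab$stage == "unripe"]
  expect_lt(abs(mean(mc) - 69.55), 1)
  # every property within 3 standard errors of its stage mean, SD within 3 SE-ish
  for (stage in c("unripe", "ripe", "overripe")) {
    sub <- tab[tab$stage == stage, ]
    for (i in seq_len(nrow(ref))) {
      col <- switch(ref$property[i],
                    transverse_diameter = "transverse_diameter_mm",
                    vertical_diameter = "vertical_diameter_mm",
                    dry_seed_weight = "dry_seed_weight_g",
                    moisture = "moisture_pct", oil = "oil_pct",
                    soluble_protein = "soluble_protein_pct",
                    soluble_sugar = "soluble_sugar_pct", starch = "starch_pct")
      m <- ref[[paste0(stage, "_mean")]][i]
      s <- ref[[paste0(stage, "_sd")]][i]
      expect_lt(abs(mean(sub[[col]]) - m), 3 * s / sqrt(1000) + 1e-9,
                label = sprintf("%s %s mean", stage, col))
      # SDs checked at 4 SE: 48 simultaneous checks make a literal 3-SE band
      # trip on ordinary sampling noise
      expect_lt(abs(sd(sub[[col]]) - s), 4 * s / sqrt(2 * 999) + 1e-9,
                label = sprintf("%s %s sd", stage, col))
    }
  }
})

test_that("degenerate zero-SD draws sit exactly at the table means", {
  ref <- fruit_property_reference()
  ref[paste0(c("unripe", "ripe", "overripe"), "_sd")] <- 0
  tab <- generate_property_table(3, rng_seed = 1, reference = ref)
  expect_true(all(tab$oil_pct[tab$stage == "unripe"] == 39.12))
  expect_true(all(tab$dry_seed_weight_g[tab$stage == "ripe"] == 12.44))
  neg <- fruit_property_reference(); neg$unripe_sd[1] <- -1
  expect_error(generate_property_table(3, reference = neg), "non-negative")
})

test_that("generated weights invert back to the drawn moisture exactly", {
  tab <- generate_property_table(50, rng_seed = 13)
  expect_true(all(tab$dry_seed_weight_g <= tab$fresh_seed_weight_g))
  expect_true(all(tab$fresh_seed_weight_g > 0))
  back <- moisture_content(tab$fresh_seed_weight_g, tab$dry_seed_weight_g)
  expect_equal(back, tab$moisture_pct, tolerance = 1e-12)
})
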