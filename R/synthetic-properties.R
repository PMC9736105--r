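#' Reference means and standard deviations of fruit properties by stage
#'
#' Stage-wise means and SDs for the physical properties (transverse and
#' vertical diameter, dry seed weight, seed moisture content) and quality
#' properties (seed oil, soluble protein, soluble sugar, starch content) used
#' as the defaults of [generate_property_table()]. Diameters are in mm,
#' weights in g, everything else in percent.
#'
#' @return data.frame with columns `property`, `unit`, and `<stage>_mean` /
#'   `<stage>_sd` for the three maturity stages.
#' @export
fruit_property_reference <- function() {
  data.frame(
    property = c("transverse_diameter", "vertical_diameter", "dry_seed_weight",
                 "moisture", "oil", "soluble_protein", "soluble_sugar", "starch"),
    unit = c("mm", "mm", "g", "%", "%", "%", "%", "%"),
    unripe_mean   = c(46.05, 38.78,  8.06, 69.55, 39.12, 5.21, 25.69, 3.31),
    unripe_sd     = c( 1.54,  1.33,  0.41,  3.74,  0.99, 0.22,  1.16, 0.55),
    ripe_mean     = c(47.31, 40.10, 12.44, 58.79, 46.05, 5.61, 19.28, 2.30),
    ripe_sd       = c( 1.65,  1.95,  1.02,  2.13,  0.49, 0.16,  3.85, 0.24),
    overripe_mean = c(49.32, 40.64, 11.05, 48.15, 44.42, 6.11, 13.75, 1.54),
    overripe_sd   = c( 1.57,  1.71,  0.38,  0.62,  0.53, 0.07,  0.93, 0.82),
    stringsAsFactors = FALSE
  )
}

#' Generate a per-sample property table
#'
#' Draws one record per fruit sample: each property is Normal(stage mean,
#' stage SD) from the reference table (overridable). Seed moisture content and
#' dry seed weight are drawn first and the fresh seed weight is back-computed
#' as `W_f = W_d / (1 - M_c / 100)`, so that [moisture_content()] applied to
#' the generated weights returns the drawn moisture exactly. Values are
#' clipped to their physical ranges (percentages to `[0.5, 99]`, weights and
#' diameters strictly positive).
#'
#' @param counts_per_stage a single count (>= 2), or a named vector with
#'   entries `unripe`, `ripe`, `overripe`.
#' @param rng_seed integer seed.
#' @param reference reference table in the format of
#'   [fruit_property_reference()]. Negative SDs are rejected; an SD of 0 gives
#'   degenerate draws at the mean.
#' @return data.frame with one row per sample: `sample_id`, `stage`,
#'   `transverse_diameter_mm`, `vertical_diameter_mm`, `fresh_seed_weight_g`,
#'   `dry_seed_weight_g`, `moisture_pct`, `oil_pct`, `soluble_protein_pct`,
#'   `soluble_sugar_pct`, `starch_pct`.
#' @export
generate_property_table <- function(counts_per_stage, rng_seed = NULL,
                                    reference = fruit_property_reference()) {
  if (length(counts_per_stage) == 1L) {
    counts <- stats::setNames(rep(as.integer(counts_per_stage), 3), MATURITY_STAGES)
  } else {
    if (!all(MATURITY_STAGES %in% names(counts_per_stage))) {
      stop_input("counts_per_stage must be one count or named for all three stages")
    }
    counts <- as.integer(counts_per_stage[MATURITY_STAGES])
    names(counts) <- MATURITY_STAGES
  }
  if (any(counts < 2)) stop_input("need at least two samples per stage")
  sds <- as.matrix(reference[, paste0(MATURITY_STAGES, "_sd")])
  if (any(sds < 0)) stop_input("standard deviations must be non-negative")

  ref_get <- function(prop, stage, what) {
    reference[reference$property == prop, paste0(stage, "_", what)]
  }
  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

  with_rng_seed(rng_seed, {
    rows <- list()
    i <- 0
    for (stage in MATURITY_STAGES) {
      n <- counts[[stage]]
      draw <- function(prop) rnorm(n, ref_get(prop, stage, "mean"),
                                   ref_get(prop, stage, "sd"))
      mc <- clip(draw("moisture"), 0.5, 99)
      wd <- pmax(0.05, draw("dry_seed_weight"))
      wf <- wd / (1 - mc / 100)
      rows[[stage]] <- data.frame(
        sample_id = sprintf("p%04d", i + seq_len(n)),
        stage = stage,
        transverse_diameter_mm = pmax(1, draw("transverse_diameter")),
        vertical_diameter_mm = pmax(1, draw("vertical_diameter")),
        fresh_seed_weight_g = wf,
        dry_seed_weight_g = wd,
        moisture_pct = mc,
        oil_pct = clip(draw("oil"), 0.5, 99),
        soluble_protein_pct = clip(draw("soluble_protein"), 0.5, 99),
        soluble_sugar_pct = clip(draw("soluble_sugar"), 0.5, 99),
        starch_pct = clip(draw("starch"), 0.5, 99),
        stringsAsFactors = FALSE
      )
      i <- i + n
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
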