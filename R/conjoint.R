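# Coerce (x, group) or a named list of numeric vectors into a clean
# value/group pair with >= 2 groups.
as_property_groups <- function(x, group = NULL) {
  if (is.list(x) && is.null(group)) {
    group <- rep(names(x) %||% as.character(seq_along(x)), lengths(x))
    x <- unlist(x, use.names = FALSE)
  }
  keep <- is.finite(x)
  x <- x[keep]
  group <- factor(group[keep], levels = unique(group))
  if (nlevels(group) < 2L) stop_input("need at least two groups")
  if (any(table(group) < 2L)) stop_input("need at least two values per group")
  list(values = as.numeric(x), group = group)
}

#' One-way analysis of variance
#'
#' Standard between/within variance decomposition across groups (maturity
#' stages), fitted with [stats::aov()].
#'
#' @param x numeric values, or a named list of per-group numeric vectors.
#' @param group grouping factor (ignored when `x` is a list).
#' @return object of class `rc_anova`: `F`, `p`, `MSE`, `df_between`,
#'   `df_error`, `group_means`, `group_sd`, `group_n`.
#' @export
one_way_anova <- function(x, group = NULL) {
  g <- as_property_groups(x, group)
  if (all(tapply(g$values, g$group, stats::var) == 0) &&
      length(unique(tapply(g$values, g$group, mean))) == 1L) {
    stop_input("degenerate input: all groups identical with zero variance")
  }
  fit <- aov(values ~ group, data = data.frame(values = g$values, group = g$group))
  tab <- anova(fit)
  structure(list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1],
                 MSE = tab$`Mean Sq`[2],
                 df_between = tab$Df[1], df_error = tab$Df[2],
                 group_means = c(tapply(g$values, g$group, mean)),
                 group_sd = c(tapply(g$values, g$group, sd)),
                 group_n = as.integer(table(g$group))),
            class = "rc_anova")
}

# Compact letter display for means sorted in descending order, given the
# k x k logical nonsignificance matrix over sorted positions. Because
# multiple-range nonsignificance is contiguous over sorted means, letters are
# the maximal nonsignificant intervals (insert step); intervals contained in
# a larger one are dropped (absorb step).
letters_from_nonsig <- function(nonsig) {
  k <- nrow(nonsig)
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && nonsig[i, j + 1L]) j <- j + 1L
    intervals[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) {
    for (b in seq_along(intervals)) {
      if (a != b && keep[a] &&
          intervals[[b]][1] <= intervals[[a]][1] &&
          intervals[[a]][2] <= intervals[[b]][2] &&
          !identical(intervals[[a]], intervals[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  intervals <- unique(intervals[keep])
  intervals <- intervals[order(vapply(intervals, `[`, numeric(1), 1))]
  lab <- character(k)
  for (m in seq_along(intervals)) {
    span <- intervals[[m]][1]:intervals[[m]][2]
    lab[span] <- paste0(lab[span], letters[m])
  }
  lab
}

#' Duncan's multiple range test
#'
#' Post-hoc comparison of group means after a one-way ANOVA. Means are sorted
#' in descending order; for a span of `p` consecutive sorted means the least
#' significant range is `R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h)` with
#' the protection level `alpha_p = 1 - (1 - alpha)^(p - 1)` (studentized-range
#' quantiles from [stats::qtukey()]) and `n_h` the harmonic mean group size.
#' Two means differ when their gap exceeds the range of their span and they
#' are not enclosed by a wider nonsignificant range; groups not separated
#' share a compact-display letter (a = highest mean).
#'
#' @param x numeric values or a named list of per-group vectors.
#' @param group grouping factor.
#' @param alpha significance level (default 0.05).
#' @param n_eff optional effective per-group sample size. Measurement
#'   protocols that pool replicate assays (e.g. quality assays run as three
#'   independent determinations per stage) can make the effective replication
#'   smaller than the number of records; when given, `n_h = n_eff` and the
#'   error degrees of freedom become `k (n_eff - 1)`.
#' @return object of class `rc_duncan`: `anova`, sorted `means`/`sd`/`n`,
#'   `ranges` (`R_p` for p = 2..k), `nonsig` matrix, `letters` (named by
#'   group), `alpha`, `df`, `n_h`.
#' @export
duncan_mrt <- function(x, group = NULL, alpha = 0.05, n_eff = NULL) {
  an <- one_way_anova(x, group)
  k <- length(an$group_means)
  if (k < 2L) stop_input("Duncan's test needs at least two groups")
  if (is.null(n_eff)) {
    n_h <- k / sum(1 / an$group_n)
    df <- an$df_error
  } else {
    assert_scalar_number(n_eff, "n_eff", 2)
    n_h <- n_eff
    df <- k * (n_eff - 1)
  }
  se <- sqrt(an$MSE / n_h)
  spans <- 2:k
  ranges <- qtukey((1 - alpha)^(spans - 1), spans, df) * se
  names(ranges) <- paste0("R", spans)

  ord <- order(an$group_means, decreasing = TRUE)
  m_sorted <- an$group_means[ord]
  nonsig <- diag(TRUE, k)
  # widest spans first; a nonsignificant range shields everything inside it
  shielded <- matrix(FALSE, k, k)
  for (p in rev(spans)) {
    for (i in seq_len(k - p + 1L)) {
      j <- i + p - 1L
      if (shielded[i, j] || (m_sorted[i] - m_sorted[j]) <= ranges[[paste0("R", p)]]) {
        nonsig[i, j] <- nonsig[j, i] <- TRUE
        for (a in i:j) for (b in a:j) shielded[a, b] <- TRUE
      }
    }
  }
  lab_sorted <- letters_from_nonsig(nonsig)
  letters_by_group <- stats::setNames(character(k), names(an$group_means))
  letters_by_group[names(m_sorted)] <- lab_sorted
  structure(list(anova = an,
                 means = m_sorted,
                 sd = an$group_sd[ord], n = an$group_n[ord],
                 ranges = ranges, nonsig = nonsig,
                 letters = letters_by_group,
                 alpha = alpha, df = df, n_h = n_h),
            class = "rc_duncan")
}

#' @export
print.rc_duncan <- function(x, ...) {
  cat(sprintf("Duncan's multiple range test (alpha = %g, df = %g, n_h = %.3g)\n",
              x$alpha, x$df, x$n_h))
  cat(sprintf("ANOVA F = %.4g, p = %.3g, MSE = %.4g\n", x$anova$F, x$anova$p,
              x$anova$MSE))
  for (g in names(x$means)) {
    cat(sprintf("  %-10s %8.3f +- %.3f  %s\n", g, x$means[[g]],
                x$sd[[g]], x$letters[[g]]))
  }
  invisible(x)
}

# Measurement columns understood by conjoint_report, with display names.
conjoint_properties <- function() {
  c(transverse_diameter_mm = "Transverse diameter (mm)",
    vertical_diameter_mm = "Vertical diameter (mm)",
    dry_seed_weight_g = "Dry seed weight (g)",
    moisture_pct = "Moisture content (%)",
    oil_pct = "Seed oil content (%)",
    soluble_protein_pct = "Seed-soluble protein content (%)",
    soluble_sugar_pct = "Seed-soluble sugar content (%)",
    starch_pct = "Seed starch content (%)")
}

#' Conjoint property analysis across maturity stages
#'
#' Runs one-way ANOVA plus Duncan's multiple range test per physical/quality
#' property against the stage labels (from clustering or truth), and formats
#' stage means as `mean ± SD letter` in the conventional conjoint-table
#' layout. Properties with fewer than two records in any stage are flagged
#' and skipped. Missing `moisture_pct` is derived from the seed weights.
#'
#' @param records data.frame of per-sample property records (see
#'   [generate_property_table()] for the column schema).
#' @param stage_labels stage per record; defaults to `records$stage`.
#' @param properties character vector of property columns to analyze
#'   (default: all known measurement columns present).
#' @param alpha significance level.
#' @param n_eff effective per-group n passed to [duncan_mrt()].
#' @return object of class `rc_conjoint`: `table` (long data.frame with
#'   property, stage, n, mean, sd, letter, label), `results` (named list of
#'   `rc_duncan`), `flagged` (skipped properties).
#' @export
conjoint_report <- function(records, stage_labels = NULL, properties = NULL,
                            alpha = 0.05, n_eff = NULL) {
  stage_labels <- stage_labels %||% records$stage
  if (is.null(stage_labels) || length(stage_labels) != nrow(records)) {
    stop_input("every record needs a stage label")
  }
  stage_labels <- as.character(stage_labels)
  lev <- if (all(stage_labels %in% MATURITY_STAGES)) {
    intersect(MATURITY_STAGES, stage_labels)
  } else unique(stage_labels)
  stage <- factor(stage_labels, levels = lev)
  if (!("moisture_pct" %in% names(records)) &&
      all(c("fresh_seed_weight_g", "dry_seed_weight_g") %in% names(records))) {
    records$moisture_pct <- moisture_content(records$fresh_seed_weight_g,
                                             records$dry_seed_weight_g)
  }
  properties <- properties %||% intersect(names(conjoint_properties()), names(records))
  if (length(properties) == 0L) stop_input("no property columns found")
  results <- list()
  flagged <- character(0)
  rows <- list()
  for (prop in properties) {
    vals <- records[[prop]]
    ok <- !is.na(vals)
    if (any(tapply(ok, stage, sum, default = 0L) < 2L)) {
      flagged <- c(flagged, prop)
      next
    }
    dr <- duncan_mrt(vals[ok], stage[ok], alpha = alpha, n_eff = n_eff)
    results[[prop]] <- dr
    rows[[prop]] <- data.frame(
      property = prop, stage = lev,
      n = as.integer(table(stage[ok])),
      mean = as.numeric(dr$anova$group_means[lev]),
      sd = as.numeric(dr$anova$group_sd[lev]),
      letter = as.character(dr$letters[lev]),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) {
    tab$label <- sprintf("%.2f ± %.2f %s", tab$mean, tab$sd, tab$letter)
    rownames(tab) <- NULL
  }
  structure(list(table = tab, results = results, flagged = flagged,
                 alpha = alpha, n_eff = n_eff),
            class = "rc_conjoint")
}

#' @export
print.rc_conjoint <- function(x, ...) {
  if (is.null(x$table)) { cat("<rc_conjoint: nothing computed>\n"); return(invisible(x)) }
  disp <- conjoint_properties()
  stages <- unique(x$table$stage)
  cat(sprintf("%-34s %s\n", "Property", paste(sprintf("%-18s", stages), collapse = " ")))
  for (prop in unique(x$table$property)) {
    sub <- x$table[x$table$property == prop, ]
    cells <- sub$label[match(stages, sub$stage)]
    cat(sprintf("%-34s %s\n", disp[[prop]] %||% prop,
                paste(sprintf("%-18s", cells), collapse = " ")))
  }
  if (length(x$flagged)) cat("flagged (insufficient records):",
                             paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
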