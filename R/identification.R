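all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Name clusters as maturity stages
#'
#' Cluster ids coming out of K-Means are arbitrary; this maps them onto the
#' ordered stages (unripe, ripe, overripe) using one of two kinds of evidence:
#'
#' * `truth`: stage labels known for a subset of anchor samples (`NA`
#'   elsewhere). The stage-to-cluster bijection maximizing anchor agreement is
#'   found by exact search over permutations (the Hungarian assignment for
#'   square profit matrices at small `k`).
#' * `proxy`: a per-image scalar maturity proxy. With `proxy_type = "crack"`
#'   (crack-pixel fraction, monotone in maturity) clusters are ranked by mean
#'   proxy ascending -> unripe, ripe, overripe. With `proxy_type = "oil"`
#'   (seed oil content rises to a ripe maximum then falls) the lowest mean is
#'   unripe, the highest ripe, the middle overripe; this non-monotone
#'   ordering is flagged in the result.
#'
#' @param assignments integer cluster labels in 1..k.
#' @param truth character stage labels with `NA` for non-anchors (mode a).
#' @param proxy numeric per-image maturity proxy (mode b; requires k = 3).
#' @param proxy_type `"crack"` or `"oil"`.
#' @param stage_names ordered stage names.
#' @return list: `map` (character vector, cluster id -> stage name),
#'   `agreement` (anchor agreement rate, mode a only), `method`, `note`.
#' @export
map_clusters_to_stages <- function(assignments, truth = NULL, proxy = NULL,
                                   proxy_type = c("crack", "oil"),
                                   stage_names = MATURITY_STAGES) {
  assignments <- as.integer(assignments)
  k <- max(assignments)
  if (!is.null(truth)) {
    if (length(truth) != length(assignments)) {
      stop_input("truth must match assignments in length")
    }
    anchors <- !is.na(truth)
    if (!any(anchors)) stop_input("no anchor labels supplied")
    if (k > 8L) stop_input("exact permutation search supports k <= 8")
    tab <- table(factor(assignments[anchors], levels = seq_len(k)),
                 factor(truth[anchors], levels = stage_names))
    best <- NULL; best_hits <- -1
    for (p in all_permutations(k)) {
      hits <- sum(tab[cbind(seq_len(k), p)])
      if (hits > best_hits) { best_hits <- hits; best <- p }
    }
    map <- stage_names[best]
    return(list(map = map, agreement = best_hits / sum(anchors),
                method = "anchor", note = NULL))
  }
  if (is.null(proxy)) stop_input("supply either truth anchors or a maturity proxy")
  proxy_type <- match.arg(proxy_type)
  if (k != 3L) stop_input("proxy-based naming requires exactly 3 clusters")
  if (length(proxy) != length(assignments)) {
    stop_input("proxy must match assignments in length")
  }
  means <- tapply(proxy, factor(assignments, levels = 1:3), mean)
  if (any(is.na(means))) stop_input("every cluster needs at least one proxy value")
  ord <- order(means)  # cluster ids, ascending proxy
  map <- character(3)
  note <- NULL
  if (proxy_type == "crack") {
    map[ord] <- stage_names
  } else {
    # oil: low -> unripe, high -> ripe, middle -> overripe
    map[ord[1]] <- stage_names[1]
    map[ord[3]] <- stage_names[2]
    map[ord[2]] <- stage_names[3]
    note <- "oil proxy uses the non-monotone low->high->mid stage ordering"
  }
  list(map = map, agreement = NA_real_, method = paste0("proxy_", proxy_type),
       note = note)
}

#' Build a confusion matrix
#'
#' @param true_stages,predicted_stages equal-length label vectors; values must
#'   belong to `stage_names`.
#' @param stage_names ordered class labels (defaults to the three maturity
#'   stages when the data uses them, otherwise the sorted unique labels).
#' @return `k x k` integer matrix of class `rc_confusion`; rows are true
#'   classes, columns predictions.
#' @export
build_confusion <- function(true_stages, predicted_stages, stage_names = NULL) {
  if (length(true_stages) != length(predicted_stages)) {
    stop_input("label vectors differ in length")
  }
  labs <- unique(c(as.character(true_stages), as.character(predicted_stages)))
  if (is.null(stage_names)) {
    stage_names <- if (all(labs %in% MATURITY_STAGES)) MATURITY_STAGES else sort(labs)
  }
  if (!all(labs %in% stage_names)) {
    stop_input(sprintf("unknown label(s): %s",
                       paste(setdiff(labs, stage_names), collapse = ", ")))
  }
  cm <- table(factor(true_stages, levels = stage_names),
              factor(predicted_stages, levels = stage_names))
  cm <- unclass(as.matrix(cm))
  dimnames(cm) <- list(true = stage_names, predicted = stage_names)
  structure(cm, class = c("rc_confusion", class(cm)))
}

#' Confusion matrix from printed counts
#'
#' Convenience constructor when only the counts are available (e.g. a reported
#' confusion matrix): rows are true classes in `stage_names` order.
#'
#' @param counts `k x k` matrix or row-major vector of counts.
#' @param stage_names ordered class labels.
#' @return `rc_confusion` matrix.
#' @export
confusion_from_counts <- function(counts, stage_names = MATURITY_STAGES) {
  k <- length(stage_names)
  cm <- matrix(as.integer(counts), k, k, byrow = !is.matrix(counts))
  if (any(cm < 0)) stop_input("counts must be non-negative")
  dimnames(cm) <- list(true = stage_names, predicted = stage_names)
  structure(cm, class = c("rc_confusion", class(cm)))
}

#' Precision, recall, F1, and overall accuracy from a confusion matrix
#'
#' One-vs-rest per class: `Prec = TP / (TP + FP)`, `Rec = TP / (TP + FN)`,
#' `F1 = 2 Prec Rec / (Prec + Rec)`, all in percent. Overall accuracy is the
#' diagonal sum over the total count; in the one-vs-rest reading of
#' `(TP + TN) / (TP + FP + FN + TN)` this equals the micro-averaged recall,
#' and both reduce to correct/total. A class never predicted has undefined
#' precision, reported as `NA` with `undefined_precision` listing the class.
#'
#' @param cm an `rc_confusion` (or plain k x k count matrix with at least one
#'   sample per true class).
#' @return object of class `rc_metrics`: `per_stage` data.frame (stage,
#'   precision, recall, f1, support), `overall_accuracy`, `n_correct`, `n`,
#'   `undefined_precision`. Values are kept in full precision; printing
#'   rounds half-up to 2 decimals.
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(unclass(cm))
  if (nrow(cm) != ncol(cm) || sum(cm) == 0) stop_input("empty or non-square confusion matrix")
  if (any(rowSums(cm) == 0)) stop_input("every true class needs at least one sample")
  stages <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  rec <- 100 * tp / (tp + fn)
  f1 <- ifelse(!is.na(prec) & prec + rec > 0, 2 * prec * rec / (prec + rec), NA_real_)
  structure(list(
    per_stage = data.frame(stage = stages, precision = prec, recall = rec,
                           f1 = f1, support = rowSums(cm), row.names = NULL),
    overall_accuracy = 100 * sum(tp) / sum(cm),
    n_correct = sum(tp), n = sum(cm),
    undefined_precision = stages[is.na(prec)]
  ), class = "rc_metrics")
}

#' @export
print.rc_metrics <- function(x, ...) {
  tab <- x$per_stage
  cat(sprintf("Maturity identification: %d/%d correct, overall accuracy %.2f%%\n",
              x$n_correct, x$n, round_half_up(x$overall_accuracy)))
  cat(sprintf("%-10s %10s %10s %10s\n", "Maturity", "Prec (%)", "Rec (%)", "F1 (%)"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-10s %10.2f %10.2f %10.2f\n", tab$stage[i],
                round_half_up(tab$precision[i]), round_half_up(tab$recall[i]),
                round_half_up(tab$f1[i])))
  }
  if (length(x$undefined_precision)) {
    cat("undefined precision for:", paste(x$undefined_precision, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Seed moisture content from fresh and dry weight
#'
#' `M_c = 100 (W_f - W_d) / W_f`, the weight fraction lost on drying.
#'
#' @param W_f fresh seed weight in grams (`> 0`).
#' @param W_d dry seed weight in grams (`0 < W_d <= W_f`).
#' @return moisture content in percent. Vectorized.
#' @export
moisture_content <- function(W_f, W_d) {
  if (any(W_f <= 0) || any(W_d <= 0)) stop_input("weights must be positive")
  if (any(W_d > W_f)) stop_input("dry weight cannot exceed fresh weight")
  100 * (W_f - W_d) / W_f
}
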