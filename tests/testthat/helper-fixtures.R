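# Shared fixtures, built in code.

# Two well-separated Gaussian blobs in d dimensions.
make_blobs <- function(n_per, d = 2, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    rbind(matrix(rnorm(n_per * d), n_per, d),
          matrix(rnorm(n_per * d, mean = sep), n_per, d))
  })
}

# The reported testing-set confusion counts (rows = true unripe/ripe/overripe).
testing_set_confusion <- function() {
  confusion_from_counts(c(48, 2, 0,
                          3, 52, 5,
                          0, 4, 46))
}

# Independent NMI oracle: direct plug-in formula over the contingency table,
# written as an explicit double loop (no shared code with the package).
nmi_oracle <- function(a, b) {
  ta <- table(a); tb <- table(b); n <- length(a)
  ha <- -sum((ta / n) * log(ta / n))
  hb <- -sum((tb / n) * log(tb / n))
  mi <- 0
  for (u in names(ta)) for (v in names(tb)) {
    nij <- sum(a == u & b == v)
    if (nij > 0) mi <- mi + (nij / n) * log((nij * n) / (ta[[u]] * tb[[v]]))
  }
  mi / sqrt(ha * hb)
}

# Exhaustive best k=2 partition objective (mean within-cluster squared
# distance to the cluster mean), enumerating all 2^n labelings.
brute_force_k2_objective <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- as.integer(intToBits(code))[seq_len(n)] + 1L
    if (length(unique(lab)) < 2L) next
    obj <- 0
    for (g in unique(lab)) {
      S <- X[lab == g, , drop = FALSE]
      obj <- obj + sum(sweep(S, 2, colMeans(S))^2)
    }
    best <- min(best, obj / n)
  }
  best
}

# Phenotypes in which only the crack/seed signal differs between stages.
crack_only_phenotypes <- function() {
  list(unripe   = stage_phenotype("unripe",   65, 4, 0.15, 0,    0),
       ripe     = stage_phenotype("ripe",     65, 4, 0.15, 0.08, 0.03),
       overripe = stage_phenotype("overripe", 65, 4, 0.15, 0.20, 0.10))
}

stage_accuracy <- function(assignments, truth) {
  map_clusters_to_stages(assignments, truth = truth)$agreement
}
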