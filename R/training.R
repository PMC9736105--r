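#' Training configuration for the pseudo-label loop
#'
#' @param learning_rate SGD learning rate (default 0.1, as used for the fruit
#'   maturity model).
#' @param momentum SGD momentum (default 0.9).
#' @param epochs number of alternating rounds (clustering + one training pass).
#' @param batch_size mini-batch size.
#' @param reassign_every epochs between clustering rounds (default 1: new
#'   pseudo-labels every epoch).
#' @param uniform_label_sampling sample mini-batches uniformly over
#'   pseudo-labels, preventing a large cluster from dominating the gradient
#'   and collapsing training into a single class (default on).
#' @param clip_grad_norm cap on the global gradient L2 norm per mini-batch
#'   (default 1). At learning rate 0.1 with momentum 0.9 the raw cross-entropy
#'   gradients of wide fully connected layers can exceed the weight norm
#'   itself, killing ReLU units and collapsing the representation; clipping
#'   keeps each step a small fraction of the parameter scale. `Inf` disables.
#' @param rng_seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, momentum = 0.9, epochs = 20,
                         batch_size = 32, reassign_every = 1,
                         uniform_label_sampling = TRUE, clip_grad_norm = 1,
                         rng_seed = 1) {
  assert_scalar_number(learning_rate, "learning_rate", lower = 0)
  assert_scalar_number(momentum, "momentum", 0, 1)
  assert_scalar_number(epochs, "epochs", 1)
  if (!(is.numeric(clip_grad_norm) && length(clip_grad_norm) == 1L &&
        clip_grad_norm > 0)) {
    stop_input("clip_grad_norm must be a positive number (Inf to disable)")
  }
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 reassign_every = as.integer(reassign_every),
                 uniform_label_sampling = isTRUE(uniform_label_sampling),
                 clip_grad_norm = clip_grad_norm,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Create a fresh classifier head
#'
#' The head is the last fully connected layer mapping penultimate-FC features
#' to `k` class logits; it is reinitialized after every cluster reassignment
#' (pseudo-label identities change between rounds, so stale logit bindings
#' would corrupt learning).
#'
#' @param feature_dim input feature dimension.
#' @param k number of classes (clusters).
#' @param init_seed seed for the random initialization.
#' @return list with weight matrix `W` (`k x feature_dim`) and bias `b`.
#' @export
new_classifier_head <- function(feature_dim, k, init_seed = NULL) {
  with_rng_seed(init_seed, {
    list(W = matrix(rnorm(k * feature_dim, 0, sqrt(1 / feature_dim)), k, feature_dim),
         b = numeric(k), k = as.integer(k))
  })
}

softmax_rows <- function(logits) {
  m <- apply(logits, 1L, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

#' Mean negative log-softmax loss on pseudo-labels
#'
#' @param logits `N x k` matrix of class scores.
#' @param labels integer labels in 1..k.
#' @return mean over samples of `-log softmax(logits)[label]`.
#' @export
pseudo_label_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  if (any(!is.finite(logits))) stop_input("non-finite logits")
  labels <- as.integer(labels)
  if (length(labels) != nrow(logits)) stop_input("labels do not match logits rows")
  if (any(labels < 1L | labels > ncol(logits))) stop_input("labels out of range")
  m <- apply(logits, 1L, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_len(nrow(logits)), labels)])
}

# One epoch of mini-batch SGD with momentum on the FC layers + head, given
# precomputed conv features (rows = samples). Returns updated parameters,
# momentum state, and the mean running loss.
sgd_epoch <- function(fc, head, conv_feats, labels, config, state = NULL,
                      epoch_seed = NULL) {
  n <- nrow(conv_feats)
  k <- head$k
  if (is.null(state)) {
    state <- list(fc = lapply(fc, function(l) list(W = 0 * l$W, b = 0 * l$b,
                                                   gamma = 0 * l$gamma,
                                                   beta = 0 * l$beta)),
                  head = list(W = 0 * head$W, b = 0 * head$b))
  }
  order_idx <- with_rng_seed(epoch_seed, {
    if (config$uniform_label_sampling) {
      cls <- sample(rep_len(seq_len(k), n))                  # balanced class slots
      pools <- split(seq_len(n), factor(labels, levels = seq_len(k)))
      vapply(cls, function(cl) {
        pool <- pools[[cl]]
        if (length(pool) == 0L) sample.int(n, 1L)
        else pool[sample.int(length(pool), 1L)]
      }, integer(1))
    } else {
      sample.int(n)
    }
  })
  lr <- config$learning_rate
  mom <- config$momentum
  losses <- numeric(0)
  for (start in seq(1L, n, by = config$batch_size)) {
    sel <- order_idx[start:min(n, start + config$batch_size - 1L)]
    X <- conv_feats[sel, , drop = FALSE]
    y <- labels[sel]
    m <- length(sel)
    fwd <- fc_forward(fc, X, keep_cache = TRUE, training = m > 1L)
    fc <- fwd$fc  # running BN statistics advance with each batch
    logits <- sweep(fwd$out %*% t(head$W), 2L, head$b, `+`)
    losses <- c(losses, pseudo_label_loss(logits, y))
    P <- softmax_rows(logits)
    Y <- matrix(0, m, k); Y[cbind(seq_len(m), y)] <- 1
    dlogits <- (P - Y) / m
    gW_head <- t(dlogits) %*% fwd$out
    gb_head <- colSums(dlogits)
    dA <- dlogits %*% head$W
    grads <- vector("list", length(fc))
    for (j in rev(seq_along(fc))) {
      dS <- dA * (fwd$ss[[j]] > 0)
      xhat <- fwd$xhats[[j]]
      g_gamma <- colSums(dS * xhat)
      g_beta <- colSums(dS)
      dxhat <- sweep(dS, 2L, fc[[j]]$gamma, `*`)
      inv_sd <- 1 / sqrt(fwd$vars[[j]] + BN_EPS)
      if (m > 1L) {
        dZ <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dxhat), byrow = TRUE) -
                      xhat * matrix(colMeans(dxhat * xhat), m, ncol(dxhat),
                                    byrow = TRUE),
                    2L, inv_sd, `*`)
      } else {
        dZ <- sweep(dxhat, 2L, inv_sd, `*`)  # eval-mode stats for a lone sample
      }
      grads[[j]] <- list(W = t(dZ) %*% fwd$acts[[j]], b = colSums(dZ),
                         gamma = g_gamma, beta = g_beta)
      if (j > 1L) dA <- dZ %*% fc[[j]]$W
    }
    clip <- config$clip_grad_norm %||% Inf
    if (is.finite(clip)) {
      gnorm <- sqrt(sum(gW_head^2) + sum(gb_head^2) +
                      sum(vapply(grads, function(g)
                        sum(g$W^2) + sum(g$b^2) + sum(g$gamma^2) + sum(g$beta^2),
                        numeric(1))))
      if (gnorm > clip) {
        sc <- clip / gnorm
        gW_head <- gW_head * sc; gb_head <- gb_head * sc
        grads <- lapply(grads, function(g)
          list(W = g$W * sc, b = g$b * sc, gamma = g$gamma * sc,
               beta = g$beta * sc))
      }
    }
    state$head$W <- mom * state$head$W + gW_head
    state$head$b <- mom * state$head$b + gb_head
    head$W <- head$W - lr * state$head$W
    head$b <- head$b - lr * state$head$b
    for (j in seq_along(fc)) {
      for (par in c("W", "b", "gamma", "beta")) {
        state$fc[[j]][[par]] <- mom * state$fc[[j]][[par]] + grads[[j]][[par]]
        fc[[j]][[par]] <- fc[[j]][[par]] - lr * state$fc[[j]][[par]]
      }
    }
    if (!all(is.finite(head$W)) || !all(is.finite(losses))) {
      stop_input("training diverged (non-finite parameters or loss)")
    }
  }
  list(fc = fc, head = head, state = state, loss = mean(losses))
}

#' One training epoch on pseudo-labels
#'
#' Runs one pass of mini-batch SGD with momentum over the images, updating the
#' fully connected layers of the backbone and the classifier head under the
#' mean negative log-softmax objective. The convolutional filters stay at
#' their random initialization (random conv features are a strong image
#' representation; the fully connected stage is where the pseudo-label signal
#' is absorbed). Deterministic for a fixed seed.
#'
#' @param backbone an `rc_backbone`.
#' @param head a [new_classifier_head()] (or `NULL` to create one).
#' @param images list of images (alternatively supply `conv_features`).
#' @param pseudo_labels integer cluster assignments in 1..k, one per image.
#' @param config a [train_config()].
#' @param conv_features optional precomputed `N x flat_dim` conv-feature
#'   matrix (skips the conv forward pass).
#' @param state momentum state carried between epochs (`NULL` to start fresh).
#' @param epoch_seed seed for this epoch's batch sampling.
#' @return list: updated `backbone`, `head`, `state`, and mean `loss`.
#' @export
train_epoch <- function(backbone, head, images, pseudo_labels, config,
                        conv_features = NULL, state = NULL, epoch_seed = NULL) {
  stopifnot(inherits(backbone, "rc_backbone"), inherits(config, "train_config"))
  if (is.null(conv_features)) conv_features <- extract_conv_features(backbone, images)
  pseudo_labels <- as.integer(pseudo_labels)
  if (length(pseudo_labels) != nrow(conv_features)) {
    stop_input("pseudo_labels must match the number of images")
  }
  if (is.null(head)) {
    head <- new_classifier_head(backbone$config$feature_dim, max(pseudo_labels),
                                init_seed = epoch_seed)
  }
  res <- sgd_epoch(backbone$fc, head, conv_features, pseudo_labels, config,
                   state = state, epoch_seed = epoch_seed)
  backbone$fc <- res$fc
  list(backbone = backbone, head = res$head, state = res$state, loss = res$loss)
}

#' Run the alternating clustering / pseudo-label training loop
#'
#' Per round: extract penultimate-FC features under the current weights, fit
#' and apply PCA, L2-normalize, cluster with K-Means, reinitialize the
#' classifier head, and train the fully connected layers one epoch on the
#' cluster assignments as pseudo-labels. The loop records, per round, the
#' training loss, clustering objective, NMI between consecutive rounds'
#' assignments, and cluster sizes. Fully seeded: two runs with the same
#' configuration and seed give identical histories.
#'
#' @param images list of at least `k` images of uniform size.
#' @param backbone_config a [backbone_config()].
#' @param reduction_config list with `n_components` and `whiten`.
#' @param k number of maturity clusters (default 3).
#' @param config a [train_config()]; `epochs` is the number of rounds.
#' @param n_restarts K-Means restarts per round.
#' @return object of class `rc_model`: `backbone`, `head`, `reduction` (last
#'   fit), `clustering` (final round), `history` (one row per round),
#'   `projection` (first two PCA coordinates of the final features), `k`,
#'   and a `stage_map` slot (filled by [map_clusters_to_stages()]).
#' @export
run_deepcluster <- function(images, backbone_config = NULL,
                            reduction_config = list(n_components = NULL,
                                                    whiten = FALSE),
                            k = 3, config = train_config(),
                            n_restarts = 5) {
  if (length(images) < k) stop_input("need at least k images")
  backbone_config <- backbone_config %||%
    backbone_config()
  backbone <- build_backbone(backbone_config)
  conv_feats <- extract_conv_features(backbone, images)
  prev_assign <- NULL
  history <- list()
  state <- NULL
  head <- NULL
  clustering <- NULL
  reduction <- NULL
  reduced <- NULL
  for (round in seq_len(config$epochs)) {
    feats <- fc_forward(backbone$fc, conv_feats)
    if ((round - 1L) %% config$reassign_every == 0L) {
      reduction <- fit_reduction(feats,
                                 n_components = reduction_config$n_components,
                                 whiten = isTRUE(reduction_config$whiten))
      reduced <- l2_normalize(apply_reduction(reduction, feats))
      clustering <- kmeans_fit(reduced, k = k, n_restarts = n_restarts,
                               rng_seed = derive_seed(config$rng_seed, round, 1L))
      head <- new_classifier_head(backbone$config$feature_dim, k,
                                  init_seed = derive_seed(config$rng_seed, round, 2L))
      state <- NULL
    }
    nmi <- if (is.null(prev_assign)) NA_real_ else
      clustering_agreement(prev_assign, clustering$assignments)
    prev_assign <- clustering$assignments
    res <- sgd_epoch(backbone$fc, head, conv_feats, clustering$assignments,
                     config, state = state,
                     epoch_seed = derive_seed(config$rng_seed, round, 3L))
    backbone$fc <- res$fc
    head <- res$head
    state <- res$state
    history[[round]] <- data.frame(
      round = round, loss = res$loss, objective = clustering$objective,
      nmi_prev = nmi,
      t(stats::setNames(clustering$sizes, paste0("size_", seq_len(k)))))
  }
  projection <- apply_reduction(reduction, fc_forward(backbone$fc, conv_feats))
  projection <- projection[, seq_len(min(2L, ncol(projection))), drop = FALSE]
  structure(list(backbone = backbone, head = head, reduction = reduction,
                 clustering = clustering,
                 history = do.call(rbind, history),
                 projection = projection,
                 ids = image_ids(images), k = as.integer(k),
                 config = config, stage_map = NULL),
            class = "rc_model")
}

#' @export
print.rc_model <- function(x, ...) {
  cat(sprintf("<rc_model k=%d rounds=%d final objective=%.5g final loss=%.4f>\n",
              x$k, nrow(x$history), x$clustering$objective,
              x$history$loss[nrow(x$history)]))
  if (!is.null(x$stage_map)) {
    cat("stage map:", paste(sprintf("%d->%s", seq_along(x$stage_map), x$stage_map),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Identify maturity of images with a trained model
#'
#' Predicts the cluster (or, if the model carries a stage naming, the
#' maturity stage) of each image as the argmax of the classifier-head logits.
#' Deterministic; softmax probabilities are attached as an attribute.
#'
#' @param model an `rc_model` from [run_deepcluster()].
#' @param images list of images.
#' @return integer cluster labels (1..k), or a character vector of stage names
#'   when `model$stage_map` is set; softmax probabilities in
#'   `attr(, "probabilities")`.
#' @export
identify_maturity <- function(model, images) {
  if (!inherits(model, "rc_model") || is.null(model$head)) {
    stop_input("model is not a trained rc_model")
  }
  conv_feats <- extract_conv_features(model$backbone, images)
  feats <- fc_forward(model$backbone$fc, conv_feats)
  logits <- sweep(feats %*% t(model$head$W), 2L, model$head$b, `+`)
  labels <- max.col(logits, ties.method = "first")
  probs <- softmax_rows(logits)
  out <- if (!is.null(model$stage_map)) model$stage_map[labels] else labels
  attr(out, "probabilities") <- probs
  out
}
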