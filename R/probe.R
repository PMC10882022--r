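#' Area under the ROC curve (rank formula)
#'
#' Computes AUROC by the Mann-Whitney rank statistic with midrank tie
#' correction: `AUC = (sum of positive ranks - n1(n1+1)/2) / (n1 * n0)`.
#' Invariant to any strictly monotone transform of the scores.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUROC in `[0, 1]`; `NA` if only one class is present.
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))  # 1
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    abort_enctsf("scores and labels must have equal length", "enctsf_validation_error")
  }
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Probe a trained model's embedding for a latent attribute
#'
#' Quantifies latent-information leakage: a single dense (linear) layer
#' with sigmoid output -- no hidden layers, no further feature
#' transformations -- is trained to predict a non-targeted attribute from
#' the frozen penultimate embeddings of a trained model, using binary
#' cross-entropy, Adam at learning rate 0.001 and batch size 256, with the
#' best-on-validation parameters retained. Only training-split embeddings
#' are used for fitting; AUROC is reported on the held-out test split.
#' Binary attributes give a single AUROC; multiclass attributes are probed
#' one-vs-rest with one linear layer per class and reported as macro AUROC
#' (unweighted mean).
#'
#' @param model An `embedding_model`.
#' @param ds The `cohort` the model was trained on (original or encoded).
#' @param attribute Name of a column of `ds$attributes`.
#' @param seed Integer seed.
#' @param epochs Probe training epochs, default 100 (probes are a single
#'   linear layer on a low-dimensional embedding, so epochs are cheap and
#'   the fixed learning rate needs enough steps to converge; the retained
#'   parameters are the validation-best ones regardless).
#' @param batch_size,lr Training contract; defaults 256 and 0.001.
#' @return An object of class `probe_result`: list with `attribute`,
#'   `auroc` (macro for multiclass), `per_class`, `n_train`, `n_test`,
#'   `seed`.
#' @export
probe_latent <- function(model, ds, attribute, seed = 1, epochs = 100,
                         batch_size = 256, lr = 0.001) {
  stopifnot(inherits(model, "embedding_model"), inherits(ds, "cohort"))
  if (!attribute %in% names(ds$attributes)) {
    abort_enctsf(sprintf("attribute '%s' not present in cohort (have: %s)",
                         attribute, paste(names(ds$attributes), collapse = ", ")),
                 "enctsf_validation_error")
  }
  a <- ds$attributes[[attribute]]
  tr <- ds$split == "train"; va <- ds$split == "validation"; te <- ds$split == "test"
  E <- embed(model, ds)
  sdv <- apply(E[tr, , drop = FALSE], 2, stats::sd)
  if (all(sdv == 0 | !is.finite(sdv))) {
    warning("embeddings are constant across training examples; probe AUROC set to 0.5")
    return(structure(list(attribute = attribute, auroc = 0.5, per_class = NULL,
                          n_train = sum(tr), n_test = sum(te), seed = as.integer(seed)),
                     class = "probe_result"))
  }
  mu <- colMeans(E[tr, , drop = FALSE])
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Es <- sweep(sweep(E, 2, mu, "-"), 2, sdv, "/")
  classes <- sort(unique(a))
  targets <- if (length(classes) == 2) max(classes) else classes
  per_class <- vapply(targets, function(cl) {
    y <- as.integer(a == cl)
    if (length(unique(y[tr])) < 2) return(NA_real_)
    fit <- fit_dense(Es[tr, , drop = FALSE], y[tr], Es[va, , drop = FALSE], y[va],
                     hidden = 0L, epochs = epochs, batch_size = batch_size,
                     lr = lr, seed = derive_seed(seed, as.integer(cl) + 1L))
    auroc(dense_forward(fit$params, Es[te, , drop = FALSE], 0L)$score, y[te])
  }, numeric(1))
  names(per_class) <- paste0("class", targets)
  structure(list(attribute = attribute,
                 auroc = mean(per_class, na.rm = TRUE),
                 per_class = per_class,
                 n_train = sum(tr), n_test = sum(te), seed = as.integer(seed)),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe_result '%s': AUROC %.3f (train n=%d, test n=%d)>\n",
              x$attribute, x$auroc, x$n_train, x$n_test))
  invisible(x)
}
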