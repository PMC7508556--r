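# Discriminant-based sex assignment from pelvic shape variables, with a
# posterior-probability acceptance threshold and split validation.

#' Fit a (regularized) linear discriminant model
#'
#' Gaussian linear discriminant with pooled within-class covariance and
#' priors proportional to class frequencies (or equal). Because 54 shape
#' variables can exceed the available class counts, the pooled covariance
#' is shrunk toward its diagonal,
#' `S* = (1 - lambda) S + lambda diag(S)`, keeping it positive-definite.
#'
#' @param x numeric matrix of predictors (e.g. pelvic Procrustes shape
#'   variables), rows = specimens.
#' @param labels class label per row (e.g. `"male"` / `"female"`); at least
#'   2 classes with at least 2 rows each.
#' @param shrinkage diagonal shrinkage coefficient `lambda` in [0, 1]
#'   (default 0.1; 0 = plain pooled covariance).
#' @param priors `"frequency"` (default) or `"equal"`.
#' @return An object of class `lda_model`: class `means`, regularized
#'   pooled `cov` and its inverse, `priors`, `classes`, training dimension
#'   `p`.
#' @export
lda_fit <- function(x, labels, shrinkage = 0.1,
                    priors = c("frequency", "equal")) {
  priors <- match.arg(priors)
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) .stopf("need at least 2 classes, got %d",
                                   length(classes))
  counts <- table(factor(labels, classes))
  if (any(counts < 2L))
    .stopf("class(es) with fewer than 2 rows: %s",
           paste(names(counts)[counts < 2L], collapse = ", "))
  p <- ncol(x)
  means <- rowsum(x, labels) / as.vector(counts)
  s <- matrix(0, p, p)
  for (cl in classes) {
    rows <- x[labels == cl, , drop = FALSE]
    dev <- sweep(rows, 2L, means[cl, ])
    s <- s + crossprod(dev)
  }
  s <- s / (nrow(x) - length(classes))
  if (shrinkage > 0) s <- (1 - shrinkage) * s + shrinkage * diag(diag(s), p)
  cov_inv <- tryCatch(chol2inv(chol(s)), error = function(e)
    .stopf("pooled covariance is singular; increase shrinkage"))
  pr <- if (priors == "equal") rep(1 / length(classes), length(classes))
        else as.vector(counts) / nrow(x)
  names(pr) <- classes
  structure(list(means = means, cov = s, cov_inv = cov_inv, priors = pr,
                 classes = classes, p = p, shrinkage = shrinkage),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("lda_model: %d classes (%s), %d predictors, shrinkage %.2f\n",
              length(x$classes), paste(x$classes, collapse = ", "), x$p,
              x$shrinkage))
  invisible(x)
}

#' Assign classes with a posterior-probability acceptance threshold
#'
#' Gaussian posteriors under the shared-covariance discriminant; an
#' assignment is accepted only when the winning posterior reaches the
#' threshold (default 0.8), otherwise the specimen stays unassigned.
#'
#' @param model an [lda_fit()] model.
#' @param x matrix of new rows, same columns as the training data.
#' @param threshold minimum posterior for acceptance (default 0.8).
#' @return data.frame with `specimen_id` (row names of `x`), `predicted`,
#'   `posterior` and `accepted`; posteriors over classes sum to 1.
#' @export
lda_assign <- function(model, x, threshold = 0.8) {
  stopifnot(inherits(model, "lda_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$p)
    .stopf("dimension mismatch: model trained on %d predictors, got %d",
           model$p, ncol(x))
  k <- length(model$classes)
  logd <- matrix(NA_real_, nrow(x), k, dimnames = list(NULL, model$classes))
  for (j in seq_len(k)) {
    dev <- sweep(x, 2L, model$means[model$classes[j], ])
    logd[, j] <- log(model$priors[j]) -
      0.5 * rowSums((dev %*% model$cov_inv) * dev)
  }
  logd <- logd - apply(logd, 1L, max)
  post <- exp(logd) / rowSums(exp(logd))
  win <- max.col(post, ties.method = "first")
  data.frame(
    specimen_id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
                  else rownames(x),
    predicted = model$classes[win],
    posterior = post[cbind(seq_len(nrow(x)), win)],
    accepted = post[cbind(seq_len(nrow(x)), win)] >= threshold,
    stringsAsFactors = FALSE)
}

#' Split validation of the discriminant sex assignment
#'
#' Stratified-by-class random split into training (default 60%) and test
#' sets; the model is fit on the training rows and accuracy is reported on
#' the test rows among accepted assignments, together with the acceptance
#' rate. If a class drops out of either split, the split is redrawn with a
#' derived seed (up to 10 attempts).
#'
#' @inheritParams lda_fit
#' @param train_fraction fraction of rows in the training set.
#' @param threshold posterior acceptance threshold.
#' @param seed integer seed.
#' @return List: `accuracy` (among accepted test assignments),
#'   `acceptance_rate`, `n_train`, `n_test`.
#' @export
split_validate <- function(x, labels, train_fraction = 0.6, threshold = 0.8,
                           seed = NULL, shrinkage = 0.1) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  for (attempt in seq_len(10L)) {
    att_seed <- if (is.null(seed)) NULL else derive_seed(seed, "split", attempt)
    train_idx <- with_seed(att_seed, {
      unlist(lapply(classes, function(cl) {
        rows <- which(labels == cl)
        sample(rows, max(1L, round(train_fraction * length(rows))))
      }))
    })
    test_idx <- setdiff(seq_len(nrow(x)), train_idx)
    ok <- all(table(factor(labels[train_idx], classes)) >= 2L) &&
      all(classes %in% labels[test_idx])
    if (ok) break
    if (attempt == 10L) .stopf("could not produce a split with all classes")
  }
  model <- lda_fit(x[train_idx, , drop = FALSE], labels[train_idx],
                   shrinkage = shrinkage)
  res <- lda_assign(model, x[test_idx, , drop = FALSE], threshold = threshold)
  acc_rows <- res$accepted
  list(accuracy = if (any(acc_rows))
         mean(res$predicted[acc_rows] == labels[test_idx][acc_rows])
       else NA_real_,
       acceptance_rate = mean(res$accepted),
       n_train = length(train_idx), n_test = length(test_idx))
}
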