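#' Stratify screen activities into high / medium / low tertile classes
#'
#' Ranks thermostability activities in descending order and assigns the top
#' `ceiling(top_fraction * n)` records to `high`, the bottom
#' `ceiling(bottom_fraction * n)` to `low`, and the remainder to `medium`.
#' Ties are broken by stable input order, so stratification never depends on
#' a seed. With the default 34 percent tails and n = 214 this gives
#' 73 high, 73 low and 68 medium.
#'
#' @param activities Numeric vector of thermostability activities (percent
#'   retained or any monotone transform thereof).
#' @param top_fraction,bottom_fraction Tail proportions; must sum to less
#'   than 1.
#' @return Factor with levels `high`, `medium`, `low` and attribute
#'   `"counts"` (named integer vector of class sizes).
#' @export
#' @examples
#' table(stratify_by_tertiles(rnorm(214)))
stratify_by_tertiles <- function(activities, top_fraction = 0.34,
                                 bottom_fraction = 0.34) {
  n <- length(activities)
  if (n < 3L) stop("need at least 3 records to stratify", call. = FALSE)
  if (any(!is.finite(activities))) stop("activities must be finite", call. = FALSE)
  if (top_fraction + bottom_fraction >= 1) {
    stop("top_fraction + bottom_fraction must be < 1", call. = FALSE)
  }
  n_high <- ceiling(top_fraction * n)
  n_low <- ceiling(bottom_fraction * n)
  # order() with method = "radix" is stable: ties keep input order
  ord <- order(-activities, method = "radix")
  labels <- rep("medium", n)
  labels[ord[seq_len(n_high)]] <- "high"
  labels[ord[n - seq_len(n_low) + 1L]] <- "low"
  out <- factor(labels, levels = c("high", "medium", "low"))
  attr(out, "counts") <- c(high = n_high, medium = n - n_high - n_low,
                           low = n_low)
  out
}

#' Lambda-selection policy for the L1 discriminators
#'
#' @param method `"cv"`: regularization strength chosen by inner k-fold
#'   cross-validated binomial deviance every time a model is fitted
#'   (including inside each leave-one-out fold); `"cv_once"`: chosen once by
#'   inner cross-validation on the full training set and then held fixed
#'   across leave-one-out folds (the default for [loocv()] — see the
#'   vignette); `"fixed"`: use the supplied `lambda`.
#' @param nfolds Inner folds for cross-validation.
#' @param lambda Regularization strength for `method = "fixed"`.
#' @param seed Seed controlling inner-fold assignment (the only randomness
#'   in fitting).
#' @return A `lambda_policy` list.
#' @export
lambda_policy <- function(method = c("cv", "cv_once", "fixed"), nfolds = 10L,
                          lambda = NULL, seed = 1L) {
  method <- match.arg(method)
  if (method == "fixed" && is.null(lambda)) {
    stop("method 'fixed' requires a lambda value", call. = FALSE)
  }
  structure(list(method = method, nfolds = as.integer(nfolds),
                 lambda = lambda, seed = as.integer(seed)),
            class = "lambda_policy")
}

# Deterministic fold assignment for cv.glmnet.
make_foldid <- function(n, nfolds, seed) {
  with_local_seed(seed, sample(rep_len(seq_len(nfolds), n)))
}

# Cross-validated lambda (minimum mean binomial deviance).
cv_lambda <- function(x, y01, policy) {
  foldid <- make_foldid(length(y01), min(policy$nfolds, length(y01)), policy$seed)
  cv <- glmnet::cv.glmnet(x, y01, family = "binomial", alpha = 1,
                          standardize = FALSE, foldid = foldid,
                          type.measure = "deviance")
  cv$lambda.min
}

#' Fit an L1-penalized logistic discriminator
#'
#' One stage of the discrimination cascade: a binary logistic model with a
#' lasso penalty, giving sparse signed weights over the 39 physicochemical
#' features and a probability for the positive class. Features are
#' standardized internally (population mean/sd scaler, stored in the model)
#' so that penalized weights are comparable across descriptor scales; the
#' penalty strength is chosen by the supplied [lambda_policy()].
#'
#' @param x Feature matrix (raw encoded features, one row per variant).
#' @param labels Class labels (character or factor), exactly two distinct
#'   values.
#' @param positive The label to model as the positive class (probability
#'   output is P(positive)).
#' @param policy A [lambda_policy()].
#' @param contrast Optional tag naming the contrast (e.g.
#'   `"improved_vs_nonimproved"`), stored in the model.
#' @return A `discrimination_model`: weights (per standardized feature),
#'   intercept, lambda, scaler, classes, and training metadata.
#' @export
fit_lasso_discriminator <- function(x, labels, positive,
                                    policy = lambda_policy("cv"),
                                    contrast = NULL) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L) {
    stop("need exactly 2 classes present, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  if (!positive %in% classes) {
    stop("positive class '", positive, "' absent from labels", call. = FALSE)
  }
  negative <- setdiff(classes, positive)
  y01 <- as.numeric(labels == positive)
  scaler <- fit_scaler(x)
  xs <- apply_scaler(x, scaler)
  lam <- switch(policy$method,
    fixed = policy$lambda,
    cv = ,
    cv_once = cv_lambda(xs, y01, policy)
  )
  fit <- glmnet::glmnet(xs, y01, family = "binomial", alpha = 1,
                        standardize = FALSE, lambda = lam)
  beta <- as.numeric(fit$beta)
  names(beta) <- colnames(x)
  structure(list(
    weights = beta,
    intercept = as.numeric(fit$a0),
    lambda = lam,
    scaler = scaler,
    positive = positive,
    negative = negative,
    contrast = contrast,
    training_meta = list(n = nrow(x), label_counts = table(labels),
                         policy = policy)
  ), class = "discrimination_model")
}

#' Predict with a discrimination model
#'
#' @param object A `discrimination_model`.
#' @param newx Raw (unstandardized) feature matrix; the model's stored
#'   scaler is applied.
#' @param type `"prob"` for P(positive class), `"class"` for labels.
#' @param ... Unused.
#' @return Numeric probabilities or character labels.
#' @export
predict.discrimination_model <- function(object, newx,
                                         type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$weights)) {
    stop(sprintf("model has %d features, newx has %d columns",
                 length(object$weights), ncol(newx)), call. = FALSE)
  }
  xs <- apply_scaler(newx, object$scaler)
  p <- plogis(object$intercept + drop(xs %*% object$weights))
  if (type == "prob") p else ifelse(p > 0.5, object$positive, object$negative)
}

#' @export
print.discrimination_model <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("discrimination_model [%s]: P(%s) vs %s\n",
              x$contrast %||% "unnamed", x$positive, x$negative))
  cat(sprintf("  n = %d, lambda = %.5g, %d/%d nonzero weights\n",
              x$training_meta$n, x$lambda, nz, length(x$weights)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out cross-validation of a discriminator
#'
#' Each variant is predicted by a model refitted on the remaining n - 1
#' records. The lambda policy governs the penalty inside folds: with the
#' default `"cv_once"` the strength is selected once on the full training
#' set and held fixed across folds; `"cv"` reruns the inner cross-validation
#' in every fold. A fold whose training set is left with fewer than two
#' members of either class (including losing a class entirely) is predicted
#' by the training majority class and flagged.
#'
#' @param x Raw feature matrix.
#' @param labels Two-class labels.
#' @param positive Positive class label.
#' @param policy A [lambda_policy()]; default `cv_once`.
#' @return A `loocv_report`: `accuracy` plus a `per_sample` data frame of
#'   held-out predictions and probabilities.
#' @export
loocv <- function(x, labels, positive, policy = lambda_policy("cv_once")) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 samples for LOOCV", call. = FALSE)
  if (length(unique(labels)) != 2L) {
    stop("need exactly 2 classes present", call. = FALSE)
  }
  negative <- setdiff(unique(labels), positive)
  fold_policy <- policy
  if (policy$method == "cv_once") {
    scaler <- fit_scaler(x)
    lam <- cv_lambda(apply_scaler(x, scaler), as.numeric(labels == positive),
                     policy)
    fold_policy <- lambda_policy("fixed", lambda = lam, seed = policy$seed)
  }
  pred <- character(n); p_pos <- numeric(n); degen <- logical(n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    # the penalized fit needs at least 2 members per class in the fold
    if (length(unique(tr_lab)) < 2L || min(table(tr_lab)) < 2L) {
      maj <- names(which.max(table(tr_lab)))
      pred[i] <- maj
      p_pos[i] <- if (maj == positive) 1 else 0
      degen[i] <- TRUE
      next
    }
    if (fold_policy$method == "cv") {
      # re-seed per fold so inner-fold assignment is deterministic but varies
      fold_policy$seed <- policy$seed + i
    }
    m <- fit_lasso_discriminator(x[-i, , drop = FALSE], tr_lab, positive,
                                 policy = fold_policy)
    p_pos[i] <- predict(m, x[i, , drop = FALSE], type = "prob")
    pred[i] <- if (p_pos[i] > 0.5) positive else negative
  }
  per_sample <- data.frame(index = seq_len(n), true = labels,
                           predicted = pred, p_positive = p_pos,
                           degenerate_fold = degen,
                           correct = pred == labels,
                           stringsAsFactors = FALSE)
  structure(list(accuracy = mean(per_sample$correct),
                 per_sample = per_sample,
                 positive = positive, policy = policy),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("loocv_report: accuracy %.3f (%d/%d correct)\n", x$accuracy,
              sum(x$per_sample$correct), nrow(x$per_sample)))
  invisible(x)
}

#' Reshape model weights into a descriptor-by-position table
#'
#' Undoes the position-major feature layout: row d, column k of the table is
#' the weight of descriptor d at mutated position k. Positive weights are
#' evidence for the model's positive class; exact zeros mark features
#' dropped by the L1 penalty.
#'
#' @param model A `discrimination_model` with `3 * length(descriptor_names)`
#'   weights.
#' @param descriptor_names Character vector of descriptor row names.
#' @param position_names Optional column names (default `pos1..pos3`).
#' @return Numeric matrix, descriptors x positions.
#' @export
extract_weight_table <- function(model, descriptor_names,
                                 position_names = c("pos1", "pos2", "pos3")) {
  w <- model$weights
  d <- length(descriptor_names)
  if (length(w) != 3L * d) {
    stop(sprintf("model has %d weights; expected %d (= 3 x %d descriptors)",
                 length(w), 3L * d, d), call. = FALSE)
  }
  matrix(w, nrow = d, ncol = 3L,
         dimnames = list(descriptor_names, position_names))
}
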