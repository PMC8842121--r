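# Predictive models of promoter activity: ordinary least squares on binary
# mutation-feature indicators (minimum-norm solution for rank-deficient
# designs) and the parameter-free additive predictor built directly from
# single-mutation effect measurements.

#' Build the binary mutation-feature design matrix
#'
#' One row per construct, one column per vocabulary feature; entry 1 iff the
#' construct's provenance names the feature. A wild type maps to an all-zero
#' row.
#'
#' @param constructs list of \code{designed_construct}, or a list of
#'   character vectors of feature labels
#' @param vocabulary ordered character vector of features; defaults to the
#'   union of observed labels
#' @return binary matrix (rownames = construct ids when available)
#' @export
featurize <- function(constructs, vocabulary = NULL) {
  feats <- lapply(constructs, function(x)
    if (inherits(x, "designed_construct")) x$provenance else as.character(x))
  if (is.null(vocabulary)) vocabulary <- sort(unique(unlist(feats)))
  unknown <- setdiff(unlist(feats), vocabulary)
  if (length(unknown))
    stop("feature(s) missing from vocabulary: ", paste(unique(unknown), collapse = ", "))
  X <- matrix(0L, nrow = length(feats), ncol = length(vocabulary),
              dimnames = list(names(constructs) %||%
                                vapply(constructs, function(x)
                                  if (inherits(x, "designed_construct")) x$id else NA_character_,
                                  character(1)),
                              vocabulary))
  for (i in seq_along(feats)) X[i, match(feats[[i]], vocabulary)] <- 1L
  X
}

#' Ordinary least squares on binary mutation indicators
#'
#' Fits y = intercept + X b by least squares; rank-deficient designs get the
#' minimum-norm solution via the SVD pseudo-inverse (p-values are NA for
#' aliased directions). Reports in-sample predictions, Pearson r and the
#' prediction band scale.
#'
#' @param X binary design matrix (no intercept column)
#' @param y log2 expression per construct
#' @param band_sd scale of the y = x +/- 3 SD band; defaults to the residual
#'   SD (pass the library sd_noise to mirror the assay's noise estimate)
#' @return object of class \code{linear_fit}: intercept, coefficients,
#'   p_values, predictions, pearson_r, band_sd, rank, residual_sd
#' @export
fit_linear <- function(X, y, band_sd = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("rows(X) must equal length(y)")
  if (n < 2L) stop("fit_linear needs at least 2 observations")
  X1 <- cbind(`(Intercept)` = 1, X)
  sv <- svd(X1)
  tol <- max(dim(X1)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  r <- sum(pos)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  pinv <- sv$v %*% (dinv * t(sv$u))
  beta <- as.numeric(pinv %*% y)
  names(beta) <- colnames(X1)
  pred <- as.numeric(X1 %*% beta)
  resid <- y - pred
  df <- n - r
  sigma2 <- if (df > 0) sum(resid^2) / df else 0
  var_beta <- sigma2 * rowSums(pinv^2)  # diag of sigma2 * pinv %*% t(pinv)
  se <- sqrt(var_beta)
  pvals <- rep(NA_real_, length(beta))
  if (df > 0) {
    ok <- se > 0
    tstat <- beta[ok] / se[ok]
    pvals[ok] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  }
  names(pvals) <- names(beta)
  pr <- if (stats::sd(pred) > 0 && stats::sd(y) > 0) stats::cor(pred, y) else NA_real_
  structure(list(intercept = beta[1], coefficients = beta[-1],
                 se = se[-1], p_values = pvals[-1],
                 predictions = pred, pearson_r = pr,
                 band_sd = band_sd %||% sqrt(sigma2),
                 rank = r, df = df, residual_sd = sqrt(sigma2),
                 full_rank = (r == ncol(X1))),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("linear fit: %d features (rank %d%s), in-sample r = %.3f, residual SD = %.3f\n",
              length(x$coefficients), x$rank,
              if (x$full_rank) "" else ", rank-deficient: minimum-norm solution",
              x$pearson_r, x$residual_sd))
  invisible(x)
}

#' Predict with a fitted linear model
#' @param object a \code{linear_fit}
#' @param newdata design matrix with the same feature columns
#' @param ... unused
#' @export
predict.linear_fit <- function(object, newdata, ...) {
  as.numeric(object$intercept + as.matrix(newdata) %*% object$coefficients)
}

#' Parameter-free additive predictor
#'
#' prediction = wild-type mean + sum over present features of the measured
#' single-mutation effect; no fitting involved. Constructs with a feature
#' missing from the single-effect table are skipped and counted.
#'
#' @param single_effect_table named numeric vector: feature -> delta_log2 of
#'   the corresponding single-mutation construct versus wild type
#' @param construct_features list of character vectors (features per
#'   construct) or a binary design matrix
#' @param wt_mean wild-type mean log2 expression
#' @return list(predictions (NA for skipped), n_skipped)
#' @export
additive_predict <- function(single_effect_table, construct_features, wt_mean) {
  if (is.matrix(construct_features)) {
    construct_features <- apply(construct_features, 1, function(r)
      colnames(construct_features)[r != 0], simplify = FALSE)
  }
  preds <- vapply(construct_features, function(f) {
    if (!length(f)) return(wt_mean)
    if (!all(f %in% names(single_effect_table))) return(NA_real_)
    wt_mean + sum(single_effect_table[f])
  }, numeric(1))
  list(predictions = preds, n_skipped = sum(is.na(preds)))
}

#' Evaluate predictions against observations
#'
#' @param predictions,observations numeric vectors of equal length >= 2
#' @param band_sd prediction band scale; the fraction of points with
#'   |obs - pred| <= 3 * band_sd is reported
#' @return list(pearson_r, fraction_in_band); r is NA when either vector has
#'   zero variance
#' @export
evaluate_predictions <- function(predictions, observations, band_sd) {
  stopifnot(length(predictions) == length(observations), length(predictions) >= 2L)
  ok <- !is.na(predictions) & !is.na(observations)
  p <- predictions[ok]; o <- observations[ok]
  r <- if (stats::sd(p) > 0 && stats::sd(o) > 0) stats::cor(p, o) else NA_real_
  list(pearson_r = r,
       fraction_in_band = mean(abs(o - p) <= 3 * band_sd))
}
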