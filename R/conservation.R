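# Binding-site conservation against per-species sampled nulls. The observed
# statistic S is the mean log-odds score difference between the reference
# (D. melanogaster) site and the aligned species-X site; the null B_i is the
# same statistic after resampling each reference site through a
# position-specific substitution model learned from alignment context columns
# within +/-10 positions of the sites. The conservation score is
# Scons = (1/N) * sum_i (B_i - S) / B_i: 1 for perfect conservation, 0 for
# background-level divergence.

#' Observed mean log-odds score difference over aligned site pairs
#'
#' @param pwm a \code{pwm}
#' @param pairs data.frame with columns \code{mel} and \code{x} (aligned site
#'   strings, same length as the motif; gaps marked "-")
#' @param gap_policy "skip" drops gapped pairs (default); "as_n" scores gap
#'   columns like N
#' @return list(S, n_used, n_skipped)
#' @export
observed_divergence <- function(pwm, pairs, gap_policy = c("skip", "as_n")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(pwm, "pwm"), nrow(pairs) >= 1L)
  gapped <- grepl("-", pairs$mel, fixed = TRUE) | grepl("-", pairs$x, fixed = TRUE)
  if (gap_policy == "skip") {
    used <- pairs[!gapped, , drop = FALSE]
  } else {
    used <- pairs
    used$mel <- gsub("-", "N", used$mel, fixed = TRUE)
    used$x <- gsub("-", "N", used$x, fixed = TRUE)
  }
  if (!nrow(used)) return(list(S = NA_real_, n_used = 0L, n_skipped = sum(gapped)))
  d <- vapply(seq_len(nrow(used)), function(i) {
    score_window(pwm, used$mel[i], 0L) - score_window(pwm, used$x[i], 0L)
  }, numeric(1))
  list(S = mean(d), n_used = nrow(used), n_skipped = if (gap_policy == "skip") sum(gapped) else 0L)
}

#' Learn a position-specific substitution model from aligned context columns
#'
#' Per alignment position, a 4x4 row-stochastic matrix of
#' P(species-X base | reference base), estimated from paired context bases by
#' row normalization with additive pseudocount.
#'
#' @param context data.frame with columns \code{position} (1-based model
#'   position), \code{mel}, \code{x} (single aligned bases; "-" rows are
#'   dropped)
#' @param n_positions number of model positions (default max position seen)
#' @param pseudocount additive pseudocount per cell (default 0.5)
#' @return object of class \code{substitution_model}: list of 4x4 matrices
#' @export
learn_substitution_model <- function(context, n_positions = max(context$position),
                                     pseudocount = 0.5) {
  stopifnot(pseudocount > 0 || nrow(context) > 0)
  mats <- vector("list", n_positions)
  for (j in seq_len(n_positions)) {
    sub <- context[context$position == j & context$mel %in% DNA_BASES &
                     context$x %in% DNA_BASES, , drop = FALSE]
    m <- matrix(pseudocount, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    if (nrow(sub)) {
      t <- table(factor(sub$mel, DNA_BASES), factor(sub$x, DNA_BASES))
      m <- m + as.matrix(t)
    } else if (pseudocount == 0) {
      warning("all-gap/empty context at position ", j, "; uniform row")
      m <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
    }
    mats[[j]] <- m / rowSums(m)
  }
  structure(list(matrices = mats), class = "substitution_model")
}

#' Identity substitution model (no divergence)
#' @param n_positions model length
#' @export
identity_substitution_model <- function(n_positions) {
  m <- diag(4); dimnames(m) <- list(DNA_BASES, DNA_BASES)
  structure(list(matrices = rep(list(m), n_positions)), class = "substitution_model")
}

#' Sample null mean score differences from a substitution model
#'
#' For each of \code{n_sets} null sets, every reference site is resampled
#' base-by-base through the position-specific substitution model and the mean
#' log-odds score difference (reference minus resampled) is recorded.
#'
#' @param model a \code{substitution_model} covering the motif positions
#' @param pwm a \code{pwm}
#' @param mel_sites character vector of reference sites (motif length)
#' @param n_sets number of null sets N (default 50)
#' @param seed RNG seed for reproducibility (optional)
#' @return numeric vector B of length \code{n_sets}
#' @export
sample_null <- function(model, pwm, mel_sites, n_sets = 50L, seed = NULL) {
  stopifnot(inherits(model, "substitution_model"), inherits(pwm, "pwm"))
  L <- pwm$length
  if (length(model$matrices) < L) stop("substitution model shorter than motif")
  if (!is.null(seed)) set.seed(seed)
  mel_scores <- vapply(mel_sites, function(s) score_window(pwm, s, 0L), numeric(1))
  codes <- lapply(mel_sites, base_codes)
  vapply(seq_len(n_sets), function(i) {
    null_scores <- vapply(seq_along(mel_sites), function(k) {
      cd <- codes[[k]]
      nb <- vapply(seq_len(L), function(j) {
        if (cd[j] == 5L) return("N")
        sample(DNA_BASES, 1L, prob = model$matrices[[j]][cd[j], ])
      }, character(1))
      score_window(pwm, chars_seq(nb), 0L)
    }, numeric(1))
    mean(mel_scores - null_scores)
  }, numeric(1))
}

#' Conservation score from observed and null divergences
#'
#' \code{Scons = (1/N') * sum_i (B_i - S) / B_i} over the N' terms with
#' B_i != 0; zero terms are excluded and counted. If every term is excluded
#' the score is the sentinel \code{NA} with status "degenerate_null".
#'
#' @param S observed mean score difference
#' @param B numeric vector of null means
#' @return list(score, n_used, n_excluded, status)
#' @export
conservation_score <- function(S, B) {
  if (!length(B)) stop("B must be non-empty")
  ok <- B != 0
  if (!any(ok)) return(list(score = NA_real_, n_used = 0L,
                            n_excluded = length(B), status = "degenerate_null"))
  list(score = mean((B[ok] - S) / B[ok]), n_used = sum(ok),
       n_excluded = sum(!ok), status = "ok")
}
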