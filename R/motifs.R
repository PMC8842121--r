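# Motif models: position probability matrices (PPM), log-odds position weight
# matrices (PWM), window scoring, region-constrained scanning, information
# content and consensus extraction. All log-odds and information content are
# in log2 (bits). Coordinates are 0-based half-open; TSS-relative coordinates
# are carried as a declared 0-based TSS offset per sequence (TSS = position 0,
# core promoter = -80..+50 inclusive, 131 nt).

#' Construct a position probability matrix
#'
#' A PPM is a 4 x L matrix of per-position base probabilities with rows
#' A, C, G, T. Every column must sum to one.
#'
#' @param name motif identifier
#' @param mat numeric 4 x L matrix (rows A,C,G,T) or L x 4 (transposed input
#'   is detected by row names)
#' @return an object of class \code{ppm}
#' @export
new_ppm <- function(name, mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L && ncol(mat) == 4L) mat <- t(mat)
  if (nrow(mat) != 4L) stop("PPM must have 4 rows (A,C,G,T)")
  if (ncol(mat) < 1L) stop("PPM must have length >= 1")
  rownames(mat) <- DNA_BASES
  if (any(mat < 0)) stop("PPM entries must be >= 0")
  cs <- colSums(mat)
  if (any(abs(cs - 1) > 1e-9)) stop("every PPM column must sum to 1 within 1e-9")
  structure(list(name = name, mat = mat, length = ncol(mat)), class = "ppm")
}

#' @export
print.ppm <- function(x, ...) {
  cat(sprintf("PPM '%s' (%d nt), consensus %s\n", x$name, x$length,
              consensus(x)$consensus))
  print(round(x$mat, 3))
  invisible(x)
}

#' Construct a position weight matrix (log-odds, bits)
#'
#' @param name motif identifier
#' @param weights numeric 4 x L matrix of log2-odds weights (rows A,C,G,T)
#' @param background named base distribution (sums to 1)
#' @param min_score_threshold minimal match score for \code{\link{scan_pwm}};
#'   may be \code{NA} until calibrated
#' @param enriched_region optional TSS-relative inclusive interval
#'   \code{c(lo, hi)} restricting hit start positions
#' @param source "sequence-derived" or "expression-derived"
#' @return an object of class \code{pwm}
#' @export
new_pwm <- function(name, weights, background = rep(0.25, 4),
                    min_score_threshold = NA_real_, enriched_region = NULL,
                    source = "sequence-derived") {
  weights <- as.matrix(weights)
  if (nrow(weights) != 4L && ncol(weights) == 4L) weights <- t(weights)
  if (nrow(weights) != 4L) stop("PWM must have 4 rows (A,C,G,T)")
  rownames(weights) <- DNA_BASES
  if (any(!is.finite(weights))) stop("PWM weights must be finite")
  background <- as.numeric(background)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
    stop("background must be a base distribution summing to 1 within 1e-9")
  names(background) <- DNA_BASES
  if (!is.na(min_score_threshold)) {
    lo <- sum(apply(weights, 2, min)); hi <- sum(apply(weights, 2, max))
    if (min_score_threshold < lo - 1e-9 || min_score_threshold > hi + 1e-9)
      stop("min_score_threshold outside attainable score range [", lo, ", ", hi, "]")
  }
  if (!is.null(enriched_region)) {
    stopifnot(length(enriched_region) == 2L, enriched_region[1] <= enriched_region[2])
  }
  structure(list(name = name, weights = weights, length = ncol(weights),
                 background = background,
                 min_score_threshold = min_score_threshold,
                 enriched_region = enriched_region,
                 log_base = 2, source = source),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s' (%d nt, log2), threshold %s, region %s\n",
              x$name, x$length,
              if (is.na(x$min_score_threshold)) "unset" else
                format(round(x$min_score_threshold, 3)),
              if (is.null(x$enriched_region)) "none" else
                paste(x$enriched_region, collapse = "..")))
  invisible(x)
}

#' Convert a PPM into a log-odds PWM
#'
#' Weight(j, b) = log2((p(j,b) + pseudocount * q(b)) / ((1 + pseudocount) * q(b))).
#' The score threshold is left unset; calibrate it afterwards (e.g. with
#' \code{\link{optimize_threshold}} or \code{\link{calibrate_threshold}}).
#'
#' @param ppm a \code{ppm}
#' @param background base distribution (default uniform)
#' @param pseudocount additive smoothing, >= 0; must be > 0 if the PPM has
#'   zero entries
#' @inheritParams new_pwm
#' @return a \code{pwm}
#' @export
ppm_to_pwm <- function(ppm, background = rep(0.25, 4), pseudocount = 0.01,
                       enriched_region = NULL, source = "sequence-derived") {
  stopifnot(inherits(ppm, "ppm"), pseudocount >= 0)
  q <- as.numeric(background)
  if (pseudocount == 0 && any(ppm$mat == 0))
    stop("PPM has zero entries; pseudocount must be > 0 to avoid -Inf weights")
  w <- log2((ppm$mat + pseudocount * q) / ((1 + pseudocount) * q))
  new_pwm(ppm$name, w, background = background,
          enriched_region = enriched_region, source = source)
}

#' Smoothed PPM implied by a PWM (algebraic inverse of ppm_to_pwm)
#' @param pwm a \code{pwm}
#' @return a \code{ppm} (the pseudocount-smoothed probabilities)
#' @export
pwm_to_ppm <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  p <- 2^pwm$weights * pwm$background
  p <- sweep(p, 2, colSums(p), "/")
  new_ppm(pwm$name, p)
}

#' Score one window of a sequence with a PWM
#'
#' The score is the sum of per-position log2-odds weights for the window
#' bases; for the minus strand the window is reverse-complemented first.
#' An ambiguous base N contributes the background-expected weight of its
#' column (zero in expectation), never the best match.
#'
#' @param pwm a \code{pwm}
#' @param sequence DNA string over A,C,G,T,N
#' @param offset 0-based forward-strand window start
#' @param strand "+" or "-"
#' @return numeric log2-odds score
#' @export
score_window <- function(pwm, sequence, offset, strand = "+") {
  stopifnot(inherits(pwm, "pwm"))
  L <- pwm$length
  n <- nchar(sequence)
  if (offset < 0 || offset + L > n)
    stop("window [", offset, ", ", offset + L, ") out of bounds for sequence of length ", n)
  win <- substr(sequence, offset + 1L, offset + L)
  if (strand == "-") win <- revcomp(win)
  code <- base_codes(win)
  w <- pwm$weights
  exp_w <- as.numeric(pwm$background %*% w)  # background-expected column weight
  sum(ifelse(code == 5L, exp_w, w[cbind(pmin(code, 4L), seq_len(L))]))
}

# Scores for all windows of a sequence on one strand; NA-free numeric vector
# of length n - L + 1 (empty if the sequence is shorter than the motif).
all_window_scores <- function(pwm, sequence, strand = "+") {
  L <- pwm$length
  n <- nchar(sequence)
  if (n < L) return(numeric(0))
  w <- pwm$weights
  if (strand == "-") {  # equivalent reverse-complemented matrix, scan forward
    w <- w[4:1, L:1, drop = FALSE]
    rownames(w) <- DNA_BASES
  }
  code <- base_codes(sequence)
  exp_w <- as.numeric(pwm$background %*% w)
  ncol_w <- ncol(w)
  per_pos <- matrix(0, nrow = length(code), ncol = ncol_w)
  for (j in seq_len(ncol_w)) {
    col <- c(w[, j], exp_w[j])  # N -> expected weight
    per_pos[, j] <- col[code]
  }
  nwin <- n - L + 1L
  out <- numeric(nwin)
  for (j in seq_len(ncol_w)) out <- out + per_pos[seq_len(nwin) + (j - 1L), j]
  out
}

#' Scan a sequence for motif hits above the PWM score threshold
#'
#' Returns all and only windows scoring at least the PWM's minimal score
#' threshold whose start lies inside \code{region} (when given). Offsets are
#' 0-based forward-strand window starts; \code{tss_rel} is the TSS-relative
#' start given the sequence's declared TSS offset. Hits are sorted by offset,
#' then strand (+ before -).
#'
#' @param pwm a \code{pwm}
#' @param sequence DNA string
#' @param sequence_id identifier carried into the hit table
#' @param tss_offset 0-based position of the TSS within \code{sequence}
#' @param region optional TSS-relative inclusive interval \code{c(lo, hi)}
#'   constraining hit starts; defaults to the PWM's enriched region
#' @param both_strands scan the minus strand as well
#' @param threshold override of the PWM's stored threshold (use \code{-Inf}
#'   to keep every window)
#' @return data.frame with columns sequence_id, motif, offset, tss_rel,
#'   strand, score
#' @export
scan_pwm <- function(pwm, sequence, sequence_id = "seq", tss_offset = 0L,
                     region = pwm$enriched_region, both_strands = TRUE,
                     threshold = pwm$min_score_threshold) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.na(threshold)) stop("PWM '", pwm$name, "' has no calibrated threshold; pass `threshold`")
  n <- nchar(sequence)
  empty <- data.frame(sequence_id = character(), motif = character(),
                      offset = integer(), tss_rel = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (n < pwm$length) return(empty)
  strands <- if (both_strands) c("+", "-") else "+"
  if (!is.null(region) &&
      (region[2] < -tss_offset || region[1] > (n - pwm$length - tss_offset)))
    warning("region ", region[1], "..", region[2],
            " lies outside sequence '", sequence_id, "'")
  rows <- list()
  for (st in strands) {
    sc <- all_window_scores(pwm, sequence, st)
    offs <- seq_along(sc) - 1L
    keep <- sc >= threshold
    if (!is.null(region)) {
      tssr <- offs - tss_offset
      keep <- keep & tssr >= region[1] & tssr <= region[2]
    }
    if (any(keep)) {
      rows[[st]] <- data.frame(sequence_id = sequence_id, motif = pwm$name,
                               offset = offs[keep],
                               tss_rel = offs[keep] - tss_offset,
                               strand = st, score = sc[keep],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$offset, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Information content of a PPM (relative entropy to a background)
#'
#' Per column, sum over bases of p * log2(p/q) with 0*log(0) = 0.
#'
#' @param ppm a \code{ppm}
#' @param background strictly positive base distribution
#' @return list with \code{per_column} (bits) and \code{total} (bits)
#' @export
information_content <- function(ppm, background = rep(0.25, 4)) {
  stopifnot(inherits(ppm, "ppm"))
  q <- as.numeric(background)
  if (any(q <= 0)) stop("background entries must be strictly positive")
  p <- ppm$mat
  term <- p * log2(sweep(p, 1, q, "/"))
  term[p == 0] <- 0
  per_col <- colSums(term)
  list(per_column = per_col, total = sum(per_col))
}

#' Consensus string of a PPM
#'
#' Per-column argmax base; ties are broken alphabetically and flagged.
#'
#' @param ppm a \code{ppm}
#' @return list with \code{consensus} (string), \code{ties} (logical per
#'   column), \code{has_ties}
#' @export
consensus <- function(ppm) {
  stopifnot(inherits(ppm, "ppm"))
  idx <- apply(ppm$mat, 2, which.max)  # which.max is first = alphabetical
  mx <- ppm$mat[cbind(idx, seq_len(ppm$length))]
  ties <- colSums(abs(sweep(ppm$mat, 2, mx, "-")) < 1e-12) > 1L
  list(consensus = chars_seq(DNA_BASES[idx]), ties = ties, has_ties = any(ties))
}

#' Build a PPM from an IUPAC consensus pattern
#'
#' Literature consensus patterns (e.g. the initiator TCAKTY) become PPMs
#' with probability \code{1 - mismatch_prob} spread over the allowed bases
#' per position and the remainder over the others. Useful as a stand-in when
#' a study's fitted matrices are not available in machine-readable form.
#'
#' @param name motif identifier
#' @param pattern IUPAC string (ACGTRYKMSWBDHVN)
#' @param mismatch_prob total probability mass on disallowed bases per
#'   column (default 0.02)
#' @return a \code{ppm}
#' @export
iupac_ppm <- function(name, pattern, mismatch_prob = 0.02) {
  amb <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), K = c("G", "T"),
              M = c("A", "C"), S = c("C", "G"), W = c("A", "T"),
              B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = DNA_BASES)
  ch <- seq_chars(pattern)
  bad <- setdiff(ch, names(amb))
  if (length(bad)) stop("non-IUPAC symbol(s): ", paste(bad, collapse = ","))
  mat <- vapply(ch, function(c) {
    allowed <- amb[[c]]
    p <- stats::setNames(rep(0, 4), DNA_BASES)
    if (length(allowed) == 4L) {
      p[] <- 0.25
    } else {
      p[allowed] <- (1 - mismatch_prob) / length(allowed)
      rest <- setdiff(DNA_BASES, allowed)
      p[rest] <- mismatch_prob / length(rest)
    }
    p
  }, numeric(4))
  new_ppm(name, unname(mat))
}

#' Calibrate a PWM threshold separating a planted consensus from background
#'
#' Sets the threshold at \code{frac} of the way from the background score
#' quantile to the maximal attainable score, then verifies that the consensus
#' scores above it and that sampled i.i.d. background windows score below.
#'
#' @param pwm a \code{pwm}
#' @param frac position of the threshold between background and maximum
#' @param n_background background windows sampled for verification
#' @param quantile_bg background quantile anchoring the low end
#' @return the \code{pwm} with \code{min_score_threshold} set
#' @export
calibrate_threshold <- function(pwm, frac = 0.7, n_background = 2000,
                                quantile_bg = 0.999) {
  stopifnot(inherits(pwm, "pwm"))
  max_score <- sum(apply(pwm$weights, 2, max))
  bg <- vapply(seq_len(n_background),
               function(i) score_window(pwm, random_dna(pwm$length), 0L),
               numeric(1))
  lo <- stats::quantile(bg, quantile_bg, names = FALSE)
  thr <- lo + frac * (max_score - lo)
  if (thr >= max_score) thr <- (lo + max_score) / 2
  pwm$min_score_threshold <- thr
  pwm
}
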