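# Downstream analytics on normalized log2 expression: effect sizes versus a
# reference construct, pairwise log-additivity with noise gating,
# expression-based activity logos from saturation point-mutation panels,
# positional-shift effect profiles, and hormone inducibility.

#' Effect of a construct versus a reference
#'
#' delta_log2 = mean(construct replicates) - mean(reference replicates);
#' the standard error comes from the pooled replicate variance.
#'
#' @param construct_reps,reference_reps numeric log2 replicate vectors
#'   (outliers already removed)
#' @return list(delta_log2, fold, n, se)
#' @export
effect_estimate <- function(construct_reps, reference_reps) {
  if (!length(construct_reps) || !length(reference_reps))
    stop("effect_estimate: empty replicate set")
  d <- mean(construct_reps) - mean(reference_reps)
  n1 <- length(construct_reps); n2 <- length(reference_reps)
  v1 <- if (n1 > 1) stats::var(construct_reps) else 0
  v2 <- if (n2 > 1) stats::var(reference_reps) else 0
  df <- max(n1 - 1, 0) + max(n2 - 1, 0)
  pooled <- if (df > 0) ((n1 - 1) * v1 + (n2 - 1) * v2) / df else 0
  se <- sqrt(pooled * (1 / n1 + 1 / n2))
  list(delta_log2 = d, fold = 2^d, n = n1 + n2, se = se)
}

#' Pairwise additivity of two motif effects
#'
#' additivity = effect_ab - (effect_a + effect_b) in log2 units; positive is
#' subadditive, negative superadditive, |additivity| <= tol is called
#' additive. The record is gated (considered reliable) only when all three
#' effects exceed 3 x sd_noise in magnitude.
#'
#' @param effect_a,effect_b,effect_ab log2 effects sharing one reference
#' @param sd_noise assay noise scale (median of per-construct replicate SDs)
#' @param tol additive-call tolerance in log2 units (default 0.2)
#' @return list(additivity, cls, gated, sd_noise)
#' @export
additivity <- function(effect_a, effect_b, effect_ab, sd_noise, tol = 0.2) {
  add <- effect_ab - (effect_a + effect_b)
  cls <- if (abs(add) <= tol) "additive" else if (add > 0) "subadditive" else "superadditive"
  gated <- all(abs(c(effect_a, effect_b, effect_ab)) > 3 * sd_noise)
  list(additivity = add, cls = cls, gated = gated, sd_noise = sd_noise)
}

#' Expression-based PPM and activity logo from a point-mutation panel
#'
#' Per motif position j and base b, E(j, b) is the mean linear-scale (2^x)
#' expression of the single-base variant carrying b at j (the consensus
#' base's value is the consensus construct's expression). Columns are
#' normalized to probabilities, p(j, b) = E(j, b) / sum_b' E(j, b').
#'
#' @param point_mutant_table data.frame with columns \code{position}
#'   (1-based), \code{base}, \code{x} (mean log2 expression of the variant)
#' @param consensus_x mean log2 expression of the consensus construct
#' @param consensus consensus string (defines the panel's reference base per
#'   column)
#' @param motif motif name for the resulting PPM
#' @param floor linear-scale floor applied before normalization
#' @param log_scale use log2 expression (shifted positive) instead of linear
#' @return list(ppm, ic_per_column, ic_total, consensus, incomplete)
#' @export
expression_ppm <- function(point_mutant_table, consensus_x, consensus,
                           motif = "activity", floor = 1e-9, log_scale = FALSE) {
  L <- nchar(consensus)
  cc <- seq_chars(consensus)
  E <- matrix(NA_real_, 4, L, dimnames = list(DNA_BASES, NULL))
  E[cbind(match(cc, DNA_BASES), seq_len(L))] <- consensus_x
  for (i in seq_len(nrow(point_mutant_table))) {
    r <- point_mutant_table[i, ]
    E[r$base, r$position] <- r$x
  }
  if (log_scale) {
    shift <- min(E, na.rm = TRUE)
    Elin <- pmax(E - shift + 1, floor)
  } else {
    Elin <- pmax(2^E, floor)
  }
  incomplete <- which(colSums(is.na(E)) > 0)
  Elin[is.na(E)] <- 0  # missing variants excluded from the column sum
  p <- sweep(Elin, 2, colSums(Elin), "/")
  ppm <- new_ppm(motif, p)
  ic <- information_content(ppm)
  list(ppm = ppm, ic_per_column = ic$per_column, ic_total = ic$total,
       consensus = consensus(ppm)$consensus, incomplete = incomplete)
}

#' Positional-shift effect profile
#'
#' Maps each shift delta to the effect (log2) of the shifted construct versus
#' wild type; delta = 0 is 0 by construction. Duplicate deltas are averaged
#' with a warning. Reports per-side monotonicity violations (effects are
#' expected to decrease away from the native position).
#'
#' @param shift_effects data.frame with columns \code{delta} and \code{x}
#'   (mean log2 expression of the shifted construct)
#' @param wild_type_x mean log2 expression of the wild type
#' @return data.frame(delta, effect) sorted by delta, with attribute
#'   \code{monotonicity_violations}
#' @export
shift_profile <- function(shift_effects, wild_type_x) {
  if (anyDuplicated(shift_effects$delta)) {
    warning("duplicate shift deltas averaged")
    shift_effects <- stats::aggregate(x ~ delta, shift_effects, mean)
  }
  out <- data.frame(delta = c(0, shift_effects$delta),
                    effect = c(0, shift_effects$x - wild_type_x))
  out <- out[!duplicated(out$delta), , drop = FALSE]
  out <- out[order(out$delta), , drop = FALSE]
  rownames(out) <- NULL
  viol <- 0L
  right <- out$effect[out$delta >= 0]
  if (length(right) > 1L) viol <- viol + sum(diff(right) > 1e-12)
  left <- rev(out$effect[out$delta <= 0])
  if (length(left) > 1L) viol <- viol + sum(diff(left) > 1e-12)
  attr(out, "monotonicity_violations") <- viol
  out
}

#' Hormone inducibility of one construct
#'
#' log2 ratio of induced over basal mean expression.
#'
#' @param basal_reps,induced_reps log2 replicate vectors
#' @return list(basal_x, induced_x, log2_ratio, fold)
#' @export
inducibility <- function(basal_reps, induced_reps) {
  if (!length(basal_reps) || !length(induced_reps))
    stop("inducibility: a condition is missing")
  b <- mean(basal_reps); i <- mean(induced_reps)
  list(basal_x = b, induced_x = i, log2_ratio = i - b, fold = 2^(i - b))
}

#' Inducibility table across constructs
#'
#' @param summary construct summary (from \code{\link{summarize_constructs}})
#'   containing both ecdysone conditions
#' @return data.frame(construct, basal_x, induced_x, log2_ratio, fold) plus
#'   attribute \code{skipped} (constructs missing one condition)
#' @export
inducibility_table <- function(summary) {
  basal <- summary[!summary$ecdysone, c("construct", "mean")]
  induced <- summary[summary$ecdysone, c("construct", "mean")]
  merged <- merge(basal, induced, by = "construct", suffixes = c("_basal", "_induced"))
  skipped <- length(union(basal$construct, induced$construct)) - nrow(merged)
  out <- data.frame(construct = merged$construct,
                    basal_x = merged$mean_basal,
                    induced_x = merged$mean_induced,
                    log2_ratio = merged$mean_induced - merged$mean_basal)
  out$fold <- 2^out$log2_ratio
  attr(out, "skipped") <- skipped
  out
}

#' Two-group comparison (standard tests)
#'
#' @param values_a,values_b numeric groups (each n >= 2)
#' @param test "wilcoxon_rank_sum" or "two_sample_t"
#' @return list(statistic, p_value, test)
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("wilcoxon_rank_sum", "two_sample_t")) {
  test <- match.arg(test)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("compare_groups: each group needs n >= 2")
  if (test == "wilcoxon_rank_sum") {
    res <- suppressWarnings(stats::wilcox.test(values_a, values_b))
  } else {
    if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0)
      stop("compare_groups: degenerate groups (zero variance)")
    res <- stats::t.test(values_a, values_b)
  }
  list(statistic = unname(res$statistic), p_value = res$p.value, test = test)
}
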