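# Dual-luciferase plate normalization and QC. Each plate carries sample wells
# plus negative controls (empty vector pUC19 and untransfected cells UTC) and
# positive controls (pUG9 normalization standard, pZQ3 inducibility check).
# The firefly channel is read twice: FF1 before and FF2 after strong wells
# (> 2e5 RLU) are removed and quenched, so FF1 is valid for strong wells and
# the crosstalk-free FF2 for weak ones. Renilla (REN) is the co-transfection
# control.
#
# Per plate: BG = mean of pooled negative-control FF2; Norm_pUG9 = mean over
# pUG9 wells of (FF1 - BG)/REN; per sample x = log2(((FF - BG)/REN)/Norm)
# with FF = FF1 for strong wells and FF2 otherwise. Wells with REN outside
# [300, 10000] RLU are dropped. Outliers per construct: |x_i - median| over
# the library-wide median of per-construct SDs >= 3.

PLATE_COLUMNS <- c("plate", "well", "role", "construct", "ecdysone",
                   "FF1", "FF2", "REN")

#' Plate background from negative controls
#'
#' Arithmetic mean of the pooled second-read firefly (FF2) values of all
#' pUC19 and UTC wells on the plate.
#'
#' @param plate data.frame of wells (columns \code{role}, \code{FF2}, ...)
#' @return numeric BG in RLU
#' @export
plate_background <- function(plate) {
  neg <- plate$FF2[plate$role %in% c("pUC19", "UTC")]
  if (!length(neg)) stop("normalization error: no negative control wells (pUC19/UTC)")
  mean(neg)
}

#' Plate normalization factor from the pUG9 positive control
#'
#' Mean over pUG9 wells of (FF1 - BG) / REN. Wells with REN = 0 are skipped
#' with a warning; a non-positive factor rejects the plate.
#'
#' @param plate data.frame of wells
#' @param BG plate background (see \code{\link{plate_background}})
#' @return numeric normalization factor
#' @export
norm_factor <- function(plate, BG = plate_background(plate)) {
  p <- plate[plate$role == "pUG9", , drop = FALSE]
  if (!nrow(p)) stop("normalization error: no pUG9 wells")
  zero <- p$REN == 0
  if (any(zero)) {
    warning(sum(zero), " pUG9 well(s) with REN = 0 skipped")
    p <- p[!zero, , drop = FALSE]
  }
  if (!nrow(p)) stop("normalization error: all pUG9 wells have REN = 0")
  nf <- mean((p$FF1 - BG) / p$REN)
  if (nf <= 0) stop("plate rejected: non-positive pUG9 normalization factor (", nf, ")")
  nf
}

#' Normalize one plate of dual-luciferase readouts
#'
#' @param plate data.frame with columns plate, well, role, construct,
#'   ecdysone, FF1, FF2, REN
#' @param ff1_strong FF1 threshold above which FF1 (not FF2) is the readout
#'   (default 2e5 RLU)
#' @param ren_range admissible REN interval (default \code{c(300, 10000)} RLU)
#' @return data.frame of sample wells: construct, ecdysone, plate, well, x
#'   (log2 normalized expression, NA when dropped), qc ("" /
#'   "ren_out_of_range" / "nonpositive_signal")
#' @export
normalize_plate <- function(plate, ff1_strong = 2e5, ren_range = c(300, 10000)) {
  miss <- setdiff(c("role", "FF1", "FF2", "REN"), names(plate))
  if (length(miss)) stop("plate table lacks column(s): ", paste(miss, collapse = ", "))
  BG <- plate_background(plate)
  NF <- norm_factor(plate, BG)
  s <- plate[plate$role == "sample", , drop = FALSE]
  out <- data.frame(construct = s$construct,
                    ecdysone = s$ecdysone,
                    plate = s$plate, well = s$well,
                    x = NA_real_, qc = "", stringsAsFactors = FALSE)
  ren_bad <- s$REN < ren_range[1] | s$REN > ren_range[2]
  out$qc[ren_bad] <- "ren_out_of_range"
  strong <- s$FF1 > ff1_strong
  FF <- ifelse(strong, s$FF1, s$FF2)
  nonpos <- !ren_bad & FF <= BG
  out$qc[nonpos] <- "nonpositive_signal"
  ok <- !ren_bad & !nonpos
  out$x[ok] <- log2(((FF[ok] - BG) / s$REN[ok]) / NF)
  out
}

#' Library noise scale: median of per-construct replicate SDs
#'
#' Computed over constructs with at least two un-dropped replicates; this is
#' the SD_noise used for outlier scoring, additivity gating and prediction
#' bands.
#'
#' @param measurements normalized table (columns construct, x, qc)
#' @return numeric scale in log2 units
#' @export
noise_scale <- function(measurements) {
  m <- measurements[measurements$qc == "" & !is.na(measurements$x), , drop = FALSE]
  sds <- tapply(m$x, m$construct, function(v) if (length(v) >= 2L) stats::sd(v) else NA_real_)
  sds <- sds[!is.na(sds)]
  if (!length(sds)) return(NA_real_)
  stats::median(sds)
}

#' Flag replicate outliers per construct
#'
#' score_i = (x_i - median(construct)) / scale with scale the library-wide
#' median of per-construct SDs; |score| >= 3 flags the replicate.
#'
#' @param measurements normalized table (columns construct, x, qc)
#' @param scale noise scale; default \code{\link{noise_scale}} of the input
#' @param cutoff absolute score cutoff (default 3)
#' @return the input with columns \code{outlier_score} and updated \code{qc}
#'   ("outlier" appended for flagged rows)
#' @export
outlier_flags <- function(measurements, scale = noise_scale(measurements),
                          cutoff = 3) {
  out <- measurements
  out$outlier_score <- NA_real_
  ok <- out$qc == "" & !is.na(out$x)
  if (is.na(scale) || scale == 0) {
    warning("degenerate noise scale; no outlier flags set")
    return(out)
  }
  med <- tapply(out$x[ok], out$construct[ok], stats::median)
  out$outlier_score[ok] <- (out$x[ok] - med[out$construct[ok]]) / scale
  flag <- ok & abs(out$outlier_score) >= cutoff
  out$qc[flag] <- ifelse(out$qc[flag] == "", "outlier",
                         paste(out$qc[flag], "outlier", sep = ";"))
  out
}

#' Per-construct summary statistics
#'
#' Statistics over un-flagged replicates; the coefficient of variation is
#' computed on the linear scale (2^x) by default (sample SD / mean, percent),
#' with the log-scale SD also reported.
#'
#' @param measurements normalized table after \code{\link{outlier_flags}}
#' @return data.frame: construct, ecdysone, n, mean, median, sd, cv_linear
#' @export
summarize_constructs <- function(measurements) {
  m <- measurements[measurements$qc == "" & !is.na(measurements$x), , drop = FALSE]
  if (!nrow(m)) {
    return(data.frame(construct = character(), ecdysone = logical(),
                      n = integer(), mean = numeric(), median = numeric(),
                      sd = numeric(), cv_linear = numeric()))
  }
  key <- interaction(m$construct, m$ecdysone, drop = TRUE)
  rows <- lapply(split(m, key), function(g) {
    lin <- 2^g$x
    cv <- if (length(lin) >= 2L) stats::sd(lin) / mean(lin) * 100 else 0
    data.frame(construct = g$construct[1], ecdysone = g$ecdysone[1],
               n = nrow(g), mean = mean(g$x), median = stats::median(g$x),
               sd = if (nrow(g) >= 2L) stats::sd(g$x) else 0,
               cv_linear = cv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize a set of plates end to end
#'
#' Runs per-plate normalization, pools the results, computes the library
#' noise scale and flags outliers.
#'
#' @param plates data.frame of wells for one or more plates, or a list of
#'   per-plate data.frames
#' @inheritParams normalize_plate
#' @return list(measurements, sd_noise, summary)
#' @export
normalize_library <- function(plates, ff1_strong = 2e5, ren_range = c(300, 10000)) {
  if (is.data.frame(plates)) plates <- split(plates, plates$plate)
  norm <- do.call(rbind, lapply(plates, normalize_plate,
                                ff1_strong = ff1_strong, ren_range = ren_range))
  rownames(norm) <- NULL
  sd_noise <- noise_scale(norm)
  norm <- outlier_flags(norm, scale = sd_noise)
  list(measurements = norm, sd_noise = sd_noise,
       summary = summarize_constructs(norm))
}

#' Read plate CSVs
#' @param paths CSV file path(s) with the documented header (plate, well,
#'   role, construct, ecdysone, FF1, FF2, REN)
#' @return pooled data.frame of wells
#' @export
read_plates <- function(paths) {
  out <- do.call(rbind, lapply(paths, utils::read.csv, stringsAsFactors = FALSE))
  miss <- setdiff(PLATE_COLUMNS, names(out))
  if (length(miss)) stop("plate CSV lacks column(s): ", paste(miss, collapse = ", "))
  out$ecdysone <- as.logical(out$ecdysone)
  out
}

#' Write a plate table as CSV
#' @param plate data.frame of wells
#' @param path output file
#' @export
write_plate <- function(plate, path) {
  utils::write.csv(plate[, PLATE_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
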