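# Promoter architecture statistics: gene-set construction, mutual-information
# optimized PWM score thresholds, binary motif/feature association (MI, MCC),
# enrichment Z-profiles over ranked genes, architecture class assignment, and
# positional sequence profiles (dinucleotides, site-position histograms).

#' Default gene-set rules
#'
#' Eighteen overlapping sets: top/bottom 10\% for each expression-derived
#' feature column, the "medhigh" top 40\% of expression inducibility
#' (mad_expression), narrow/broad peak classes, and the lowest-decile TSS
#' width. A set of stalled genes is supplied externally (see
#' \code{\link{build_gene_sets}}).
#'
#' @return list of rule descriptors (name, column, type, value)
#' @export
default_gene_set_rules <- function() {
  quant_cols <- c("min_expr", "max_expr", "mad_expression",
                  "embryo_expr", "larva_expr", "female_expr", "adult_expr")
  rules <- list()
  for (col in quant_cols) {
    rules[[paste0(col, "_high")]] <- list(column = col, type = "top_frac", value = 0.10)
    rules[[paste0(col, "_low")]]  <- list(column = col, type = "bottom_frac", value = 0.10)
  }
  rules[["mad_expression_medhigh"]] <- list(column = "mad_expression",
                                            type = "top_frac", value = 0.40)
  rules[["NP"]] <- list(column = "peak_class", type = "equals", value = "NP")
  rules[["BP"]] <- list(column = "peak_class", type = "equals", value = "BP")
  rules[["tss_mad_low"]] <- list(column = "tss_mad", type = "bottom_frac", value = 0.10)
  rules
}

#' Build overlapping gene sets from a gene feature table
#'
#' @param features data.frame with a \code{gene_id} column plus the feature
#'   columns the rules reference
#' @param rules named list of rule descriptors: \code{top_frac} /
#'   \code{bottom_frac} (value = fraction) or \code{equals} (value = level)
#' @param stalled optional character vector of stalled gene ids, added as the
#'   externally supplied "stalled" set
#' @return named list of character vectors of gene ids
#' @export
build_gene_sets <- function(features, rules = default_gene_set_rules(),
                            stalled = NULL) {
  stopifnot("gene_id" %in% names(features))
  sets <- lapply(names(rules), function(nm) {
    r <- rules[[nm]]
    if (!r$column %in% names(features))
      stop("gene-set rule '", nm, "' references missing column '", r$column, "'")
    v <- features[[r$column]]
    if (r$type == "equals") return(features$gene_id[!is.na(v) & v == r$value])
    v_ok <- !is.na(v)
    if (!any(v_ok)) return(character(0))
    vv <- v[v_ok]
    if (length(unique(vv)) == 1L) {
      warning("gene-set rule '", nm, "': constant column, empty set")
      return(character(0))
    }
    k <- max(1L, floor(r$value * length(vv)))
    ord <- order(vv, decreasing = (r$type == "top_frac"))
    features$gene_id[v_ok][ord[seq_len(k)]]
  })
  names(sets) <- names(rules)
  if (!is.null(stalled)) sets$stalled <- intersect(stalled, features$gene_id)
  sets
}

#' Write gene sets as a two-column TSV (set, gene)
#' @param sets named list of gene-id vectors
#' @param path output file
#' @export
write_gene_sets <- function(sets, path) {
  df <- data.frame(set = rep(names(sets), lengths(sets)),
                   gene = unlist(sets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a two-column TSV (set, gene)
#' @param path TSV file
#' @return named list of gene-id vectors
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  split(df$gene, df$set)
}

#' Plug-in mutual information between two binary vectors (bits)
#' @param x,y 0/1 vectors of equal length
#' @return non-negative MI in bits
#' @export
binary_mi <- function(x, y) {
  if (length(x) != length(y)) stop("binary_mi: length mismatch")
  n <- length(x)
  if (n < 1L) stop("binary_mi: empty input")
  mi <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- sum(x == a & y == b) / n
    if (pab > 0) {
      pa <- sum(x == a) / n; pb <- sum(y == b) / n
      mi <- mi + pab * log2(pab / (pa * pb))
    }
  }
  max(mi, 0)
}

#' Matthews correlation coefficient between two binary vectors
#'
#' Returns 0 when any margin of the 2x2 table is zero.
#' @param x,y 0/1 vectors of equal length
#' @return value in [-1, 1]
#' @export
binary_mcc <- function(x, y) {
  if (length(x) != length(y)) stop("binary_mcc: length mismatch")
  tp <- sum(x == 1 & y == 1); tn <- sum(x == 0 & y == 0)
  fp <- sum(x == 1 & y == 0); fn <- sum(x == 0 & y == 1)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Best in-region match score per promoter for one PWM
#'
#' Convenience used by threshold optimization: the maximal window score
#' within the PWM's enriched region (or the whole sequence if none), both
#' strands; \code{-Inf} if no window lies in the region.
#'
#' @param pwm a \code{pwm}
#' @param sequences named character vector of promoter sequences
#' @param tss_offset 0-based TSS position within each sequence
#' @return numeric vector of best scores, one per sequence
#' @export
best_scores <- function(pwm, sequences, tss_offset = 0L) {
  vapply(sequences, function(s) {
    hits <- scan_pwm(pwm, s, tss_offset = tss_offset, threshold = -Inf)
    if (!nrow(hits)) -Inf else max(hits$score)
  }, numeric(1))
}

#' Optimize a PWM's minimal score threshold by mutual information
#'
#' For every threshold on the grid, motif presence in a gene is defined as
#' best in-region hit score >= threshold; the MI between presence and each
#' positively correlated gene set (phi > 0 at that threshold) is computed and
#' the threshold maximizing MI over all sets is returned (smallest threshold
#' on ties). When no set is positively correlated at any threshold the
#' sentinel status "uninformative" is returned.
#'
#' @param pwm a \code{pwm}
#' @param promoter_sequences named character vector (names = gene ids), or
#'   \code{NULL} if \code{scores} is given
#' @param gene_sets named list of gene-id vectors
#' @param grid \code{c(from, to, by)}; default (-15, 30, 0.1), 451 points
#' @param tss_offset 0-based TSS position within each sequence
#' @param scores optional precomputed named best-score vector (overrides
#'   scanning)
#' @return list(threshold, best_set, mi, status)
#' @export
optimize_threshold <- function(pwm, promoter_sequences, gene_sets,
                               grid = c(-15, 30, 0.1), tss_offset = 0L,
                               scores = NULL) {
  if (is.null(scores)) {
    stopifnot(!is.null(names(promoter_sequences)))
    scores <- best_scores(pwm, promoter_sequences, tss_offset)
  }
  genes <- names(scores)
  grid_pts <- seq(grid[1], grid[2], by = grid[3])
  member <- lapply(gene_sets, function(s) as.integer(genes %in% s))
  best <- list(threshold = NA_real_, best_set = NA_character_, mi = -Inf,
               status = "uninformative")
  for (thr in grid_pts) {
    pres <- as.integer(scores >= thr)
    if (all(pres == 0L) || all(pres == 1L)) next
    for (nm in names(member)) {
      y <- member[[nm]]
      if (all(y == 0L) || all(y == 1L)) next
      if (binary_mcc(pres, y) <= 0) next   # positive-correlation gate (phi > 0)
      mi <- binary_mi(pres, y)
      if (mi > best$mi + 1e-12) {
        best <- list(threshold = thr, best_set = nm, mi = mi, status = "ok")
      }
    }
  }
  best
}

#' Grid point count for a threshold grid
#' @param grid c(from, to, by)
#' @export
grid_points <- function(grid = c(-15, 30, 0.1)) length(seq(grid[1], grid[2], by = grid[3]))

#' Per-bin enrichment Z-scores of motif presence along ranked genes
#'
#' Genes must be pre-ordered by the feature of interest. For each bin of
#' \code{bin} consecutive genes, Z = (k - n*p) / sqrt(n*p*(1-p)) under a
#' binomial null with the global presence frequency p; a trailing partial bin
#' uses its own size.
#'
#' @param presence 0/1 vector over genes, ordered by the feature
#' @param bin bin size (default 50)
#' @return data.frame: bin, n, k, z
#' @export
zscore_profile <- function(presence, bin = 50L) {
  presence <- as.integer(presence)
  p <- mean(presence)
  nb <- ceiling(length(presence) / bin)
  idx <- rep(seq_len(nb), each = bin)[seq_along(presence)]
  n <- as.numeric(tabulate(idx, nb))
  k <- as.numeric(tapply(presence, idx, sum))
  if (p <= 0 || p >= 1) {
    warning("presence frequency is degenerate (p = ", p, "); zero profile")
    z <- rep(0, nb)
  } else {
    z <- (k - n * p) / sqrt(n * p * (1 - p))
  }
  data.frame(bin = seq_len(nb), n = n, k = k, z = z)
}

#' Default architecture class motif lists
#'
#' Class 1: INR, MTEDPE, CGpal, GAGA, GAGArev. Class 2: TATA-Box, ATGAA.
#' Class 3.1: DRE, Ohler7; class 3.2: INR2, Ohler6; shared class 3 motifs:
#' E-Box1, TTGTT, TTGTTrev, INR2rev, AAG3. Class 4: TCT, RDPE.
#' @return named list of character vectors
#' @export
architecture_classes <- function() {
  list(Ar1   = c("INR", "MTEDPE", "CGpal", "GAGA", "GAGArev"),
       Ar2   = c("TATA-Box", "ATGAA"),
       Ar3.1 = c("DRE", "Ohler7", "E-Box1", "TTGTT", "TTGTTrev", "INR2rev", "AAG3"),
       Ar3.2 = c("INR2", "Ohler6", "E-Box1", "TTGTT", "TTGTTrev", "INR2rev", "AAG3"),
       Ar4   = c("TCT", "RDPE"))
}

#' Assign a promoter's architecture from its motif hits
#'
#' The label is the class with most distinct motif hits; no hits gives
#' "motif-less" and a tie across classes gives "mixed" (per-class counts are
#' always reported).
#'
#' @param motif_names character vector of motif names hit in the promoter
#' @param class_motif_lists named list of per-class motif vectors
#' @return list(label, counts)
#' @export
assign_architecture <- function(motif_names, class_motif_lists = architecture_classes()) {
  motif_names <- unique(motif_names)
  known <- unique(unlist(class_motif_lists))
  unknown <- setdiff(motif_names, known)
  if (length(unknown))
    stop("unknown motif name(s): ", paste(unknown, collapse = ", "))
  counts <- vapply(class_motif_lists, function(m) length(intersect(motif_names, m)),
                   integer(1))
  if (all(counts == 0L)) return(list(label = "motif-less", counts = counts))
  top <- which(counts == max(counts))
  label <- if (length(top) > 1L) "mixed" else names(counts)[top]
  list(label = label, counts = counts)
}

#' Positioned dinucleotide frequencies around the TSS
#'
#' For sequences aligned at their TSS, the frequency of each of the 16
#' dinucleotides starting at each position of a window centered on the TSS.
#'
#' @param sequences character vector of TSS-aligned sequences
#' @param tss_offset 0-based TSS position within each sequence
#' @param window window width in bp (default 500); positions
#'   \code{-window/2 .. window/2 - 1} relative to the TSS
#' @return 16 x window matrix (rows = dinucleotides, columns sum to 1);
#'   attribute \code{skipped} counts sequences too short for the window
#' @export
dinucleotide_profile <- function(sequences, tss_offset = 250L, window = 500L) {
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  lo <- tss_offset - window %/% 2L
  counts <- matrix(0, nrow = 16L, ncol = window, dimnames = list(dinucs, NULL))
  skipped <- 0L
  for (s in sequences) {
    if (lo < 0L || lo + window + 1L > nchar(s)) { skipped <- skipped + 1L; next }
    ch <- seq_chars(substr(s, lo + 1L, lo + window + 1L))
    di <- paste0(ch[-length(ch)], ch[-1L])
    m <- match(di, dinucs)
    ok <- !is.na(m)
    counts[cbind(m[ok], which(ok))] <- counts[cbind(m[ok], which(ok))] + 1
  }
  if (skipped) attr(counts, "skipped") <- skipped
  used <- length(sequences) - skipped
  if (used > 0) counts <- counts / used
  colnames(counts) <- seq_len(window) - 1L - window %/% 2L
  counts
}

#' Smoothed histogram of TSS-relative binding-site start positions
#'
#' @param tss_rel_starts integer vector of TSS-relative hit starts
#' @param smoothing odd rectangular kernel width (default 5)
#' @param range optional \code{c(lo, hi)} of positions; defaults to the data
#'   range
#' @return data.frame(position, density) plus attribute \code{peak} (argmax
#'   position; leftmost on ties); empty data.frame when no hits
#' @export
site_position_histogram <- function(tss_rel_starts, smoothing = 5L, range = NULL) {
  if (!length(tss_rel_starts)) {
    out <- data.frame(position = integer(), density = numeric())
    attr(out, "peak") <- NA_integer_
    return(out)
  }
  if (is.null(range)) range <- range(tss_rel_starts)
  pos <- seq(range[1], range[2])
  h <- tabulate(tss_rel_starts - range[1] + 1L, length(pos))
  sm <- smooth_track(h, smoothing)
  out <- data.frame(position = pos, density = sm)
  attr(out, "peak") <- pos[which.max(sm)]
  out
}
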