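# TSS tag-cluster calling and the MAD peakedness score ("TSS width").
# A tag track is per-position non-negative tag counts on one contig/strand;
# clusters are maximal runs where the 41-nt rectangular-kernel smoothed track
# exceeds the genomic background rate. Cluster peakedness is the mean absolute
# deviation of tag positions from their median, which unlike a shape index is
# independent of cluster size.

#' Construct a tag track
#' @param counts per-position non-negative integer tag counts
#' @param contig contig identifier
#' @param strand "+" or "-"
#' @param background_rate tags per bp; defaults to total tags / track length
#' @return object of class \code{tag_track}
#' @export
new_tag_track <- function(counts, contig = "chr", strand = "+",
                          background_rate = NULL) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("tag counts must be >= 0")
  if (is.null(background_rate))
    background_rate <- if (length(counts)) sum(counts) / length(counts) else 0
  if (background_rate < 0) stop("background_rate must be >= 0")
  structure(list(contig = contig, strand = strand, counts = counts,
                 background_rate = background_rate), class = "tag_track")
}

#' Smooth a tag track with a centered rectangular kernel
#'
#' Centered moving average; edge positions use truncated windows.
#'
#' @param track a \code{tag_track} or numeric vector
#' @param width odd kernel width (default 41)
#' @return same type as input, smoothed
#' @export
smooth_track <- function(track, width = 41L) {
  if (width %% 2L != 1L || width < 1L) stop("kernel width must be odd and >= 1")
  x <- if (inherits(track, "tag_track")) track$counts else as.numeric(track)
  n <- length(x)
  if (n == 0L) return(track)
  h <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(track, "tag_track")) { track$counts <- sm; track } else sm
}

#' Mean absolute deviation of tag positions from their median
#'
#' \code{(1/n) * sum(|x_i - median(x)|)} over tag positions counted with
#' multiplicity; the size-independent TSS-width score.
#'
#' @param positions numeric vector of tag positions (one entry per tag)
#' @return non-negative numeric
#' @export
mad_score <- function(positions) {
  if (length(positions) < 1L) stop("mad_score requires at least one tag position")
  mean(abs(positions - stats::median(positions)))
}

#' Call TSS tag clusters on a track
#'
#' Clusters are maximal runs where the smoothed signal strictly exceeds the
#' background rate. Each cluster's TSS is the position with most raw tags
#' (leftmost on ties). Filters, applied in order and recorded as rejection
#' reasons: \code{min_tags} (total raw tags); isolation (both members of any
#' TSS pair closer than \code{isolation} bp are dropped); association (an
#' annotated gene start within 250 bp upstream of the TSS, the TSS inside an
#' annotated 5'UTR, or an annotated TSS within the cluster).
#'
#' @param track a \code{tag_track}
#' @param min_tags minimal raw tag count per cluster (default 5)
#' @param isolation minimal distance between cluster TSSs (default 150)
#' @param annotation optional list with elements \code{gene_starts} (numeric),
#'   \code{utr_intervals} (2-column matrix, 0-based half-open), and
#'   \code{annotated_tss} (numeric); required when \code{associate = TRUE}
#' @param associate apply the association filter
#' @param smooth_width rectangular kernel width for cluster definition
#' @return data.frame: contig, start, end (0-based half-open), n, tss, mad,
#'   passes_filters, reason
#' @export
call_clusters <- function(track, min_tags = 5L, isolation = 150L,
                          annotation = NULL, associate = !is.null(annotation),
                          smooth_width = 41L) {
  stopifnot(inherits(track, "tag_track"))
  if (associate && is.null(annotation))
    stop("association filtering requested but no annotation supplied")
  empty <- data.frame(contig = character(), start = integer(), end = integer(),
                      n = numeric(), tss = integer(), mad = numeric(),
                      passes_filters = logical(), reason = character(),
                      stringsAsFactors = FALSE)
  x <- track$counts
  if (!length(x) || sum(x) == 0) return(empty)
  sm <- smooth_track(x, smooth_width)
  above <- sm > track$background_rate
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(empty)
  cl <- lapply(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- x[i0:i1]
    n <- sum(seg)
    if (n < 1) return(NULL)
    tss <- i0 + which.max(seg) - 1L          # leftmost mode
    pos <- rep(i0:i1, times = seg)           # tags with multiplicity
    data.frame(contig = track$contig, start = i0 - 1L, end = i1, n = n,
               tss = tss - 1L, mad = mad_score(pos),
               passes_filters = TRUE, reason = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cl[!vapply(cl, is.null, logical(1))])
  if (is.null(out)) return(empty)

  fail <- function(i, why) {
    out$passes_filters[i] <<- FALSE
    out$reason[i] <<- ifelse(out$reason[i] == "", why, paste(out$reason[i], why, sep = ";"))
  }
  fail(which(out$n < min_tags), "min_tags")
  # isolation: drop both clusters of any too-close TSS pair (among survivors)
  alive <- which(out$passes_filters)
  if (length(alive) > 1L) {
    tsspos <- out$tss[alive]
    d <- abs(outer(tsspos, tsspos, "-"))
    close_pair <- d < isolation & upper.tri(d)
    bad <- unique(c(row(d)[close_pair], col(d)[close_pair]))
    if (length(bad)) fail(alive[bad], "isolation")
  }
  if (associate) {
    alive <- which(out$passes_filters)
    for (i in alive) {
      ok <- FALSE
      gs <- annotation$gene_starts %||% numeric(0)
      if (any(gs >= out$tss[i] - 250 & gs <= out$tss[i])) ok <- TRUE
      utr <- annotation$utr_intervals
      if (!ok && !is.null(utr) && nrow(utr) &&
          any(out$tss[i] >= utr[, 1] & out$tss[i] < utr[, 2])) ok <- TRUE
      at <- annotation$annotated_tss %||% numeric(0)
      if (!ok && any(at >= out$start[i] & at < out$end[i])) ok <- TRUE
      if (!ok) fail(i, "association")
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a tag track as bedGraph
#' @param track a \code{tag_track}
#' @param path output file
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "tag_track"))
  x <- track$counts
  nz <- which(x != 0)
  df <- data.frame(chrom = track$contig, start = nz - 1L, end = nz, value = x[nz])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a tag track (single contig)
#' @param path bedGraph file
#' @param length track length; defaults to the maximal end coordinate
#' @export
read_bedgraph <- function(path, length = NULL) {
  df <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  n <- length %||% max(df$end)
  x <- numeric(n)
  for (i in seq_len(nrow(df))) x[(df$start[i] + 1L):df$end[i]] <- df$value[i]
  new_tag_track(x, contig = df$chrom[1])
}

#' Write called clusters as BED6 (score = MAD x 1000, capped) plus full TSV
#' @param clusters data.frame from \code{\link{call_clusters}}
#' @param bed_path BED6 output path
#' @param tsv_path optional TSV with all fields
#' @export
write_clusters <- function(clusters, bed_path, tsv_path = NULL) {
  bed <- data.frame(chrom = clusters$contig, start = clusters$start,
                    end = clusters$end,
                    name = sprintf("cluster_%d", seq_len(nrow(clusters))),
                    score = pmin(round(clusters$mad * 1000), 1000000),
                    strand = "+")
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(tsv_path))
    utils::write.table(clusters, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(bed_path)
}
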