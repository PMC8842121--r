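# Motif model serialization: MEME minimal motif format for PPMs and a JSON
# dialect carrying the per-motif score threshold, enriched region, background
# and source tag. FASTA is handled through Biostrings.

#' Write PPMs in MEME minimal motif format
#'
#' @param ppms a list of \code{ppm} objects
#' @param path output file
#' @param background base distribution written to the header
#' @export
write_meme <- function(ppms, path, background = rep(0.25, 4)) {
  if (inherits(ppms, "ppm")) ppms <- list(ppms)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background), collapse = " "),
               ""), con)
  for (p in ppms) {
    stopifnot(inherits(p, "ppm"))
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       p$length), con)
    for (j in seq_len(p$length))
      writeLines(paste(sprintf("%.6f", p$mat[, j]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PPMs from a MEME minimal motif file
#'
#' @param path MEME file
#' @return named list of \code{ppm} objects
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    if (grepl("^MOTIF\\s+", ln)) {
      name <- strsplit(trimws(sub("^MOTIF", "", ln)), "\\s+")[[1]][1]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j])) j <- j + 1L
      if (j > length(lines)) stop("MEME motif '", name, "' lacks a probability matrix")
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
      rows <- lines[(j + 1L):(j + w)]
      mat <- t(vapply(rows,
                      function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                      numeric(4), USE.NAMES = FALSE))
      # rows may drift from 1 by formatting precision; renormalize
      mat <- mat / rowSums(mat)
      out[[name]] <- new_ppm(name, t(mat))
      i <- j + w
    }
    i <- i + 1L
  }
  out
}

#' Write a full motif set (PPM + PWM + threshold metadata) as JSON
#'
#' @param motif_set a \code{motif_set} (see \code{\link{gen_motifs}})
#' @param path output file
#' @export
write_motif_json <- function(motif_set, path) {
  stopifnot(inherits(motif_set, "motif_set"))
  lst <- lapply(motif_set$motifs, function(m) {
    list(name = m$ppm$name,
         ppm = unname(lapply(seq_len(m$ppm$length), function(j) m$ppm$mat[, j])),
         background = as.numeric(m$pwm$background),
         log_base = 2,
         min_score_threshold = m$pwm$min_score_threshold,
         enriched_region = m$pwm$enriched_region,
         source = m$pwm$source,
         consensus = m$consensus)
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a motif set from the JSON dialect written by \code{write_motif_json}
#' @param path JSON file
#' @return a \code{motif_set}
#' @export
read_motif_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  motifs <- lapply(lst, function(m) {
    mat <- vapply(m$ppm, function(col) as.numeric(unlist(col)), numeric(4))
    ppm <- new_ppm(m$name, mat)
    pwm <- ppm_to_pwm(ppm, background = as.numeric(unlist(m$background)),
                      enriched_region = if (is.null(m$enriched_region)) NULL else
                        as.numeric(unlist(m$enriched_region)),
                      source = m$source %||% "sequence-derived")
    pwm$min_score_threshold <- m$min_score_threshold %||% NA_real_
    list(ppm = ppm, pwm = pwm, consensus = m$consensus %||% consensus(ppm)$consensus)
  })
  names(motifs) <- vapply(motifs, function(m) m$ppm$name, character(1))
  structure(list(motifs = motifs), class = "motif_set")
}

#' Read promoter sequences from FASTA
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta_seqs <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
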