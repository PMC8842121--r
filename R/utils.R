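DNA_BASES <- c("A", "C", "G", "T")

#' Split a DNA string into a character vector of single bases
#' @param x a single character string
#' @return character vector of upper-case bases
#' @keywords internal
seq_chars <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  strsplit(toupper(x), "", fixed = TRUE)[[1]]
}

#' @keywords internal
chars_seq <- function(x) paste0(x, collapse = "")

#' Reverse complement of a DNA string (A/C/G/T/N)
#' @param x single DNA string
#' @return reverse-complemented string
#' @keywords internal
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  ch <- seq_chars(x)
  bad <- !(ch %in% names(comp))
  if (any(bad)) stop("non-IUPAC character in sequence: ", paste(unique(ch[bad]), collapse = ","))
  chars_seq(rev(unname(comp[ch])))
}

#' Map bases to integer codes A=1 C=2 G=3 T=4, N=5; error otherwise
#' @keywords internal
base_codes <- function(x) {
  ch <- seq_chars(x)
  code <- match(ch, c(DNA_BASES, "N"))
  if (anyNA(code)) {
    stop("non-IUPAC character in sequence: ",
         paste(unique(ch[is.na(code)]), collapse = ","))
  }
  code
}

#' Sample a random DNA string of i.i.d. uniform bases
#' @keywords internal
random_dna <- function(n) chars_seq(sample(DNA_BASES, n, replace = TRUE))

`%||%` <- function(a, b) if (is.null(a)) b else a
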