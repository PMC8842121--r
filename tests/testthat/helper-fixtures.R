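# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; no binary data.

fix_motifs <- gen_motifs(42)
fix_promoters <- gen_promoters(42, fix_motifs)

# a tiny handcrafted PWM: 2 columns, distinct weights per base
tiny_pwm <- new_pwm("tiny",
                    matrix(c(1, -1, 0.5, -0.5,
                             2, -2, 0.25, -0.25), nrow = 4,
                           dimnames = list(c("A", "C", "G", "T"), NULL)),
                    min_score_threshold = 0)

# brute-force window scorer used as the independent oracle for scanning
oracle_score <- function(pwm, seq, offset, strand = "+") {
  win <- substr(seq, offset + 1, offset + pwm$length)
  if (strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    win <- paste(rev(unname(comp[strsplit(win, "")[[1]]])), collapse = "")
  }
  ch <- strsplit(win, "")[[1]]
  s <- 0
  for (j in seq_along(ch)) {
    s <- s + if (ch[j] == "N") sum(pwm$background * pwm$weights[, j]) else
      pwm$weights[ch[j], j]
  }
  unname(s)
}

oracle_scan <- function(pwm, seq, threshold, both = TRUE) {
  n <- nchar(seq); L <- pwm$length
  hits <- list()
  for (st in if (both) c("+", "-") else "+") {
    for (o in 0:(n - L)) {
      sc <- oracle_score(pwm, seq, o, st)
      if (sc >= threshold) hits[[length(hits) + 1]] <- c(o, st, sc)
    }
  }
  hits
}

all_kmers <- function(L) {
  do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L)) |>
    apply(1, paste0, collapse = "")
}
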