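# Motif models: scoring, scanning, information content, consensus, log-odds
# construction.

test_that("score_window matches closed forms and the brute-force oracle", {
  zero <- new_pwm("zero", matrix(0, 4, 3), min_score_threshold = 0)
  expect_identical(score_window(zero, "ACGTACGT", 2), 0)

  # exhaustive dinucleotide scoring: max equals sum of column maxima
  scores <- vapply(all_kmers(2), function(k) score_window(tiny_pwm, k, 0), numeric(1))
  expect_equal(max(scores), sum(apply(tiny_pwm$weights, 2, max)))
  expect_equal(min(scores), sum(apply(tiny_pwm$weights, 2, min)))

  # minus-strand score equals plus-strand score of the revcomp at the mirror
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = "")
    o <- sample(0:10, 1)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(score_window(tiny_pwm, s, o, "-"),
                 score_window(tiny_pwm, rc, 12 - o - 2, "+"))
    expect_equal(score_window(tiny_pwm, s, o, "+"), oracle_score(tiny_pwm, s, o))
    expect_equal(score_window(tiny_pwm, s, o, "-"), oracle_score(tiny_pwm, s, o, "-"))
  }

  # N scores as the background expectation of its column
  expect_equal(score_window(tiny_pwm, "NA", 0),
               sum(tiny_pwm$background * tiny_pwm$weights[, 1]) +
                 unname(tiny_pwm$weights["A", 2]))

  expect_error(score_window(tiny_pwm, "ACG", 2), "out of bounds")
  expect_error(score_window(tiny_pwm, "AXGT", 0), "non-IUPAC")
})

test_that("scan finds all and only threshold-passing windows", {
  m <- fix_motifs$motifs$INR
  # impossible threshold -> empty
  hi <- sum(apply(m$pwm$weights, 2, max)) + 1
  expect_identical(nrow(scan_pwm(m$pwm, "ACGTACGTACGTACGT", region = NULL,
                                 threshold = hi)), 0L)
  # threshold -Inf returns 2*(n - L + 1) hits on both strands
  n <- 40L
  set.seed(2)
  s <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  h <- scan_pwm(m$pwm, s, region = NULL, threshold = -Inf)
  expect_identical(nrow(h), 2L * (n - m$pwm$length + 1L))

  # planted consensus in rejection-checked background: exactly one hit
  set.seed(3)
  repeat {
    bg <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
    if (nrow(scan_pwm(m$pwm, bg, region = NULL)) == 0) break
  }
  planted <- paste0(substr(bg, 1, 20), m$consensus,
                    substr(bg, 21 + m$pwm$length, 80))
  h <- scan_pwm(m$pwm, planted, region = NULL)
  expect_identical(h$offset, 20L)

  # agreement with the brute-force scan oracle at a mid threshold
  thr <- m$pwm$min_score_threshold - 5
  h2 <- scan_pwm(m$pwm, planted, region = NULL, threshold = thr)
  expect_identical(nrow(h2), length(oracle_scan(m$pwm, planted, thr)))

  # strand consistency: hits on the revcomp are mirror images
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(planted)))
  hr <- scan_pwm(m$pwm, rc, region = NULL, threshold = thr)
  L <- m$pwm$length
  mirrored <- data.frame(offset = nchar(planted) - hr$offset - L,
                         strand = ifelse(hr$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  expect_equal(sort(mirrored$offset), sort(h2$offset))

  # region outside the sequence warns and returns no rows
  expect_warning(h3 <- scan_pwm(m$pwm, "ACGTACGTAC", tss_offset = 0,
                                region = c(500, 600), threshold = -Inf),
                 "outside")
  expect_identical(nrow(h3), 0L)
})

test_that("information content follows the closed forms", {
  unif <- new_ppm("u", matrix(0.25, 4, 2))
  expect_equal(information_content(unif)$total, 0)
  point <- new_ppm("p", matrix(c(1, 0, 0, 0), 4, 1))
  expect_equal(information_content(point)$total, 2)
  half <- new_ppm("h", matrix(c(0.5, 0.5, 0, 0), 4, 1))
  expect_equal(information_content(half)$total, 1)
  expect_error(information_content(unif, c(0, 0.5, 0.25, 0.25)), "positive")
  # non-negative and bounded by 2L bits for every generated motif
  for (m in fix_motifs$motifs) {
    ic <- information_content(m$ppm)
    expect_true(all(ic$per_column >= 0))
    expect_lte(ic$total, 2 * m$ppm$length)
  }
})

test_that("consensus takes per-column argmax with flagged alphabetical ties", {
  point <- new_ppm("p", diag(4)[, c(3, 1, 4, 2)])
  expect_identical(consensus(point)$consensus, "GATC")
  tie <- new_ppm("t", matrix(0.25, 4, 1))
  cs <- consensus(tie)
  expect_identical(cs$consensus, "A")
  expect_true(cs$has_ties)
  # consensus attains the maximal PWM score (brute force over all L-mers)
  p <- new_ppm("x", cbind(c(.7, .1, .1, .1), c(.05, .6, .3, .05), c(.25, .25, .4, .1)))
  w <- ppm_to_pwm(p, pseudocount = 0.01)
  sc <- vapply(all_kmers(3), function(k) score_window(w, k, 0), numeric(1))
  expect_equal(unname(max(sc)), score_window(w, consensus(p)$consensus, 0))
})

test_that("ppm_to_pwm implements the smoothed log-odds and round-trips", {
  unif <- new_ppm("u", matrix(0.25, 4, 3))
  expect_true(all(abs(ppm_to_pwm(unif, pseudocount = 0)$weights) < 1e-12))
  point <- new_ppm("p", matrix(c(1, 0, 0, 0), 4, 1))
  w <- ppm_to_pwm(point, pseudocount = 0.01)
  expect_equal(unname(w$weights["A", 1]),
               log2((1 + 0.01 * 0.25) / (1.01 * 0.25)))
  expect_error(ppm_to_pwm(point, pseudocount = 0), "pseudocount")
  # softmax-normalizing 2^w * q recovers the smoothed PPM
  p <- fix_motifs$motifs$DRE$ppm
  w2 <- ppm_to_pwm(p, pseudocount = 0.05)
  smoothed <- (p$mat + 0.05 * 0.25) / 1.05
  expect_equal(pwm_to_ppm(w2)$mat, smoothed, tolerance = 1e-9)
})

test_that("PPM/PWM invariants are enforced", {
  expect_error(new_ppm("bad", matrix(c(0.5, 0.5, 0.5, 0), 4, 1)), "sum to 1")
  expect_error(new_ppm("bad", matrix(c(-0.1, 0.5, 0.3, 0.3), 4, 1)), ">= 0")
  expect_error(new_pwm("bad", matrix(0, 4, 2), min_score_threshold = 5),
               "outside attainable")
  expect_error(new_pwm("bad", matrix(Inf, 4, 2)), "finite")
})

test_that("iupac_ppm spreads probability over allowed bases", {
  p <- iupac_ppm("x", "TCAKTY")
  expect_identical(p$length, 6L)
  expect_equal(sum(p$mat[c("G", "T"), 4]), 0.98)
  expect_equal(unname(p$mat["A", 4]), 0.01)
  expect_equal(unname(iupac_ppm("n", "N")$mat[, 1]), rep(0.25, 4))
  expect_error(iupac_ppm("bad", "AXG"), "non-IUPAC")
})

test_that("the bundled control-plasmid core carries a scannable initiator", {
  # the moderate-activity control construct's core is documented to contain
  # an initiator; a literature-consensus INR model (TCAKTY) finds exactly
  # one high-scoring site, at the TCATTC. The construct's downstream element
  # is only represented by an unpublished 17-nt fitted matrix, so no
  # literature consensus stand-in can verify it; see the project notes.
  fa <- read_fasta_seqs(system.file("extdata", "pzq3_core.fa",
                                    package = "promlab"))
  core <- unname(fa[1])
  inr <- ppm_to_pwm(iupac_ppm("INR", "TCAKTY"), pseudocount = 0.01)
  mx <- sum(apply(inr$weights, 2, max))
  hits <- scan_pwm(inr, core, region = NULL, threshold = 0.8 * mx)
  expect_identical(nrow(hits), 1L)
  expect_identical(substr(core, hits$offset + 1, hits$offset + 6), "TCATTC")
})

test_that("MEME and JSON round trips preserve the models", {
  tmp <- tempfile(fileext = ".meme")
  write_meme(lapply(fix_motifs$motifs, `[[`, "ppm"), tmp)
  back <- read_meme(tmp)
  expect_identical(names(back), names(fix_motifs$motifs))
  for (nm in names(back))
    expect_equal(back[[nm]]$mat, fix_motifs$motifs[[nm]]$ppm$mat, tolerance = 1e-5)

  tmp2 <- tempfile(fileext = ".json")
  write_motif_json(fix_motifs, tmp2)
  back2 <- read_motif_json(tmp2)
  for (nm in names(back2$motifs)) {
    expect_equal(back2$motifs[[nm]]$ppm$mat, fix_motifs$motifs[[nm]]$ppm$mat,
                 tolerance = 1e-9)
    expect_equal(back2$motifs[[nm]]$pwm$min_score_threshold,
                 fix_motifs$motifs[[nm]]$pwm$min_score_threshold)
    expect_identical(back2$motifs[[nm]]$consensus, fix_motifs$motifs[[nm]]$consensus)
  }
})
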