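# Gene sets, MI-optimized thresholds, binary association measures,
# Z-profiles, architecture assignment, positional profiles.

make_features <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             min_expr = runif(n), max_expr = runif(n) + 1,
             mad_expression = runif(n), embryo_expr = runif(n),
             larva_expr = runif(n), female_expr = runif(n),
             adult_expr = runif(n),
             peak_class = sample(c("NP", "BP"), n, TRUE),
             tss_mad = runif(n, 0, 20), stringsAsFactors = FALSE)
}

test_that("build_gene_sets applies quantile and equality rules", {
  f <- make_features(100)
  sets <- build_gene_sets(f, stalled = c("g001", "g002", "nope"))
  expect_length(sets, 19L)  # 18 rules + stalled
  # top-10% rule on 100 distinct values -> exactly 10 members
  expect_length(sets$min_expr_high, 10L)
  expect_setequal(sets$min_expr_high,
                  f$gene_id[order(f$min_expr, decreasing = TRUE)[1:10]])
  # medhigh = top 40% of mad_expression
  expect_length(sets$mad_expression_medhigh, 40L)
  f10 <- make_features(10)
  s10 <- build_gene_sets(f10)
  expect_length(s10$mad_expression_medhigh, 4L)
  # stalled restricted to table genes
  expect_setequal(sets$stalled, c("g001", "g002"))
  # empty table -> all sets empty
  s0 <- build_gene_sets(make_features(0))
  expect_true(all(lengths(s0) == 0L))
  # constant column warns and yields an empty set
  fc <- make_features(20); fc$min_expr <- 1
  sc <- suppressWarnings(withCallingHandlers(
    build_gene_sets(fc),
    warning = function(w) expect_match(conditionMessage(w), "constant")))
  expect_length(sc$min_expr_high, 0L)
  expect_error(build_gene_sets(f, rules = list(bad = list(column = "nope",
                                                          type = "top_frac",
                                                          value = 0.1))),
               "missing column")
  # TSV round trip
  tmp <- tempfile(fileext = ".tsv")
  write_gene_sets(sets[lengths(sets) > 0], tmp)
  back <- read_gene_sets(tmp)
  expect_setequal(back$min_expr_high, sets$min_expr_high)
})

test_that("binary_mi matches the cell-sum oracle and its invariants", {
  x <- rep(c(0, 1), each = 50)
  expect_equal(binary_mi(x, x), 1)
  # exact product table -> 0
  xi <- rep(c(0, 0, 1, 1), 25); yi <- rep(c(0, 1, 0, 1), 25)
  expect_equal(binary_mi(xi, yi), 0)
  # table (40,10,10,40)
  x2 <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y2 <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  oracle <- 0
  for (a in 0:1) for (b in 0:1) {
    pab <- mean(x2 == a & y2 == b)
    oracle <- oracle + pab * log2(pab / (mean(x2 == a) * mean(y2 == b)))
  }
  expect_equal(binary_mi(x2, y2), oracle, tolerance = 1e-12)
  expect_error(binary_mi(0:1, c(0, 1, 1)), "length mismatch")
  # non-negative on random tables; zero iff the table factorizes
  set.seed(4)
  for (i in 1:100) {
    a <- rbinom(60, 1, 0.4); b <- rbinom(60, 1, 0.6)
    expect_gte(binary_mi(a, b), 0)
  }
})

test_that("binary_mcc matches the closed form", {
  x <- rep(c(0, 1), each = 20)
  expect_equal(binary_mcc(x, x), 1)
  expect_equal(binary_mcc(x, 1 - x), -1)
  x2 <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  y2 <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  expect_equal(binary_mcc(x2, y2), 0.6)
  expect_equal(binary_mcc(rep(1, 10), rbinom(10, 1, 0.5)), 0)  # zero margin
  # brute-force oracle on random tables
  set.seed(5)
  for (i in 1:100) {
    a <- rbinom(40, 1, 0.5); b <- rbinom(40, 1, 0.5)
    tp <- sum(a & b); tn <- sum(!a & !b); fp <- sum(a & !b); fn <- sum(!a & b)
    den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
    want <- if (den == 0) 0 else (tp * tn - fp * fn) / den
    expect_equal(binary_mcc(a, b), want, tolerance = 1e-12)
  }
})

test_that("optimize_threshold recovers a planted rule and handles degenerate cases", {
  expect_identical(grid_points(c(-15, 30, 0.1)), 451L)
  # noise-free planted rule: membership = score >= tau*, with a score-free
  # margin just below tau* so the planted partition is exactly representable
  set.seed(6)
  tau <- 4.3
  scores <- setNames(runif(500, tau - 5, tau + 5), sprintf("g%03d", 1:500))
  scores <- scores[scores < tau - 0.15 | scores >= tau]
  sets <- list(planted = names(scores)[scores >= tau],
               other = sample(names(scores), 100))
  m <- fix_motifs$motifs$INR
  res <- optimize_threshold(m$pwm, NULL, sets, scores = scores)
  expect_identical(res$status, "ok")
  expect_identical(res$best_set, "planted")
  expect_lte(abs(res$threshold - tau), 0.1 + 1e-9)
  # padding invariance: genes with no motif window (score -Inf) don't change it
  scores_pad <- c(scores, setNames(rep(-Inf, 50), sprintf("pad%02d", 1:50)))
  res_pad <- optimize_threshold(m$pwm, NULL, sets, scores = scores_pad)
  expect_equal(res_pad$threshold, res$threshold)
  # motif independent of all sets -> uninformative sentinel
  set.seed(7)
  sets_ind <- list(s = sample(names(scores), 250))
  best_mi <- optimize_threshold(m$pwm, NULL, sets_ind, scores = scores)
  perm99 <- quantile(replicate(50, {
    y <- as.integer(names(scores) %in% sample(names(scores), 250))
    binary_mi(as.integer(scores >= median(scores)), y)
  }), 0.99)
  if (best_mi$status == "ok") expect_lte(best_mi$mi, perm99 * 3)
})

test_that("zscore_profile follows the binomial null", {
  set.seed(8)
  pres <- rbinom(5000, 1, 0.5)
  z <- zscore_profile(pres, 50L)
  expect_identical(nrow(z), 100L)
  expect_lt(abs(mean(abs(z$z)) - sqrt(2 / pi)), 0.15)  # half-normal mean ~0.80
  expect_true(all(abs(z$z) < 4))
  # presence only in the first bin
  pres2 <- c(rep(1, 30), rep(0, 470))
  z2 <- zscore_profile(pres2, 50L)
  expect_gt(z2$z[1], 0)
  expect_true(all(z2$z[-1] < 0))
  # degenerate p = 1
  expect_warning(z3 <- zscore_profile(rep(1, 100)), "degenerate")
  expect_true(all(z3$z == 0))
  # trailing partial bin uses its own n
  z4 <- zscore_profile(rbinom(120, 1, 0.5), 50L)
  expect_identical(z4$n, c(50, 50, 20))
})

test_that("assign_architecture labels by dominant class", {
  expect_identical(assign_architecture(c("INR", "MTEDPE"))$label, "Ar1")
  expect_identical(assign_architecture(c("TCT", "RDPE"))$label, "Ar4")
  expect_identical(assign_architecture(character(0))$label, "motif-less")
  expect_identical(assign_architecture(c("INR", "TATA-Box"))$label, "mixed")
  expect_identical(assign_architecture(c("DRE", "Ohler7", "E-Box1"))$label, "Ar3.1")
  expect_error(assign_architecture("NOPE"), "unknown motif")
})

test_that("dinucleotide_profile has the documented shape and limits", {
  polyA <- strrep("A", 600)
  prof <- dinucleotide_profile(rep(polyA, 3), tss_offset = 300L, window = 500L)
  expect_identical(dim(prof), c(16L, 500L))
  expect_true(all(prof["AA", ] == 1))
  expect_true(all(colSums(prof) == 1))
  # i.i.d. uniform sequences: every frequency near 1/16
  set.seed(9)
  seqs <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), character(1))
  prof2 <- dinucleotide_profile(seqs, tss_offset = 60L, window = 100L)
  expect_true(all(abs(prof2 - 1 / 16) < 0.04))
  # too-short sequences are skipped with a count
  prof3 <- dinucleotide_profile(c(polyA, "ACGT"), tss_offset = 300L, window = 500L)
  expect_identical(attr(prof3, "skipped"), 1L)
})

test_that("site_position_histogram peaks where the sites are", {
  h <- site_position_histogram(rep(-30L, 20))
  expect_identical(attr(h, "peak"), -30L)
  # bimodal: peak at the larger mode
  h2 <- site_position_histogram(c(rep(-30L, 10), rep(5L, 25)), smoothing = 5L)
  expect_identical(attr(h2, "peak"), 5L)
  # smoothing width 1 is the raw histogram
  h3 <- site_position_histogram(c(-2L, -2L, 0L), smoothing = 1L)
  expect_equal(h3$density, c(2, 0, 1))
  h4 <- site_position_histogram(integer(0))
  expect_identical(nrow(h4), 0L)
})
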