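# The mutation design engine: annotation, every mutation family, block
# assembly, UTR sanitization, validation and clone resolution.

test_that("annotate recovers planted compositions and is idempotent", {
  p <- fix_promoters$Ar1
  expect_setequal(p$annotations$name, c("INR", "MTEDPE"))
  expect_identical(sort(p$annotations$start), c(-2L, 18L))
  # motif-less background carries zero annotations by construction
  expect_identical(nrow(fix_promoters$motifless$annotations), 0L)
  # idempotent on its own sequence
  again <- annotate(p$core, fix_motifs, id = p$id)
  expect_equal(again$annotations[, c("name", "start", "strand")],
               p$annotations[, c("name", "start", "strand")])
  expect_error(annotate("ACGT", fix_motifs), "131")
})

test_that("knockouts remove the target and leave the rest untouched", {
  p <- fix_promoters$Ar1
  for (kind in c("knockout_random", "knockout_background")) {
    spec <- list(kind = kind, targets = "INR", seed = 101,
                 params = list(background_core = fix_promoters$motifless$core))
    ko <- apply_mutation(p, spec, fix_motifs)[[1]]
    expect_identical(nchar(ko$core), 131L)
    rep <- validate_construct(ko, p, fix_motifs)
    expect_false(rep$dirty)
    expect_true(any(grepl("^INR@", rep$losses)))
    expect_identical(rep$unintended_gains, character(0))
  }
  # pairwise knockout loses both motifs
  kp <- apply_mutation(p, list(kind = "knockout_pair",
                               targets = c("INR", "MTEDPE"), seed = 102),
                       fix_motifs)[[1]]
  rec <- annotate(kp$core, fix_motifs)
  expect_identical(nrow(rec$annotations), 0L)
  # knockout_all empties every promoter with annotations
  ka <- apply_mutation(fix_promoters$Ar3, list(kind = "knockout_all", seed = 103),
                       fix_motifs)[[1]]
  expect_identical(nrow(annotate(ka$core, fix_motifs)$annotations), 0L)
  # rescan oracle: no hits above threshold anywhere in the mutated window
  for (m in fix_motifs$motifs) {
    h <- scan_pwm(m$pwm, ka$core, tss_offset = 80L, region = NULL)
    expect_identical(nrow(h), 0L)
  }
  # seeded reproducibility is bit-exact
  s <- list(kind = "knockout_random", targets = "INR", seed = 101)
  expect_identical(apply_mutation(p, s, fix_motifs)[[1]]$core,
                   apply_mutation(p, s, fix_motifs)[[1]]$core)
})

test_that("consensus replacement and insertion write the consensus", {
  p <- fix_promoters$Ar2
  cr <- apply_mutation(p, list(kind = "consensus_replace", targets = "TATA-Box"),
                       fix_motifs)[[1]]
  a <- p$annotations[p$annotations$name == "TATA-Box", ]
  L <- fix_motifs$motifs[["TATA-Box"]]$pwm$length
  expect_identical(substr(cr$core, a$start + 81, a$start + 80 + L),
                   fix_motifs$motifs[["TATA-Box"]]$consensus)
  # insertion into the motif-less promoter creates exactly the planted motif
  ins <- apply_mutation(fix_promoters$motifless,
                        list(kind = "consensus_insert", targets = "INR",
                             params = list(position = -2L)), fix_motifs)[[1]]
  rec <- annotate(ins$core, fix_motifs)
  expect_identical(rec$annotations$name, "INR")
  expect_identical(rec$annotations$start, -2L)
})

test_that("strength series lands in the requested score bins", {
  p <- fix_promoters$Ar1
  m <- fix_motifs$motifs$MTEDPE
  hi <- sum(apply(m$pwm$weights, 2, max))
  thr <- m$pwm$min_score_threshold
  bins <- rbind(c(thr - 8, thr - 4), c(thr - 4, thr), c(thr, hi), c(hi - 2, hi))
  ss <- apply_mutation(p, list(kind = "strength_series", targets = "MTEDPE",
                               params = list(bins = bins), seed = 104),
                       fix_motifs)
  expect_length(ss, nrow(bins))
  a <- p$annotations[p$annotations$name == "MTEDPE", ]
  for (i in seq_along(ss)) {
    achieved <- score_window(m$pwm, substr(ss[[i]]$core, a$start + 81,
                                           a$start + 80 + m$pwm$length), 0)
    expect_gte(achieved, bins[i, 1])
    expect_lte(achieved, bins[i, 2])
  }
})

test_that("point mutation panels cover all 3L single-base variants", {
  p <- fix_promoters$Ar3
  pm <- apply_mutation(p, list(kind = "point_mutation", targets = "DRE"),
                       fix_motifs)
  L <- fix_motifs$motifs$DRE$pwm$length  # 10 nt -> 30 variants + consensus
  expect_length(pm, 3L * L + 1L)
  a <- p$annotations[p$annotations$name == "DRE", ]
  cons <- fix_motifs$motifs$DRE$consensus
  winds <- vapply(pm, function(x) substr(x$core, a$start + 81, a$start + 80 + L),
                  character(1))
  expect_identical(unname(winds[1]), cons)
  # each variant differs from the consensus in exactly one position
  dists <- vapply(winds[-1], function(w)
    sum(strsplit(w, "")[[1]] != strsplit(cons, "")[[1]]), integer(1))
  expect_true(all(dists == 1L))
  expect_identical(anyDuplicated(winds), 0L)
})

test_that("substitution anchors the donor on the target", {
  p <- fix_promoters$Ar2
  sub <- apply_mutation(p, list(kind = "substitute", targets = "INR",
                                params = list(donor = "Ohler7",
                                              target_anchor = 3L,
                                              donor_anchor = 5L), seed = 105),
                        fix_motifs)[[1]]
  a <- p$annotations[p$annotations$name == "INR", ]
  start <- a$start + (3L - 5L)
  L <- fix_motifs$motifs$Ohler7$pwm$length
  expect_identical(substr(sub$core, start + 81, start + 80 + L),
                   fix_motifs$motifs$Ohler7$consensus)
  expect_identical(nchar(sub$core), 131L)
})

test_that("shifts move the target, keep length, and reject out-of-core moves", {
  p <- fix_promoters$Ar3
  sh <- apply_mutation(p, list(kind = "shift_motif", targets = "Ohler7",
                               params = list(deltas = c(-5L, 0L, 5L))),
                       fix_motifs)
  expect_identical(sh[[2]]$core, p$core)  # delta 0 is the identity
  for (d in c(1, 3)) {
    rec <- annotate(sh[[d]]$core, fix_motifs)
    o <- rec$annotations[rec$annotations$name == "Ohler7", ]
    dd <- attr(sh[[d]], "delta")
    expect_identical(o$start, p$annotations$start[p$annotations$name == "Ohler7"] + dd)
    # the non-target motif stays put
    dre <- rec$annotations[rec$annotations$name == "DRE", ]
    expect_identical(dre$start, p$annotations$start[p$annotations$name == "DRE"])
  }
  # joint shift moves every motif
  sha <- apply_mutation(p, list(kind = "shift_all_motifs",
                                params = list(deltas = 4L)), fix_motifs)[[1]]
  reca <- annotate(sha$core, fix_motifs)
  expect_identical(sort(reca$annotations$start),
                   sort(p$annotations$start + 4L))
  # context shift keeps the motifs fixed
  shc <- apply_mutation(p, list(kind = "shift_context",
                                params = list(deltas = 7L)), fix_motifs)[[1]]
  recc <- annotate(shc$core, fix_motifs)
  expect_identical(sort(recc$annotations$start), sort(p$annotations$start))
  # a shift pushing a motif outside -80..+50 is a design error
  expect_error(apply_mutation(p, list(kind = "shift_motif", targets = "DRE",
                                      params = list(deltas = -40L)), fix_motifs),
               "leaves the core")
})

test_that("context exchange transplants donor motifs into a host background", {
  host <- fix_promoters$Ar1
  donor <- fix_promoters$Ar3
  cx <- apply_mutation(host, list(kind = "context_exchange",
                                  params = list(donor_record = donor),
                                  seed = 106), fix_motifs)[[1]]
  rec <- annotate(cx$core, fix_motifs)
  expect_setequal(rec$annotations$name, donor$annotations$name)
  expect_identical(sort(rec$annotations$start), sort(donor$annotations$start))
})

test_that("combinatorial enumeration gives the product of pool sizes", {
  p <- fix_promoters$Ar1
  a_inr <- p$annotations[p$annotations$name == "INR", ]
  a_mte <- p$annotations[p$annotations$name == "MTEDPE", ]
  pools <- list(
    INR = list(NULL,
               list(label = "INR:ko", start = a_inr$start,
                    replacement = strrep("A", fix_motifs$motifs$INR$pwm$length)),
               list(label = "INR:cons", start = a_inr$start,
                    replacement = fix_motifs$motifs$INR$consensus)),
    MTEDPE = list(NULL,
                  list(label = "MTEDPE:cons", start = a_mte$start,
                       replacement = fix_motifs$motifs$MTEDPE$consensus)))
  combos <- enumerate_combinatorial(p, "intra", pools)
  expect_length(combos, 6L)
  # all-wild-type choice reproduces the parent
  wt <- Filter(function(x) !length(x$provenance), combos)
  expect_length(wt, 1L)
  expect_identical(wt[[1]]$core, p$core)
  # seeded subsampling is deterministic
  s1 <- enumerate_combinatorial(p, "intra", pools, n_sample = 3, seed = 9)
  s2 <- enumerate_combinatorial(p, "intra", pools, n_sample = 3, seed = 9)
  expect_identical(names(s1), names(s2))

  # inter-block: pools of sizes 4,5,4,6 -> 480 cores (the study's pool sizes)
  bl <- lapply(fix_promoters, function(x) extract_blocks(x$core))
  pools_i <- list(
    block3 = setNames(vapply(bl, `[[`, character(1), "block3"), names(bl)),
    block4 = c(vapply(bl, `[[`, character(1), "block4"),
               extra = extract_blocks(fix_promoters$Ar1$core)$block4),
    block5 = setNames(vapply(bl, `[[`, character(1), "block5"), names(bl)),
    block6 = c(vapply(bl, `[[`, character(1), "block6"),
               e1 = extract_blocks(fix_promoters$Ar2$core)$block6,
               e2 = extract_blocks(fix_promoters$Ar3$core)$block6))
  expect_identical(lengths(pools_i), c(block3 = 4L, block4 = 5L,
                                       block5 = 4L, block6 = 6L))
  inter <- enumerate_combinatorial(mode = "inter_block", pools = pools_i)
  expect_length(inter, 480L)
  expect_true(all(vapply(inter, function(x) nchar(x$core), integer(1)) == 131L))
  expect_error(enumerate_combinatorial(mode = "inter_block",
                                       pools = c(pools_i[1:3],
                                                 list(block6 = character(0)))),
               "empty")
})

test_that("assembly reproduces the printed construct lengths exactly", {
  set.seed(20)
  b1 <- random_dna(239); b2 <- random_dna(73); b7 <- random_dna(240)
  core <- fix_promoters$Ar1$core
  with7 <- assemble(b1, b2, core, b7)
  expect_identical(nchar(with7$sequence), 703L)
  without <- assemble(b1, b2, core)
  expect_identical(nchar(without$sequence), 459L)
  # coordinate round trip recovers each input block exactly
  off <- with7$offsets
  expect_identical(substr(with7$sequence, off["block1"] + 1, off["block1"] + 239), b1)
  expect_identical(substr(with7$sequence, off["core"] + 1, off["core"] + 131), core)
  expect_identical(substr(with7$sequence, off["block7"] + 1, off["block7"] + 240), b7)
  expect_error(assemble(random_dna(238), b2, core), "block1")
})

test_that("sanitize_utr rewrites only downstream ATGs", {
  expect_identical(sanitize_utr("CCCCCATGCC", 2L), "CCCCCTAGCC")
  expect_identical(sanitize_utr("CCCCCTTTCC", 2L), "CCCCCTTTCC")
  # non-overlapping left-to-right rewrite
  expect_identical(sanitize_utr("CATGATG", 0L), "CTAGTAG")
  # an ATG upstream of (or straddling) the TSS is untouched
  expect_identical(sanitize_utr("ATGCCC", 4L), "ATGCCC")
  expect_identical(sanitize_utr("CATGC", 1L), "CATGC")
  # exhaustive 6-mers downstream: output never contains ATG
  for (k in all_kmers(3)) {
    s <- paste0("C", k, k)
    expect_false(grepl("ATG", substr(sanitize_utr(s, 0L), 2, nchar(s))))
  }
})

test_that("validate_construct flags exactly the unintended changes", {
  p <- fix_promoters$Ar1
  self <- validate_construct(structure(list(id = "x", core = p$core,
                                            parent_id = p$id,
                                            provenance = character(0),
                                            specs = list(), intended = character(0)),
                                       class = "designed_construct"),
                             p, fix_motifs)
  expect_identical(self$gains, character(0))
  expect_identical(self$losses, character(0))
  expect_false(self$dirty)
  # a knockout that secretly plants a TATA-Box is dirty with gain = TATA-Box
  a <- p$annotations[p$annotations$name == "INR", ]
  bad_core <- replace_window(p$core, a$start,
                             strrep("A", fix_motifs$motifs$INR$pwm$length))
  bad_core <- replace_window(bad_core, -45L, fix_motifs$motifs[["TATA-Box"]]$consensus)
  bad <- structure(list(id = "bad", core = bad_core, parent_id = p$id,
                        provenance = "x", specs = list(), intended = "INR"),
                   class = "designed_construct")
  repb <- validate_construct(bad, p, fix_motifs)
  expect_true(repb$dirty)
  expect_true(any(grepl("^TATA-Box@", repb$unintended_gains)))
})

test_that("resolve_clone enforces 3-fold enrichment and the identity cutoff", {
  lib <- c(want = fix_promoters$Ar1$core, other = fix_promoters$Ar2$core)
  expect_identical(resolve_clone(c(setNames(60, lib["want"]), B = 20), lib)$status, "ok")
  expect_identical(resolve_clone(setNames(c(60, 20), c(lib["want"], "B")),
                                 lib)$match, "want")
  r <- resolve_clone(setNames(c(59, 20), c(lib["want"], "B")), lib)
  expect_identical(r$status, "ambiguous")
  one <- resolve_clone(setNames(10, lib["want"]), lib)
  expect_identical(one$status, "ok")
  expect_equal(one$identity, 1)
  # heavily corrupted sequence is rejected as defective
  junk <- paste(rep("A", 131), collapse = "")
  expect_identical(resolve_clone(setNames(50, junk), lib)$status, "defective")
  # a few point errors still map to the right library member
  mut <- lib[["want"]]
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  expect_identical(resolve_clone(setNames(50, mut), lib)$match, "want")
  expect_error(resolve_clone(numeric(0), lib), "empty")
})

test_that("non-insert mutations always preserve the 131-nt core", {
  p <- fix_promoters$Ar2
  specs <- list(list(kind = "knockout_random", targets = "INR", seed = 1),
                list(kind = "consensus_replace", targets = "INR"),
                list(kind = "point_mutation", targets = "TATA-Box"),
                list(kind = "shift_motif", targets = "INR",
                     params = list(deltas = c(-1L, 1L))))
  for (s in specs) {
    for (cst in apply_mutation(p, s, fix_motifs))
      expect_identical(nchar(cst$core), 131L)
  }
})
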