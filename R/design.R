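# Synthetic promoter mutation design engine. The motif-rich core promoter is
# the 131-nt region -80..+50 around the TSS (TSS = position 0); it tiles into
# block 3 (-80..-35), block 4 (-34..-10), block 5 (-9..+8) and block 6
# (+9..+50). Mutation families: motif knockouts (random or fixed motif-free
# background sequence), consensus replacement/insertion, strength series,
# saturation point mutations, substitution by functionally/positionally
# equivalent motifs, positional shifts (motif, all motifs, context), context
# exchange, and intra-/inter-architectural combinatorial libraries.

CORE_LEN <- 131L
CORE_TSS <- 80L  # 0-based index of the TSS within the core (-80..+50)

#' Core promoter block layout
#'
#' TSS-relative inclusive intervals of the core blocks plus fixed flanking
#' block lengths and the 4-nt assembly junction overhang.
#' @return list with core/block intervals and lengths
#' @export
block_layout <- function() {
  list(core = c(-80L, 50L),
       block3 = c(-80L, -35L), block4 = c(-34L, -10L),
       block5 = c(-9L, 8L), block6 = c(9L, 50L),
       block1_len = 239L, block2_len = 73L, block7_len = 240L,
       overhang_len = 4L)
}

# TSS-relative position -> 1-based core string index
tssrel_to_idx <- function(pos) as.integer(pos) + CORE_TSS + 1L

#' Extract the block 3-6 pieces of a core sequence
#' @param core 131-nt core string
#' @return named list of block sequences (block3..block6)
#' @export
extract_blocks <- function(core) {
  stopifnot(nchar(core) == CORE_LEN)
  bl <- block_layout()
  out <- lapply(c("block3", "block4", "block5", "block6"), function(b) {
    iv <- bl[[b]]
    substr(core, tssrel_to_idx(iv[1]), tssrel_to_idx(iv[2]))
  })
  names(out) <- c("block3", "block4", "block5", "block6")
  out
}

# overwrite a window of the core; TSS-relative start, length from replacement
replace_window <- function(core, tss_rel_start, replacement) {
  i <- tssrel_to_idx(tss_rel_start)
  L <- nchar(replacement)
  if (i < 1L || i + L - 1L > nchar(core))
    stop("replacement window ", tss_rel_start, "..", tss_rel_start + L - 1L,
         " leaves the core")
  paste0(substr(core, 1L, i - 1L), replacement, substr(core, i + L, nchar(core)))
}

#' Annotate core promoter motifs in a sequence
#'
#' Scans every motif model (within its enriched region, above its calibrated
#' threshold) and records all hits; overlapping hits are allowed and flagged.
#'
#' @param core_sequence 131-nt core promoter string
#' @param motif_set a \code{motif_set}
#' @param id promoter identifier
#' @param wild_type flag carried on the record
#' @param architecture optional architecture label; derived from the hits via
#'   \code{\link{assign_architecture}} when the motif names are known classes
#' @return object of class \code{promoter_record}: id, core, annotations
#'   (data.frame name, start (TSS-relative), strand, score, overlaps),
#'   architecture, wild_type
#' @export
annotate <- function(core_sequence, motif_set, id = "promoter",
                     wild_type = TRUE, architecture = NULL) {
  stopifnot(inherits(motif_set, "motif_set"))
  if (nchar(core_sequence) != CORE_LEN)
    stop("core sequence must be exactly ", CORE_LEN, " nt")
  hits <- do.call(rbind, lapply(motif_set$motifs, function(m)
    scan_pwm(m$pwm, core_sequence, sequence_id = id, tss_offset = CORE_TSS)))
  if (is.null(hits) || !nrow(hits)) {
    ann <- data.frame(name = character(), start = integer(), strand = character(),
                      score = numeric(), overlaps = logical(),
                      stringsAsFactors = FALSE)
  } else {
    lens <- vapply(hits$motif, function(nm) motif_set$motifs[[nm]]$pwm$length,
                   integer(1))
    ov <- vapply(seq_len(nrow(hits)), function(i) {
      s1 <- hits$tss_rel[i]; e1 <- s1 + lens[i]
      any(hits$tss_rel[-i] < e1 & (hits$tss_rel[-i] + lens[-i]) > s1)
    }, logical(1))
    ann <- data.frame(name = hits$motif, start = hits$tss_rel,
                      strand = hits$strand, score = hits$score, overlaps = ov,
                      stringsAsFactors = FALSE)
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
  }
  structure(list(id = id, core = core_sequence, annotations = ann,
                 architecture = architecture, wild_type = wild_type),
            class = "promoter_record")
}

#' @export
print.promoter_record <- function(x, ...) {
  cat(sprintf("promoter '%s' (%s%s): %d motif annotation(s)\n", x$id,
              x$architecture %||% "unclassified",
              if (isTRUE(x$wild_type)) ", wild type" else "",
              nrow(x$annotations)))
  if (nrow(x$annotations)) print(x$annotations)
  invisible(x)
}

new_construct <- function(id, core, parent, features, specs, intended = character(0)) {
  structure(list(id = id, core = core, parent_id = parent$id,
                 provenance = features, specs = specs, intended = intended,
                 blocks = extract_blocks(core)),
            class = "designed_construct")
}

# motif annotation row for a named target; errors if absent/ambiguous
target_annotation <- function(promoter, name) {
  rows <- promoter$annotations[promoter$annotations$name == name, , drop = FALSE]
  if (!nrow(rows)) stop("motif '", name, "' not annotated in promoter '", promoter$id, "'")
  rows[1L, , drop = FALSE]  # first (leftmost) occurrence
}

motif_len <- function(motif_set, name) motif_set$motifs[[name]]$pwm$length
max_motif_len <- function(motif_set)
  max(vapply(motif_set$motifs, function(m) m$pwm$length, integer(1)))

# is the window [start, start+len) of `core` free of any motif hit that
# overlaps it? scanned with +/-(max motif length - 1) context so boundary-
# crossing hits are seen; returns the colliding motif name or NULL
window_collision <- function(core, start, len, motif_set) {
  if (!length(motif_set$motifs)) return(NULL)
  ctx <- max_motif_len(motif_set) - 1L
  lo <- max(start - ctx, -CORE_TSS)
  hi <- min(start + len + ctx, CORE_LEN - CORE_TSS)  # exclusive, TSS-relative
  sub <- substr(core, tssrel_to_idx(lo), tssrel_to_idx(hi - 1L))
  for (m in motif_set$motifs) {
    h <- scan_pwm(m$pwm, sub, tss_offset = 0L, region = NULL)
    if (nrow(h)) {
      hs <- lo + h$offset
      if (any(hs < start + len & hs + m$pwm$length > start)) return(m$pwm$name)
    }
  }
  NULL
}

# random same-length replacement accepted only if no PWM in the set gains a
# hit overlapping the replaced window; <= max_attempts draws, then a design
# error naming a colliding PWM
knockout_window_random <- function(core, start, len, motif_set, max_attempts = 1000L) {
  last_collision <- NULL
  for (attempt in seq_len(max_attempts)) {
    cand <- replace_window(core, start, random_dna(len))
    coll <- window_collision(cand, start, len, motif_set)
    if (is.null(coll)) return(cand)
    last_collision <- coll
  }
  stop("knockout_random: rejection sampling exhausted after ", max_attempts,
       " attempts (colliding PWM: ", last_collision, ")")
}

# reassemble a core with motif placements pinned and context closing up:
# `placements` (data.frame start, seq; TSS-relative starts) occupy their
# windows, the remaining positions are filled left to right with the context
# characters (core minus the excised windows), optionally rotated
place_motifs <- function(core, excise, placements, rotate_context = 0L) {
  occupied_old <- logical(CORE_LEN)
  for (i in seq_len(nrow(excise))) {
    idx <- tssrel_to_idx(excise$start[i]) + seq_len(nchar(excise$seq[i])) - 1L
    occupied_old[idx] <- TRUE
  }
  context <- seq_chars(core)[!occupied_old]
  if (rotate_context != 0L && length(context)) {
    k <- ((-rotate_context) %% length(context))
    if (k) context <- c(context[(k + 1L):length(context)], context[seq_len(k)])
  }
  out <- character(CORE_LEN)
  occupied_new <- logical(CORE_LEN)
  for (i in seq_len(nrow(placements))) {
    L <- nchar(placements$seq[i])
    idx <- tssrel_to_idx(placements$start[i]) + seq_len(L) - 1L
    if (any(idx < 1L) || any(idx > CORE_LEN))
      stop("shift leaves the core: motif placement at ", placements$start[i])
    if (any(occupied_new[idx])) stop("motif placements overlap after shift")
    out[idx] <- seq_chars(placements$seq[i])
    occupied_new[idx] <- TRUE
  }
  free <- which(!occupied_new)
  if (length(free) != length(context)) stop("internal: context length mismatch")
  out[free] <- context
  chars_seq(out)
}

motif_seq_at <- function(core, start, len)
  substr(core, tssrel_to_idx(start), tssrel_to_idx(start) + len - 1L)

#' Apply a mutation specification to a promoter
#'
#' The design engine's central operation. \code{spec} is a list with
#' \code{kind}, \code{targets} (motif names) and kind-specific \code{params}:
#' \describe{
#'   \item{knockout_random}{same-length i.i.d.-uniform replacement of each
#'     target, rejection-checked so no motif model gains a hit overlapping the
#'     replaced window (max 1000 attempts)}
#'   \item{knockout_background}{splice of a designated motif-free background
#'     core (\code{params$background_core}) at identical TSS-relative
#'     coordinates}
#'   \item{knockout_pair}{random knockout of two targets at once}
#'   \item{knockout_all}{knockout of every annotated motif
#'     (\code{params$method} = "random" or "background")}
#'   \item{consensus_replace}{target replaced by its consensus at the native
#'     position}
#'   \item{consensus_insert}{consensus written into a motif-less core at
#'     \code{params$position} (TSS-relative start, typically the peak of the
#'     genomic site-position histogram)}
#'   \item{strength_series}{rejection-sampled replacements whose PWM scores
#'     fall in \code{params$bins} (2-column matrix lo/hi), default five bins
#'     spanning sub-threshold to the maximum}
#'   \item{point_mutation}{consensus placed at the native position, then all
#'     3L single-base variants}
#'   \item{substitute}{target knocked out, then \code{params$donor} motif
#'     placed; TSS-anchor alignment when \code{params$target_anchor} and
#'     \code{params$donor_anchor} (1-based positions within the motifs) are
#'     given, start-alignment otherwise; \code{params$donor_seq} defaults to
#'     the donor consensus}
#'   \item{shift_motif}{target excised and re-inserted at +/- delta
#'     (\code{params$deltas}), other motifs pinned, displaced context closed
#'     up; shifts leaving the core are design errors}
#'   \item{shift_all_motifs}{all annotated motifs shifted jointly}
#'   \item{shift_context}{motifs pinned, context rotated by delta}
#'   \item{context_exchange}{all host motifs knocked out, then
#'     \code{params$donor_record}'s motifs spliced in at their native
#'     TSS-relative positions}
#' }
#'
#' @param promoter a \code{promoter_record} (see \code{\link{annotate}})
#' @param spec mutation specification list (kind, targets, params, seed)
#' @param motif_set a \code{motif_set}
#' @return list of \code{designed_construct}
#' @export
apply_mutation <- function(promoter, spec, motif_set) {
  stopifnot(inherits(promoter, "promoter_record"), inherits(motif_set, "motif_set"))
  kind <- spec$kind
  params <- spec$params %||% list()
  if (!is.null(spec$seed)) set.seed(spec$seed)
  core <- promoter$core
  pid <- promoter$id
  out <- list()
  lab <- function(...) paste(pid, ..., sep = ":")

  if (kind %in% c("knockout_random", "knockout_pair")) {
    targets <- spec$targets
    if (kind == "knockout_pair" && length(targets) != 2L)
      stop("knockout_pair requires exactly two targets")
    cand <- core
    for (tg in targets) {
      a <- target_annotation(promoter, tg)
      cand <- knockout_window_random(cand, a$start, motif_len(motif_set, tg), motif_set)
    }
    id <- paste0(pid, "_ko_", paste(targets, collapse = "+"))
    out[[id]] <- new_construct(id, cand, promoter,
                               lab(targets, "knockout"), list(spec), targets)

  } else if (kind == "knockout_background") {
    bg <- params$background_core
    if (is.null(bg) || nchar(bg) != CORE_LEN)
      stop("knockout_background requires a 131-nt params$background_core")
    cand <- core
    for (tg in spec$targets) {
      a <- target_annotation(promoter, tg)
      L <- motif_len(motif_set, tg)
      cand <- replace_window(cand, a$start, motif_seq_at(bg, a$start, L))
    }
    id <- paste0(pid, "_kobg_", paste(spec$targets, collapse = "+"))
    out[[id]] <- new_construct(id, cand, promoter,
                               lab(spec$targets, "knockout_background"),
                               list(spec), spec$targets)

  } else if (kind == "knockout_all") {
    method <- params$method %||% "random"
    targets <- unique(promoter$annotations$name)
    if (!length(targets)) stop("knockout_all: promoter has no annotated motifs")
    cand <- core
    for (tg in targets) {
      a <- target_annotation(promoter, tg)
      L <- motif_len(motif_set, tg)
      cand <- if (method == "background") {
        bg <- params$background_core
        if (is.null(bg)) stop("knockout_all background method needs params$background_core")
        replace_window(cand, a$start, motif_seq_at(bg, a$start, L))
      } else {
        knockout_window_random(cand, a$start, L, motif_set)
      }
    }
    id <- paste0(pid, "_ko_all_", method)
    out[[id]] <- new_construct(id, cand, promoter, lab("all", "knockout", method),
                               list(spec), targets)

  } else if (kind == "consensus_replace") {
    for (tg in spec$targets) {
      a <- target_annotation(promoter, tg)
      cand <- replace_window(core, a$start, motif_set$motifs[[tg]]$consensus)
      id <- paste0(pid, "_cons_", tg)
      out[[id]] <- new_construct(id, cand, promoter, lab(tg, "consensus"),
                                 list(spec), tg)
    }

  } else if (kind == "consensus_insert") {
    tg <- spec$targets[1]
    pos <- params$position
    if (is.null(pos)) stop("consensus_insert requires params$position (TSS-relative start)")
    cand <- replace_window(core, pos, motif_set$motifs[[tg]]$consensus)
    id <- paste0(pid, "_ins_", tg)
    out[[id]] <- new_construct(id, cand, promoter,
                               lab(tg, "consensus_insert", pos), list(spec), tg)

  } else if (kind == "strength_series") {
    tg <- spec$targets[1]
    a <- target_annotation(promoter, tg)
    m <- motif_set$motifs[[tg]]
    L <- m$pwm$length
    lo_s <- sum(apply(m$pwm$weights, 2, min))
    hi_s <- sum(apply(m$pwm$weights, 2, max))
    thr <- m$pwm$min_score_threshold
    bins <- params$bins
    if (is.null(bins)) {
      edges <- seq(lo_s + 0.1 * (hi_s - lo_s), hi_s, length.out = 6L)
      bins <- cbind(edges[-6], edges[-1])
    }
    for (b in seq_len(nrow(bins))) {
      # redraw if the replacement creates a hit of a *different* motif
      # overlapping the window (design soundness)
      others <- motif_set
      others$motifs <- others$motifs[setdiff(names(others$motifs), tg)]
      for (attempt in 1:25) {
        repl <- sample_seq_in_bin(m, bins[b, 1], bins[b, 2],
                                  max_attempts = params$max_attempts %||% 5000L)
        cand <- replace_window(core, a$start, repl)
        if (is.null(window_collision(cand, a$start, L, others))) break
        if (attempt == 25) stop("strength_series: could not avoid creating ",
                                "other-motif hits after 25 draws")
      }
      bin_lab <- if (bins[b, 2] <= thr) "sub" else sprintf("bin%d", b)
      id <- paste0(pid, "_str_", tg, "_", b)
      out[[id]] <- new_construct(id, cand, promoter,
                                 lab(tg, "strength", bin_lab), list(spec), tg)
      attr(out[[id]], "requested_bin") <- bins[b, ]
      attr(out[[id]], "achieved_score") <- score_window(m$pwm, repl, 0L)
    }

  } else if (kind == "point_mutation") {
    tg <- spec$targets[1]
    a <- target_annotation(promoter, tg)
    cons <- motif_set$motifs[[tg]]$consensus
    L <- nchar(cons)
    base_core <- replace_window(core, a$start, cons)
    id0 <- paste0(pid, "_pm_", tg, "_consensus")
    out[[id0]] <- new_construct(id0, base_core, promoter,
                                lab(tg, "consensus"), list(spec), tg)
    cc <- seq_chars(cons)
    for (j in seq_len(L)) for (b in setdiff(DNA_BASES, cc[j])) {
      var <- cc; var[j] <- b
      cand <- replace_window(core, a$start, chars_seq(var))
      id <- paste0(pid, "_pm_", tg, "_", j, b)
      out[[id]] <- new_construct(id, cand, promoter,
                                 lab(tg, "pm", paste0(j, b)), list(spec), tg)
      attr(out[[id]], "position") <- j
      attr(out[[id]], "base") <- b
    }

  } else if (kind == "substitute") {
    tg <- spec$targets[1]
    donor <- params$donor
    if (is.null(donor)) stop("substitute requires params$donor (motif name)")
    a <- target_annotation(promoter, tg)
    Lt <- motif_len(motif_set, tg)
    donor_seq <- params$donor_seq %||% motif_set$motifs[[donor]]$consensus
    cand <- knockout_window_random(core, a$start, Lt, motif_set)
    start <- if (!is.null(params$target_anchor) && !is.null(params$donor_anchor)) {
      a$start + (params$target_anchor - params$donor_anchor)
    } else a$start
    cand <- replace_window(cand, start, donor_seq)
    id <- paste0(pid, "_sub_", tg, "to", donor)
    out[[id]] <- new_construct(id, cand, promoter,
                               lab(tg, "substitute", donor), list(spec),
                               c(tg, donor))

  } else if (kind %in% c("shift_motif", "shift_all_motifs", "shift_context")) {
    deltas <- params$deltas %||% c(-10L, -5L, -3L, -1L, 1L, 3L, 5L, 10L)
    ann <- promoter$annotations
    if (!nrow(ann)) stop(kind, ": promoter has no annotated motifs")
    lens <- vapply(ann$name, function(nm) motif_len(motif_set, nm), integer(1))
    excise <- data.frame(start = ann$start,
                         seq = vapply(seq_len(nrow(ann)), function(i)
                           motif_seq_at(core, ann$start[i], lens[i]), character(1)),
                         stringsAsFactors = FALSE)
    for (d in deltas) {
      placements <- excise
      rot <- 0L
      moved <- switch(kind,
                      shift_motif = spec$targets[1],
                      shift_all_motifs = ann$name,
                      shift_context = character(0))
      if (kind == "shift_motif") {
        i <- which(ann$name == spec$targets[1])[1]
        if (is.na(i)) stop("motif '", spec$targets[1], "' not annotated")
        placements$start[i] <- placements$start[i] + d
      } else if (kind == "shift_all_motifs") {
        placements$start <- placements$start + d
      } else {
        rot <- d
      }
      cand <- place_motifs(core, excise, placements, rotate_context = rot)
      id <- paste0(pid, "_", sub("_motif[s]?$|_context$", "", kind), "_",
                   if (kind == "shift_motif") paste0(spec$targets[1], "_") else
                     if (kind == "shift_all_motifs") "all_" else "ctx_",
                   ifelse(d >= 0, paste0("p", d), paste0("m", -d)))
      out[[id]] <- new_construct(id, cand, promoter,
                                 lab(if (kind == "shift_motif") spec$targets[1] else
                                       sub("shift_", "", kind),
                                     "shift", d),
                                 list(spec), unique(c(moved, ann$name)))
      attr(out[[id]], "delta") <- d
    }

  } else if (kind == "context_exchange") {
    donor <- params$donor_record
    if (!inherits(donor, "promoter_record"))
      stop("context_exchange requires params$donor_record (promoter_record)")
    cand <- core
    host_targets <- unique(promoter$annotations$name)
    for (tg in host_targets) {
      a <- target_annotation(promoter, tg)
      cand <- knockout_window_random(cand, a$start, motif_len(motif_set, tg), motif_set)
    }
    don_ann <- donor$annotations
    for (i in seq_len(nrow(don_ann))) {
      L <- motif_len(motif_set, don_ann$name[i])
      cand <- replace_window(cand, don_ann$start[i],
                             motif_seq_at(donor$core, don_ann$start[i], L))
    }
    id <- paste0(pid, "_ctxex_", donor$id)
    out[[id]] <- new_construct(id, cand, promoter,
                               lab("context_exchange", donor$id), list(spec),
                               unique(c(host_targets, don_ann$name)))
  } else {
    stop("unknown mutation kind: ", kind)
  }
  out
}

# rejection-sample a motif-length sequence whose PWM score lies in [lo, hi];
# proposals are drawn from tempered PPM columns (temperature sweep from
# uniform to sharply consensus-like) so every bin up to the maximum is
# reachable
sample_seq_in_bin <- function(motif, lo, hi, max_attempts = 5000L) {
  pwm <- motif$pwm; ppm <- motif$ppm
  max_score <- sum(apply(pwm$weights, 2, max))
  if (hi >= max_score - 1e-9 && lo <= max_score + 1e-9) {
    cs <- motif$consensus
    if (score_window(pwm, cs, 0L) >= lo) return(cs)
  }
  betas <- rep(seq(0, 3, length.out = 16L), length.out = max_attempts)
  for (k in seq_len(max_attempts)) {
    probs <- ppm$mat^betas[k] + 1e-9
    probs <- sweep(probs, 2, colSums(probs), "/")
    s <- chars_seq(vapply(seq_len(ppm$length), function(j)
      sample(DNA_BASES, 1L, prob = probs[, j]), character(1)))
    sc <- score_window(pwm, s, 0L)
    if (sc >= lo && sc <= hi) return(s)
  }
  stop("strength_series: no sequence found with score in [",
       round(lo, 2), ", ", round(hi, 2), "] after ", max_attempts, " attempts")
}

#' Enumerate combinatorial construct libraries
#'
#' \code{mode = "intra"}: free combination of per-motif single-mutation
#' options within one promoter. \code{pools} is a named list (one entry per
#' motif) of option lists; each option is either \code{NULL} (wild type) or
#' \code{list(label, start, replacement)}. \code{mode = "inter_block"}:
#' block-wise swaps; \code{pools} is a named list for block3..block6 of named
#' block sequence vectors (lengths 46/25/18/42).
#'
#' @param promoter a \code{promoter_record} (intra mode; ignored for
#'   inter_block)
#' @param mode "intra" or "inter_block"
#' @param pools option pools (see above)
#' @param n_sample optional seeded uniform subsample size (without
#'   replacement); default full enumeration
#' @param seed RNG seed for subsampling
#' @return list of \code{designed_construct}; each carries its feature labels
#'   in \code{provenance}
#' @export
enumerate_combinatorial <- function(promoter = NULL,
                                    mode = c("intra", "inter_block"),
                                    pools, n_sample = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(pools) || any(!vapply(pools, length, integer(1))))
    stop("empty option pool")
  sizes <- vapply(pools, length, integer(1))
  combos <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  if (!is.null(n_sample) && n_sample < nrow(combos)) {
    set.seed(seed)
    combos <- combos[sample.int(nrow(combos), n_sample), , drop = FALSE]
  }
  out <- vector("list", nrow(combos))
  if (mode == "intra") {
    stopifnot(inherits(promoter, "promoter_record"))
    for (r in seq_len(nrow(combos))) {
      core <- promoter$core
      feats <- character(0)
      for (m in seq_along(pools)) {
        opt <- pools[[m]][[combos[r, m]]]
        if (!is.null(opt)) {
          core <- replace_window(core, opt$start, opt$replacement)
          feats <- c(feats, opt$label)
        }
      }
      id <- paste0(promoter$id, "_intra_", r)
      out[[r]] <- new_construct(id, core, promoter, feats,
                                list(list(kind = "intra", choice = unlist(combos[r, ]))),
                                names(pools))
    }
  } else {
    bl <- block_layout()
    expected <- c(block3 = 46L, block4 = 25L, block5 = 18L, block6 = 42L)
    if (!all(names(pools) == names(expected)))
      stop("inter_block pools must be named block3, block4, block5, block6")
    for (b in names(pools)) {
      bad <- nchar(pools[[b]]) != expected[[b]]
      if (any(bad)) stop("pool ", b, " has sequences of wrong length (need ",
                         expected[[b]], " nt)")
    }
    parent <- list(id = "inter")
    for (r in seq_len(nrow(combos))) {
      picks <- vapply(seq_along(pools), function(m) pools[[m]][[combos[r, m]]],
                      character(1))
      core <- paste0(picks, collapse = "")
      labels <- vapply(seq_along(pools), function(m) {
        nm <- names(pools[[m]])[combos[r, m]] %||% as.character(combos[r, m])
        paste0(names(pools)[m], ":", nm)
      }, character(1))
      id <- paste0("inter_", r)
      out[[r]] <- structure(list(id = id, core = core, parent_id = "inter",
                                 provenance = labels,
                                 specs = list(list(kind = "inter_block",
                                                   choice = unlist(combos[r, ]))),
                                 intended = character(0),
                                 blocks = extract_blocks(core)),
                            class = "designed_construct")
    }
  }
  names(out) <- vapply(out, function(x) x$id, character(1))
  out
}

#' Assemble a full synthetic promoter from its building blocks
#'
#' Concatenation [ovh1, block1, ovh2, block2, ovh3, core, (ovh4, block7,)
#' ovh_end] with 4-nt junction overhangs, giving 703 nt with block 7 and
#' 459 nt without.
#'
#' @param block1 239-nt upstream (-1 nucleosome) block
#' @param block2 73-nt hormone-receptor binding block
#' @param core 131-nt core (block 3-6)
#' @param block7 optional 240-nt downstream (+1 nucleosome) block
#' @param overhangs character vector of five 4-nt junction overhangs; the
#'   defaults include the printed assembly overhangs of the receptor block
#'   and backbone junctions
#' @return list(sequence, offsets) where offsets give each block's 0-based
#'   start in the assembly
#' @export
assemble <- function(block1, block2, core, block7 = NULL,
                     overhangs = c("ATGA", "GGAT", "CCAC", "TCTG", "AATG")) {
  lens <- c(block1 = 239L, block2 = 73L, core = 131L)
  got <- c(nchar(block1), nchar(block2), nchar(core))
  bad <- which(got != lens)
  if (length(bad)) stop("assembly error: block '", names(lens)[bad[1]],
                        "' has length ", got[bad[1]], ", expected ", lens[bad[1]])
  if (!is.null(block7) && nchar(block7) != 240L)
    stop("assembly error: block 'block7' has length ", nchar(block7), ", expected 240")
  if (any(nchar(overhangs) != 4L)) stop("assembly error: overhangs must be 4 nt")
  parts <- if (is.null(block7)) {
    list(overhangs[1], block1, overhangs[2], block2, overhangs[3], core, overhangs[4])
  } else {
    list(overhangs[1], block1, overhangs[2], block2, overhangs[3], core,
         overhangs[4], block7, overhangs[5])
  }
  seqs <- unlist(parts)
  starts <- cumsum(c(0L, nchar(seqs)[-length(seqs)]))
  names(starts) <- c("ovh1", "block1", "ovh2", "block2", "ovh3", "core",
                     if (is.null(block7)) "ovh_end" else
                       c("ovh4", "block7", "ovh_end"))
  list(sequence = paste0(seqs, collapse = ""), offsets = starts)
}

#' Mutate TSS-downstream ATG codons to TAG
#'
#' Every ATG starting strictly downstream of the TSS is replaced by TAG,
#' left to right; upstream sequence (and any ATG straddling the TSS) is left
#' untouched.
#'
#' @param sequence DNA string
#' @param tss_offset 0-based TSS position within the sequence
#' @return sanitized sequence
#' @export
sanitize_utr <- function(sequence, tss_offset) {
  n <- nchar(sequence)
  if (tss_offset < 0L || tss_offset >= n) stop("tss_offset outside sequence")
  head <- substr(sequence, 1L, tss_offset + 1L)
  tail <- substr(sequence, tss_offset + 2L, n)
  paste0(head, gsub("ATG", "TAG", tail, fixed = TRUE))
}

#' Validate a designed construct against its parent
#'
#' Both sequences are scanned threshold-passing but region-free (a motif
#' created anywhere is a side effect), hits are compared at (motif, start,
#' strand) resolution, and any gain or loss whose motif is not named by the
#' construct's intended-target list is reported as unintended; the construct
#' is flagged dirty if that set is non-empty.
#'
#' @param construct a \code{designed_construct}
#' @param parent the parent \code{promoter_record}
#' @param motif_set a \code{motif_set}
#' @param intended motif names allowed to change; defaults to the
#'   construct's recorded intended set
#' @return list(gains, losses, unintended_gains, unintended_losses, dirty)
#' @export
validate_construct <- function(construct, parent, motif_set,
                               intended = construct$intended) {
  scan_all <- function(core) {
    h <- do.call(rbind, lapply(motif_set$motifs, function(m)
      scan_pwm(m$pwm, core, tss_offset = CORE_TSS, region = NULL)))
    if (is.null(h) || !nrow(h)) return(character(0))
    paste(h$motif, h$tss_rel, h$strand, sep = "@")
  }
  hp <- scan_all(parent$core)
  hc <- scan_all(construct$core)
  gains <- setdiff(hc, hp)
  losses <- setdiff(hp, hc)
  motif_of <- function(k) sub("@.*", "", k)
  un_g <- gains[!(motif_of(gains) %in% intended)]
  un_l <- losses[!(motif_of(losses) %in% intended)]
  list(gains = gains, losses = losses,
       unintended_gains = un_g, unintended_losses = un_l,
       dirty = length(un_g) + length(un_l) > 0L)
}

#' Resolve a sequenced clone against the designed library
#'
#' The most frequent observed sequence is accepted only with at least
#' 3-fold enrichment over the second most frequent (a single candidate is
#' always accepted); the accepted sequence is then globally aligned (unit
#' match/mismatch scores) to the designed library and the best identity
#' match returned, or rejected as defective below the identity cutoff.
#'
#' @param candidate_counts named numeric vector: observed sequence -> read
#'   count for one clone
#' @param designed_library named character vector of designed core sequences
#' @param min_fold enrichment requirement (default 3)
#' @param min_identity identity cutoff (default 0.95)
#' @return list(status, match, identity, fold); status one of "ok",
#'   "ambiguous", "defective"
#' @export
resolve_clone <- function(candidate_counts, designed_library,
                          min_fold = 3, min_identity = 0.95) {
  if (!length(candidate_counts)) stop("empty candidate counts")
  ord <- order(candidate_counts, decreasing = TRUE)
  top_seq <- names(candidate_counts)[ord[1]]
  fold <- if (length(candidate_counts) == 1L) Inf else
    candidate_counts[ord[1]] / candidate_counts[ord[2]]
  if (fold < min_fold)
    return(list(status = "ambiguous", match = NA_character_,
                identity = NA_real_, fold = unname(fold)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  ids <- vapply(designed_library, function(lib) {
    aln <- Biostrings::pairwiseAlignment(top_seq, lib, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1)
    Biostrings::pid(aln, type = "PID1") / 100
  }, numeric(1))
  best <- which.max(ids)
  if (ids[best] < min_identity)
    return(list(status = "defective", match = NA_character_,
                identity = unname(ids[best]), fold = unname(fold)))
  list(status = "ok", match = names(designed_library)[best],
       identity = unname(ids[best]), fold = unname(fold))
}

#' Write designed constructs as FASTA plus a manifest TSV
#'
#' @param constructs list of \code{designed_construct}
#' @param fasta_path FASTA of core sequences
#' @param manifest_path TSV manifest (id, parent, features)
#' @export
write_designs <- function(constructs, fasta_path, manifest_path) {
  seqs <- vapply(constructs, function(x) x$core, character(1))
  names(seqs) <- vapply(constructs, function(x) x$id, character(1))
  write_fasta_seqs(seqs, fasta_path)
  man <- data.frame(id = names(seqs),
                    parent = vapply(constructs, function(x) x$parent_id, character(1)),
                    features = vapply(constructs, function(x)
                      paste(x$provenance, collapse = ";"), character(1)),
                    stringsAsFactors = FALSE)
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest_path)
}
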