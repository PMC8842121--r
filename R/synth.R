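# Seeded generators for every input the pipeline consumes, with planted
# ground truth for parameter-recovery testing: motif models with calibrated
# thresholds, architecture-typical promoters assembled in motif-free
# background, dual-luciferase plate readouts under an additive log2 activity
# model with lognormal multiplicative noise, TSS tag tracks with narrow and
# broad clusters, and toy two-species binding-site alignments with tunable
# substitution rates. All generators are pure functions of (seed, spec).

#' Default synthetic motif panel specification
#'
#' Five core-promoter-element-like motifs with field-typical lengths, target
#' information contents and TSS-relative enriched regions: a strictly
#' positioned initiator and TATA-like motif, a downstream element, and two
#' broadly positioned upstream housekeeping motifs.
#' @return data.frame(name, length, target_ic, region_lo, region_hi)
#' @export
default_motif_spec <- function() {
  data.frame(name = c("INR", "TATA-Box", "MTEDPE", "DRE", "Ohler7"),
             length = c(7L, 10L, 17L, 10L, 13L),
             target_ic = c(9, 12, 16, 11, 12),
             region_lo = c(-5L, -40L, 5L, -75L, -70L),
             region_hi = c(5L, -20L, 35L, -15L, -10L),
             stringsAsFactors = FALSE)
}

# per-column probability (1-e) on the consensus base solving for a column
# relative entropy of `bits` against uniform background
column_eps_for_ic <- function(bits) {
  if (bits <= 0) return(0.75)
  if (bits >= 2) return(0)
  f <- function(e) {
    p <- c(1 - e, rep(e / 3, 3))
    sum(p[p > 0] * log2(p[p > 0] / 0.25)) - bits
  }
  stats::uniroot(f, c(1e-9, 0.749999), tol = 1e-12)$root
}

#' Generate a seeded motif set with calibrated thresholds
#'
#' Each motif gets a random consensus, per-column probabilities solving the
#' per-column information-content target (total IC within +/-10 percent of
#' the target by construction), a log-odds PWM, and a score threshold
#' calibrated so the consensus scores above it while i.i.d. background
#' windows score below.
#'
#' @param seed RNG seed
#' @param spec data.frame as \code{\link{default_motif_spec}}
#' @param background base distribution
#' @return object of class \code{motif_set}
#' @export
gen_motifs <- function(seed = 1L, spec = default_motif_spec(),
                       background = rep(0.25, 4)) {
  set.seed(seed)
  motifs <- lapply(seq_len(nrow(spec)), function(i) {
    L <- spec$length[i]
    ic <- spec$target_ic[i]
    if (ic > 2 * L) stop("infeasible information content ", ic, " bits for length ", L)
    eps <- column_eps_for_ic(ic / L)
    cons_idx <- sample.int(4L, L, replace = TRUE)
    mat <- matrix(eps / 3, 4, L)
    mat[cbind(cons_idx, seq_len(L))] <- 1 - eps
    ppm <- new_ppm(spec$name[i], mat)
    pwm <- ppm_to_pwm(ppm, background = background, pseudocount = 0.01,
                      enriched_region = c(spec$region_lo[i], spec$region_hi[i]))
    pwm <- calibrate_threshold(pwm)
    list(ppm = ppm, pwm = pwm, consensus = consensus(ppm)$consensus)
  })
  names(motifs) <- spec$name
  structure(list(motifs = motifs), class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  for (m in x$motifs)
    cat(sprintf("%-10s %2d nt  IC %5.2f bits  thr %6.2f  region %s  %s\n",
                m$ppm$name, m$ppm$length,
                information_content(m$ppm)$total,
                m$pwm$min_score_threshold,
                paste(m$pwm$enriched_region, collapse = ".."), m$consensus))
  invisible(x)
}

#' Default architecture-typical promoter placements
#'
#' TSS-relative motif start positions used when planting motifs per
#' architecture; all positions lie inside the panel's enriched regions.
#' @return named list: architecture -> data.frame(name, start)
#' @export
default_promoter_spec <- function() {
  list(Ar1 = data.frame(name = c("INR", "MTEDPE"), start = c(-2L, 18L)),
       Ar2 = data.frame(name = c("TATA-Box", "INR"), start = c(-30L, -2L)),
       Ar3 = data.frame(name = c("DRE", "Ohler7"), start = c(-55L, -35L)),
       motifless = data.frame(name = character(), start = integer()))
}

# rejection-sample a 131-nt core with no motif hits anywhere (region-free)
motif_free_core <- function(motif_set, max_attempts = 500L) {
  for (k in seq_len(max_attempts)) {
    cand <- random_dna(CORE_LEN)
    hit <- FALSE
    for (m in motif_set$motifs) {
      if (nrow(scan_pwm(m$pwm, cand, tss_offset = CORE_TSS, region = NULL))) {
        hit <- TRUE; break
      }
    }
    if (!hit) return(cand)
  }
  stop("could not sample a motif-free background core in ", max_attempts, " attempts")
}

#' Generate annotated synthetic promoters
#'
#' For each requested promoter, motif consensi are planted at
#' architecture-typical TSS-relative positions into a rejection-sampled
#' motif-free background; the result is re-annotated and accepted only when
#' the annotation equals the planted composition exactly, so the returned
#' records carry exact ground-truth annotations.
#'
#' @param seed RNG seed
#' @param motif_set a \code{motif_set}
#' @param promoter_spec named list architecture -> data.frame(name, start)
#' @param n_per_arch promoters generated per architecture
#' @return named list of \code{promoter_record}
#' @export
gen_promoters <- function(seed = 1L, motif_set = gen_motifs(seed),
                          promoter_spec = default_promoter_spec(),
                          n_per_arch = 1L) {
  set.seed(seed + 1000L)
  out <- list()
  for (arch in names(promoter_spec)) {
    placing <- promoter_spec[[arch]]
    for (k in seq_len(n_per_arch)) {
      for (attempt in 1:100) {
        core <- motif_free_core(motif_set)
        if (nrow(placing)) {
          for (i in seq_len(nrow(placing))) {
            core <- replace_window(core, placing$start[i],
                                   motif_set$motifs[[placing$name[i]]]$consensus)
          }
        }
        id <- if (n_per_arch > 1L) paste0(arch, "_", k) else arch
        rec <- annotate(core, motif_set, id = id, architecture = arch)
        ok <- nrow(rec$annotations) == nrow(placing) &&
          (!nrow(placing) ||
             (setequal(rec$annotations$name, placing$name) &&
                all(sort(rec$annotations$start) == sort(placing$start)) &&
                all(rec$annotations$strand == "+")))
        if (ok) { out[[id]] <- rec; break }
        if (attempt == 100) stop("placement conflict for architecture ", arch)
      }
    }
  }
  out
}

#' Construct a synthetic ground-truth activity model
#'
#' Activity of a construct = per-promoter baseline + sum of per-feature
#' log2 effects + pairwise interaction terms for co-occurring feature pairs;
#' hormone induction adds min(boost, ceiling - basal activity).
#'
#' @param baselines named numeric, log2 baseline per promoter/parent
#' @param effects named numeric, log2 effect per feature label
#' @param interactions named numeric, names "featureA|featureB"
#' @param boost induced log2 boost (default 3)
#' @param ceiling saturation ceiling on induced activity (default 12)
#' @param noise list(sigma_ff, sigma_ren, bg, ff2_degradation, norm_true,
#'   ren_true)
#' @return object of class \code{truth_model}
#' @export
new_truth_model <- function(baselines, effects = numeric(0),
                            interactions = numeric(0), boost = 3,
                            ceiling = 12,
                            noise = list()) {
  noise <- utils::modifyList(list(sigma_ff = 0.2, sigma_ren = 0.1, bg = 100,
                                  ff2_degradation = 1, norm_true = 9,
                                  ren_true = 2000, quench = 10), noise)
  if (length(baselines) && ceiling < max(baselines))
    stop("ceiling must be >= the maximal baseline")
  if (any(c(noise$sigma_ff, noise$sigma_ren) < 0)) stop("noise sigmas must be >= 0")
  structure(list(baselines = baselines, effects = effects,
                 interactions = interactions, boost = boost, ceiling = ceiling,
                 noise = noise), class = "truth_model")
}

#' Ground-truth activity of a construct
#' @param truth a \code{truth_model}
#' @param parent promoter/parent id (baseline lookup)
#' @param features character vector of feature labels present
#' @param induced hormone induction flag
#' @return log2 activity
#' @export
truth_activity <- function(truth, parent, features = character(0), induced = FALSE) {
  a <- unname(truth$baselines[parent])
  if (is.na(a)) stop("unknown parent '", parent, "' in truth model")
  known <- intersect(features, names(truth$effects))
  a <- a + sum(truth$effects[known])
  if (length(truth$interactions)) {
    for (nm in names(truth$interactions)) {
      pair <- strsplit(nm, "|", fixed = TRUE)[[1]]
      if (all(pair %in% features)) a <- a + truth$interactions[[nm]]
    }
  }
  if (induced) a <- a + max(0, min(truth$boost, truth$ceiling - a))
  a
}

#' Simulate dual-luciferase plates for a set of construct activities
#'
#' Each activity row is measured \code{n_replicates} times; wells are
#' distributed over plates of \code{plate_samples} sample wells, each plate
#' carrying 2 pUC19, 2 UTC, 2 pUG9 and 1 pZQ3 control wells. Signal model
#' per well: FF_true = Norm_true * REN_true * 2^activity + BG; FF1 =
#' FF_true * lognormal(sigma_ff); FF2 = FF_true * degradation * lognormal
#' for weak wells and a quench sentinel for strong wells (FF1 > 2e5 RLU);
#' REN = REN_true * lognormal(sigma_ren).
#'
#' @param activities data.frame(construct_id, activity, ecdysone)
#' @param truth a \code{truth_model} (noise and plate constants)
#' @param n_replicates replicate wells per activity row
#' @param plate_samples sample wells per plate (default 88)
#' @param seed RNG seed
#' @return data.frame of wells with the standard plate columns
#' @export
simulate_plates <- function(activities, truth, n_replicates = 3L,
                            plate_samples = 88L, seed = 1L) {
  stopifnot(inherits(truth, "truth_model"))
  set.seed(seed)
  nz <- truth$noise
  reps <- activities[rep(seq_len(nrow(activities)), each = n_replicates), , drop = FALSE]
  n <- nrow(reps)
  plate_of <- (seq_len(n) - 1L) %/% plate_samples + 1L
  lnorm <- function(k, s) if (s > 0) exp(stats::rnorm(k, -s^2 / 2, s)) else rep(1, k)
  rows <- list()
  for (p in unique(plate_of)) {
    idx <- which(plate_of == p)
    ctrl <- data.frame(role = c("pUC19", "pUC19", "UTC", "UTC", "pUG9", "pUG9", "pZQ3"),
                       activity = c(NA, NA, NA, NA, 0, 0, 1.5),
                       stringsAsFactors = FALSE)
    k_s <- length(idx); k_c <- nrow(ctrl); k <- k_s + k_c
    act <- c(reps$activity[idx], ctrl$activity)
    role <- c(rep("sample", k_s), ctrl$role)
    ren_true <- ifelse(role == "UTC", 0, nz$ren_true)
    ff_true <- ifelse(is.na(act), nz$bg, nz$norm_true * nz$ren_true * 2^act + nz$bg)
    ff1 <- ff_true * lnorm(k, nz$sigma_ff)
    strong <- ff1 > 2e5
    ff2 <- ff_true * nz$ff2_degradation * lnorm(k, nz$sigma_ff)
    ff2[strong] <- nz$quench
    ren <- ren_true * lnorm(k, nz$sigma_ren)
    rows[[p]] <- data.frame(plate = sprintf("plate%03d", p),
                            well = sprintf("%s%02d", LETTERS[(seq_len(k) - 1L) %% 8L + 1L],
                                           (seq_len(k) - 1L) %/% 8L + 1L),
                            role = role,
                            construct = c(reps$construct_id[idx], rep(NA, k_c)),
                            ecdysone = c(reps$ecdysone[idx], rep(FALSE, k_c)),
                            FF1 = ff1, FF2 = ff2, REN = ren,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a full reporter study from a feature design matrix
#'
#' Computes each construct's ground-truth activity from the truth model,
#' simulates plates (basal condition, plus induced when \code{induced}),
#' and runs the normalization pipeline.
#'
#' @param X binary feature matrix (rownames = construct ids); a row of
#'   zeros is the wild type
#' @param truth a \code{truth_model}; baselines must contain \code{parent}
#' @param parent baseline id used for every construct
#' @param n_replicates replicates per condition
#' @param seed RNG seed
#' @param induced also simulate the hormone-induced condition
#' @return list(plates, norm (from \code{\link{normalize_library}}),
#'   activities)
#' @export
simulate_study <- function(X, truth, parent, n_replicates = 3L, seed = 1L,
                           induced = FALSE) {
  ids <- rownames(X) %||% sprintf("c%04d", seq_len(nrow(X)))
  acts <- vapply(seq_len(nrow(X)), function(i)
    truth_activity(truth, parent, colnames(X)[X[i, ] != 0]), numeric(1))
  df <- data.frame(construct_id = ids, activity = acts, ecdysone = FALSE,
                   stringsAsFactors = FALSE)
  if (induced) {
    acts_i <- vapply(seq_len(nrow(X)), function(i)
      truth_activity(truth, parent, colnames(X)[X[i, ] != 0], induced = TRUE),
      numeric(1))
    df <- rbind(df, data.frame(construct_id = ids, activity = acts_i,
                               ecdysone = TRUE, stringsAsFactors = FALSE))
  }
  plates <- simulate_plates(df, truth, n_replicates = n_replicates, seed = seed)
  list(plates = plates, norm = normalize_library(plates), activities = df)
}

#' Generate TSS tag tracks with narrow and broad clusters
#'
#' One track per requested cluster (each on its own contig): \code{tags}
#' tag positions drawn uniformly from a window of width \code{spread + 1}
#' centered at the track midpoint (spread 0 puts every tag on one position,
#' giving MAD 0).
#'
#' @param seed RNG seed
#' @param spec data.frame(n_clusters, spread, tags) - one row per cluster
#'   class
#' @param track_len per-cluster contig length
#' @return list(tracks = list of \code{tag_track}, truth = data.frame(contig,
#'   spread, center))
#' @export
gen_tss_tags <- function(seed = 1L,
                         spec = data.frame(n_clusters = c(5L, 5L),
                                           spread = c(0L, 50L),
                                           tags = c(50L, 50L)),
                         track_len = 400L) {
  set.seed(seed)
  tracks <- list(); truth <- list()
  center <- track_len %/% 2L
  i <- 0L
  for (r in seq_len(nrow(spec))) {
    for (k in seq_len(spec$n_clusters[r])) {
      i <- i + 1L
      sp <- spec$spread[r]
      offs <- if (sp == 0L) rep(0L, spec$tags[r]) else
        sample.int(sp + 1L, spec$tags[r], replace = TRUE) - 1L - sp %/% 2L
      pos <- center + offs
      counts <- tabulate(pos, track_len)
      contig <- sprintf("cl_%03d", i)
      tracks[[contig]] <- new_tag_track(counts, contig = contig)
      truth[[contig]] <- data.frame(contig = contig, spread = sp,
                                    center = center, stringsAsFactors = FALSE)
    }
  }
  list(tracks = tracks, truth = do.call(rbind, truth))
}

#' Generate toy two-species binding-site alignments
#'
#' Reference sites are drawn from the motif's PPM; the aligned species-X
#' site mutates each base independently with probability \code{site_rate}
#' (to a uniformly chosen different base). Context columns (for learning the
#' substitution model) are uniform reference bases diverging at
#' \code{context_rate}.
#'
#' @param seed RNG seed
#' @param motif one entry of a \code{motif_set} (list with ppm/pwm/consensus)
#' @param n_sites number of aligned site pairs
#' @param site_rate per-base substitution probability at sites
#' @param context_rate per-base substitution probability in context columns
#' @param n_context_per_pos context pairs per motif position
#' @return list(pairs = data.frame(mel, x), context = data.frame(position,
#'   mel, x))
#' @export
gen_alignments <- function(seed = 1L, motif, n_sites = 200L, site_rate = 0.1,
                           context_rate = 0.1, n_context_per_pos = 500L) {
  stopifnot(site_rate >= 0, site_rate <= 0.75, context_rate >= 0, context_rate <= 0.75)
  set.seed(seed)
  L <- motif$ppm$length
  mutate <- function(ch, rate) {
    hit <- stats::runif(length(ch)) < rate
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA_BASES, b), 1L),
                      character(1))
    ch
  }
  mel <- vapply(seq_len(n_sites), function(i)
    chars_seq(vapply(seq_len(L), function(j)
      sample(DNA_BASES, 1L, prob = motif$ppm$mat[, j]), character(1))),
    character(1))
  x <- vapply(mel, function(s) chars_seq(mutate(seq_chars(s), site_rate)),
              character(1))
  ctx <- do.call(rbind, lapply(seq_len(L), function(j) {
    mb <- sample(DNA_BASES, n_context_per_pos, replace = TRUE)
    xb <- mutate(mb, context_rate)
    data.frame(position = j, mel = mb, x = xb, stringsAsFactors = FALSE)
  }))
  list(pairs = data.frame(mel = unname(mel), x = unname(x), stringsAsFactors = FALSE),
       context = ctx)
}
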