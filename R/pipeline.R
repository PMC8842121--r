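# Orchestration: a single JSON configuration (a YAML-compatible dialect)
# with per-stage sections drives fixture generation, promoter design, plate
# normalization, effect analytics and model fitting, writing versioned
# outputs plus a machine-readable run report. Assay constants (FF selection
# 2e5 RLU, REN bounds 300/10000, outlier cutoff 3) surface as configuration
# defaults rather than inline values.

#' Default pipeline configuration
#' @param out_dir output directory
#' @param seed global seed
#' @return nested configuration list
#' @export
default_config <- function(out_dir = tempfile("promlab_run_"), seed = 1L) {
  list(seed = seed, out_dir = out_dir,
       stages = c("make_fixtures", "design", "normalize", "effects", "fit", "report"),
       thresholds = list(ff1_strong = 2e5, ren_range = c(300, 10000),
                         outlier = 3, sd_noise_override = NULL),
       fixtures = list(n_per_arch = 1L),
       design = list(kinds = c("knockout_random", "consensus_replace")),
       simulate = list(n_replicates = 3L, sigma_ff = 0.2, sigma_ren = 0.1,
                       baseline = 4, effect_sd = 1.5))
}

#' Read a pipeline configuration from JSON
#' @param path JSON config file
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_config(), cfg)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic fixtures:
#' motif/promoter generation, mutation design, plate simulation plus
#' normalization, effect estimation, linear-model fitting, and a summary
#' report. Every output lands under \code{config$out_dir}; a run report JSON
#' records the configuration, seeds and output checksums. Reruns with an
#' identical configuration are byte-identical.
#'
#' @param config list from \code{\link{default_config}} or
#'   \code{\link{read_config}}
#' @return invisible list of stage results
#' @export
run_pipeline <- function(config = default_config()) {
  stages <- config$stages
  known <- c("make_fixtures", "design", "normalize", "effects", "fit", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("config error: unknown stage(s): ", paste(bad, collapse = ", "))
  deps <- list(design = "make_fixtures", normalize = "design",
               effects = "normalize", fit = "normalize", report = "effects")
  for (s in stages) {
    need <- deps[[s]]
    if (!is.null(need) && !need %in% stages)
      stop("config error: stage '", s, "' requires stage '", need, "'")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if ("make_fixtures" %in% stages) {
    res$motifs <- gen_motifs(config$seed)
    res$promoters <- gen_promoters(config$seed, res$motifs,
                                   n_per_arch = config$fixtures$n_per_arch)
    write_motif_json(res$motifs, file.path(config$out_dir, "motifs.json"))
    write_fasta_seqs(vapply(res$promoters, function(p) p$core, character(1)),
                     file.path(config$out_dir, "promoters.fa"))
  }

  if ("design" %in% stages) {
    constructs <- list()
    for (p in res$promoters) {
      if (!nrow(p$annotations)) next
      for (kind in config$design$kinds) {
        for (tg in unique(p$annotations$name)) {
          spec <- list(kind = kind, targets = tg, seed = config$seed)
          constructs <- c(constructs, apply_mutation(p, spec, res$motifs))
        }
      }
    }
    res$constructs <- constructs
    write_designs(constructs, file.path(config$out_dir, "designs.fa"),
                  file.path(config$out_dir, "designs.tsv"))
  }

  if ("normalize" %in% stages) {
    set.seed(config$seed)
    feats <- sort(unique(unlist(lapply(res$constructs, function(x) x$provenance))))
    parents <- unique(vapply(res$constructs, function(x) x$parent_id, character(1)))
    truth <- new_truth_model(
      baselines = stats::setNames(rep(config$simulate$baseline, length(parents)), parents),
      effects = stats::setNames(stats::rnorm(length(feats), 0,
                                             config$simulate$effect_sd), feats),
      noise = list(sigma_ff = config$simulate$sigma_ff,
                   sigma_ren = config$simulate$sigma_ren))
    acts <- data.frame(
      construct_id = vapply(res$constructs, function(x) x$id, character(1)),
      activity = vapply(res$constructs, function(x)
        truth_activity(truth, x$parent_id, x$provenance), numeric(1)),
      ecdysone = FALSE, stringsAsFactors = FALSE)
    wt <- data.frame(construct_id = parents,
                     activity = unname(truth$baselines[parents]),
                     ecdysone = FALSE)
    acts <- rbind(acts, wt)
    res$truth <- truth
    res$plates <- simulate_plates(acts, truth,
                                  n_replicates = config$simulate$n_replicates,
                                  seed = config$seed)
    res$norm <- normalize_library(res$plates,
                                  ff1_strong = config$thresholds$ff1_strong,
                                  ren_range = config$thresholds$ren_range)
    write_plate(res$plates, file.path(config$out_dir, "plates.csv"))
    utils::write.table(res$norm$measurements,
                       file.path(config$out_dir, "normalized.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("effects" %in% stages) {
    s <- res$norm$summary
    meas <- res$norm$measurements
    reps_of <- function(id) meas$x[meas$construct == id & meas$qc == "" & !is.na(meas$x)]
    eff <- lapply(res$constructs, function(cst) {
      wt <- reps_of(cst$parent_id); mt <- reps_of(cst$id)
      if (!length(wt) || !length(mt)) return(NULL)
      e <- effect_estimate(mt, wt)
      data.frame(construct = cst$id, parent = cst$parent_id,
                 delta_log2 = e$delta_log2, fold = e$fold, se = e$se, n = e$n)
    })
    res$effects <- do.call(rbind, eff[!vapply(eff, is.null, logical(1))])
    utils::write.table(res$effects, file.path(config$out_dir, "effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("fit" %in% stages) {
    X <- featurize(res$constructs)
    y_map <- stats::setNames(res$norm$summary$mean, res$norm$summary$construct)
    keep <- rownames(X) %in% names(y_map)
    fit <- fit_linear(X[keep, , drop = FALSE], unname(y_map[rownames(X)[keep]]),
                      band_sd = res$norm$sd_noise)
    res$fit <- fit
    jsonlite::write_json(
      list(features = names(fit$coefficients),
           coefficients = unname(fit$coefficients),
           p_values = unname(fit$p_values), pearson_r = fit$pearson_r,
           band_sd = fit$band_sd),
      file.path(config$out_dir, "model_card.json"), auto_unbox = TRUE, digits = NA)
  }

  if ("report" %in% stages) {
    report <- list(seed = config$seed,
                   n_promoters = length(res$promoters),
                   n_constructs = length(res$constructs),
                   sd_noise = res$norm$sd_noise,
                   fit_r = if (!is.null(res$fit)) res$fit$pearson_r else NA,
                   outputs = stats::setNames(
                     as.list(tools::md5sum(list.files(config$out_dir,
                                                      full.names = TRUE))),
                     list.files(config$out_dir)))
    jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA)
    res$report <- report
  }
  invisible(res)
}
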