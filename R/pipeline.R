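#' Pipeline configuration
#'
#' Nested configuration for the end-to-end pipeline
#' (simulate -> preprocess -> features -> select -> fuse -> report).
#' `read_pipeline_config()` loads a YAML file against this schema and
#' rejects unknown keys; one global `seed` fans out to fixed per-stage
#' seeds so every stage is independently reproducible.
#'
#' @param synth named list of [synth_config()] overrides.
#' @param features list: `de_band`, `psd_band`, `psd_scope`, `zscore`
#'   (`"global"` or `"train"`).
#' @param aso named list of [aso_config()] overrides (swarm size,
#'   iterations, ...).
#' @param fusion named list of [fusion_config()] overrides.
#' @param seed global seed.
#' @param out_dir optional artifact directory.
#' @param keep_intermediates write per-stage feature CSVs?
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(synth = list(), features = list(), aso = list(),
                            fusion = list(), seed = 1L, out_dir = NULL,
                            keep_intermediates = FALSE) {
  defaults <- list(
    synth = list(), features = list(de_band = c(0.5, 45), psd_band = c(0.01, 0.1),
                                    psd_scope = "subtask", zscore = "global"),
    aso = list(), fusion = list(), seed = 1L, out_dir = NULL,
    keep_intermediates = FALSE
  )
  cfg <- list(synth = synth, features = utils::modifyList(defaults$features, features),
              aso = aso, fusion = fusion, seed = as.integer(seed),
              out_dir = out_dir, keep_intermediates = keep_intermediates)
  check_known_keys(cfg$features, names(defaults$features), "features")
  check_known_keys(cfg$synth, names(formals(synth_config)), "synth")
  check_known_keys(cfg$aso, names(formals(aso_config)), "aso")
  check_known_keys(cfg$fusion, names(formals(fusion_config)), "fusion")
  structure(cfg, class = "pipeline_config")
}

check_known_keys <- function(x, known, section) {
  bad <- setdiff(names(x), known)
  if (length(bad) > 0) {
    abort(paste0("unknown ", section, " key(s): ", paste(bad, collapse = ", ")))
  }
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_known_keys(raw, c("synth", "features", "aso", "fusion", "seed",
                          "out_dir", "keep_intermediates"), "pipeline")
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a paired dataset, runs both preprocessing chains, extracts
#' the four feature blocks (EEG time/frequency, fNIRS time/frequency),
#' Z-scores, performs wrapper selection per modality, and evaluates the
#' standard seven-way comparison: each single-domain block, each
#' modality's selected multi-domain block, the direct-splicing baseline,
#' and the proposed progressive-learning fusion. Identical configurations
#' yield identical reports.
#'
#' @param cfg a [pipeline_config()].
#' @return list with `report` (tibble of condition/accuracy), `fusion`
#'   (the [fuse()] object), `selection` (per-modality masks), `counts`
#'   (subtask bookkeeping) and `config`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  scfg <- do.call(synth_config, c(cfg$synth, list(seed = stage_seed(cfg$seed, "synth"))))
  ds <- generate_dataset(scfg)

  eeg_sub <- preprocess_eeg(ds$eeg)
  fnirs_sub <- preprocess_fnirs(ds$nirs)

  e1 <- statistic_features(eeg_sub)
  e2 <- de_feature(eeg_sub, band = cfg$features$de_band)
  f1 <- statistic_features(fnirs_sub)
  f2 <- psd_feature(fnirs_sub, band = cfg$features$psd_band,
                    scope = cfg$features$psd_scope)

  zs <- function(fm) zscore_apply(fm, zscore_fit(fm))
  e1z <- zs(e1); e2z <- zs(e2); f1z <- zs(f1); f2z <- zs(f2)
  E <- combine_domains(e1z, e2z)
  F <- combine_domains(f1z, f2z)

  acfg_e <- do.call(aso_config, c(cfg$aso, list(seed = stage_seed(cfg$seed, "aso_eeg"))))
  acfg_f <- do.call(aso_config, c(cfg$aso, list(seed = stage_seed(cfg$seed, "aso_nirs"))))
  sel_e <- select_features(E, acfg_e)
  sel_f <- select_features(F, acfg_f)

  fcfg <- do.call(fusion_config, c(cfg$fusion, list(seed = stage_seed(cfg$seed, "fusion"))))
  cv_seed <- stage_seed(cfg$seed, "cv")
  fused <- fuse(sel_e$features, sel_f$features, fcfg)

  report <- tibble::tibble(
    condition = c("eeg_time", "eeg_freq", "eeg_multidomain",
                  "fnirs_time", "fnirs_freq", "fnirs_multidomain",
                  "direct_splice", "fusion"),
    accuracy = c(
      modality_cv_accuracy(e1z, fcfg$n_folds, cv_seed),
      modality_cv_accuracy(e2z, fcfg$n_folds, cv_seed),
      modality_cv_accuracy(sel_e$features, fcfg$n_folds, cv_seed),
      modality_cv_accuracy(f1z, fcfg$n_folds, cv_seed),
      modality_cv_accuracy(f2z, fcfg$n_folds, cv_seed),
      modality_cv_accuracy(sel_f$features, fcfg$n_folds, cv_seed),
      direct_splice_baseline(sel_e$features, sel_f$features,
                             do.call(fusion_config,
                                     c(cfg$fusion, list(seed = stage_seed(cfg$seed, "splice"))))),
      fused$mean
    )
  )

  out <- list(report = report, fusion = fused,
              selection = list(eeg = sel_e, fnirs = sel_f),
              counts = list(
                n_trials = length(unique(eeg_sub$parent_trial)),
                n_subtasks = n_trials(eeg_sub),
                n_subtasks_per_session = scfg$n_repetitions * 10L
              ),
              config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(out, e1z, e2z, f1z, f2z)
  out
}

write_pipeline_artifacts <- function(out, e1z, e2z, f1z, f2z) {
  dir.create(out$config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out$config$out_dir, f)
  readr::write_csv(out$report, p("report.csv"))
  snapshot <- unclass(out$config)
  snapshot$fusion$learners <- NULL   # closures are not serialisable config
  jsonlite::write_json(snapshot, p("config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write_selection(out$selection$eeg, p("selection_eeg.json"))
  write_selection(out$selection$fnirs, p("selection_fnirs.json"))
  if (isTRUE(out$config$keep_intermediates)) {
    write_features(e1z, p("eeg_time.csv")); write_features(e2z, p("eeg_freq.csv"))
    write_features(f1z, p("fnirs_time.csv")); write_features(f2z, p("fnirs_freq.csv"))
  }
  invisible(out)
}
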