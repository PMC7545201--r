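# File I/O, run configuration and the end-to-end pipeline with provenance.
# CSV dialect throughout: UTF-8, comma-separated, "." decimal, header row.

#' Write one spectrum as a two-column CSV (ppm descending)
#' @param s an [nmr_spectrum].
#' @param path output path.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "nmr_spectrum"))
  o <- order(s$ppm, decreasing = TRUE)
  utils::write.csv(data.frame(ppm = s$ppm[o], intensity = s$intensity[o]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column ppm/intensity CSV
#' @param path input path; columns `ppm`, `intensity`.
#' @param sample_id,matrix spectrum metadata.
#' @export
read_spectrum_csv <- function(path, sample_id, matrix) {
  if (!file.exists(path)) stop_f("spectrum file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("ppm", "intensity") %in% names(df)))
    stop_f("%s: expected columns ppm, intensity", path)
  if (anyNA(df$ppm) || anyNA(df$intensity))
    stop_f("%s: NA values (first at line %d)", path,
           which(is.na(df$ppm) | is.na(df$intensity))[1] + 1L)
  d <- diff(df$ppm)
  if (!(all(d > 0) || all(d < 0)))
    stop_f("%s: ppm column is not strictly monotonic", path)
  nmr_spectrum(df$ppm, df$intensity, sample_id, matrix)
}

#' Write a simulated cohort to disk
#'
#' Emits one `<sample_id>.csv` per spectrum plus `metadata.csv`
#' (sample_id, group, matrix) and `ground_truth.csv`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$spectra)
    write_spectrum_csv(s, file.path(dir, paste0(s$sample_id, ".csv")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a directory of spectra guided by a metadata table
#'
#' Every metadata row must have a matching `<sample_id>.csv`; spectra present
#' on disk but absent from the metadata are ignored with a warning. Row
#' order follows the metadata.
#'
#' @param dir directory of per-sample CSVs.
#' @param metadata_path CSV with columns `sample_id`, `group`, `matrix`.
#' @return list with `spectra` and `metadata`.
#' @export
read_spectra <- function(dir, metadata_path = file.path(dir, "metadata.csv")) {
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "matrix")
  if (!all(need %in% names(md)))
    stop_f("metadata needs columns %s", paste(need, collapse = ", "))
  files <- file.path(dir, paste0(md$sample_id, ".csv"))
  missing_ <- !file.exists(files)
  if (any(missing_))
    stop_f("no spectrum file for sample_id(s): %s",
           paste(md$sample_id[missing_], collapse = ", "))
  extra <- setdiff(list.files(dir, pattern = "\\.csv$"),
                   c(paste0(md$sample_id, ".csv"), "metadata.csv",
                     "ground_truth.csv"))
  if (length(extra))
    warning(sprintf("ignoring %d spectrum file(s) not in metadata: %s",
                    length(extra), paste(extra, collapse = ", ")),
            call. = FALSE)
  spectra <- lapply(seq_len(nrow(md)), function(i)
    read_spectrum_csv(files[i], md$sample_id[i], md$matrix[i]))
  list(spectra = spectra, metadata = md)
}

#' Assemble a full pipeline run configuration
#'
#' All seeds are explicit after construction; the object round-trips
#' losslessly through [write_run_config()] / [read_run_config()].
#'
#' @param profile simulated-cohort profile for [default_cohort_design()]
#'   (`"plasma"`, `"cortex"`, `"hippocampus"`), or NULL when reading spectra
#'   from `input_dir`.
#' @param input_dir directory of spectra + metadata.csv (used when
#'   `profile` is NULL).
#' @param matrix sample matrix; inferred from profile when simulating.
#' @param out_dir output directory.
#' @param bin_width bin width in ppm.
#' @param tsp_normalize apply TSP normalization after total-area (brain
#'   only; default TRUE for brain).
#' @param n_ortho,scaling model parameters.
#' @param k_folds,iterations,stratified CV parameters.
#' @param vip_threshold strict VIP cut-off for the report.
#' @param seed_simulate,seed_cv,seed_permute independent named RNG streams:
#'   changing one stage's seed leaves the others untouched.
#' @param noise_in_folds refit RSD-noise bins inside each training fold.
#' @param verbose print stage progress.
#' @return list of class `run_config`.
#' @export
run_config <- function(profile = "plasma", input_dir = NULL, matrix = NULL,
                       out_dir = tempfile("metabopls_run_"),
                       bin_width = 0.02, tsp_normalize = NULL,
                       n_ortho = 1L, scaling = "unit_variance",
                       k_folds = 10L, iterations = 100L, stratified = TRUE,
                       vip_threshold = 1.0,
                       seed_simulate = 1L, seed_cv = 2L, seed_permute = 3L,
                       noise_in_folds = TRUE, verbose = FALSE) {
  if (is.null(profile) && is.null(input_dir))
    stop_f("provide either a simulation profile or an input_dir")
  if (!is.null(profile))
    matrix <- if (profile == "plasma") "plasma" else "brain"
  if (is.null(matrix)) stop_f("matrix must be given when reading spectra")
  matrix <- match_matrix_type(matrix)
  if (is.null(tsp_normalize)) tsp_normalize <- matrix == "brain"
  cfg <- list(schema_version = 1L, profile = profile, input_dir = input_dir,
              matrix = matrix, out_dir = out_dir, bin_width = bin_width,
              tsp_normalize = tsp_normalize, n_ortho = as.integer(n_ortho),
              scaling = scaling, k_folds = as.integer(k_folds),
              iterations = as.integer(iterations), stratified = stratified,
              vip_threshold = vip_threshold,
              seed_simulate = as.integer(seed_simulate),
              seed_cv = as.integer(seed_cv),
              seed_permute = as.integer(seed_permute),
              noise_in_folds = noise_in_folds, verbose = verbose)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.integer(raw$schema_version), 1L))
    stop_f("unsupported config schema version: %s", raw$schema_version)
  do.call(run_config, raw[setdiff(names(raw), "schema_version")])
}

stage_log <- function(prov, stage, params, files = character(0)) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  c(prov, list(list(stage = stage, params = params, outputs = digests,
                    timestamp = format(Sys.time(), tz = "UTC"))))
}

#' Run the full pipeline
#'
#' Executes simulate/read -> reference -> bin -> fixed exclusions -> noise
#' detection -> normalization -> true-label and permuted-label CV ensembles
#' -> null comparison -> full-data OPLS-DA -> VIP/annotation/direction
#' report, writing every artifact plus a provenance JSON to
#' `config$out_dir`. Fails fast on invalid configurations (e.g. stratified
#' folds larger than the smallest class) before any compute.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the binned matrix, both ensembles, the
#'   comparison, the full-data model and the report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))

  # --- load or simulate -----------------------------------------------------
  if (!is.null(config$profile)) {
    design <- default_cohort_design(config$profile,
                                    seed = config$seed_simulate)
    if (config$stratified &&
        min(design$n_group_a, design$n_group_b) < config$k_folds)
      stop_f(paste0("stratified %d-fold CV impossible: smallest group has ",
                    "%d samples; lower k_folds"), config$k_folds,
             min(design$n_group_a, design$n_group_b))
    cohort <- simulate_cohort(design)
    spectra <- cohort$spectra
    metadata <- cohort$metadata
  } else {
    inp <- read_spectra(config$input_dir)
    spectra <- inp$spectra
    metadata <- inp$metadata
    cohort <- NULL
  }
  groups <- metadata$group
  counts <- table(groups)
  if (length(counts) != 2L)
    stop_f("pipeline needs exactly two groups, got: %s",
           paste(names(counts), collapse = ", "))
  if (config$stratified && any(counts < config$k_folds))
    stop_f(paste0("stratified %d-fold CV impossible: smallest group has %d",
                  " samples; lower k_folds"), config$k_folds, min(counts))
  positive <- metadata$group[!duplicated(metadata$group)][2]

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list()

  # --- processing -----------------------------------------------------------
  say("referencing %d spectra", length(spectra))
  spectra <- lapply(spectra, reference_spectrum)
  bm <- bin_cohort(spectra, metadata, width = config$bin_width)
  policy <- default_exclusion_policy(config$matrix)
  bm <- apply_exclusions(bm, policy)
  bm <- detect_noise_bins(bm, policy)
  bm <- normalize_bins(bm, "total_area")
  if (isTRUE(config$tsp_normalize)) bm <- normalize_bins(bm, "tsp")
  say("binned matrix: %d x %d (%d retained)", nrow(bm$values),
      length(bm$labels), sum(!bm$excluded & !bm$noise))

  binned_path <- file.path(config$out_dir, "binned_matrix.csv")
  utils::write.csv(data.frame(sample_id = bm$sample_ids, group = bm$groups,
                              bm$values, check.names = FALSE),
                   binned_path, row.names = FALSE)
  mask_path <- file.path(config$out_dir, "bin_mask.csv")
  utils::write.csv(data.frame(bin = bm$labels, excluded = bm$excluded,
                              reason = bm$reason, noise = bm$noise),
                   mask_path, row.names = FALSE)
  prov <- stage_log(prov, "process",
                    list(bin_width = config$bin_width,
                         matrix = config$matrix,
                         normalization = bm$normalization),
                    c(binned_path, mask_path))

  # --- ensembles ------------------------------------------------------------
  X <- model_matrix(bm, drop_noise = !config$noise_in_folds)
  np <- if (config$noise_in_folds) policy else NULL
  cfg_cv <- cv_config(k_folds = config$k_folds,
                      iterations = config$iterations,
                      stratified = config$stratified,
                      n_ortho = config$n_ortho, scaling = config$scaling,
                      seed = config$seed_cv, noise_policy = np,
                      positive_class = positive)
  say("true-label ensemble (%d iterations)", config$iterations)
  obs <- ensemble_cv(X, groups, cfg_cv)
  cfg_null <- cfg_cv
  cfg_null$seed <- config$seed_permute
  say("permuted-label ensemble (%d iterations)", config$iterations)
  null <- permutation_null(X, groups, cfg_null)
  cmp <- compare_to_null(obs, null)

  ens_path <- file.path(config$out_dir, "ensembles.json")
  jsonlite::write_json(list(
    true = list(iterations = obs$iterations, summary = obs$summary),
    permuted = list(iterations = null$iterations, summary = null$summary),
    comparison = list(delta = as.list(cmp$delta),
                      p_accuracy = cmp$p_accuracy)),
    ens_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  ens_csv <- file.path(config$out_dir, "ensemble_iterations.csv")
  utils::write.csv(rbind(cbind(label_mode = "true", obs$iterations),
                         cbind(label_mode = "permuted", null$iterations)),
                   ens_csv, row.names = FALSE)
  prov <- stage_log(prov, "discriminate",
                    list(k_folds = config$k_folds,
                         iterations = config$iterations,
                         n_ortho = config$n_ortho, scaling = config$scaling,
                         seed_cv = config$seed_cv,
                         seed_permute = config$seed_permute),
                    c(ens_path, ens_csv))

  # --- report ---------------------------------------------------------------
  Xfull <- model_matrix(bm, drop_noise = TRUE)
  model <- fit_opls_da(Xfull, groups, n_ortho = config$n_ortho,
                       scaling = config$scaling, positive_class = positive)
  report <- discriminant_report(bm, groups, model,
                                vip_threshold = config$vip_threshold,
                                positive_class = positive)
  rep_csv <- file.path(config$out_dir, "discriminant_report.csv")
  rep_md <- file.path(config$out_dir, "discriminant_report.md")
  write_report(report, rep_csv, rep_md)
  prov <- stage_log(prov, "report",
                    list(vip_threshold = config$vip_threshold),
                    c(rep_csv, rep_md))

  prov_path <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(list(
    tool = "metabopls",
    version = as.character(utils::packageVersion("metabopls")),
    config = unclass(config), stages = prov),
    prov_path, auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(binned = bm, observed = obs, null = null, comparison = cmp,
                 model = model, report = report, metadata = metadata,
                 cohort = cohort, out_dir = config$out_dir))
}
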