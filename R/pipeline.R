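# Cohort bookkeeping, run configuration and the end-to-end pipeline driver:
# prep-microbiome -> dual regression -> linked ICA -> component report.

#' Read a cohort manifest
#'
#' TSV with columns `subject_id`, `exclusion_reason` (`none` or one of
#' `depression_score`, `missing_feces`, `movement_gt_4mm`) and optionally
#' `fmri_path`.
#'
#' @param path TSV file.
#' @return data.frame manifest.
#' @export
read_cohort_manifest <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("subject_id", "exclusion_reason") %in% names(df))) {
    stop("manifest needs subject_id and exclusion_reason columns")
  }
  df
}

#' Apply the cohort exclusion rules
#'
#' Removes every subject carrying an exclusion reason (high depression score,
#' missing feces sample, or movement exceeding 4 mm between acquisitions)
#' and reports the bookkeeping, reproducing the enrolled-to-included
#' arithmetic of the study design.
#'
#' @param manifest data.frame from [read_cohort_manifest()] (or equivalent).
#' @return character vector of included subject ids, with attributes
#'   `n_enrolled`, `n_excluded` and `reasons` (a table).
#' @export
apply_exclusions <- function(manifest) {
  reasons_ok <- c("none", "", "depression_score", "missing_feces", "movement_gt_4mm")
  rs <- manifest$exclusion_reason
  rs[is.na(rs)] <- "none"
  if (any(grepl("[;,]", rs))) {
    stop("excluded subjects must carry exactly one exclusion reason: ",
         paste(manifest$subject_id[grepl("[;,]", rs)], collapse = ", "))
  }
  bad <- !rs %in% reasons_ok
  if (any(bad)) {
    stop("unknown exclusion reason(s): ", paste(unique(rs[bad]), collapse = ", "))
  }
  excluded <- !(rs %in% c("none", ""))
  included <- manifest$subject_id[!excluded]
  if (length(included) == 0L) warning("all subjects excluded")
  message(sprintf("cohort: %d enrolled, %d excluded (%s), %d included",
                  nrow(manifest), sum(excluded),
                  paste(sprintf("%s: %d", names(table(rs[excluded])),
                                table(rs[excluded])), collapse = ", "),
                  length(included)))
  structure(included,
            n_enrolled = nrow(manifest), n_excluded = sum(excluded),
            reasons = table(rs[excluded]))
}

#' Default run configuration
#'
#' All stage parameters of the pipeline in one list, serializable to a single
#' YAML file; re-running from the serialized config is bit-identical.
#'
#' @param ... overrides of the defaults.
#' @return a named list (class `run_config`).
#' @export
run_config <- function(...) {
  cfg <- list(
    out_dir = "gblica-run",
    seed = 1L,
    counts_table = NULL,
    template_file = NULL,
    subject_manifest = NULL,
    min_prevalence = 0.30,
    prep_order = "filter-first",
    networks = NULL,            # NULL = all templates
    output_stat = "z",
    n_components = 10L,
    max_iter = 1000L,
    tol = 1e-6,
    select_threshold = 0.2,
    dominance_threshold = 0.5,
    brain_z = 3.0,
    micro_z = 2.3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  structure(modifyList(cfg, over, keep.null = TRUE), class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()] list.
#' @param path YAML file path.
#' @return `path` (write) or the config list (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(config), tf)
  unname(tools::md5sum(tf))
}

# TSV writer with a header comment carrying the config hash.
write_stage_tsv <- function(mat, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  rn <- !is.null(rownames(mat))
  write.table(as.data.frame(mat), con, sep = "\t", quote = FALSE,
              row.names = rn, col.names = if (rn) NA else TRUE)
}

#' Write a synthetic cohort to disk in pipeline input formats
#'
#' Materializes a [make_joint_dataset()] cohort as the files the pipeline
#' driver consumes: a 4D template NIfTI, per-subject 4D fMRI NIfTI volumes,
#' a TSV genus count table, a subject manifest, ground-truth TSV matrices
#' and a YAML parameter manifest.
#'
#' @param cohort a `synthetic_cohort` generated with `timepoints` set and
#'   `depth` set (so fMRI volumes and counts exist).
#' @param dir output directory.
#' @return `dir`, invisibly; files are named `templates.nii.gz`,
#'   `sub*_fmri.nii.gz`, `counts.tsv`, `manifest.tsv`, `truth_*.tsv`,
#'   `params.yaml`.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$fmri)) stop("cohort has no fMRI volumes; regenerate with timepoints set")
  if (is.null(cohort$counts)) stop("cohort has no count table; regenerate with depth set")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_templates(cohort$templates, file.path(dir, "templates.nii.gz"))
  grid <- cohort$templates$grid
  fmri_paths <- character(length(cohort$subject_ids))
  for (r in seq_along(cohort$subject_ids)) {
    f <- cohort$fmri[[r]]
    arr <- array(f, dim = c(grid, ncol(f)))
    fmri_paths[r] <- file.path(dir, sprintf("%s_fmri.nii.gz", cohort$subject_ids[r]))
    RNifti::writeNifti(RNifti::asNifti(arr), fmri_paths[r])
  }
  write_abundance(cohort$counts, file.path(dir, "counts.tsv"))
  manifest <- data.frame(subject_id = cohort$subject_ids,
                         exclusion_reason = "none",
                         fmri_path = fmri_paths)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$truth$H_true, file.path(dir, "truth_H.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(cohort$truth$lambda_true, file.path(dir, "truth_lambda.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  yaml::write_yaml(list(n_subjects = length(cohort$subject_ids),
                        n_genera = length(cohort$genus_ids),
                        grid_shape = as.integer(cohort$grid_shape),
                        n_networks = length(cohort$network_maps),
                        n_components = nrow(cohort$truth$H_true),
                        noise_sd = cohort$truth$noise_sd,
                        seed = cohort$truth$seed),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Run the full pipeline from a configuration
#'
#' Chains the stages: cohort exclusions, microbiome preparation, dual
#' regression, linked-ICA fit, and component reporting; writes all stage
#' outputs, the effective config and a run log under `config$out_dir`.
#' Subjects are aligned across modalities by id intersection with a hard
#' failure (naming the differing subjects) on mismatch.
#'
#' @param config a [run_config()] list or the path to its YAML serialization.
#' @return invisibly, a list with `model`, `P`, `reports`, `included`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (f in c("counts_table", "template_file", "subject_manifest")) {
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]])) stop("stage input missing: ", f, " = ", config[[f]])
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  }
  cat(sprintf("gblica %s run, config_hash %s\n",
              as.character(utils::packageVersion("gblica")), hash),
      file = logf)
  for (f in c("counts_table", "template_file", "subject_manifest")) {
    log_line("inputs", sprintf("%s = %s (md5 %s)", f, config[[f]],
                               unname(tools::md5sum(config[[f]]))))
  }
  log_line("config", paste(names(unclass(config)),
                           vapply(unclass(config), function(x)
                             paste(format(x), collapse = ","), ""),
                           sep = "=", collapse = "; "))

  stage <- "exclusions"
  res <- tryCatch({
    manifest <- read_cohort_manifest(config$subject_manifest)
    included <- suppressMessages(apply_exclusions(manifest))
    log_line(stage, sprintf("%d of %d subjects included",
                            length(included), nrow(manifest)))

    stage <- "prep-microbiome"
    counts <- read_abundance(config$counts_table)
    comp <- prepare_microbiome(counts, min_prevalence = config$min_prevalence,
                               order = config$prep_order)
    missing_comp <- setdiff(included, comp$sample_ids)
    if (length(missing_comp)) {
      stop("included subjects absent from the count table: ",
           paste(missing_comp, collapse = ", "))
    }
    comp_m <- comp$relabund[included, , drop = FALSE]
    log_line(stage, sprintf("%d genera retained at prevalence >= %g",
                            ncol(comp_m), config$min_prevalence))

    stage <- "dualreg"
    templates <- read_templates(config$template_file)
    select <- config$networks %||% templates$network_names
    man_inc <- manifest[match(included, manifest$subject_id), ]
    if (is.null(man_inc$fmri_path)) stop("manifest lacks fmri_path column")
    fmri <- lapply(man_inc$fmri_path, read_fmri)
    maps <- run_dual_regression(templates, fmri, select = select,
                                output = config$output_stat,
                                subject_ids = included)
    log_line(stage, sprintf("networks: %s; mask excludes %d voxels",
                            paste(select, collapse = ","),
                            sum(!maps[[1]]$mask)))

    stage <- "fit"
    modalities <- c(lapply(maps, function(m) t(m$maps)), list(t(comp_m)))
    names(modalities) <- c(select, "microbiome")
    input <- standardize_modalities(modalities, subject_ids = included)
    model <- fit_lica(input, n_components = config$n_components,
                      max_iter = config$max_iter, tol = config$tol,
                      seed = config$seed)
    P <- contribution_fractions(model)
    log_line(stage, sprintf("%d components, %d iterations, converged=%s",
                            model$n_components, model$n_iter, model$converged))

    stage <- "report"
    reports <- component_reports(model,
                                 select_threshold = config$select_threshold,
                                 dominance_threshold = config$dominance_threshold,
                                 brain_z = config$brain_z,
                                 micro_z = config$micro_z)
    render_report(reports, model, file.path(config$out_dir, "report"),
                  grid = templates$grid)
    write_stage_tsv(model$H, file.path(config$out_dir, "H.tsv"), hash)
    write_stage_tsv(model$lambda, file.path(config$out_dir, "lambda.tsv"), hash)
    write_stage_tsv(as.matrix(P), file.path(config$out_dir, "P.tsv"), hash)
    write_stage_tsv(matrix(model$beta, ncol = 1,
                           dimnames = list(model$modality_names, "beta")),
                    file.path(config$out_dir, "beta.tsv"), hash)
    write_run_config(config, file.path(config$out_dir, "config_used.yaml"))
    log_line(stage, "done")
    list(model = model, P = P, reports = reports, included = included,
         out_dir = config$out_dir)
  }, error = function(e) {
    log_line(stage, paste("ERROR:", conditionMessage(e)))
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(res)
}
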