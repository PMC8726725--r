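# Component selection, quality control and reporting: the rules by which
# joint components are kept (non-marginal contribution of both microbiome
# and brain), discarded (single-subject dominance, constant brain maps), and
# displayed (thresholded standardized loadings).

#' Select components with non-marginal contribution on both sides
#'
#' A component is selected iff its microbiome contribution fraction exceeds
#' `threshold` AND the summed contribution over all brain-network modalities
#' exceeds `threshold` (the non-marginal > 0.2 rule). Per-network exceedance
#' flags are also returned so the per-network reading is inspectable.
#'
#' @param P a [contribution_fractions()] matrix (modality x component);
#'   microbiome row identified by `micro_modality`.
#' @param threshold marginality threshold, default 0.2.
#' @param micro_modality index or name of the microbiome row (default: the
#'   row named "microbiome", else the last row).
#' @return data.frame with columns `component`, `micro_fraction`,
#'   `brain_fraction`, `selected`, plus one logical `above_<network>` column
#'   per brain modality.
#' @export
select_components <- function(P, threshold = 0.2, micro_modality = NULL) {
  P <- as.matrix(P)
  if (is.null(micro_modality)) {
    micro_modality <- if ("microbiome" %in% rownames(P)) "microbiome" else nrow(P)
  }
  if (is.character(micro_modality)) micro_modality <- match(micro_modality, rownames(P))
  brain_rows <- setdiff(seq_len(nrow(P)), micro_modality)
  micro <- P[micro_modality, ]
  brain <- colSums(P[brain_rows, , drop = FALSE])
  out <- data.frame(component = seq_len(ncol(P)),
                    micro_fraction = micro, brain_fraction = brain,
                    selected = micro > threshold & brain > threshold,
                    row.names = NULL)
  for (k in brain_rows) {
    nm <- rownames(P)[k] %||% paste0("mod", k)
    out[[paste0("above_", nm)]] <- P[k, ] > threshold
  }
  out
}

#' Single-subject dominance of a component
#'
#' Fraction of a component's loading energy carried by its largest-loading
#' subject: `max_r H[c, r]^2 / sum_r H[c, r]^2`. A component dominated by a
#' single subject is an artifact and is disregarded.
#'
#' @param model a fitted [fit_lica()] model.
#' @param component component index.
#' @param flag_threshold dominance above which the component is flagged
#'   (default 0.5).
#' @return list with `dominance`, `dominant_subject` (id), `flagged`.
#' @export
subject_dominance <- function(model, component, flag_threshold = 0.5) {
  stopifnot(inherits(model, "lica_model"),
            component >= 1, component <= model$n_components)
  h <- model$H[component, ]
  tot <- sum(h^2)
  if (tot <= 1e-300) stop(sprintf("component %d has an all-zero loading row", component))
  dom <- max(h^2) / tot
  list(dominance = dom,
       dominant_subject = model$subject_ids[which.max(h^2)],
       flagged = dom > flag_threshold)
}

#' Flag a (numerically) constant brain source map
#'
#' Flags component `component` in brain modality `modality` when the variance
#' of its source column across voxels is below `rel_var_threshold` times the
#' mean column variance of that modality — i.e. the map is equal-valued to
#' numerical precision, which renders interpretation impossible.
#'
#' @param model a fitted [fit_lica()] model.
#' @param modality brain modality index.
#' @param component component index.
#' @param rel_var_threshold relative variance threshold, default 1e-8.
#' @return logical flag.
#' @export
flag_constant_map <- function(model, modality, component, rel_var_threshold = 1e-8) {
  stopifnot(inherits(model, "lica_model"))
  Sk <- model$S[[modality]]
  col_var <- apply(Sk, 2, var)
  ref <- mean(col_var)
  if (ref <= 0) return(TRUE)
  col_var[component] < rel_var_threshold * ref
}

#' Threshold standardized component loadings for display
#'
#' Each source column is standardized to mean 0, sd 1 over its features
#' ("standardized loading z"; not a model-posterior z), then entries with
#' |z| above the modality-appropriate threshold are reported with their sign
#' (positive = more abundant / stronger connectivity with higher component
#' loading). Brain maps use z > 3, microbiome loadings z > 2.3 (sparser),
#' both two-sided. Constant columns are routed to [flag_constant_map()] and
#' yield no thresholded entries.
#'
#' @param model a fitted [fit_lica()] model.
#' @param brain_z,micro_z display thresholds (defaults 3.0 and 2.3).
#' @param micro_modality index of the microbiome modality (default: named
#'   "microbiome", else the last).
#' @return list of per-component `component_report` lists with fields
#'   `component_id`, `thresholded` (per modality, a data.frame of feature,
#'   z, sign), and `constant_map_flags`.
#' @export
threshold_loadings <- function(model, brain_z = 3.0, micro_z = 2.3,
                               micro_modality = NULL) {
  stopifnot(inherits(model, "lica_model"))
  K <- length(model$S)
  if (is.null(micro_modality)) {
    micro_modality <- match("microbiome", model$modality_names)
    if (is.na(micro_modality)) micro_modality <- K
  }
  lapply(seq_len(model$n_components), function(c) {
    thr_list <- setNames(vector("list", K), model$modality_names)
    const_flags <- logical(K)
    for (k in seq_len(K)) {
      s <- model$S[[k]][, c]
      const_flags[k] <- k != micro_modality && flag_constant_map(model, k, c)
      if (sd(s) <= 0 || const_flags[k]) {
        thr_list[[k]] <- data.frame(feature = character(0), z = numeric(0),
                                    sign = character(0))
        next
      }
      z <- (s - mean(s)) / sd(s)
      thr <- if (k == micro_modality) micro_z else brain_z
      keep <- abs(z) > thr
      ids <- rownames(model$S[[k]]) %||% sprintf("f%04d", seq_along(s))
      thr_list[[k]] <- data.frame(feature = ids[keep], z = z[keep],
                                  sign = ifelse(z[keep] > 0, "+", "-"),
                                  row.names = NULL)
    }
    structure(list(component_id = c, thresholded = thr_list,
                   constant_map_flags = const_flags[-micro_modality]),
              class = "component_report")
  })
}

#' Build full per-component reports
#'
#' Combines contribution fractions, the selection rule, subject-dominance
#' and constant-map QC, and thresholded loadings into one report object per
#' component.
#'
#' @param model a fitted [fit_lica()] model.
#' @param select_threshold marginality threshold (default 0.2).
#' @param dominance_threshold dominance flag threshold (default 0.5).
#' @param brain_z,micro_z display thresholds (defaults 3.0, 2.3).
#' @return list of `component_report` lists, one per component, each with
#'   `component_id`, `P_column`, `selected`, `dominance`, `dominant_subject`,
#'   `dominance_flag`, `constant_map_flags`, `thresholded`.
#' @export
component_reports <- function(model, select_threshold = 0.2,
                              dominance_threshold = 0.5,
                              brain_z = 3.0, micro_z = 2.3) {
  P <- contribution_fractions(model)
  sel <- select_components(P, threshold = select_threshold)
  thr <- threshold_loadings(model, brain_z = brain_z, micro_z = micro_z)
  lapply(seq_len(model$n_components), function(c) {
    dom <- subject_dominance(model, c, flag_threshold = dominance_threshold)
    rep_c <- thr[[c]]
    rep_c$P_column <- setNames(P[, c], rownames(P))
    rep_c$selected <- sel$selected[c]
    rep_c$dominance <- dom$dominance
    rep_c$dominant_subject <- dom$dominant_subject
    rep_c$dominance_flag <- dom$flagged
    rep_c
  })
}

# Digest name in network-Genus+/-Genus- style, e.g. "NET01-Blautia+-Prevotella-"; falls back to
# a note when nothing survives thresholding.
digest_name <- function(report, micro_name = "microbiome") {
  bn <- setdiff(names(report$P_column), micro_name)
  nets <- bn[report$P_column[bn] > 0.2]
  gen <- report$thresholded[[micro_name]]
  gpart <- if (is.null(gen) || nrow(gen) == 0) {
    "no genus loadings above threshold"
  } else {
    gen <- gen[order(-abs(gen$z)), , drop = FALSE]
    paste0(gen$feature, ifelse(gen$z > 0, "+", "-"), collapse = "-")
  }
  npart <- if (length(nets)) paste(nets, collapse = "-") else "no-network"
  paste(npart, gpart, sep = ": ")
}

#' Render component reports to files
#'
#' Writes, under `dir`: per-component TSVs of signed supra-threshold genus
#' loadings, 4D NIfTI volumes of thresholded brain maps per network (when a
#' grid is supplied), a contribution summary TSV (components x modalities,
#' the stacked-fraction table), a JSON machine-readable summary, and a plain
#' text digest naming each component.
#'
#' @param reports output of [component_reports()].
#' @param model the fitted model the reports came from.
#' @param dir output directory (created if needed).
#' @param grid optional 3-vector; brain source maps are exported as NIfTI
#'   with supra-threshold voxels carrying their z value and others zero.
#' @param micro_modality name of the microbiome modality (default: the one
#'   named "microbiome", else the last).
#' @return `dir`, invisibly.
#' @export
render_report <- function(reports, model, dir, grid = NULL,
                          micro_modality = NULL) {
  if (is.null(micro_modality) || !(micro_modality %in% model$modality_names)) {
    micro_modality <- if ("microbiome" %in% model$modality_names) "microbiome"
      else model$modality_names[length(model$modality_names)]
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  P <- t(vapply(reports, function(r) r$P_column, numeric(length(model$S))))
  colnames(P) <- names(reports[[1]]$P_column)
  ptab <- data.frame(component = vapply(reports, `[[`, 0, "component_id"), P,
                     selected = vapply(reports, `[[`, NA, "selected"),
                     dominance = vapply(reports, `[[`, 0, "dominance"),
                     check.names = FALSE)
  write.table(ptab, file.path(dir, "contributions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  digests <- character(length(reports))
  for (r in reports) {
    gen <- r$thresholded[[micro_modality]]
    write.table(gen, file.path(dir, sprintf("component%02d_genera.tsv", r$component_id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    digests[r$component_id] <- digest_name(r, micro_name = micro_modality)
    if (!is.null(grid)) {
      for (nm in setdiff(model$modality_names, micro_modality)) {
        k <- match(nm, model$modality_names)
        s <- model$S[[k]][, r$component_id]
        if (sd(s) > 0) {
          z <- (s - mean(s)) / sd(s)
          zthr <- ifelse(abs(z) > 3, z, 0)
        } else zthr <- rep(0, length(s))
        arr <- array(zthr, dim = grid)
        RNifti::writeNifti(RNifti::asNifti(arr),
                           file.path(dir, sprintf("component%02d_%s_zthr.nii.gz",
                                                  r$component_id, nm)))
      }
    }
  }
  writeLines(sprintf("component %d [%s]: %s",
                     vapply(reports, `[[`, 0, "component_id"),
                     ifelse(vapply(reports, `[[`, NA, "selected"), "selected", "marginal"),
                     digests),
             file.path(dir, "digest.txt"))
  summary_list <- lapply(reports, function(r) {
    list(component = r$component_id,
         fractions = as.list(r$P_column),
         selected = r$selected,
         dominance = r$dominance,
         dominant_subject = r$dominant_subject,
         dominance_flag = r$dominance_flag,
         constant_map_flags = as.list(setNames(as.logical(r$constant_map_flags),
                                               setdiff(model$modality_names, micro_modality))),
         genera = r$thresholded[[micro_modality]])
  })
  jsonlite::write_json(summary_list, file.path(dir, "components.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
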