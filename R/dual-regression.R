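# Dual (spatial then temporal) regression: project template resting-state
# network maps onto each subject's 4D fMRI to obtain subject-specific network
# z-maps, the brain modalities of the linked decomposition.

#' Construct a template set
#'
#' Group-level network z-maps sharing one 3D grid, the spatial designs of
#' stage-1 dual regression.
#'
#' @param maps voxel x network numeric matrix (z units).
#' @param grid integer 3-vector of grid dimensions; `prod(grid)` must equal
#'   the voxel count.
#' @param network_names character vector, one per network.
#' @return an object of class `template_set`.
#' @export
template_set <- function(maps, grid, network_names = colnames(maps)) {
  maps <- as.matrix(maps)
  grid <- as.integer(grid)
  if (length(grid) != 3L || prod(grid) != nrow(maps)) {
    stop(sprintf("grid %s does not match voxel count %d",
                 paste(grid, collapse = "x"), nrow(maps)))
  }
  if (is.null(network_names)) network_names <- sprintf("NET%02d", seq_len(ncol(maps)))
  zero <- colSums(maps^2) == 0
  if (any(zero)) {
    stop("all-zero template column(s): ", paste(network_names[zero], collapse = ", "))
  }
  colnames(maps) <- network_names
  structure(list(maps = maps, grid = grid,
                 network_names = as.character(network_names)),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("template_set: %d networks on a %s grid (%s)\n", ncol(x$maps),
              paste(x$grid, collapse = "x"),
              paste(x$network_names, collapse = ", ")))
  invisible(x)
}

#' Construct a per-network stack of subject maps
#'
#' @param maps subject x voxel matrix (z or beta units) for one network.
#' @param network_name network label.
#' @param grid integer 3-vector of grid dimensions.
#' @param mask logical voxel vector; `FALSE` marks voxels excluded from
#'   analysis (e.g. zero temporal variance in some subject). Default all TRUE.
#' @param subject_ids optional subject labels.
#' @return an object of class `subject_network_maps`.
#' @export
subject_network_maps <- function(maps, network_name, grid,
                                 mask = rep(TRUE, ncol(maps)),
                                 subject_ids = rownames(maps)) {
  maps <- as.matrix(maps)
  if (any(!is.finite(maps))) stop("subject maps must be finite")
  if (prod(grid) != ncol(maps)) stop("grid does not match voxel count")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(nrow(maps)))
  rownames(maps) <- subject_ids
  structure(list(maps = maps, network_name = network_name,
                 grid = as.integer(grid), mask = as.logical(mask),
                 subject_ids = as.character(subject_ids)),
            class = "subject_network_maps")
}

#' @export
print.subject_network_maps <- function(x, ...) {
  cat(sprintf("subject_network_maps '%s': %d subjects x %d voxels (%d masked out)\n",
              x$network_name, nrow(x$maps), ncol(x$maps), sum(!x$mask)))
  invisible(x)
}

# ---------------------------------------------------------------------------

# Report pairs of near-collinear design columns for error messages.
collinear_pairs <- function(m, names) {
  cc <- suppressWarnings(stats::cor(m))
  cc[!is.finite(cc)] <- 1
  bad <- which(abs(cc) > 0.9999 & upper.tri(cc), arr.ind = TRUE)
  if (nrow(bad) == 0L) return("design is numerically rank-deficient")
  paste(apply(bad, 1, function(ij) paste(names[ij[1]], names[ij[2]], sep = " ~ ")),
        collapse = ", ")
}

#' Stage 1: spatial regression of each volume on all templates
#'
#' Each timepoint's volume is regressed jointly on all template maps
#' (multiple regression over voxels); the intercept is absorbed by demeaning
#' templates and volumes over voxels. The coefficients are the subject's
#' network timecourses.
#'
#' @param templates a [template_set()].
#' @param fmri voxel x timepoint matrix.
#' @return timepoint x network matrix of timecourses.
#' @export
stage1_spatial_regression <- function(templates, fmri) {
  fmri <- as.matrix(fmri)
  A <- templates$maps
  if (nrow(A) != nrow(fmri)) {
    stop(sprintf("voxel count mismatch: templates %d, fmri %d", nrow(A), nrow(fmri)))
  }
  if (ncol(fmri) <= ncol(A)) {
    stop("need more timepoints than networks for stage-1 regression")
  }
  A <- sweep(A, 2, colMeans(A))
  Y <- sweep(fmri, 2, colMeans(fmri))
  qr_a <- qr(A)
  if (qr_a$rank < ncol(A)) {
    stop("rank-deficient templates; collinear: ",
         collinear_pairs(A, templates$network_names))
  }
  tc <- t(qr.coef(qr_a, Y))  # timepoint x network
  colnames(tc) <- templates$network_names
  tc
}

#' Stage 2: temporal regression of each voxel on the network timecourses
#'
#' Per voxel, the time series (demeaned over time) is regressed jointly on
#' all network timecourses; with `output = "z"` each coefficient is divided
#' by its standard error and the resulting t statistic mapped to a z-score
#' through the exact t-to-z quantile transform at the residual degrees of
#' freedom.
#'
#' @param timecourses timepoint x network matrix (stage-1 output).
#' @param fmri voxel x timepoint matrix.
#' @param output `"z"` (default) or `"beta"`.
#' @param variance_normalize scale each timecourse to unit variance before
#'   fitting (default TRUE), so betas are comparable across subjects.
#' @return voxel x network matrix of z-scores or betas.
#' @export
stage2_temporal_regression <- function(timecourses, fmri,
                                       output = c("z", "beta"),
                                       variance_normalize = TRUE) {
  output <- match.arg(output)
  X <- as.matrix(timecourses)
  Y <- as.matrix(fmri)
  if (nrow(X) != ncol(Y)) stop("timepoints of timecourses and fmri disagree")
  Tn <- nrow(X); K <- ncol(X)
  df <- Tn - K - 1L  # intercept absorbed by demeaning
  if (df <= 0L) stop(sprintf("non-positive residual degrees of freedom (%d)", df))
  X <- sweep(X, 2, colMeans(X))
  if (variance_normalize) {
    s <- sqrt(colSums(X^2) / (Tn - 1))
    if (any(s < 1e-300)) {
      stop("rank-deficient timecourses; collinear: ",
           collinear_pairs(X, colnames(X) %||% paste0("tc", seq_len(K))))
    }
    X <- sweep(X, 2, s, "/")
  }
  qr_x <- qr(X)
  if (qr_x$rank < K) {
    stop("rank-deficient timecourses; collinear: ",
         collinear_pairs(X, colnames(X) %||% paste0("tc", seq_len(K))))
  }
  Yc <- Y - rowMeans(Y)                       # demean each voxel over time
  B <- t(qr.coef(qr_x, t(Yc)))                # voxel x network
  colnames(B) <- colnames(timecourses)
  if (output == "beta") return(B)
  resid <- Yc - B %*% t(X)
  sigma2 <- rowSums(resid^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qr_x)))
  se <- sqrt(outer(sigma2, xtx_inv_diag))
  tstat <- B / se
  tstat[!is.finite(tstat)] <- 0
  z <- sign(tstat) *
    qnorm(pt(abs(tstat), df = df, lower.tail = FALSE, log.p = TRUE),
          lower.tail = FALSE, log.p = TRUE)
  colnames(z) <- colnames(timecourses)
  z
}

#' Run dual regression for a cohort
#'
#' Both stages are run per subject against all templates (so each network's
#' map is conditioned on the full template set); network selection happens
#' only when assembling the output stacks. Voxels with zero temporal variance
#' in any subject are masked out of every output (zeroed and recorded in the
#' mask).
#'
#' @param templates a [template_set()].
#' @param fmri_per_subject list of voxel x timepoint matrices, one per subject.
#' @param select character vector of network names to stack (default: all).
#' @param output `"z"` (default) or `"beta"`, passed to stage 2.
#' @param subject_ids optional subject labels.
#' @return list of [subject_network_maps()], one per selected network.
#' @export
run_dual_regression <- function(templates, fmri_per_subject,
                                select = templates$network_names,
                                output = c("z", "beta"),
                                subject_ids = names(fmri_per_subject)) {
  output <- match.arg(output)
  missing_net <- setdiff(select, templates$network_names)
  if (length(missing_net)) {
    stop("unknown network(s): ", paste(missing_net, collapse = ", "))
  }
  nv <- nrow(templates$maps)
  R <- length(fmri_per_subject)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(R))
  mask <- rep(TRUE, nv)
  per_subject <- vector("list", R)
  for (r in seq_len(R)) {
    f <- as.matrix(fmri_per_subject[[r]])
    if (nrow(f) != nv) {
      stop(sprintf("subject %s: fmri has %d voxels, templates %d (grid %s)",
                   subject_ids[r], nrow(f), nv,
                   paste(templates$grid, collapse = "x")))
    }
    v <- rowSums((f - rowMeans(f))^2)
    mask <- mask & v > 0
    tc <- stage1_spatial_regression(templates, f)
    per_subject[[r]] <- stage2_temporal_regression(tc, f, output = output)
  }
  lapply(select, function(nm) {
    j <- match(nm, templates$network_names)
    stack <- t(vapply(per_subject, function(m) m[, j], numeric(nv)))
    stack[, !mask] <- 0
    subject_network_maps(stack, network_name = nm, grid = templates$grid,
                         mask = mask, subject_ids = subject_ids)
  })
}

# ---------------------------------------------------------------------------
# NIfTI-1 I/O

#' Read a 4D template NIfTI (networks along the 4th axis)
#' @param path NIfTI file.
#' @param network_names optional names; defaults to NET01..NETk.
#' @return a [template_set()].
#' @export
read_templates <- function(path, network_names = NULL) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L) stop("template file must be 4D (x, y, z, network)")
  d <- dim(arr)
  template_set(matrix(arr, prod(d[1:3]), d[4]), grid = d[1:3],
               network_names = network_names %||% sprintf("NET%02d", seq_len(d[4])))
}

#' Read a subject's 4D fMRI NIfTI as a voxel x timepoint matrix
#' @param path NIfTI file.
#' @return voxel x timepoint matrix with a `grid` attribute.
#' @export
read_fmri <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L) stop("fMRI file must be 4D (x, y, z, time)")
  d <- dim(arr)
  structure(matrix(arr, prod(d[1:3]), d[4]), grid = d[1:3])
}

#' Write a per-network stack of subject maps as 4D NIfTI (subjects along 4th axis)
#' @param snm a [subject_network_maps()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_network_maps <- function(snm, path) {
  arr <- array(t(snm$maps), dim = c(snm$grid, nrow(snm$maps)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Write a template set as a 4D NIfTI (networks along the 4th axis)
#' @param templates a [template_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(templates, path) {
  arr <- array(templates$maps, dim = c(templates$grid, ncol(templates$maps)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
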