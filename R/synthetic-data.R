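# Synthetic joint cohorts with known ground truth: shared subject loadings
# drive sparse spatial sources in each brain network and a planted signal in
# genus-level log abundances, so every downstream stage has a recoverable
# planted answer.

default_lambda_matrix <- function(n_networks, n_components) {
  # Brain networks alternate 10/7, microbiome 3/2.1 across components: with
  # unit-norm sources and loadings lambda is the modality singular value, so
  # these give clearly-visible-but-noisy signal at the default noise_sd 0.1.
  K <- n_networks + 1L
  lam <- matrix(0, K, n_components)
  for (k in seq_len(n_networks)) {
    lam[k, ] <- ifelse((k + seq_len(n_components)) %% 2 == 0, 10, 7)
  }
  lam[K, ] <- ifelse((K + seq_len(n_components)) %% 2 == 0, 3, 2.1)
  lam
}

# Sparse unit-norm source matrix: zero all but a `sparsity` fraction of
# standard-normal entries per column, then renormalize columns.
make_sparse_sources <- function(n_features, n_components, sparsity) {
  nnz <- max(1L, round(sparsity * n_features))
  S <- matrix(0, n_features, n_components)
  for (c in seq_len(n_components)) {
    idx <- sample.int(n_features, nnz)
    S[idx, c] <- rnorm(nnz)
    if (sum(S[, c]^2) < 1e-300) S[idx[1], c] <- 1
  }
  unit_cols(S)
}

#' Generate a joint brain + microbiome cohort with known ground truth
#'
#' Each modality matrix (one per network plus the genus-level log-abundance
#' signal) is built as `S_k %*% diag(lambda_k) %*% H + noise` with unit-norm
#' sparse source columns `S_k`, unit-norm shared subject-loading rows `H`,
#' and per-modality weights `lambda_k`; features are then centered across
#' subjects. The microbiome latent matrix additionally yields a composition
#' table via softmax of a baseline log-abundance profile plus the latent
#' signal, and optionally multinomial counts at a fixed depth. With
#' `timepoints` set, per-subject 4D fMRI time series are generated from the
#' subject maps so dual regression can be exercised end to end.
#'
#' @param n_subjects,n_genera,n_networks,n_components cohort dimensions.
#' @param grid_shape 3D voxel dimensions per network (default `c(6, 6, 6)`).
#' @param lambda_matrix `(n_networks + 1) x n_components` non-negative weight
#'   matrix (last row = microbiome); default [default_lambda_matrix()].
#' @param sparsity fraction of nonzero source entries, in (0, 1].
#' @param noise_sd per-modality Gaussian noise sd (scalar recycled to
#'   `n_networks + 1`).
#' @param seed integer master seed; all randomness derives from it.
#' @param loadings optional true `n_components x n_subjects` loading matrix
#'   (rows are unit-normalized); used to plant e.g. a single-subject artifact
#'   row. Default: standard-normal rows, unit-normalized.
#' @param constant_map optional component index whose source column in the
#'   first network is made constant across voxels (a planted QC artifact).
#' @param depth reads per sample for a multinomial count table; `NULL` (the
#'   default) skips counts.
#' @param timepoints fMRI timepoints per subject; `NULL` (default) skips fMRI.
#' @param fmri_noise_sd temporal noise sd for generated fMRI (default 1).
#' @return a `synthetic_cohort` list: `modalities` (list of feature x subject
#'   matrices, networks then microbiome), `network_maps` (list of
#'   [subject_network_maps()]), `composition` ([composition_table()]),
#'   `counts` ([abundance_table()] or NULL), `templates`, `fmri` (list or
#'   NULL), `timecourses`, and `truth` (H_true, S_true, lambda_true,
#'   noise_sd, baseline_log, seed).
#' @export
make_joint_dataset <- function(n_subjects = 40, n_genera = 30,
                               grid_shape = c(6, 6, 6), n_networks = 2,
                               n_components = 3, lambda_matrix = NULL,
                               sparsity = 0.1, noise_sd = 0.1, seed = 1,
                               loadings = NULL, constant_map = NULL,
                               depth = NULL, timepoints = NULL,
                               fmri_noise_sd = 1) {
  n_voxels <- prod(grid_shape)
  K <- n_networks + 1L
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  if (n_components > min(n_subjects, n_genera, n_voxels)) {
    stop(sprintf("n_components (%d) exceeds min(n_subjects, n_genera, voxels) = %d",
                 n_components, min(n_subjects, n_genera, n_voxels)))
  }
  noise_sd <- rep_len(noise_sd, K)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  lambda_matrix <- lambda_matrix %||% default_lambda_matrix(n_networks, n_components)
  lambda_matrix <- as.matrix(lambda_matrix)
  if (!all(dim(lambda_matrix) == c(K, n_components))) {
    stop(sprintf("lambda_matrix must be %d x %d (networks + microbiome rows x components), got %d x %d",
                 K, n_components, nrow(lambda_matrix), ncol(lambda_matrix)))
  }
  if (any(lambda_matrix < 0)) stop("lambda_matrix must be non-negative")

  subject_ids <- sprintf("sub%03d", seq_len(n_subjects))
  genus_ids <- sprintf("Genus%02d", seq_len(n_genera))
  network_names <- sprintf("NET%02d", seq_len(n_networks))

  H <- with_seed(child_seed(seed, 1L), {
    if (is.null(loadings)) {
      matrix(rnorm(n_components * n_subjects), n_components, n_subjects)
    } else {
      if (!all(dim(as.matrix(loadings)) == c(n_components, n_subjects))) {
        stop("loadings must be n_components x n_subjects")
      }
      as.matrix(loadings)
    }
  })
  H <- unit_rows(H)
  colnames(H) <- subject_ids

  n_features <- c(rep(n_voxels, n_networks), n_genera)
  S <- lapply(seq_len(K), function(k) {
    with_seed(child_seed(seed, 10L + k),
              make_sparse_sources(n_features[k], n_components, sparsity))
  })
  if (!is.null(constant_map)) {
    stopifnot(constant_map >= 1, constant_map <= n_components)
    S[[1]][, constant_map] <- 1 / sqrt(n_voxels)
  }

  modality_names <- c(network_names, "microbiome")
  modalities <- lapply(seq_len(K), function(k) {
    M <- S[[k]] %*% (lambda_matrix[k, ] * H)
    if (noise_sd[k] > 0) {
      M <- M + with_seed(child_seed(seed, 20L + k),
                         matrix(rnorm(length(M), sd = noise_sd[k]), nrow(M)))
    }
    M_uncentered <- M
    M <- M - rowMeans(M)
    colnames(M) <- subject_ids
    attr(M, "uncentered") <- M_uncentered
    M
  })
  names(modalities) <- modality_names

  # Composition from the (uncentered) microbiome latent signal
  baseline_log <- with_seed(child_seed(seed, 30L), rnorm(n_genera, 0, 1.5))
  logab <- baseline_log + attr(modalities[[K]], "uncentered")  # genus x subject
  expab <- exp(sweep(logab, 2, apply(logab, 2, max)))
  relab <- t(sweep(expab, 2, colSums(expab), "/"))             # subject x genus
  composition <- composition_table(relab, genus_ids = genus_ids,
                                   sample_ids = subject_ids)

  counts <- if (!is.null(depth)) {
    make_counts_table(composition, depth = depth, seed = child_seed(seed, 31L))
  } else NULL

  network_maps <- lapply(seq_len(n_networks), function(k) {
    subject_network_maps(t(modalities[[k]]), network_name = network_names[k],
                         grid = grid_shape, subject_ids = subject_ids)
  })

  # Templates + fMRI on the concatenated grid (networks stacked along z)
  full_grid <- c(grid_shape[1], grid_shape[2], grid_shape[3] * n_networks)
  tmpl <- matrix(0, n_voxels * n_networks, n_networks)
  for (k in seq_len(n_networks)) {
    block <- (k - 1L) * n_voxels + seq_len(n_voxels)
    tmpl[block, k] <- with_seed(child_seed(seed, 40L + k), rnorm(n_voxels))
  }
  templates <- template_set(tmpl, grid = full_grid, network_names = network_names)

  fmri <- timecourses <- NULL
  if (!is.null(timepoints)) {
    if (timepoints <= n_networks) stop("timepoints must exceed n_networks")
    timecourses <- lapply(seq_len(n_subjects), function(r) {
      with_seed(child_seed(seed, 1000L + r),
                matrix(rnorm(timepoints * n_networks), timepoints, n_networks))
    })
    fmri <- lapply(seq_len(n_subjects), function(r) {
      maps_r <- do.call(rbind, lapply(seq_len(n_networks), function(k) {
        m <- matrix(0, n_voxels, n_networks)
        m[, k] <- templates$maps[(k - 1L) * n_voxels + seq_len(n_voxels), k] +
          modalities[[k]][, r]
        m
      }))
      make_fmri_from_maps(maps_r, timecourses[[r]], noise_sd = fmri_noise_sd,
                          seed = child_seed(seed, 2000L + r))
    })
    names(fmri) <- names(timecourses) <- subject_ids
  }

  for (k in seq_len(K)) attr(modalities[[k]], "uncentered") <- NULL
  truth <- structure(list(H_true = H, S_true = S, lambda_true = lambda_matrix,
                          noise_sd = noise_sd, baseline_log = baseline_log,
                          seed = seed),
                     class = "lica_ground_truth")
  structure(list(modalities = modalities,
                 modality_names = modality_names,
                 network_maps = network_maps, composition = composition,
                 counts = counts, templates = templates, fmri = fmri,
                 timecourses = timecourses, subject_ids = subject_ids,
                 genus_ids = genus_ids, grid_shape = as.integer(grid_shape),
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d networks (%s voxels each), %d genera, %d planted components\n",
              length(x$subject_ids), length(x$network_maps),
              paste(x$grid_shape, collapse = "x"), length(x$genus_ids),
              nrow(x$truth$H_true)))
  invisible(x)
}

#' Generate a subject's fMRI time series from network maps
#'
#' Returns `maps %*% t(timecourses)` plus i.i.d. Gaussian noise — the exact
#' generative model that stage-1 dual regression inverts.
#'
#' @param network_maps_subject voxel x network matrix.
#' @param timecourses timepoint x network matrix.
#' @param noise_sd Gaussian noise sd (scalar, >= 0).
#' @param seed integer seed for the noise.
#' @return voxel x timepoint matrix.
#' @export
make_fmri_from_maps <- function(network_maps_subject, timecourses,
                                noise_sd = 0, seed = 1) {
  M <- as.matrix(network_maps_subject)
  Tc <- as.matrix(timecourses)
  if (ncol(M) != ncol(Tc)) stop("network counts of maps and timecourses disagree")
  if (nrow(Tc) <= ncol(Tc)) {
    stop("timepoints must exceed networks (stage-1 regression would be underdetermined)")
  }
  out <- M %*% t(Tc)
  if (noise_sd > 0) {
    out <- out + with_seed(seed, matrix(rnorm(length(out), sd = noise_sd), nrow(out)))
  }
  out
}

#' Draw multinomial sequencing counts from a composition table
#'
#' @param composition a [composition_table()] (rows on the simplex).
#' @param depth reads per sample (>= 1).
#' @param seed integer seed.
#' @return an [abundance_table()] whose rows each sum to `depth`; taxonomy
#'   strings are synthetic rank-prefixed lineages ending in the genus id.
#' @export
make_counts_table <- function(composition, depth, seed = 1) {
  stopifnot(inherits(composition, "composition_table"), depth >= 1)
  P <- composition$relabund
  if (any(P < 0)) stop("negative proportions")
  counts <- with_seed(seed, {
    t(apply(P, 1, function(p) rmultinom(1, size = depth, prob = p)[, 1]))
  })
  taxonomy <- sprintf("k__Bacteria;p__SimPhylum;c__SimClass;o__SimOrder;f__SimFamily;g__%s",
                      composition$genus_ids)
  abundance_table(counts, taxonomy = taxonomy,
                  sample_ids = composition$sample_ids,
                  taxon_ids = composition$genus_ids)
}
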