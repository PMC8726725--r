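# Shared fixtures and independent oracles used across the suite.

# Greedy matching of estimated loading rows to true rows by absolute
# correlation; returns the matched |r| per true row and the permutation.
greedy_match <- function(H_est, H_true) {
  cc <- abs(suppressWarnings(cor(t(H_est), t(H_true))))
  cc[!is.finite(cc)] <- 0
  n <- nrow(cc)
  perm <- integer(n)
  r <- numeric(n)
  free_est <- rep(TRUE, n)
  free_true <- rep(TRUE, n)
  for (step in seq_len(n)) {
    m <- cc
    m[!free_est, ] <- -1
    m[, !free_true] <- -1
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    perm[ij[2]] <- ij[1]
    r[ij[2]] <- cc[ij[1], ij[2]]
    free_est[ij[1]] <- FALSE
    free_true[ij[2]] <- FALSE
  }
  list(perm = perm, r = r)
}

# Planted contribution fractions on the standardized-modality scale:
# lambda_true rescaled by the global factors the fit input applied.
planted_fractions <- function(cohort, input) {
  lam <- cohort$truth$lambda_true * input$scales
  sweep(lam^2, 2, colSums(lam^2), "/")
}

# Small abundance fixture with known genus structure (two OTUs share a genus,
# one OTU lacks a genus rank).
fixture_abundance <- function() {
  counts <- rbind(S1 = c(3, 5, 2, 0, 10),
                  S2 = c(0, 1, 0, 4, 2),
                  S3 = c(7, 0, 1, 0, 0))
  tax <- c("k__Bacteria;p__Bacteroidetes;f__Prevotellaceae;g__Prevotella_9",
           "k__Bacteria;p__Bacteroidetes;f__Prevotellaceae;g__Prevotella_9",
           "k__Bacteria;p__Firmicutes;f__Lachnospiraceae;g__Blautia",
           "k__Bacteria;p__Firmicutes;f__Lachnospiraceae;g__",
           "k__Bacteria;p__Actinobacteria;f__Bifidobacteriaceae;g__Bifidobacterium")
  abundance_table(counts, taxonomy = tax,
                  taxon_ids = sprintf("OTU%d", 1:5))
}

# A minimal hand-built lica_model (for closed-form report/contribution tests).
toy_model <- function(lambda, H = NULL, S = NULL, feature_counts = NULL) {
  K <- nrow(lambda); C <- ncol(lambda)
  R <- if (is.null(H)) 10 else ncol(H)
  if (is.null(H)) {
    H <- unit_rows_test(matrix(sin(seq_len(C * R)), C, R))
  }
  if (is.null(feature_counts)) feature_counts <- rep(25, K)
  if (is.null(S)) {
    S <- lapply(feature_counts, function(n) {
      m <- matrix(cos(seq_len(n * C) * 0.7), n, C)
      sweep(m, 2, sqrt(colSums(m^2)), "/")
    })
  }
  structure(list(H = H, S = S, lambda = lambda,
                 beta = rep(1, K), n_components = C, n_iter = 1L,
                 objective_trace = 0, converged = TRUE, seed = 1L,
                 modality_names = c(sprintf("NET%02d", seq_len(K - 1)), "microbiome"),
                 subject_ids = sprintf("sub%03d", seq_len(ncol(H))),
                 standardization = list(centers = lapply(feature_counts, function(n) rep(0, n)),
                                        scales = rep(1, K))),
            class = "lica_model")
}

unit_rows_test <- function(m) m / sqrt(rowSums(m^2))
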