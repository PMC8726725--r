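# Linked ICA: joint factorization of K modality matrices sharing one
# subject-loading matrix.
#
# Model, per modality k (feature x subject):
#   X_k = S_k diag(lambda_k) H + E_k,   E_k ~ N(0, 1/beta_k)
# with unit-norm source columns S_k and loading rows H; lambda_{k,c} >= 0 is
# the weight (singular value) of component c in modality k, so lambda^2 is
# its explained variance on the standardized scale.
#
# Estimation is MAP block-coordinate descent in the parameterization
# W_k = S_k diag(lambda_k) (scale folded into W, factored out on exit):
#   - H has a standard-normal prior (fixes overall scale);
#   - W entries carry a two-component Gaussian mixture (spike/slab) prior --
#     the sparse, non-Gaussian source model that makes this ICA rather than
#     PCA -- with the per-(modality, component) slab variance learned by EM;
#     a slab collapsing onto the spike is the ARD route by which a component
#     vanishes from a modality (lambda_{k,c} -> 0);
#   - beta_k has its closed-form update, capped for noiseless inputs.
# Every update exactly minimizes (or, for the slab variance, monotonically
# improves via EM) the penalized objective, and the per-entry W update keeps
# the current value among its candidates, so the objective trace is monotone
# non-increasing by construction.

#' Standardize raw modality matrices for linked ICA
#'
#' Centers each feature row across subjects and rescales each modality
#' globally to unit mean-square, so modalities with vastly different feature
#' counts and units become comparable and contribution fractions are defined
#' on a common scale. Centers and scale factors are stored for inversion.
#'
#' @param raw list of feature x subject matrices (same subject count).
#' @param modality_names,subject_ids optional labels.
#' @param center,scale logicals (default TRUE); turning either off records
#'   identity centers/scales, for inputs already on a common scale.
#' @return an object of class `lica_input` with elements `modalities`
#'   (standardized), `centers`, `scales` (multipliers applied), and labels.
#' @export
standardize_modalities <- function(raw, modality_names = names(raw),
                                   subject_ids = NULL,
                                   center = TRUE, scale = TRUE) {
  stopifnot(is.list(raw), length(raw) >= 1L)
  raw <- lapply(raw, as.matrix)
  R <- unique(vapply(raw, ncol, integer(1)))
  if (length(R) != 1L) {
    stop("subject counts differ across modalities: ",
         paste(vapply(raw, ncol, integer(1)), collapse = ", "))
  }
  if (is.null(modality_names)) modality_names <- sprintf("mod%d", seq_along(raw))
  if (is.null(subject_ids)) subject_ids <- colnames(raw[[1]]) %||% sprintf("sub%03d", seq_len(R))
  centers <- vector("list", length(raw))
  scales <- numeric(length(raw))
  out <- vector("list", length(raw))
  for (k in seq_along(raw)) {
    X <- raw[[k]]
    if (nrow(X) < 2L) stop(sprintf("modality '%s' has fewer than 2 features", modality_names[k]))
    if (any(!is.finite(X))) stop(sprintf("modality '%s' contains missing or non-finite values", modality_names[k]))
    ctr <- if (center) rowMeans(X) else rep(0, nrow(X))
    Xc <- X - ctr
    ms <- mean(Xc^2)
    if (ms <= 0) stop(sprintf("modality '%s' has zero variance", modality_names[k]))
    scales[k] <- if (scale) 1 / sqrt(ms) else 1
    centers[[k]] <- ctr
    out[[k]] <- Xc * scales[k]
  }
  structure(list(modalities = out, centers = centers, scales = scales,
                 modality_names = as.character(modality_names),
                 subject_ids = as.character(subject_ids),
                 feature_ids = lapply(raw, function(X) rownames(X))),
            class = "lica_input")
}

#' Invert the standardization of one modality
#' @param input a `lica_input`.
#' @param modality modality index.
#' @param X matrix on the standardized scale (default: the stored one).
#' @return matrix on the original scale.
#' @export
destandardize_modality <- function(input, modality, X = input$modalities[[modality]]) {
  X / input$scales[modality] + input$centers[[modality]]
}

# Negative log of the spike/slab mixture density, vectorized; v1 may be scalar.
neglog_mog <- function(w, pi1, v0, v1) {
  a0 <- log1p(-pi1) - 0.5 * log(2 * pi * v0) - w^2 / (2 * v0)
  a1 <- log(pi1) - 0.5 * log(2 * pi * v1) - w^2 / (2 * v1)
  m <- pmax(a0, a1)
  -(m + log(exp(a0 - m) + exp(a1 - m)))
}

#' Fit a linked ICA model
#'
#' Factorizes all modalities jointly as `X_k ~ S_k diag(lambda_k) H` with one
#' shared subject-loading matrix `H`. See the package vignette for the model
#' and estimation details. Components are returned ordered by total explained
#' variance `sum_k lambda_{k,c}^2` (descending) with each loading row's
#' largest-magnitude entry made positive.
#'
#' @param input a `lica_input` from [standardize_modalities()], or a plain
#'   list of feature x subject matrices (standardized automatically).
#' @param n_components number of components (default 10, following the
#'   forced 10-component solution used at this sample size); must not exceed
#'   the subject count.
#' @param max_iter maximum block-coordinate iterations (default 1000).
#' @param tol relative objective-change convergence threshold (default 1e-6).
#' @param seed integer seed driving the restart initializations; the fit is
#'   a deterministic function of the input and this seed.
#' @param slab_prob prior probability that a source entry is in the slab
#'   (i.e. genuinely nonzero); default 0.1.
#' @param init `"svd"` (default) starts from the SVD of the row-stacked
#'   modalities; `"random"` from seeded random loadings.
#' @param n_restarts number of additional seeded random starts (default 2);
#'   the run with the lowest final objective is returned. The spike/slab
#'   objective is multimodal in the component rotation, so a single start
#'   can converge to a mixed local optimum.
#' @return an object of class `lica_model`: `H` (component x subject,
#'   unit-norm rows), `S` (list of feature x component matrices, unit-norm
#'   columns), `lambda` (modality x component, >= 0), `beta` (noise
#'   precisions), `n_iter`, `objective_trace`, `converged`, `seed`, labels
#'   and the standardization info.
#' @export
fit_lica <- function(input, n_components = 10, max_iter = 1000, tol = 1e-6,
                     seed = 1, slab_prob = 0.1, init = c("svd", "random"),
                     n_restarts = 2) {
  init <- match.arg(init)
  if (!inherits(input, "lica_input")) input <- standardize_modalities(input)
  X <- input$modalities
  K <- length(X)
  R <- ncol(X[[1]])
  C <- as.integer(n_components)
  if (C < 1L || C > R) stop(sprintf("n_components must be in [1, %d subjects]", R))
  if (max_iter < 1L) stop("max_iter must be >= 1")
  Nk <- vapply(X, nrow, integer(1))

  pi1 <- slab_prob
  v0 <- 1e-4          # spike variance (standardized units)
  v1_floor <- 1e-3
  beta_max <- 1e12

  Xstack <- do.call(rbind, X)

  objective <- function(H, W, v1, beta) {
    J <- 0.5 * sum(H^2)
    for (k in seq_len(K)) {
      rss <- sum((X[[k]] - W[[k]] %*% H)^2)
      J <- J + beta[k] / 2 * rss - Nk[k] * R / 2 * log(beta[k])
      for (c in seq_len(C)) {
        J <- J + sum(neglog_mog(W[[k]][, c], pi1, v0, v1[[k]][c]))
      }
    }
    J
  }

  # Jacobi-style pairwise search within the fitted subspace. Two families of
  # product-preserving moves on a component pair (c, d):
  #   rotation  W[, (c,d)] <- W[, (c,d)] R(theta),  H[(c,d), ] <- R(theta)' H[(c,d), ]
  #   shear     W[, c] <- W[, c] - a W[, d],        H[d, ] <- H[d, ] + a H[c, ]
  # Rotations leave both the reconstruction and the H prior unchanged, so the
  # spike/slab penalty alone decides; shears additionally trade H-prior mass,
  # which is what separates components whose subject loadings are correlated
  # (an oblique, non-orthogonal unmixing). This is the ICA step proper: the
  # non-Gaussian source prior picks one representation out of the continuum
  # of equally-well-reconstructing ones. Moves are accepted only when they
  # lower the objective, so the trace stays monotone.
  pen_col <- function(W, v1, c) {
    s <- 0
    for (k in seq_len(K)) s <- s + sum(neglog_mog(W[[k]][, c], pi1, v0, v1[[k]][c]))
    s
  }
  subspace_sweep <- function(W, H, v1) {
    improved <- FALSE
    angles <- seq(-pi / 4, pi / 4, length.out = 33)
    zero_idx <- 17L  # angles[17] == 0
    shear_t <- setdiff(seq(-1, 1, length.out = 17), 0)
    for (c in seq_len(C - 1L)) {
      for (d in seq((c + 1L), C)) {
        pen <- vapply(angles, function(th) {
          cs <- cos(th); sn <- sin(th)
          s <- 0
          for (k in seq_len(K)) {
            wc <- W[[k]][, c] * cs + W[[k]][, d] * sn
            wd <- -W[[k]][, c] * sn + W[[k]][, d] * cs
            s <- s + sum(neglog_mog(wc, pi1, v0, v1[[k]][c])) +
              sum(neglog_mog(wd, pi1, v0, v1[[k]][d]))
          }
          s
        }, numeric(1))
        best <- which.min(pen)
        if (best != zero_idx && pen[best] < pen[zero_idx] - 1e-10) {
          cs <- cos(angles[best]); sn <- sin(angles[best])
          for (k in seq_len(K)) {
            wc <- W[[k]][, c] * cs + W[[k]][, d] * sn
            wd <- -W[[k]][, c] * sn + W[[k]][, d] * cs
            W[[k]][, c] <- wc; W[[k]][, d] <- wd
          }
          hc <- cs * H[c, ] + sn * H[d, ]
          hd <- -sn * H[c, ] + cs * H[d, ]
          H[c, ] <- hc; H[d, ] <- hd
          improved <- TRUE
        }
        # shear moves, both orientations
        for (pr in list(c(c, d), c(d, c))) {
          a1 <- pr[1]; a2 <- pr[2]
          nw1 <- sqrt(sum(vapply(W, function(Wk) sum(Wk[, a1]^2), numeric(1))))
          nw2 <- sqrt(sum(vapply(W, function(Wk) sum(Wk[, a2]^2), numeric(1))))
          if (nw2 < 1e-300) next
          alphas <- shear_t * (nw1 / nw2)
          base <- pen_col(W, v1, a1) + 0.5 * sum(H[a2, ]^2)
          obj_a <- vapply(alphas, function(a) {
            s <- 0.5 * sum((H[a2, ] + a * H[a1, ])^2)
            for (k in seq_len(K)) {
              s <- s + sum(neglog_mog(W[[k]][, a1] - a * W[[k]][, a2],
                                      pi1, v0, v1[[k]][a1]))
            }
            s
          }, numeric(1))
          bi <- which.min(obj_a)
          if (obj_a[bi] < base - 1e-10) {
            a <- alphas[bi]
            for (k in seq_len(K)) W[[k]][, a1] <- W[[k]][, a1] - a * W[[k]][, a2]
            H[a2, ] <- H[a2, ] + a * H[a1, ]
            improved <- TRUE
          }
        }
      }
    }
    list(W = W, H = H, improved = improved)
  }

  rot_every <- 10L

  # Full block-coordinate optimization from one loading initialization.
  run_from <- function(H) {
  HHt <- tcrossprod(H)
  W <- lapply(X, function(Xk) {
    t(solve(HHt + 1e-8 * diag(C), H %*% t(Xk)))
  })
  v1 <- lapply(W, function(Wk) pmax(3 * colMeans(Wk^2), v1_floor))
  beta <- vapply(seq_len(K), function(k) {
    rss <- sum((X[[k]] - W[[k]] %*% H)^2)
    min(Nk[k] * R / max(rss, 1e-300), beta_max)
  }, numeric(1))

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  J_prev <- objective(H, W, v1, beta)
  for (iter in seq_len(max_iter)) {
    # (i) shared loading update, pooled over modalities weighted by beta
    A <- diag(C)
    Bm <- matrix(0, C, R)
    for (k in seq_len(K)) {
      A <- A + beta[k] * crossprod(W[[k]])
      Bm <- Bm + beta[k] * crossprod(W[[k]], X[[k]])
    }
    H <- solve(A, Bm)
    if (any(!is.finite(H))) stop(sprintf("NaN in loading update at iteration %d", iter))

    # (ii) per-modality source updates with spike/slab shrinkage
    for (k in seq_len(K)) {
      Rfull <- X[[k]] - W[[k]] %*% H
      for (c in seq_len(C)) {
        hc <- H[c, ]
        hn2 <- sum(hc^2)
        if (hn2 < 1e-300) next
        w_cur <- W[[k]][, c]
        m <- drop(Rfull %*% hc) / hn2 + w_cur
        kap <- beta[k] * hn2
        cand <- cbind(w_cur,
                      m,
                      m * kap / (kap + 1 / v0),
                      m * kap / (kap + 1 / v1[[k]][c]))
        g <- kap / 2 * (cand - m)^2 +
          matrix(neglog_mog(as.vector(cand), pi1, v0, v1[[k]][c]), nrow(cand))
        pick <- max.col(-g, ties.method = "first")
        w_new <- cand[cbind(seq_along(m), pick)]
        Rfull <- Rfull - tcrossprod(w_new - w_cur, hc)
        W[[k]][, c] <- w_new
      }
      if (any(!is.finite(W[[k]]))) stop(sprintf("NaN in source update at iteration %d", iter))

      # (iii) slab-variance EM step (the ARD mechanism) and noise precision
      for (c in seq_len(C)) {
        w <- W[[k]][, c]
        a0 <- log1p(-pi1) - 0.5 * log(v0) - w^2 / (2 * v0)
        a1 <- log(pi1) - 0.5 * log(v1[[k]][c]) - w^2 / (2 * v1[[k]][c])
        r1 <- 1 / (1 + exp(a0 - a1))
        v1[[k]][c] <- max(sum(r1 * w^2) / max(sum(r1), 1e-12), v1_floor)
      }
      rss <- sum(Rfull^2)
      beta[k] <- min(Nk[k] * R / max(rss, 1e-300), beta_max)
    }

    if (C > 1L && iter %% rot_every == 0L) {
      rot <- subspace_sweep(W, H, v1)
      W <- rot$W; H <- rot$H
    }

    J <- objective(H, W, v1, beta)
    trace <- c(trace, J)
    if (abs(J_prev - J) <= tol * (abs(J_prev) + 1e-10)) {
      # at convergence, insist on a solution stable under the pair moves
      rot <- if (C > 1L) subspace_sweep(W, H, v1) else list(improved = FALSE)
      if (!rot$improved) {
        converged <- TRUE
        J_prev <- J
        break
      }
      W <- rot$W; H <- rot$H
      J <- objective(H, W, v1, beta)
      trace[length(trace)] <- J
    }
    J_prev <- J
  }
  list(H = H, W = W, v1 = v1, beta = beta, trace = trace,
       converged = converged, iter = iter, J = J_prev)
  }

  # --- seeded multi-start: deterministic SVD init plus seeded random
  # restarts; the run with the lowest final objective wins (ties keep the
  # earlier, i.e. the SVD, run). The spike/slab objective is multimodal in
  # the component rotation, and a single deterministic start can converge to
  # a mixed local optimum; restarts make the selection reliable while the
  # whole procedure remains a deterministic function of `seed`.
  inits <- list()
  if (init == "svd") {
    sv <- svd(Xstack, nu = 0, nv = C)
    inits$svd <- t(sv$v[, seq_len(C), drop = FALSE]) * sqrt(R)
  }
  n_rand <- if (init == "random") max(1L, n_restarts) else n_restarts
  for (r in seq_len(n_rand)) {
    inits[[paste0("rand", r)]] <-
      with_seed(child_seed(seed, 7L + r), matrix(rnorm(C * R), C, R))
  }
  best <- NULL
  for (ini in inits) {
    res <- run_from(ini)
    if (is.null(best) || res$J < best$J - 1e-9 * (abs(best$J) + 1)) best <- res
  }
  H <- best$H; W <- best$W; beta <- best$beta
  trace <- best$trace; converged <- best$converged; iter <- best$iter

  # --- factor out scale: unit-norm S columns and H rows, lambda >= 0 -------
  h_norm <- sqrt(rowSums(H^2))
  lambda <- matrix(0, K, C, dimnames = list(input$modality_names, NULL))
  S <- vector("list", K)
  for (k in seq_len(K)) {
    w_norm <- sqrt(colSums(W[[k]]^2))
    lambda[k, ] <- w_norm * h_norm
    Sk <- W[[k]]
    for (c in seq_len(C)) {
      Sk[, c] <- if (w_norm[c] > 1e-300) Sk[, c] / w_norm[c] else
        c(1, rep(0, nrow(Sk) - 1L))
    }
    rownames(Sk) <- input$feature_ids[[k]]
    S[[k]] <- Sk
  }
  Hn <- H
  for (c in seq_len(C)) {
    Hn[c, ] <- if (h_norm[c] > 1e-300) H[c, ] / h_norm[c] else 0
  }

  ord <- order(colSums(lambda^2), decreasing = TRUE)
  Hn <- Hn[ord, , drop = FALSE]
  lambda <- lambda[, ord, drop = FALSE]
  S <- lapply(S, function(Sk) Sk[, ord, drop = FALSE])
  for (c in seq_len(C)) {
    i <- which.max(abs(Hn[c, ]))
    if (Hn[c, i] < 0) {
      Hn[c, ] <- -Hn[c, ]
      for (k in seq_len(K)) S[[k]][, c] <- -S[[k]][, c]
    }
  }
  colnames(Hn) <- input$subject_ids
  colnames(lambda) <- sprintf("IC%d", seq_len(C))
  names(S) <- input$modality_names

  structure(list(H = Hn, S = S, lambda = lambda, beta = beta,
                 n_components = C, n_iter = iter,
                 objective_trace = trace, converged = converged, seed = seed,
                 modality_names = input$modality_names,
                 subject_ids = input$subject_ids,
                 standardization = list(centers = input$centers,
                                        scales = input$scales)),
            class = "lica_model")
}

#' @export
print.lica_model <- function(x, ...) {
  cat(sprintf("lica_model: %d components, %d modalities (%s), %d subjects\n",
              x$n_components, length(x$S),
              paste(x$modality_names, collapse = ", "), ncol(x$H)))
  cat(sprintf("  %d iterations, %sconverged\n", x$n_iter,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Per-component modality contribution fractions
#'
#' `P[k, c] = lambda[k, c]^2 / sum_k' lambda[k', c]^2`: the share of
#' component c's explained variance attributable to modality k, on the
#' standardized-modality scale. Columns sum to 1. The non-marginal
#' (> 0.2) component-selection rule operates on this matrix.
#'
#' @param model a fitted [fit_lica()] model.
#' @return a modality x component matrix of fractions (class
#'   `contribution_matrix`); components whose weights are zero in every
#'   modality get a uniform column and are flagged in the `degenerate`
#'   attribute.
#' @export
contribution_fractions <- function(model) {
  stopifnot(inherits(model, "lica_model"))
  lam2 <- model$lambda^2
  tot <- colSums(lam2)
  degenerate <- tot <= 1e-300
  P <- lam2
  for (c in seq_along(tot)) {
    P[, c] <- if (degenerate[c]) 1 / nrow(lam2) else lam2[, c] / tot[c]
  }
  structure(P, degenerate = degenerate, class = c("contribution_matrix", class(P)))
}

#' @export
print.contribution_matrix <- function(x, ...) {
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(m, ...)
  if (any(attr(x, "degenerate"))) {
    cat("degenerate component(s):",
        paste(which(attr(x, "degenerate")), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruct (part of) one modality from the model
#'
#' Sums `S_k[, c] * lambda[k, c] * H[c, ]` over the requested components; an
#' empty subset yields the zero matrix (useful for variance accounting).
#'
#' @param model a fitted [fit_lica()] model.
#' @param modality modality index.
#' @param components component indices (default: all).
#' @param destandardize if TRUE, map back to the original feature scale.
#' @return feature x subject matrix.
#' @export
reconstruct <- function(model, modality, components = seq_len(model$n_components),
                        destandardize = FALSE) {
  stopifnot(inherits(model, "lica_model"),
            modality >= 1, modality <= length(model$S))
  Sk <- model$S[[modality]]
  if (length(components) &&
      (any(components < 1) || any(components > model$n_components))) {
    stop("invalid component indices")
  }
  out <- matrix(0, nrow(Sk), ncol(model$H))
  for (c in components) {
    out <- out + tcrossprod(Sk[, c] * model$lambda[modality, c], model$H[c, ])
  }
  if (destandardize) {
    out <- out / model$standardization$scales[modality] +
      model$standardization$centers[[modality]]
  }
  out
}
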