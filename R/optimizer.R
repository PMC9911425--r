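# Particle optimization engine: coarse-to-fine entropy-based correspondence
# optimization with pluggable temporal models (constant mean, disentangled
# group entropies, per-coordinate linear regression, principal-component
# polynomial regression with elastic net).

#' Optimizer configuration
#'
#' @param target_particles particles per shape at the finest level; must be
#'   a power of two (reached by repeated splitting from 1).
#' @param iterations total gradient-descent iteration budget.
#' @param step_size base step multiplier; per-shape steps are additionally
#'   scaled by local particle spacing.  Halved on objective increase
#'   (backtracking), reset at each split level.
#' @param alpha_weight relative weight of the correspondence (shape-space
#'   entropy) term; annealed from 5% to 100% of this value over the first
#'   half of the iteration budget.  The default 4 makes the correspondence
#'   term dominate the late-stage tug-of-war against per-shape uniform
#'   spreading, which is what yields tight temporal trajectories (and
#'   anchors the rotational gauge freedom of nearly-symmetric shapes).
#' @param cov_regularization eigenvalue regularizer of the shape-space
#'   covariance; `NULL` (default) uses the adaptive value
#'   1e-5 * trace(Y'Y) / K recomputed at every model refit.
#' @param covariance_update_period refit the temporal model / shape-space
#'   statistics every this many iterations (1 = every iteration).
#' @param cv_update_period re-run the (r1, r2) cross validation every this
#'   many model refits (between refreshes the previously selected weights
#'   are reused).
#' @param degree polynomial degree for the pc-polynomial method; `NULL`
#'   means T - 1 (T = number of distinct observed time values).
#' @param regularization_grid data.frame of (r1, r2) candidates for CV.
#' @param init_fraction fraction of the budget spent on the coarse-to-fine
#'   cross-sectional initialization for the temporal methods.
#' @param sampling_weight weight on the per-shape sampling (spread) term;
#'   0 disables it (diagnostic collapse mode).
#' @param corr_step_frac median correspondence-step length as a fraction of
#'   the median particle spacing (before backtracking).
#' @param cov_rel_reg adaptive covariance regularizer as a fraction of the
#'   mean per-direction residual variance (used when `cov_regularization`
#'   is NULL).
#' @param split_offset_rel split offset relative to the mean surface
#'   bounding diagonal.
#' @param rng_seed integer seed; all randomness (split directions, CV folds)
#'   derives from it deterministically.
#' @param verbose print per-iteration objective values.
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(target_particles = 128L, iterations = 1000L,
                             step_size = 1.0, alpha_weight = 4.0,
                             cov_regularization = NULL,
                             covariance_update_period = 1L,
                             cv_update_period = 25L,
                             degree = NULL,
                             regularization_grid = default_regularization_grid(),
                             init_fraction = 0.5,
                             sampling_weight = 1.0,
                             corr_step_frac = 0.3,
                             cov_rel_reg = 0.1,
                             split_offset_rel = 0.02,
                             rng_seed = 42L,
                             verbose = FALSE) {
  target_particles <- as.integer(target_particles)
  if (target_particles < 1L || bitwAnd(target_particles, target_particles - 1L) != 0L)
    stop("invalid-parameter: target_particles must be a power of two")
  if (iterations < 1L) stop("invalid-parameter: iterations must be positive")
  if (step_size <= 0) stop("invalid-parameter: step_size must be positive")
  if (alpha_weight < 0) stop("invalid-parameter: alpha_weight must be >= 0")
  if (!is.null(cov_regularization) && cov_regularization <= 0)
    stop("invalid-parameter: cov_regularization must be positive")
  if (covariance_update_period < 1L)
    stop("invalid-parameter: covariance_update_period must be positive")
  structure(list(target_particles = target_particles,
                 iterations = as.integer(iterations),
                 step_size = step_size, alpha_weight = alpha_weight,
                 cov_regularization = cov_regularization,
                 covariance_update_period = as.integer(covariance_update_period),
                 cv_update_period = as.integer(cv_update_period),
                 degree = degree,
                 regularization_grid = regularization_grid,
                 init_fraction = init_fraction,
                 sampling_weight = sampling_weight,
                 corr_step_frac = corr_step_frac,
                 cov_rel_reg = cov_rel_reg,
                 split_offset_rel = split_offset_rel,
                 rng_seed = as.integer(rng_seed),
                 verbose = isTRUE(verbose)),
            class = "optimizer_config")
}

anneal_factor <- function(giter, total) {
  ramp <- min(1, giter / max(1, 0.5 * total))
  0.05 + 0.95 * ramp
}

# correspondence gradient given a precomputed residual matrix:
# G = Y (Y'Y + (K-1) a I)^{-1}, the exact gradient of residual_entropy
# (the 1/(K-1) covariance normalization cancels), computed via the K x K
# dual/Gram system
corr_grad_from_Y <- function(Y, alpha_cov) {
  K <- nrow(Y)
  lambda <- (K - 1) * alpha_cov
  A <- tcrossprod(Y)
  diag(A) <- diag(A) + lambda
  ch <- tryCatch(chol(A), error = function(e)
    stop("numerical error: singular correspondence system despite regularization"))
  backsolve(ch, forwardsolve(t(ch), Y))
}

# adaptive covariance regularizer: a fraction of the mean per-direction
# residual variance.  Much smaller values whiten the near-null eigenmodes so
# aggressively that their gradients saturate and oscillate instead of
# contracting.
adaptive_cov_reg <- function(Y, K, cfg) {
  if (!is.null(cfg$cov_regularization)) return(cfg$cov_regularization)
  max(cfg$cov_rel_reg * sum(Y^2) / ((K - 1) * ncol(Y)), 1e-30)
}

# combined Parzen entropy + gradient for one shape (shares the kernel matrix)
samp_terms <- function(P, sig) {
  M <- nrow(P); d <- ncol(P)
  if (M < 2L) return(list(H = 0, G = matrix(0, M, d)))
  D2 <- pairwise_sq_dists(P)
  W <- exp(-D2 / (2 * sig^2))
  diag(W) <- 0
  s <- pmax(rowSums(W), 1e-300)
  H <- -mean(log(s / ((M - 1) * (2 * pi * sig^2)^(d / 2))))
  B <- (W / s) / sig^2
  C <- B + t(B)
  G <- (rowSums(C) * P - C %*% P) / M
  list(H = H, G = G)
}

# temporal-model refit; returns updated model state
refit_state <- function(mode, Z, cells, cfg, state, N, T) {
  K <- nrow(Z)
  state$refit_count <- state$refit_count + 1L
  if (mode == "disentangled") {
    mu_t <- lapply(seq_len(T), function(tt)
      colMeans(Z[cells$t == tt, , drop = FALSE]))
    mu_n <- lapply(seq_len(N), function(nn)
      colMeans(Z[cells$n == nn, , drop = FALSE]))
    Yc <- sweep(Z, 2L, colMeans(Z))
    state$mu_t <- mu_t; state$mu_n <- mu_n
    state$alpha_cov <- adaptive_cov_reg(Yc, K, cfg)
    state$model <- NULL
    return(state)
  }
  times <- cells$time_value
  model <- switch(mode,
    constant = fit_constant_model(Z),
    linear = fit_linear_regression(Z, times),
    pcpoly = {
      sub <- fit_pca_subspace(Z)
      keep <- which(sub$eigenvalues > 1e-12 * sub$eigenvalues[1L])
      if (!length(keep)) keep <- 1L
      sub$eigenvectors <- sub$eigenvectors[, keep, drop = FALSE]
      sub$eigenvalues <- sub$eigenvalues[keep]
      scores <- project_scores(sub, Z)
      Td <- length(unique(times))
      P_deg <- if (is.null(cfg$degree)) Td - 1L else as.integer(cfg$degree)
      P_deg <- max(1L, min(P_deg, Td - 1L))
      cv_due <- is.null(state$r1r2) ||
        (state$refit_count - state$last_cv_refit) >= cfg$cv_update_period
      if (cv_due && K >= 10L) {
        sel <- select_regularization_cv(scores, times, P_deg,
                                        cfg$regularization_grid,
                                        rng_seed = cfg$rng_seed + 7919L,
                                        subjects = cells$subject_id)
        state$r1r2 <- c(sel$r1, sel$r2)
        state$last_cv_refit <- state$refit_count
      } else if (is.null(state$r1r2)) {
        state$r1r2 <- c(0, 1e-3)   # small-cohort fallback, no CV possible
        state$last_cv_refit <- state$refit_count
      }
      fit_polynomial_elastic_net(scores, times, P_deg,
                                 r1 = state$r1r2[1L], r2 = state$r1r2[2L],
                                 subspace = sub)
    },
    stop("unknown model mode"))
  pred <- stats::predict(model, times = times)
  Y <- Z - pred
  state$model <- model
  state$pred <- pred
  state$alpha_cov <- adaptive_cov_reg(Y, K, cfg)
  state
}

# entropy value (and optionally gradient) of the correspondence part with
# the temporal model held fixed
entropy_terms <- function(mode, Z, cells, state, N, T, want_grad = TRUE) {
  if (mode == "disentangled") {
    H <- 0
    G <- if (want_grad) matrix(0, nrow(Z), ncol(Z)) else NULL
    for (tt in seq_len(T)) {
      rows <- which(cells$t == tt)
      Y <- sweep(Z[rows, , drop = FALSE], 2L, state$mu_t[[tt]])
      H <- H + residual_entropy(Y, state$alpha_cov)
      if (want_grad)
        G[rows, ] <- G[rows, ] + corr_grad_from_Y(Y, state$alpha_cov)
    }
    for (nn in seq_len(N)) {
      rows <- which(cells$n == nn)
      Y <- sweep(Z[rows, , drop = FALSE], 2L, state$mu_n[[nn]])
      H <- H + residual_entropy(Y, state$alpha_cov)
      if (want_grad)
        G[rows, ] <- G[rows, ] + corr_grad_from_Y(Y, state$alpha_cov)
    }
    list(H = H, G = G)
  } else {
    Y <- Z - state$pred
    list(H = residual_entropy(Y, state$alpha_cov),
         G = if (want_grad) corr_grad_from_Y(Y, state$alpha_cov) else NULL)
  }
}

#' Disentangled entropy gradient
#'
#' Gradient of \eqn{\alpha [\sum_t H(Z_t) + \sum_n H(Z_n)]} with respect to
#' all particle positions: every (subject, time) cell receives the sum of
#' its per-time-point (inter-subject) and per-subject (intra-subject)
#' correspondence-gradient terms.  Requires a complete N x T grid.
#'
#' @param system a `particle_system` on a complete grid.
#' @param alpha_weight weight of the entropy terms.
#' @param cov_regularization positive covariance regularizer.
#' @return N x T x dM array of gradients.
#' @export
disentangled_gradient <- function(system, alpha_weight, cov_regularization) {
  if (!all(system$observed))
    stop("unsupported-design: the disentangled scheme requires a complete N x T grid")
  Z <- as_shape_matrix(system)
  cells <- attr(Z, "cells")
  N <- nrow(system$observed); T <- ncol(system$observed)
  st <- list(mu_t = lapply(seq_len(T), function(tt)
               colMeans(Z[cells$t == tt, , drop = FALSE])),
             mu_n = lapply(seq_len(N), function(nn)
               colMeans(Z[cells$n == nn, , drop = FALSE])),
             alpha_cov = cov_regularization)
  et <- entropy_terms("disentangled", Z, cells, st, N, T)
  out <- array(0, c(N, T, ncol(Z)))
  for (k in seq_len(nrow(cells)))
    out[cells$n[k], cells$t[k], ] <- alpha_weight * et$G[k, ]
  out
}

# one optimization phase at fixed particle count
run_phase <- function(ps, mode, iters, cfg, giter0, total, state, trace_rows) {
  cohort <- ps$cohort
  cells <- observed_cells(cohort)
  N <- n_subjects(cohort); T <- n_timepoints(cohort)
  K <- nrow(cells); M <- n_particles(ps)
  diags <- vapply(seq_len(K), function(k)
    surface_diagonal(cohort$surfaces[[cells$n[k], cells$t[k]]]), numeric(1))
  step_scale <- cfg$step_size
  q_hist <- numeric(0)
  skipped <- 0L
  it <- 0L
  while (it < iters) {
    it <- it + 1L
    giter <- giter0 + it
    alpha_t <- cfg$alpha_weight * anneal_factor(giter, total)
    Z <- as_shape_matrix(ps)
    if (is.null(state$model_ready) ||
        ((it - 1L) %% cfg$covariance_update_period == 0L)) {
      state <- refit_state(mode, Z, cells, cfg, state, N, T)
      state$model_ready <- TRUE
    }
    # per-shape kernel widths, sampling terms, normals
    sig_list <- vector("list", K)
    samp_H <- numeric(K)
    delta <- vector("list", K)
    ent <- entropy_terms(mode, Z, cells, state, N, T)
    gpart_norms <- numeric(0)
    corr_parts <- vector("list", K)
    for (k in seq_len(K)) {
      P <- matrix(Z[k, ], ncol = 3L, byrow = TRUE)
      nnd <- nearest_neighbor_dists(P)
      sig <- pmin(pmax(nnd, 1e-3 * diags[k]), 0.5 * diags[k])
      sig_list[[k]] <- sig
      st <- samp_terms(P, sig)
      samp_H[k] <- st$H
      u_s <- (M * sig^2) * st$G
      u_s <- cap_rows(u_s, 0.5 * sig)
      corr <- matrix(ent$G[k, ], ncol = 3L, byrow = TRUE)
      corr_parts[[k]] <- corr
      gpart_norms <- c(gpart_norms, sqrt(rowSums(corr^2)))
      delta[[k]] <- cfg$sampling_weight * u_s     # correspondence added below
    }
    gscale <- cfg$corr_step_frac * stats::median(unlist(sig_list)) /
      max(stats::median(gpart_norms), 1e-300)
    for (k in seq_len(K)) {
      u_c <- cap_rows(-gscale * corr_parts[[k]], 0.5 * sig_list[[k]])
      delta[[k]] <- delta[[k]] + alpha_t * u_c
    }
    Q_pre <- alpha_t * ent$H - cfg$sampling_weight * sum(samp_H)
    if (!is.finite(Q_pre))
      stop(structure(list(message = "optimization-failure: non-finite objective",
                          call = sys.call(),
                          trace = if (length(trace_rows)) do.call(rbind, trace_rows) else NULL),
                     class = c("dynshape_optimization_failure", "error", "condition")))
    # backtracking: evaluate candidate with model and kernel widths fixed
    accepted <- FALSE
    tries <- 0L
    Q_post <- Q_pre
    repeat {
      cand <- ps
      Zc <- Z
      for (k in seq_len(K)) {
        P <- matrix(Z[k, ], ncol = 3L, byrow = TRUE)
        s <- cohort$surfaces[[cells$n[k], cells$t[k]]]
        nor <- surface_normal(P, s, tol = Inf)
        if (is.null(dim(nor))) nor <- matrix(nor, 1L, 3L)
        d <- step_scale * delta[[k]]
        d <- d - rowSums(d * nor) * nor
        Pn <- project_to_surface(P + d, s)
        if (is.null(dim(Pn))) Pn <- matrix(Pn, 1L, 3L)
        Zc[k, ] <- as.vector(t(Pn))
      }
      entc <- entropy_terms(mode, Zc, cells, state, N, T, want_grad = FALSE)
      sampc <- vapply(seq_len(K), function(k)
        samp_terms(matrix(Zc[k, ], ncol = 3L, byrow = TRUE), sig_list[[k]])$H,
        numeric(1))
      Q_cand <- alpha_t * entc$H - cfg$sampling_weight * sum(sampc)
      if (is.finite(Q_cand) && Q_cand <= Q_pre + 1e-10 * (1 + abs(Q_pre))) {
        ps <- set_shape_matrix(ps, Zc)
        Q_post <- Q_cand
        accepted <- TRUE
        # trust-region-style recovery: a clean first-try accept re-grows the
        # step (capped at the base step); without this the persistent
        # halving freezes the optimization early
        if (tries == 0L) step_scale <- min(2 * step_scale, cfg$step_size)
        break
      }
      tries <- tries + 1L
      if (tries > 8L) break
      step_scale <- step_scale / 2
    }
    skipped <- if (accepted) 0L else skipped + 1L
    q_hist <- c(q_hist, Q_post)
    trace_rows[[length(trace_rows) + 1L]] <-
      data.frame(iter = giter, mode = mode, M = M, alpha = alpha_t,
                 Q_pre = Q_pre, Q_post = Q_post,
                 H_corr = ent$H, H_samp = sum(samp_H),
                 step_scale = step_scale, accepted = accepted)
    if (cfg$verbose)
      message(sprintf("[%s] iter %d M=%d Q=%.6g (corr %.4g, samp %.4g) step=%.3g",
                      mode, giter, M, Q_post, ent$H, sum(samp_H), step_scale))
    # convergence-to-split / early stop: relative change < 1e-4 over 10 its
    nh <- length(q_hist)
    if (nh > 10L &&
        abs(q_hist[nh] - q_hist[nh - 10L]) < 1e-4 * (1 + abs(q_hist[nh])))
      break
    if (skipped >= 25L) break   # stalled at minimal step: treat as converged
  }
  list(ps = ps, state = state, trace_rows = trace_rows, used = it)
}

cap_rows <- function(X, caps) {
  nrm <- sqrt(rowSums(X^2))
  f <- pmin(1, caps / pmax(nrm, 1e-300))
  X * f
}

optimize_engine <- function(cohort, config, method) {
  stopifnot(inherits(cohort, "shape_cohort"), inherits(config, "optimizer_config"))
  method <- match.arg(method, c("cross_sectional", "disentangled",
                                "linear_regression", "pc_polynomial"))
  cells <- observed_cells(cohort)
  if (nrow(cells) < 2L) stop("cohort must contain >= 2 observed shapes")
  if (method == "disentangled" && !all(cohort$observed))
    stop("unsupported-design: the disentangled scheme requires a complete N x T grid")
  if (method %in% c("linear_regression", "pc_polynomial") &&
      length(unique(cells$time_value)) < 2L)
    stop("regression methods need at least two distinct time values")
  mode <- switch(method, cross_sectional = "constant",
                 disentangled = "disentangled",
                 linear_regression = "linear", pc_polynomial = "pcpoly")
  total <- config$iterations
  n_levels <- as.integer(log2(config$target_particles)) + 1L
  if (method == "cross_sectional") {
    init_budget <- total; temporal_budget <- 0L
  } else {
    init_budget <- max(n_levels, floor(total * config$init_fraction))
    temporal_budget <- total - init_budget
  }
  per_level <- rep(init_budget %/% n_levels, n_levels)
  per_level[n_levels] <- per_level[n_levels] + init_budget %% n_levels
  ps <- init_particles(cohort)
  state <- list(refit_count = 0L, last_cv_refit = 0L)
  trace_rows <- list()
  giter <- 0L
  carry <- 0L
  mean_diag <- mean(vapply(seq_len(nrow(cells)), function(k)
    surface_diagonal(cohort$surfaces[[cells$n[k], cells$t[k]]]), numeric(1)))
  for (lev in seq_len(n_levels)) {
    budget <- per_level[lev] + carry
    if (budget > 0L) {
      r <- run_phase(ps, "constant", budget, config, giter, total,
                     list(refit_count = state$refit_count,
                          last_cv_refit = state$last_cv_refit),
                     trace_rows)
      ps <- r$ps; trace_rows <- r$trace_rows
      state$refit_count <- r$state$refit_count
      giter <- giter + r$used
      carry <- budget - r$used
    }
    if (lev < n_levels) {
      ps <- split_particles(ps, offset = config$split_offset_rel * mean_diag,
                            rng_seed = config$rng_seed + lev)
    }
  }
  model <- NULL
  if (method != "cross_sectional") {
    budget <- temporal_budget + carry
    st <- list(refit_count = state$refit_count,
               last_cv_refit = state$last_cv_refit)
    r <- run_phase(ps, mode, budget, config, giter, total, st, trace_rows)
    ps <- r$ps; trace_rows <- r$trace_rows
    giter <- giter + r$used
    model <- r$state$model
    if (mode == "disentangled")
      model <- structure(list(mu_t = r$state$mu_t, mu_n = r$state$mu_n),
                         class = "st_disentangled_means")
  } else {
    Z <- as_shape_matrix(ps)
    model <- fit_constant_model(Z)
  }
  trace <- if (length(trace_rows)) do.call(rbind, trace_rows) else NULL
  list(system = ps, model = model, trace = trace, method = method)
}

#' Cross-sectional particle optimization
#'
#' Coarse-to-fine entropy-based correspondence optimization treating every
#' observed (subject, time) shape as an independent sample with a constant
#' shape-space mean.
#'
#' @param cohort a `shape_cohort` with at least 2 observed shapes.
#' @param config an [optimizer_config()].
#' @return a `particle_system`; the optimization trace is attached as
#'   attribute `"trace"` and the fitted constant model as `"model"`.
#' @export
optimize_cross_sectional <- function(cohort, config = optimizer_config()) {
  res <- optimize_engine(cohort, config, "cross_sectional")
  out <- res$system
  attr(out, "trace") <- res$trace
  attr(out, "model") <- res$model
  out
}

#' Spatiotemporal particle optimization
#'
#' Runs the coarse-to-fine cross-sectional initialization, then alternates
#' between refitting the chosen temporal model and entropy-gradient particle
#' updates on the model residuals.
#'
#' @param cohort a `shape_cohort`.
#' @param method one of `"cross_sectional"`, `"disentangled"`,
#'   `"linear_regression"`, `"pc_polynomial"`.
#' @param config an [optimizer_config()].
#' @return list with elements `system` (the `particle_system`), `model`
#'   (the fitted temporal model), `trace` (per-iteration objective values)
#'   and `method`.
#' @export
optimize_spatiotemporal <- function(cohort, method = "pc_polynomial",
                                    config = optimizer_config()) {
  optimize_engine(cohort, config, method)
}
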