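# Two-modality, two-unit model: each modality has one input and one output
# neuron, feedforward gains w11/w22, and only the two cross-modal recurrent
# connections (K12, K21) are learnable. Inputs are independent zero-mean
# Gaussians. All expectations on the analysis path are deterministic
# Gauss-Hermite quadratures, so the learning map, its Jacobian and the phase
# diagram are reproducible to quadrature accuracy.

.gh_env <- new.env(parent = emptyenv())

.gauss_hermite <- function(order) {
  key <- as.character(order)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(order)
  .gh_env[[key]]
}

# E[f(sigma * Z)] for Z ~ N(0,1), vectorized f
.gauss_expect <- function(f, sigma, order) {
  gh <- .gauss_hermite(order)
  sum(gh$w * f(sqrt(2) * sigma * gh$x)) / sqrt(pi)
}

#' Specification of the two-unit cross-modal model
#'
#' @param w11,w22 feedforward gains of the two modalities
#' @param sigma1,sigma2 standard deviations of the two independent zero-mean
#'   Gaussian inputs
#' @param quadrature_order Gauss-Hermite order used for all expectations
#'   (tensor product in two dimensions); high orders are needed because at
#'   large input sigma the integrands approach step functions and the
#'   quadrature converges slowly
#' @return a list of class `synmax_simple_spec`
#' @export
simple_model_spec <- function(sigma1, sigma2, w11 = 1, w22 = 1,
                              quadrature_order = 128) {
  stopifnot(sigma1 > 0, sigma2 > 0, quadrature_order >= 16)
  structure(list(w11 = w11, w22 = w22, sigma1 = sigma1, sigma2 = sigma2,
                 quadrature_order = as.integer(quadrature_order)),
            class = "synmax_simple_spec")
}

#' Build the two-unit network for given cross-talk weights
#'
#' The mask restricts learning to the two cross-modal entries; the
#' within-modality recurrent entries are structural zeros.
#'
#' @param spec a [simple_model_spec()]
#' @param K12 weight from unit 2 to unit 1
#' @param K21 weight from unit 1 to unit 2
#' @return a [network_params()] object
#' @export
simple_network <- function(spec, K12 = 0, K21 = 0) {
  W <- diag(c(spec$w11, spec$w22))
  K <- matrix(c(0, K21, K12, 0), 2, 2)  # column-major: K[1,2] = K12
  mask <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  network_params(W, K, mask_K = mask)
}

#' Steady-state output variance of a single logistic unit
#'
#' Var\[g(w x)\] for x ~ N(0, sigma^2), by Gauss-Hermite quadrature. The
#' variance grows monotonically with sigma from 0 toward the supremum 0.25
#' (the unit's output approaches a Bernoulli(1/2) variable as the input
#' saturates it), which is why the phase diagram lives on (0, 0.25)^2.
#'
#' @param sigma input standard deviation (> 0)
#' @param w feedforward gain
#' @param order quadrature order
#' @return scalar variance in (0, 0.25)
#' @export
output_variance <- function(sigma, w = 1, order = 64) {
  stopifnot(sigma > 0)
  g <- logistic_activation()$g
  m1 <- .gauss_expect(function(x) g(w * x), sigma, order)
  m2 <- .gauss_expect(function(x) g(w * x)^2, sigma, order)
  m2 - m1^2
}

#' Input standard deviation producing a target output variance
#'
#' Inverts [output_variance()] by bisection on the monotone map, so the
#' phase diagram can be parameterized directly by output variance.
#'
#' @param v target output variance, in (0, 0.25)
#' @param w feedforward gain
#' @param tol absolute tolerance on the achieved variance
#' @param sigma_max guard on the search interval; v near 0.25 needs very
#'   large sigma and eventually trips this guard
#' @param order quadrature order
#' @return scalar sigma
#' @export
sigma_for_output_variance <- function(v, w = 1, tol = 1e-8, sigma_max = 1e6,
                                      order = 64) {
  if (v <= 0 || v >= 0.25) {
    stop("output variance must lie in (0, 0.25); got ", v)
  }
  lo <- 1e-9; hi <- 1
  while (output_variance(hi, w, order) < v) {
    hi <- hi * 10
    if (hi > sigma_max) stop("sigma exceeds guard ", sigma_max,
                             " before reaching variance ", v)
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    vm <- output_variance(mid, w, order)
    if (abs(vm - v) <= tol) return(mid)
    if (vm < v) lo <- mid else hi <- mid
  }
  mid
}

#' Expected infomax update map of the cross-talk weights
#'
#' F(K12, K21): the expectation over the two independent input Gaussians of
#' the analytic update direction for (K12, K21), computed by tensor-product
#' Gauss-Hermite quadrature. Zero cross-talk is a fixed point: F(0, 0) = 0.
#' The stochastic learning dynamics are K <- K + eta * F(K) plus sampling
#' noise; the stability of the origin under this map is what the phase
#' diagram classifies.
#'
#' @param spec a [simple_model_spec()]
#' @param K12,K21 cross-talk weights at which to evaluate the map
#' @param solver_cfg a [solver_config()]
#' @return numeric length-2 vector (F12, F21)
#' @export
expected_update_map <- function(spec, K12, K21, solver_cfg = solver_config()) {
  gh <- .gauss_hermite(spec$quadrature_order)
  drop(.simple_update_map_cpp(spec$w11, spec$w22,
                              sqrt(2) * spec$sigma1 * gh$x, gh$w / sqrt(pi),
                              sqrt(2) * spec$sigma2 * gh$x, gh$w / sqrt(pi),
                              K12, K21, solver_cfg$alpha, solver_cfg$tol,
                              solver_cfg$max_iter))
}

# reference implementation through the generic network / susceptibility /
# gradient machinery; quadratically slower than the closed-form path above
# and kept as its cross-check
.expected_update_map_generic <- function(spec, K12, K21,
                                         solver_cfg = solver_config()) {
  params <- simple_network(spec, K12, K21)
  gh <- .gauss_hermite(spec$quadrature_order)
  n <- length(gh$x)
  F12 <- 0; F21 <- 0
  for (i in seq_len(n)) {
    x1 <- sqrt(2) * spec$sigma1 * gh$x[i]
    for (j in seq_len(n)) {
      x2 <- sqrt(2) * spec$sigma2 * gh$x[j]
      wgt <- gh$w[i] * gh$w[j] / pi
      st <- solve_steady_state(params, c(x1, x2), solver_cfg)
      if (!st$converged) stop("steady state did not converge at quadrature node (",
                              i, ",", j, ")")
      sb <- susceptibility(params, st$s, c(x1, x2))
      G <- t(sb$chi %*% sb$Gamma) + t(sb$phi) %*% (sb$a %o% sb$s)
      F12 <- F12 + wgt * G[1, 2]
      F21 <- F21 + wgt * G[2, 1]
    }
  }
  c(F12, F21)
}

#' Linear stability of the no-cross-talk fixed point
#'
#' Central-difference Jacobian of the expected update map at the origin
#' (K12 = K21 = 0), its eigenvalues, a stability flag for the continuous
#' (learning-rate -> 0) flow, and the critical learning rate of the discrete
#' map K <- K + eta F(K): the largest eta for which every multiplier
#' 1 + eta * lambda stays inside the unit circle,
#' eta_critical = min over stable eigenvalues of -2 Re(lambda) / |lambda|^2.
#' When the origin is already unstable for the flow, eta_critical = 0.
#'
#' @param spec a [simple_model_spec()]
#' @param fd_step central-difference step on K
#' @param solver_cfg a [solver_config()]
#' @return list of class `synmax_stability`: `jacobian`, `eigenvalues`,
#'   `stable`, `eta_critical`
#' @export
stability_at_origin <- function(spec, fd_step = 1e-4,
                                solver_cfg = solver_config()) {
  J <- matrix(0, 2, 2)
  Fp <- expected_update_map(spec, fd_step, 0, solver_cfg)
  Fm <- expected_update_map(spec, -fd_step, 0, solver_cfg)
  J[, 1] <- (Fp - Fm) / (2 * fd_step)
  Fp <- expected_update_map(spec, 0, fd_step, solver_cfg)
  Fm <- expected_update_map(spec, 0, -fd_step, solver_cfg)
  J[, 2] <- (Fp - Fm) / (2 * fd_step)
  ev <- eigen(J, only.values = TRUE)$values
  stable <- all(Re(ev) < 0)
  eta_c <- if (!stable) 0 else min(-2 * Re(ev) / Mod(ev)^2)
  structure(list(jacobian = J, eigenvalues = ev, stable = stable,
                 eta_critical = eta_c),
            class = "synmax_stability")
}

#' @export
print.synmax_stability <- function(x, ...) {
  cat("<synmax_stability> ", if (x$stable) "stable" else "unstable",
      " origin; eigenvalues ", paste(format(x$eigenvalues, digits = 4),
                                     collapse = ", "),
      "; eta_critical ", format(x$eta_critical, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Phase diagram of cross-talk stability over output variances
#'
#' For every pair (v1, v2) of output variances, converts each variance to
#' the input sigma that produces it, runs the linear stability analysis at
#' the origin, and records the classification and the critical learning
#' rate. The central region of the (v1, v2) plane is stable (no cross-talk,
#' no synaesthesia); leaving it by lowering one variance (sensory
#' deprivation) or raising the other (sensory flooding) destabilizes the
#' no-cross-talk state.
#'
#' @param v1,v2 vectors of output variances in (0, 0.25); the grid is their
#'   Cartesian product
#' @param w11,w22 feedforward gains
#' @param quadrature_order Gauss-Hermite order for the update-map quadrature
#' @param solver_cfg a [solver_config()]
#' @return data frame: v1, v2, stable, eta_critical, eig_re1, eig_im1,
#'   eig_re2, eig_im2, ok (FALSE where the analysis failed)
#' @export
phase_diagram <- function(v1, v2, w11 = 1, w22 = 1, quadrature_order = 128,
                          solver_cfg = solver_config()) {
  sig1 <- vapply(v1, sigma_for_output_variance, numeric(1), w = w11)
  sig2 <- vapply(v2, sigma_for_output_variance, numeric(1), w = w22)
  out <- expand.grid(i = seq_along(v1), j = seq_along(v2))
  res <- lapply(seq_len(nrow(out)), function(r) {
    i <- out$i[r]; j <- out$j[r]
    spec <- simple_model_spec(sig1[i], sig2[j], w11, w22, quadrature_order)
    st <- tryCatch(stability_at_origin(spec, solver_cfg = solver_cfg),
                   error = function(e) NULL)
    if (is.null(st)) {
      data.frame(v1 = v1[i], v2 = v2[j], stable = NA, eta_critical = NA_real_,
                 eig_re1 = NA_real_, eig_im1 = NA_real_,
                 eig_re2 = NA_real_, eig_im2 = NA_real_, ok = FALSE)
    } else {
      data.frame(v1 = v1[i], v2 = v2[j], stable = st$stable,
                 eta_critical = st$eta_critical,
                 eig_re1 = Re(st$eigenvalues[1]), eig_im1 = Im(st$eigenvalues[1]),
                 eig_re2 = Re(st$eigenvalues[2]), eig_im2 = Im(st$eigenvalues[2]),
                 ok = TRUE)
    }
  })
  do.call(rbind, res)
}

#' Stochastic learning outcomes over the output-variance grid
#'
#' For every (v1, v2) pair, initializes the cross-talk weights uniformly on
#' a ring of radius `init_ring_radius` around the origin, trains with
#' online stochastic infomax updates on Gaussian input samples, and
#' classifies the outcome by the final distance from the origin:
#' "crosstalk" if it grew past `grow_threshold` times the initial radius,
#' "none" if it shrank below `shrink_threshold` times, otherwise
#' "undecided" (near the stability borderline the dynamics are very slow,
#' so undecided is a legitimate outcome there).
#'
#' @inheritParams phase_diagram
#' @param eta learning rate
#' @param n_updates gradient updates per grid point
#' @param batch_size stimuli averaged per update (averaging keeps the
#'   stochastic diffusion floor of ||(K12, K21)|| below the shrink
#'   threshold at stable points)
#' @param init_ring_radius radius of the random initial condition; large
#'   enough to sit clearly above the diffusion floor, small enough to stay
#'   in the linearization's basin
#' @param seed base seed; each grid point derives its own child seed
#' @param grow_threshold,shrink_threshold classification multipliers on the
#'   initial radius
#' @return data frame: v1, v2, outcome, final_norm_ratio
#' @export
simulate_learning_grid <- function(v1, v2, eta = 0.012, n_updates = 15000,
                                   batch_size = 4, init_ring_radius = 0.5,
                                   seed = 1,
                                   grow_threshold = 4, shrink_threshold = 0.3,
                                   w11 = 1, w22 = 1,
                                   solver_cfg = solver_config()) {
  sig1 <- vapply(v1, sigma_for_output_variance, numeric(1), w = w11)
  sig2 <- vapply(v2, sigma_for_output_variance, numeric(1), w = w22)
  grid <- expand.grid(i = seq_along(v1), j = seq_along(v2))
  res <- lapply(seq_len(nrow(grid)), function(r) {
    i <- grid$i[r]; j <- grid$j[r]
    child <- derive_seed(seed, r)
    set.seed(child)
    ang <- stats::runif(1, 0, 2 * pi)
    fit <- tryCatch(
      .simple_train_cpp(w11, w22, sig1[i], sig2[j],
                        init_ring_radius * cos(ang),
                        init_ring_radius * sin(ang),
                        eta, as.integer(n_updates), as.integer(batch_size),
                        solver_cfg$alpha, solver_cfg$tol, solver_cfg$max_iter),
      error = function(e) NULL)
    ratio <- if (is.null(fit)) Inf else
      sqrt(fit$k12^2 + fit$k21^2) / init_ring_radius
    outcome <- if (ratio > grow_threshold) "crosstalk"
               else if (ratio < shrink_threshold) "none"
               else "undecided"
    data.frame(v1 = v1[i], v2 = v2[j], outcome = outcome,
               final_norm_ratio = ratio)
  })
  do.call(rbind, res)
}
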