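#' Recurrent rate network parameters
#'
#' Bundles the full model: an N-dimensional input layer drives an
#' M-dimensional output layer through feedforward weights `W`; the output
#' units interact through recurrent weights `K` and pass their net input
#' through a squashing activation. Only overcomplete representations
#' (M >= N) are supported. `mask_K` marks which recurrent entries are
#' learnable; masked-out entries are structural zeros and stay exactly 0
#' through construction and every learning update (used e.g. to forbid
#' within-modality connections in the two-unit model).
#'
#' @param W feedforward weight matrix, M x N
#' @param K recurrent weight matrix, M x M (defaults to all zero)
#' @param tau time constant of the rate dynamics (only sets the time scale;
#'   steady states do not depend on it)
#' @param activation a [activation()] bundle; default [logistic_activation()]
#' @param mask_K logical M x M, TRUE where K is learnable; default all TRUE
#' @return an object of class `synmax_network`
#' @export
network_params <- function(W, K = NULL, tau = 1,
                           activation = logistic_activation(),
                           mask_K = NULL) {
  W <- as.matrix(W)
  M <- nrow(W); N <- ncol(W)
  if (M < N) {
    stop("only overcomplete representations are supported (need M >= N, got M = ",
         M, ", N = ", N, ")")
  }
  if (is.null(K)) K <- matrix(0, M, M)
  K <- as.matrix(K)
  stopifnot(nrow(K) == M, ncol(K) == M)
  if (is.null(mask_K)) mask_K <- matrix(TRUE, M, M)
  mask_K <- matrix(as.logical(mask_K), M, M)
  K[!mask_K] <- 0
  stopifnot(is.numeric(tau), tau > 0)
  stopifnot(inherits(activation, "synmax_activation"))
  structure(list(W = W, K = K, tau = tau, activation = activation,
                 mask_K = mask_K, M = M, N = N),
            class = "synmax_network")
}

#' @export
print.synmax_network <- function(x, ...) {
  cat("<synmax_network> ", x$N, " inputs -> ", x$M, " outputs (",
      x$activation$name, " activation), ",
      sum(x$mask_K), "/", x$M * x$M, " recurrent entries learnable\n",
      sep = "")
  invisible(x)
}

#' Replace the recurrent weights of a network
#'
#' Re-applies the structural-zero mask, so masked entries can never be
#' smuggled in.
#'
#' @param params a `synmax_network`
#' @param K new recurrent matrix, M x M
#' @return the modified `synmax_network`
#' @export
set_recurrent <- function(params, K) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == params$M, ncol(K) == params$M)
  K[!params$mask_K] <- 0
  params$K <- K
  params
}

#' Steady-state solver configuration
#'
#' The steady state s = g(Wx + Ks) is found by damped fixed-point iteration
#' s <- (1 - alpha) s + alpha g(Wx + Ks), equivalent to explicit Euler on the
#' rate dynamics with step alpha * tau. Iteration stops when the max-abs
#' change in s falls to `tol`; the iteration count is the operational
#' convergence time used for critical-slowing-down diagnostics.
#'
#' @param alpha damping step in (0, 1]
#' @param tol convergence tolerance on the max-abs update
#' @param max_iter iteration cap; non-convergence is flagged, not fatal
#' @return a list of class `synmax_solver_cfg`
#' @export
solver_config <- function(alpha = 0.1, tol = 1e-9, max_iter = 2e5) {
  stopifnot(alpha > 0, alpha <= 1, tol > 0, max_iter >= 1)
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter)),
            class = "synmax_solver_cfg")
}

#' Solve for the network steady state
#'
#' Iterates the damped fixed-point map from the recurrence-free start
#' s0 = g(Wx) (fresh for every stimulus, so iteration counts are comparable
#' across learning stages). Returns the activities, the iteration count, a
#' convergence flag and the final residual.
#'
#' @param params a [network_params()] object
#' @param x stimulus vector of length N
#' @param solver_cfg a [solver_config()]
#' @return list with elements `s`, `iterations`, `converged`, `residual`
#' @export
solve_steady_state <- function(params, x, solver_cfg = solver_config()) {
  x <- as.numeric(x)
  stopifnot(length(x) == params$N, all(is.finite(x)))
  h <- drop(params$W %*% x)
  act <- params$activation
  s0 <- act$g(h)
  if (identical(act$name, "logistic")) {
    res <- .steady_state_cpp(h, params$K, s0, solver_cfg$alpha,
                             solver_cfg$tol, solver_cfg$max_iter)
    res$s <- drop(res$s)
  } else {
    res <- .steady_state_r(h, params$K, s0, act$g, solver_cfg)
  }
  if (!all(is.finite(res$s))) stop("steady-state solver produced non-finite activities")
  res
}

# pure-R fallback for non-logistic activations
.steady_state_r <- function(h, K, s0, g, cfg) {
  s <- s0
  converged <- FALSE
  resid <- Inf
  for (it in seq_len(cfg$max_iter)) {
    snew <- (1 - cfg$alpha) * s + cfg$alpha * g(h + drop(K %*% s))
    resid <- max(abs(snew - s))
    s <- snew
    if (!all(is.finite(s))) stop("steady-state iteration produced non-finite activities")
    if (resid <= cfg$tol) { converged <- TRUE; break }
  }
  list(s = s, iterations = it, converged = converged, residual = resid)
}

#' Susceptibility and learning-rule auxiliaries at a steady state
#'
#' Given a converged steady state s for stimulus x, computes the derived
#' matrices the infomax objective and its gradient are built from:
#' \itemize{
#'   \item G = diag(g'(u)) at the net inputs u = Wx + Ks;
#'   \item phi = (G^-1 - K)^-1, the recurrent amplification matrix;
#'   \item chi = phi W, the susceptibility (Jacobian ds/dx of the
#'     input-to-steady-state map);
#'   \item Gamma = (chi' chi)^-1 chi' phi;
#'   \item a_k = [chi Gamma]_kk g''_k / (g'_k)^3.
#' }
#' A singular (G^-1 - K) means the linearized recurrent dynamics have lost
#' stability (the super-critical, attractor-dominated regime) and is an
#' error; a singular chi' chi means the representation is degenerate.
#'
#' @param params a [network_params()] object
#' @param s converged steady-state activity vector (length M)
#' @param x the stimulus that produced `s` (length N)
#' @return list of class `synmax_sensitivity` with elements
#'   `s`, `g1` (vector g'), `G`, `phi`, `chi`, `Gamma`, `a`
#' @export
susceptibility <- function(params, s, x) {
  act <- params$activation
  u <- drop(params$W %*% as.numeric(x)) + drop(params$K %*% s)
  g1 <- act$g_prime(u)
  g2 <- act$g_double_prime(u)
  if (any(g1 <= 0)) stop("non-positive activation slope; susceptibility undefined")
  # phi = (G^-1 - K)^-1, evaluated via the algebraically equivalent
  # (I - GK)^-1 G: I - GK keeps O(1) entries even where g' is minuscule
  # (saturated units), where G^-1 - K is catastrophically scaled
  A <- diag(params$M) - g1 * params$K
  phi <- tryCatch(solve(A, diag(g1, params$M), tol = 0),
                  error = function(e) stop(
                    "(G^-1 - K) is numerically singular: super-critical / attractor regime",
                    call. = FALSE))
  if (!all(is.finite(phi))) {
    stop("(G^-1 - K) is numerically singular: super-critical / attractor regime",
         call. = FALSE)
  }
  chi <- phi %*% params$W
  ctc <- crossprod(chi)
  Gamma <- tryCatch(solve(ctc, crossprod(chi, phi), tol = 0),
                    error = function(e) stop(
                      "chi' chi is numerically singular: degenerate representation",
                      call. = FALSE))
  if (!all(is.finite(Gamma))) {
    stop("chi' chi is numerically singular: degenerate representation",
         call. = FALSE)
  }
  # a_k = [chi Gamma]_kk g''_k / (g'_k)^3; evaluated as sequential divisions
  # so the intermediate (g')^3 cannot underflow at saturating net inputs
  a <- (diag(chi %*% Gamma) / g1 / g1) * (g2 / g1)
  structure(list(s = s, g1 = g1, G = diag(g1, params$M), phi = phi, chi = chi,
                 Gamma = Gamma, a = a, log_det_ctc = determinant(ctc)$modulus[1]),
            class = "synmax_sensitivity")
}
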