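#' Infomax objective over a stimulus set
#'
#' With deterministic rate dynamics, maximizing the mutual information
#' between inputs and steady-state outputs is equivalent to maximizing the
#' output entropy, and is implemented as minimizing
#' epsilon = -1/2 < ln det(chi' chi) >, the average over stimuli of the
#' log-volume amplification of the input-to-output map. Lower epsilon means
#' the network is more sensitive to input changes.
#'
#' @param params a [network_params()] object
#' @param samples stimulus samples: a matrix with one row per sample (n x N)
#'   or a list of length-N vectors
#' @param solver_cfg a [solver_config()]
#' @return scalar epsilon
#' @export
objective_epsilon <- function(params, samples, solver_cfg = solver_config()) {
  X <- .as_sample_matrix(samples, params$N)
  vals <- vapply(seq_len(nrow(X)), function(i) {
    st <- solve_steady_state(params, X[i, ], solver_cfg)
    if (!st$converged) {
      stop("steady state did not converge for sample ", i)
    }
    sb <- tryCatch(susceptibility(params, st$s, X[i, ]),
                   error = function(e) stop("sample ", i, ": ",
                                            conditionMessage(e), call. = FALSE))
    -0.5 * sb$log_det_ctc
  }, numeric(1))
  mean(vals)
}

.as_sample_matrix <- function(samples, N) {
  if (is.list(samples)) samples <- do.call(rbind, lapply(samples, as.numeric))
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = N)
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == N)
  samples
}

#' Analytic infomax gradient update direction for the recurrent weights
#'
#' Returns the sample-averaged update direction
#' < (chi Gamma)' + phi' a s' >, which is exactly -d epsilon / dK (the
#' implicit dependence of the steady state on K is accounted for by the
#' a-vector term). The learning step is K <- K + eta * grad. Entries masked
#' out in `params$mask_K` are forced to zero.
#'
#' @inheritParams objective_epsilon
#' @return M x M matrix: the update direction per unit learning rate
#' @seealso [grad_K_numeric()] for the brute-force finite-difference oracle
#' @export
grad_K_analytic <- function(params, samples, solver_cfg = solver_config()) {
  X <- .as_sample_matrix(samples, params$N)
  G <- matrix(0, params$M, params$M)
  for (i in seq_len(nrow(X))) {
    st <- solve_steady_state(params, X[i, ], solver_cfg)
    if (!st$converged) stop("steady state did not converge for sample ", i)
    sb <- susceptibility(params, st$s, X[i, ])
    G <- G + t(sb$chi %*% sb$Gamma) + t(sb$phi) %*% (sb$a %o% sb$s)
  }
  G <- G / nrow(X)
  G[!params$mask_K] <- 0
  G
}

#' Finite-difference gradient of the infomax objective (oracle)
#'
#' Brute-force central differences of [objective_epsilon()] with respect to
#' each learnable entry of K, re-solving the steady states at K +/- delta.
#' Slow and only for verification: the analytic rule must agree with
#' -1 times this matrix.
#'
#' @inheritParams objective_epsilon
#' @param delta perturbation size; the default 1e-5 balances truncation
#'   against cancellation at the solver tolerance
#' @return M x M matrix d epsilon / dK (masked entries zero)
#' @export
grad_K_numeric <- function(params, samples, solver_cfg = solver_config(),
                           delta = 1e-5) {
  G <- matrix(0, params$M, params$M)
  for (i in seq_len(params$M)) {
    for (j in seq_len(params$M)) {
      if (!params$mask_K[i, j]) next
      Kp <- params$K; Kp[i, j] <- Kp[i, j] + delta
      Km <- params$K; Km[i, j] <- Km[i, j] - delta
      ep <- objective_epsilon(set_recurrent(params, Kp), samples, solver_cfg)
      em <- objective_epsilon(set_recurrent(params, Km), samples, solver_cfg)
      G[i, j] <- (ep - em) / (2 * delta)
    }
  }
  G
}

#' Learning configuration
#'
#' @param eta learning rate per update (fixed across training)
#' @param n_updates number of gradient updates
#' @param batch_size stimuli averaged per update (default 1: online learning)
#' @param checkpoint_every evaluate the objective on the frozen evaluation
#'   set every this many updates
#' @param eval_set_size size of the evaluation set, drawn once at the start
#' @param seed RNG seed for stimulus sampling
#' @param max_nonconverged_frac abort when more than this fraction of all
#'   steady-state solves has failed to converge
#' @return a list of class `synmax_learning_cfg`
#' @export
learning_config <- function(eta, n_updates, batch_size = 1,
                            checkpoint_every = 100, eval_set_size = 100,
                            seed = 1, max_nonconverged_frac = 0.1) {
  stopifnot(eta >= 0, n_updates >= 0, batch_size >= 1,
            checkpoint_every >= 1, eval_set_size >= 1)
  structure(list(eta = eta, n_updates = as.integer(n_updates),
                 batch_size = as.integer(batch_size),
                 checkpoint_every = as.integer(checkpoint_every),
                 eval_set_size = as.integer(eval_set_size),
                 seed = as.integer(seed),
                 max_nonconverged_frac = max_nonconverged_frac),
            class = "synmax_learning_cfg")
}

#' Train the recurrent weights by infomax gradient ascent on sensitivity
#'
#' Presents random stimuli from `input_sampler` and updates
#' K <- K + eta * grad after each batch. Because the learning rate is kept
#' fixed, the objective can rise again once the network approaches a
#' critical point; the trace therefore checkpoints the objective on a frozen
#' evaluation set and keeps the interaction pattern with the minimal
#' objective (`best_K`) alongside the final one. Near-singular update steps
#' are skipped and counted rather than fatal. Per-sample solver iteration
#' counts are recorded: their growth along training is the critical-slowing-
#' down diagnostic.
#'
#' @param params a [network_params()] object (its K is the initial condition)
#' @param input_sampler function(n) returning an n x N matrix of stimuli;
#'   must consume the R RNG so that training is reproducible under the seed
#' @param cfg a [learning_config()]
#' @param solver_cfg a [solver_config()]
#' @return object of class `synmax_trace`: list with `checkpoints` (data
#'   frame: step, epsilon, relaxes), `iterations` (per-sample solver counts),
#'   `best_K`, `best_epsilon`, `best_step`, `final_K`, `n_skipped`,
#'   `n_nonconverged`
#' @export
train <- function(params, input_sampler, cfg, solver_cfg = solver_config()) {
  set.seed(cfg$seed)
  eval_X <- input_sampler(cfg$eval_set_size)
  K <- params$K
  p <- params
  iters <- integer(cfg$n_updates * cfg$batch_size)
  n_skipped <- 0L
  n_nonconv <- 0L
  n_solved <- 0L
  steps <- integer(0)
  eps <- numeric(0)

  eval_eps <- function(p) {
    tryCatch(objective_epsilon(p, eval_X, solver_cfg), error = function(e) NA_real_)
  }
  # recorded per checkpoint as a diagnostic: does the network still relax
  # under zero input, its most excitable state? FALSE marks patterns that
  # are super-critical at rest (the attractor/hallucination regime).
  relax_cfg <- solver_config(solver_cfg$alpha, solver_cfg$tol,
                             max(solver_cfg$max_iter, 2e5))
  relaxes <- function(p) {
    tryCatch(solve_steady_state(p, rep(0, p$N), relax_cfg)$converged,
             error = function(e) FALSE)
  }

  e0 <- eval_eps(p)
  r0 <- relaxes(p)
  steps <- 0L; eps <- e0; relax <- r0
  best_eps <- e0
  best_K <- K; best_step <- 0L
  # also track the best pattern among those that relax at rest, as a
  # probe-safe alternative when the global optimum is super-critical under
  # weak input
  best_rx_eps <- if (r0) e0 else NA_real_
  best_rx_K <- K; best_rx_step <- 0L

  for (t in seq_len(cfg$n_updates)) {
    X <- input_sampler(cfg$batch_size)
    G <- matrix(0, p$M, p$M)
    n_ok <- 0L
    for (b in seq_len(cfg$batch_size)) {
      st <- solve_steady_state(p, X[b, ], solver_cfg)
      n_solved <- n_solved + 1L
      iters[n_solved] <- st$iterations
      if (!st$converged) {
        n_nonconv <- n_nonconv + 1L
        next
      }
      sb <- tryCatch(susceptibility(p, st$s, X[b, ]), error = function(e) NULL)
      if (is.null(sb)) next
      G <- G + t(sb$chi %*% sb$Gamma) + t(sb$phi) %*% (sb$a %o% sb$s)
      n_ok <- n_ok + 1L
    }
    if (n_solved >= 50 && n_nonconv / n_solved > cfg$max_nonconverged_frac) {
      stop("training aborted: ", n_nonconv, "/", n_solved,
           " steady-state solves failed to converge")
    }
    if (n_ok > 0L) {
      # average over the usable part of the batch; near criticality single
      # samples fail to converge or hit singular susceptibilities, and
      # discarding whole batches there would stall learning entirely
      G <- G / n_ok
      G[!p$mask_K] <- 0
      K <- K + cfg$eta * G
      p <- set_recurrent(p, K)
    } else {
      n_skipped <- n_skipped + 1L
    }
    if (t %% cfg$checkpoint_every == 0L) {
      e <- eval_eps(p)
      r <- relaxes(p)
      steps <- c(steps, t); eps <- c(eps, e); relax <- c(relax, r)
      if (is.finite(e) && (!is.finite(best_eps) || e < best_eps)) {
        best_eps <- e; best_K <- K; best_step <- t
      }
      if (r && is.finite(e) && (!is.finite(best_rx_eps) || e < best_rx_eps)) {
        best_rx_eps <- e; best_rx_K <- K; best_rx_step <- t
      }
    }
  }

  structure(list(checkpoints = data.frame(step = steps, epsilon = eps,
                                          relaxes = relax),
                 iterations = iters,
                 best_K = best_K, best_epsilon = best_eps,
                 best_step = best_step,
                 best_relaxing_K = best_rx_K,
                 best_relaxing_epsilon = best_rx_eps,
                 best_relaxing_step = best_rx_step,
                 final_K = K,
                 n_skipped = n_skipped, n_nonconverged = n_nonconv),
            class = "synmax_trace")
}

#' @export
print.synmax_trace <- function(x, ...) {
  cat("<synmax_trace> ", length(x$iterations), " samples, ",
      nrow(x$checkpoints), " checkpoints; best epsilon ",
      format(x$best_epsilon, digits = 6), " at step ", x$best_step, "\n",
      sep = "")
  invisible(x)
}

#' Critical-slowing-down ratio of a training trace
#'
#' Ratio of the median per-sample solver iteration count over the final
#' fraction of training to that over the initial fraction. Values well above
#' 1 indicate the learned interactions have moved the network toward a
#' critical point, where relaxation to steady state slows down dramatically.
#'
#' @param trace a `synmax_trace`
#' @param frac fraction of samples at each end to compare (default 0.05)
#' @return scalar ratio (late / early)
#' @export
slowing_ratio <- function(trace, frac = 0.05) {
  it <- trace$iterations
  n <- length(it)
  k <- max(1L, floor(frac * n))
  stats::median(it[(n - k + 1L):n]) / stats::median(it[1:k])
}
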