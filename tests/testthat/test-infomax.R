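test_that("objective has its closed-form value on decoupled units", {
  # single logistic unit at x = 0: chi = g'(0) = 0.25, eps = -0.5 ln(0.25^2)
  p1 <- network_params(matrix(1, 1, 1))
  expect_equal(objective_epsilon(p1, matrix(0, 1, 1)), log(4), tolerance = 1e-12)
  # two decoupled identical units: determinant factorizes
  p2 <- network_params(diag(2))
  expect_equal(objective_epsilon(p2, matrix(0, 1, 2)), 2 * log(4),
               tolerance = 1e-12)
})

test_that("objective equals the mean of independently computed log-determinants", {
  p <- random_network(4, 3, k_sd = 0.15, seed = 31)
  X <- random_samples(10, 3, seed = 32)
  eps <- objective_epsilon(p, X)
  # independent route: eigenvalue-based log-determinant per sample
  vals <- sapply(seq_len(nrow(X)), function(i) {
    st <- solve_steady_state(p, X[i, ])
    sb <- susceptibility(p, st$s, X[i, ])
    -0.5 * sum(log(eigen(crossprod(sb$chi), symmetric = TRUE,
                         only.values = TRUE)$values))
  })
  expect_equal(eps, mean(vals), tolerance = 1e-10)
})

test_that("analytic update direction equals minus the finite-difference gradient", {
  # the central oracle-equivalence property, across many random networks
  set.seed(77)
  sizes <- cbind(M = sample(3:6, 20, replace = TRUE),
                 N = sample(2:3, 20, replace = TRUE))
  for (r in seq_len(nrow(sizes))) {
    p <- random_network(sizes[r, "M"], sizes[r, "N"],
                        k_sd = 0.12, seed = 500 + r)
    X <- random_samples(20, sizes[r, "N"], seed = 900 + r)
    ga <- grad_K_analytic(p, X)
    gn <- grad_K_numeric(p, X)
    expect_equal(ga, -gn, tolerance = 1e-4)
  }
})

test_that("the second gradient term vanishes when all activities sit at 0.5", {
  # symmetric construction: x = 0 gives s = 0.5 everywhere, where g'' = 0
  p <- network_params(diag(3))
  X <- matrix(0, 1, 3)
  st <- solve_steady_state(p, X[1, ])
  expect_equal(st$s, rep(0.5, 3))
  sb <- susceptibility(p, st$s, X[1, ])
  expect_equal(sb$a, rep(0, 3))
  expect_equal(grad_K_analytic(p, X), t(sb$chi %*% sb$Gamma), tolerance = 1e-12)
})

test_that("a small step along the update direction does not increase the objective", {
  p <- random_network(4, 2, k_sd = 0.1, seed = 41)
  X <- random_samples(15, 2, seed = 42)
  e0 <- objective_epsilon(p, X)
  g <- grad_K_analytic(p, X)
  p1 <- set_recurrent(p, p$K + 1e-3 * g)
  expect_lte(objective_epsilon(p1, X), e0)
})

test_that("training with zero learning rate leaves the weights untouched", {
  p <- random_network(3, 2, k_sd = 0.1, seed = 51)
  cfg <- learning_config(eta = 0, n_updates = 20, checkpoint_every = 10,
                         eval_set_size = 5, seed = 7)
  sampler <- function(n) matrix(rnorm(2 * n), n, 2)
  tr <- train(p, sampler, cfg)
  expect_identical(tr$final_K, p$K)
})

test_that("training is deterministic under a fixed seed", {
  p <- random_network(3, 2, k_sd = 0.1, seed = 52)
  cfg <- learning_config(eta = 0.05, n_updates = 60, checkpoint_every = 20,
                         eval_set_size = 10, seed = 13)
  sampler <- function(n) matrix(rnorm(2 * n), n, 2)
  tr1 <- train(p, sampler, cfg)
  tr2 <- train(p, sampler, cfg)
  expect_identical(tr1$final_K, tr2$final_K)
  expect_identical(tr1$checkpoints, tr2$checkpoints)
  expect_identical(tr1$iterations, tr2$iterations)
})

test_that("the checkpointed best objective is the minimum of the trace", {
  p <- random_network(3, 2, k_sd = 0.15, seed = 53)
  cfg <- learning_config(eta = 0.1, n_updates = 200, checkpoint_every = 25,
                         eval_set_size = 20, seed = 5)
  sampler <- function(n) matrix(rnorm(2 * n, sd = 1.5), n, 2)
  tr <- train(p, sampler, cfg)
  expect_equal(tr$best_epsilon, min(tr$checkpoints$epsilon, na.rm = TRUE))
  eval_direct <- local({
    set.seed(cfg$seed)
    X <- sampler(cfg$eval_set_size)
    objective_epsilon(set_recurrent(p, tr$best_K), X)
  })
  expect_equal(eval_direct, tr$best_epsilon, tolerance = 1e-12)
})

test_that("masked entries stay exactly zero throughout training", {
  spec <- simple_model_spec(2, 2)
  p <- simple_network(spec, 0.05, -0.05)
  cfg <- learning_config(eta = 0.05, n_updates = 100, checkpoint_every = 50,
                         eval_set_size = 5, seed = 3)
  sampler <- function(n) matrix(rnorm(2 * n, sd = 2), n, 2)
  tr <- train(p, sampler, cfg)
  expect_identical(diag(tr$final_K), c(0, 0))
  expect_identical(diag(tr$best_K), c(0, 0))
})

test_that("stable-regime two-unit training contracts toward zero cross-talk", {
  # mid-range equal variances are inside the stable region, so learning
  # from a small ring should shrink the cross-talk norm
  sig <- sigma_for_output_variance(0.15)
  spec <- simple_model_spec(sig, sig)
  p <- simple_network(spec, 0.3, -0.3)
  cfg <- learning_config(eta = 0.01, n_updates = 2000, checkpoint_every = 2001,
                         eval_set_size = 1, seed = 9)
  sampler <- function(n) cbind(rnorm(n, 0, sig), rnorm(n, 0, sig))
  tr <- train(p, sampler, cfg)
  n0 <- sqrt(p$K[1, 2]^2 + p$K[2, 1]^2)
  n1 <- sqrt(tr$final_K[1, 2]^2 + tr$final_K[2, 1]^2)
  expect_lt(n1, n0)
})
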