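test_that("output variance rises monotonically from 0 toward the 0.25 bound", {
  expect_lt(output_variance(1e-4), 1e-8)
  v_top <- output_variance(1e3)
  expect_lte(v_top, 0.25)
  expect_gte(v_top, 0.249)
  sweep <- vapply(c(0.1, 0.3, 1, 3, 10), output_variance, numeric(1))
  expect_true(all(diff(sweep) > 0))
})

test_that("variance inversion round-trips and preserves order", {
  s <- sigma_for_output_variance(0.1)
  expect_equal(output_variance(s), 0.1, tolerance = 1e-7)
  expect_lt(sigma_for_output_variance(0.05), sigma_for_output_variance(0.15))
  expect_error(sigma_for_output_variance(0.3), "0, 0.25")
  expect_error(sigma_for_output_variance(0.23, sigma_max = 10), "guard")
})

test_that("zero cross-talk is a fixed point of the expected learning map", {
  set.seed(8)
  for (r in 1:10) {
    spec <- simple_model_spec(runif(1, 0.3, 8), runif(1, 0.3, 8))
    expect_lt(max(abs(expected_update_map(spec, 0, 0))), 1e-8)
  }
})

test_that("the closed-form quadrature path matches the generic network path", {
  spec <- simple_model_spec(sigma_for_output_variance(0.1),
                            sigma_for_output_variance(0.15),
                            quadrature_order = 32)
  for (K in list(c(0.3, -0.2), c(-1, 0.5), c(0, 0.8))) {
    expect_equal(expected_update_map(spec, K[1], K[2]),
                 synmax:::.expected_update_map_generic(spec, K[1], K[2]),
                 tolerance = 1e-6)
  }
})

test_that("expected map respects the exchange symmetry of the two modalities", {
  spec <- simple_model_spec(2.5, 2.5)
  F1 <- expected_update_map(spec, 0.4, -0.1)
  F2 <- expected_update_map(spec, -0.1, 0.4)
  expect_equal(F1, rev(F2), tolerance = 1e-9)
})

test_that("expected map matches a Monte-Carlo average of the analytic gradient", {
  spec <- simple_model_spec(sigma_for_output_variance(0.08),
                            sigma_for_output_variance(0.12))
  Fq <- expected_update_map(spec, 0.2, -0.3)
  p <- simple_network(spec, 0.2, -0.3)
  set.seed(123)
  nmc <- 4e4
  X <- cbind(rnorm(nmc, 0, spec$sigma1), rnorm(nmc, 0, spec$sigma2))
  vals12 <- numeric(nmc); vals21 <- numeric(nmc)
  for (i in seq_len(nmc)) {
    g <- grad_K_analytic(p, X[i, , drop = FALSE])
    vals12[i] <- g[1, 2]; vals21[i] <- g[2, 1]
  }
  se <- c(sd(vals12), sd(vals21)) / sqrt(nmc)
  expect_lt(abs(Fq[1] - mean(vals12)), 3 * se[1])
  expect_lt(abs(Fq[2] - mean(vals21)), 3 * se[2])
})

test_that("quadrature is converged at moderate variances", {
  spec1 <- simple_model_spec(sigma_for_output_variance(0.06),
                             sigma_for_output_variance(0.1),
                             quadrature_order = 128)
  spec2 <- simple_model_spec(spec1$sigma1, spec1$sigma2,
                             quadrature_order = 256)
  for (K in list(c(0, 0), c(0.3, -0.2))) {
    expect_lt(max(abs(expected_update_map(spec1, K[1], K[2]) -
                      expected_update_map(spec2, K[1], K[2]))), 1e-8)
  }
})

test_that("origin stability flags follow the eigenvalue real parts", {
  sv <- sigma_for_output_variance
  st_mid <- stability_at_origin(simple_model_spec(sv(0.15), sv(0.15)))
  expect_true(st_mid$stable)
  expect_true(all(Re(st_mid$eigenvalues) < 0))
  expect_gt(st_mid$eta_critical, 0)
  # discrete-map multiplier formula for real eigenvalues
  expect_equal(st_mid$eta_critical,
               min(-2 * Re(st_mid$eigenvalues) / Mod(st_mid$eigenvalues)^2))

  # sensory flooding: one variance high, the other moderate -> unstable
  st_fl <- stability_at_origin(simple_model_spec(sv(0.23), sv(0.1)))
  expect_false(st_fl$stable)
  expect_identical(st_fl$eta_critical, 0)
})

test_that("phase diagram is symmetric under swapping the two modalities", {
  v <- c(0.05, 0.15, 0.22)
  pd <- phase_diagram(v, v)
  m <- matrix(pd$stable, 3, 3)
  expect_identical(m, t(m))
  expect_true(all(pd$ok))
})

test_that("stochastic one-sample updates match the generic gradient path", {
  # the C++ grid trainer's closed-form gradient against the R machinery
  set.seed(61)
  for (r in 1:4) {
    w1 <- runif(1, 0.5, 2); w2 <- runif(1, 0.5, 2)
    s1 <- runif(1, 0.5, 5); s2 <- runif(1, 0.5, 5)
    k12 <- rnorm(1, 0, 0.8); k21 <- rnorm(1, 0, 0.8)
    seed <- 700 + r
    set.seed(seed)
    fit <- synmax:::.simple_train_cpp(w1, w2, s1, s2, k12, k21, 0.3,
                                      1L, 1L, 0.1, 1e-9, 200000L)
    set.seed(seed)
    x <- c(rnorm(1, 0, s1), rnorm(1, 0, s2))
    g <- grad_K_analytic(simple_network(simple_model_spec(s1, s2, w1, w2),
                                        k12, k21),
                         matrix(x, 1, 2))
    expect_equal(fit$k12 - k12, 0.3 * g[1, 2], tolerance = 1e-6)
    expect_equal(fit$k21 - k21, 0.3 * g[2, 1], tolerance = 1e-6)
  }
})
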