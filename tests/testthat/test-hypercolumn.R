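test_that("feedforward drive is cosine-tuned and strictly within-modality", {
  cfg <- hypercolumn_config(m_per_modality = 16, r1 = 0.5, r2 = 1, seed = 2)
  p <- build_network(cfg)
  expect_equal(p$M, 32)
  expect_equal(p$N, 4)
  # every feedforward row is a unit vector
  expect_equal(sqrt(rowSums(p$W^2)), rep(1, 32))
  # stimulus (r, phi) in modality 1 drives its neuron i with r cos(theta_i - phi)
  r <- 0.7; phi <- 73
  x <- c(r * cos(pi / 180 * phi), r * sin(pi / 180 * phi), 0, 0)
  drive <- drop(p$W %*% x)
  th <- preferred_angles(16)
  expect_equal(drive[1:16], r * cos(pi / 180 * (th - phi)), tolerance = 1e-12)
  # no feedforward drive to the other modality
  expect_equal(drive[17:32], rep(0, 16))
})

test_that("stimulus sampler matches its declared statistics", {
  cfg <- hypercolumn_config(m_per_modality = 8, r1 = 0.2, r2 = 2,
                            radius_cv = 0.2, seed = 1)
  stim <- sample_inputs(cfg, 1e5, seed = 42)
  # law of large numbers on the mean radius
  se1 <- 0.2 * cfg$r1 / sqrt(1e5)
  expect_lt(abs(mean(stim$radius1) - cfg$r1), 3 * se1)
  se2 <- 0.2 * cfg$r2 / sqrt(1e5)
  expect_lt(abs(mean(stim$radius2) - cfg$r2), 3 * se2)
  expect_true(all(stim$radius1 >= 0))
  # uniform angles: circular resultant near zero
  z <- mean(exp(1i * pi / 180 * stim$angle1))
  expect_lt(Mod(z), 0.01)
  # modalities are statistically independent
  X <- stimuli_matrix(stim)
  for (i in 1:2) for (j in 3:4) {
    r <- cor(X[, i], X[, j])
    expect_lt(abs(r), 3 / sqrt(1e5))
  }
})

test_that("population vector decodes angle and cancels uniform activity", {
  th <- preferred_angles(12)
  # equal activities: roots of unity sum to zero
  pv <- population_vector(rep(0.7, 12), th)
  expect_lt(pv$magnitude, 1e-12)
  expect_true(is.na(pv$angle))
  # one-hot at the neuron preferring 30 degrees
  s <- rep(0, 12); s[which(th == 30)] <- 1
  expect_equal(population_vector(s, th)$angle, 30)
  # rectified cosine hill at 120 degrees, against direct complex summation
  s <- pmax(0, cos(pi / 180 * (th - 120)))
  pv <- population_vector(s, th)
  z <- sum(s * exp(1i * pi / 180 * th))
  expect_equal(pv$angle, 120, tolerance = 1e-9)
  expect_equal(pv$magnitude, Mod(z))
  expect_gt(pv$magnitude, 0)
  # invariance to adding a constant to all activities
  pv2 <- population_vector(s + 0.35, th)
  expect_equal(pv2$magnitude, pv$magnitude, tolerance = 1e-9)
})

test_that("an untrained network shows no functional cross-talk", {
  cfg <- hypercolumn_config(m_per_modality = 16, r1 = 0.2, r2 = 2, seed = 5)
  p <- build_network(cfg)
  pr <- probe_response(p, cfg, inducer_modality = 2, probe_angle = 30)
  expect_lt(pr$magnitude, 10 * cfg$k0 * cfg$m_per_modality)
  pr1 <- probe_response(p, cfg, inducer_modality = 1, probe_angle = 200)
  expect_lt(pr1$magnitude, 10 * cfg$k0 * cfg$m_per_modality)
})

test_that("a cosine cross-block yields a shifted monotonic unidirectional mapping", {
  net <- synthetic_crossmodal_network(m = 16, gain = 0.4, shift_deg = 40)
  map <- extract_mapping(net$params, net$cfg, inducer_modality = 2)
  expect_equal(map$monotonicity_score, 1)
  expect_gt(map$directionality_index, 0.95)
  expect_true(map$unidirectional)
  # response angle tracks probe angle plus the built-in shift
  err <- wrap_angle(map$pv_angle_forward - map$probe_angles - 40 + 180) - 180
  expect_lt(max(abs(err)), 1)
})

test_that("probe plumbing carries no hidden angle anisotropy", {
  net <- synthetic_crossmodal_network(m = 16, gain = 0.4, shift_deg = 40)
  probes <- seq(0, 315, by = 45)
  base <- vapply(probes, function(a)
    probe_response(net$params, net$cfg, 2, a)$angle, numeric(1))
  rot <- vapply(probes + 10, function(a)
    probe_response(net$params, net$cfg, 2, a)$angle, numeric(1))
  d <- wrap_angle(rot - base - 10 + 180) - 180
  expect_lt(max(abs(d)), 1e-4)
})

test_that("unwrapping recovers monotone structure across the circular jump", {
  probes <- seq(0, 355, by = 5)
  # identity mapping
  expect_equal(cor(probes, unwrap_angles(probes), method = "spearman"), 1)
  # shifted decreasing mapping: monotone after unwrapping
  resp <- wrap_angle(300 - probes)
  expect_equal(abs(cor(probes, unwrap_angles(resp), method = "spearman")), 1)
  # shifted increasing mapping with noise stays near +1
  set.seed(31)
  resp2 <- wrap_angle(probes + 120 + rnorm(length(probes), 0, 5))
  expect_gt(cor(probes, unwrap_angles(resp2), method = "spearman"), 0.95)
  # randomly permuted angles carry no monotone structure
  set.seed(8)
  scores <- replicate(20, {
    cor(probes, unwrap_angles(sample(resp)), method = "spearman")
  })
  expect_gt(mean(abs(scores) < 0.3), 0.8)
})

test_that("block decomposition tiles K exactly and summarizes structure", {
  m <- 8
  th <- pi / 180 * preferred_angles(m)
  A11 <- 0.5 * cos(outer(th, th, "-"))        # symmetric cosine block
  A22 <- 0.1 * cos(outer(th, th, "-"))
  A12 <- matrix(0.02, m, m)
  A21 <- matrix(-0.03, m, m)
  K <- rbind(cbind(A11, A12), cbind(A21, A22))
  bl <- block_decompose(K, m)
  expect_equal(bl$K11, A11)
  expect_equal(bl$K12, A12)
  expect_equal(bl$K21, A21)
  expect_equal(bl$K22, A22)
  st <- bl$stats
  expect_equal(st$mean[st$block == "K12"], 0.02)
  expect_equal(st$mean[st$block == "K21"], -0.03)
  expect_equal(st$symmetry_defect[st$block == "K11"], 0)
  # cosine interaction profile: excitatory at small, inhibitory at large
  # angular difference, with the stronger block showing larger amplitude
  expect_gt(bl$profile$mean_w1[1], 0)
  expect_lt(bl$profile$mean_w1[nrow(bl$profile)], 0)
  expect_gt(bl$amplitude1, bl$amplitude2)
  expect_equal(bl$amplitude1, 1, tolerance = 1e-12)
})

test_that("hypercolumn training is reproducible and keeps the best checkpoint", {
  cfg <- hypercolumn_config(m_per_modality = 8, r1 = 0.3, r2 = 0.6,
                            eta = 0.01, seed = 3)
  f1 <- train_hypercolumn(cfg, n_updates = 40, checkpoint_every = 10,
                          eval_set_size = 10)
  f2 <- train_hypercolumn(cfg, n_updates = 40, checkpoint_every = 10,
                          eval_set_size = 10)
  expect_identical(f1$trace$final_K, f2$trace$final_K)
  expect_identical(f1$trace$checkpoints, f2$trace$checkpoints)
  expect_equal(f1$trace$best_epsilon,
               min(f1$trace$checkpoints$epsilon, na.rm = TRUE))
})
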