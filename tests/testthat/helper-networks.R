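# fixture builders: small random networks and stimulus batches

random_network <- function(M, N, k_sd = 0.1, seed = 1) {
  set.seed(seed)
  W <- matrix(rnorm(M * N), M, N)
  K <- matrix(rnorm(M * M, sd = k_sd), M, M)
  network_params(W, K)
}

random_samples <- function(n, N, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n * N, sd = sd), n, N)
}

# a hand-built two-hypercolumn network with a prescribed cosine-structured
# cross-talk block from modality 2 into modality 1 (and none the other way):
# a deterministic stand-in for a deprivation-trained network, used to
# exercise the probe / population-vector / mapping machinery without training
synthetic_crossmodal_network <- function(m = 16, gain = 0.4, shift_deg = 40) {
  cfg <- hypercolumn_config(m_per_modality = m, r1 = 0.2, r2 = 2, seed = 1,
                            k0 = 0)
  params <- build_network(cfg)
  th <- pi / 180 * preferred_angles(m)
  K <- matrix(0, 2 * m, 2 * m)
  K[1:m, (m + 1):(2 * m)] <-
    gain / m * cos(outer(th, th, "-") - pi / 180 * shift_deg)
  list(params = set_recurrent(params, K), cfg = cfg)
}
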