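# Two-hypercolumn model: each modality is a ring of output neurons with
# equally spaced preferred angles and cosine-tuned feedforward drive from a
# two-dimensional input (angle = feature, radius = intensity). The combined
# output layer is fully recurrently connected and the recurrent weights are
# learned by infomax; synaesthesia shows up as functional cross-modality
# blocks of K, read out with population vectors.

#' Configuration of the two-hypercolumn model
#'
#' @param m_per_modality output neurons per modality (>= 8); preferred
#'   angles are equally spaced on \[0, 360)
#' @param r1,r2 characteristic stimulus radii (intensities) of the two
#'   modalities; lowering one models sensory deprivation, raising one
#'   sensory flooding
#' @param radius_cv coefficient of variation (sd/mean) of the Gaussian
#'   radius distribution
#' @param eta learning rate for recurrent-weight updates
#' @param seed RNG seed (weight initialization and stimulus sampling)
#' @param k0 half-width of the uniform near-zero initialization of K
#' @return a list of class `synmax_hc_config`
#' @export
hypercolumn_config <- function(m_per_modality = 16, r1 = 0.2, r2 = 0.2,
                               radius_cv = 0.2, eta = 1, seed = 1,
                               k0 = 1e-3) {
  stopifnot(m_per_modality >= 8, r1 > 0, r2 > 0, radius_cv >= 0, eta >= 0,
            k0 >= 0)
  structure(list(m_per_modality = as.integer(m_per_modality),
                 r1 = r1, r2 = r2, radius_cv = radius_cv, eta = eta,
                 seed = as.integer(seed), k0 = k0),
            class = "synmax_hc_config")
}

#' Preferred angles of a hypercolumn
#' @param m number of neurons
#' @return vector of m angles in degrees, equally spaced on \[0, 360)
#' @export
preferred_angles <- function(m) 360 * (seq_len(m) - 1) / m

#' Build the two-hypercolumn network
#'
#' The feedforward matrix is block-diagonal: row i of modality m is the unit
#' vector (cos theta_i, sin theta_i) applied to that modality's 2-D input
#' only, so a stimulus at angle phi and radius r drives its own modality's
#' neuron i with r cos(theta_i - phi) and gives no feedforward drive to the
#' other modality. The full recurrent matrix (both intra- and cross-modality
#' blocks, self-connections included) is learnable and initialized i.i.d.
#' uniform on \[-k0, k0\].
#'
#' @param cfg a [hypercolumn_config()]
#' @return a [network_params()] object with M = 2 m_per_modality, N = 4
#' @export
build_network <- function(cfg) {
  m <- cfg$m_per_modality
  th <- .deg2rad(preferred_angles(m))
  W <- matrix(0, 2 * m, 4)
  W[1:m, 1] <- cos(th);        W[1:m, 2] <- sin(th)
  W[(m + 1):(2 * m), 3] <- cos(th); W[(m + 1):(2 * m), 4] <- sin(th)
  set.seed(derive_seed(cfg$seed, 1L))
  K <- matrix(stats::runif(4 * m * m, -cfg$k0, cfg$k0), 2 * m, 2 * m)
  network_params(W, K)
}

#' Sample paired stimuli for the two modalities
#'
#' Per sample and per modality, independent draws: angle uniform on
#' \[0, 360), radius Gaussian around the characteristic radius with standard
#' deviation proportional to it (negative draws clamped at 0). The two
#' modalities are statistically independent: any systematic cross-modal
#' mapping the network develops is not inherited from input correlations.
#'
#' @param cfg a [hypercolumn_config()]
#' @param n number of samples
#' @param seed optional seed; if NULL the current RNG stream is used
#' @return data frame: angle1, radius1, angle2, radius2
#' @export
sample_inputs <- function(cfg, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw_r <- function(rm) pmax(0, stats::rnorm(n, rm, cfg$radius_cv * rm))
  data.frame(angle1 = stats::runif(n, 0, 360), radius1 = draw_r(cfg$r1),
             angle2 = stats::runif(n, 0, 360), radius2 = draw_r(cfg$r2))
}

#' Convert sampled stimuli to network input vectors
#' @param stim data frame from [sample_inputs()]
#' @return n x 4 matrix of Cartesian inputs (x1, y1, x2, y2)
#' @export
stimuli_matrix <- function(stim) {
  cbind(stim$radius1 * cos(.deg2rad(stim$angle1)),
        stim$radius1 * sin(.deg2rad(stim$angle1)),
        stim$radius2 * cos(.deg2rad(stim$angle2)),
        stim$radius2 * sin(.deg2rad(stim$angle2)))
}

# stimulus sampler closure drawing from the current RNG stream (train()
# seeds the stream once, so training is reproducible)
.hc_sampler <- function(cfg) {
  function(n) stimuli_matrix(sample_inputs(cfg, n))
}

#' Population vector of a block of activities
#'
#' Activity-weighted vector sum of the preferred-direction unit vectors:
#' the complex sum of s_i exp(i theta_i). Its angle decodes the represented
#' feature and its magnitude the response strength. With equally spaced
#' preferred angles, any uniform activity component (e.g. the g(0) = 0.5
#' baseline) cancels exactly, so the magnitude measures structured response
#' only, and is invariant to adding a constant to all activities.
#'
#' @param s_block activity vector of one modality
#' @param thetas preferred angles in degrees (same length)
#' @param angle_floor magnitudes below this report an NA angle
#' @return list with `magnitude` and `angle` (degrees in \[0, 360), NA when
#'   undefined)
#' @export
population_vector <- function(s_block, thetas, angle_floor = 1e-9) {
  stopifnot(length(s_block) == length(thetas))
  z <- sum(s_block * exp(1i * .deg2rad(thetas)))
  mag <- Mod(z)
  ang <- if (mag < angle_floor) NA_real_ else wrap_angle(.rad2deg(Arg(z)))
  list(magnitude = mag, angle = ang)
}

#' Cross-modal response to stimulation of a single modality
#'
#' Sets the stimulated modality's input to the given polar stimulus and the
#' other modality's input to zero, solves the steady state, and returns the
#' population vector of the NON-stimulated modality: the operational test
#' for synaesthesia (the inducer is the stimulated modality, the concurrent
#' the responding one).
#'
#' @param params a trained or untrained [network_params()] from
#'   [build_network()]
#' @param cfg the matching [hypercolumn_config()]
#' @param inducer_modality 1 or 2: which modality is stimulated
#' @param probe_angle stimulus angle in degrees
#' @param probe_radius stimulus radius; default: the stimulated modality's
#'   characteristic radius
#' @param solver_cfg a [solver_config()]
#' @return list: `magnitude`, `angle` (population vector of the concurrent
#'   modality), `iterations` (solver convergence time)
#' @export
probe_response <- function(params, cfg, inducer_modality, probe_angle,
                           probe_radius = NULL,
                           solver_cfg = solver_config()) {
  stopifnot(inducer_modality %in% c(1, 2))
  m <- cfg$m_per_modality
  stopifnot(params$M == 2 * m)
  if (is.null(probe_radius)) {
    probe_radius <- if (inducer_modality == 1) cfg$r1 else cfg$r2
  }
  xy <- probe_radius * c(cos(.deg2rad(probe_angle)), sin(.deg2rad(probe_angle)))
  x <- if (inducer_modality == 1) c(xy, 0, 0) else c(0, 0, xy)
  st <- solve_steady_state(params, x, solver_cfg)
  if (!st$converged) stop("steady state did not converge for probe at angle ",
                          probe_angle, " (residual ", format(st$residual), ")")
  idx <- if (inducer_modality == 1) (m + 1):(2 * m) else 1:m
  pv <- population_vector(st$s[idx], preferred_angles(m))
  c(pv, list(iterations = st$iterations))
}

#' Extract the synaesthetic mapping between the two modalities
#'
#' Sweeps probe stimuli over the circle in both directions (inducer ->
#' concurrent and the reverse), records the concurrent population vectors,
#' and summarizes:
#' \itemize{
#'   \item monotonicity_score: Spearman correlation between the probe
#'     angles and the unwrapped concurrent response angles in the forward
#'     direction (a shifted monotonic circular mapping scores +/-1);
#'   \item directionality_index: |m_f - m_r| / (m_f + m_r) of the two mean
#'     population-vector magnitudes (0 = symmetric, 1 = one-way);
#'   \item unidirectional: directionality above `dir_threshold` AND the weak
#'     direction's mean magnitude below `floor_fraction` of the strong one.
#' }
#'
#' @inheritParams probe_response
#' @param probe_angles probe grid in degrees (default every 5 degrees)
#' @param dir_threshold directionality index required for unidirectionality
#' @param floor_fraction "effectively zero" cutoff for the weak direction,
#'   as a fraction of the strong direction's mean magnitude
#' @return list of class `synmax_mapping`: `probe_angles`,
#'   `pv_magnitude_forward`, `pv_magnitude_reverse`, `pv_angle_forward`,
#'   `monotonicity_score`, `directionality_index`, `unidirectional`,
#'   `n_undefined` (probes excluded from the monotonicity score)
#' @export
extract_mapping <- function(params, cfg, inducer_modality = 2,
                            probe_angles = seq(0, 355, by = 5),
                            dir_threshold = 0.8, floor_fraction = 0.05,
                            solver_cfg = solver_config()) {
  sweep_dir <- function(ind) {
    mags <- numeric(length(probe_angles))
    angs <- numeric(length(probe_angles))
    for (i in seq_along(probe_angles)) {
      # a probe leaves one modality at zero input, where activities sit at
      # the maximum-gain baseline: patterns that relax fine under ordinary
      # stimuli can be super-critical for the probe, so a failed probe is
      # recorded as undefined rather than fatal
      pr <- tryCatch(probe_response(params, cfg, ind, probe_angles[i],
                                    solver_cfg = solver_cfg),
                     error = function(e) list(magnitude = NA_real_,
                                              angle = NA_real_))
      mags[i] <- pr$magnitude
      angs[i] <- pr$angle
    }
    list(mags = mags, angs = angs)
  }
  fwd <- sweep_dir(inducer_modality)
  rev <- sweep_dir(if (inducer_modality == 1) 2 else 1)
  keep <- !is.na(fwd$angs) & !is.na(fwd$mags)
  mono <- if (sum(keep) >= 3) {
    stats::cor(probe_angles[keep], unwrap_angles(fwd$angs[keep]),
               method = "spearman")
  } else NA_real_
  mf <- mean(fwd$mags, na.rm = TRUE)
  mr <- mean(rev$mags, na.rm = TRUE)
  if (!is.finite(mf)) mf <- 0
  if (!is.finite(mr)) mr <- 0
  cov_f <- mean(!is.na(fwd$mags))
  cov_r <- mean(!is.na(rev$mags))
  di <- if (mf + mr > 0) abs(mf - mr) / (mf + mr) else 0
  # a mapping counts as demonstrated unidirectional only if the forward
  # sweep was actually measurable over most of the circle
  uni <- isTRUE(cov_f >= 0.5 &&
                di > dir_threshold &&
                min(mf, mr) < floor_fraction * max(mf, mr))
  structure(list(probe_angles = probe_angles,
                 pv_magnitude_forward = fwd$mags,
                 pv_magnitude_reverse = rev$mags,
                 pv_angle_forward = fwd$angs,
                 monotonicity_score = mono,
                 directionality_index = di,
                 unidirectional = uni,
                 coverage_forward = cov_f,
                 coverage_reverse = cov_r,
                 n_undefined = sum(!keep),
                 inducer_modality = inducer_modality),
            class = "synmax_mapping")
}

#' @export
print.synmax_mapping <- function(x, ...) {
  cat("<synmax_mapping> inducer modality ", x$inducer_modality,
      ": directionality ", format(x$directionality_index, digits = 3),
      ", monotonicity ", format(x$monotonicity_score, digits = 3),
      if (x$unidirectional) " (unidirectional)" else "", "\n", sep = "")
  invisible(x)
}

#' Block decomposition of the recurrent matrix
#'
#' Splits K into the two intra-modality blocks (K11, K22) and the two
#' cross-talk blocks (K12: input from modality 2 into modality 1; K21: from
#' 1 into 2), with per-block summaries: Frobenius norm, mean weight,
#' symmetry defect ||B - B'||_F / ||B||_F for the intra blocks, and the
#' interaction profile (mean intra-block weight binned by circular
#' preferred-angle difference). The profile amplitude (max - min) measures
#' how strongly a modality amplifies its own inputs.
#'
#' @param K recurrent matrix, 2m x 2m
#' @param m_per neurons per modality
#' @return list of class `synmax_blocks`: the four blocks, `stats` (data
#'   frame), `profile` (data frame: dtheta, mean_w1, mean_w2),
#'   `amplitude1`, `amplitude2`
#' @export
block_decompose <- function(K, m_per) {
  m <- m_per
  stopifnot(nrow(K) == 2 * m, ncol(K) == 2 * m)
  i1 <- 1:m; i2 <- (m + 1):(2 * m)
  B <- list(K11 = K[i1, i1], K12 = K[i1, i2], K21 = K[i2, i1], K22 = K[i2, i2])
  fro <- function(A) sqrt(sum(A^2))
  sym_defect <- function(A) if (fro(A) == 0) 0 else fro(A - t(A)) / fro(A)
  stats <- data.frame(
    block = names(B),
    mean = vapply(B, mean, numeric(1)),
    frobenius = vapply(B, fro, numeric(1)),
    symmetry_defect = c(sym_defect(B$K11), NA, NA, sym_defect(B$K22)),
    row.names = NULL)
  th <- preferred_angles(m)
  dth <- abs(outer(th, th, "-"))
  dth <- pmin(dth, 360 - dth)           # circular difference in [0, 180]
  prof <- function(A) tapply(as.vector(A), round(as.vector(dth), 6), mean)
  p1 <- prof(B$K11); p2 <- prof(B$K22)
  profile <- data.frame(dtheta = as.numeric(names(p1)),
                        mean_w1 = as.numeric(p1), mean_w2 = as.numeric(p2))
  profile <- profile[order(profile$dtheta), ]
  structure(c(B, list(stats = stats, profile = profile,
                      amplitude1 = max(p1) - min(p1),
                      amplitude2 = max(p2) - min(p2))),
            class = "synmax_blocks")
}

#' @export
print.synmax_blocks <- function(x, ...) {
  cat("<synmax_blocks>\n")
  print(x$stats)
  invisible(x)
}

#' Train a two-hypercolumn network by infomax
#'
#' Convenience wrapper: builds the network from the configuration, attaches
#' the paired-stimulus sampler, and runs [train()]. The returned trace keeps
#' both the final weights and the best (minimum-objective) checkpoint, which
#' is the interaction pattern used for probing.
#'
#' @param cfg a [hypercolumn_config()]
#' @param n_updates number of gradient updates
#' @param batch_size stimuli averaged per update; batching tames the
#'   stochastic-gradient noise that otherwise dominates desk-scale weight
#'   structure
#' @param checkpoint_every,eval_set_size objective checkpointing controls
#' @param max_nonconverged_frac abort threshold on the fraction of failed
#'   steady-state solves; the default 1 never aborts, because a network
#'   optimizing its sensitivity is expected to wander into the critical
#'   regime where individual samples stop converging — such samples are
#'   skipped and the minimum-objective checkpoint recovers the best
#'   sub-critical pattern
#' @param solver_cfg a [solver_config()]
#' @return list: `params` (network with best_K installed), `trace`
#'   (the [train()] trace), `cfg`
#' @export
train_hypercolumn <- function(cfg, n_updates = 3000, batch_size = 8,
                              checkpoint_every = 50,
                              eval_set_size = 50, max_nonconverged_frac = 1,
                              solver_cfg = solver_config()) {
  params <- build_network(cfg)
  lcfg <- learning_config(eta = cfg$eta, n_updates = n_updates,
                          batch_size = batch_size,
                          checkpoint_every = checkpoint_every,
                          eval_set_size = eval_set_size,
                          seed = derive_seed(cfg$seed, 2L),
                          max_nonconverged_frac = max_nonconverged_frac)
  tr <- train(params, .hc_sampler(cfg), lcfg, solver_cfg)
  list(params = set_recurrent(params, tr$best_K), trace = tr, cfg = cfg)
}
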