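#' Specify a synthetic resting-state cohort
#'
#' The generative model: each network s carries a unit-variance latent signal
#' L_s, plus one global signal G shared by all vertices. A vertex in network
#' s emits `a * L_s + b * G + noise_sd * e` with coefficients solved so the
#' expected correlation of two same-network vertices equals
#' `within_network_corr` and of two cross-network vertices equals
#' `between_network_corr`. Subcortical voxels couple to their true network's
#' latent through the same coefficients. Framewise displacement traces are
#' baseline jitter |N(0, 0.05 mm)| plus Poisson-placed bursts of 1-3 frames
#' at 0.35-1.0 mm, so both the 0.3 mm processing mask and the 0.2 mm
#' analysis mask are exercised.
#'
#' @param n_subjects Subjects per cohort.
#' @param n_frames Frames per run (T).
#' @param repetition_time TR in seconds (default 0.8, i.e. 800 ms).
#' @param within_network_corr Target correlation of same-network vertices.
#' @param between_network_corr Target cross-network correlation.
#' @param noise_sd Observation noise standard deviation.
#' @param motion_burst_rate Expected number of high-motion bursts per run.
#' @param n_subcortical Number of subcortical voxels per subject.
#' @param seed Integer seed for the cohort.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 40L, n_frames = 600L,
                        repetition_time = 0.8,
                        within_network_corr = 0.35,
                        between_network_corr = 0.05,
                        noise_sd = 1.0,
                        motion_burst_rate = 2,
                        n_subcortical = 300L,
                        seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!(between_network_corr >= 0 &&
        between_network_corr < within_network_corr &&
        within_network_corr <= 1))
    stop("need 0 <= between_network_corr < within_network_corr <= 1")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (within_network_corr == 1 && noise_sd > 0)
    stop("within_network_corr = 1 is unreachable with noise_sd > 0")
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_frames = as.integer(n_frames),
         repetition_time = repetition_time,
         within_network_corr = within_network_corr,
         between_network_corr = between_network_corr,
         noise_sd = noise_sd,
         motion_burst_rate = motion_burst_rate,
         n_subcortical = as.integer(n_subcortical),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Solve the signal coefficients a (network latent) and b (global) from the
# correlation targets. With unit-variance latents and total signal variance
# V = a^2 + b^2 + noise_sd^2:
#   same-network r  = (a^2 + b^2) / V = within
#   cross-network r =        b^2 / V  = between
# so V = noise_sd^2 / (1 - within), a^2 = (within - between) V, b^2 =
# between * V. With noise_sd = 0 the correlations are 1/ b^2/(a^2+b^2)
# regardless of scale; we then use a^2 = within - between, b^2 = between.
signal_coefficients <- function(within, between, noise_sd) {
  if (noise_sd > 0) {
    v <- noise_sd^2 / (1 - within)
    a2 <- (within - between) * v
    b2 <- between * v
  } else {
    a2 <- within - between
    b2 <- between
  }
  if (a2 < 0) stop("unreachable correlation targets (a^2 would be negative)")
  c(a = sqrt(a2), b = sqrt(b2))
}

# FD trace: folded-Gaussian baseline plus Poisson-count motion bursts.
simulate_fd <- function(n_frames, burst_rate) {
  fd <- abs(rnorm(n_frames, 0, 0.05))
  n_burst <- rpois(1L, burst_rate)
  for (i in seq_len(n_burst)) {
    len <- sample(1:3, 1L)
    start <- sample.int(max(1L, n_frames - len + 1L), 1L)
    idx <- start:min(n_frames, start + len - 1L)
    fd[idx] <- pmax(fd[idx], runif(length(idx), 0.35, 1.0))
  }
  fd
}

#' Simulate one subject's resting-state data
#'
#' @param template A `network_template` giving the true cortical networks.
#' @param spec A [cohort_spec()].
#' @param subject_seed Integer seed; different seeds give different time
#'   series under identical truth labels.
#' @return A `subject_data` list: `timeseries` (vertex x frame),
#'   `fd_trace` (mm per frame), `subcortical_timeseries` (voxel x frame),
#'   `subcortical_truth` (character label per voxel).
#' @export
simulate_subject <- function(template, spec, subject_seed) {
  stopifnot(inherits(template, "network_template"),
            inherits(spec, "cohort_spec"))
  ab <- signal_coefficients(spec$within_network_corr,
                            spec$between_network_corr, spec$noise_sd)
  n_v <- length(template$labels)
  tt <- spec$n_frames
  net_idx <- match(template$labels, template$names)
  withr::with_seed(subject_seed, {
    latents <- matrix(rnorm(template$K * tt), template$K, tt)
    global <- rnorm(tt)
    noise <- matrix(rnorm(n_v * tt, sd = spec$noise_sd), n_v, tt)
    ts <- ab["a"] * latents[net_idx, , drop = FALSE] +
      matrix(ab["b"] * global, n_v, tt, byrow = TRUE) + noise
    # subcortical voxels: round-robin truth over networks, same coupling
    n_sc <- spec$n_subcortical
    if (n_sc > 0) {
      sc_idx <- rep_len(seq_len(template$K), n_sc)
      sc_noise <- matrix(rnorm(n_sc * tt, sd = spec$noise_sd), n_sc, tt)
      sc <- ab["a"] * latents[sc_idx, , drop = FALSE] +
        matrix(ab["b"] * global, n_sc, tt, byrow = TRUE) + sc_noise
      sc_truth <- template$names[sc_idx]
    } else {
      sc <- matrix(numeric(0), 0, tt)
      sc_truth <- character(0)
    }
    fd <- simulate_fd(tt, spec$motion_burst_rate)
    structure(
      list(timeseries = ts, fd_trace = fd,
           subcortical_timeseries = sc, subcortical_truth = sc_truth),
      class = "subject_data"
    )
  })
}

#' Simulate a full cohort
#'
#' Subject seeds are drawn once from the cohort seed, so the cohort is
#' bit-reproducible given `(template, spec)`.
#'
#' @inheritParams simulate_subject
#' @return A `cohort` list: `subjects` (list of `subject_data`), `spec`,
#'   `subject_seeds`.
#' @export
simulate_cohort <- function(template, spec) {
  subject_seeds <- withr::with_seed(
    spec$seed, sample.int(.Machine$integer.max, spec$n_subjects))
  subjects <- lapply(subject_seeds, function(s)
    simulate_subject(template, spec, s))
  structure(
    list(subjects = subjects, spec = spec, subject_seeds = subject_seeds),
    class = "cohort"
  )
}
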