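test_that("frame flagging applies the strict FD rule", {
  expect_identical(flag_frames(c(0.1, 0.25, 0.15), 0.2),
                   c(TRUE, FALSE, TRUE))
  expect_true(all(flag_frames(rep(0, 10), 0.2)))
  expect_identical(flag_frames(0.2, 0.2), FALSE) # strict inequality
  expect_error(flag_frames(c(0.1, -0.1), 0.2), "nonnegative")
})

test_that("contiguity enforcement censors short runs and is idempotent", {
  retain <- c(rep(TRUE, 4), FALSE, rep(TRUE, 7))
  out <- enforce_contiguity(retain, 5)
  expect_equal(sum(out), 7)
  expect_true(all(out[6:12]))

  full <- rep(TRUE, 600)
  expect_identical(enforce_contiguity(full, 5), full)

  alt <- rep(c(TRUE, FALSE), 10)
  expect_false(any(enforce_contiguity(alt, 5)))

  once <- enforce_contiguity(retain, 5)
  expect_identical(enforce_contiguity(once, 5), once)
})

test_that("subject inclusion composes flagging and contiguity", {
  expect_true(subject_included(rep(TRUE, 601), 600))
  expect_false(subject_included(rep(TRUE, 599), 600))
  # 600 frames in runs of 4 are all lost to the contiguity rule
  runs4 <- rep(c(rep(TRUE, 4), FALSE), 150)
  expect_false(subject_included(enforce_contiguity(runs4, 5), 600))
})

test_that("lowering the FD threshold never increases retention", {
  withr::with_seed(42, {
    for (i in 1:20) {
      fd <- abs(rnorm(200, 0.15, 0.1))
      thr <- sort(runif(2, 0.05, 0.4))
      expect_lte(sum(censor_mask(fd, thr[1], 5)),
                 sum(censor_mask(fd, thr[2], 5)))
    }
  })
})

test_that("demean/detrend removes linear structure exactly", {
  tt <- 1:100
  const <- rbind(rep(3, 100))
  expect_lt(max(abs(demean_detrend(const))), 1e-12)
  line <- rbind(2 + 0.5 * tt)
  expect_lt(max(abs(demean_detrend(line))), 1e-9)
  wave <- sin(2 * pi * 5 * tt / 100)
  mixed <- rbind(1 + 0.2 * tt + wave)
  resid <- demean_detrend(mixed)
  # direct regression oracle
  oracle <- stats::residuals(stats::lm(mixed[1, ] ~ tt))
  expect_lt(max(abs(resid[1, ] - oracle)), 1e-8)
})

test_that("nuisance regression matches the normal-equations oracle", {
  withr::with_seed(7, {
    n_frames <- 60
    regs <- matrix(rnorm(n_frames * 3), n_frames)
    ts <- matrix(rnorm(5 * n_frames), 5)
    retain <- rep(TRUE, n_frames)
    out <- nuisance_regress(ts, regs, retain, add_derivatives = FALSE)
    x <- cbind(1, regs)
    beta <- solve(t(x) %*% x) %*% t(x) %*% t(ts)
    oracle <- ts - t(x %*% beta)
    expect_lt(max(abs(out - oracle)), 1e-10)

    # a node equal to a regressor is annihilated
    self <- rbind(regs[, 1])
    expect_lt(max(abs(nuisance_regress(self, regs,
                                       add_derivatives = FALSE))), 1e-10)

    # data orthogonal to the regressors is unchanged
    q <- qr.Q(qr(cbind(1, regs, matrix(rnorm(n_frames * 2), n_frames))))
    ortho <- rbind(q[, 6])
    expect_lt(max(abs(nuisance_regress(ortho, regs,
                                       add_derivatives = FALSE) - ortho)),
              1e-10)
  })
})

test_that("spectral interpolation reconstructs band-limited signal", {
  tt <- (0:599) * 0.8
  x <- rbind(sin(2 * pi * 0.05 * tt))
  expect_identical(interpolate_censored(x, rep(TRUE, 600), 0.8), x)

  withr::with_seed(3, {
    cens <- sample(600, 60)
    retain <- !(seq_len(600) %in% cens)
    xi <- interpolate_censored(x, retain, 0.8)
    expect_identical(xi[, retain], x[, retain])
    rmse <- sqrt(mean((xi[1, !retain] - x[1, !retain])^2))
    expect_lt(rmse, 0.1) # < 10% of unit amplitude

    noise <- rbind(rnorm(600))
    ni <- interpolate_censored(noise, retain, 0.8)
    expect_identical(ni[, retain], noise[, retain])
  })
  expect_error(interpolate_censored(x, c(rep(TRUE, 10), rep(FALSE, 590)),
                                    0.8), "insufficient retained data")
})

test_that("band-pass filter passes and stops the right frequencies", {
  tt <- (0:599) * 0.8
  amp <- function(y, f) 2 * abs(sum(y * exp(-2i * pi * f * tt))) / length(y)
  x05 <- sin(2 * pi * 0.05 * tt)
  y05 <- bandpass(rbind(x05), tr = 0.8)[1, ]
  expect_gt(amp(y05, 0.05) / amp(x05, 0.05), 0.95)

  x20 <- sin(2 * pi * 0.2 * tt)
  y20 <- bandpass(rbind(x20), tr = 0.8)[1, ]
  expect_lt(amp(y20, 0.2) / amp(x20, 0.2), 0.10)

  const <- bandpass(rbind(rep(5, 600)), tr = 0.8)
  expect_lt(max(abs(const)), 1e-10) # DC removed exactly
})

test_that("the denoising chain is linear under fixed masks/regressors", {
  withr::with_seed(11, {
    n_frames <- 300
    retain <- rep(TRUE, n_frames)
    retain[sample(n_frames, 20)] <- FALSE
    regs <- matrix(rnorm(n_frames * 2), n_frames)
    chain <- function(x) {
      x <- demean_detrend(x, retain)
      x <- interpolate_censored(x, retain, 0.8)
      x <- nuisance_regress(x, regs, retain)
      bandpass(x, tr = 0.8)
    }
    a <- matrix(rnorm(4 * n_frames), 4)
    b <- matrix(rnorm(4 * n_frames), 4)
    expect_lt(max(abs(chain(a + b) - (chain(a) + chain(b)))), 1e-8)
  })
})

test_that("preprocess_subject applies masks in the documented order", {
  withr::with_seed(5, {
    tmpl <- make_template(fix_mesh2, 4, seed = 1)
    spec <- cohort_spec(n_subjects = 1L, n_frames = 400L,
                        motion_burst_rate = 3, n_subcortical = 0L, seed = 2)
    s <- simulate_subject(tmpl, spec, 3)
    cfg <- denoise_config(min_retained = 160L)
    pre <- preprocess_subject(s$timeseries, s$fd_trace, cfg, 0.8)
    expect_identical(pre$retain_process, s$fd_trace < 0.3)
    expect_identical(pre$retain,
                     as.logical(censor_mask(s$fd_trace, 0.2, 5)))
    expect_equal(pre$n_retained, sum(pre$retain))
    expect_identical(dim(pre$timeseries), dim(s$timeseries))
  })
})
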