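cfg_for <- function(model, ..., sigma = 1) {
  diffusion_config(model, alpha = 1, beta = 0.1, sigma = sigma,
                   gamma = 0.1, ...)
}

test_that("finite differences match hand-evaluated stencils", {
  const <- matrix(5, 6, 6)
  fd <- forward_differences(const)
  expect_equal(fd$ux, matrix(0, 6, 6))
  expect_equal(fd$uy, matrix(0, 6, 6))
  ramp <- outer(1:6, 1:6, function(i, j) i)   # I(i,j) = i
  fd <- forward_differences(ramp)
  expect_equal(fd$ux[1:5, ], matrix(1, 5, 6))
  expect_equal(fd$ux[6, ], rep(0, 6))         # replicated ghost row
  m <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  expect_equal(forward_differences(m)$ux[1, 1], 3)  # I(2,1) - I(1,1)
  expect_equal(forward_differences(m)$uy[1, 1], 1)

  sd2 <- second_differences(ramp)
  expect_equal(sd2$uxx[2:5, ], matrix(0, 4, 6))
  bil <- outer(1:6, 1:6, function(i, j) i * j)
  expect_equal(second_differences(bil)$uxy[1:5, 1:5], matrix(1, 5, 5))
  quad <- outer(1:8, 1:8, function(i, j) i^2)
  expect_equal(second_differences(quad)$uxx[2:7, ], matrix(2, 6, 8))
})

test_that("directional curvatures sum to the Laplacian and resolve a cone", {
  img <- random_image(16, seed = 5)
  dc <- directional_curvatures(img)
  sd2 <- second_differences(img)
  ok <- dc$d >= 1e-12
  expect_equal((dc$unn + dc$utt)[ok], (sd2$uxx + sd2$uyy)[ok],
               tolerance = 1e-10)
  expect_equal(directional_curvatures(matrix(3, 5, 5))$unn, matrix(0, 5, 5))
  # cone -sqrt(i^2+j^2): tangential curvature -1/r, normal ~ 0
  n <- 33; c0 <- 17
  cone <- outer(1:n, 1:n, function(i, j) -sqrt((i - c0)^2 + (j - c0)^2))
  r <- outer(1:n, 1:n, function(i, j) sqrt((i - c0)^2 + (j - c0)^2))
  dc <- directional_curvatures(cone)
  ann <- r > 6 & r < 12
  expect_lt(max(abs(dc$utt[ann] + 1 / r[ann])), 0.05)
  expect_lt(max(abs(dc$unn[ann])), 0.05)
})

test_that("constant images are fixed points of every model", {
  const <- matrix(42, 16, 16)
  for (model in c("pm", "ddnd", "m8", "m13")) {
    cfg <- cfg_for(model)
    expect_equal(diffusion_step(const, cfg), const,
                 info = model, tolerance = 1e-15)
  }
})

test_that("divergence-form steps conserve the pixel sum", {
  img <- random_image(32, seed = 9)
  for (model in c("pm", "ddnd", "m8")) {
    cfg <- cfg_for(model, sigma = 2)
    I <- img
    for (k in 1:20) {
      I <- diffusion_step(I, cfg)
      expect_lt(abs(sum(I) - sum(img)) / sum(img), 1e-8)
    }
  }
})

test_that("explicit PM steps obey the discrete maximum principle", {
  img <- random_image(24, seed = 2)
  cfg <- diffusion_config("pm", beta = 0.1, gamma = 0.25, grad_smooth = 0)
  I <- img
  for (k in 1:50) {
    I2 <- diffusion_step(I, cfg)
    expect_gte(min(I2), min(I) - 1e-10)
    expect_lte(max(I2), max(I) + 1e-10)
    I <- I2
  }
})

test_that("the speckle-indicator model is invariant to the noise scale", {
  img <- random_image(24, seed = 4, lo = 0, hi = 255)
  run5 <- function(sig) {
    cfg <- cfg_for("m8", sigma = sig)
    I <- img
    for (k in 1:5) I <- diffusion_step(I, cfg)
    I
  }
  expect_equal(run5(1), run5(3), tolerance = 1e-10)
  # sigma = 0 degenerates to the constant operator
  cfg0 <- cfg_for("m8", sigma = 0)
  expect_identical(diffusion_step(img, cfg0), img)
})

test_that("a PM step reproduces a scalar-loop flux evaluation", {
  # independent reimplementation: explicit loops over faces, harmonic
  # conductance of (1 + |grad I|^2)^(-(1-beta)/2) with forward one-sided
  # gradients, zero-flux boundaries
  img <- matrix(0, 5, 5); img[3, 3] <- 1
  beta <- 0.5; gamma <- 0.1
  n <- 5
  g <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dx <- if (i < n) img[i + 1, j] - img[i, j] else 0
    dy <- if (j < n) img[i, j + 1] - img[i, j] else 0
    g[i, j] <- (1 + dx^2 + dy^2)^(-(1 - beta) / 2)
  }
  harm <- function(a, b) if (a + b > 0) 2 * a * b / (a + b) else 0
  ref <- img
  for (i in 1:n) for (j in 1:n) {
    acc <- 0
    if (i < n) acc <- acc + harm(g[i, j], g[i + 1, j]) * (img[i + 1, j] - img[i, j])
    if (i > 1) acc <- acc + harm(g[i, j], g[i - 1, j]) * (img[i - 1, j] - img[i, j])
    if (j < n) acc <- acc + harm(g[i, j], g[i, j + 1]) * (img[i, j + 1] - img[i, j])
    if (j > 1) acc <- acc + harm(g[i, j], g[i, j - 1]) * (img[i, j - 1] - img[i, j])
    ref[i, j] <- img[i, j] + gamma * acc
  }
  cfg <- diffusion_config("pm", beta = beta, gamma = gamma, grad_smooth = 0)
  expect_equal(diffusion_step(img, cfg), ref, tolerance = 1e-14)
  # forcing d(I) to 1 reduces the gray-level baseline to PM
  flat <- matrix(100, 5, 5); flat[3, 3] <- 101
  cfgd <- diffusion_config("ddnd", alpha = 1e-9, beta = beta, gamma = gamma,
                           grad_smooth = 0)
  cfgp <- diffusion_config("pm", beta = beta, gamma = gamma, grad_smooth = 0)
  expect_equal(diffusion_step(flat, cfgd), diffusion_step(flat, cfgp),
               tolerance = 1e-6)
})

test_that("the gated model matches the divergence form when ungated", {
  I <- smooth_field(48)
  s8 <- diffusion_step(I, cfg_for("m8", grad_smooth = 0))
  s13 <- diffusion_step(I, cfg_for("m13", grad_smooth = 0),
                        gate = matrix(1, 48, 48))
  d8 <- s8 - I; d13 <- s13 - I
  expect_lt(max(abs(d8 - d13)) / max(abs(d8)), 0.01)
})

test_that("a fully gated straight edge diffuses only tangentially", {
  n <- 32
  base <- step_image(n, split = 16, lo = 60, hi = 180)
  cfg <- diffusion_config("m13", alpha = 1, beta = 0.1, sigma = 1,
                          gamma = 0.1, grad_smooth = 0, max_iters = 50L)
  gate <- matrix(0, n, n)          # tangential-only everywhere
  # a clean straight step has no tangential curvature: it is a fixed point
  I <- base
  for (k in 1:50) I <- diffusion_step(I, cfg, gate = gate)
  expect_equal(I, base, tolerance = 1e-6)
  # noise confined to one line is smoothed along that line, and pixels a
  # safe distance away (isotropic limit of a flat region) never move
  set.seed(10)
  noisy <- matrix(100, n, n)
  noisy[, 16] <- noisy[, 16] + rnorm(n, sd = 5)
  I <- noisy
  for (k in 1:100) I <- diffusion_step(I, cfg, gate = gate)
  expect_lt(stats::sd(I[, 16]), 0.6 * stats::sd(noisy[, 16]))
  far <- c(1:11, 21:32)
  expect_lt(max(abs(I[, far] - noisy[, far])), 1e-6)
})

test_that("despeckle applies the oracle policy and honors its contracts", {
  ph <- shepp_logan(64)
  noisy <- add_speckle(ph, 1, seed = 21)
  cfg <- diffusion_config("m8", alpha = 1, beta = 0.1, sigma = 1,
                          max_iters = 400L)
  res <- despeckle(noisy, cfg, ground_truth = ph)
  expect_s3_class(res, "despeckle_result")
  expect_gt(psnr(res$restored, ph), psnr(noisy, ph))
  expect_equal(res$stopped_by, "psnr")
  expect_gt(res$iterations, 0)
  expect_equal(res$diagnostics$psnr[res$iterations],
               psnr(res$restored, ph))
  # noise-free observation: any diffusion only hurts, iterate 0 wins
  res0 <- despeckle(ph + 0.0, cfg, ground_truth = ph)
  expect_identical(res0$iterations, 0L)
  expect_identical(res0$restored, ph)
  # max_iters = 1 runs exactly one step
  cfg1 <- diffusion_config("m8", alpha = 1, beta = 0.1, sigma = 1,
                           max_iters = 1L,
                           stopping = stopping_policy("max-iters"))
  r1 <- despeckle(noisy, cfg1)
  expect_equal(r1$restored, diffusion_step(noisy, cfg1))
  expect_error(diffusion_config("m8", sigma = 1, max_iters = 0), "max_iters")
  # blow-up is reported with the iteration (near-linear diffusion far
  # beyond the stability bound amplifies until overflow)
  cfgbad <- suppressWarnings(
    diffusion_config("pm", beta = 1, gamma = 1e8,
                     stopping = stopping_policy("max-iters")))
  expect_error(despeckle(noisy, cfgbad), "iteration")
})
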