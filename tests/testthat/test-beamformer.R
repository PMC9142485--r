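# small fixture lead field shared by the beamformer tests
bf_grid <- source_grid(spacing = 20)
bf_lf <- build_leadfield(bf_grid, test_montage)

test_that("window covariances are symmetric PSD and shrink to the
           average-reference projector on white noise", {
  set.seed(41)
  ep <- array(rnorm(80 * 156 * 700, 0, 2), c(80, 156, 700))
  ep <- rereference_average(ep)
  C <- window_csd(ep, 0, c(8, 12), t0 = 351)
  expect_lt(max(abs(C - t(C))), 1e-9)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-9)
  # off-diagonal structure ~ average-reference projector (-1/n off-diag)
  dm <- mean(diag(C))
  offd <- C[upper.tri(C)]
  expect_lt(abs(mean(offd) / dm + 1 / 156), 0.05 / 156 * 10)
  expect_lt(sd(offd) / dm, 0.2)
  expect_error(window_csd(ep, 600, c(8, 12), t0 = 351), "outside")
})

test_that("a single common source gives a rank-1 dominant covariance", {
  set.seed(42)
  topo <- dipole_potential(c(0.02, 0.01, 0.06), c(5, 5, 10), test_montage)
  ep <- array(0, c(20, 156, 700))
  for (tr in 1:20) {
    s <- sin(2 * pi * 10 * (1:700) / 1000 + runif(1, 0, 2 * pi))
    ep[tr, , ] <- outer(topo, s) + rnorm(156 * 700, 0, 0.01)
  }
  C <- window_csd(ep, 0, c(8, 12), t0 = 351)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(ev[1] / ev[2], 100)
})

test_that("beamformer weights satisfy unit gain and the identity limit", {
  set.seed(43)
  gain <- bf_lf$gain[, , 40]
  C <- crossprod(matrix(rnorm(400 * 156), 400, 156)) / 400
  wt <- scalar_mv_weights(C, gain, lambda = 0.05)
  l <- drop(gain %*% wt$orientation)
  expect_equal(sum(wt$w * l), 1, tolerance = 1e-9)
  # identity covariance: weights equal the pseudoinverse closed form
  wt_id <- scalar_mv_weights(diag(156), gain, lambda = 0.05)
  l_id <- drop(gain %*% wt_id$orientation)
  expect_equal(wt_id$w, unname(l_id) / sum(l_id^2), tolerance = 1e-9)
})

test_that("weights and output power vary smoothly and monotonically in lambda", {
  set.seed(44)
  topo <- bf_lf$gain[, 3, 100]
  ep <- array(0, c(30, 156, 700))
  for (tr in 1:30) {
    s <- sin(2 * pi * 6 * (1:700) / 1000 + runif(1, 0, 2 * pi)) * 40
    ep[tr, , ] <- outer(topo, s) + rnorm(156 * 700, 0, 3)
  }
  C <- window_csd(ep, 0, c(4, 7), t0 = 351)
  lams <- c(0.01, 0.02, 0.05, 0.2, 1)
  wts <- lapply(lams, function(lam)
    scalar_mv_weights(C, bf_lf$gain[, , 100], lambda = lam))
  # unit-gain output power 1/(l' (C + lam m I)^-1 l) grows monotonically
  # with the regularizer (the inverse quadratic form shrinks in lambda)
  pows <- sapply(wts, `[[`, "power")
  expect_true(all(diff(pows) > 0))
  # continuity: nearby lambdas give nearby weights
  dw <- sapply(seq_along(lams)[-1], function(i)
    sqrt(sum((wts[[i]]$w - wts[[i - 1]]$w)^2)) /
      sqrt(sum(wts[[i - 1]]$w^2)))
  expect_lt(dw[1], 0.5)
})

test_that("a simulated dipole is localized at the true voxel", {
  set.seed(45)
  vox <- 150
  pos <- bf_grid$pos[vox, ] / 1000
  u <- c(0.2, 0.6, 0.77); u <- u / sqrt(sum(u^2))
  topo <- dipole_potential(pos, u * 25, test_montage)
  noise_sd <- max(abs(topo)) / sqrt(10)          # SNR 10 at the peak channel
  ep <- array(0, c(30, 156, 700))
  for (tr in 1:30) {
    s <- sin(2 * pi * 10 * (1:700) / 1000 + runif(1, 0, 2 * pi))
    ep[tr, , ] <- outer(topo, s) +
      matrix(rnorm(156 * 700, 0, noise_sd), 156, 700)
  }
  C <- window_csd(ep, 0, c(8, 12), t0 = 351, win_ms = 500)
  scan <- beamformer_scan(C, bf_lf)
  expect_equal(unname(scan$peak_mni), unname(bf_grid$pos[vox, ]))
  # output power at the source beats voxels two or more steps away
  d <- sqrt(rowSums(sweep(bf_grid$pos, 2, bf_grid$pos[vox, ], "-")^2))
  expect_true(all(scan$nai[vox] >= scan$nai[d >= 2 * bf_grid$spacing]))
})

test_that("source dB maps are stationary-flat and amplitude-scale free", {
  # strictly stationary data (fixed sinusoidal sources): every window has
  # identical power, so corrected maps must sit at 0 dB
  lf_small <- bf_lf
  keep <- seq(1, dim(bf_lf$gain)[3], by = 8)
  lf_small$gain <- bf_lf$gain[, , keep, drop = FALSE]
  lf_small$grid$pos <- bf_lf$grid$pos[keep, , drop = FALSE]
  set.seed(46)
  t1 <- dipole_potential(c(0.01, 0.03, 0.05), c(0, 10, 20), test_montage)
  t2 <- dipole_potential(c(-0.02, -0.02, 0.06), c(10, 0, 15), test_montage)
  tt <- (1:1400) / 1000
  ep <- array(0, c(5, 156, 1400))
  # both sources at one frequency: each channel then carries a single
  # stationary sinusoid, so every window has exactly the same power
  for (tr in 1:5) {
    ep[tr, , ] <- outer(t1, sin(2 * pi * 5.5 * tt + tr)) +
      outer(t2, sin(2 * pi * 5.5 * tt + 2 * tr + 1))
  }
  sp <- source_power_maps(ep, lf_small, bands = band_specs()["theta"])
  expect_lt(max(abs(sp$db)), 0.1)
  sp2 <- source_power_maps(2 * ep, lf_small, bands = band_specs()["theta"])
  expect_equal(sp$db, sp2$db, tolerance = 1e-9)
  # stochastic stationary noise stays near 0 dB on average
  set.seed(47)
  epn <- array(0, c(30, 156, 1400))
  for (tr in 1:30) epn[tr, , ] <- t(pink_noise(1400, 156)) * 5
  spn <- source_power_maps(rereference_average(epn), lf_small,
                           bands = band_specs()["theta"])
  post <- spn$centers > 0
  dev <- abs(rowMeans(spn$db[, 1, post]))
  expect_lt(stats::median(dev), 0.5)             # no systematic offset
  expect_lt(max(dev), 1.5)                       # finite-sample spread only
})

test_that("an injected theta burst peaks near its source voxel in-window", {
  set.seed(47)
  vox <- 60
  keep <- seq(1, dim(bf_lf$gain)[3], by = 4)
  if (!(vox %in% keep)) keep <- sort(c(keep, vox))
  lf_small <- bf_lf
  lf_small$gain <- bf_lf$gain[, , keep, drop = FALSE]
  lf_small$grid$pos <- bf_lf$grid$pos[keep, , drop = FALSE]
  pos <- bf_lf$grid$pos[vox, ] / 1000
  topo <- dipole_potential(pos, c(0, 10, 24), test_montage)
  env <- orfieeg:::.window_env((1:1400 - 701), c(150, 450), 3)
  ep <- array(0, c(30, 156, 1400))
  for (tr in 1:30) {
    s <- sin(2 * pi * 5 * (1:1400) / 1000 + runif(1, 0, 2 * pi)) * env
    ep[tr, , ] <- outer(topo, s) + t(pink_noise(1400, 156)) *
      max(abs(topo)) / 4
  }
  sp <- source_power_maps(ep, lf_small, bands = band_specs()["theta"])
  win <- which.min(abs(sp$centers - 300))
  peak <- which.max(sp$db[, 1, win])
  dist <- sqrt(sum((lf_small$grid$pos[peak, ] - bf_lf$grid$pos[vox, ])^2))
  expect_lte(dist, 2 * bf_grid$spacing)
})

test_that("the SnPM cluster test finds a common cube and nothing when null", {
  set.seed(48)
  nv <- nrow(bf_grid$pos)
  S <- 20
  ctr <- bf_grid$pos[200, ]
  inside <- which(apply(abs(sweep(bf_grid$pos, 2, ctr, "-")), 1, max) <=
                    bf_grid$spacing)
  b <- matrix(rnorm(S * nv, 0, 1), S, nv)
  a <- b + matrix(rnorm(S * nv, 0, 0.3), S, nv)
  a[, inside] <- a[, inside] + 1.2
  res <- snpm_cluster_test(a, b, bf_grid, n_perm = 300, seed = 5)
  sig <- res$clusters[res$clusters$significant, , drop = FALSE]
  expect_gte(nrow(sig), 1)
  big <- sig$id[which.max(sig$size)]
  expect_gt(length(intersect(which(res$labels == big), inside)),
            length(inside) * 0.6)
  # A vs B with A = B: empty result, not an error
  res0 <- snpm_cluster_test(b, b, bf_grid, n_perm = 200, seed = 2)
  expect_equal(nrow(res0$clusters), 0)
})
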