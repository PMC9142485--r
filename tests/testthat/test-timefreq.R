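test_that("window centers span exactly -550..+550 ms for 1400 ms epochs", {
  centers <- stft_centers(1400)
  expect_equal(min(centers), -550)
  expect_equal(max(centers), 550)
  expect_equal(length(centers), 111)
  expect_true(all(diff(centers) == 10))
  expect_true(0 %in% centers)
})

test_that("a stationary sinusoid yields the analytic Hanning-gain power", {
  fs <- 1000
  A <- 3
  x <- A * sin(2 * pi * 10 * (1:1400 - 701) / fs)
  tf <- stft_power(matrix(x, 1, 1400), fmin = 3, fmax = 45)
  p10 <- tf$power[1, 1, tf$freqs == 10, ]
  # constant over centers within 1%
  expect_lt((max(p10) - min(p10)) / mean(p10), 0.01)
  # analytic coherent gain of a symmetric Hanning window: sum(w)/2
  nwin <- 300
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  expect_lt(abs(mean(p10) / (A * sum(w) / 2)^2 - 1), 0.02)
  # zero signal: zero power
  tf0 <- stft_power(array(0, c(1, 2, 1400)))
  expect_true(all(tf0$power == 0))
})

test_that("raw power matches the unvectorized windowed-DFT oracle", {
  set.seed(14)
  x <- rnorm(1400)
  tf <- stft_power(matrix(x, 1, 1400))
  for (cse in list(c(-550, 5), c(0, 20), c(550, 45), c(130, 7))) {
    expect_equal(tf$power[1, 1, tf$freqs == cse[2], tf$centers == cse[1]],
                 direct_window_power(x, cse[1], cse[2]), tolerance = 1e-9)
  }
  expect_error(stft_power(matrix(rnorm(1400), 1, 1400), fmax = 600),
               "Nyquist")
})

test_that("dB baseline correction matches its definition and a brute force", {
  set.seed(15)
  ep <- array(rnorm(6 * 2 * 1400, 0, 4), c(6, 2, 1400))
  tf <- stft_power(ep)
  out <- log_baseline_correct(tf)
  # brute force on channel 2, frequency index 5
  avg <- apply(tf$power[, 2, 5, ], 2, mean)
  bl <- tf$centers >= -550 & tf$centers <= 0
  manual <- 10 * log10(avg) - mean(10 * log10(avg[bl]))
  expect_equal(out$db[2, 5, ], manual, tolerance = 1e-9)
  # baseline mean of corrected power is 0 by construction
  expect_lt(max(abs(apply(out$db[, , bl], c(1, 2), mean))), 1e-9)
  # a strictly stationary signal reads 0 dB at every window center
  xs <- 4 * sin(2 * pi * 10 * (1:1400) / 1000)
  tfs <- stft_power(matrix(xs, 1, 1400))
  outs <- log_baseline_correct(tfs)
  expect_lt(max(abs(outs$db[1, tfs$freqs == 10, ])), 0.1)
})

test_that("a 10x post-stimulus power step reads +10 dB", {
  x <- sin(2 * pi * 10 * (1:1400) / 1000)
  x[701:1400] <- x[701:1400] * sqrt(10)
  tf <- stft_power(array(x, c(1, 1, 1400)))
  out <- log_baseline_correct(tf)
  late <- tf$centers >= 200 & tf$centers <= 400
  early <- tf$centers >= -500 & tf$centers <= -300
  expect_equal(mean(out$db[1, tf$freqs == 10, late]) -
                 mean(out$db[1, tf$freqs == 10, early]), 10,
               tolerance = 0.3)
})

test_that("total raw power tracks windowed variance on white noise", {
  set.seed(16)
  x <- rnorm(1400)
  tf <- stft_power(matrix(x, 1, 1400), fmin = 1, fmax = 499, fstep = 1)
  nwin <- 300
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / (nwin - 1))
  # Parseval with a taper: sum over DFT bins of |X|^2 = N * sum(w^2 x^2);
  # the 1 Hz grid approximates bins up to Nyquist (x2 for two-sided)
  ic <- which(tf$centers == 0)
  seg <- x[(701 - 150):(701 + 149)]
  lhs <- 2 * sum(tf$power[1, 1, , ic]) / 1000   # integral over the 1 Hz grid
  rhs <- sum((w * seg)^2)                       # Parseval: windowed energy
  expect_lt(abs(lhs / rhs - 1), 0.05)
})

test_that("dB maps commute with channel permutation and topo maps average", {
  set.seed(17)
  ep <- array(rnorm(4 * 3 * 1400, 0, 2), c(4, 3, 1400))
  out1 <- log_baseline_correct(stft_power(ep))
  perm <- c(3, 1, 2)
  out2 <- log_baseline_correct(stft_power(ep[, perm, , drop = FALSE]))
  expect_equal(out2$db, out1$db[perm, , ], tolerance = 1e-12)
  tp <- topo_power(out1$db, out1$freqs, out1$centers, c(0, 300), c(4, 7))
  manual <- mean(out1$db[2, out1$freqs >= 4 & out1$freqs <= 7,
                         out1$centers >= 0 & out1$centers <= 300])
  expect_equal(tp[2], manual, tolerance = 1e-12)
  expect_error(topo_power(out1$db, out1$freqs, out1$centers,
                          c(900, 950), c(4, 7)), "empty")
  # uniform map stays uniform; a single-channel effect peaks there
  db2 <- out1$db; db2[] <- 2
  expect_true(all(topo_power(db2, out1$freqs, out1$centers,
                             c(0, 300), c(4, 7)) == 2))
})

test_that("the 2-D cluster test finds an injected theta box and not phantoms", {
  set.seed(18)
  S <- 20; nf <- 20; nt <- 40
  freqs <- 3:22; centers <- seq(-200, 590, by = 20)
  b <- array(rnorm(S * nf * nt, 0, 1), c(S, nf, nt))
  a <- b + array(rnorm(S * nf * nt, 0, 0.3), c(S, nf, nt))
  fbox <- which(freqs >= 4 & freqs <= 7)
  tbox <- which(centers >= 200 & centers <= 500)
  a[, fbox, tbox] <- a[, fbox, tbox] + 1.2
  res <- tf_cluster_test(a, b, freqs, centers, n_perm = 300, seed = 3)
  sig <- res$clusters[res$clusters$significant, , drop = FALSE]
  expect_gte(nrow(sig), 1)
  top <- sig[which.max(sig$size), ]
  expect_lte(top$fmin, 5); expect_gte(top$fmax, 6)
  expect_lte(top$tmin, 260); expect_gte(top$tmax, 440)
  # identical arrays: nothing
  res0 <- tf_cluster_test(b, b, freqs, centers, n_perm = 200, seed = 2)
  expect_equal(nrow(res0$clusters), 0)
})
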