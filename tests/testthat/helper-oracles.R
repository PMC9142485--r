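# Shared fixtures and independent oracles. Everything here is built in
# code at test time; oracles deliberately use different algorithms from
# the implementation they check.

test_montage <- build_montage()
test_adjacency <- electrode_adjacency(test_montage)

# truncated Legendre-series surface potential for a dipole in a
# homogeneous sphere (term-by-term recurrence summation; the package
# implementation uses the analytically summed closed form instead)
series_dipole_potential <- function(position, moment, montage,
                                    order = 150) {
  sph <- montage$sphere
  r0 <- as.numeric(position) - sph$center
  f <- sqrt(sum(r0^2)); R <- sph$radius
  q <- as.numeric(moment) * 1e-9
  k <- 1 / (4 * pi * sph$sigma * R^2)
  e <- sweep(montage$pos, 2, sph$center, "-") / R
  rhat <- r0 / f; x <- f / R
  cth <- pmin(1, pmax(-1, drop(e %*% rhat)))
  qr <- sum(q * rhat)
  qe <- drop(e %*% q) - cth * qr   # tangential moment projected on the
                                   # electrode great-circle direction
  p_nm1 <- rep(1, length(cth)); p_n <- cth
  dp_nm1 <- rep(0, length(cth)); dp_n <- rep(1, length(cth))
  v <- 3 * qr * p_n + 3 * qe * dp_n
  for (n in 2:order) {
    p_np <- ((2 * n - 1) * cth * p_n - (n - 1) * p_nm1) / n
    dp_np <- ((2 * n - 1) * (p_n + cth * dp_n) - (n - 1) * dp_nm1) / n
    v <- v + x^(n - 1) * ((2 * n + 1) * qr * p_np +
                            (2 * n + 1) / n * qe * dp_np)
    p_nm1 <- p_n; p_n <- p_np; dp_nm1 <- dp_n; dp_n <- dp_np
  }
  v <- k * v
  (v - mean(v)) * 1e6
}

# textbook two-way within-subject ANOVA, scalar loops over the printed
# sums-of-squares formulas; GG epsilon via eigen() on the contrast
# covariance (the implementation uses a closed 2x2 form instead)
rm_anova_oracle <- function(y) {
  # y: subjects x 2 x 3
  S <- dim(y)[1]
  gm <- mean(y)
  ma <- apply(y, 2, mean); mb <- apply(y, 3, mean)
  mab <- apply(y, c(2, 3), mean)
  ms <- apply(y, 1, mean)
  msa <- apply(y, c(1, 2), mean); msb <- apply(y, c(1, 3), mean)
  ss_a <- 0; for (a in 1:2) ss_a <- ss_a + 3 * S * (ma[a] - gm)^2
  ss_b <- 0; for (b in 1:3) ss_b <- ss_b + 2 * S * (mb[b] - gm)^2
  ss_ab <- 0
  for (a in 1:2) for (b in 1:3) {
    ss_ab <- ss_ab + S * (mab[a, b] - ma[a] - mb[b] + gm)^2
  }
  ss_as <- 0
  for (s in 1:S) for (a in 1:2) {
    ss_as <- ss_as + 3 * (msa[s, a] - ms[s] - ma[a] + gm)^2
  }
  ss_bs <- 0
  for (s in 1:S) for (b in 1:3) {
    ss_bs <- ss_bs + 2 * (msb[s, b] - ms[s] - mb[b] + gm)^2
  }
  ss_abs <- 0
  for (s in 1:S) for (a in 1:2) for (b in 1:3) {
    ss_abs <- ss_abs + (y[s, a, b] - msa[s, a] - msb[s, b] - mab[a, b] +
                          ma[a] + mb[b] + ms[s] - gm)^2
  }
  f_a <- (ss_a / 1) / (ss_as / (S - 1))
  f_b <- (ss_b / 2) / (ss_bs / (2 * (S - 1)))
  f_ab <- (ss_ab / 2) / (ss_abs / (2 * (S - 1)))
  gg <- function(scores) {
    # scores: S x d matrix of orthonormal contrast scores
    V <- stats::cov(scores)
    lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    sum(lam)^2 / (ncol(scores) * sum(lam^2))
  }
  Hb <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  eps_b <- gg(msb %*% Hb)
  yA <- (y[, 1, ] - y[, 2, ]) / sqrt(2)         # S x 3
  eps_ab <- gg(yA %*% Hb)
  p_gg <- function(f, df1, df2, eps) {
    stats::pf(f, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  list(F = c(A = f_a, B = f_b, AB = f_ab),
       eps = c(B = eps_b, AB = eps_ab),
       p_gg = c(A = stats::pf(f_a, 1, S - 1, lower.tail = FALSE),
                B = p_gg(f_b, 2, 2 * (S - 1), eps_b),
                AB = p_gg(f_ab, 2, 2 * (S - 1), eps_ab)),
       eta = c(A = ss_a / (ss_a + ss_as), B = ss_b / (ss_b + ss_bs),
               AB = ss_ab / (ss_ab + ss_abs)))
}

# direct windowed DFT at a single frequency (loop form) - oracle for the
# vectorized short-time Fourier implementation
direct_window_power <- function(x, center_ms, freq, fs = 1000, t0 = 701,
                                win_ms = 300) {
  nwin <- round(win_ms * fs / 1000)
  start <- round(center_ms * fs / 1000) + t0 - nwin %/% 2
  acc <- 0 + 0i
  for (i in seq_len(nwin)) {
    w <- 0.5 - 0.5 * cos(2 * pi * (i - 1) / (nwin - 1))
    acc <- acc + x[start + i - 1] * w *
      exp(-2i * pi * freq * (i - 1) / fs)
  }
  Mod(acc)^2
}

# minimal hand-built schedule for scoring tests
tiny_schedule <- function(outcomes, squares, condition = "identical") {
  sched <- data.frame(trial = seq_along(outcomes),
                      outcome = factor(outcomes,
                                       levels = c("SAME", "SIMI", "DIFF")),
                      correct_square = squares,
                      stringsAsFactors = FALSE)
  attr(sched, "condition") <- condition
  attr(sched, "block_id") <- 1L
  attr(sched, "object_triplet") <- c("hat", "hat2", "cake")
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

tiny_log <- function(sched, choices, rts = NULL) {
  n <- nrow(sched)
  correct <- choices == sched$correct_square
  shown <- ifelse(correct, as.character(sched$outcome), "DIFF")
  log <- data.frame(trial = sched$trial, block = 1L,
                    condition = attr(sched, "condition"),
                    outcome = as.character(sched$outcome),
                    shown_outcome = shown, choice = choices,
                    correct = correct,
                    rt_ms = if (is.null(rts)) rep(500, n) else rts,
                    stringsAsFactors = FALSE)
  class(log) <- c("behavior_log", "data.frame")
  log
}
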