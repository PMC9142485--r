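#' Window centers for the sliding short-time Fourier transform
#'
#' Valid (non-padded) centers on the hop grid for an epoch of `n_samples`
#' at `fs`: a window "at center t" spans t-win/2 .. t+win/2-1 samples, so
#' 1400 ms epochs (-700..+699 ms) with 300 ms windows yield centers
#' exactly spanning -550..+550 ms.
#'
#' @param n_samples epoch length in samples
#' @param fs sampling rate, Hz
#' @param t0 index (1-based) of the 0 ms sample
#' @param win_ms,hop_ms window length and hop in ms
#' @return numeric vector of center times in ms
#' @export
stft_centers <- function(n_samples, fs = 1000, t0 = 701, win_ms = 300,
                         hop_ms = 10) {
  half <- round(win_ms * fs / 2000)
  t_min <- (1 + half - t0) * 1000 / fs
  t_max <- (n_samples - half + 1 - t0) * 1000 / fs
  lo <- ceiling(t_min / hop_ms) * hop_ms
  hi <- floor(t_max / hop_ms) * hop_ms
  seq(lo, hi, by = hop_ms)
}

#' Hanning-tapered short-time Fourier power
#'
#' Raw spectral power per trial, channel, frequency and window center:
#' each 300 ms window is Hanning-tapered and projected onto complex
#' exponentials at the requested 1 Hz frequency grid (direct windowed DFT;
#' the grid is finer than the ~3.3 Hz Rayleigh resolution of the window,
#' i.e. interpolative). Only fully supported windows are evaluated - no
#' zero padding at the epoch edges.
#'
#' @param epochs trials x channels x samples array (uV), or channels x
#'   samples matrix for a single trial
#' @param fs sampling rate Hz
#' @param t0 1-based index of outcome onset
#' @param fmin,fmax,fstep frequency grid, Hz
#' @param win_ms,hop_ms window and hop, ms
#' @return `tf_power` object: list with `power` (trials x channels x
#'   n_freq x n_centers, uV^2), `freqs` (Hz), `centers` (ms), window spec
#' @export
stft_power <- function(epochs, fs = 1000, t0 = 701, fmin = 3, fmax = 45,
                       fstep = 1, win_ms = 300, hop_ms = 10) {
  if (length(dim(epochs)) == 2) {
    epochs <- array(epochs, c(1, dim(epochs)))
  }
  stopifnot(length(dim(epochs)) == 3)
  if (fmax > fs / 2) stop("fmax exceeds the Nyquist frequency")
  nwin <- round(win_ms * fs / 1000)
  if (dim(epochs)[3] < nwin) stop("epoch shorter than the analysis window")
  freqs <- seq(fmin, fmax, by = fstep)
  centers <- stft_centers(dim(epochs)[3], fs, t0, win_ms, hop_ms)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))
  tt <- (seq_len(nwin) - 1) / fs
  basis <- exp(-2i * pi * outer(freqs, tt)) *
    matrix(taper, length(freqs), nwin, byrow = TRUE)    # F x nwin
  half <- nwin %/% 2
  starts <- round(centers * fs / 1000) + t0 - half
  ntr <- dim(epochs)[1]; nch <- dim(epochs)[2]
  pow <- array(NA_real_, c(ntr, nch, length(freqs), length(centers)))
  for (tr in seq_len(ntr)) {
    xm <- epochs[tr, , , drop = TRUE]
    if (is.null(dim(xm))) xm <- matrix(xm, nrow = nch)
    for (w in seq_along(starts)) {
      seg <- xm[, starts[w]:(starts[w] + nwin - 1), drop = FALSE]
      cf <- basis %*% t(seg)                            # F x channels
      pow[tr, , , w] <- t(Mod(cf)^2)
    }
  }
  structure(list(power = pow, freqs = freqs, centers = centers,
                 win_ms = win_ms, hop_ms = hop_ms, fs = fs),
            class = "tf_power")
}

#' Log-transform and baseline-correct trial-averaged power
#'
#' Event-related spectral perturbation convention: power is averaged over
#' trials, converted to decibels (10 log10), and the mean log power of the
#' baseline window centers (default -550..0 ms) is subtracted per channel
#' and frequency.
#'
#' @param tf a `tf_power` object from [stft_power()]
#' @param baseline c(start, end) of baseline center times, ms
#' @param eps floor applied to zero power before the log, with a warning
#' @return list with `db` (channels x freqs x centers), `freqs`,
#'   `centers`, `baseline`
#' @export
log_baseline_correct <- function(tf, baseline = c(-550, 0), eps = 1e-20) {
  stopifnot(inherits(tf, "tf_power"))
  bl <- tf$centers >= baseline[1] & tf$centers <= baseline[2]
  if (!any(bl)) stop("no window centers inside the baseline interval")
  avg <- apply(tf$power, c(2, 3, 4), mean)    # channels x F x W
  if (any(avg <= 0)) {
    warning("non-positive power floored at eps before log transform")
    avg <- pmax(avg, eps)
  }
  logp <- 10 * log10(avg)
  base <- apply(logp[, , bl, drop = FALSE], c(1, 2), mean)
  db <- sweep(logp, c(1, 2), base, "-")
  list(db = db, freqs = tf$freqs, centers = tf$centers, baseline = baseline)
}

#' 2-D time-frequency cluster-permutation test
#'
#' Paired comparison of per-subject time-frequency power (freq x time)
#' between two conditions with the same sign-flip cluster engine as the
#' waveform analysis, using 4-connectivity in the time-frequency plane
#' and cluster size (number of bins) as the cluster statistic.
#'
#' @param a,b arrays subjects x freqs x centers (dB)
#' @param freqs,centers axis labels for reporting
#' @param n_perm permutations
#' @param cluster_alpha cluster-forming alpha
#' @param seed integer seed
#' @return list as [cluster_perm_graph()] plus `clusters` augmented with
#'   bounding boxes (fmin, fmax, tmin, tmax)
#' @export
tf_cluster_test <- function(a, b, freqs, centers, n_perm = 1000,
                            cluster_alpha = 0.05, seed = 1) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3)
  nf <- dim(a)[2]; nt <- dim(a)[3]
  d <- a - b
  dim(d) <- c(dim(a)[1], nf * nt)
  nb <- .grid2d_neighbors(nf, nt)
  res <- cluster_perm_graph(d, nb, n_perm = n_perm,
                            cluster_alpha = cluster_alpha, seed = seed)
  if (nrow(res$clusters)) {
    fi <- ((seq_len(nf * nt) - 1) %% nf) + 1
    ti <- ((seq_len(nf * nt) - 1) %/% nf) + 1
    res$clusters$fmin <- vapply(res$clusters$id, function(id)
      min(freqs[fi[res$labels == id]]), numeric(1))
    res$clusters$fmax <- vapply(res$clusters$id, function(id)
      max(freqs[fi[res$labels == id]]), numeric(1))
    res$clusters$tmin <- vapply(res$clusters$id, function(id)
      min(centers[ti[res$labels == id]]), numeric(1))
    res$clusters$tmax <- vapply(res$clusters$id, function(id)
      max(centers[ti[res$labels == id]]), numeric(1))
  }
  res$freqs <- freqs; res$centers <- centers; res$dim <- c(nf, nt)
  res
}

.grid2d_neighbors <- function(nf, nt) {
  idx <- matrix(seq_len(nf * nt), nf, nt)
  nb <- matrix(NA_integer_, nf * nt, 4L)
  nb[as.vector(idx[-1, ]), 1] <- as.vector(idx[-nf, ])
  nb[as.vector(idx[-nf, ]), 2] <- as.vector(idx[-1, ])
  nb[as.vector(idx[, -1]), 3] <- as.vector(idx[, -nt])
  nb[as.vector(idx[, -nt]), 4] <- as.vector(idx[, -1])
  nb
}

#' Topographic band/interval power map
#'
#' Mean dB power over a requested time interval and frequency band, per
#' electrode - the quantity mapped in the topographical power
#' distributions.
#'
#' @param db channels x freqs x centers array of corrected power (dB)
#' @param freqs,centers axes of `db`
#' @param time_int c(start, end) ms
#' @param freq_band c(low, high) Hz
#' @return named numeric vector, one mean dB value per channel
#' @export
topo_power <- function(db, freqs, centers, time_int, freq_band) {
  fi <- freqs >= freq_band[1] & freqs <= freq_band[2]
  ti <- centers >= time_int[1] & centers <= time_int[2]
  if (!any(fi) || !any(ti)) stop("empty time/frequency selection")
  apply(db[, fi, ti, drop = FALSE], 1, mean)
}
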