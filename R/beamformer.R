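#' Frequency band definitions for the source analysis
#'
#' theta 4-7, alpha 8-12, low beta 13-20, high beta 21-30, gamma 31-45 Hz.
#' @return named list of c(low, high) pairs, Hz
#' @export
band_specs <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), low_beta = c(13, 20),
       high_beta = c(21, 30), gamma = c(31, 45))
}

#' Band-limited sensor covariance of a sliding window
#'
#' Hanning-tapered windowed Fourier coefficients on the 1 Hz frequency
#' grid inside the band, accumulated over trials into a real sensor
#' covariance, Re(sum_f x_f x_f^H) / n_trials - symmetric positive
#' semi-definite, the quantity the minimum-variance filter is built from.
#'
#' @param epochs trials x channels x samples array
#' @param center_ms window center, ms relative to the onset sample
#' @param band c(low, high) Hz
#' @param fs sampling rate, Hz
#' @param t0 1-based onset sample index
#' @param win_ms window length, ms
#' @return channels x channels covariance matrix (uV^2 scale)
#' @export
window_csd <- function(epochs, center_ms, band, fs = 1000, t0 = 701,
                       win_ms = 300) {
  stopifnot(length(dim(epochs)) == 3, dim(epochs)[1] >= 1)
  nwin <- round(win_ms * fs / 1000)
  half <- nwin %/% 2
  start <- round(center_ms * fs / 1000) + t0 - half
  if (start < 1 || start + nwin - 1 > dim(epochs)[3]) {
    stop("window at ", center_ms, " ms falls outside the epoch")
  }
  freqs <- seq(ceiling(band[1]), floor(band[2]), by = 1)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / (nwin - 1))
  tt <- (seq_len(nwin) - 1) / fs
  basis <- exp(-2i * pi * outer(freqs, tt)) *
    matrix(taper, length(freqs), nwin, byrow = TRUE)
  nch <- dim(epochs)[2]
  C <- matrix(0, nch, nch)
  for (tr in seq_len(dim(epochs)[1])) {
    seg <- epochs[tr, , start:(start + nwin - 1), drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = nch)
    cf <- basis %*% t(seg)                       # F x channels
    C <- C + Re(Conj(t(cf)) %*% cf)
  }
  C / dim(epochs)[1]
}

#' Scalar minimum-variance beamformer weights at one voxel
#'
#' Regularizes the covariance as C + lambda * mean(diag(C)) * I, picks the
#' source orientation maximizing output power (the generalized
#' eigenvector, i.e. the minimum eigenvector of L' C^-1 L over the three
#' gain columns), and returns unit-gain weights w = C^-1 l / (l' C^-1 l)
#' so that w'l = 1.
#'
#' @param csd channels x channels covariance
#' @param gain channels x 3 lead-field columns at the voxel
#' @param lambda regularization as a fraction of the mean diagonal
#'   (default 0.05)
#' @return list with `w` (weights), `orientation` (unit 3-vector),
#'   `power` (w' C w), `noise_power` (w'w, for noise normalization)
#' @export
scalar_mv_weights <- function(csd, gain, lambda = 0.05, Cinv = NULL) {
  stopifnot(ncol(gain) == 3)
  nch <- nrow(csd)
  if (is.null(Cinv)) {
    Cr <- csd + lambda * mean(diag(csd)) * diag(nch)
    Ci_g <- solve(Cr, gain)                      # C^-1 L
  } else {
    Ci_g <- Cinv %*% gain
  }
  M <- crossprod(gain, Ci_g)                     # L' C^-1 L, 3 x 3
  qrg <- qr(gain)
  if (qrg$rank < 3) stop("rank-deficient gain at voxel")
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  u <- es$vectors[, 3]                           # min eigenvalue direction
  l <- drop(gain %*% u)
  Ci_l <- drop(Ci_g %*% u)
  denom <- sum(l * Ci_l)
  w <- Ci_l / denom
  list(w = w, orientation = u, power = 1 / denom,
       noise_power = sum(w^2))
}

#' Per-subject beamformer source power maps
#'
#' Scalar minimum-variance projection of band-limited windowed power onto
#' the source grid. Weights are computed once per band from the
#' all-window covariance (common spatial filter) and applied to each
#' 300 ms window (50 ms hop, centers -550..+550 ms); power is
#' log-transformed and baseline-corrected (dB re the -550..0 ms window
#' average) per voxel and band.
#'
#' @param epochs trials x channels x samples array for one subject/cell
#' @param leadfield a [build_leadfield()] object
#' @param bands named list of c(low, high); default [band_specs()]
#' @param lambda beamformer regularization fraction
#' @param fs,t0 sampling rate and onset index
#' @param hop_ms window hop (default 50)
#' @param baseline baseline interval for the dB correction, ms
#' @return list with `db` (voxels x bands x centers), `raw` (uncorrected
#'   power), `centers`, `bands`, `grid`
#' @export
source_power_maps <- function(epochs, leadfield, bands = band_specs(),
                              lambda = 0.05, fs = 1000, t0 = 701,
                              hop_ms = 50, baseline = c(-550, 0)) {
  centers <- stft_centers(dim(epochs)[3], fs, t0, win_ms = 300,
                          hop_ms = hop_ms)
  nv <- dim(leadfield$gain)[3]
  nb <- length(bands)
  raw <- array(NA_real_, c(nv, nb, length(centers)),
               dimnames = list(NULL, names(bands), NULL))
  for (b in seq_len(nb)) {
    csd_w <- lapply(centers, function(cc) {
      window_csd(epochs, cc, bands[[b]], fs, t0)
    })
    Call <- Reduce(`+`, csd_w) / length(csd_w)
    Cinv <- solve(Call + lambda * mean(diag(Call)) * diag(nrow(Call)))
    for (v in seq_len(nv)) {
      wt <- scalar_mv_weights(Call, leadfield$gain[, , v], lambda,
                              Cinv = Cinv)
      raw[v, b, ] <- vapply(csd_w, function(C) {
        drop(crossprod(wt$w, C %*% wt$w))
      }, numeric(1))
    }
  }
  bl <- centers >= baseline[1] & centers <= baseline[2]
  logp <- 10 * log10(pmax(raw, 1e-30))
  base <- apply(logp[, , bl, drop = FALSE], c(1, 2), mean)
  db <- sweep(logp, c(1, 2), base, "-")
  list(db = db, raw = raw, centers = centers, bands = bands,
       grid = leadfield$grid)
}

#' Neural-activity-index source scan for localization
#'
#' Noise-normalized scalar beamformer output (unit-gain output power
#' divided by w'w), which removes the depth bias of raw minimum-variance
#' power; the argmax voxel is the localization estimate for a dominant
#' source.
#'
#' @param csd sensor covariance
#' @param leadfield a [build_leadfield()] object
#' @param lambda regularization fraction
#' @return list with `nai` (per-voxel index), `power` (raw output power),
#'   `peak` (voxel index of max NAI), `peak_mni` (its MNI coordinates)
#' @export
beamformer_scan <- function(csd, leadfield, lambda = 0.05) {
  nv <- dim(leadfield$gain)[3]
  nai <- power <- numeric(nv)
  Cinv <- solve(csd + lambda * mean(diag(csd)) * diag(nrow(csd)))
  for (v in seq_len(nv)) {
    wt <- scalar_mv_weights(csd, leadfield$gain[, , v], lambda,
                            Cinv = Cinv)
    power[v] <- wt$power
    nai[v] <- wt$power / wt$noise_power
  }
  peak <- which.max(nai)
  list(nai = nai, power = power, peak = peak,
       peak_mni = leadfield$grid$pos[peak, ])
}

#' SnPM-style spatial cluster test on source maps
#'
#' Voxel-wise t statistics (paired difference or one-sample against zero)
#' with a sign-flip permutation null; spatial clusters are 6-connected
#' components of supra-threshold voxels, retained when larger than the
#' 95th percentile of the permutation maximum cluster size.
#'
#' @param maps_a subjects x voxels matrix
#' @param maps_b optional second condition (paired); when `NULL` a
#'   one-sample test of `maps_a` against zero is run
#' @param grid the [source_grid()] the maps live on
#' @param n_perm permutations (>= 100)
#' @param cluster_alpha voxel-level threshold
#' @param seed integer seed
#' @return [cluster_perm_graph()] result augmented with per-cluster peak
#'   MNI coordinates
#' @export
snpm_cluster_test <- function(maps_a, maps_b = NULL, grid, n_perm = 1000,
                              cluster_alpha = 0.05, seed = 1) {
  d <- if (is.null(maps_b)) maps_a else maps_a - maps_b
  if (all(d == 0)) {
    return(list(t = rep(0, ncol(d)),
                labels = rep(0L, ncol(d)),
                clusters = data.frame(id = integer(0), size = integer(0),
                                      p_corrected = numeric(0),
                                      significant = logical(0)),
                null_q95 = 0, n_perm = n_perm))
  }
  nb <- grid_neighbors(grid)
  res <- cluster_perm_graph(d, nb, n_perm = n_perm,
                            cluster_alpha = cluster_alpha, seed = seed)
  if (nrow(res$clusters)) {
    res$clusters$peak_x <- res$clusters$peak_y <- res$clusters$peak_z <- NA
    for (i in seq_len(nrow(res$clusters))) {
      vox <- which(res$labels == res$clusters$id[i])
      pk <- vox[which.max(abs(res$t[vox]))]
      res$clusters[i, c("peak_x", "peak_y", "peak_z")] <- grid$pos[pk, ]
    }
  }
  res
}

#' Export a per-voxel map as NIfTI in MNI space
#'
#' Writes the (sparse) grid values into a dense volume with a diagonal
#' affine at the grid spacing. Requires the RNifti package.
#' @param values per-voxel values (grid order)
#' @param grid the [source_grid()]
#' @param path output .nii path
#' @export
write_source_nifti <- function(values, grid, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  sp <- grid$spacing
  rng <- apply(grid$pos, 2, range)
  dims <- (rng[2, ] - rng[1, ]) / sp + 1
  vol <- array(NA_real_, dims)
  idx <- sweep(grid$pos, 2, rng[1, ], "-") / sp + 1
  vol[cbind(idx[, 1], idx[, 2], idx[, 3])] <- values
  img <- RNifti::asNifti(vol)
  aff <- diag(c(sp, sp, sp, 1))
  aff[1:3, 4] <- rng[1, ]
  RNifti::qform(img) <- structure(aff, code = 4L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
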