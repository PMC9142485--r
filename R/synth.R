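#' Effect specification for the synthetic EEG generator
#'
#' Describes the statistical structure of the simulated experiment: per
#' (condition, trial type) cell a set of transient ERP components (dipole
#' source, peak latency, Gaussian width, moment in nAm) and of ongoing
#' narrow-band oscillatory sources whose envelope changes by a given dB
#' amount inside a time window; plus 1/f background noise mixed through
#' random superficial sources, sensor noise, occasional large artifact
#' epochs, and multiplicative between-subject amplitude variability.
#'
#' The default preset mirrors the outcome-monitoring pattern of the task:
#' outcomes that signal a behavioral switch (DIFF always; SIMI only in
#' condition "identical") evoke a frontal positivity at 200-300 ms, a
#' central negativity near 350 ms and a central/posterior positivity at
#' 400-600 ms, together with a frontocentral theta-band power increase
#' and a later centroparietal beta-band suppression; stay-signalling
#' outcomes carry the same components strongly attenuated. Epoch counts
#' per cell reproduce the retained-epoch bookkeeping of the study
#' (~50-56 per cell) and `n_subjects = 22`.
#'
#' @param name `"default"` (effects as above) or `"null"` (identical
#'   cells, noise only - for false-positive calibration)
#' @param n_subjects number of simulated subjects
#' @param noise_sd target per-channel background noise sd, uV
#' @param artifact_rate fraction of epochs receiving injected > 100 uV
#'   excursions
#' @param subject_sd sd of the log-normal between-subject amplitude factor
#' @param epochs_per_cell optional 2 x 3 matrix (conditions x SAME/SIMI/
#'   DIFF) of generated epoch counts, overriding the preset
#' @return object of class `effect_spec`
#' @export
effect_preset <- function(name = c("default", "null"), n_subjects = 22,
                          noise_sd = 9, artifact_rate = 0.05,
                          subject_sd = 0.3, epochs_per_cell = NULL) {
  name <- match.arg(name)
  if (is.null(epochs_per_cell)) {
    epochs_per_cell <- matrix(c(57, 54, 54, 59, 57, 53), 2, 3, byrow = TRUE,
                              dimnames = list(c("identical", "semantical"),
                                              c("SAME", "SIMI", "DIFF")))
  }
  # sources in MNI mm (head sphere center (0,0,40), brain radius 81 mm)
  src_frontal <- c(0, 55, 25)
  src_central <- c(0, 0, 75)
  src_parietal <- c(0, -35, 60)
  src_ofc <- c(0, 40, 0)
  src_centropar <- c(0, -30, 65)
  erp_component <- function(src, lat, width, amp, orient = NULL) {
    list(source = src, latency_ms = lat, width_ms = width, amp_nAm = amp,
         orient = orient)
  }
  osc_component <- function(src, freq, window, change_db, base_nAm,
                            orient = NULL) {
    list(source = src, freq_hz = freq, window_ms = window,
         change_db = change_db, base_nAm = base_nAm, orient = orient)
  }
  cell_effects <- function(is_switch) {
    if (name == "null") return(list(erp = list(), osc = list()))
    if (is_switch) {
      list(
        erp = list(
          erp_component(src_frontal, 250, 45, 40),
          erp_component(src_central, 350, 30, -25),
          erp_component(src_parietal, 500, 80, 35)
        ),
        osc = list(
          osc_component(src_ofc, 5.5, c(150, 650), 4, 110, c(0, 0.2, 1)),
          osc_component(src_centropar, 20, c(350, 600), -4, 35)
        )
      )
    } else {
      list(
        erp = list(
          erp_component(src_frontal, 250, 45, -10),
          erp_component(src_central, 350, 30, -8),
          erp_component(src_parietal, 500, 80, 8)
        ),
        osc = list(
          osc_component(src_ofc, 5.5, c(150, 650), 1.5, 110, c(0, 0.2, 1)),
          osc_component(src_centropar, 20, c(350, 600), -1.5, 35)
        )
      )
    }
  }
  cells <- list()
  for (cond in c("identical", "semantical")) {
    for (ty in c("SAME", "SIMI", "DIFF")) {
      is_switch <- ty == "DIFF" || (ty == "SIMI" && cond == "identical")
      cells[[paste(cond, ty, sep = ".")]] <- cell_effects(is_switch)
    }
  }
  structure(list(
    name = name, n_subjects = n_subjects, cells = cells,
    epochs_per_cell = epochs_per_cell,
    noise = list(exponent = 1, sd_uV = noise_sd, n_sources = 60,
                 sensor_sd_uV = 1.5, band = c(0.7, 46)),
    artifact_rate = artifact_rate, subject_sd = subject_sd,
    fs = 1000, n_samples = 1400L, t0 = 701L
  ), class = "effect_spec")
}

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Deterministic 31-bit hash so every stage / subject / cell gets an
#' independent, logged stream without seed collisions.
#' @param seed master integer seed
#' @param tag character tag (stage name, subject id, ...)
#' @return integer in [0, 2^31 - 2]
#' @export
derive_seed <- function(seed, tag) {
  # multiplicative rolling hash: distinct tags map to distinct streams
  h <- as.numeric(seed) %% 2147483647
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Band-limited 1/f background noise
#'
#' Columns of unit-variance noise whose power spectrum falls as
#' 1/f^exponent inside `band` (soft high-edge rolloff, zero below the low
#' edge), synthesized by randomized-amplitude, random-phase spectra - the
#' background process the synthetic EEG and the statistical calibration
#' simulations assume.
#'
#' @param n samples per column
#' @param k number of columns (independent traces)
#' @param fs sampling rate, Hz
#' @param exponent spectral exponent (1 = pink)
#' @param band c(low, high) Hz
#' @return n x k matrix, each column scaled to unit sd
#' @export
pink_noise <- function(n, k, fs = 1000, exponent = 1, band = c(0.7, 46)) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  shape <- f^(-exponent / 2)
  shape[f < band[1]] <- 0
  roll <- f > band[2]
  shape[roll] <- shape[roll] * exp(-(f[roll] - band[2]) / 2)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    ph <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = shape * stats::rnorm(nf, 1, 0.3), argument = ph)
    full <- c(0, spec, rev(Conj(spec[-nf])))
    x <- Re(stats::fft(full, inverse = TRUE))[1:n]
    out[, j] <- x / stats::sd(x)
  }
  out
}

#' Generate the epochs of one subject for selected cells
#'
#' Deterministic under `(seed, subject)`: ERP components are projected to
#' the scalp through the spherical forward model and added to every trial;
#' oscillatory sources run through the whole epoch with random phase per
#' trial and an envelope stepping by the specified dB inside their window
#' (raised-cosine ramps); background noise is pink noise from random
#' superficial sources mixed through the same forward model plus white
#' sensor noise, scaled to the target channel sd. A per-subject
#' log-normal factor scales all effect amplitudes.
#'
#' @param spec an [effect_preset()] specification
#' @param montage the montage to project onto
#' @param subject subject index (1-based)
#' @param seed master dataset seed
#' @param cells character vector of `"condition.TYPE"` cell names
#'   (default: all six)
#' @param inject_artifacts add the spec's artifact epochs (default TRUE)
#' @return named list per cell of trials x channels x samples arrays
#'   (uV) with attributes `condition`, `trial_type`, `subject`, `fs`,
#'   `t0`, and `artifact_epochs` (indices of injected artifacts)
#' @export
generate_subject_epochs <- function(spec, montage, subject, seed,
                                    cells = NULL,
                                    inject_artifacts = TRUE) {
  stopifnot(inherits(spec, "effect_spec"))
  if (is.null(cells)) cells <- names(spec$cells)
  set.seed(derive_seed(seed, paste0("subject", subject)))
  n <- spec$n_samples
  fs <- spec$fs
  tms <- (seq_len(n) - spec$t0) * 1000 / fs
  # subject-level amplitude factor and noise mixing
  amp_factor <- stats::rlnorm(1, 0, spec$subject_sd)
  ns <- spec$noise$n_sources
  ctr <- montage$sphere$center
  # random superficial noise sources, 50-70 mm from the sphere center
  dirs <- matrix(stats::rnorm(3 * ns), ns, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rad <- stats::runif(ns, 0.050, 0.070)
  gmix <- vapply(seq_len(ns), function(k) {
    dipole_potential(ctr + dirs[k, ] * rad[k], stats::rnorm(3, 0, 5),
                     montage)
  }, numeric(length(montage$labels)))
  # scale so projected + sensor noise hits the target channel sd
  sensor_sd <- min(spec$noise$sensor_sd_uV, spec$noise$sd_uV)
  ch_var <- rowSums(gmix^2)
  target <- max(0, spec$noise$sd_uV^2 - sensor_sd^2)
  gmix <- gmix * sqrt(target / mean(ch_var))
  out <- list()
  for (cl in cells) {
    parts <- strsplit(cl, ".", fixed = TRUE)[[1]]
    cond <- parts[1]; ty <- parts[2]
    ntr <- spec$epochs_per_cell[cond, ty]
    eff <- spec$cells[[cl]]
    # deterministic scalp template of the transient components
    erp_tmpl <- matrix(0, length(montage$labels), n)
    for (cp in eff$erp) {
      topo <- dipole_potential(cp$source / 1000, .component_moment(
        cp, montage$sphere, cp$amp_nAm * amp_factor), montage)
      erp_tmpl <- erp_tmpl +
        outer(topo, exp(-(tms - cp$latency_ms)^2 / (2 * cp$width_ms^2)))
    }
    osc <- lapply(eff$osc, function(cp) {
      topo <- dipole_potential(cp$source / 1000, .component_moment(
        cp, montage$sphere, cp$base_nAm), montage)
      gain <- 10^(cp$change_db * amp_factor / 20)
      list(topo = topo, freq = cp$freq_hz,
           env = .window_env(tms, cp$window_ms, gain))
    })
    ep <- array(0, c(ntr, length(montage$labels), n))
    for (tr in seq_len(ntr)) {
      x <- erp_tmpl
      if (spec$noise$sd_uV > 0) {
        src <- pink_noise(n, ns, fs, spec$noise$exponent, spec$noise$band)
        x <- x + gmix %*% t(src) +
          matrix(stats::rnorm(length(montage$labels) * n, 0, sensor_sd),
                 length(montage$labels), n)
      }
      for (oc in osc) {
        ph <- stats::runif(1, 0, 2 * pi)
        wave <- sin(2 * pi * oc$freq * tms / 1000 + ph) * oc$env
        x <- x + outer(oc$topo, wave)
      }
      ep[tr, , ] <- x
    }
    attr(ep, "condition") <- cond
    attr(ep, "trial_type") <- ty
    attr(ep, "subject") <- subject
    attr(ep, "fs") <- fs
    attr(ep, "t0") <- spec$t0
    attr(ep, "artifact_epochs") <- integer(0)
    if (inject_artifacts && spec$artifact_rate > 0) {
      ep <- inject_artifacts(ep, spec$artifact_rate,
                             derive_seed(seed, paste0("art", subject, cl)))
    }
    out[[cl]] <- ep
  }
  out
}

# moment of `amp` nAm along the component's orientation (radial default)
.component_moment <- function(cp, sphere, amp) {
  if (!is.null(cp$orient)) {
    return(cp$orient / sqrt(sum(cp$orient^2)) * amp)
  }
  .radial_moment(cp$source / 1000, sphere, amp)
}

# unit radial direction at a source, scaled to `amp` nAm
.radial_moment <- function(pos_m, sphere, amp) {
  r <- pos_m - sphere$center
  nr <- sqrt(sum(r^2))
  if (nr < 1e-9) return(c(0, 0, amp))
  r / nr * amp
}

# envelope 1 outside the window, `gain` inside, 100 ms raised-cosine ramps
.window_env <- function(tms, window, gain, ramp = 100) {
  e <- rep(1, length(tms))
  rise <- tms >= window[1] - ramp & tms < window[1]
  fall <- tms > window[2] & tms <= window[2] + ramp
  inside <- tms >= window[1] & tms <= window[2]
  e[inside] <- gain
  e[rise] <- 1 + (gain - 1) * (1 - cos(pi * (tms[rise] - window[1] + ramp) / ramp)) / 2
  e[fall] <- 1 + (gain - 1) * (1 + cos(pi * (tms[fall] - window[2]) / ramp)) / 2
  e
}

#' Inject large-amplitude artifact epochs
#'
#' Adds a 200 ms half-sine excursion of 180 uV on one random channel of
#' `round(rate * n)` randomly chosen epochs, guaranteeing they exceed the
#' +/- 100 uV rejection criterion; affected epochs are recorded in the
#' `artifact_epochs` attribute so downstream rejection can be verified.
#'
#' @param epochs trials x channels x samples array
#' @param rate fraction of epochs to corrupt, in [0, 1]
#' @param seed integer seed
#' @return the array with artifacts added and `artifact_epochs` attribute
#' @export
inject_artifacts <- function(epochs, rate, seed) {
  stopifnot(rate >= 0, rate <= 1, length(dim(epochs)) == 3)
  n <- dim(epochs)[1]
  k <- round(rate * n)
  at <- attributes(epochs)
  if (k == 0) {
    attr(epochs, "artifact_epochs") <- integer(0)
    return(epochs)
  }
  set.seed(as.integer(seed))
  idx <- sort(sample.int(n, k))
  ns <- dim(epochs)[3]
  len <- min(200, ns)
  burst <- 180 * sin(pi * seq_len(len) / len)
  for (i in idx) {
    ch <- sample.int(dim(epochs)[2], 1)
    start <- sample.int(ns - len + 1, 1)
    epochs[i, ch, start:(start + len - 1)] <-
      epochs[i, ch, start:(start + len - 1)] + burst
  }
  for (nm in setdiff(names(at), c("dim"))) attr(epochs, nm) <- at[[nm]]
  attr(epochs, "artifact_epochs") <- idx
  epochs
}

#' Generate a complete multi-subject dataset
#'
#' Convenience wrapper over [generate_subject_epochs()]; intended for
#' reduced configurations (few subjects or cells) - a full 22-subject
#' six-cell dataset is better processed subject by subject.
#'
#' @inheritParams generate_subject_epochs
#' @param subjects subject indices (default all in the spec)
#' @return list (one element per subject) of per-cell epoch lists
#' @export
generate_dataset <- function(spec, montage, seed, cells = NULL,
                             subjects = seq_len(spec$n_subjects),
                             inject_artifacts = TRUE) {
  lapply(subjects, function(s) {
    generate_subject_epochs(spec, montage, s, seed, cells,
                            inject_artifacts = inject_artifacts)
  })
}
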