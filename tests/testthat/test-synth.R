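noiseless_spec <- function(n_epochs = 4) {
  spec <- effect_preset(n_subjects = 1, noise_sd = 0, artifact_rate = 0,
                        subject_sd = 0, epochs_per_cell = matrix(
                          n_epochs, 2, 3,
                          dimnames = list(c("identical", "semantical"),
                                          c("SAME", "SIMI", "DIFF"))))
  spec
}

test_that("with zero noise the trial average equals the injected template", {
  spec <- noiseless_spec()
  # a single transient component, no oscillations
  spec$cells$identical.SIMI <- list(
    erp = list(list(source = c(0, 55, 25), latency_ms = 250,
                    width_ms = 35, amp_nAm = 30, orient = NULL)),
    osc = list())
  eps <- generate_subject_epochs(spec, test_montage, 1, seed = 2,
                                 cells = "identical.SIMI")[[1]]
  avg <- average_erp(eps)$erp
  tms <- (1:1400 - 701)
  topo <- dipole_potential(c(0, 55, 25) / 1000,
                           c(0, 55, -15) / sqrt(55^2 + 15^2) * 30,
                           test_montage)
  tmpl <- outer(topo, exp(-(tms - 250)^2 / (2 * 35^2)))
  expect_lt(max(abs(avg - tmpl)), 1e-9)
  peak_ch <- which.max(abs(topo))
  expect_equal(avg[peak_ch, ], tmpl[peak_ch, ], tolerance = 1e-12)
})

test_that("an injected 5 Hz burst maximizes oracle power at 5 Hz in-window", {
  spec <- noiseless_spec(6)
  spec$cells$identical.SIMI <- list(
    erp = list(),
    osc = list(list(source = c(0, 40, 0), freq_hz = 5,
                    window_ms = c(150, 450), change_db = 6,
                    base_nAm = 60, orient = c(0, 0.2, 1))))
  eps <- generate_subject_epochs(spec, test_montage, 1, seed = 3,
                                 cells = "identical.SIMI")[[1]]
  ch <- which.max(apply(abs(eps[1, , ]), 1, max))
  # oracle windowed DFT, trial-averaged raw power
  pow <- function(center, freq) {
    mean(sapply(seq_len(dim(eps)[1]), function(tr)
      direct_window_power(eps[tr, ch, ], center, freq)))
  }
  inside <- pow(300, 5)
  expect_gt(inside, pow(-300, 5) * 2)        # in-window increase
  for (f in c(3, 8, 12)) expect_gt(inside, pow(300, f))
})

test_that("generation is bit-identical under the same seed", {
  spec <- effect_preset(n_subjects = 2, epochs_per_cell = matrix(
    5, 2, 3, dimnames = list(c("identical", "semantical"),
                             c("SAME", "SIMI", "DIFF"))))
  a <- generate_subject_epochs(spec, test_montage, 1, seed = 7,
                               cells = c("identical.SIMI", "semantical.SIMI"))
  b <- generate_subject_epochs(spec, test_montage, 1, seed = 7,
                               cells = c("identical.SIMI", "semantical.SIMI"))
  expect_identical(a, b)
  c2 <- generate_subject_epochs(spec, test_montage, 2, seed = 7,
                                cells = "identical.SIMI")
  expect_false(identical(a[[1]], c2[[1]]))
})

test_that("cell-mean error shrinks as one over sqrt of the epoch count", {
  tmpl_err <- sapply(c(6, 24, 96), function(n) {
    spec <- effect_preset(n_subjects = 1, subject_sd = 0,
                          artifact_rate = 0, noise_sd = 6,
                          epochs_per_cell = matrix(
                            n, 2, 3,
                            dimnames = list(c("identical", "semantical"),
                                            c("SAME", "SIMI", "DIFF"))))
    spec$cells$identical.SIMI$osc <- list()
    eps <- generate_subject_epochs(spec, test_montage, 1, seed = 11,
                                   cells = "identical.SIMI")[[1]]
    avg <- average_erp(eps)$erp
    tms <- (1:1400 - 701)
    tmpl <- 0 * avg
    for (cp in spec$cells$identical.SIMI$erp) {
      topo <- dipole_potential(cp$source / 1000,
                               orfieeg:::.component_moment(
                                 cp, test_montage$sphere, cp$amp_nAm),
                               test_montage)
      tmpl <- tmpl + outer(topo, exp(-(tms - cp$latency_ms)^2 /
                                       (2 * cp$width_ms^2)))
    }
    sqrt(mean((avg - tmpl)^2))
  })
  expect_lt(tmpl_err[2] / tmpl_err[1], 0.7)
  expect_lt(tmpl_err[3] / tmpl_err[2], 0.7)
})

test_that("artifact injection corrupts exactly the requested fraction", {
  set.seed(21)
  ep <- array(rnorm(50 * 8 * 300, 0, 5), c(50, 8, 300))
  out <- inject_artifacts(ep, 0.1, seed = 5)
  flagged <- attr(out, "artifact_epochs")
  expect_length(flagged, 5)
  for (i in flagged) expect_gt(max(abs(out[i, , ])), 100)
  clean <- setdiff(1:50, flagged)
  expect_equal(out[clean, , ], ep[clean, , ], tolerance = 1e-14)
})

test_that("the epoch metadata records the simulated cell", {
  spec <- noiseless_spec(2)
  eps <- generate_subject_epochs(spec, test_montage, 3, seed = 1,
                                 cells = "semantical.DIFF")[[1]]
  expect_equal(attr(eps, "condition"), "semantical")
  expect_equal(attr(eps, "trial_type"), "DIFF")
  expect_equal(attr(eps, "subject"), 3)
  expect_equal(attr(eps, "fs"), 1000)
  expect_equal(dim(eps), c(2L, 156L, 1400L))
})
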