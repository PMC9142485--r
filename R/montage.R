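#' High-density EEG montage on a spherical head model
#'
#' Constructs the 156-channel template montage used throughout the package.
#' Labels follow the extended 10/20 ("10/05") naming scheme: longitudinal
#' rows from Fp (prefrontal) to I (inion) and lateral columns at 9-degree
#' steps along coronal great circles through the preauricular axis, with
#' `h`-suffixed labels at half (9, 27, ...) positions and `z` on the
#' midline. Positions are generated analytically on the model sphere
#' (radius 90 mm, center at MNI (0, 0, 40) mm) rather than digitized, and
#' are expressed in meters in a head frame identical to the MNI frame.
#'
#' @param sphere list with `center` (3-vector, meters) and `radius`
#'   (meters); defaults to [head_sphere()].
#' @return An object of class `eeg_montage`: list with `labels` (character,
#'   length 156), `pos` (156 x 3 matrix, meters), `sphere`, and
#'   `cluster_sets`, the three named 5-electrode regional clusters (frontal,
#'   central, posterior) used in the focused waveform and time-frequency
#'   analyses.
#' @export
build_montage <- function(sphere = head_sphere()) {
  rows <- list(
    Fp  = list(ap =  72, cols = c("z", "1", "2")),
    AFp = list(ap =  63, cols = c("z", "1", "2")),
    AF  = list(ap =  54, cols = c("z", paste0(1:8))),
    AFF = list(ap =  45, cols = c("z", paste0(1:8, "h"))),
    F   = list(ap =  36, cols = c("z", paste0(1:10))),
    FFC = list(ap =  27, cols = c("z", paste0(1:10, "h"))),
    FC  = list(ap =  18, cols = c("z", paste0(1:10))),
    FCC = list(ap =   9, cols = c("z", paste0(1:10, "h"))),
    C   = list(ap =   0, cols = c("z", paste0(1:10))),
    CCP = list(ap =  -9, cols = c("z", paste0(1:10, "h"))),
    CP  = list(ap = -18, cols = c("z", paste0(1:10))),
    CPP = list(ap = -27, cols = c("z", paste0(1:10, "h"))),
    P   = list(ap = -36, cols = c("z", paste0(1:10))),
    PPO = list(ap = -45, cols = c("z", paste0(1:10, "h"))),
    PO  = list(ap = -54, cols = c("z", paste0(1:10))),
    POO = list(ap = -63, cols = c("z", paste0(1:4))),
    O   = list(ap = -72, cols = c("z", "1", "2")),
    I   = list(ap = -81, cols = c("z", "1", "2"))
  )
  labels <- character(0)
  ap <- lat <- numeric(0)
  for (row in names(rows)) {
    for (col in rows[[row]]$cols) {
      labels <- c(labels, .montage_label(row, col))
      ap <- c(ap, rows[[row]]$ap)
      lat <- c(lat, .column_angle(col))
    }
  }
  stopifnot(!anyDuplicated(labels), length(labels) == 156L)
  a <- ap * pi / 180
  b <- lat * pi / 180
  # coronal great circle through the preauricular axis and the row's
  # midline point; beta measured from the midline toward the right ear
  m <- cbind(0, sin(a), cos(a))
  pos <- sphere$radius * (cos(b) * m + cbind(sin(b), 0, 0))
  pos <- sweep(pos, 2, sphere$center, "+")
  rownames(pos) <- labels
  structure(list(
    labels = labels, pos = pos, sphere = sphere,
    cluster_sets = list(
      frontal   = c("AFp1", "AFp2", "AFz", "AFF1h", "AFF2h"),
      central   = c("Cz", "CCP1h", "CCP2h", "FCC1h", "FCC2h"),
      posterior = c("POz", "PPO1h", "PPO2h", "POO1", "POO2")
    )
  ), class = "eeg_montage")
}

#' Model sphere geometry
#'
#' Single homogeneous conducting sphere standing in for the head: radius
#' 90 mm, center 40 mm above the MNI origin, brain conductivity 0.33 S/m.
#' @param radius sphere radius in meters
#' @param center sphere center, meters, MNI-aligned RAS frame
#' @param sigma conductivity, S/m
#' @return list with `radius`, `center`, `sigma`
#' @export
head_sphere <- function(radius = 0.090, center = c(0, 0, 0.040),
                        sigma = 0.33) {
  list(radius = radius, center = center, sigma = sigma)
}

# row prefix + column suffix -> 10/05-style label; the C/FC/CP rows take
# T/FT/TP names at 72 degrees and beyond, as on physical caps
.montage_label <- function(row, col) {
  if (col == "z") return(paste0(row, "z"))
  n <- as.integer(sub("h$", "", col))
  temporal <- n >= 7 && row %in% c("FC", "C", "CP")
  if (temporal) {
    row <- c(FC = "FT", C = "T", CP = "TP")[[row]]
  }
  paste0(row, col)
}

# lateral angle in degrees for a column suffix; odd = left (negative x),
# even = right; "h" columns sit 9 degrees inboard of the full column
.column_angle <- function(col) {
  if (col == "z") return(0)
  half <- grepl("h$", col)
  n <- as.integer(sub("h$", "", col))
  k <- if (n %% 2L == 1L) (n + 1L) %/% 2L else n %/% 2L
  ang <- 18 * k - if (half) 9 else 0
  if (n %% 2L == 1L) -ang else ang
}

#' Mirror a channel label across the sagittal midline
#'
#' Swaps the odd (left) and even (right) column suffixes; midline `z`
#' labels map to themselves. Used to exercise the left/right symmetry of
#' the spherical forward model.
#' @param labels character vector of montage labels
#' @return character vector of mirrored labels
#' @export
mirror_labels <- function(labels) {
  vapply(labels, function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)([0-9]+)(h?)$", lab))[[1]]
    if (length(m) == 0) return(lab)  # z labels
    n <- as.integer(m[3])
    n2 <- if (n %% 2L == 1L) n + 1L else n - 1L
    paste0(m[2], n2, m[4])
  }, character(1), USE.NAMES = FALSE)
}

#' Electrode adjacency graph
#'
#' Contiguity structure for the spatial-extent criterion of the
#' mass-univariate analysis: Delaunay triangulation of the electrode
#' positions in an azimuthal-equidistant projection about the vertex, with
#' edges longer than `max_dist` (3-D chord) pruned.
#'
#' @param montage an `eeg_montage`
#' @param max_dist maximum neighbor distance in meters (default 0.05)
#' @return symmetric logical adjacency matrix (156 x 156), `FALSE` diagonal
#' @export
electrode_adjacency <- function(montage, max_dist = 0.05) {
  u <- sweep(montage$pos, 2, montage$sphere$center, "-") /
    montage$sphere$radius
  rho <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1])
  xy <- cbind(rho * cos(phi), rho * sin(phi))
  # break the exact collinearities of the symmetric cap (they can stall
  # the triangulation); the perturbation is far below electrode spacing
  i <- seq_len(nrow(xy))
  xy <- xy + 1e-7 * cbind(sin(37 * i), cos(53 * i))
  tri <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  adj <- matrix(FALSE, nrow(xy), nrow(xy),
                dimnames = list(montage$labels, montage$labels))
  for (k in seq_len(nrow(tri$delsgs))) {
    i <- tri$delsgs$ind1[k]; j <- tri$delsgs$ind2[k]
    if (sqrt(sum((montage$pos[i, ] - montage$pos[j, ])^2)) <= max_dist) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  adj
}

#' Read or write electrode positions as SFP
#'
#' Plain-text SFP exchange format: one `label x y z` line per electrode,
#' coordinates in millimeters.
#' @param montage an `eeg_montage`
#' @param path file path
#' @return `read_sfp` returns a data.frame with columns label, x, y, z (mm).
#' @export
write_sfp <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   round(montage$pos * 1000, 4))
  utils::write.table(df, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sfp
#' @export
read_sfp <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("label", "x", "y", "z"))
  df
}
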