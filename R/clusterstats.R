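#' Spatiotemporal extent thresholding of a significance map
#'
#' Retains supra-threshold points (p < `alpha`) only where the effect is
#' sustained for at least `min_ms` contiguous timeframes and, at every
#' retained timeframe, spans at least `min_electrodes` contiguous
#' electrodes of the adjacency graph. The two prunings are iterated to a
#' fixed point so every retained point satisfies both criteria jointly;
#' both prunings are monotone in the input mask, so relaxing any threshold
#' can only grow the result.
#'
#' @param p matrix electrodes x timeframes of p values (or a `stat_map`)
#' @param alpha significance threshold (default 0.01)
#' @param min_ms minimum duration in ms (default 20)
#' @param min_electrodes minimum contiguous electrodes (default 5)
#' @param adjacency logical electrode adjacency matrix,
#'   see [electrode_adjacency()]
#' @param dt_ms timeframe step in ms (default 1)
#' @return logical matrix electrodes x timeframes (class
#'   `significance_mask`, with the provenance thresholds as attributes)
#' @export
extent_filter <- function(p, alpha = 0.01, min_ms = 20, min_electrodes = 5,
                          adjacency, dt_ms = 1) {
  if (inherits(p, "stat_map")) p <- matrix(p$p, p$dim[1], p$dim[2])
  stopifnot(is.matrix(p), nrow(p) == nrow(adjacency))
  deg <- rowSums(adjacency)
  if (mean(deg == 0) > 0.2) {
    warning("more than 20% of electrodes are disconnected in the adjacency")
  }
  min_frames <- ceiling(min_ms / dt_ms)
  mask <- !is.na(p) & p < alpha
  nb <- apply(adjacency, 1, which, simplify = FALSE)
  repeat {
    prev <- mask
    # spatial: per timeframe keep connected components >= min_electrodes
    for (t in which(colSums(mask) > 0)) {
      on <- which(mask[, t])
      if (length(on) < min_electrodes) { mask[, t] <- FALSE; next }
      comp <- .components_graph(on, nb)
      small <- on[comp %in% which(tabulate(comp) < min_electrodes)]
      mask[small, t] <- FALSE
    }
    # temporal: per electrode keep runs >= min_frames
    for (e in which(rowSums(mask) > 0)) {
      r <- rle(mask[e, ])
      r$values[r$values & r$lengths < min_frames] <- FALSE
      mask[e, ] <- inverse.rle(r)
    }
    if (identical(mask, prev)) break
  }
  structure(mask, class = c("significance_mask", class(mask)),
            alpha = alpha, min_ms = min_ms, min_electrodes = min_electrodes)
}

# connected components among node subset `on` given neighbor list `nb`;
# returns component id per element of `on`
.components_graph <- function(on, nb) {
  id <- integer(length(on))
  names(id) <- on
  comp <- 0L
  inset <- logical(length(nb))
  inset[on] <- TRUE
  pos <- stats::setNames(seq_along(on), on)
  for (i in seq_along(on)) {
    if (id[i] > 0L) next
    comp <- comp + 1L
    queue <- on[i]
    id[i] <- comp
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nb[[v]]) {
        if (inset[w]) {
          j <- pos[[as.character(w)]]
          if (id[j] == 0L) { id[j] <- comp; queue <- c(queue, w) }
        }
      }
    }
  }
  id
}

#' Regional electrode-cluster mean timecourse
#'
#' Averages the five member electrodes of a named regional cluster set
#' (frontal, central, posterior).
#' @param erp channels x samples matrix (montage channel order)
#' @param set_name one of `names(montage$cluster_sets)`
#' @param montage the montage defining the sets
#' @return numeric vector, one value per sample
#' @export
cluster_timecourse <- function(erp, set_name, montage) {
  if (!set_name %in% names(montage$cluster_sets)) {
    stop("unknown cluster set: ", set_name)
  }
  members <- montage$cluster_sets[[set_name]]
  idx <- match(members, montage$labels)
  if (anyNA(idx)) stop("cluster electrodes missing from montage")
  colMeans(erp[idx, , drop = FALSE])
}

#' Paired-t test with temporal cluster-permutation correction
#'
#' Two-sided paired t statistic at every timeframe; contiguous runs of
#' timeframes exceeding the cluster-forming threshold (p < `cluster_alpha`)
#' form observed clusters. The null distribution of the maximum cluster
#' size (in timeframes) is built by random within-subject sign flips of
#' the difference waves; an observed cluster is retained when its size
#' exceeds the 95th percentile of that distribution. Corrected p values
#' use the permutation rank with the observed statistic included,
#' p = (1 + #{max size >= observed}) / (n_perm + 1).
#'
#' @param a,b matrices subjects x timeframes (paired observations)
#' @param n_perm number of sign-flip permutations (>= 100)
#' @param cluster_alpha cluster-forming significance level (default 0.05)
#' @param seed integer seed for the permutation draw
#' @param times optional vector of times (ms) labelling the frames
#' @return `cluster_result`: list with `t` (observed statistic),
#'   `clusters` (data.frame: start, end, size, p_corrected, significant),
#'   `null_q95` (95th-percentile max null cluster size), `n_perm`.
#' @export
paired_t_cluster_perm <- function(a, b, n_perm = 5000, cluster_alpha = 0.05,
                                  seed = 1, times = NULL) {
  stopifnot(identical(dim(a), dim(b)), n_perm >= 100)
  d <- a - b
  S <- nrow(d)
  tcrit <- stats::qt(1 - cluster_alpha / 2, S - 1)
  tstat <- function(m) {
    mu <- colMeans(m)
    v <- (colSums(m^2) - S * mu^2) / (S - 1)
    ifelse(v > 0, mu / sqrt(v / S), 0)
  }
  t_obs <- tstat(d)
  obs_runs <- .runs(abs(t_obs) > tcrit)
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
  mu_p <- signs %*% d / S                      # n_perm x T
  ss <- colSums(d^2)                           # invariant under sign flip
  v_p <- sweep(-S * mu_p^2, 2, ss, "+") / (S - 1)
  t_p <- mu_p / sqrt(v_p / S)
  t_p[!is.finite(t_p)] <- 0
  supra <- abs(t_p) > tcrit
  max_sz <- vapply(seq_len(n_perm), function(i) {
    r <- rle(supra[i, ])
    m <- r$lengths[r$values]
    if (length(m)) max(m) else 0L
  }, integer(1))
  q95 <- sort(max_sz)[ceiling(0.95 * n_perm)]
  clusters <- if (nrow(obs_runs)) {
    data.frame(
      start = if (is.null(times)) obs_runs$start else times[obs_runs$start],
      end = if (is.null(times)) obs_runs$end else times[obs_runs$end],
      size = obs_runs$end - obs_runs$start + 1L,
      p_corrected = vapply(obs_runs$end - obs_runs$start + 1L, function(sz) {
        (1 + sum(max_sz >= sz)) / (n_perm + 1)
      }, numeric(1))
    )
  } else {
    data.frame(start = numeric(0), end = numeric(0), size = integer(0),
               p_corrected = numeric(0))
  }
  # retention by the exact permutation rank (observed statistic included
  # in the null, as in the corrected p): at n_perm = 5000 this coincides
  # with "size greater than the null 95th percentile" up to rounding,
  # and it guarantees family-wise error <= 5% at any n_perm
  clusters$significant <- clusters$p_corrected <= 0.05
  structure(list(t = t_obs, clusters = clusters, null_q95 = q95,
                 n_perm = n_perm, cluster_alpha = cluster_alpha),
            class = "cluster_result")
}

.runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Generic sign-flip cluster permutation test on an arbitrary feature graph
#'
#' Engine shared by the 2-D time-frequency and 3-D source-space cluster
#' corrections: paired (or one-sample) t per feature, clusters as
#' connected components of supra-threshold features on the supplied
#' neighbor table, max-cluster-size null by sign flipping.
#'
#' @param d matrix subjects x features of paired differences (or values
#'   for a one-sample test against zero)
#' @param neighbors integer matrix features x K (NA-padded) of neighbor
#'   indices
#' @param n_perm permutations (>= 100)
#' @param cluster_alpha cluster-forming alpha (two-sided)
#' @param seed integer seed
#' @return list with `t`, `labels` (observed cluster id per feature, 0 =
#'   none), `clusters` (data.frame: id, size, p_corrected, significant),
#'   `null_q95`, `n_perm`
#' @export
cluster_perm_graph <- function(d, neighbors, n_perm = 1000,
                               cluster_alpha = 0.05, seed = 1) {
  stopifnot(n_perm >= 100)
  S <- nrow(d); P <- ncol(d)
  tcrit <- stats::qt(1 - cluster_alpha / 2, S - 1)
  tstat <- function(mu, ss) {
    v <- (ss - S * mu^2) / (S - 1)
    tt <- ifelse(v > 0, mu / sqrt(v / S), 0)
    tt
  }
  ss <- colSums(d^2)
  t_obs <- tstat(colMeans(d), ss)
  lab_obs <- .label_components(abs(t_obs) > tcrit, neighbors)
  sizes <- if (any(lab_obs > 0)) tabulate(lab_obs) else integer(0)
  set.seed(as.integer(seed))
  signs <- matrix(sample(c(-1, 1), n_perm * S, replace = TRUE), n_perm, S)
  mu_p <- signs %*% d / S
  max_sz <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    tp <- tstat(mu_p[i, ], ss)
    li <- .label_components(abs(tp) > tcrit, neighbors)
    max_sz[i] <- if (any(li > 0)) max(tabulate(li)) else 0
  }
  q95 <- sort(max_sz)[ceiling(0.95 * n_perm)]
  clusters <- if (length(sizes)) {
    data.frame(id = seq_along(sizes), size = sizes,
               p_corrected = vapply(sizes, function(sz) {
                 (1 + sum(max_sz >= sz)) / (n_perm + 1)
               }, numeric(1)))
  } else {
    data.frame(id = integer(0), size = integer(0), p_corrected = numeric(0))
  }
  clusters$significant <- clusters$p_corrected <= 0.05
  list(t = t_obs, labels = lab_obs, clusters = clusters, null_q95 = q95,
       n_perm = n_perm)
}

# connected-component labels on a NA-padded neighbor index table, by
# iterative max-label propagation restricted to the supra-threshold set
.label_components <- function(supra, neighbors) {
  P <- length(supra)
  lab <- ifelse(supra, seq_len(P), 0L)
  if (!any(supra)) return(lab)
  K <- ncol(neighbors)
  repeat {
    new <- lab
    for (k in seq_len(K)) {
      nk <- neighbors[, k]
      ok <- supra & !is.na(nk)
      cand <- rep(0L, P)
      cand[ok] <- lab[nk[ok]]
      new <- pmax(new, cand)
    }
    if (identical(new, lab)) break
    lab <- new
  }
  # renumber to consecutive ids
  u <- sort(unique(lab[lab > 0]))
  match(lab, u, nomatch = 1L) * (lab > 0)
}
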