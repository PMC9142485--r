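#' Mass-univariate 2 x 3 repeated-measures ANOVA
#'
#' Vectorized within-subject ANOVA with factors condition (2 levels) and
#' trial type (3 levels), computed independently at every feature
#' (electrode x timeframe). Each effect is tested against its own
#' subject-by-effect interaction error term. Sphericity of the 3-level
#' and interaction effects is assessed per feature with Mauchly's test;
#' where it is violated at the 0.05 level the Greenhouse-Geisser
#' epsilon-corrected degrees of freedom are used for the p value (the
#' epsilon estimate itself is always reported).
#'
#' @param x numeric array, subjects x 2 x 3 x features (features may be a
#'   trailing vector of any length, e.g. flattened electrodes x time), or
#'   subjects x 2 x 3 x electrodes x time.
#' @param gg_gate apply GG correction only when Mauchly p < 0.05 (the
#'   reporting convention of the study); set `FALSE` to always correct.
#' @return list of three `stat_map` objects (`interaction`,
#'   `main_condition`, `main_trial`), each a list with `F`, `p`,
#'   `epsilon`, `mauchly_p`, `df` (uncorrected numerator/denominator),
#'   `eta_sq` (partial eta squared), and `dim` (feature dimensions).
#' @export
pointwise_rm_anova <- function(x, gg_gate = TRUE) {
  d <- dim(x)
  stopifnot(length(d) >= 4, d[2] == 2L, d[3] == 3L)
  S <- d[1]
  if (S < 3) stop("need at least 3 subjects")
  fdim <- d[-(1:3)]
  P <- prod(fdim)
  dim(x) <- c(S, 2L, 3L, P)
  if (anyNA(x)) stop("missing cell values")
  # all quantities held as S x P (or P) matrices; cells indexed [a][b]
  cell <- function(a, b) {
    m <- x[, a, b, , drop = FALSE]
    dim(m) <- c(S, P)
    m
  }
  cells <- lapply(1:2, function(a) lapply(1:3, function(b) cell(a, b)))
  m_sa <- lapply(1:2, function(a) (cells[[a]][[1]] + cells[[a]][[2]] +
                                     cells[[a]][[3]]) / 3)
  m_sb <- lapply(1:3, function(b) (cells[[1]][[b]] + cells[[2]][[b]]) / 2)
  m_s <- (m_sa[[1]] + m_sa[[2]]) / 2
  m_ab <- lapply(cells, function(row) lapply(row, colMeans))  # [a][b] -> P
  m_a <- lapply(m_sa, colMeans)
  m_b <- lapply(m_sb, colMeans)
  M <- (m_a[[1]] + m_a[[2]]) / 2
  ss_a <- 3 * S * ((m_a[[1]] - M)^2 + (m_a[[2]] - M)^2)
  ss_b <- 2 * S * Reduce(`+`, lapply(m_b, function(v) (v - M)^2))
  ss_ab <- ss_as <- ss_bs <- ss_abs <- 0
  for (a in 1:2) {
    ss_as <- ss_as + 3 * colSums(sweep(m_sa[[a]] - m_s, 2, m_a[[a]] - M, "-")^2)
    for (b in 1:3) {
      dev <- m_ab[[a]][[b]] - m_a[[a]] - m_b[[b]] + M
      ss_ab <- ss_ab + S * dev^2
      resid <- sweep(cells[[a]][[b]] - m_sa[[a]] - m_sb[[b]] + m_s, 2, dev, "-")
      ss_abs <- ss_abs + colSums(resid^2)
    }
  }
  for (b in 1:3) {
    ss_bs <- ss_bs + 2 * colSums(sweep(m_sb[[b]] - m_s, 2, m_b[[b]] - M, "-")^2)
  }
  f_a <- (ss_a / 1) / (ss_as / (S - 1))
  f_b <- (ss_b / 2) / (ss_bs / (2 * (S - 1)))
  f_ab <- (ss_ab / 2) / (ss_abs / (2 * (S - 1)))
  # GG epsilon from orthonormal within-subject contrasts (d = 2)
  Hb <- cbind(c(1, -1, 0) / sqrt(2), c(1, 1, -2) / sqrt(6))
  yb1 <- m_sb[[1]] * Hb[1, 1] + m_sb[[2]] * Hb[2, 1] + m_sb[[3]] * Hb[3, 1]
  yb2 <- m_sb[[1]] * Hb[1, 2] + m_sb[[2]] * Hb[2, 2] + m_sb[[3]] * Hb[3, 2]
  cA <- c(1, -1) / sqrt(2)
  yab1 <- yab2 <- matrix(0, S, P)
  for (a in 1:2) {
    w <- cA[a]
    yab1 <- yab1 + w * (cells[[a]][[1]] * Hb[1, 1] +
                          cells[[a]][[2]] * Hb[2, 1] +
                          cells[[a]][[3]] * Hb[3, 1])
    yab2 <- yab2 + w * (cells[[a]][[1]] * Hb[1, 2] +
                          cells[[a]][[2]] * Hb[2, 2] +
                          cells[[a]][[3]] * Hb[3, 2])
  }
  eps_mauchly <- function(y1, y2) {
    c11 <- .colvar(y1); c22 <- .colvar(y2)
    c12 <- .colcov(y1, y2)
    tr <- c11 + c22
    tr2 <- c11^2 + 2 * c12^2 + c22^2
    eps <- ifelse(tr2 > 0, tr^2 / (2 * tr2), 1)
    detc <- pmax(c11 * c22 - c12^2, 0)
    W <- ifelse(tr > 0, detc / (tr / 2)^2, 1)
    dd <- 2
    rho <- 1 - (2 * dd^2 + dd + 2) / (6 * dd * (S - 1))
    chi <- -(S - 1) * rho * log(pmax(W, .Machine$double.xmin))
    mp <- stats::pchisq(chi, df = dd * (dd + 1) / 2 - 1, lower.tail = FALSE)
    list(eps = pmin(pmax(eps, 1 / dd), 1), mauchly_p = mp)
  }
  eb <- eps_mauchly(yb1, yb2)
  eab <- eps_mauchly(yab1, yab2)
  pval <- function(f, df1, df2, eps, mp) {
    use <- if (gg_gate) ifelse(mp < 0.05, eps, 1) else eps
    stats::pf(f, df1 * use, df2 * use, lower.tail = FALSE)
  }
  mk <- function(f, p, eps, mp, df1, df2, ss_e, ss_err, label) {
    structure(list(F = array(f, fdim), p = array(p, fdim),
                   epsilon = array(eps, fdim),
                   mauchly_p = array(mp, fdim),
                   df = c(df1, df2),
                   eta_sq = array(ss_e / (ss_e + ss_err), fdim),
                   effect = label, dim = fdim), class = "stat_map")
  }
  list(
    interaction = mk(f_ab, pval(f_ab, 2, 2 * (S - 1), eab$eps, eab$mauchly_p),
                     eab$eps, eab$mauchly_p, 2, 2 * (S - 1), ss_ab, ss_abs,
                     "interaction"),
    main_condition = mk(f_a, stats::pf(f_a, 1, S - 1, lower.tail = FALSE),
                        rep(1, P), rep(NA_real_, P), 1, S - 1, ss_a, ss_as,
                        "main_condition"),
    main_trial = mk(f_b, pval(f_b, 2, 2 * (S - 1), eb$eps, eb$mauchly_p),
                    eb$eps, eb$mauchly_p, 2, 2 * (S - 1), ss_b, ss_bs,
                    "main_trial")
  )
}

.colvar <- function(m) {
  n <- nrow(m)
  (colSums(m^2) - n * colMeans(m)^2) / (n - 1)
}

.colcov <- function(a, b) {
  n <- nrow(a)
  (colSums(a * b) - n * colMeans(a) * colMeans(b)) / (n - 1)
}

#' Repeated-measures ANOVA and effect sizes for behavioral cell means
#'
#' The behavioral analysis applied to per-subject condition x trial-type
#' cell means (RT or accuracy): Greenhouse-Geisser-gated omnibus tests,
#' Bonferroni-corrected paired post-hoc t tests between trial types within
#' each condition, partial eta squared for each omnibus effect, and
#' Cohen's d (mean difference over the average of the two cell standard
#' deviations) for each contrast.
#'
#' @param cells numeric array subjects x 2 x 3; `dimnames` for conditions
#'   and trial types are used in the output when present.
#' @return list with `omnibus` (data.frame: effect, F, df1, df2, epsilon,
#'   p, eta_sq) and `posthoc` (data.frame: condition, contrast, t, df,
#'   p_raw, p_bonferroni, cohens_d).
#' @export
rt_rm_anova <- function(cells) {
  d <- dim(cells)
  stopifnot(length(d) == 3, d[2] == 2L, d[3] == 3L)
  if (d[1] < 3) stop("need at least 3 subjects")
  res <- pointwise_rm_anova(array(cells, c(d, 1L)))
  omnibus <- do.call(rbind, lapply(res, function(sm) {
    data.frame(effect = sm$effect, F = sm$F[1], df1 = sm$df[1],
               df2 = sm$df[2], epsilon = sm$epsilon[1], p = sm$p[1],
               eta_sq = sm$eta_sq[1])
  }))
  conds <- dimnames(cells)[[2]]
  if (is.null(conds)) conds <- c("cond1", "cond2")
  trials <- dimnames(cells)[[3]]
  if (is.null(trials)) trials <- c("t1", "t2", "t3")
  pairs <- utils::combn(3, 2)
  ph <- list()
  ncomp <- ncol(pairs) * 2
  for (a in 1:2) for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    di <- cells[, a, i] - cells[, a, j]
    tt <- stats::t.test(di)
    dz <- mean(di) / ((stats::sd(cells[, a, i]) + stats::sd(cells[, a, j])) / 2)
    ph[[length(ph) + 1]] <- data.frame(
      condition = conds[a],
      contrast = paste(trials[i], "vs", trials[j]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_raw = tt$p.value,
      p_bonferroni = min(1, tt$p.value * ncomp),
      cohens_d = dz)
  }
  list(omnibus = omnibus, posthoc = do.call(rbind, ph))
}
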