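#' Cosinor fit of one time series
#'
#' Fits x(t) = b0 + b1*cos(b3 + 2*pi*t/period) by least squares. The
#' solution is obtained from the exact linear harmonic regression
#' x = b0 + a*cos(wt) + c*sin(wt) (the same model, reparameterized) and
#' polished by Gauss-Newton iterations on (b0, b1, b3). The amplitude
#' p-value is the F-test of the two harmonic degrees of freedom against
#' the intercept-only model; the phase confidence interval comes from the
#' delta method on (a, c).
#'
#' `phase_hours` is the peak time of the fitted curve, ((-b3) mod 2*pi) *
#' period / (2*pi); the raw b3 is retained. b1 is canonicalized to be
#' nonnegative (a negative amplitude is folded into b3 by adding pi).
#'
#' @param t sampling times in hours (at least 4 distinct values)
#' @param x observed values
#' @param period oscillation period in hours (default 24)
#' @return object of class `cosine_fit`: list with b0, b1, b3,
#'   phase_hours, amplitude_p, ci_phase (lo, hi hours), se_phase, rss,
#'   dof, fitted, ok (FALSE for degenerate input)
#' @export
fit_cosine <- function(t, x, period = 24) {
  keep <- is.finite(t) & is.finite(x)
  t <- t[keep]; x <- x[keep]
  n <- length(x)
  flagged <- function() structure(
    list(b0 = mean(x), b1 = 0, b3 = 0, phase_hours = NA_real_,
         amplitude_p = 1, ci_phase = c(NA_real_, NA_real_),
         se_phase = NA_real_, rss = sum((x - mean(x))^2), dof = max(n - 3, 0),
         fitted = rep(mean(x), n), ok = FALSE),
    class = "cosine_fit")
  if (length(unique(t)) < 4 || n < 4) return(flagged())
  if (max(x) - min(x) == 0) return(flagged())
  w <- 2 * pi / period
  X <- cbind(1, cos(w * t), sin(w * t))
  fit <- lm.fit(X, x)
  b0 <- fit$coefficients[1]; a <- fit$coefficients[2]; cc <- fit$coefficients[3]
  b1 <- sqrt(a^2 + cc^2)
  b3 <- atan2(-cc, a)
  # Gauss-Newton polish (same model; converges at once from the exact start)
  th <- c(b0, b1, b3)
  for (it in 1:50) {
    r <- x - (th[1] + th[2] * cos(th[3] + w * t))
    J <- cbind(1, cos(th[3] + w * t), -th[2] * sin(th[3] + w * t))
    step <- tryCatch(solve(crossprod(J), crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) break
    th_new <- th + as.numeric(step)
    r_new <- x - (th_new[1] + th_new[2] * cos(th_new[3] + w * t))
    if (sum(r_new^2) <= sum(r^2) + 1e-12) th <- th_new
    if (sum(abs(step)) < 1e-12) break
  }
  b0 <- th[1]; b1 <- th[2]; b3 <- th[3]
  if (b1 < 0) { b1 <- -b1; b3 <- b3 + pi }
  b3 <- wrap_pi(b3)
  fitted <- b0 + b1 * cos(b3 + w * t)
  rss <- sum((x - fitted)^2)
  dof <- n - 3
  rss0 <- sum((x - mean(x))^2)
  Fstat <- ((rss0 - rss) / 2) / (rss / dof)
  amplitude_p <- if (rss == 0) 0 else pf(Fstat, 2, dof, lower.tail = FALSE)
  phase_hours <- ((-b3) %% (2 * pi)) / w
  # delta method on (a, c): phase angle = atan2(c, a)
  se_phase <- NA_real_; ci <- c(NA_real_, NA_real_)
  s2 <- rss / dof
  V <- tryCatch(s2 * solve(crossprod(X))[2:3, 2:3], error = function(e) NULL)
  amp2 <- a^2 + cc^2
  if (!is.null(V) && amp2 > 0) {
    g <- c(-cc, a) / amp2
    v <- drop(t(g) %*% V %*% g)
    se_phase <- sqrt(max(v, 0)) * period / (2 * pi)
    hw <- qt(0.975, dof) * se_phase
    ci <- wrap24(c(phase_hours - hw, phase_hours + hw))
  }
  structure(list(b0 = unname(b0), b1 = unname(b1), b3 = unname(b3),
                 phase_hours = unname(phase_hours),
                 amplitude_p = unname(amplitude_p), ci_phase = ci,
                 se_phase = se_phase, rss = rss, dof = dof,
                 fitted = fitted, ok = TRUE),
            class = "cosine_fit")
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("cosine_fit: mean %.3g, amplitude %.3g, peak ZT%.2f, amplitude p %.3g\n",
              x$b0, x$b1, x$phase_hours, x$amplitude_p))
  invisible(x)
}

#' Cosinor fits for every row of a matrix
#'
#' @param mat numeric matrix, rows = peaks/genes, columns = time points
#' @param timepoints column times in hours
#' @param period hours (default 24)
#' @return data.table with one row per input row: b0, b1, b3,
#'   phase_hours, amplitude_p, ci_lo, ci_hi, rss
#' @export
fit_cosine_matrix <- function(mat, timepoints, period = 24) {
  stopifnot(ncol(mat) == length(timepoints))
  res <- lapply(seq_len(nrow(mat)), function(i) {
    f <- fit_cosine(timepoints, mat[i, ], period)
    data.table(b0 = f$b0, b1 = f$b1, b3 = f$b3, phase_hours = f$phase_hours,
               amplitude_p = f$amplitude_p, ci_lo = f$ci_phase[1],
               ci_hi = f$ci_phase[2], rss = f$rss)
  })
  out <- rbindlist(res)
  out[, id := rownames(mat) %||% as.character(.I)]
  setcolorder(out, "id")
  out[]
}

#' Joint cosinor fit for two genotypes with batch offsets
#'
#' Fits x(t) = (b0 + b0_gt*GT) + (b1 + b1_gt*GT) * cos((b3 + b3_gt*GT) +
#' w t) + b4*B1 + b5*B2, where GT is 0 for the reference genotype (WT)
#' and 1 for the other (KO), and B1, B2 dummy-code up to two non-reference
#' batches entering additively. The model is linear in per-genotype
#' harmonic coordinates, so the least-squares optimum is exact; collinear
#' batch columns are dropped with a warning.
#'
#' @param t_wt,x_wt,t_ko,x_ko times (hours) and values per genotype
#' @param batch optional factor/vector of batch labels, one per sample in
#'   c(x_wt, x_ko) order; up to 3 levels (2 dummy coefficients)
#' @param period hours (default 24)
#' @return list of class `genotype_cosine_fit`: b0, b1, b3, b0_gt, b1_gt,
#'   b3_gt, b4, b5, phase_wt, phase_ko, phase_shift (KO - WT, hours in
#'   (-12, 12]), amplitude_p_wt, amplitude_p_ko, rss, dof
#' @export
fit_cosine_genotype <- function(t_wt, x_wt, t_ko, x_ko, batch = NULL,
                                period = 24) {
  stopifnot(length(t_wt) == length(x_wt), length(t_ko) == length(x_ko))
  if (length(unique(t_wt)) < 4 || length(unique(t_ko)) < 4)
    stop("each genotype needs at least 4 distinct time points", call. = FALSE)
  w <- 2 * pi / period
  t <- c(t_wt, t_ko); x <- c(x_wt, x_ko)
  gt <- rep(c(0, 1), c(length(t_wt), length(t_ko)))
  # per-genotype harmonic coding: exact linear reparameterization
  Xg <- cbind(int = 1, gt = gt,
              c0 = (1 - gt) * cos(w * t), s0 = (1 - gt) * sin(w * t),
              c1 = gt * cos(w * t), s1 = gt * sin(w * t))
  B <- NULL; bnames <- character()
  if (!is.null(batch)) {
    batch <- factor(batch)
    if (nlevels(batch) > 3)
      stop("at most 3 batch levels (2 offset coefficients) supported", call. = FALSE)
    if (nlevels(batch) > 1) {
      B <- stats::model.matrix(~batch)[, -1, drop = FALSE]
      bnames <- paste0("b", 3 + seq_len(ncol(B)))
      colnames(B) <- bnames
    }
  }
  X <- cbind(Xg, B)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    dropped <- colnames(X)[drop_idx]
    if (!all(dropped %in% bnames))
      stop("rank-deficient design beyond batch terms", call. = FALSE)
    warning(sprintf("dropping collinear batch term(s): %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, -drop_idx, drop = FALSE]
    bnames <- setdiff(bnames, dropped)
  }
  fit <- lm.fit(X, x)
  cf <- fit$coefficients
  harm <- function(a, cc) {
    a <- unname(a); cc <- unname(cc)
    b1 <- sqrt(a^2 + cc^2)
    b3 <- if (b1 > 0) atan2(-cc, a) else 0
    c(b1, b3)
  }
  h0 <- harm(cf["c0"], cf["s0"]); h1 <- harm(cf["c1"], cf["s1"])
  phase_wt <- ((-h0[2]) %% (2 * pi)) / w
  phase_ko <- ((-h1[2]) %% (2 * pi)) / w
  rss <- sum(fit$residuals^2)
  dof <- length(x) - ncol(X)
  amp_p <- function(cols) {
    Xr <- X[, setdiff(colnames(X), cols), drop = FALSE]
    rss_r <- sum(lm.fit(Xr, x)$residuals^2)
    if (rss == 0) return(0)
    Fs <- ((rss_r - rss) / 2) / (rss / dof)
    pf(Fs, 2, dof, lower.tail = FALSE)
  }
  b4 <- unname(cf[bnames[1]] %||% NA_real_)
  b5 <- unname(cf[bnames[2]] %||% NA_real_)
  if (length(bnames) < 1) b4 <- NA_real_
  if (length(bnames) < 2) b5 <- NA_real_
  structure(list(
    b0 = unname(cf["int"]), b0_gt = unname(cf["gt"]),
    b1 = h0[1], b3 = h0[2],
    b1_gt = h1[1] - h0[1], b3_gt = wrap_pi(h1[2] - h0[2]),
    b4 = b4, b5 = b5,
    phase_wt = phase_wt, phase_ko = phase_ko,
    phase_shift = wrap24(phase_ko - phase_wt, centered = TRUE),
    amplitude_p_wt = amp_p(c("c0", "s0")),
    amplitude_p_ko = amp_p(c("c1", "s1")),
    rss = rss, dof = dof), class = "genotype_cosine_fit")
}

#' @export
print.genotype_cosine_fit <- function(x, ...) {
  cat(sprintf("genotype cosinor: WT peak ZT%.2f (amp %.3g), KO peak ZT%.2f (amp %.3g), shift %+.2f h\n",
              x$phase_wt, x$b1, x$phase_ko, x$b1 + x$b1_gt, x$phase_shift))
  invisible(x)
}

#' Hierarchical clustering of temporal profiles
#'
#' Rows are clustered with distance 1 - Pearson correlation and the tree
#' cut into k groups. Zero-variance rows (no defined correlation) are
#' held out and assigned post hoc to the cluster with the nearest mean
#' profile (Euclidean).
#'
#' @param mat numeric matrix, rows = profiles
#' @param k number of clusters
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   "average")
#' @return integer vector of cluster labels (1..k), named by rownames
#' @export
cluster_profiles <- function(mat, k, linkage = "average") {
  mat <- as.matrix(mat)
  if (k > nrow(mat)) stop("k exceeds the number of profiles", call. = FALSE)
  v <- apply(mat, 1, sd)
  ok <- which(v > 0)
  if (length(ok) < k) stop("fewer non-constant profiles than clusters", call. = FALSE)
  d <- as.dist(1 - cor(t(mat[ok, , drop = FALSE])))
  hc <- hclust(d, method = linkage)
  lab <- rep(NA_integer_, nrow(mat))
  lab[ok] <- cutree(hc, k = k)
  if (length(ok) < nrow(mat)) {
    cent <- vapply(seq_len(k), function(g)
      colMeans(mat[ok[lab[ok] == g], , drop = FALSE]), numeric(ncol(mat)))
    for (i in setdiff(seq_len(nrow(mat)), ok))
      lab[i] <- which.min(colSums((cent - mat[i, ])^2))
  }
  names(lab) <- rownames(mat)
  lab
}

#' Shortest circular arc containing a fraction of phases
#'
#' Finds the minimal-length arc on the 24-h circle containing at least
#' ceil(coverage * n) of the given phases; ties are broken by the
#' earliest start.
#'
#' @param phases numeric phases in hours (wrapped to [0, 24))
#' @param coverage required fraction (default 0.5)
#' @return list of class `phase_interval`: start_zt, end_zt, length
#'   (hours), coverage (achieved fraction)
#' @export
shortest_phase_interval <- function(phases, coverage = 0.5) {
  stopifnot(length(phases) >= 1, coverage > 0, coverage <= 1)
  p <- sort(wrap24(phases))
  n <- length(p)
  m <- ceiling(coverage * n)
  best_len <- Inf; best_start <- NA_real_; best_end <- NA_real_
  for (i in seq_len(n)) {
    j <- i + m - 1L
    endv <- if (j <= n) p[j] else p[j - n] + 24
    len <- endv - p[i]
    if (len < best_len - 1e-12 ||
        (abs(len - best_len) <= 1e-12 && p[i] < best_start)) {
      best_len <- len; best_start <- p[i]; best_end <- wrap24(endv)
    }
  }
  structure(list(start_zt = best_start, end_zt = best_end,
                 length = best_len, coverage = m / n),
            class = "phase_interval")
}

#' @export
print.phase_interval <- function(x, ...) {
  cat(sprintf("phase interval [ZT%.2f, ZT%.2f], length %.2f h, coverage %.0f%%\n",
              x$start_zt, x$end_zt, x$length, 100 * x$coverage))
  invisible(x)
}

#' Wrapped-Gaussian kernel density of phases on the 24-h circle
#'
#' @param phases hours
#' @param bandwidth kernel sd in hours (default 1)
#' @param n grid size over [0, 24) (default 240)
#' @return list with `x` (grid, hours) and `y` (density, integrates to 1
#'   over the circle)
#' @export
phase_density <- function(phases, bandwidth = 1, n = 240L) {
  stopifnot(length(phases) >= 2, bandwidth > 0)
  p <- wrap24(phases)
  grid <- seq(0, 24, length.out = n + 1L)[seq_len(n)]
  y <- rep(0, n)
  for (k in -5:5) y <- y + colMeans(outer(p, grid, function(a, b)
    dnorm(b - a + 24 * k, sd = bandwidth)))
  list(x = grid, y = y)
}
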