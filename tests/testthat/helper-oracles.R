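library(data.table)

# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive each quantity from first principles with no
# shared code paths (plain loops and sums).

# literal transcription of the border-trim schedule: trim the lighter
# border while the remaining interval keeps >= retain of the ORIGINAL
# total; halve the width on failure; stop below min_border
oracle_refine <- function(start, end, density, init_border = 50L,
                          retain = 0.75, min_border = 10L) {
  total <- sum(density)
  if (total == 0) return(c(start, end))
  lo <- 1L; hi <- length(density)
  w <- as.integer(init_border)
  while (w >= min_border) {
    if (hi - lo + 1L <= w) { w <- w %/% 2L; next }
    left <- sum(density[lo:(lo + w - 1L)])
    right <- sum(density[(hi - w + 1L):hi])
    cand <- min(left, right)
    if ((sum(density[lo:hi]) - cand) / total >= retain) {
      if (left <= right) lo <- lo + w else hi <- hi - w
    } else {
      w <- w %/% 2L
    }
  }
  c(start + lo - 1L, start + hi)
}

# O(n^2) shortest covering arc: try every arc anchored at a phase and
# ending at a phase, count membership by circular offset
oracle_arc <- function(phases, coverage = 0.5) {
  p <- phases %% 24
  n <- length(p)
  m <- ceiling(coverage * n)
  best <- c(len = Inf, start = NA_real_)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    len <- (p[j] - p[i]) %% 24
    inside <- sum(((p - p[i]) %% 24) <= len + 1e-12)
    if (inside >= m) {
      if (len < best["len"] - 1e-12 ||
          (abs(len - best["len"]) <= 1e-12 && p[i] < best["start"]))
        best <- c(len = len, start = p[i])
    }
  }
  best
}

# two-sided Fisher exact p as an explicit hypergeometric sum
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
  s / choose(n, 2)
}

# closed-form linear harmonic regression rss (independent of fit_cosine)
oracle_harmonic_rss <- function(t, x, period = 24) {
  w <- 2 * pi / period
  sum(lm(x ~ cos(w * t) + sin(w * t))$residuals^2)
}

# small shared fixture for module tests (kept light; the full-scale world
# lives in test-acceptance.R)
small_cfg <- function(seed = 11) {
  sim_config(seed = seed, chrom_lengths = c(chr1 = 2e5, chrBg = 1e5),
             n_sites = 8L, depth = 8e4, n_genes = 80L)
}
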