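# Independent oracles used to cross-check the package's estimators.
# Each one deliberately takes a different computational route from the
# implementation it checks.

# Cross-correlation lag wave-speed estimator: the lag maximizing the
# discrete cross-correlation of each offset's velocity time series against
# the innermost offset gives its relative transit delay; the speed is the
# OLS slope of position on delay.
xcorr_swv_oracle <- function(field, offsets = seq(1.0e-3, 2.4e-3, 2e-4),
                             depth = NULL) {
  depth <- depth %||% (if (!is.null(field$beam)) field$beam$focal_depth
                       else stats::median(field$z))
  iz <- which.min(abs(field$z - depth))
  dtf <- field$t[2] - field$t[1]
  sig <- sapply(offsets, function(off) {
    ix <- which.min(abs(field$x - off))
    diff(field$u[ix, iz, ])
  })
  ref <- sig[, 1]
  delays <- sapply(seq_along(offsets), function(i) {
    b <- sig[, i]
    lags <- 0:(length(ref) - 3L)
    cc <- sapply(lags, function(L) {
      n <- length(ref) - L
      sum(ref[seq_len(n)] * b[seq_len(n) + L])
    })
    k <- which.max(cc)
    L <- lags[k]
    if (k > 1 && k < length(cc)) {   # parabolic sub-lag refinement
      den <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
      if (den < 0) L <- L + 0.5 * (cc[k - 1] - cc[k + 1]) / den
    }
    L * dtf
  })
  unname(stats::coef(stats::lm(offsets ~ delays))[2])
}

# Two-sided Welch p-value from first principles: statistic and
# Welch-Satterthwaite df by hand, tail probability by numerical
# integration of the t density (normalisation via lgamma).
welch_p_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t_obs <- (mean(a) - mean(b)) / sqrt(va + vb)
  nu <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  dens <- function(x) {
    exp(lgamma((nu + 1) / 2) - lgamma(nu / 2)) / sqrt(nu * pi) *
      (1 + x^2 / nu)^(-(nu + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(t_obs), Inf, rel.tol = 1e-10)$value
  list(t = t_obs, df = nu, p = 2 * tail)
}

# Brute-force Mann-Whitney concordance: explicit double loop.
auc_bruteforce <- function(pos, neg) {
  s <- 0
  for (x in pos) for (y in neg) {
    if (x > y) s <- s + 1 else if (x == y) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}

# Permutation test for a difference in means between two groups.
perm_p_oracle <- function(x, y, n_perm = 1e4, seed = 1) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  hits <- with_seed(seed, {
    sum(replicate(n_perm, {
      idx <- sample(length(pooled), nx)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
    }))
  })
  (hits + 1) / (n_perm + 1)
}

with_seed <- tautr:::with_seed
`%||%` <- function(a, b) if (is.null(a)) b else a
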