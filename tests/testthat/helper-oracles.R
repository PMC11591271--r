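# Independent oracles used by the tests. These deliberately reimplement the
# quantities with naive table()/loop code so they share no code path with the
# package internals they check.

# plug-in MI in bits via table(), same equal-frequency binning definition
oracle_mi <- function(x, y, bins = 16L) {
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  bin1 <- function(z) {
    r <- rank(z, ties.method = "average")
    pmin(pmax(as.integer(ceiling(r * bins / length(z))), 1L), bins)
  }
  tab <- table(factor(bin1(x), levels = 1:bins),
               factor(bin1(y), levels = 1:bins))
  n <- length(x)
  mi <- 0
  for (i in 1:bins) for (j in 1:bins) {
    if (tab[i, j] > 0) {
      p <- tab[i, j] / n
      mi <- mi + p * log2(p / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
    }
  }
  mi
}

# exhaustive greedy MRMR (MIQ): recomputes every MI term at every step
oracle_mrmr <- function(X, y, k, bins = 16L) {
  nm <- colnames(X)
  rel <- vapply(nm, function(f) oracle_mi(X[, f], y, bins), numeric(1))
  sel <- character(0)
  cand <- nm
  while (length(sel) < k) {
    if (length(sel) == 0L) {
      score <- rel[cand]
    } else {
      score <- vapply(cand, function(f) {
        red <- mean(vapply(sel, function(s) oracle_mi(X[, f], X[, s], bins),
                           numeric(1)))
        rel[f] / max(red, 1e-12)
      }, numeric(1))
    }
    best <- cand[order(-score, cand)[1L]]
    sel <- c(sel, best)
    cand <- setdiff(cand, best)
  }
  sel
}

# direct DFT evaluation by explicit summation
oracle_dft_mag <- function(x, k_max = 8L) {
  n <- length(x)
  x <- x - mean(x)
  vapply(seq_len(k_max), function(k) {
    re <- sum(x * cos(-2 * pi * k * (0:(n - 1)) / n)) / n
    im <- sum(x * sin(-2 * pi * k * (0:(n - 1)) / n)) / n
    sqrt(re^2 + im^2)
  }, numeric(1))
}

# synthetic beat train from the pulse template: HR in bpm, returns a
# uniform_series at `rate`
template_train <- function(n_beats = 60, hr = 60, rate = 100,
                           dbp = 60, pp = 40, dicrotic_amp = 0.12) {
  n <- as.integer(round(n_beats * 60 / hr * rate))
  u <- cumsum(rep(hr / 60 / rate, n))
  uniform_series(dbp + pp * pulse_template(u, dicrotic_amp = dicrotic_amp),
                 rate, 0)
}

# minimal volume-series object for closed-form metric tests
make_volume_series <- function(times, cum_hem, cum_wb = rep(0, length(times))) {
  structure(list(times = times, cum_hemorrhaged = cum_hem,
                 cum_wb_infused = cum_wb, net_balance = cum_hem - cum_wb,
                 total_shed = max(cum_hem)),
            class = "volume_series")
}
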