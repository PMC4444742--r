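# Independent oracles: deliberately different code paths from the package
# (raw-sum formulas, head/tail slicing) so agreement is informative.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x * x) - sx^2) * sqrt(n * sum(y * y) - sy^2)
  num / den
}

oracle_pearson_p <- function(r, n) {
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), n - 2)
}

# exhaustive lag scan with head/tail slicing; same tie-break contract
oracle_best_lag <- function(rate, kin, L) {
  n <- length(rate)
  scan <- do.call(rbind, lapply(-L:L, function(l) {
    if (l >= 0) {
      a <- utils::head(rate, n - l); b <- utils::tail(kin, n - l)
    } else {
      a <- utils::tail(rate, n + l); b <- utils::head(kin, n + l)
    }
    data.frame(l = l, r = oracle_pearson(a, b))
  }))
  amax <- max(abs(scan$r))
  tied <- scan[abs(scan$r) >= amax - 1e-12, ]
  tied[order(abs(tied$l), tied$l), ][1, ]
}

oracle_chi2_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  chi2 <- n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

# one-way ANOVA from raw sums of squares
oracle_anova1 <- function(values, groups) {
  m <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - m)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- length(unique(groups)) - 1
  df2 <- length(values) - length(unique(groups))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# compact tracking builders
make_tracking <- function(duration = 10, fps = 30,
                          fx = function(t) rep(0, length(t)),
                          fy = fx) {
  t <- seq(0, duration, by = 1 / fps)
  tracking_series(t, fx(t), fy(t), frame_rate_nominal = fps)
}

# fabricated encoding result, for population-level tests
fake_result <- function(id, class_variable, r = 0.4, lag_s = 0,
                        p = 1e-4) {
  vars <- kinematic_components()
  tab <- data.frame(variable = vars, best_lag_s = 0, r = 0, p = 1,
                    n = 1000L, r_aligned = NA_real_)
  if (class_variable != "uncorrelated") {
    tab[tab$variable == class_variable,
        c("best_lag_s", "r", "p")] <- list(lag_s, r, p)
    sgn <- if (r > 0) "positive" else "negative"
  } else {
    sgn <- "none"; r <- NA_real_; lag_s <- NA_real_
  }
  structure(list(unit_id = id, table = tab,
                 class_variable = class_variable, sign = sgn,
                 class_r = r, class_lag_s = lag_s, alpha = 0.05),
            class = "encoding_result")
}

fake_unit <- function(id, hemisphere = "unknown", mean_rate = 5,
                      fwhm = 1.1, class = "DA") {
  unit_recording(id, numeric(0), hemisphere = hemisphere,
                 mean_rate = mean_rate, spike_width_fwhm = fwhm,
                 putative_class = class)
}
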