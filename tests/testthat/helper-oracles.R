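# Independent oracles and small fixture builders used across tests.

# Brute-force root-onset: OLS slope over every 3-date window, first window
# with slope strictly above the threshold wins.
oracle_root_onset <- function(doy, value, threshold = 0.5) {
  n <- length(doy)
  if (n < 3) stop("need >= 3 dates")
  for (i in seq_len(n - 2)) {
    x <- doy[i:(i + 2)]; y <- value[i:(i + 2)]
    b <- coef(lm(y ~ x))[2]
    if (b > threshold) return(doy[i])
  }
  NA_real_
}

# Trapezoid integral of a daily-grid curve (negative values clipped).
oracle_trapz <- function(grid, values) {
  v <- pmax(values, 0)
  sum((v[-1] + v[-length(v)]) / 2 * diff(grid))
}

# Classical pooled two-sample t test quantities.
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  est <- mean(b) - mean(a)
  list(estimate = est, se = se, t = est / se, df = na + nb - 2)
}

# Closed-form OLS slope and slope SE.
oracle_ols <- function(y, x) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  res <- y - (mean(y) - slope * mean(x)) - slope * x
  se <- sqrt(sum(res^2) / (length(y) - 2) / sxx)
  list(slope = slope, se = se)
}

pixel_f1 <- function(mask, truth) {
  tp <- sum(mask & truth)
  2 * tp / (sum(mask) + sum(truth))
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1]

# Minimal smooth_fit stand-in for extractor tests.
fake_fit <- function(grid, fitted) {
  structure(list(unit_id = "u", variable = "greenness", grid = grid,
                 fitted = fitted, edf = NA, r2 = NA), class = "smooth_fit")
}
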