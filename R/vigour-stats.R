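# Photosynthetic vigour index and the comparison statistics used in
# season-manipulation studies: unadjusted pairwise group contrasts from a
# one-way linear model, paired max-vs-last changes, and simple regressions.

#' Photosynthetic vigour index
#'
#' A proxy for photosynthetically active leaf tissue of one individual:
#' `max_leaf_length * (1 + sqrt(n_leaves)) * (1 - brown_fraction) *
#' chlorophyll`. The square root discounts the smaller size of each leaf
#' beyond the largest one; a fully brown individual scores zero. Units are
#' arbitrary -- the index is used after percent-of-maximum scaling.
#'
#' @param max_leaf_length length of the longest leaf (cm).
#' @param n_leaves number of intact leaves (>= 0).
#' @param brown_fraction fraction of brown leaf area, in \[0, 1\].
#' @param chlorophyll chlorophyll content (fluorescence ratio units, >= 0).
#' @return Index value (vectorized over inputs).
#' @examples
#' vigour_index(10, 4, 0.2, 300)  # 7200
#' @export
vigour_index <- function(max_leaf_length, n_leaves, brown_fraction,
                         chlorophyll) {
  if (any(max_leaf_length < 0) || any(n_leaves < 0) || any(chlorophyll < 0) ||
      any(brown_fraction < 0) || any(brown_fraction > 1))
    stop_ap("invalid_input",
            "inputs must be non-negative with brown_fraction in [0, 1]")
  max_leaf_length * (1 + sqrt(n_leaves)) * (1 - brown_fraction) * chlorophyll
}

#' Scale vigour values to percent of maximum per species and group
#'
#' @param df data.frame with columns `species`, `group`, `value`.
#' @return The data.frame with `value` replaced by percent of the
#'   species-by-group maximum.
#' @export
scale_vigour <- function(df) {
  stopifnot(all(c("species", "group", "value") %in% names(df)))
  key <- interaction(df$species, df$group, drop = TRUE)
  mx <- tapply(df$value, key, max)
  if (any(mx <= 0)) stop_ap("degenerate_scaling",
                            "non-positive maximum in some species x group")
  df$value <- 100 * df$value / as.numeric(mx[key])
  df
}

#' Pairwise group contrasts from a one-way linear model
#'
#' Fits `value ~ group` and reports all pairwise differences of group means
#' with the pooled residual standard error, two-sided t tests on the
#' residual degrees of freedom, and no multiplicity adjustment (matching
#' common reporting of post-hoc contrasts).
#'
#' @param values numeric per-unit metric.
#' @param groups group labels (factor or character).
#' @return data.frame with `label`, `estimate`, `se`, `t`, `df`, `p`.
#' @export
group_contrasts <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_ap("invalid_input", "need >= 2 groups")
  if (any(table(groups) < 2))
    warn_ap("df_warning", "some group has < 2 units; pooled df may be fragile")
  n <- tapply(values, groups, length)
  m <- tapply(values, groups, mean)
  fit <- lm(values ~ groups)
  sigma2 <- sum(fit$residuals^2) / fit$df.residual
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  out <- data.frame(
    label = apply(combs, 2, function(p) paste(p[2], "-", p[1])),
    estimate = apply(combs, 2, function(p) m[p[2]] - m[p[1]]),
    se = apply(combs, 2, function(p) sqrt(sigma2 * (1 / n[p[1]] + 1 / n[p[2]]))),
    stringsAsFactors = FALSE
  )
  out$t <- out$estimate / out$se
  out$df <- fit$df.residual
  out$p <- 2 * pt(-abs(out$t), out$df)
  rownames(out) <- NULL
  out
}

#' Paired percent change between maximum and last values
#'
#' Per-unit percent change `100 * (last - max) / max`, summarized with a
#' paired t test. (For two timepoints per unit, a mixed model with a random
#' unit intercept reduces exactly to this.)
#'
#' @param max_vals,last_vals paired per-unit values (same length, n >= 2).
#' @return List with `delta` (per-unit percent change), `mean`, `se`, `t`,
#'   `df`, `p`, and `degenerate` (TRUE when all changes are identical).
#' @export
paired_change <- function(max_vals, last_vals) {
  stopifnot(length(max_vals) == length(last_vals))
  if (length(max_vals) < 2) stop_ap("invalid_input", "need n >= 2 pairs")
  if (any(max_vals == 0)) stop_ap("undefined_change", "a maximum value is 0")
  delta <- 100 * (last_vals - max_vals) / max_vals
  s <- stats::sd(delta)
  n <- length(delta)
  se <- s / sqrt(n)
  degenerate <- s == 0
  t <- if (degenerate) NA_real_ else mean(delta) / se
  list(delta = delta, mean = mean(delta), se = se, t = t, df = n - 1,
       p = if (degenerate) NA_real_ else 2 * pt(-abs(t), n - 1),
       degenerate = degenerate)
}

#' Simple linear regression with slope inference
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, its standard
#' error, r-squared, the slope F statistic (= t squared) and its two-sided
#' p value.
#'
#' @param y,x numeric vectors (n >= 3, non-constant x).
#' @return List with `slope`, `intercept`, `se_slope`, `r2`, `F`, `p`, `df`.
#' @export
simple_regression <- function(y, x) {
  if (length(y) < 3) stop_ap("invalid_input", "need n >= 3")
  if (var(x) == 0) stop_ap("invalid_input", "constant x")
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  df <- n - 2
  sigma2 <- sum(res^2) / df
  se_slope <- sqrt(sigma2 / sxx)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  t <- slope / se_slope
  list(slope = slope, intercept = intercept, se_slope = se_slope, r2 = r2,
       F = t^2, p = 2 * pt(-abs(t), df), df = df)
}
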