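#' Construct a statistical test result
#'
#' Lightweight container used by all behavioural and channel-level tests.
#'
#' @param test_name label of the test.
#' @param statistic test statistic value.
#' @param df degrees of freedom (or `NA`).
#' @param n sample size used (or `NA`).
#' @param p p-value (two-tailed unless the name says otherwise).
#' @param effect_r effect size r in \[-1, 1\] (or `NA`).
#' @param correction label + factor of any multiplicity correction.
#' @param detail optional list of auxiliary quantities.
#' @return A `wm_stat` object.
#' @export
stat_result <- function(test_name, statistic, df = NA_real_, n = NA_integer_,
                        p = NA_real_, effect_r = NA_real_,
                        correction = NULL, detail = NULL) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  if (!is.na(effect_r) && abs(effect_r) > 1 + 1e-12)
    stop("effect size r must lie in [-1, 1]")
  out <- list(test_name = test_name, statistic = statistic, df = df, n = n,
              p = p, effect_r = effect_r, correction = correction,
              detail = detail)
  class(out) <- "wm_stat"
  out
}

#' @export
print.wm_stat <- function(x, ...) {
  cat(sprintf("<wm_stat> %s: statistic = %.4g%s%s, p = %.4g%s%s\n",
              x$test_name, x$statistic,
              if (!is.na(x$df)) sprintf(", df = %g", x$df) else "",
              if (!is.na(x$n)) sprintf(", n = %d", x$n) else "",
              x$p,
              if (!is.na(x$effect_r)) sprintf(", r = %.3f", x$effect_r) else "",
              if (!is.null(x$correction)) paste0(" [", x$correction, "]") else ""))
  invisible(x)
}

#' Effect size r from a standardized Wilcoxon Z
#'
#' `r = Z / sqrt(N)` with `N` the total number of observations entering the
#' paired comparison (twice the number of pairs, zero differences included).
#'
#' @param z standardized test statistic.
#' @param n_obs total observations N.
#' @return r.
#' @export
#' @examples
#' effect_r_from_z(-5.001, 68)   # about -0.606
effect_r_from_z <- function(z, n_obs) {
  stopifnot(n_obs >= 1)
  z / sqrt(n_obs)
}

#' Effect size r from a t statistic
#'
#' `r = sqrt(t^2 / (t^2 + df))`, carrying the sign of t.
#' @param t t statistic.
#' @param df degrees of freedom.
#' @return r.
#' @export
#' @examples
#' effect_r_from_t(4.69, 27)     # about 0.67
effect_r_from_t <- function(t, df) {
  stopifnot(df >= 1)
  sign(t) * sqrt(t^2 / (t^2 + df))
}

#' Per-condition trial rates across a cohort
#'
#' Per subject, the percentage of trials in each condition over *all* trials
#' (answered and unanswered); then the cohort mean and standard deviation.
#'
#' @param behaviors list of behaviour tables (one per subject).
#' @return data.frame with `condition`, `mean_pct`, `sd_pct`, plus the
#'   per-subject rate matrix as attribute `"rates"`.
#' @export
condition_rates <- function(behaviors) {
  stopifnot(length(behaviors) >= 1)
  conds <- conditions_all()
  rates <- t(vapply(behaviors, function(b) {
    100 * vapply(conds, function(cd) mean(b$condition == cd), 0)
  }, numeric(length(conds))))
  colnames(rates) <- conds
  out <- data.frame(condition = conds,
                    mean_pct = colMeans(rates),
                    sd_pct = apply(rates, 2, sd),
                    row.names = NULL)
  attr(out, "rates") <- rates
  out
}

#' Friedman omnibus test on per-subject condition medians
#'
#' Tie-corrected Friedman chi-square across `k` related samples (the three
#' condition columns), with `df = k - 1`.
#'
#' @param x subjects x conditions matrix (e.g. per-subject median RTs).
#' @return A `wm_stat` (statistic chi-square).
#' @export
friedman_rt <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) != 3)
    stop("need >= 2 subjects and exactly 3 conditions")
  if (all(apply(x, 1, function(r) length(unique(r)) == 1))) {
    # every subject ranks the conditions as fully tied: no effect by definition
    return(stat_result("Friedman ANOVA (chi-square)", statistic = 0,
                       df = ncol(x) - 1, n = nrow(x), p = 1))
  }
  ft <- friedman.test(x)
  stat_result("Friedman ANOVA (chi-square)",
              statistic = unname(ft$statistic), df = unname(ft$parameter),
              n = nrow(x), p = ft$p.value)
}

#' Wilcoxon signed-rank test with tie-corrected normal approximation
#'
#' Zero differences are dropped; the remaining absolute differences are
#' ranked (midranks for ties); `Z = (W+ - mu) / sigma` with the tie-corrected
#' variance. The effect size is `r = Z / sqrt(N)`, `N` = total observations
#' = twice the number of pairs (zero differences included), matching the
#' convention in which a 34-pair comparison has N = 68.
#'
#' @param x,y paired samples.
#' @param correction optional label of the multiplicity regime, e.g.
#'   "Bonferroni x3" (purely descriptive).
#' @return A `wm_stat` with `statistic` = Z and two-tailed normal p.
#' @export
wilcoxon_z <- function(x, y, correction = NULL) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n_pairs <- length(d)
  d <- d[!is.na(d)]
  dz <- d[d != 0]
  n <- length(dz)
  if (n < 5)
    warning("fewer than 5 non-zero differences; normal approximation is poor")
  r <- rank(abs(dz))
  w_plus <- sum(r[dz > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_plus - mu) / sqrt(sigma2) else 0
  p <- 2 * pnorm(-abs(z))
  N <- 2L * n_pairs
  stat_result("Wilcoxon signed-rank (normal approximation)",
              statistic = z, n = N, p = min(1, p),
              effect_r = effect_r_from_z(z, N), correction = correction,
              detail = list(w_plus = w_plus, n_nonzero = n))
}

#' Spearman rank correlation
#'
#' Midrank-tied Spearman rho. The p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` by default, or a seeded
#' permutation of one margin.
#'
#' @param x,y numeric vectors.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @param seed permutation seed.
#' @return A `wm_stat` with `statistic` = rho.
#' @export
spearman_test <- function(x, y, method = c("t", "permutation"),
                          n_perm = 5000, seed = 1) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  rho <- cor(rank(x), rank(y))
  if (method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), n - 2)
    }
  } else {
    p <- with_local_seed(seed, {
      null <- replicate(n_perm, cor(rank(x), rank(sample(y))))
      (1 + sum(abs(null) >= abs(rho) - 1e-12)) / (1 + n_perm)
    })
  }
  stat_result(sprintf("Spearman correlation (%s p)", method),
              statistic = rho, n = n, p = p, effect_r = rho)
}

#' Serial-position recognition accuracy
#'
#' Per subject and encoded serial position (1-4), the percentage of probed
#' items recognised; cohort mean and SD per position, and a recency contrast
#' (position 4 vs the mean of positions 1-3) via [wilcoxon_z()]. Positions
#' never probed for a subject are reported missing, not zero.
#'
#' @param behaviors list of behaviour tables containing `sp1`..`sp4`.
#' @return List: `table` (position, mean_pct, sd_pct), `recency` (`wm_stat`),
#'   and the per-subject matrix `rates`.
#' @export
serial_position_accuracy <- function(behaviors) {
  cols <- paste0("sp", 1:4)
  if (!all(cols %in% names(behaviors[[1]])))
    stop("behaviour tables lack serial-recognition columns sp1..sp4")
  rates <- t(vapply(behaviors, function(b) {
    vapply(cols, function(cl) {
      v <- b[[cl]]
      if (all(is.na(v))) NA_real_ else 100 * mean(v, na.rm = TRUE)
    }, 0)
  }, numeric(4)))
  tab <- data.frame(position = 1:4,
                    mean_pct = colMeans(rates, na.rm = TRUE),
                    sd_pct = apply(rates, 2, sd, na.rm = TRUE))
  rec <- suppressWarnings(
    wilcoxon_z(rates[, 4], rowMeans(rates[, 1:3, drop = FALSE], na.rm = TRUE)))
  rec$test_name <- "recency contrast (position 4 vs 1-3), Wilcoxon"
  list(table = tab, recency = rec, rates = rates)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS distance against a normal with estimated mean and SD
#' (Lilliefors variant), p by the Lilliefors approximation.
#'
#' @param x numeric sample (n >= 5).
#' @return A `wm_stat` with `statistic` = D.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5) stop("need at least 5 values")
  if (sd(x) == 0) stop("degenerate input: zero variance")
  lt <- nortest::lillie.test(x)
  stat_result("Kolmogorov-Smirnov (Lilliefors) normality",
              statistic = unname(lt$statistic), n = length(x), p = lt$p.value)
}

#' Correlation between cluster power and mean response time
#'
#' Per subject, the mean normalised power over a significant cluster's
#' triplets and the mean RT over answered trials are paired; subjects whose
#' (power, RT) point falls outside the bivariate normal 95% confidence
#' ellipse (squared Mahalanobis distance above the chi-square quantile) are
#' excluded, then a Spearman correlation is computed on the remainder.
#'
#' @param cluster one cluster (with a `triplets` data.frame) from a
#'   [permutation_test()] result; pass a significant retention cluster.
#' @param subject_means list of per-subject condition-agnostic mean arrays
#'   on the same axes the cluster was computed on (see [tfr_mean()] /
#'   [subset_box()]).
#' @param mean_rts per-subject mean RT over answered trials (seconds).
#' @param conf confidence level of the exclusion ellipse (default 0.95).
#' @return A `wm_stat`; `$detail` holds the per-subject powers, RTs and the
#'   excluded subject indices.
#' @export
power_rt_correlation <- function(cluster, subject_means, mean_rts,
                                 conf = 0.95) {
  if (is.null(cluster) || is.null(cluster$triplets))
    stop("no cluster supplied; operation skipped without a significant cluster")
  trip <- cluster$triplets
  pow <- vapply(subject_means, function(a) {
    dn <- dimnames(a)
    ic <- match(trip$channel, dn[[1]])
    jf <- match(as.character(round(trip$freq, 6)), dn[[2]])
    jt <- match(as.character(round(trip$time, 6)), dn[[3]])
    if (anyNA(ic) || anyNA(jf) || anyNA(jt))
      stop("cluster triplets not found on the subject array axes")
    mean(a[cbind(ic, jf, jt)], na.rm = TRUE)
  }, 0)
  stopifnot(length(pow) == length(mean_rts))
  xy <- cbind(power = pow, rt = mean_rts)
  md2 <- mahalanobis(xy, colMeans(xy), cov(xy))
  excl <- which(md2 > qchisq(conf, df = 2))
  keep <- setdiff(seq_along(pow), excl)
  if (length(excl))
    message(length(excl), " subject(s) outside the ", 100 * conf,
            "% confidence ellipse excluded")
  st <- spearman_test(pow[keep], mean_rts[keep])
  st$test_name <- "ICF cluster power vs mean RT (Spearman)"
  st$detail <- list(power = pow, rt = mean_rts, excluded = excl)
  st
}
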