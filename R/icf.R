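#' Detect a subject's individual central frequency (ICF)
#'
#' The ICF is the frequency in `f_lim` (default \[10, 26\] Hz) with the
#' strongest baseline-normalised power increase, averaged over the detection
#' channels (default P4, P8, O2), the detection window (default the second
#' half of the retention interval, \[1.5, 2.0\] s) and all trials. Ties break
#' toward the lower frequency. If no candidate shows a power increase the
#' argmax is still returned, with a low-SNR warning.
#'
#' @param tfr a normalised `wm_tfr`.
#' @param channels detection channels.
#' @param window detection window in seconds (intersected with the TFR's
#'   window-centre axis).
#' @param f_lim candidate frequency range in Hz.
#' @return A `wm_icf` object: `subject`, `icf` (Hz), `peak_power` (% change),
#'   `channels`, `window`, and the candidate `profile` (named vector).
#' @export
detect_icf <- function(tfr, channels = c("P4", "P8", "O2"),
                       window = c(1.5, 2.0), f_lim = c(10, 26)) {
  stopifnot(inherits(tfr, "wm_tfr"))
  if (!tfr$normalized) stop("TFR must be baseline-normalised first")
  ic <- match(channels, tfr$channel_names)
  if (anyNA(ic)) stop("detection channels missing from TFR")
  jt <- which(tfr$times >= window[1] - 1e-9 & tfr$times <= window[2] + 1e-9)
  if (!length(jt)) stop("detection window outside the TFR time axis")
  jf <- which(tfr$freqs >= f_lim[1] - 1e-9 & tfr$freqs <= f_lim[2] + 1e-9)
  prof <- apply(tfr$power[, ic, jf, jt, drop = FALSE], 3, mean, na.rm = TRUE)
  names(prof) <- tfr$freqs[jf]
  best <- which.max(prof)                 # which.max takes the first maximum
  if (prof[best] <= 0)
    warning("no power increase among ICF candidates (low SNR); ",
            "argmax returned anyway")
  res <- list(subject = tfr$subject, icf = tfr$freqs[jf][best],
              peak_power = unname(prof[best]), channels = channels,
              window = window, profile = prof)
  class(res) <- "wm_icf"
  res
}

#' @export
print.wm_icf <- function(x, ...) {
  cat(sprintf("<wm_icf> subject %s: ICF = %g Hz (peak %+.1f%% over %s, [%g, %g] s)\n",
              x$subject, x$icf, x$peak_power,
              paste(x$channels, collapse = "/"), x$window[1], x$window[2]))
  invisible(x)
}

#' Shift a TFR's frequency axis to align the subject's ICF on a reference
#'
#' The frequency axis is translated by `ref - icf` in whole grid bins so the
#' subject's ICF lands on `ref`. Bins shifted beyond the TFR's frequency
#' support become `NA` ("missing"); they are excluded from cluster statistics
#' rather than zero-filled. The shift is invertible on non-missing bins.
#'
#' @param tfr a `wm_tfr`.
#' @param icf the subject's ICF in Hz (on the frequency grid).
#' @param ref the reference frequency in Hz (on the frequency grid).
#' @return The shifted `wm_tfr` (attribute `"icf_shift"` records the bins).
#' @export
align_to_icf <- function(tfr, icf, ref) {
  stopifnot(inherits(tfr, "wm_tfr"))
  df <- diff(tfr$freqs)
  if (length(unique(round(df, 9))) != 1)
    stop("frequency axis must be uniform for alignment")
  df <- df[1]
  for (v in c(icf = icf, ref = ref)) {
    sh <- (v - tfr$freqs[1]) / df
    if (abs(sh - round(sh)) > 1e-9)
      stop("icf/ref must lie on the frequency grid")
  }
  shift <- as.integer(round((ref - icf) / df))
  if (shift != 0) {
    d <- dim(tfr$power)
    out <- array(NA_real_, d, dimnames = dimnames(tfr$power))
    src <- seq_len(d[3])
    dst <- src + shift
    ok <- dst >= 1 & dst <= d[3]
    out[, , dst[ok], ] <- tfr$power[, , src[ok], , drop = FALSE]
    tfr$power <- out
    if (!is.null(tfr$baseline)) {
      b <- matrix(NA_real_, nrow(tfr$baseline), ncol(tfr$baseline))
      b[, dst[ok]] <- tfr$baseline[, src[ok]]
      tfr$baseline <- b
    }
  }
  attr(tfr, "icf_shift") <- shift
  tfr
}

#' Right-vs-left hemispheric lateralization of ICF-band retention power
#'
#' Per subject, the mean normalised power in `[icf - 2, icf + 2]` Hz over the
#' detection window is computed for the right (P4, P8, O2) and left (P3, P7,
#' O1) channel sets; the paired difference (right minus left) is tested with
#' a two-sided dependent-samples t-test and the effect size
#' `r = sqrt(t^2 / (t^2 + df))` (carrying t's sign) is reported.
#'
#' @param tfrs list of normalised per-subject `wm_tfr` objects.
#' @param icfs numeric vector of per-subject ICFs (Hz).
#' @param right,left channel sets for the two hemispheres.
#' @param window analysis window in seconds.
#' @param halfwidth half-width of the ICF band in Hz (default 2).
#' @return A `wm_stat` result (statistic t, df, p, effect size r) with the
#'   per-subject differences in `$detail`.
#' @export
lateralization_test <- function(tfrs, icfs,
                                right = c("P4", "P8", "O2"),
                                left = c("P3", "P7", "O1"),
                                window = c(1.5, 2.0), halfwidth = 2) {
  if (length(tfrs) < 2) stop("need at least 2 subjects")
  stopifnot(length(tfrs) == length(icfs))
  vals <- t(vapply(seq_along(tfrs), function(s) {
    fl <- c(icfs[s] - halfwidth, icfs[s] + halfwidth)
    c(right = band_average(tfrs[[s]], right, fl, window, per_trial = FALSE),
      left = band_average(tfrs[[s]], left, fl, window, per_trial = FALSE))
  }, numeric(2)))
  dd <- vals[, "right"] - vals[, "left"]
  df <- length(dd) - 1
  if (sd(dd) == 0) {
    # no variability in the asymmetry: uninformative, not an error
    t <- 0; p <- 1
  } else {
    tt <- t.test(vals[, "right"], vals[, "left"], paired = TRUE)
    t <- unname(tt$statistic); p <- tt$p.value
  }
  stat_result("lateralization t-test (right - left)", statistic = t,
              df = df, p = p, effect_r = effect_r_from_t(t, df),
              detail = list(diff = dd))
}
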