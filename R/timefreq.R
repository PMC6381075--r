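#' Sliding Hanning-window spectrogram
#'
#' Time-frequency power per trial, channel, frequency bin and window centre:
#' the squared magnitude of the Hanning-tapered Fourier coefficient at each
#' requested frequency, scaled so that a unit-amplitude sinusoid at a bin
#' frequency yields a power of 1/2 (amplitude^2 / 2). Window centres are
#' restricted to `[tmin + window/2, tmax - window/2]`; windows never extend
#' past the epoch (no padding). Requested frequencies must be resolvable by
#' the window (multiples of `1/window` at or above the Rayleigh resolution).
#'
#' @param epochs a `wm_epochs` object (rejected trials are dropped first).
#' @param window taper length in seconds (default 0.5).
#' @param step hop between window centres in seconds (default 0.05).
#' @param freqs analysis frequencies in Hz (default 2-32 in 2 Hz steps).
#' @param channels channel subset to analyse (default: all).
#' @return A `wm_tfr` object: `power` (trials x channels x freqs x times,
#'   microvolt^2), `freqs`, `times` (window centres, s), `channel_names`,
#'   `trial_ids`, `normalized = FALSE`, `baseline = NULL`, `subject`, `icf`.
#' @export
compute_tfr <- function(epochs, window = 0.5, step = 0.05,
                        freqs = seq(2, 32, by = 2), channels = NULL) {
  stopifnot(inherits(epochs, "wm_epochs"))
  ep <- drop_rejected(epochs)
  fs <- ep$sfreq
  if (is.null(channels)) channels <- ep$channel_names
  ic <- match(channels, ep$channel_names)
  if (anyNA(ic)) stop("unknown channel(s): ",
                      paste(channels[is.na(ic)], collapse = ", "))
  n_win <- round(window * fs)
  if (n_win > dim(ep$data)[3]) stop("window longer than the epoch")
  rayleigh <- 1 / window
  k <- freqs * window                       # DFT bin index per frequency
  if (any(freqs < rayleigh - 1e-9))
    stop("frequencies below the window's Rayleigh resolution (",
         rayleigh, " Hz)")
  if (any(abs(k - round(k)) > 1e-6))
    stop("frequencies must be multiples of 1/window = ", rayleigh, " Hz")
  k <- as.integer(round(k))
  tmin <- min(ep$times); tmax <- max(ep$times) + 1 / fs
  centers <- seq(tmin + window / 2, tmax - window / 2 + 1e-9, by = step)
  centers <- round(centers / step) * step
  n_tr <- dim(ep$data)[1]; n_ch <- length(ic)
  nf <- length(freqs); nt <- length(centers)

  taper <- 0.5 * (1 - cos(2 * pi * seq_len(n_win) / n_win))  # periodic Hanning
  S2 <- sum(taper)^2
  pw <- array(NA_real_, c(n_tr, n_ch, nf, nt),
              dimnames = list(NULL, channels, freqs, NULL))
  for (j in seq_len(nt)) {
    i0 <- round((centers[j] - window / 2 - tmin) * fs)
    idx <- i0 + seq_len(n_win)
    seg <- ep$data[, ic, idx, drop = FALSE]             # trials x ch x n_win
    m <- matrix(seg, nrow = n_tr * n_ch)                # (tr*ch) x n_win
    m <- sweep(m, 2, taper, `*`)
    co <- mvfft(t(m))[k + 1L, , drop = FALSE]           # nf x (tr*ch)
    p <- 2 * (Re(co)^2 + Im(co)^2) / S2
    pw[, , , j] <- aperm(array(p, c(nf, n_tr, n_ch)), c(2, 3, 1))
  }
  tfr <- list(power = pw, freqs = freqs, times = centers,
              channel_names = channels, trial_ids = ep$trial_ids,
              normalized = FALSE, baseline = NULL,
              subject = ep$subject, icf = ep$icf)
  class(tfr) <- "wm_tfr"
  tfr
}

#' @export
print.wm_tfr <- function(x, ...) {
  cat(sprintf("<wm_tfr>%s %d trials x %d channels x %d freqs [%g-%g Hz] x %d times [%g, %g] s\n",
              if (x$normalized) " (%-change)" else " (µV²)",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              min(x$freqs), max(x$freqs), dim(x$power)[4],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Percent-change baseline normalisation
#'
#' Converts raw power to percent change from a pre-stimulus baseline:
#' `Pnorm(f, t) = 100 * (P(f, t) - Pbase(f)) / Pbase(f)`, where `Pbase(f)` is
#' the mean power over *all* trials (condition-agnostic) and all window
#' centres falling inside `baseline_window`, per channel and frequency.
#' Applied per subject, before any trial selection.
#'
#' @param tfr an unnormalised `wm_tfr`.
#' @param baseline_window two-element interval in seconds (default
#'   `c(-1, -0.3)` relative to first-stimulus onset).
#' @return The normalised `wm_tfr` (`normalized = TRUE`, `baseline` holds
#'   `Pbase` as a channels x freqs matrix).
#' @export
baseline_normalize <- function(tfr, baseline_window = c(-1, -0.3)) {
  stopifnot(inherits(tfr, "wm_tfr"))
  if (tfr$normalized) stop("TFR is already normalised")
  jb <- which(tfr$times >= baseline_window[1] - 1e-9 &
                tfr$times <= baseline_window[2] + 1e-9)
  if (!length(jb)) stop("no window centre inside the baseline interval")
  base <- apply(tfr$power[, , , jb, drop = FALSE], c(2, 3), mean)
  if (any(base == 0))
    stop("zero baseline power at some (channel, frequency); degenerate input")
  d <- dim(tfr$power)
  bfull <- aperm(array(base, c(d[2], d[3], d[1], d[4])), c(3, 1, 2, 4))
  tfr$power <- 100 * (tfr$power - bfull) / bfull
  tfr$normalized <- TRUE
  tfr$baseline <- base
  tfr
}

#' Average power over a channel-frequency-time box
#'
#' Arithmetic mean of (normalised) power over the selected channels, the
#' frequency range and the window-centre range, per trial or pooled.
#'
#' @param tfr a `wm_tfr`.
#' @param channels channel labels to include.
#' @param f_lim,t_lim two-element inclusive ranges (Hz, s).
#' @param per_trial if `TRUE` (default) return one value per trial, else a
#'   single pooled mean.
#' @param trials optional subset of trial ids.
#' @return Numeric vector (per trial) or scalar, in the TFR's units.
#' @export
band_average <- function(tfr, channels, f_lim, t_lim, per_trial = TRUE,
                         trials = NULL) {
  stopifnot(inherits(tfr, "wm_tfr"))
  ic <- match(channels, tfr$channel_names)
  if (anyNA(ic)) stop("unknown channel(s): ",
                      paste(channels[is.na(ic)], collapse = ", "))
  jf <- which(tfr$freqs >= f_lim[1] - 1e-9 & tfr$freqs <= f_lim[2] + 1e-9)
  jt <- which(tfr$times >= t_lim[1] - 1e-9 & tfr$times <= t_lim[2] + 1e-9)
  if (!length(jf) || !length(jt)) stop("empty frequency/time selection")
  it <- if (is.null(trials)) seq_len(dim(tfr$power)[1]) else
    match(trials, tfr$trial_ids)
  if (anyNA(it)) stop("unknown trial id(s)")
  box <- tfr$power[it, ic, jf, jt, drop = FALSE]
  if (per_trial) apply(box, 1, mean, na.rm = TRUE)
  else mean(box, na.rm = TRUE)
}

#' Mean TFR over a set of trials
#'
#' @param tfr a `wm_tfr`.
#' @param trials trial ids to average over (default: all).
#' @return A channels x freqs x times array (dimnames carry the axes).
#' @export
tfr_mean <- function(tfr, trials = NULL) {
  it <- if (is.null(trials)) seq_len(dim(tfr$power)[1]) else
    match(trials, tfr$trial_ids)
  if (anyNA(it)) stop("unknown trial id(s)")
  out <- apply(tfr$power[it, , , , drop = FALSE], c(2, 3, 4), mean)
  dimnames(out) <- list(tfr$channel_names, as.character(tfr$freqs),
                        as.character(round(tfr$times, 6)))
  out
}

#' Heatmap of a trial-averaged time-frequency representation
#' @param x a `wm_tfr`.
#' @param channels channels to average over (default: all).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.wm_tfr <- function(x, channels = x$channel_names, ...) {
  m <- tfr_mean(x)
  ic <- match(channels, x$channel_names)
  img <- apply(m[ic, , , drop = FALSE], c(2, 3), mean)
  image(x = x$times, y = x$freqs, z = t(img), xlab = "time (s)",
        ylab = "frequency (Hz)", col = hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(img)
}
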