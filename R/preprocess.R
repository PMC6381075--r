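#' Zero-phase Butterworth bandpass filter
#'
#' Applies an order-`order` Butterworth bandpass forward and backward
#' (`signal::filtfilt`), so the effective magnitude response is squared (about
#' -6 dB at the cutoffs) and the phase response is zero. Ocular channels are
#' filtered identically; events are untouched.
#'
#' @param raw a `wm_raw` recording.
#' @param low,high cutoff frequencies in Hz, `0 < low < high < sfreq/2`.
#' @param order filter order of each pass (default 4).
#' @return The filtered `wm_raw`.
#' @export
bandpass <- function(raw, low = 0.2, high = 100, order = 4) {
  stopifnot(inherits(raw, "wm_raw"))
  nyq <- raw$sfreq / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("cutoffs must satisfy 0 < low < high < sampling_rate/2")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  for (ch in seq_len(nrow(raw$signal)))
    raw$signal[ch, ] <- signal::filtfilt(bf, raw$signal[ch, ])
  raw
}

#' Extract demeaned epochs around first-stimulus events
#'
#' One epoch per event, covering `[tmin, tmax]` seconds relative to the event
#' sample; each trial and channel is demeaned over its own extent. Events too
#' close to a recording edge for a full window are dropped with a warning.
#'
#' @param raw a `wm_raw` recording.
#' @param tmin,tmax epoch window in seconds (defaults -1 and 2).
#' @return A `wm_epochs` object: `data` (trials x channels x samples, microvolt),
#'   `times` (s), `trial_ids`, `channel_names`, `sfreq`, `eog_channels`,
#'   `rejected` (logical per trial), `subject`, `icf`.
#' @export
epoch_and_demean <- function(raw, tmin = -1, tmax = 2) {
  stopifnot(inherits(raw, "wm_raw"), tmin < tmax)
  fs <- raw$sfreq
  n_samp <- round((tmax - tmin) * fs)
  off <- round(tmin * fs)
  n_total <- ncol(raw$signal)
  first <- raw$events$sample + off + 1L           # 1-based start
  ok <- first >= 1L & (first + n_samp - 1L) <= n_total
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  ev <- raw$events[ok, , drop = FALSE]
  n_tr <- nrow(ev)
  n_ch <- nrow(raw$signal)
  data <- array(NA_real_, c(n_tr, n_ch, n_samp),
                dimnames = list(NULL, raw$channel_names, NULL))
  for (i in seq_len(n_tr)) {
    idx <- (ev$sample[i] + off + 1L):(ev$sample[i] + off + n_samp)
    seg <- raw$signal[, idx, drop = FALSE]
    data[i, , ] <- seg - rowMeans(seg)
  }
  ep <- list(data = data,
             times = tmin + (seq_len(n_samp) - 1L) / fs,
             trial_ids = ev$trial_id,
             channel_names = raw$channel_names,
             sfreq = fs,
             eog_channels = raw$eog_channels,
             rejected = rep(FALSE, n_tr),
             subject = raw$subject, icf = raw$icf)
  class(ep) <- "wm_epochs"
  ep
}

#' @export
print.wm_epochs <- function(x, ...) {
  cat(sprintf("<wm_epochs> %d trials x %d channels x %d samples @ %g Hz [%g, %g] s; %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq,
              min(x$times), max(x$times), sum(x$rejected)))
  invisible(x)
}

# Symmetric fixed-point FastICA with tanh contrast on pre-whitened data.
# Returns the unmixing matrix W (components x channels) such that S = W X
# for centred X, or NULL on non-convergence.
fastica_unmix <- function(X, n_comp, max_iter = 200, tol = 1e-4) {
  # X: channels x samples, rows centred
  cv <- tcrossprod(X) / ncol(X)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > max(eg$values) * 1e-10)
  m <- min(n_comp, rank)
  d <- eg$values[seq_len(m)]
  E <- eg$vectors[, seq_len(m), drop = FALSE]
  K <- diag(1 / sqrt(d), length(d)) %*% t(E)     # whitening: Z = K X
  Z <- K %*% X
  p <- nrow(Z)
  W <- matrix(rnorm(p * p), p, p)
  sym_decorr <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorr(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- G %*% t(Z) / ncol(Z) - diag(gp, p) %*% W
    W1 <- sym_decorr(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) return(W %*% K)
  }
  NULL
}

#' Remove ocular artifacts by independent component analysis
#'
#' FastICA (symmetric fixed-point, tanh contrast) is estimated on the
#' concatenated EEG epochs; independent components whose absolute Pearson
#' correlation with either ocular channel exceeds `corr_threshold` are zeroed
#' before back-projection. The unmixing matrix is estimated on an evenly
#' decimated subset of at most `max_samples` time points and applied to all
#' samples. On non-convergence the estimation restarts with a fresh random
#' initialisation, up to `max_retries` times.
#'
#' @param epochs a `wm_epochs` object.
#' @param eog ocular channel labels (>= 2 required; default from the object).
#' @param corr_threshold absolute correlation above which a component is
#'   deemed ocular (default 0.7; 1.0 disables removal).
#' @param n_comp number of components (default: number of EEG channels).
#' @param max_samples cap on time points used for unmixing estimation.
#' @param max_retries restarts allowed on non-convergence.
#' @param seed RNG seed for the ICA initialisation.
#' @return The cleaned `wm_epochs`; the number of removed components is
#'   reported via `message()` and stored as attribute `"n_removed"`.
#' @export
remove_ocular_ica <- function(epochs, eog = epochs$eog_channels,
                              corr_threshold = 0.7, n_comp = NULL,
                              max_samples = 20000, max_retries = 5, seed = 1) {
  stopifnot(inherits(epochs, "wm_epochs"))
  if (length(eog) < 2) stop("need at least 2 EOG channels")
  ch_eeg <- setdiff(epochs$channel_names, eog)
  d <- dim(epochs$data)
  if (d[1] * d[3] <= length(ch_eeg))
    stop("need more trials x samples than channels")
  ie <- match(ch_eeg, epochs$channel_names)
  io <- match(eog, epochs$channel_names)
  # concatenate epochs: channels x (trials * samples)
  X <- matrix(aperm(epochs$data[, ie, , drop = FALSE], c(2, 1, 3)),
              nrow = length(ie))
  O <- matrix(aperm(epochs$data[, io, , drop = FALSE], c(2, 1, 3)),
              nrow = length(io))
  mu <- rowMeans(X)
  Xc <- X - mu
  if (is.null(n_comp)) n_comp <- length(ch_eeg)
  sub <- if (ncol(Xc) > max_samples)
    seq(1, ncol(Xc), length.out = max_samples) else seq_len(ncol(Xc))
  sub <- unique(round(sub))
  W <- NULL
  with_local_seed(seed, {
    for (r in seq_len(max_retries)) {
      W <- fastica_unmix(Xc[, sub, drop = FALSE], n_comp)
      if (!is.null(W)) break
    }
  })
  if (is.null(W)) stop("FastICA failed to converge after ", max_retries, " restarts")
  S <- W %*% Xc
  cors <- apply(abs(cor(t(S), t(O))), 1, max)
  bad <- which(cors > corr_threshold)
  message(length(bad), " ocular component(s) removed (|r| > ",
          corr_threshold, ")")
  if (length(bad)) {
    A <- MASS_ginv(W)
    Xclean <- Xc - A[, bad, drop = FALSE] %*% S[bad, , drop = FALSE] + mu
    arr <- array(Xclean, c(length(ie), d[1], d[3]))
    epochs$data[, ie, ] <- aperm(arr, c(2, 1, 3))
    # re-demean each trial/channel after component subtraction
    for (i in seq_len(d[1]))
      epochs$data[i, , ] <- epochs$data[i, , ] - rowMeans(epochs$data[i, , ])
  }
  attr(epochs, "n_removed") <- length(bad)
  epochs
}

# Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency for one call).
MASS_ginv <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Reject trials by peak-to-peak amplitude
#'
#' A deterministic stand-in for visual inspection: any trial whose
#' peak-to-peak amplitude on any EEG (non-ocular) channel exceeds
#' `amp_threshold` is flagged in `rejected` and excluded downstream.
#'
#' @param epochs a `wm_epochs` object.
#' @param amp_threshold peak-to-peak threshold in microvolt (default 200).
#' @return The `wm_epochs` with an updated rejection mask.
#' @export
reject_artifact_trials <- function(epochs, amp_threshold = 200) {
  stopifnot(inherits(epochs, "wm_epochs"), amp_threshold > 0)
  ie <- match(setdiff(epochs$channel_names, epochs$eog_channels),
              epochs$channel_names)
  n_tr <- dim(epochs$data)[1]
  p2p <- vapply(seq_len(n_tr), function(i) {
    seg <- epochs$data[i, ie, , drop = FALSE]
    max(apply(seg[1, , , drop = TRUE], 1, function(v) diff(range(v))))
  }, numeric(1))
  epochs$rejected <- epochs$rejected | (p2p > amp_threshold)
  if (all(epochs$rejected))
    stop("all trials rejected at threshold ", amp_threshold, " µV")
  message(sum(!epochs$rejected), " of ", n_tr, " trials retained")
  epochs
}

#' Drop rejected trials from an epochs object
#' @param epochs a `wm_epochs` object.
#' @return The `wm_epochs` containing only retained trials.
#' @export
drop_rejected <- function(epochs) {
  keep <- !epochs$rejected
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_ids <- epochs$trial_ids[keep]
  epochs$rejected <- epochs$rejected[keep]
  epochs
}
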