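# Fixture builders used across the suite. Everything is generated in code.

# A wm_tfr built directly from a power array (trials x channels x freqs x
# times), bypassing the spectrogram, for testing algebraic identities.
make_tfr <- function(power, freqs, times, channels,
                     normalized = FALSE, subject = 1L, icf = NA_real_) {
  dimnames(power) <- list(NULL, channels, freqs, NULL)
  structure(list(power = power, freqs = freqs, times = times,
                 channel_names = channels,
                 trial_ids = seq_len(dim(power)[1]),
                 normalized = normalized, baseline = NULL,
                 subject = subject, icf = icf),
            class = "wm_tfr")
}

# A wm_epochs built directly from a data array (trials x channels x samples).
make_epochs <- function(data, sfreq, tmin = -1, channels = NULL,
                        eog = character(0)) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data,
                 times = tmin + (seq_len(dim(data)[3]) - 1) / sfreq,
                 trial_ids = seq_len(dim(data)[1]),
                 channel_names = channels, sfreq = sfreq,
                 eog_channels = eog,
                 rejected = rep(FALSE, dim(data)[1]),
                 subject = 1L, icf = NA_real_),
            class = "wm_epochs")
}

# A wm_raw from a signal matrix and event samples.
make_raw <- function(signal, sfreq, events, channels = NULL,
                     eog = character(0)) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(signal)))
  rownames(signal) <- channels
  structure(list(signal = signal, channel_names = channels, sfreq = sfreq,
                 events = data.frame(sample = as.integer(events),
                                     marker = "S  1",
                                     trial_id = seq_along(events)),
                 eog_channels = eog, subject = 1L, icf = NA_real_),
            class = "wm_raw")
}

# Per-subject condition-mean arrays (channels x freqs x times) of pure
# noise, optionally with an additive effect inside a box.
noise_means <- function(n_sub, channels, freqs, times, sd = 1,
                        effect = 0, box = NULL) {
  lapply(seq_len(n_sub), function(s) {
    a <- array(rnorm(length(channels) * length(freqs) * length(times),
                     sd = sd),
               c(length(channels), length(freqs), length(times)),
               dimnames = list(channels, as.character(freqs),
                               as.character(round(times, 6))))
    if (effect != 0 && !is.null(box))
      a[box$ch, box$f, box$t] <- a[box$ch, box$f, box$t] + effect
    a
  })
}

# A quiet single-subject analysis: generate, epoch, spectrogram, normalise.
quiet_subject_tfr <- function(cfg, subject,
                              channels = c("O1", "Oz", "O2", "P3", "P4",
                                           "P7", "P8")) {
  beh <- generate_behavior(cfg, subject)
  rec <- generate_recording(cfg, beh, subject)
  ep <- epoch_and_demean(rec)
  list(behavior = beh, recording = rec,
       tfr = baseline_normalize(compute_tfr(ep, channels = channels)))
}

# Exact two-sided signed-rank p by enumeration of all sign assignments.
exact_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- as.vector(signs %*% r)
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-12)
}

# Exact Friedman p by enumeration of independent within-subject rank orders
# (no ties assumed in the observed data).
exact_friedman_p <- function(x) {
  n <- nrow(x); k <- ncol(x)
  obs <- friedman.test(as.matrix(x))$statistic
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- as.matrix(expand.grid(rep(list(1:6), n)))
  stat <- apply(idx, 1, function(sel) {
    R <- colSums(perms[sel, , drop = FALSE])
    12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  })
  mean(stat >= obs - 1e-12)
}
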