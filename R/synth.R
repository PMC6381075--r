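#' Configuration for the synthetic VWM-EEG cohort generator
#'
#' Defines the study conditions emulated by the generator: a sequential
#' visual recognition task (fixation 1.25 +/- 0.25 s, four 0.25 s stimuli,
#' retention 1.25 +/- 0.25 s, probe response within 4 s) with three
#' behavioural outcomes plus unanswered trials, occipital theta bursts during
#' encoding whose amplitude depends on the trial outcome, subject-specific
#' alpha-beta bursts (individual central frequency, ICF) over right
#' parieto-occipital channels during the second half of retention, 1/f
#' background activity, and stereotyped ocular (blink) artifacts.
#'
#' Condition probabilities default to the observed cohort rates
#' (correct 51.10, false memory 9.75, error 38.18, unanswered 0.97 percent).
#' Response-time distributions are shifted lognormals whose defaults
#' approximate the observed per-condition medians and interquartile ranges
#' (1.145, 1.176 and 1.330 s for correct, false memory and error).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_trials trials per subject (task length is 216).
#' @param sampling_rate sampling rate in Hz, >= 250.
#' @param channels channel labels; must contain O1, Oz, O2, P3, P4, P7, P8,
#'   Fz and two ocular channels (VEOG, HEOG).
#' @param condition_probs named probabilities over
#'   `c("correct", "false_memory", "error", "unanswered")`; must sum to 1.
#' @param rt_params named list per answered condition with elements
#'   `shift`, `meanlog`, `sdlog` of a shifted lognormal on (0, 4] s.
#' @param theta_burst list: `freq` (Hz, in \[6, 8\]), `window` (s, within the
#'   encoding interval, relative to first-stimulus onset), `amp` (named
#'   per-condition amplitude, microvolt), `channels`, `weights`.
#' @param icf_burst list: `window` (s, within retention), `amp` (named
#'   per-condition amplitude, microvolt), `channels`/`weights` for the right
#'   hemisphere and `contra_channels`/`contra_weight` for the attenuated
#'   left-hemisphere counterpart. Subject ICFs are drawn uniformly from the
#'   even frequencies in \[10, 26\] Hz (the 2 Hz analysis grid).
#' @param alpha_bg list describing the ongoing posterior alpha rhythm that
#'   desynchronizes on visual input: `freq` (centre, Hz), `bw` (full
#'   bandwidth, Hz — posterior alpha is narrowband noise, not a line),
#'   `amp` (RMS microvolt), `channels`, `suppression` (fractional amplitude
#'   reduction during the encoding interval) and `window` (s, the
#'   suppressed interval relative to first-stimulus onset). This produces
#'   the canonical encoding pattern of an alpha power decrease alongside
#'   the theta increase.
#' @param noise list: `exponent` of the 1/f amplitude spectrum, `rms` total
#'   root-mean-square per channel (microvolt), `am_depth`, the depth of the
#'   slow log-normal amplitude modulation that gives the background its
#'   waxing-and-waning, super-Gaussian character (0 disables it), and
#'   `artifact_prob`, the per-trial probability of a large residual
#'   (non-ocular) artifact used to emulate trials that fail visual
#'   inspection.
#' @param eog list: blink `rate` (Hz), blink `amp` on the vertical ocular
#'   channel (microvolt), and `lambda`, the spatial decay constant of the
#'   blink propagation weights over the scalp.
#' @param serial_recog per-position recognition probabilities for the four
#'   encoded items; the fourth (recency) position defaults to the highest.
#' @param seed integer master seed; all per-subject draws derive from it.
#' @return A validated list of class `wm_synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 2, n_trials = 20)
#' cfg$condition_probs
synth_config <- function(n_subjects = 10,
                         n_trials = 216,
                         sampling_rate = 250,
                         channels = default_channels(),
                         condition_probs = c(correct = 0.5110,
                                             false_memory = 0.0975,
                                             error = 0.3818,
                                             unanswered = 0.0097),
                         rt_params = list(
                           correct = c(shift = 0.3, meanlog = log(0.845), sdlog = 0.300),
                           false_memory = c(shift = 0.3, meanlog = log(0.876), sdlog = 0.380),
                           error = c(shift = 0.3, meanlog = log(1.030), sdlog = 0.392)),
                         theta_burst = list(
                           freq = 7, window = c(0.30, 0.70),
                           amp = c(correct = 4, false_memory = 4, error = 7, unanswered = 4),
                           channels = c("O1", "Oz", "O2"),
                           weights = c(0.9, 1, 0.9)),
                         icf_burst = list(
                           window = c(1.50, 2.00),
                           amp = c(correct = 3, false_memory = 5.5, error = 5.5, unanswered = 3),
                           channels = c("P4", "P8", "O2"),
                           weights = c(1, 0.9, 0.9),
                           contra_channels = c("P3", "P7", "O1"),
                           contra_weight = 0.25),
                         alpha_bg = list(freq = 10, bw = 3, amp = 2.5,
                                         channels = c("O1", "Oz", "O2",
                                                      "P3", "P4", "P7", "P8"),
                                         suppression = 0.7,
                                         window = c(0, 1)),
                         noise = list(exponent = 1, rms = 10, am_depth = 0.5,
                                      artifact_prob = 0.065),
                         eog = list(rate = 0.2, amp = 250, lambda = 0.4),
                         serial_recog = c(0.656, 0.656, 0.678, 0.9255),
                         seed = 1L) {
  conds <- c("correct", "false_memory", "error", "unanswered")
  condition_probs <- condition_probs[conds]
  if (anyNA(condition_probs))
    stop("condition_probs must be named over ", paste(conds, collapse = ", "))
  if (any(condition_probs < 0) || abs(sum(condition_probs) - 1) > 1e-9)
    stop("condition_probs must be non-negative and sum to 1")
  if (sampling_rate < 250) stop("sampling_rate must be >= 250 Hz")
  required <- c("O1", "Oz", "O2", "P3", "P4", "P7", "P8", "Fz", "VEOG", "HEOG")
  if (!all(required %in% channels))
    stop("channel layout must contain ", paste(required, collapse = ", "))
  if (theta_burst$freq < 6 || theta_burst$freq > 8)
    stop("theta burst centre frequency must lie in [6, 8] Hz")
  if (any(theta_burst$amp < 0) || any(icf_burst$amp < 0))
    stop("burst amplitudes must be non-negative")
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_trials = as.integer(n_trials),
              sampling_rate = sampling_rate,
              channels = channels,
              condition_probs = condition_probs,
              rt_params = rt_params,
              theta_burst = theta_burst,
              icf_burst = icf_burst,
              alpha_bg = alpha_bg,
              noise = noise, eog = eog,
              serial_recog = serial_recog,
              seed = as.integer(seed))
  class(cfg) <- "wm_synth_config"
  cfg
}

conditions_all <- function() c("correct", "false_memory", "error", "unanswered")

#' Condition label implied by a (probe type, response) pair
#'
#' The task shows two probes; responses classify both as old/new. A trial is
#' *correct* when both probes are classified correctly, *false memory* when a
#' lure is accepted as old while the accompanying target is also recognised,
#' *error* for every other answered combination, and *unanswered* when no
#' response was given.
#'
#' @param probe_type one of `"target_target"`, `"target_lure"`,
#'   `"lure_target"` (order is upper slot, lower slot).
#' @param response one of `"old_old"`, `"old_new"`, `"new_old"`,
#'   `"new_new"`, `"none"`. Vectorised over both arguments.
#' @return Character vector of condition labels.
#' @export
#' @examples
#' derive_condition("target_lure", "old_old")   # lure accepted -> false memory
#' derive_condition("target_target", "old_old") # both targets -> correct
derive_condition <- function(probe_type, response) {
  stopifnot(length(probe_type) == length(response) || length(probe_type) == 1 ||
              length(response) == 1)
  map1 <- function(pt, rs) {
    if (!pt %in% c("target_target", "target_lure", "lure_target"))
      stop("unknown probe_type: ", pt)
    if (!rs %in% c("old_old", "old_new", "new_old", "new_new", "none"))
      stop("unknown response: ", rs)
    if (rs == "none") return("unanswered")
    correct <- switch(pt, target_target = "old_old",
                      target_lure = "old_new", lure_target = "new_old")
    if (rs == correct) return("correct")
    if (rs == "old_old" && pt != "target_target") return("false_memory")
    "error"
  }
  mapply(map1, probe_type, response, USE.NAMES = FALSE)
}

rt_draw <- function(n, par) {
  rt <- par[["shift"]] + rlnorm(n, par[["meanlog"]], par[["sdlog"]])
  # the task allows at most 4 s to answer
  bad <- rt > 4
  tries <- 0
  while (any(bad) && tries < 20) {
    rt[bad] <- par[["shift"]] + rlnorm(sum(bad), par[["meanlog"]], par[["sdlog"]])
    bad <- rt > 4
    tries <- tries + 1
  }
  pmin(rt, 4)
}

#' Generate a per-trial behaviour table for one synthetic subject
#'
#' Trial conditions are drawn independently from the configured condition
#' probabilities; probe types are balanced across the three probe layouts
#' (with lure-containing probes reserved first for false-memory trials);
#' responses are drawn among the combinations consistent with the condition;
#' response times come from per-condition shifted lognormals (errors
#' stochastically slower). Per encoded item, a recognised flag with a recency
#' boost on the fourth serial position is recorded for the probed positions.
#'
#' Deterministic given `(cfg$seed, subject)`.
#'
#' @param cfg a [synth_config()].
#' @param subject subject index (1-based).
#' @return A `data.frame` of class `wm_behavior` with columns `trial_id`,
#'   `probe_type`, `response`, `rt_s`, `condition` and serial-recognition
#'   columns `sp1`..`sp4` (1 recognised, 0 not, NA not probed).
#' @export
#' @examples
#' beh <- generate_behavior(synth_config(n_trials = 12, seed = 2), subject = 1)
#' table(beh$condition)
generate_behavior <- function(cfg, subject) {
  stopifnot(inherits(cfg, "wm_synth_config"))
  n <- cfg$n_trials
  with_local_seed(subject_seed(cfg$seed, subject, 1L), {
    cond <- sample(conditions_all(), n, replace = TRUE, prob = cfg$condition_probs)

    # balanced probe pool; false-memory trials need a lure probe
    types <- c("target_target", "target_lure", "lure_target")
    pool <- sample(rep(types, length.out = n))
    probe <- character(n)
    fm <- which(cond == "false_memory")
    lure_slots <- which(pool != "target_target")
    if (length(fm) > length(lure_slots)) {
      # extremely lopsided configs: convert as many slots as needed
      extra <- setdiff(seq_len(n), lure_slots)[seq_len(length(fm) - length(lure_slots))]
      pool[extra] <- "target_lure"
      lure_slots <- which(pool != "target_target")
    }
    take <- lure_slots[seq_along(fm)]
    probe[fm] <- pool[take]
    probe[-fm] <- if (length(fm)) pool[-take] else pool
    if (!length(fm)) probe <- pool

    resp <- character(n)
    for (i in seq_len(n)) {
      resp[i] <- switch(cond[i],
        correct = switch(probe[i], target_target = "old_old",
                         target_lure = "old_new", lure_target = "new_old"),
        false_memory = "old_old",
        unanswered = "none",
        error = {
          opts <- setdiff(c("old_old", "old_new", "new_old", "new_new"),
                          switch(probe[i], target_target = "old_old",
                                 target_lure = "old_new", lure_target = "new_old"))
          if (probe[i] != "target_target") opts <- setdiff(opts, "old_old")
          sample(opts, 1)
        })
    }

    rt <- rep(NA_real_, n)
    for (cd in names(cfg$rt_params)) {
      k <- which(cond == cd)
      if (length(k)) rt[k] <- rt_draw(length(k), cfg$rt_params[[cd]])
    }

    sp <- matrix(NA_real_, n, 4, dimnames = list(NULL, paste0("sp", 1:4)))
    for (i in seq_len(n)) {
      n_probed <- if (probe[i] == "target_target") 2L else 1L
      pos <- sample(1:4, n_probed)
      sp[i, pos] <- as.numeric(runif(n_probed) < cfg$serial_recog[pos])
    }

    beh <- data.frame(trial_id = seq_len(n), probe_type = probe,
                      response = resp, rt_s = rt, condition = cond,
                      stringsAsFactors = FALSE)
    beh <- cbind(beh, as.data.frame(sp))
    stopifnot(identical(derive_condition(beh$probe_type, beh$response),
                        beh$condition))
    class(beh) <- c("wm_behavior", class(beh))
    attr(beh, "subject") <- as.integer(subject)
    beh
  })
}

#' Ground-truth individual central frequency of a synthetic subject
#'
#' Drawn uniformly from the even frequencies in \[10, 26\] Hz, matching the
#' 2 Hz analysis grid; deterministic given `(cfg$seed, subject)`.
#' @param cfg a [synth_config()].
#' @param subject subject index.
#' @return ICF in Hz.
#' @export
subject_icf <- function(cfg, subject) {
  with_local_seed(subject_seed(cfg$seed, subject, 2L),
                  sample(seq(10, 26, by = 2), 1))
}

hann_env <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

# flat-topped taper (Tukey): cosine ramps over a fraction `r` at each end;
# keeps the burst narrowband while still avoiding edge splatter
tukey_env <- function(n, r = 0.2) {
  x <- (seq_len(n) - 1) / (n - 1)
  env <- rep(1, n)
  lo <- x < r / 2
  hi <- x > 1 - r / 2
  env[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / r - 1)))
  env[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / r + 1)))
  env
}

pink_noise <- function(n, exponent, fs) {
  # shape white Gaussian noise in the frequency domain by f^(-exponent/2);
  # synthesis happens at a 2-3-5-smooth length (fast FFT), then truncates
  m <- stats::nextn(n, c(2, 3, 5))
  nf <- m %/% 2
  f <- seq_len(nf) * fs / m
  amp <- f^(-exponent / 2)
  spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  full <- complex(length.out = m)
  full[2:(nf + 1)] <- spec
  full[m:(m - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  Re(fft(full, inverse = TRUE))[seq_len(n)] / m
}

# narrowband Gaussian process: white noise shaped by a Gaussian spectral
# window centred on `freq` with full bandwidth `bw` (at ~2 sigma)
narrowband_noise <- function(n, freq, bw, fs) {
  m <- stats::nextn(n, c(2, 3, 5))
  nf <- m %/% 2
  f <- seq_len(nf) * fs / m
  amp <- exp(-((f - freq) / (bw / 2))^2)
  spec <- complex(real = rnorm(nf), imaginary = rnorm(nf)) * amp
  full <- complex(length.out = m)
  full[2:(nf + 1)] <- spec
  full[m:(m - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(fft(full, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

# slow (~0.5 Hz) log-normal amplitude envelope; real EEG background waxes
# and wanes, which also makes it non-Gaussian (identifiable by ICA)
am_envelope <- function(n, fs, depth) {
  if (depth <= 0) return(rep(1, n))
  knots <- max(3, ceiling(n / fs / 2) + 1)
  z <- rnorm(knots)
  env <- approx(seq(0, 1, length.out = knots), z,
                xout = seq(0, 1, length.out = n))$y
  exp(depth * env)
}

blink_template <- function(fs) {
  # stereotyped 300 ms biphasic deflection
  n <- round(0.3 * fs)
  t <- seq_len(n) / n
  main <- sin(pi * t)^2
  rebound <- -0.25 * sin(2 * pi * t) * (t > 0.5)
  main + rebound
}

#' Generate a continuous synthetic EEG recording for one subject
#'
#' The signal is 1/f background noise plus, per trial: a Hanning-tapered
#' theta burst over the occipital channels during encoding whose amplitude
#' follows the trial condition; a Hanning-tapered sinusoidal burst at the
#' subject's ICF over right parieto-occipital channels (with an attenuated
#' left-hemisphere counterpart) during the second half of retention, again
#' condition-dependent; Poisson-arriving blink artifacts written undiluted to
#' the ocular channels and propagated to the scalp with distance-decaying
#' weights; and occasional large residual artifacts emulating trials that
#' would fail visual inspection. Event markers are placed at each
#' first-stimulus onset.
#'
#' @param cfg a [synth_config()].
#' @param behavior the matching [generate_behavior()] table.
#' @param subject subject index.
#' @return A `wm_raw` object: list with `signal` (channels x samples matrix,
#'   microvolt), `channel_names`, `sfreq`, `events` (data.frame `sample`,
#'   `marker`, `trial_id`), `eog_channels`, `subject`, and the ground-truth
#'   `icf`.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 1, n_trials = 4, seed = 3)
#' rec <- generate_recording(cfg, generate_behavior(cfg, 1), 1)
#' dim(rec$signal); rec$events$sample
generate_recording <- function(cfg, behavior, subject) {
  stopifnot(inherits(cfg, "wm_synth_config"))
  if (nrow(behavior) != cfg$n_trials)
    stop("behavior table has ", nrow(behavior), " trials; config expects ",
         cfg$n_trials)
  fs <- cfg$sampling_rate
  n_tr <- cfg$n_trials
  icf <- subject_icf(cfg, subject)

  with_local_seed(subject_seed(cfg$seed, subject, 3L), {
    fix <- runif(n_tr, 1.0, 1.5)
    ret <- runif(n_tr, 1.0, 1.5)
    probe <- ifelse(is.na(behavior$rt_s), 4, behavior$rt_s) + 0.5
    # fixation | 4 x 0.25 s encoding | retention | probe + feedback
    dur <- fix + 1.0 + ret + probe
    onset_in_trial <- fix
    start <- cumsum(c(1.0, dur[-n_tr]))          # 1 s lead-in
    events <- round((start + onset_in_trial) * fs)
    n_samp <- ceiling((sum(dur) + 2.5) * fs)

    n_ch <- length(cfg$channels)
    sig <- matrix(0, n_ch, n_samp, dimnames = list(cfg$channels, NULL))
    if (cfg$noise$rms > 0) {
      am <- if (is.null(cfg$noise$am_depth)) 0.5 else cfg$noise$am_depth
      for (ch in seq_len(n_ch)) {
        x <- pink_noise(n_samp, cfg$noise$exponent, fs)
        x <- x * am_envelope(n_samp, fs, am)
        sig[ch, ] <- x * (cfg$noise$rms / sd(x))
      }
    }

    add_burst <- function(trial, window, freq, amp, channels, weights,
                          env = hann_env) {
      if (amp <= 0) return()
      i0 <- events[trial] + round(window[1] * fs)
      len <- round((window[2] - window[1]) * fs)
      idx <- i0 + seq_len(len)
      tone <- sin(2 * pi * freq * seq_len(len) / fs + runif(1, 0, 2 * pi))
      wave <- amp * env(len) * tone
      for (k in seq_along(channels)) {
        ci <- match(channels[k], cfg$channels)
        sig[ci, idx] <<- sig[ci, idx] + weights[k] * wave
      }
    }

    for (i in seq_len(n_tr)) {
      cd <- behavior$condition[i]
      add_burst(i, cfg$theta_burst$window, cfg$theta_burst$freq,
                cfg$theta_burst$amp[[cd]], cfg$theta_burst$channels,
                cfg$theta_burst$weights)
      add_burst(i, cfg$icf_burst$window, icf,
                cfg$icf_burst$amp[[cd]], cfg$icf_burst$channels,
                cfg$icf_burst$weights, env = tukey_env)
      add_burst(i, cfg$icf_burst$window, icf,
                cfg$icf_burst$amp[[cd]] * cfg$icf_burst$contra_weight,
                cfg$icf_burst$contra_channels,
                rep(1, length(cfg$icf_burst$contra_channels)),
                env = tukey_env)
    }

    # ongoing posterior alpha, gated down during each encoding interval
    if (!is.null(cfg$alpha_bg) && cfg$alpha_bg$amp > 0) {
      ab <- cfg$alpha_bg
      gate <- rep(1, n_samp)
      for (i in seq_len(n_tr)) {
        j0 <- events[i] + round(ab$window[1] * fs)
        j1 <- events[i] + round(ab$window[2] * fs)
        gate[max(1, j0):min(n_samp, j1)] <- 1 - ab$suppression
      }
      bw <- if (is.null(ab$bw)) 3 else ab$bw
      wave <- ab$amp * narrowband_noise(n_samp, ab$freq, bw, fs) * gate
      for (ch in ab$channels) {
        ci <- match(ch, cfg$channels)
        if (!is.na(ci)) sig[ci, ] <- sig[ci, ] + wave
      }
    }

    # blinks: full template on VEOG (0.3 on HEOG), distance-decayed on scalp
    if (cfg$eog$rate > 0 && cfg$eog$amp > 0) {
      tmpl <- blink_template(fs) * cfg$eog$amp
      n_blink <- rpois(1, cfg$eog$rate * n_samp / fs)
      pos <- montage_positions()
      w <- vapply(cfg$channels, function(ch) {
        k <- match(ch, pos$channel)
        if (is.na(k)) return(0)
        d <- sqrt((pos$x[k] - 0)^2 + (pos$y[k] - 1.1)^2)
        0.6 * exp(-d / cfg$eog$lambda)
      }, numeric(1))
      w[match(c("VEOG", "HEOG"), cfg$channels)] <- c(1, 0.3)
      if (n_blink > 0) {
        at <- sort(sample.int(n_samp - length(tmpl), n_blink))
        for (b in at) {
          idx <- b + seq_along(tmpl)
          scale <- runif(1, 0.8, 1.2)
          sig[, idx] <- sig[, idx] + outer(w, tmpl * scale)
        }
      }
    }

    # occasional large residual artifacts within the epoch window
    if (cfg$noise$artifact_prob > 0) {
      hit <- which(runif(n_tr) < cfg$noise$artifact_prob)
      for (i in hit) {
        len <- round(0.5 * fs)
        i0 <- events[i] + round(runif(1, -0.5, 1.5) * fs)
        idx <- i0 + seq_len(len)
        ch <- sample(which(!cfg$channels %in% c("VEOG", "HEOG")), 1)
        sig[ch, idx] <- sig[ch, idx] + 400 * hann_env(len)
      }
    }

    rec <- list(signal = sig, channel_names = cfg$channels, sfreq = fs,
                events = data.frame(sample = as.integer(events),
                                    marker = "S  1",
                                    trial_id = seq_len(n_tr)),
                eog_channels = c("VEOG", "HEOG"),
                subject = as.integer(subject), icf = icf)
    class(rec) <- "wm_raw"
    rec
  })
}

#' @export
print.wm_raw <- function(x, ...) {
  cat(sprintf("<wm_raw> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$sfreq, nrow(x$events)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' One BrainVision triplet and one behaviour CSV per subject, plus a JSON
#' manifest listing the files, so the cohort round-trips through
#' [read_brainvision()] / [read_behavior()].
#'
#' @param recordings list of `wm_raw` objects.
#' @param behaviors list of matching behaviour tables.
#' @param path output directory (created if needed).
#' @param format BrainVision binary dialect, `"int16"` (0.1 microvolt
#'   resolution) or `"float32"`.
#' @return Invisibly, the manifest as a list.
#' @export
write_dataset <- function(recordings, behaviors, path, format = c("int16", "float32")) {
  format <- match.arg(format)
  if (length(recordings) != length(behaviors))
    stop("need one recording per behavior table")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  subjects <- list()
  for (i in seq_along(recordings)) {
    base <- sprintf("sub-%02d", i)
    write_brainvision(recordings[[i]], file.path(path, base), format = format)
    bfile <- file.path(path, paste0(base, "_behavior.csv"))
    write.csv(behaviors[[i]], bfile, row.names = FALSE)
    subjects[[i]] <- list(id = base,
                          vhdr = paste0(base, ".vhdr"),
                          behavior = paste0(base, "_behavior.csv"),
                          icf = recordings[[i]]$icf)
  }
  manifest <- list(n_subjects = length(recordings), format = format,
                   subjects = subjects)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort previously written by [write_dataset()]
#' @param path dataset directory containing `manifest.json`.
#' @return List with `recordings`, `behaviors`, `manifest`.
#' @export
read_dataset <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"))
  recs <- list(); behs <- list()
  for (i in seq_along(mf$subjects)) {
    s <- mf$subjects[[i]]
    recs[[i]] <- read_brainvision(file.path(path, s$vhdr))
    behs[[i]] <- read_behavior(file.path(path, s$behavior))
  }
  list(recordings = recs, behaviors = behs, manifest = mf)
}
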