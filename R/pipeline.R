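#' Full analysis configuration
#'
#' Aggregates every stage's settings. Defaults follow the study protocol:
#' 0.2-100 Hz 4th-order zero-phase Butterworth; 3 s epochs from -1 to 2 s
#' around the first-stimulus onset; 500 ms Hanning windows stepped by 50 ms
#' over 2-32 Hz in 2 Hz bins; baseline -1.00 to -0.30 s pooled over all
#' trials; encoding analysis on O1/Oz/O2 over theta (4-8 Hz) and alpha
#' (10-14 Hz) in (0, 1) s; retention analysis on P4/P8/O2 over
#' \[ICF - 2, ICF + 2\] Hz in (1, 2) s after ICF alignment; cluster
#' permutation with triplet alpha 0.05, 30000 permutations, 0.025 per tail,
#' Bonferroni factor 2 for the merged-condition contrasts.
#'
#' @param synth a [synth_config()] describing the cohort to simulate, or
#'   `NULL` when reading data from `data_dir`.
#' @param data_dir directory of a written dataset (see [write_dataset()]).
#' @param filter list `low`, `high`, `order`.
#' @param epoch_window c(tmin, tmax) seconds.
#' @param tfr list `window`, `step`, `freqs`, `channels` (NULL = all EEG).
#' @param baseline_window baseline interval in seconds.
#' @param reject_threshold peak-to-peak rejection threshold, microvolt.
#' @param ica list `corr_threshold`, `seed`, `enabled`.
#' @param encoding_box list `channels`, `f_lim`, `t_lim`.
#' @param retention_box list `channels`, `f_halfwidth`, `t_lim`.
#' @param icf list `channels`, `window`, `f_lim`, `ref` ("median" or a
#'   frequency on the grid), optional named `override` per subject.
#' @param cluster list `alpha_triplet`, `n_perm`, `tail_alpha`,
#'   `bonferroni_merged`, `seed`.
#' @param selection_seed seed of the trial-balancing draw.
#' @param out_dir optional output directory for JSON/CSV results.
#' @return A list of class `wm_pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            data_dir = NULL,
                            filter = list(low = 0.2, high = 100, order = 4),
                            epoch_window = c(-1, 2),
                            tfr = list(window = 0.5, step = 0.05,
                                       freqs = seq(2, 32, 2), channels = NULL),
                            baseline_window = c(-1, -0.3),
                            reject_threshold = 200,
                            ica = list(corr_threshold = 0.7, seed = 11,
                                       enabled = TRUE),
                            encoding_box = list(channels = c("O1", "Oz", "O2"),
                                                f_lim = c(4, 14),
                                                t_lim = c(0, 1)),
                            retention_box = list(channels = c("P4", "P8", "O2"),
                                                 f_halfwidth = 2,
                                                 t_lim = c(1, 2)),
                            icf = list(channels = c("P4", "P8", "O2"),
                                       window = c(1.5, 2), f_lim = c(10, 26),
                                       ref = "median", override = NULL),
                            cluster = list(alpha_triplet = 0.05,
                                           n_perm = 30000,
                                           tail_alpha = 0.025,
                                           bonferroni_merged = 2,
                                           seed = 7),
                            selection_seed = 5,
                            out_dir = NULL) {
  cfg <- list(synth = synth, data_dir = data_dir, filter = filter,
              epoch_window = epoch_window, tfr = tfr,
              baseline_window = baseline_window,
              reject_threshold = reject_threshold, ica = ica,
              encoding_box = encoding_box, retention_box = retention_box,
              icf = icf, cluster = cluster, selection_seed = selection_seed,
              out_dir = out_dir)
  class(cfg) <- "wm_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the [pipeline_config()] defaults;
#' the `synth` block, if any, is passed to [synth_config()].
#'
#' @param path YAML file.
#' @return A `wm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$synth)) args$synth <- do.call(synth_config, y$synth)
  for (f in setdiff(names(y), "synth")) args[[f]] <- y[[f]]
  do.call(pipeline_config, args)
}

config_digest <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL            # analysis parameters only, not the sink
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  unname(tools::md5sum(tf))
}

preprocess_subject <- function(rec, cfg) {
  rec <- bandpass(rec, cfg$filter$low, cfg$filter$high, cfg$filter$order)
  ep <- epoch_and_demean(rec, cfg$epoch_window[1], cfg$epoch_window[2])
  if (isTRUE(cfg$ica$enabled))
    ep <- suppressMessages(remove_ocular_ica(
      ep, corr_threshold = cfg$ica$corr_threshold, seed = cfg$ica$seed))
  suppressMessages(reject_artifact_trials(ep, cfg$reject_threshold))
}

# condition -> per-subject mean arrays for one contrast, honouring balancing
contrast_means <- function(tfrs, behaviors, cond_a, cond_b, merged_from,
                           seed, box_fun) {
  a <- list(); b <- list()
  for (s in seq_along(tfrs)) {
    beh <- behaviors[[s]]
    beh <- beh[beh$trial_id %in% tfrs[[s]]$trial_ids, , drop = FALSE]
    if (!is.null(merged_from))
      beh <- merge_conditions(beh, merged_from[1], merged_from[2])
    plan <- balance_trials(beh, cond_a, cond_b, seed = seed + s)
    if (is.null(plan)) return(NULL)
    a[[s]] <- box_fun(tfr_mean(tfrs[[s]], plan$trial_ids[[cond_a]]))
    b[[s]] <- box_fun(tfr_mean(tfrs[[s]], plan$trial_ids[[cond_b]]))
  }
  list(a = a, b = b)
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) the cohort; filter, epoch, clean and reject; compute
#' and baseline-normalise spectrograms; detect each subject's ICF; run the
#' encoding and retention cluster contrasts (correct vs error, plus both
#' merged-condition variants, Bonferroni-corrected); compute the behavioural
#' statistics and the cluster-power vs RT correlation. Deterministic under
#' the configured seeds.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print stage progress.
#' @return A list of class `wm_pipeline_result` with elements `behavior`
#'   (rates, RT tests, correlations, serial position), `icf` (table,
#'   lateralization), `clusters` (the six contrasts), `retained_trials`,
#'   `config_digest`, `config`. When `cfg$out_dir` is set, JSON/CSV results
#'   and a run log are written there.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "wm_pipeline_config"))
  digest <- config_digest(cfg)
  say <- function(...) if (verbose) message(sprintf(...))

  # ---- data ----
  if (!is.null(cfg$data_dir)) {
    say("reading dataset from %s", cfg$data_dir)
    ds <- read_dataset(cfg$data_dir)
    recs <- ds$recordings; behaviors <- ds$behaviors
  } else {
    say("simulating cohort: %d subjects x %d trials @ %g Hz",
        cfg$synth$n_subjects, cfg$synth$n_trials, cfg$synth$sampling_rate)
    recs <- list(); behaviors <- list()
    for (s in seq_len(cfg$synth$n_subjects)) {
      behaviors[[s]] <- generate_behavior(cfg$synth, s)
      recs[[s]] <- generate_recording(cfg$synth, behaviors[[s]], s)
    }
  }
  n_sub <- length(recs)

  # ---- preprocess + TFR per subject ----
  tfr_channels <- cfg$tfr$channels
  if (is.null(tfr_channels))
    tfr_channels <- unique(c(cfg$encoding_box$channels,
                             cfg$retention_box$channels,
                             cfg$icf$channels, "P3", "P7", "O1"))
  tfrs <- list(); retained <- integer(n_sub)
  for (s in seq_len(n_sub)) {
    say("subject %d/%d: preprocess + TFR", s, n_sub)
    ep <- preprocess_subject(recs[[s]], cfg)
    retained[s] <- sum(!ep$rejected)
    tf <- compute_tfr(ep, cfg$tfr$window, cfg$tfr$step, cfg$tfr$freqs,
                      channels = intersect(tfr_channels, ep$channel_names))
    tfrs[[s]] <- baseline_normalize(tf, cfg$baseline_window)
    recs[s] <- list(NULL)                      # free the raw signal
  }

  # ---- ICF ----
  icfs <- vapply(seq_len(n_sub), function(s) {
    ov <- cfg$icf$override
    if (!is.null(ov) && !is.na(ov[s])) return(ov[s])
    detect_icf(tfrs[[s]], cfg$icf$channels, cfg$icf$window,
               cfg$icf$f_lim)$icf
  }, 0)
  ref <- if (identical(cfg$icf$ref, "median")) {
    md <- median(icfs)
    # snap to the analysis grid (even number of subjects can give midpoints)
    grid <- cfg$tfr$freqs
    grid[which.min(abs(grid - md))]
  } else cfg$icf$ref
  say("ICFs: %s; reference %g Hz", paste(icfs, collapse = " "), ref)
  later <- lateralization_test(tfrs, icfs, window = cfg$icf$window)

  # ---- cluster contrasts ----
  adj <- channel_adjacency(tfrs[[1]]$channel_names)
  enc_fun <- function(m) subset_box(m, cfg$encoding_box$channels,
                                    cfg$encoding_box$f_lim,
                                    cfg$encoding_box$t_lim)
  ret_fun <- function(m) subset_box(m, cfg$retention_box$channels,
                                    c(ref - cfg$retention_box$f_halfwidth,
                                      ref + cfg$retention_box$f_halfwidth),
                                    cfg$retention_box$t_lim)
  aligned <- lapply(seq_len(n_sub), function(s)
    align_to_icf(tfrs[[s]], icfs[s], ref))

  run_contrast <- function(tfr_list, box_fun, cond_a, cond_b, merged_from,
                           bonf, label) {
    say("cluster contrast: %s", label)
    cm <- contrast_means(tfr_list, behaviors, cond_a, cond_b, merged_from,
                         cfg$selection_seed, box_fun)
    if (is.null(cm)) return(NULL)
    permutation_test(cm$a, cm$b, adjacency = adj,
                     alpha_triplet = cfg$cluster$alpha_triplet,
                     n_perm = cfg$cluster$n_perm,
                     tail_alpha = cfg$cluster$tail_alpha,
                     bonferroni = bonf, seed = cfg$cluster$seed)
  }
  bm <- cfg$cluster$bonferroni_merged
  clusters <- list(
    encoding_error_vs_correct =
      run_contrast(tfrs, enc_fun, "error", "correct", NULL, 1,
                   "encoding: error vs correct"),
    encoding_error_vs_correct_fm =
      run_contrast(tfrs, enc_fun, "error", "correct",
                   c("correct", "false_memory"), bm,
                   "encoding: error vs correct+false-memory"),
    encoding_error_fm_vs_correct =
      run_contrast(tfrs, enc_fun, "error", "correct",
                   c("error", "false_memory"), bm,
                   "encoding: error+false-memory vs correct"),
    retention_error_vs_correct =
      run_contrast(aligned, ret_fun, "error", "correct", NULL, 1,
                   "retention: error vs correct"),
    retention_error_fm_vs_correct =
      run_contrast(aligned, ret_fun, "error", "correct",
                   c("error", "false_memory"), bm,
                   "retention: error+false-memory vs correct"),
    retention_error_vs_correct_fm =
      run_contrast(aligned, ret_fun, "error", "correct",
                   c("correct", "false_memory"), bm,
                   "retention: error vs correct+false-memory"))

  # ---- behavioural statistics ----
  say("behavioural statistics")
  rates <- condition_rates(behaviors)
  med_rt <- t(vapply(behaviors, function(b) {
    vapply(c("correct", "false_memory", "error"), function(cd)
      median(b$rt_s[b$condition == cd], na.rm = TRUE), 0)
  }, numeric(3)))
  friedman <- friedman_rt(med_rt)
  posthoc <- list(
    error_vs_correct = wilcoxon_z(med_rt[, "error"], med_rt[, "correct"],
                                  correction = "Bonferroni x3 (alpha 0.017)"),
    error_vs_false_memory = wilcoxon_z(med_rt[, "error"],
                                       med_rt[, "false_memory"],
                                       correction = "Bonferroni x3 (alpha 0.017)"),
    correct_vs_false_memory = wilcoxon_z(med_rt[, "correct"],
                                         med_rt[, "false_memory"],
                                         correction = "Bonferroni x3 (alpha 0.017)"))
  rate_mat <- attr(rates, "rates")
  fm_err <- spearman_test(rate_mat[, "false_memory"], rate_mat[, "error"])
  serial <- serial_position_accuracy(behaviors)
  # the Lilliefors screen needs n >= 5 subjects to say anything
  ks_rt <- if (n_sub >= 5) ks_normality(med_rt[, "error"]) else NULL

  # ---- cluster power vs RT ----
  ret_sig <- significant_clusters(clusters$retention_error_vs_correct)
  power_rt <- NULL
  if (length(ret_sig)) {
    sub_means <- lapply(aligned, function(tf) ret_fun(tfr_mean(tf)))
    mean_rts <- vapply(behaviors, function(b) mean(b$rt_s, na.rm = TRUE), 0)
    power_rt <- power_rt_correlation(ret_sig[[1]], sub_means, mean_rts)
  } else say("no significant retention cluster; power-RT correlation skipped")

  res <- list(
    behavior = list(rates = rates, median_rt = med_rt, friedman = friedman,
                    posthoc = posthoc, fm_error_correlation = fm_err,
                    serial_position = serial, ks_rt = ks_rt,
                    power_rt = power_rt),
    icf = list(values = icfs, reference = ref, lateralization = later),
    clusters = clusters,
    retained_trials = retained,
    config_digest = digest,
    config = cfg)
  class(res) <- "wm_pipeline_result"
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

#' @export
print.wm_pipeline_result <- function(x, ...) {
  cat("<wm_pipeline_result>\n")
  cat(sprintf("  %d subjects, mean retained trials %.1f\n",
              length(x$retained_trials), mean(x$retained_trials)))
  cat(sprintf("  ICFs %s (ref %g Hz)\n",
              paste(x$icf$values, collapse = " "), x$icf$reference))
  for (nm in names(x$clusters)) {
    cl <- x$clusters[[nm]]
    if (is.null(cl)) { cat(sprintf("  %s: skipped\n", nm)); next }
    sig <- significant_clusters(cl)
    cat(sprintf("  %s: %d cluster(s), %d significant%s\n", nm,
                length(cl$clusters), length(sig),
                if (length(sig)) sprintf(" (best corrected p = %.4g)",
                                         sig[[1]]$p_corrected) else ""))
  }
  cat(sprintf("  config digest %s\n", x$config_digest))
  invisible(x)
}

cluster_summary_list <- function(cl) {
  if (is.null(cl)) return(list(skipped = TRUE))
  list(n_clusters = length(cl$clusters),
       n_perm = cl$n_perm, seed = cl$seed, bonferroni = cl$bonferroni,
       p_resolution = 1 / (cl$n_perm + !cl$exact),
       clusters = lapply(cl$clusters, function(c1)
         list(mass = c1$mass, sign = c1$sign, p = c1$p,
              p_corrected = c1$p_corrected, significant = c1$significant,
              channels = sort(unique(c1$triplets$channel)),
              f_range = range(c1$triplets$freq),
              t_range = range(c1$triplets$time))))
}

#' Persist a pipeline result as JSON + CSV files
#' @param res a `wm_pipeline_result`.
#' @param out_dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stat_to_list <- function(s) if (is.null(s)) NULL else
    list(test = s$test_name, statistic = s$statistic, df = s$df, n = s$n,
         p = s$p, effect_r = s$effect_r, correction = s$correction)
  out <- list(
    config_digest = res$config_digest,
    retained_trials = res$retained_trials,
    icf = list(values = res$icf$values, reference = res$icf$reference,
               lateralization = stat_to_list(res$icf$lateralization)),
    behavior = list(
      rates = res$behavior$rates,
      friedman = stat_to_list(res$behavior$friedman),
      posthoc = lapply(res$behavior$posthoc, stat_to_list),
      fm_error_correlation = stat_to_list(res$behavior$fm_error_correlation),
      serial_position = res$behavior$serial_position$table,
      recency = stat_to_list(res$behavior$serial_position$recency),
      ks_rt = stat_to_list(res$behavior$ks_rt),
      power_rt = stat_to_list(res$behavior$power_rt)),
    clusters = lapply(res$clusters, cluster_summary_list))
  jpath <- file.path(out_dir, "results.json")
  jsonlite::write_json(out, jpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, null = "null")
  cpath <- file.path(out_dir, "condition_rates.csv")
  write.csv(res$behavior$rates, cpath, row.names = FALSE)
  spath <- file.path(out_dir, "serial_position.csv")
  write.csv(res$behavior$serial_position$table, spath, row.names = FALSE)
  ipath <- file.path(out_dir, "icf.csv")
  write.csv(data.frame(subject = seq_along(res$icf$values),
                       icf_hz = res$icf$values), ipath, row.names = FALSE)
  invisible(c(jpath, cpath, spath, ipath))
}
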