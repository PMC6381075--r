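#' Equal-N trial balancing with response-time prioritisation
#'
#' The condition with more trials is subsampled (seeded, without replacement)
#' to match the smaller condition; trials whose RT lies within one standard
#' deviation of that condition's mean RT are drawn first, and trials outside
#' the window are used only when the in-window pool is insufficient. The
#' smaller condition is kept whole. Trials merged in from another condition
#' (a non-empty `orig_condition` differing from `condition`, see
#' [merge_conditions()]) are always retained.
#'
#' RT means and standard deviations are computed per condition on answered
#' trials only.
#'
#' @param behavior a behaviour table (post artifact rejection).
#' @param cond_a,cond_b condition labels to contrast.
#' @param seed RNG seed recorded in the plan.
#' @return A `wm_selection_plan`: list with per-arm `trial_ids`, `seed`,
#'   `n_per_arm` and per-arm counts of in-window vs out-of-window draws.
#' @export
#' @examples
#' cfg <- synth_config(n_trials = 60, seed = 4)
#' beh <- generate_behavior(cfg, 1)
#' plan <- balance_trials(beh, "correct", "error", seed = 1)
#' lengths(plan$trial_ids)
balance_trials <- function(behavior, cond_a, cond_b, seed = 1) {
  orig <- if ("orig_condition" %in% names(behavior)) behavior$orig_condition
          else behavior$condition
  arms <- list()
  for (cd in c(cond_a, cond_b)) {
    k <- behavior$condition == cd
    if (!any(k)) {
      message("condition '", cd, "' is empty; contrast skipped")
      return(NULL)
    }
    arms[[cd]] <- behavior[k, , drop = FALSE]
  }
  n_target <- min(vapply(arms, nrow, integer(1)))
  plan <- list(trial_ids = list(), seed = as.integer(seed),
               n_per_arm = n_target, priority = list())
  with_local_seed(seed, {
    for (cd in c(cond_a, cond_b)) {
      arm <- arms[[cd]]
      forced <- arm$trial_id[orig[match(arm$trial_id, behavior$trial_id)] != cd]
      if (nrow(arm) == n_target) {
        plan$trial_ids[[cd]] <- arm$trial_id
        plan$priority[[cd]] <- c(in_window = NA_integer_,
                                 out_window = NA_integer_)
        next
      }
      rt <- arm$rt_s
      mu <- mean(rt, na.rm = TRUE); sdv <- sd(rt, na.rm = TRUE)
      in_win <- !is.na(rt) & abs(rt - mu) <= sdv
      pool_forced <- arm$trial_id[arm$trial_id %in% forced]
      rest <- setdiff(arm$trial_id, pool_forced)
      in_ids <- intersect(arm$trial_id[in_win], rest)
      out_ids <- setdiff(rest, in_ids)
      need <- n_target - length(pool_forced)
      if (need < 0) stop("merged trials exceed the balanced target count")
      take_in <- if (need <= length(in_ids)) sample(in_ids, need) else in_ids
      need_out <- need - length(take_in)
      take_out <- if (need_out > 0) sample(out_ids, need_out) else integer(0)
      sel <- c(pool_forced, take_in, take_out)
      plan$trial_ids[[cd]] <- sort(sel)
      plan$priority[[cd]] <- c(in_window = length(take_in),
                               out_window = length(take_out))
    }
  })
  stopifnot(length(plan$trial_ids[[cond_a]]) == length(plan$trial_ids[[cond_b]]))
  class(plan) <- "wm_selection_plan"
  plan
}

#' @export
print.wm_selection_plan <- function(x, ...) {
  cat(sprintf("<wm_selection_plan> %d trials per arm (seed %d)\n",
              x$n_per_arm, x$seed))
  for (cd in names(x$trial_ids)) {
    pr <- x$priority[[cd]]
    cat(sprintf("  %s: %d trials (in-window %s, out-of-window %s)\n", cd,
                length(x$trial_ids[[cd]]),
                ifelse(is.na(pr[1]), "all", pr[1]),
                ifelse(is.na(pr[2]), "-", pr[2])))
  }
  invisible(x)
}

#' Merge one condition into another for a combined-condition contrast
#'
#' Trials of `added_cond` are relabelled as `base_cond` in the `condition`
#' column; the original labels are preserved in `orig_condition`, which
#' [balance_trials()] uses to guarantee that every merged-in trial is
#' retained during balancing.
#'
#' @param behavior a behaviour table.
#' @param base_cond condition receiving the merged trials.
#' @param added_cond condition being merged in (disjoint from `base_cond`).
#' @return The relabelled behaviour table with an `orig_condition` column.
#' @export
#' @examples
#' cfg <- synth_config(n_trials = 40, seed = 5)
#' beh <- merge_conditions(generate_behavior(cfg, 1), "error", "false_memory")
#' table(beh$condition, beh$orig_condition)
merge_conditions <- function(behavior, base_cond, added_cond) {
  if (base_cond == added_cond) stop("conditions must be disjoint")
  if (anyDuplicated(behavior$trial_id))
    stop("duplicate trial ids in behavior table")
  if (!"orig_condition" %in% names(behavior))
    behavior$orig_condition <- behavior$condition
  k <- behavior$condition == added_cond
  behavior$condition[k] <- base_cond
  behavior
}
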