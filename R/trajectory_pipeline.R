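# Trajectory processing: baseline-trial selection, time-normalised baselines,
# baseline subtraction and analysis-window means.
#
# Baselines are word-specific mean trajectories built from unperturbed trials,
# excluding unperturbed trials that immediately follow a perturbed trial
# (those can carry one-shot adaptive responses). Each contributing trial is
# resampled to 100 points between vowel onset and offset so trials of
# different durations average cleanly; the baseline is then stretched back to
# each trial's duration before subtraction. Trials shorter than the 400 ms
# analysis window are excluded (with bookkeeping).

#' Select trials eligible for baseline estimation
#'
#' Keeps unperturbed word trials whose immediately preceding word trial was
#' not perturbed. Sentence trials are transparent: they neither block nor
#' qualify eligibility. The first word trial (no predecessor) is eligible.
#'
#' @param trials data.frame in presentation order with a logical `perturbed`
#'   column and optionally a `kind` column (non-"word" rows are ignored).
#' @return the subset of word-trial rows eligible for baseline estimation,
#'   with an added `word_position` column (1-based position among word
#'   trials).
#' @examples
#' tr <- data.frame(perturbed = c(FALSE, FALSE, TRUE, FALSE, FALSE))
#' select_baseline_trials(tr)$word_position  # 1 2 5
#' @export
select_baseline_trials <- function(trials) {
  stopifnot(is.data.frame(trials), "perturbed" %in% names(trials))
  if ("kind" %in% names(trials))
    trials <- trials[trials$kind == "word", , drop = FALSE]
  n <- nrow(trials)
  trials$word_position <- seq_len(n)
  prev_pert <- c(FALSE, trials$perturbed[-n][seq_len(max(0, n - 1))])
  trials[!trials$perturbed & !prev_pert, , drop = FALSE]
}

#' Resample a trajectory to a fixed number of points
#'
#' Linear interpolation onto an evenly spaced grid spanning the trajectory's
#' own time range. Resampling a 100-point series to 100 points is the
#' identity.
#'
#' @param t_ms sample times, ms.
#' @param y values at `t_ms`.
#' @param n_points number of output points (default 100).
#' @return numeric vector of length `n_points`.
#' @export
resample_trajectory <- function(t_ms, y, n_points = 100L) {
  stopifnot(length(t_ms) == length(y), length(t_ms) >= 2L)
  stats::approx(t_ms, y, xout = seq(min(t_ms), max(t_ms),
                                    length.out = n_points))$y
}

#' Build a time-normalised baseline trajectory
#'
#' Each trial's onset-to-offset trajectory is linearly resampled to
#' `n_points` points and the resampled trajectories are averaged pointwise.
#'
#' @param trials list of trial trajectories, each a data.frame with columns
#'   `t_ms`, `f1`, `f2` spanning vowel onset to offset.
#' @param n_points number of normalised time points (default 100).
#' @param word optional word label, stored for bookkeeping.
#' @return an object of class `baseline_trajectory`: list with `u` (the
#'   normalised time grid in [0, 1]), `f1`, `f2`, `n_trials`, `word`.
#' @export
build_baseline <- function(trials, n_points = 100L, word = NULL) {
  if (length(trials) == 0L)
    stop_fc("no eligible baseline trials",
            if (!is.null(word)) paste0(" for word ", word) else "")
  f1 <- rowMeans(vapply(trials, function(tr)
    resample_trajectory(tr$t_ms, tr$f1, n_points), numeric(n_points)))
  f2 <- rowMeans(vapply(trials, function(tr)
    resample_trajectory(tr$t_ms, tr$f2, n_points), numeric(n_points)))
  structure(list(u = seq(0, 1, length.out = n_points), f1 = f1, f2 = f2,
                 n_trials = length(trials), word = word),
            class = "baseline_trajectory")
}

#' Subtract a time-normalised baseline from a trial
#'
#' The baseline's `n_points` points are linearly interpolated to the trial's
#' own duration (normalised time = t / duration) and subtracted samplewise;
#' the result is truncated to the first `window_len` ms after vowel onset.
#'
#' @param trial data.frame with columns `t_ms`, `f1`, `f2` (onset at 0 ms).
#' @param baseline a `baseline_trajectory`.
#' @param window_len analysis window length, ms (default 400). Trials
#'   shorter than this are rejected with an error; callers that batch trials
#'   catch it and record the exclusion.
#' @return data.frame with columns `t_ms`, `df1`, `df2` covering
#'   `[0, window_len)` ms.
#' @export
subtract_baseline <- function(trial, baseline, window_len = 400) {
  stopifnot(inherits(baseline, "baseline_trajectory"))
  dur <- max(trial$t_ms)
  if (dur < window_len)
    stop_fc("trial duration ", dur, " ms < ", window_len,
            " ms analysis window")
  u <- trial$t_ms / dur
  b1 <- stats::approx(baseline$u, baseline$f1, xout = u)$y
  b2 <- stats::approx(baseline$u, baseline$f2, xout = u)$y
  keep <- trial$t_ms < window_len
  data.frame(t_ms = trial$t_ms[keep],
             df1 = (trial$f1 - b1)[keep],
             df2 = (trial$f2 - b2)[keep])
}

#' Mean formant change over an analysis window
#'
#' Arithmetic mean over samples with `t0 <= t_ms < t1` (half-open window;
#' sample timestamps are left edges).
#'
#' @param change data.frame with columns `t_ms`, `df1`, `df2` (or `f1`,
#'   `f2`).
#' @param window c(t0, t1) in ms.
#' @return named vector c(f1, f2) of window means, Hz.
#' @export
window_mean <- function(change, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  vcols <- intersect(c("df1", "df2", "f1", "f2"), names(change))
  if (length(vcols) != 2L)
    stop_fc("change table must have columns df1/df2 (or f1/f2)")
  sel <- change$t_ms >= window[1] & change$t_ms < window[2]
  if (!any(sel))
    stop_fc("no samples in window [", window[1], ", ", window[2], ") ms")
  c(f1 = mean(change[[vcols[1]]][sel]), f2 = mean(change[[vcols[2]]][sel]))
}

#' Process a session: baselines, subtraction, exclusions
#'
#' Runs the trajectory pipeline over a simulated (or ingested) session:
#' selects baseline-eligible unperturbed trials, builds the word-specific
#' time-normalised baselines, subtracts the stretched baseline from every
#' word trial, truncates to the first `window_len` ms, and excludes trials
#' shorter than `window_len` ms.
#'
#' @param session a `session_data` from [simulate_session()], or a list with
#'   `trajectories` (long data.frame `block`, `index`, `t_ms`, `f1`, `f2`)
#'   and `meta` (per word trial: `block`, `index`, `word`, `perturbed`,
#'   `duration`).
#' @param n_points baseline resolution (default 100).
#' @param window_len analysis window length, ms (default 400).
#' @return an object of class `processed_session`: list with `changes` (long
#'   data.frame `block`, `index`, `t_ms`, `df1`, `df2` for kept trials),
#'   `meta` (word-trial metadata with logical `kept`), `baselines` (per
#'   word), `n_excluded` and `exclusion_fraction`.
#' @export
process_session <- function(session, n_points = 100L, window_len = 400) {
  meta <- session$meta
  traj <- session$trajectories
  key <- function(b, i) paste(b, i, sep = ".")
  split_traj <- split(traj[c("t_ms", "f1", "f2")],
                      factor(key(traj$block, traj$index),
                             levels = key(meta$block, meta$index)))
  elig <- select_baseline_trials(meta)
  wds <- unique(meta$word)
  baselines <- lapply(stats::setNames(wds, wds), function(w) {
    sel <- key(elig$block, elig$index)[elig$word == w]
    build_baseline(split_traj[sel], n_points = n_points, word = w)
  })
  kept <- logical(nrow(meta))
  changes <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    tr <- split_traj[[key(meta$block[i], meta$index[i])]]
    if (max(tr$t_ms) < window_len) next
    changes[[i]] <- subtract_baseline(tr, baselines[[meta$word[i]]],
                                      window_len = window_len)
    kept[i] <- TRUE
  }
  meta$kept <- kept
  lens <- vapply(changes[kept], nrow, integer(1))
  change_df <- data.frame(
    block = rep(meta$block[kept], lens),
    index = rep(meta$index[kept], lens),
    t_ms = unlist(lapply(changes[kept], `[[`, "t_ms")),
    df1 = unlist(lapply(changes[kept], `[[`, "df1")),
    df2 = unlist(lapply(changes[kept], `[[`, "df2")))
  structure(list(changes = change_df,
                 meta = meta, baselines = baselines,
                 n_excluded = sum(!kept),
                 exclusion_fraction = mean(!kept)),
            class = "processed_session")
}

#' @export
print.processed_session <- function(x, ...) {
  cat(sprintf("Processed session: %d word trials kept, %d excluded (%.1f%%)\n",
              sum(x$meta$kept), x$n_excluded, 100 * x$exclusion_fraction))
  invisible(x)
}
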