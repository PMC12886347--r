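# Corrective and adaptive responses, normalised amplitudes, and response
# angles relative to the participant-specific eh-to-ih axis.
#
# Corrective response (within a perturbed trial): mean formant change in the
# late window (300-400 ms) minus the early window (0-100 ms). Adaptive
# response (between trials): early-window change of the unperturbed trial
# after a perturbed trial minus that of the unperturbed trial before it.
# Amplitudes are normalised by the Euclidean perturbation magnitude of the
# trial's condition (the same scalar for both formants, so angles are
# unaffected); angles are computed on the Hz responses and referenced to the
# eh-to-ih angle.

EARLY_WINDOW <- c(0, 100)
LATE_WINDOW <- c(300, 400)

#' Corrective response of a perturbed trial
#'
#' Late-window mean minus early-window mean of the baseline-subtracted
#' formant-change trajectory, per formant.
#'
#' @param change data.frame `t_ms`, `df1`, `df2` covering [0, 400) ms.
#' @param early,late analysis windows in ms (defaults c(0, 100) and
#'   c(300, 400), half-open).
#' @return named vector c(f1, f2), Hz.
#' @export
corrective_response <- function(change, early = EARLY_WINDOW,
                                late = LATE_WINDOW) {
  window_mean(change, late) - window_mean(change, early)
}

#' Adaptive (one-shot) response around a perturbed trial
#'
#' Early-window mean of the unperturbed trial after the perturbation minus
#' the early-window mean of the unperturbed trial before it.
#'
#' @param pre_change,post_change formant-change trajectories (data.frames
#'   `t_ms`, `df1`, `df2`) of the flanking unperturbed trials.
#' @param early early window in ms (default c(0, 100)).
#' @return named vector c(f1, f2), Hz.
#' @export
adaptive_response <- function(pre_change, post_change,
                              early = EARLY_WINDOW) {
  window_mean(post_change, early) - window_mean(pre_change, early)
}

#' Normalise a response and compute its relative angle
#'
#' @param resp named vector c(f1, f2): a corrective or adaptive response in
#'   Hz.
#' @param config the trial's `perturbation_config` (supplies the Euclidean
#'   magnitude used as the normalisation denominator).
#' @param space the participant's `vowel_space` (supplies the eh-to-ih
#'   angle).
#' @return list with `f1_hz`, `f2_hz`, `f1_pct`, `f2_pct` (percent of the
#'   perturbation magnitude) and `rel_angle` (degrees in (-180, 180],
#'   relative to the eh-to-ih angle; `NA` for a zero response vector).
#' @export
normalize_and_angle <- function(resp, config, space) {
  stopifnot(inherits(config, "perturbation_config"),
            inherits(space, "vowel_space"))
  if (config$magnitude_hz <= 0) stop_fc("perturbation magnitude must be > 0")
  rel <- if (all(resp == 0)) NA_real_ else
    wrap_angle(planar_angle(resp[1], resp[2]) - space$eps_ih_angle)
  list(f1_hz = unname(resp[1]), f2_hz = unname(resp[2]),
       f1_pct = unname(100 * resp[1] / config$magnitude_hz),
       f2_pct = unname(100 * resp[2] / config$magnitude_hz),
       rel_angle = unname(rel))
}

#' Condition-average response angle
#'
#' Averages the Hz response vectors first and takes the angle of the mean
#' vector (vector-average-then-angle, not mean-of-angles), relative to the
#' eh-to-ih angle.
#'
#' @param f1_hz,f2_hz per-trial response components, Hz.
#' @param eps_ih_angle the participant's eh-to-ih angle, degrees.
#' @return relative angle in degrees, or `NA` if the mean vector is zero.
#' @export
condition_average_angle <- function(f1_hz, f2_hz, eps_ih_angle) {
  m1 <- mean(f1_hz)
  m2 <- mean(f2_hz)
  if (m1 == 0 && m2 == 0) return(NA_real_)
  wrap_angle(planar_angle(m1, m2) - eps_ih_angle)
}

#' Compute the per-trial response table for a processed session
#'
#' For every kept perturbed trial, a `corrective` row. For every perturbed
#' trial whose flanking unperturbed word trials (the immediately preceding
#' and following word trials within the same block) were both kept, an
#' `adaptive` row; triads broken by exclusions or block boundaries are
#' skipped and counted.
#'
#' @param processed a `processed_session` from [process_session()].
#' @param session the originating `session_data` (supplies the vowel space
#'   and perturbation configs).
#' @return an object of class `response_table`: data.frame with one row per
#'   trial x response kind (`block`, `index`, `kind`, `direction`,
#'   `magnitude_scale`, `f1_hz`, `f2_hz`, `f1_pct`, `f2_pct`, `rel_angle`)
#'   with attribute `n_skipped_triads`.
#' @export
compute_responses <- function(processed, session) {
  meta <- processed$meta
  changes <- processed$changes
  space <- session$space
  configs <- session$configs
  key <- function(b, i) paste(b, i, sep = ".")
  ch_by_trial <- split(changes[c("t_ms", "df1", "df2")],
                       factor(key(changes$block, changes$index),
                              levels = unique(key(changes$block,
                                                  changes$index))))
  get_change <- function(row) ch_by_trial[[key(row$block, row$index)]]
  pert_idx <- which(meta$perturbed)
  rows <- list()
  n_skipped <- 0L
  for (i in pert_idx) {
    cfg <- configs[[paste0("m", meta$magnitude_scale[i])]]
    base <- list(block = meta$block[i], index = meta$index[i],
                 direction = meta$direction[i],
                 magnitude_scale = meta$magnitude_scale[i])
    if (meta$kept[i]) {
      resp <- corrective_response(get_change(meta[i, ]))
      rows[[length(rows) + 1L]] <-
        c(base, kind = "corrective", normalize_and_angle(resp, cfg, space))
    }
    pre_i <- i - 1L
    post_i <- i + 1L
    ok <- pre_i >= 1L && post_i <= nrow(meta) &&
      meta$block[pre_i] == meta$block[i] &&
      meta$block[post_i] == meta$block[i] &&
      !meta$perturbed[pre_i] && !meta$perturbed[post_i] &&
      meta$kept[pre_i] && meta$kept[post_i]
    if (ok) {
      resp <- adaptive_response(get_change(meta[pre_i, ]),
                                get_change(meta[post_i, ]))
      rows[[length(rows) + 1L]] <-
        c(base, kind = "adaptive", normalize_and_angle(resp, cfg, space))
    } else {
      n_skipped <- n_skipped + 1L
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[c("block", "index", "kind", "direction", "magnitude_scale",
               "f1_hz", "f2_hz", "f1_pct", "f2_pct", "rel_angle")]
  structure(out, n_skipped_triads = n_skipped,
            class = c("response_table", "data.frame"))
}

#' Write / read a response table
#'
#' @param responses a `response_table`.
#' @param path file path (tab-delimited).
#' @export
write_responses <- function(responses, path) {
  utils::write.table(as.data.frame(responses), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  tab <- read_table_checked(path, "responses")
  structure(tab, class = c("response_table", "data.frame"))
}
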