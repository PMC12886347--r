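# Generative model of per-trial formant trajectories under a schedule.
#
# A trial's trajectory is
#   F(t) = eh centroid + word transition(t) + a + c(t) + jitter + noise
# where the word transition is an onset offset decaying with time constant
# tau_c, `a` is the carried adaptive offset, and on perturbed trials the
# corrective component ramps up after a latency:
#   c(t) = gain * exp(-lambda * k) * (1 - exp(-(t - L)/tau_r))_+ *
#          magnitude_hz * r_hat
# with k the number of previously experienced perturbed trials and the
# response direction r_hat a normalised mixture of the anti-perturbation
# direction and the participant's eh-to-ih axis:
#   r_hat = normalise((1 - beta) * (-u_pert) + beta * u_eh_ih).
# After a perturbed trial the adaptive offset updates one-shot,
#   a <- rho * a + eta * |c(end)| * r_hat,
# and otherwise (including sentence trials, which emit no trajectory)
#   a <- rho * a.

#' Speaker simulation parameters
#'
#' Defaults describe a typical adult speaker of American English producing
#' lax front vowels under the standard protocol: vowel durations uniform in
#' 450-650 ms, corrective responses beginning 150 ms after the error (within
#' the 100-200 ms latency range typical of auditory feedback responses) and
#' ramping with a 100 ms time constant, a feedback gain of 0.15 of the
#' perturbation magnitude, a strong (beta = 0.8) bias of the response toward
#' the eh-to-ih axis, small one-shot learning (eta = 0.05) with retention
#' rho = 0.9, and a slow exponential attenuation of the corrective gain with
#' perturbation exposure (lambda = 0.005 per perturbed trial).
#'
#' @param centroids 3x2 matrix of vowel centroids (rows "ih", "eh", "ae";
#'   columns f1, f2; Hz).
#' @param transitions named list of per-word onset offsets c(f1, f2) in Hz,
#'   decaying with `tau_c`.
#' @param tau_c consonant-transition decay time constant, ms.
#' @param duration_range vowel duration range c(min, max), ms.
#' @param jitter_sd per-trial formant jitter SD, Hz.
#' @param noise_sd per-sample measurement noise SD, Hz.
#' @param gain feedback gain in [0, 1]: fraction of the perturbation
#'   magnitude corrected at full ramp. Either a scalar or a named vector
#'   with elements `eps_to_ae` and `eps_to_out`.
#' @param latency corrective response latency L, ms.
#' @param tau_r corrective ramp time constant, ms.
#' @param beta direction bias in [0, 1]: 0 = pure anti-perturbation
#'   response, 1 = response fully along the eh-to-ih axis.
#' @param eta one-shot learning rate in [0, 1].
#' @param rho adaptive retention per trial in [0, 1].
#' @param lambda exposure decay rate (per perturbed trial), >= 0.
#' @param sample_interval formant sampling interval, ms.
#' @return an object of class `speaker_params`.
#' @export
speaker_params <- function(centroids = rbind(ih = c(400, 2000),
                                             eh = c(580, 1800),
                                             ae = c(730, 1660)),
                           transitions = list(hep = c(-40, 150),
                                              hed = c(-50, 200),
                                              hek = c(-60, 250)),
                           tau_c = 30, duration_range = c(450, 650),
                           jitter_sd = 15, noise_sd = 10,
                           gain = 0.15, latency = 150, tau_r = 100,
                           beta = 0.8, eta = 0.05, rho = 0.9,
                           lambda = 0.005, sample_interval = 2) {
  colnames(centroids) <- c("f1", "f2")
  p <- list(centroids = centroids, transitions = transitions, tau_c = tau_c,
            duration_range = duration_range, jitter_sd = jitter_sd,
            noise_sd = noise_sd, gain = gain, latency = latency,
            tau_r = tau_r, beta = beta, eta = eta, rho = rho,
            lambda = lambda, sample_interval = sample_interval)
  validate_speaker_params(p)
  structure(p, class = "speaker_params")
}

validate_speaker_params <- function(p) {
  in01 <- function(x) all(is.numeric(x)) && all(x >= 0) && all(x <= 1)
  if (!all(VOWELS %in% rownames(p$centroids)))
    stop_fc("centroids must have rows: ", paste(VOWELS, collapse = ", "))
  if (!in01(p$gain)) stop_fc("gain must lie in [0, 1]")
  for (f in c("beta", "eta", "rho"))
    if (!in01(p[[f]])) stop_fc(f, " must lie in [0, 1]")
  for (f in c("tau_c", "tau_r", "jitter_sd", "noise_sd", "lambda", "latency"))
    if (!is.numeric(p[[f]]) || any(p[[f]] < 0)) stop_fc(f, " must be >= 0")
  if (p$sample_interval <= 0) stop_fc("sample_interval must be > 0")
  if (length(p$duration_range) != 2 || diff(p$duration_range) < 0 ||
      p$duration_range[1] <= 0)
    stop_fc("duration_range must be c(min, max) with 0 < min <= max")
  invisible(TRUE)
}

gain_for <- function(params, direction) {
  g <- params$gain
  if (length(g) == 1L && is.null(names(g))) return(unname(g))
  if (!direction %in% names(g))
    stop_fc("gain has no element for direction ", direction)
  unname(g[[direction]])
}

#' Ground-truth corrective response direction
#'
#' The unit response direction the simulator uses: a normalised mixture of
#' the anti-perturbation direction and the eh-to-ih axis, weighted by the
#' direction bias `beta`.
#'
#' @param space a `vowel_space` with geometry derived.
#' @param config a `perturbation_config`.
#' @param beta direction bias in [0, 1].
#' @return unit vector c(f1, f2).
#' @export
response_direction <- function(space, config, beta) {
  u_pert <- config$vector / sqrt(sum(config$vector^2))
  v_ih <- space$centroids["ih", ] - space$centroids["eh", ]
  u_ih <- v_ih / sqrt(sum(v_ih^2))
  r <- (1 - beta) * (-u_pert) + beta * u_ih
  nr <- sqrt(sum(r^2))
  if (nr == 0) stop_fc("degenerate response direction (beta mixture cancels)")
  r / nr
}

ramp_at <- function(t, latency, tau_r) {
  ifelse(t >= latency, 1 - exp(-(t - latency) / tau_r), 0)
}

#' Simulate one word trial
#'
#' Low-level single-trial simulator; most users call [simulate_session()].
#' Draws, in order: the trial duration, the per-trial jitter, then the
#' per-sample noise.
#'
#' @param state list with adaptive offset `a` (length-2, Hz) and perturbed
#'   count `k`.
#' @param trial one row of a schedule (word trial).
#' @param params a `speaker_params`.
#' @param space a `vowel_space` (derived from `params$centroids`).
#' @param config `perturbation_config` for the trial, or `NULL` if
#'   unperturbed.
#' @return list with `trajectory` (data.frame `t_ms`, `f1`, `f2`), `duration`
#'   (ms) and the updated `state`.
#' @export
simulate_trial <- function(state, trial, params, space, config = NULL) {
  iv <- params$sample_interval
  dur <- stats::runif(1, params$duration_range[1], params$duration_range[2])
  dur <- round(dur / iv) * iv
  t <- seq(0, dur, by = iv)
  base <- params$centroids["eh", ]
  tr <- params$transitions[[trial$word]]
  if (is.null(tr)) stop_fc("no transition parameters for word ", trial$word)
  trans <- outer(exp(-t / params$tau_c), tr)
  jitter <- stats::rnorm(2, 0, params$jitter_sd)
  noise <- matrix(stats::rnorm(2 * length(t), 0, params$noise_sd),
                  ncol = 2)
  f <- sweep(trans + noise, 2, base + state$a + jitter, "+")
  if (isTRUE(trial$perturbed)) {
    if (is.null(config)) stop_fc("perturbed trial needs a perturbation config")
    g <- gain_for(params, config$direction)
    r_hat <- response_direction(space, config, params$beta)
    amp <- g * exp(-params$lambda * state$k) * config$magnitude_hz
    f <- f + outer(ramp_at(t, params$latency, params$tau_r), amp * r_hat)
    c_end <- amp * ramp_at(dur, params$latency, params$tau_r)
    state$a <- unname(params$rho * state$a + params$eta * c_end * r_hat)
    state$k <- state$k + 1L
  } else {
    state$a <- params$rho * state$a
  }
  list(trajectory = data.frame(t_ms = t, f1 = f[, 1], f2 = f[, 2]),
       duration = dur, state = state)
}

#' Simulate a full session under a schedule
#'
#' Word trials are simulated in order with carried adaptive state; sentence
#' trials emit no trajectory but decay the adaptive offset by `rho`.
#'
#' @param schedule a `schedule` from [generate_session()].
#' @param params a `speaker_params`.
#' @param seed integer RNG seed.
#' @return an object of class `session_data`: list with `trajectories`
#'   (long data.frame `block`, `index`, `t_ms`, `f1`, `f2`), `meta` (one row
#'   per word trial: `block`, `index`, `word_index`, `word`, `perturbed`,
#'   `direction`, `magnitude_scale`, `duration`, `onset_ms`, `offset_ms`,
#'   `k`), the `space`, the perturbation `configs` and the `params`.
#' @export
simulate_session <- function(schedule, params = speaker_params(),
                             seed = NULL) {
  stopifnot(inherits(params, "speaker_params"))
  validate_speaker_params(params)
  space <- derive_geometry(params$centroids)
  direction <- attr(schedule, "direction")
  configs <- lapply(stats::setNames(MAG_SCALES, paste0("m", MAG_SCALES)),
                    function(s) make_perturbation(space, direction, s))
  sched <- as.data.frame(schedule)
  word_rows <- which(sched$kind == "word")
  with_seed(seed, {
    state <- list(a = c(0, 0), k = 0L)
    trajs <- vector("list", nrow(sched))
    dur <- k_at <- rep(NA_real_, nrow(sched))
    for (i in seq_len(nrow(sched))) {
      trial <- sched[i, ]
      if (trial$kind == "sentence") {
        state$a <- params$rho * state$a
        next
      }
      cfg <- if (isTRUE(trial$perturbed))
        configs[[paste0("m", trial$magnitude_scale)]] else NULL
      k_at[i] <- state$k
      sim <- simulate_trial(state, trial, params, space, cfg)
      state <- sim$state
      trajs[[i]] <- sim$trajectory
      dur[i] <- sim$duration
    }
    lens <- vapply(trajs[word_rows], nrow, integer(1))
    trajectories <- data.frame(
      block = rep(sched$block[word_rows], lens),
      index = rep(sched$index[word_rows], lens),
      t_ms = unlist(lapply(trajs[word_rows], `[[`, "t_ms")),
      f1 = unlist(lapply(trajs[word_rows], `[[`, "f1")),
      f2 = unlist(lapply(trajs[word_rows], `[[`, "f2")))
    meta <- data.frame(
      block = sched$block[word_rows], index = sched$index[word_rows],
      word_index = sched$word_index[word_rows],
      word = sched$word[word_rows], perturbed = sched$perturbed[word_rows],
      direction = sched$direction[word_rows],
      magnitude_scale = sched$magnitude_scale[word_rows],
      duration = dur[word_rows], onset_ms = 0, offset_ms = dur[word_rows],
      k = ifelse(sched$perturbed[word_rows], k_at[word_rows], NA_real_),
      stringsAsFactors = FALSE)
    structure(list(trajectories = trajectories, meta = meta,
                   space = space, configs = configs, params = params,
                   direction = direction, seed = seed),
              class = "session_data")
  })
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf("Simulated session: %d word trials (%d perturbed), direction %s\n",
              nrow(x$meta), sum(x$meta$perturbed), x$direction))
  invisible(x)
}

#' Write simulated trajectories and metadata as delimited tables
#'
#' @param session a `session_data`.
#' @param traj_path,meta_path output paths (tab-delimited).
#' @export
write_session_data <- function(session, traj_path, meta_path) {
  tr <- session$trajectories
  names(tr)[names(tr) == "f1"] <- "f1_hz"
  names(tr)[names(tr) == "f2"] <- "f2_hz"
  utils::write.table(tr, traj_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(session$meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(traj_path, meta_path))
}
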