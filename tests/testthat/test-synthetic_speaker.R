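test_that("null-response trial is exactly centroid plus transition", {
  params <- speaker_params(jitter_sd = 0, noise_sd = 0, gain = 0,
                           duration_range = c(500, 500))
  space <- derive_geometry(params$centroids)
  trial <- data.frame(word = "hed", perturbed = TRUE,
                      stringsAsFactors = FALSE)
  cfg <- make_perturbation(space, "eps_to_ae", 1)
  sim <- simulate_trial(list(a = c(0, 0), k = 0L), trial, params, space, cfg)
  tr <- sim$trajectory
  expected_f1 <- 580 + params$transitions$hed[1] * exp(-tr$t_ms / params$tau_c)
  expected_f2 <- 1800 + params$transitions$hed[2] * exp(-tr$t_ms / params$tau_c)
  expect_equal(tr$f1, expected_f1)
  expect_equal(tr$f2, expected_f2)
})

test_that("full eh-to-ih bias sends responses along the eh-ih axis for both directions", {
  sp <- std_space()
  u_ih <- c(-180, 200) / sqrt(180^2 + 200^2)
  for (d in c("eps_to_ae", "eps_to_out")) {
    r <- response_direction(sp, make_perturbation(sp, d, 1), beta = 1)
    expect_equal(unname(r), u_ih, tolerance = 1e-12)
  }
  # beta = 0: pure anti-perturbation response
  r0 <- response_direction(sp, make_perturbation(sp, "eps_to_ae", 1), beta = 0)
  expect_equal(unname(r0), -c(150, -140) / sqrt(150^2 + 140^2))
})

test_that("no learning (eta = 0) leaves the adaptive offset at zero", {
  params <- exact_params(gain = 0.3)
  space <- derive_geometry(params$centroids)
  cfg <- make_perturbation(space, "eps_to_ae", 1.5)
  state <- list(a = c(0, 0), k = 0L)
  trial <- data.frame(word = "hep", perturbed = TRUE, stringsAsFactors = FALSE)
  for (i in 1:3) {
    out <- simulate_trial(state, trial, params, space, cfg)
    state <- out$state
  }
  expect_equal(state$a, c(0, 0))
  expect_equal(state$k, 3L)
  # and with eta > 0 the offset moves after a perturbed trial
  params2 <- exact_params(gain = 0.3)
  params2$eta <- 0.1
  out2 <- simulate_trial(list(a = c(0, 0), k = 0L), trial, params2, space, cfg)
  expect_gt(sqrt(sum(out2$state$a^2)), 0)
})

test_that("latency of 100 ms or more keeps the early window feedback-free", {
  params <- exact_params(gain = 0.5, latency = 150)
  space <- derive_geometry(params$centroids)
  cfg <- make_perturbation(space, "eps_to_ae", 1)
  trial_p <- data.frame(word = "hep", perturbed = TRUE, stringsAsFactors = FALSE)
  trial_u <- data.frame(word = "hep", perturbed = FALSE, stringsAsFactors = FALSE)
  sp <- simulate_trial(list(a = c(0, 0), k = 0L), trial_p, params, space, cfg)
  su <- simulate_trial(list(a = c(0, 0), k = 0L), trial_u, params, space)
  early <- sp$trajectory$t_ms < 100
  expect_equal(sp$trajectory$f1[early], su$trajectory$f1[early])
  expect_equal(sp$trajectory$f2[early], su$trajectory$f2[early])
  late <- sp$trajectory$t_ms >= 300
  expect_true(all(abs(sp$trajectory$f1[late] - su$trajectory$f1[late]) > 1))
})

test_that("simulation is bit-identical under a fixed seed", {
  sched <- generate_session("eps_to_out", n_blocks = 1, seed = 7)
  params <- speaker_params()
  a <- simulate_session(sched, params, seed = 13)
  b <- simulate_session(sched, params, seed = 13)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$meta, b$meta)
  c <- simulate_session(sched, params, seed = 14)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("exposure decay controls corrective amplitude across trials", {
  sched <- generate_session("eps_to_ae", n_blocks = 1, seed = 31)
  # lambda = 0: corrective amplitude independent of exposure count
  p0 <- exact_params(gain = 0.2, lambda = 0)
  sim0 <- simulate_session(sched, p0, seed = 1)
  proc0 <- process_session(sim0)
  r0 <- compute_responses(proc0, sim0)
  r0 <- as.data.frame(r0[r0$kind == "corrective" & r0$magnitude_scale == 1, ])
  amp0 <- sqrt(r0$f1_hz^2 + r0$f2_hz^2)
  expect_equal(max(amp0) - min(amp0), 0, tolerance = 1e-8)
  # lambda > 0: amplitude decays with the perturbed-trial count
  p1 <- exact_params(gain = 0.2, lambda = 0.05)
  sim1 <- simulate_session(sched, p1, seed = 1)
  proc1 <- process_session(sim1)
  r1 <- compute_responses(proc1, sim1)
  r1 <- as.data.frame(r1[r1$kind == "corrective", ])
  k <- sim1$meta$k[sim1$meta$perturbed][match(
    paste(r1$block, r1$index),
    paste(sim1$meta$block[sim1$meta$perturbed],
          sim1$meta$index[sim1$meta$perturbed]))]
  amp1 <- sqrt(r1$f1_hz^2 + r1$f2_hz^2) / r1$magnitude_scale
  expect_true(all(diff(amp1[order(k)]) < 0))
})
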