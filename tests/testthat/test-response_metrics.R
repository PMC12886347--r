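test_that("corrective response is late-window minus early-window change", {
  t <- seq(0, 398, by = 2)
  ch <- data.frame(t_ms = t,
                   df1 = ifelse(t >= 300, -30, 0),
                   df2 = ifelse(t >= 300, 12, 0))
  expect_equal(unname(corrective_response(ch)), c(-30, 12))
  flat <- data.frame(t_ms = t, df1 = 5, df2 = -3)
  expect_equal(unname(corrective_response(flat)), c(0, 0))
})

test_that("adaptive response differences the early windows of flanking trials", {
  t <- seq(0, 398, by = 2)
  pre <- data.frame(t_ms = t, df1 = 0, df2 = 0)
  post <- data.frame(t_ms = t, df1 = 5, df2 = -2)
  expect_equal(unname(adaptive_response(pre, post)), c(5, -2))
  expect_equal(unname(adaptive_response(pre, pre)), c(0, 0))
})

test_that("normalisation and relative angles follow the vowel-space geometry", {
  sp <- std_space()
  cfg <- make_perturbation(sp, "eps_to_ae", 1)
  r <- normalize_and_angle(c(f1 = -30, f2 = 0), cfg, sp)
  expect_equal(r$f1_pct, -100 * 30 / sqrt(150^2 + 140^2), tolerance = 1e-10)
  expect_equal(r$f1_pct, -14.62, tolerance = 1e-3)

  # response exactly along eh -> ih: relative angle 0
  along <- c(f1 = -180, f2 = 200) * 0.05
  expect_equal(normalize_and_angle(along, cfg, sp)$rel_angle, 0,
               tolerance = 1e-10)
  expect_equal(normalize_and_angle(c(f1 = -9, f2 = 10), cfg, sp)$rel_angle, 0,
               tolerance = 1e-10)

  expect_true(is.na(normalize_and_angle(c(f1 = 0, f2 = 0), cfg, sp)$rel_angle))
})

test_that("condition-average angle averages vectors before taking the angle", {
  expect_equal(condition_average_angle(c(1, 0), c(0, 1), 0), 45)
  expect_equal(condition_average_angle(c(3, 3), c(-3, -3), 0), -45)
  expect_true(is.na(condition_average_angle(c(1, -1), c(2, -2), 0)))
})

test_that("percent responses and relative angles are scale invariant", {
  sp <- std_space()
  cfg <- make_perturbation(sp, "eps_to_out", 1.5)
  resp <- c(f1 = -22, f2 = 31)
  r1 <- normalize_and_angle(resp, cfg, sp)
  for (k in c(0.1, 3, 250)) {
    cen_k <- std_centroids() * k
    sp_k <- derive_geometry(cen_k)
    cfg_k <- make_perturbation(sp_k, "eps_to_out", 1.5)
    r2 <- normalize_and_angle(resp * k, cfg_k, sp_k)
    expect_equal(r2$f1_pct, r1$f1_pct, tolerance = 1e-10)
    expect_equal(r2$f2_pct, r1$f2_pct, tolerance = 1e-10)
    expect_equal(r2$rel_angle, r1$rel_angle, tolerance = 1e-8)
  }
})

test_that("relative angles are invariant under joint rotation", {
  resp <- c(f1 = -40, f2 = 25)
  sp0 <- std_space()
  cfg0 <- make_perturbation(sp0, "eps_to_ae", 1)
  r0 <- normalize_and_angle(resp, cfg0, sp0)
  set.seed(3)
  for (phi in runif(8, -180, 180)) {
    rad <- phi * pi / 180
    R <- matrix(c(cos(rad), sin(rad), -sin(rad), cos(rad)), 2)
    cen <- std_centroids() %*% t(R)
    colnames(cen) <- c("f1", "f2")
    sp1 <- derive_geometry(cen)
    cfg1 <- make_perturbation(sp1, "eps_to_ae", 1)
    r1 <- normalize_and_angle(drop(R %*% resp), cfg1, sp1)
    expect_equal(r1$rel_angle, r0$rel_angle, tolerance = 1e-8)
  }
})

test_that("noise-free corrective estimates match the generator closed form", {
  sched <- generate_session("eps_to_ae", n_blocks = 1, seed = 17)
  params <- exact_params(gain = 0.2, lambda = 0.03, beta = 0.7)
  sim <- simulate_session(sched, params, seed = 2)
  proc <- process_session(sim)
  resp <- compute_responses(proc, sim)
  corr <- as.data.frame(resp[resp$kind == "corrective", ])
  space <- sim$space
  t <- seq(0, 500, by = params$sample_interval)
  ramp <- ifelse(t >= params$latency,
                 1 - exp(-(t - params$latency) / params$tau_r), 0)
  ramp_diff <- mean(ramp[t >= 300 & t < 400]) - mean(ramp[t >= 0 & t < 100])
  meta_p <- sim$meta[sim$meta$perturbed, ]
  for (i in seq_len(nrow(corr))) {
    m <- meta_p[meta_p$block == corr$block[i] &
                  meta_p$index == corr$index[i], ]
    cfg <- sim$configs[[paste0("m", m$magnitude_scale)]]
    r_hat <- response_direction(space, cfg, params$beta)
    expected <- 0.2 * exp(-0.03 * m$k) * cfg$magnitude_hz * ramp_diff * r_hat
    expect_equal(c(corr$f1_hz[i], corr$f2_hz[i]), unname(expected),
                 tolerance = 1e-9)
  }
  # adaptive responses are exactly zero without learning
  ada <- as.data.frame(resp[resp$kind == "adaptive", ])
  expect_equal(max(abs(c(ada$f1_hz, ada$f2_hz))), 0, tolerance = 1e-9)
})
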