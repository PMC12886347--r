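test_that("exposure halves split 63/63 with block 4 divided 9/9", {
  s <- assign_exposure_half(generate_session("eps_to_ae", n_blocks = 7,
                                             seed = 12))
  expo <- s$exposure[s$perturbed]
  expect_equal(sum(expo == "first"), 63)
  expect_equal(sum(expo == "second"), 63)
  # every perturbed trial in exactly one half
  expect_false(any(is.na(expo)))
  expect_true(all(is.na(s$exposure[!s$perturbed])))
  # block 4 is split at its 9th perturbed trial
  b4 <- s[s$block == 4 & s$perturbed, ]
  expect_equal(b4$exposure, rep(c("first", "second"), each = 9))
  expect_true(all(s$exposure[s$perturbed & s$block <= 3] == "first"))
  expect_true(all(s$exposure[s$perturbed & s$block >= 5] == "second"))
  # ~21 trials per half per magnitude: blocks 1-3 and 5-7 contribute exactly
  # 18 each; block 4's 9/9 split has randomised magnitudes, so each cell is
  # 21 in expectation and always within 18..24
  tab <- table(expo, s$magnitude_scale[s$perturbed])
  expect_true(all(tab >= 18 & tab <= 24))
  expect_equal(as.vector(colSums(tab)), rep(42, 3))
  expect_equal(as.vector(rowSums(tab)), c(63, 63))
  # non-7-block sessions split proportionally
  s1 <- assign_exposure_half(generate_session("eps_to_ae", n_blocks = 1,
                                              seed = 12))
  expect_equal(as.vector(table(s1$exposure[s1$perturbed])), c(9, 9))
})

test_that("one-sample t-test matches the classical formula", {
  r <- one_sample_test(c(-1, 0, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- one_sample_test(c(2, 4, 6))
  expect_equal(r2$t, 4 / (2 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r2$df, 2)
  expect_error(one_sample_test(rep(0, 5)), "variance")
  expect_error(one_sample_test(3), "at least 2")
})

test_that("FDR adjustment reproduces the step-up definition", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.5, 7)), rep(0.5, 7))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  expect_equal(fdr_adjust(p), bh_bruteforce(p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("random-intercept model recovers a pure direction effect", {
  set.seed(71)
  delta <- 6
  cells <- expand.grid(participant = sprintf("p%02d", 1:14),
                       direction = c("eps_to_ae", "eps_to_out"),
                       magnitude_scale = c(0.5, 1, 1.5),
                       exposure = c("first", "second"),
                       stringsAsFactors = FALSE)
  intercepts <- rnorm(14, 0, 2)
  names(intercepts) <- sprintf("p%02d", 1:14)
  cells$y <- intercepts[cells$participant] + rnorm(nrow(cells), 0, 1) +
    ifelse(cells$direction == "eps_to_ae", delta, 0)
  m <- fit_random_intercept_model(cells, "y")
  expect_lt(m$terms$p[m$terms$term == "direction"], 1e-6)
  # sum-to-zero coding: the direction coefficient is half the cell difference
  expect_equal(2 * abs(unname(m$fixef["direction1"])), delta,
               tolerance = 0.15 * delta)
  expect_equal(nrow(m$terms), 7)  # 3 mains, 3 two-way, 1 three-way
})

test_that("mixed model refuses degenerate designs with clear errors", {
  cells <- expand.grid(participant = "p01",
                       direction = c("eps_to_ae", "eps_to_out"),
                       magnitude_scale = c(0.5, 1, 1.5),
                       exposure = c("first", "second"),
                       stringsAsFactors = FALSE)
  cells$y <- rnorm(nrow(cells))
  expect_error(fit_random_intercept_model(cells, "y"), "single participant")
  cells2 <- expand.grid(participant = sprintf("p%02d", 1:4),
                        direction = c("eps_to_ae", "eps_to_out"),
                        magnitude_scale = c(0.5, 1, 1.5),
                        exposure = c("first", "second"),
                        stringsAsFactors = FALSE)
  cells2$y <- rnorm(nrow(cells2))
  cells2 <- cells2[-5, ]
  expect_error(fit_random_intercept_model(cells2, "y"), "missing cells")
})

test_that("corrective-adaptive correlations handle exact and degenerate cases", {
  part <- sprintf("p%02d", 1:10)
  x <- seq(-2, 2.5, length.out = 10)
  base <- expand.grid(participant = part, kind = c("corrective", "adaptive"),
                      direction = "eps_to_ae", magnitude_scale = 1,
                      exposure = "first", stringsAsFactors = FALSE)
  base$f1_pct <- ifelse(base$kind == "corrective", x[match(base$participant, part)],
                        2 * x[match(base$participant, part)])
  base$f2_pct <- ifelse(base$kind == "adaptive", 7, rnorm(nrow(base)))
  cc <- corrective_adaptive_correlation(base)
  f1row <- cc[cc$formant == "f1", ]
  expect_equal(f1row$r, 1, tolerance = 1e-10)
  expect_true(is.na(cc[cc$formant == "f2", ]$r))  # constant adaptive f2
})
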