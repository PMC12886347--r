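# Shared fixtures and independent oracles for the test suite.

std_centroids <- function() {
  m <- rbind(ih = c(400, 2000), eh = c(580, 1800), ae = c(730, 1660))
  colnames(m) <- c("f1", "f2")
  m
}

std_space <- function() derive_geometry(std_centroids())

make_traj <- function(t_ms, f1, f2 = f1) data.frame(t_ms = t_ms, f1 = f1, f2 = f2)

# Speaker parameters for exact (noise-free) recovery: no noise, no jitter,
# fixed duration, flat consonant transitions, no learning.
exact_params <- function(...) {
  speaker_params(jitter_sd = 0, noise_sd = 0, duration_range = c(500, 500),
                 transitions = list(hep = c(0, 0), hed = c(0, 0),
                                    hek = c(0, 0)),
                 eta = 0, ...)
}

# Independent brute-force validator of a single block: returns a character
# vector of violations (empty when the design constraints all hold).
check_block_oracle <- function(blk) {
  bad <- character(0)
  if (nrow(blk) != 120) bad <- c(bad, "not 120 trials")
  sentence_pos <- which(blk$kind == "sentence")
  expected_pos <- sort(as.integer(outer(c(19L, 20L), 20L * (0:5), "+")))
  if (!identical(sentence_pos, expected_pos))
    bad <- c(bad, "sentences not after every 18 word trials")
  if (sum(blk$kind == "word") != 108) bad <- c(bad, "word count != 108")
  if (sum(blk$kind == "sentence") != 12) bad <- c(bad, "sentence count != 12")
  if (any(blk$perturbed[blk$kind == "sentence"])) bad <- c(bad, "perturbed sentence")
  pw <- blk$perturbed[blk$kind == "word"]
  if (sum(pw) != 18) bad <- c(bad, "perturbed count != 18")
  mg <- blk$magnitude_scale[blk$perturbed]
  cnt <- table(factor(mg, levels = c(0.5, 1, 1.5)))
  if (!all(cnt == 6)) bad <- c(bad, "magnitudes not 6/6/6")
  for (p in which(pw)) {
    if (p < 3 || pw[p - 1] || pw[p - 2])
      bad <- c(bad, sprintf("gap violation at word trial %d", p))
  }
  bad
}

# Exact permutation p-values by exhaustive enumeration of label assignments.
enum_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  obs_mean <- abs(wrap_angle(circular_mean(a) - circular_mean(b)))
  obs_dev <- abs(angular_deviation(a) - angular_deviation(b))
  sets <- utils::combn(n, na)
  dm <- dd <- numeric(ncol(sets))
  for (j in seq_len(ncol(sets))) {
    ga <- pooled[sets[, j]]
    gb <- pooled[-sets[, j]]
    dm[j] <- abs(wrap_angle(circular_mean(ga) - circular_mean(gb)))
    dd[j] <- abs(angular_deviation(ga) - angular_deviation(gb))
  }
  eps <- 1e-9
  list(p_mean = mean(dm >= obs_mean - eps), p_dev = mean(dd >= obs_dev - eps))
}

# Benjamini-Hochberg step-up from the definition: adj_(i) = min_{j >= i}
# m * p_(j) / j on the sorted p-values, capped at 1, in original order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}
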