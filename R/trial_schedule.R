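# Compensation-paradigm trial schedules.
#
# Each block has 120 trials: 108 word-reading trials with two sentence-reading
# trials after every 18 word trials. 18 word trials are perturbed (6 per
# magnitude scale 0.5/1.0/1.5), and each perturbed trial is preceded by at
# least two unperturbed word trials (sentence trials neither break nor count
# toward the gap; the block start counts as zero preceding trials).

WORDS <- c("hep", "hed", "hek")
MAG_SCALES <- c(0.5, 1.0, 1.5)
TRIALS_PER_BLOCK <- 120L
WORDS_PER_BLOCK <- 108L
SENTENCES_PER_BLOCK <- 12L
PERTURBED_PER_BLOCK <- 18L

# Sample 18 perturbed positions among the 108 word slots, uniformly over the
# sets satisfying: first position >= 3 and successive gaps >= 3 (equivalently,
# >= 2 unperturbed word trials before every perturbed one). Uses the gap
# bijection p_i = s_(i) + 2i with s an 18-subset of 1..72, which enumerates
# exactly the valid sets.
sample_perturbed_positions <- function(n_words = WORDS_PER_BLOCK,
                                       n_pert = PERTURBED_PER_BLOCK,
                                       min_gap = 2L) {
  slack <- n_words - (min_gap + 1L) * n_pert + n_pert
  if (slack < n_pert)
    stop_fc("gap constraint unsatisfiable for ", n_pert, " perturbed among ",
            n_words, " word trials")
  s <- sort(sample.int(slack, n_pert))
  s + min_gap * seq_len(n_pert)
}

generate_block_impl <- function(direction, block = 1L) {
  kind <- rep(c(rep("word", 18L), rep("sentence", 2L)), 6L)
  n <- length(kind)
  word_index <- ifelse(kind == "word", cumsum(kind == "word"), NA_integer_)
  pos <- sample_perturbed_positions()
  mags <- sample(rep(MAG_SCALES, PERTURBED_PER_BLOCK / 3L))
  perturbed_w <- logical(WORDS_PER_BLOCK)
  perturbed_w[pos] <- TRUE
  mag_w <- rep(NA_real_, WORDS_PER_BLOCK)
  mag_w[pos] <- mags
  words <- sample(WORDS, WORDS_PER_BLOCK, replace = TRUE)
  sent_ids <- sprintf("sent_%02d", seq_len(SENTENCES_PER_BLOCK))
  word_col <- character(n)
  word_col[kind == "word"] <- words
  word_col[kind == "sentence"] <- sent_ids
  perturbed <- logical(n)
  perturbed[kind == "word"] <- perturbed_w
  mag <- rep(NA_real_, n)
  mag[kind == "word"] <- mag_w
  data.frame(block = as.integer(block), index = seq_len(n),
             word_index = as.integer(word_index), kind = kind,
             word = word_col, perturbed = perturbed,
             direction = ifelse(perturbed, direction, NA_character_),
             magnitude_scale = mag, stringsAsFactors = FALSE)
}

#' Generate one compensation-task block
#'
#' @param direction perturbation direction for the block, `"eps_to_ae"` or
#'   `"eps_to_out"`.
#' @param seed integer RNG seed; the block is exactly reproducible from it.
#'   `NULL` uses (and advances) the current RNG state.
#' @return data.frame of 120 trials with columns `block`, `index`,
#'   `word_index`, `kind`, `word`, `perturbed`, `direction`,
#'   `magnitude_scale`.
#' @examples
#' b <- generate_block("eps_to_ae", seed = 1)
#' table(b$kind)
#' sum(b$perturbed)
#' @export
generate_block <- function(direction = c("eps_to_ae", "eps_to_out"),
                           seed = NULL) {
  direction <- match.arg(direction)
  with_seed(seed, generate_block_impl(direction))
}

#' Generate a session schedule
#'
#' A session is `n_blocks` independent blocks (seven in the standard
#' protocol) sharing one perturbation direction, giving
#' `6 * n_blocks` perturbed trials per magnitude scale.
#'
#' @inheritParams generate_block
#' @param n_blocks number of blocks (default 7).
#' @param seed integer RNG seed.
#' @return an object of class `schedule`: the concatenated trial data.frame
#'   with attributes `direction`, `n_blocks` and `seed`.
#' @export
generate_session <- function(direction = c("eps_to_ae", "eps_to_out"),
                             n_blocks = 7L, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(n_blocks >= 1)
  sched <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_blocks),
                          function(b) generate_block_impl(direction, b)))
  })
  structure(sched, direction = direction, n_blocks = as.integer(n_blocks),
            seed = seed, class = c("schedule", "data.frame"))
}

#' Generate a two-session counterbalanced protocol
#'
#' The two sessions are structurally identical except for the perturbation
#' direction; `order` selects which direction comes first.
#'
#' @param order `"ae_first"` or `"out_first"`.
#' @param n_blocks blocks per session (default 7).
#' @param seed integer RNG seed.
#' @return list of two `schedule` objects, in session order.
#' @export
generate_protocol <- function(order = c("ae_first", "out_first"),
                              n_blocks = 7L, seed = NULL) {
  order <- match.arg(order)
  dirs <- if (order == "ae_first") c("eps_to_ae", "eps_to_out")
          else c("eps_to_out", "eps_to_ae")
  with_seed(seed, {
    lapply(dirs, function(d) generate_session(d, n_blocks = n_blocks))
  })
}

#' Validate a schedule against the design constraints
#'
#' Independent pass over the trial list checking: block sizes (120 trials,
#' 108 word + 12 sentence), the 18-word/2-sentence layout, 18 perturbed word
#' trials per block with 6 per magnitude scale, no perturbed sentence trials,
#' and at least `min_gap` unperturbed word trials immediately before every
#' perturbed trial.
#'
#' @param schedule a `schedule` or block data.frame.
#' @param min_gap required unperturbed word trials before each perturbed
#'   trial (default 2).
#' @return `TRUE` invisibly; fails with an informative error otherwise.
#' @export
validate_schedule <- function(schedule, min_gap = 2L) {
  for (b in unique(schedule$block)) {
    blk <- schedule[schedule$block == b, , drop = FALSE]
    if (nrow(blk) != TRIALS_PER_BLOCK)
      stop_fc("block ", b, ": ", nrow(blk), " trials, expected 120")
    if (sum(blk$kind == "word") != WORDS_PER_BLOCK ||
        sum(blk$kind == "sentence") != SENTENCES_PER_BLOCK)
      stop_fc("block ", b, ": wrong word/sentence counts")
    if (!identical(blk$kind, rep(c(rep("word", 18L), rep("sentence", 2L)), 6L)))
      stop_fc("block ", b, ": sentence trials misplaced")
    if (any(blk$perturbed & blk$kind == "sentence"))
      stop_fc("block ", b, ": perturbed sentence trial")
    pw <- blk$perturbed[blk$kind == "word"]
    if (sum(pw) != PERTURBED_PER_BLOCK)
      stop_fc("block ", b, ": ", sum(pw), " perturbed trials, expected 18")
    mg <- blk$magnitude_scale[blk$perturbed]
    if (!all(table(factor(mg, levels = MAG_SCALES)) == 6L))
      stop_fc("block ", b, ": magnitudes not balanced 6/6/6")
    pos <- which(pw)
    for (p in pos) {
      before <- pw[max(1L, p - min_gap):(p - 1L)]
      if (p <= min_gap || any(before))
        stop_fc("block ", b, ": perturbed word trial ", p,
                " lacks ", min_gap, " preceding unperturbed word trials")
    }
  }
  invisible(TRUE)
}

#' @export
print.schedule <- function(x, ...) {
  cat(sprintf("Schedule: %d block(s), direction %s, %d trials (%d perturbed)\n",
              attr(x, "n_blocks"), attr(x, "direction"), nrow(x),
              sum(x$perturbed)))
  invisible(x)
}

#' Write / read a schedule as a tab-delimited trial table
#'
#' @param schedule a `schedule`.
#' @param path file path.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @param direction direction label to attach when reading (taken from the
#'   table's perturbed rows when omitted).
#' @export
read_schedule <- function(path, direction = NULL) {
  tab <- read_table_checked(path, "schedule")
  if (is.null(direction)) {
    d <- unique(stats::na.omit(tab$direction))
    direction <- if (length(d) == 1L) d else NA_character_
  }
  structure(tab, direction = direction,
            n_blocks = length(unique(tab$block)),
            class = c("schedule", "data.frame"))
}
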