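# Inference: exposure halves, a priori one-sample tests, random-intercept
# mixed models, FDR adjustment and corrective-adaptive correlations.

#' Assign perturbed trials to exposure halves
#'
#' For the standard 7-block session each half contains 3.5 blocks: perturbed
#' trials of blocks 1-3 are "first", blocks 5-7 "second", and block 4 is
#' split at its 9th perturbed trial (first 9 to "first", last 9 to
#' "second"). Sessions with other block counts are split proportionally at
#' half the perturbed-trial count (the first ceiling(n/2) perturbed trials
#' are "first").
#'
#' @param schedule a `schedule` (or its data.frame) in presentation order.
#' @return the schedule with an `exposure` column (`"first"`/`"second"` for
#'   perturbed trials, `NA` otherwise).
#' @export
assign_exposure_half <- function(schedule) {
  n_blocks <- length(unique(schedule$block))
  exposure <- rep(NA_character_, nrow(schedule))
  pert <- which(schedule$perturbed)
  if (n_blocks == 7L) {
    blk <- schedule$block[pert]
    exposure[pert[blk <= 3L]] <- "first"
    exposure[pert[blk >= 5L]] <- "second"
    b4 <- pert[blk == 4L]
    half <- 9L
    exposure[b4[seq_along(b4) <= half]] <- "first"
    exposure[b4[seq_along(b4) > half]] <- "second"
  } else {
    cut <- ceiling(length(pert) / 2)
    exposure[pert[seq_along(pert) <= cut]] <- "first"
    exposure[pert[seq_along(pert) > cut]] <- "second"
  }
  schedule$exposure <- exposure
  schedule
}

#' One-sample t-test against zero
#'
#' @param values numeric vector (n >= 2, nonzero variance).
#' @return list with `t`, `df`, `p`, `mean`.
#' @export
one_sample_test <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop_fc("need at least 2 values")
  if (stats::sd(values) == 0) stop_fc("zero variance; t-test undefined")
  tt <- stats::t.test(values, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = unname(tt$estimate))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1. All p-values from
#' one model's family of comparisons should be adjusted together.
#'
#' @param p_values numeric vector of p-values in [0, 1] (`NA` allowed).
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop_fc("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Aggregate responses into participant x condition cells
#'
#' Means of the percent-normalised responses per participant, response kind,
#' direction, magnitude scale and exposure half.
#'
#' @param responses a `response_table` (or stack of them) with added
#'   `participant` and `exposure` columns.
#' @return data.frame of condition cells with `n_trials`, `f1_pct`,
#'   `f2_pct`, `f1_hz`, `f2_hz` cell means.
#' @export
condition_cells <- function(responses) {
  need <- c("participant", "kind", "direction", "magnitude_scale", "exposure")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop_fc("responses table missing column(s): ", paste(miss, collapse = ", "))
  g <- interaction(responses$participant, responses$kind,
                   responses$direction, responses$magnitude_scale,
                   responses$exposure, drop = TRUE, sep = "\r")
  agg <- function(v) tapply(v, g, mean)
  keys <- do.call(rbind, strsplit(levels(g), "\r", fixed = TRUE))
  data.frame(participant = keys[, 1], kind = keys[, 2],
             direction = keys[, 3],
             magnitude_scale = as.numeric(keys[, 4]), exposure = keys[, 5],
             n_trials = as.integer(tapply(seq_len(nrow(responses)), g, length)),
             f1_pct = as.numeric(agg(responses$f1_pct)),
             f2_pct = as.numeric(agg(responses$f2_pct)),
             f1_hz = as.numeric(agg(responses$f1_hz)),
             f2_hz = as.numeric(agg(responses$f2_hz)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the random-intercept mixed model for one response variable
#'
#' Fits `response ~ direction * magnitude * exposure + (1 | participant)`
#' with `lmerTest` and returns the Type-III F table (Satterthwaite degrees
#' of freedom) for the main effects and all interactions. The contract is
#' the returned structure (term, F, df, p); the fitting itself is delegated
#' to the standard mixed-model machinery.
#'
#' @param cells condition-cell data.frame from [condition_cells()] (one
#'   response kind), or any data.frame with `participant`, `direction`,
#'   `magnitude_scale`, `exposure` and the response column.
#' @param response name of the response column (e.g. `"f1_pct"`).
#' @return object of class `ri_model`: list with `terms` (data.frame
#'   `term`, `F`, `df1`, `df2`, `p`), `fixef` and the fitted `model`.
#' @export
fit_random_intercept_model <- function(cells, response) {
  stopifnot(response %in% names(cells))
  if (length(unique(cells$participant)) < 2L)
    stop_fc("random intercept unidentifiable with a single participant")
  cells$direction <- factor(cells$direction)
  cells$magnitude <- factor(cells$magnitude_scale)
  cells$exposure <- factor(cells$exposure)
  full <- expand.grid(participant = unique(cells$participant),
                      direction = levels(cells$direction),
                      magnitude = levels(cells$magnitude),
                      exposure = levels(cells$exposure),
                      stringsAsFactors = FALSE)
  have <- paste(cells$participant, cells$direction, cells$magnitude,
                cells$exposure)
  missing_cells <- full[!paste(full$participant, full$direction,
                               full$magnitude, full$exposure) %in% have, ]
  if (nrow(missing_cells))
    stop_fc("design not fully crossed; missing cells: ",
            paste(utils::head(apply(missing_cells, 1, paste, collapse = "/"),
                              5L), collapse = ", "))
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fml <- stats::as.formula(paste(
    response, "~ direction * magnitude * exposure + (1 | participant)"))
  model <- lmerTest::lmer(fml, data = cells)
  an <- stats::anova(model, type = 3)
  terms <- data.frame(term = rownames(an), F = an[["F value"]],
                      df1 = an[["NumDF"]], df2 = an[["DenDF"]],
                      p = an[["Pr(>F)"]], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(terms = terms, fixef = lme4::fixef(model),
                 response = response, model = model),
            class = "ri_model")
}

#' @export
print.ri_model <- function(x, ...) {
  cat("Random-intercept model for", x$response, "\n")
  print(transform(x$terms, F = round(F, 3), df2 = round(df2, 1),
                  p = signif(p, 3)))
  invisible(x)
}

#' Corrective-adaptive response correlations
#'
#' Pearson correlation between participant-level corrective and adaptive
#' responses, per condition (direction x magnitude x exposure) and formant.
#'
#' @param cells condition-cell data.frame containing both response kinds.
#' @return data.frame with `direction`, `magnitude_scale`, `exposure`,
#'   `formant`, `n`, `r`, `p` (`NA` when fewer than 3 pairs or a constant
#'   member).
#' @export
corrective_adaptive_correlation <- function(cells) {
  conds <- unique(cells[c("direction", "magnitude_scale", "exposure")])
  out <- list()
  for (i in seq_len(nrow(conds))) {
    sel <- cells$direction == conds$direction[i] &
      cells$magnitude_scale == conds$magnitude_scale[i] &
      cells$exposure == conds$exposure[i]
    for (fm in c("f1_pct", "f2_pct")) {
      cor_d <- cells[sel & cells$kind == "corrective", c("participant", fm)]
      ada_d <- cells[sel & cells$kind == "adaptive", c("participant", fm)]
      m <- merge(cor_d, ada_d, by = "participant",
                 suffixes = c("_cor", "_ada"))
      x <- m[[paste0(fm, "_cor")]]
      y <- m[[paste0(fm, "_ada")]]
      if (nrow(m) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x, y)
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        direction = conds$direction[i],
        magnitude_scale = conds$magnitude_scale[i],
        exposure = conds$exposure[i],
        formant = sub("_pct", "", fm), n = nrow(m), r = r, p = p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
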