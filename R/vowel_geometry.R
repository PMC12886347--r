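# Participant-specific vowel-space geometry and perturbation vectors.
#
# Conventions: F1 is the abscissa and F2 the ordinate of the formant plane;
# angles are in degrees, wrapped to (-180, 180]; all frequencies in Hz.
# Vowels are labelled "ih" (/I/ as in "hid"), "eh" (/E/ as in "head") and
# "ae" (as in "had").

VOWELS <- c("ih", "eh", "ae")

#' Compute per-vowel centroids from pre-test productions
#'
#' Each centroid is the componentwise median of the (F1, F2) values of that
#' vowel's productions. Medians of an even number of values are the mean of
#' the two middle values.
#'
#' @param productions data.frame with columns `vowel` (one of "ih", "eh",
#'   "ae"), `f1` and `f2` (Hz). One row per production.
#' @return an object of class `vowel_space` holding a `centroids` matrix
#'   (rows "ih", "eh", "ae"; columns "f1", "f2"). Geometry fields are empty
#'   until [derive_geometry()] is called.
#' @examples
#' pt <- data.frame(vowel = rep(c("ih", "eh", "ae"), each = 2),
#'                  f1 = c(400, 400, 500, 520, 730, 730),
#'                  f2 = c(2000, 2000, 1800, 1800, 1660, 1660))
#' compute_centroids(pt)
#' @export
compute_centroids <- function(productions) {
  stopifnot(is.data.frame(productions))
  need <- c("vowel", "f1", "f2")
  miss <- setdiff(need, names(productions))
  if (length(miss))
    stop_fc("productions table is missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(VOWELS, unique(productions$vowel))
  if (length(absent))
    stop_fc("no productions for vowel(s): ", paste(absent, collapse = ", "))
  if (any(!is.finite(productions$f1)) || any(!is.finite(productions$f2)) ||
      any(productions$f1 <= 0) || any(productions$f2 <= 0))
    stop_fc("formant values must be finite and positive (Hz)")
  bad <- productions$f2 <= productions$f1
  if (any(bad))
    warning(sum(bad), " production(s) with f2 <= f1; unusual for front vowels",
            call. = FALSE)
  cen <- t(vapply(VOWELS, function(v) {
    rows <- productions[productions$vowel == v, , drop = FALSE]
    c(f1 = stats::median(rows$f1), f2 = stats::median(rows$f2))
  }, numeric(2)))
  structure(list(centroids = cen,
                 eps_ae_distance = NULL, eps_ae_angle = NULL,
                 eps_ih_angle = NULL),
            class = "vowel_space")
}

#' Derive vowel-space geometry from centroids
#'
#' Fills in the eh-ae distance (Euclidean, Hz) and the planar angles of the
#' eh-to-ae and eh-to-ih centroid vectors.
#'
#' @param space a `vowel_space` from [compute_centroids()], or a 3x2 centroid
#'   matrix with rows "ih", "eh", "ae".
#' @return the `vowel_space` with `eps_ae_distance`, `eps_ae_angle` and
#'   `eps_ih_angle` populated.
#' @export
derive_geometry <- function(space) {
  if (is.matrix(space)) {
    if (!all(VOWELS %in% rownames(space)))
      stop_fc("centroid matrix must have rows: ", paste(VOWELS, collapse = ", "))
    space <- structure(list(centroids = space[VOWELS, , drop = FALSE]),
                       class = "vowel_space")
  }
  stopifnot(inherits(space, "vowel_space"))
  cen <- space$centroids
  v_ae <- cen["ae", ] - cen["eh", ]
  v_ih <- cen["ih", ] - cen["eh", ]
  if (sqrt(sum(v_ae^2)) == 0)
    stop_fc("eh and ae centroids coincide; geometry undefined")
  if (sqrt(sum(v_ih^2)) == 0)
    stop_fc("eh and ih centroids coincide; geometry undefined")
  space$eps_ae_distance <- sqrt(sum(v_ae^2))
  space$eps_ae_angle <- planar_angle(v_ae[1], v_ae[2])
  space$eps_ih_angle <- planar_angle(v_ih[1], v_ih[2])
  space
}

#' Build a vowel space in one step
#'
#' Convenience wrapper: [compute_centroids()] followed by
#' [derive_geometry()].
#'
#' @inheritParams compute_centroids
#' @return a fully populated `vowel_space`.
#' @export
vowel_space <- function(productions) derive_geometry(compute_centroids(productions))

#' @export
print.vowel_space <- function(x, ...) {
  cat("Vowel space (Hz)\n")
  print(round(x$centroids, 1))
  if (!is.null(x$eps_ae_distance)) {
    cat(sprintf("eh-ae distance: %.2f Hz\n", x$eps_ae_distance))
    cat(sprintf("eh-ae angle:    %.2f deg\n", x$eps_ae_angle))
    cat(sprintf("eh-ih angle:    %.2f deg\n", x$eps_ih_angle))
  }
  invisible(x)
}

#' Construct a perturbation configuration
#'
#' Perturbations are vectors in the F1-F2 plane scaled to a multiple of the
#' participant's eh-ae distance. Direction `"eps_to_ae"` points along the
#' eh-to-ae centroid line (for typical front-vowel spaces an F1 increase and
#' F2 decrease). Direction `"eps_to_out"` is the perpendicular with positive
#' F2 component, pushing the vowel out of the vowel space (typically a
#' concurrent F1 and F2 increase).
#'
#' @param space a `vowel_space` with geometry derived.
#' @param direction `"eps_to_ae"` or `"eps_to_out"`.
#' @param magnitude_scale positive multiplier of the eh-ae distance
#'   (the experimental levels are 0.5, 1.0 and 1.5).
#' @return an object of class `perturbation_config` with fields `direction`,
#'   `magnitude_scale`, `vector` (c(f1, f2) Hz) and `magnitude_hz`.
#' @export
make_perturbation <- function(space, direction = c("eps_to_ae", "eps_to_out"),
                              magnitude_scale = 1.0) {
  direction <- match.arg(direction)
  stopifnot(inherits(space, "vowel_space"))
  if (is.null(space$eps_ae_distance))
    stop_fc("call derive_geometry() before make_perturbation()")
  if (!is.numeric(magnitude_scale) || length(magnitude_scale) != 1 ||
      magnitude_scale <= 0)
    stop_fc("magnitude_scale must be a single positive number")
  v_ae <- space$centroids["ae", ] - space$centroids["eh", ]
  if (direction == "eps_to_ae") {
    vec <- magnitude_scale * v_ae
  } else {
    perp <- c(-v_ae[2], v_ae[1])          # +90 degree rotation
    if (perp[2] < 0) perp <- -perp        # positive-F2 rule
    if (perp[1] <= 0)
      warning("outward perturbation lacks an F1 increase; atypical vowel space",
              call. = FALSE)
    vec <- magnitude_scale * perp
  }
  names(vec) <- c("f1", "f2")
  structure(list(direction = direction,
                 magnitude_scale = magnitude_scale,
                 vector = vec,
                 magnitude_hz = magnitude_scale * space$eps_ae_distance),
            class = "perturbation_config")
}

#' @export
print.perturbation_config <- function(x, ...) {
  cat(sprintf("Perturbation %s, scale %.1f: (dF1, dF2) = (%.1f, %.1f) Hz, |v| = %.1f Hz\n",
              x$direction, x$magnitude_scale, x$vector[1], x$vector[2],
              x$magnitude_hz))
  invisible(x)
}

#' Read a pre-test production table
#'
#' Expects a tab- or comma-delimited file with columns `vowel`, `f1_hz`,
#' `f2_hz` (one row per production).
#'
#' @param path file path.
#' @return data.frame with columns `vowel`, `f1`, `f2`.
#' @export
read_pretest <- function(path) {
  tab <- read_table_checked(path, "pretest")
  data.frame(vowel = tab$vowel, f1 = tab$f1_hz, f2 = tab$f2_hz)
}

#' Serialise a vowel space to a key-value text file
#'
#' @param space a `vowel_space` with geometry derived.
#' @param path output path.
#' @export
write_vowel_space <- function(space, path) {
  stopifnot(inherits(space, "vowel_space"))
  if (is.null(space$eps_ae_distance)) space <- derive_geometry(space)
  lines <- c(
    sprintf("%s_f1 = %.10g", rownames(space$centroids), space$centroids[, "f1"]),
    sprintf("%s_f2 = %.10g", rownames(space$centroids), space$centroids[, "f2"]),
    sprintf("eps_ae_distance = %.10g", space$eps_ae_distance),
    sprintf("eps_ae_angle = %.10g", space$eps_ae_angle),
    sprintf("eps_ih_angle = %.10g", space$eps_ih_angle))
  writeLines(lines, path)
  invisible(path)
}

#' Read a vowel space written by [write_vowel_space()]
#'
#' @param path input path.
#' @return a `vowel_space`.
#' @export
read_vowel_space <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  names(vals) <- keys
  cen <- rbind(ih = c(vals["ih_f1"], vals["ih_f2"]),
               eh = c(vals["eh_f1"], vals["eh_f2"]),
               ae = c(vals["ae_f1"], vals["ae_f2"]))
  colnames(cen) <- c("f1", "f2")
  derive_geometry(cen)
}
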