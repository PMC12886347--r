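# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into (-180, 180]
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap_angle(c(270, -180, 540))
#' @export
wrap_angle <- function(deg) {
  w <- deg %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Planar angle of a vector in the F1-F2 plane
#'
#' Angle (degrees) of the vector (df1, df2) with F1 on the abscissa and F2 on
#' the ordinate, wrapped to (-180, 180].
#'
#' @param df1,df2 vector components in Hz.
#' @return angle in degrees.
#' @export
planar_angle <- function(df1, df2) {
  unname(wrap_angle(atan2(df2, df1) * 180 / pi))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

stop_fc <- function(...) stop(..., call. = FALSE)
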