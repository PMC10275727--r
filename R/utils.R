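# Internal helpers shared across modules.

#' Default virtual screen geometry
#'
#' The experiment's screen dimensions are configurable; analyses that depend on
#' "screen size" (peak-prominence thresholds) use the vertical extent.
#'
#' @param width_px,height_px screen dimensions in pixels.
#' @return list with `width_px`, `height_px`, `center_y_px`.
#' @export
screen_geometry <- function(width_px = 1920, height_px = 1080) {
  stopifnot(width_px > 0, height_px > 0)
  list(width_px = width_px, height_px = height_px, center_y_px = height_px / 2)
}

# Evaluate with a locally-seeded RNG without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream index; stays below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629
}

`%||%` <- function(x, y) if (is.null(x)) y else x
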