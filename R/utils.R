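# Internal helpers shared across modules.

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals do not
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

gm_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "gaitmat_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

gm_warn <- function(msg, class = "gaitmat_warning") {
  warning(structure(
    class = c(class, "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Grid pitch of the walkway sensor matrix (cm)
#'
#' Spatial resolution of the sensor grid: cell centres sit on a square
#' lattice with this spacing, and grid indices convert to centimetres by
#' multiplication with it.
#' @export
WALKWAY_PITCH_CM <- 1.27

#' Walkway mat specification
#'
#' Dimensions and sensor pitch of the pressure-sensitive mat. The default
#' matches a 90 x 420 cm walkway sampled at 1.27 cm, with 0-based cell
#' indices at cell centres; the y axis is the long (walking) axis.
#'
#' @param width_cm mat width (short, lateral axis), cm.
#' @param length_cm mat length (long, walking axis), cm.
#' @param pitch_cm sensor pitch, cm.
#' @return object of class `mat_spec` with index bounds.
#' @export
mat_spec <- function(width_cm = 90, length_cm = 420, pitch_cm = WALKWAY_PITCH_CM) {
  stopifnot(width_cm > 0, length_cm > 0, pitch_cm > 0)
  structure(
    list(
      width_cm = width_cm, length_cm = length_cm, pitch_cm = pitch_cm,
      max_x_index = floor(width_cm / pitch_cm) - 1L,
      max_y_index = floor(length_cm / pitch_cm) - 1L
    ),
    class = "mat_spec"
  )
}
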