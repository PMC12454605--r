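`%||%` <- function(a, b) if (is.null(a)) b else a

stop_vg <- function(...) stop(sprintf(...), call. = FALSE)

warn_vg <- function(...) warning(sprintf(...), call. = FALSE)

#' Conversion between millimetres of mercury and pascal
#'
#' @param mmHg,Pa pressure values.
#' @return the converted pressure.
#' @examples
#' mmHg_to_Pa(90)
#' @export
mmHg_to_Pa <- function(mmHg) mmHg * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(Pa) Pa / 133.322
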