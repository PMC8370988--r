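#' Unit conversions for the mm-s-MPa internal system
#'
#' The package computes in millimetres, seconds and megapascals.
#' Clinical interfaces use mmHg (pressure), cm/s (velocity) and ml/min
#' (mean flow).  These converters are exact and mutually inverse to
#' machine precision.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
#' @examples
#' mmHg_to_MPa(MPa_to_mmHg(120)) # 120
NULL

# 1 mmHg = 133.322387415 Pa (conventional mercury column definition)
.MMHG_PA <- 133.322387415

#' @rdname units
#' @export
mmHg_to_MPa <- function(x) x * (.MMHG_PA * 1e-6)

#' @rdname units
#' @export
MPa_to_mmHg <- function(x) x / (.MMHG_PA * 1e-6)

#' @rdname units
#' @export
mmHg_to_Pa <- function(x) x * .MMHG_PA

#' @rdname units
#' @export
Pa_to_mmHg <- function(x) x / .MMHG_PA

#' @rdname units
#' @export
Pa_to_MPa <- function(x) x * 1e-6

#' @rdname units
#' @export
MPa_to_Pa <- function(x) x * 1e6

#' @rdname units
#' @export
ml_min_to_mm3_s <- function(x) x * 1000 / 60

#' @rdname units
#' @export
mm3_s_to_ml_min <- function(x) x * 60 / 1000

#' @rdname units
#' @export
cm_s_to_mm_s <- function(x) x * 10

#' @rdname units
#' @export
mm_s_to_cm_s <- function(x) x / 10
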