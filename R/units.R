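# Unit handling. All internal computation is SI (Pa, m, s, m^3/s); the clinical
# units of the literature (mmHg, ml/min, nm^2, nm/s) appear only at I/O boundaries.

#' Physical unit constants
#'
#' Fixed conversion constants used throughout the package.
#' `1 mmHg = 133.322 Pa` exactly (by convention here).
#'
#' @format Named numeric vector.
#' @export
unit_constants <- c(
  pa_per_mmhg   = 133.322,
  m3s_per_mlmin = 1e-6 / 60,
  m2_per_nm2    = 1e-18,
  ms_per_nms    = 1e-9
)

.unit_factors <- local({
  mmHg <- unit_constants[["pa_per_mmhg"]]
  mlmin <- unit_constants[["m3s_per_mlmin"]]
  # factor converts 1 <from> into <to>
  list(
    "mmHg->Pa"                    = mmHg,
    "Pa->mmHg"                    = 1 / mmHg,
    "ml/min->m3/s"                = mlmin,
    "m3/s->ml/min"                = 1 / mlmin,
    "nm2->m2"                     = 1e-18,
    "m2->nm2"                     = 1e18,
    "nm/s->m/s"                   = 1e-9,
    "m/s->nm/s"                   = 1e9,
    "mmHg/(ml/min)->Pa*s/m3"      = mmHg / mlmin,
    "Pa*s/m3->mmHg/(ml/min)"      = mlmin / mmHg
  )
})

#' Convert between clinical and SI units
#'
#' Exact multiplicative conversion for the unit pairs used in this package:
#' pressure (mmHg, Pa), volumetric flow (ml/min, m3/s), permeability (nm2, m2),
#' speed (nm/s, m/s) and flow resistance (mmHg/(ml/min), Pa*s/m3).
#'
#' @param value Numeric vector.
#' @param from,to Unit names, e.g. `"mmHg"`, `"Pa"`, `"ml/min"`, `"m3/s"`,
#'   `"nm2"`, `"m2"`, `"nm/s"`, `"m/s"`, `"mmHg/(ml/min)"`, `"Pa*s/m3"`.
#' @return `value` expressed in `to` units.
#' @examples
#' convert_units(1, "mmHg", "Pa")           # 133.322
#' convert_units(1.5, "ml/min", "m3/s")     # 2.5e-8
#' @export
convert_units <- function(value, from, to) {
  stopifnot(is.numeric(value), length(from) == 1L, length(to) == 1L)
  if (identical(from, to)) return(value)
  key <- paste0(from, "->", to)
  f <- .unit_factors[[key]]
  if (is.null(f)) {
    stop("unknown unit pair: ", from, " -> ", to,
         " (supported: ", paste(names(.unit_factors), collapse = ", "), ")")
  }
  value * f
}

#' Shorthand pressure and flow conversions
#'
#' Thin wrappers around [convert_units()] for the two most common pairs.
#'
#' @param x Numeric vector.
#' @name unit-shorthand
NULL

#' @rdname unit-shorthand
#' @export
mmhg_to_pa <- function(x) x * unit_constants[["pa_per_mmhg"]]

#' @rdname unit-shorthand
#' @export
pa_to_mmhg <- function(x) x / unit_constants[["pa_per_mmhg"]]

#' @rdname unit-shorthand
#' @export
mlmin_to_m3s <- function(x) x * unit_constants[["m3s_per_mlmin"]]

#' @rdname unit-shorthand
#' @export
m3s_to_mlmin <- function(x) x / unit_constants[["m3s_per_mlmin"]]
# resistance mmHg/(ml/min) -> Pa*s/m^3
rclin_to_si <- function(x) x * unit_constants[["pa_per_mmhg"]] / unit_constants[["m3s_per_mlmin"]]
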