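# Unit conversions at the I/O boundary. Internally everything is cm / s / mg
# (ml == cm^3, mg ml^-1 == mg cm^-3, permeability cm s^-1).

#' Convert hours to seconds
#'
#' @param t_h Numeric vector of durations in hours.
#' @return Durations in seconds.
#' @export
#' @examples
#' hours_to_seconds(2) # 7200
hours_to_seconds <- function(t_h) {
  stopifnot(is.numeric(t_h))
  t_h * 3600
}

#' Convert seconds to hours
#'
#' @param t_s Numeric vector of durations in seconds.
#' @return Durations in hours.
#' @export
seconds_to_hours <- function(t_s) {
  stopifnot(is.numeric(t_s))
  t_s / 3600
}

#' Convert microlitres to millilitres
#'
#' @param v_ul Numeric vector of volumes in microlitres.
#' @return Volumes in millilitres (= cm^3).
#' @export
ul_to_ml <- function(v_ul) {
  stopifnot(is.numeric(v_ul))
  v_ul / 1000
}

#' Convert millilitres to microlitres
#'
#' @param v_ml Numeric vector of volumes in millilitres.
#' @return Volumes in microlitres.
#' @export
ml_to_ul <- function(v_ml) {
  stopifnot(is.numeric(v_ml))
  v_ml * 1000
}
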