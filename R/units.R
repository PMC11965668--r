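#' Unit conversions used at the configuration boundary
#'
#' Internally everything is SI (m, s, Pa, kg). Clinical inputs arrive in
#' mm, cm/s and mmHg; these helpers convert them. The mmHg factor defaults
#' to 133 Pa/mmHg, the rounded clinical factor under which a venous
#' pressure of 8 mmHg equals 1064 Pa.
#'
#' @param x numeric vector to convert.
#' @param factor Pa per mmHg (default 133).
#' @return numeric vector in SI units.
#' @examples
#' mmhg_to_pa(8) # 1064 Pa
#' @export
mmhg_to_pa <- function(x, factor = 133) x * factor

#' @rdname mmhg_to_pa
#' @export
mm_to_m <- function(x) x * 1e-3

#' @rdname mmhg_to_pa
#' @export
cm_s_to_m_s <- function(x) x * 1e-2
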