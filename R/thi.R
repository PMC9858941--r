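#' Temperature-humidity index (THI)
#'
#' Computes the dairy-cattle temperature-humidity index from air temperature
#' and relative humidity:
#' \deqn{THI = (1.8\,t + 32) - (0.55 - 0.0055\,rh)(1.8\,t - 26)}
#' where \eqn{t} is the dry-bulb temperature in degrees Celsius and \eqn{rh}
#' the relative humidity in percent. Values of 72 and above are conventionally
#' taken as the heat-stress zone for dairy cows.
#'
#' @param temp numeric vector, air temperature in degrees Celsius.
#' @param rh numeric vector, relative humidity in percent (0-100). Recycled
#'   against `temp`.
#' @return numeric vector of THI values.
#' @examples
#' compute_thi(20, 100) # humidity term cancels: 1.8 * 20 + 32 = 68
#' compute_thi(25, 50)
#' @export
compute_thi <- function(temp, rh) {
  if (!is.numeric(temp) || !is.numeric(rh)) {
    stop("`temp` and `rh` must be numeric", call. = FALSE)
  }
  if (any(!is.na(rh) & (rh < 0 | rh > 100))) {
    stop("relative humidity must lie in [0, 100] percent", call. = FALSE)
  }
  (1.8 * temp + 32) - (0.55 - 0.0055 * rh) * (1.8 * temp - 26)
}
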