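#' Static magnetic field context
#'
#' Bundles the spectrometer proton frequency with the derived angular
#' frequencies of 1H and 15N. The 15N Larmor frequency is obtained from the
#' fixed gyromagnetic-ratio ratio; the negative sign of gamma(15N) is carried
#' through so that `omega_N` is negative, and code that needs a magnitude
#' (ppm-to-rad/s conversion) uses `abs(omega_N)`.
#'
#' @param proton_mhz spectrometer 1H frequency in MHz (e.g. 600, 950).
#' @return object of class `field_context` with elements `proton_mhz`,
#'   `omega_H` and `omega_N` (rad/s), and `gamma_ratio` = gammaH/gammaN.
#' @examples
#' f <- field_context(950)
#' abs(f$omega_N) / (2 * pi) / 1e6  # ~96.3 MHz
#' @export
field_context <- function(proton_mhz) {
  stopifnot(is.numeric(proton_mhz), length(proton_mhz) == 1L,
            is.finite(proton_mhz), proton_mhz > 0)
  omega_H <- 2 * pi * proton_mhz * 1e6
  structure(
    list(proton_mhz = proton_mhz,
         omega_H    = omega_H,
         omega_N    = omega_H * (.gamma_N / .gamma_H),
         gamma_ratio = .gamma_H / .gamma_N),
    class = "field_context")
}

#' @export
print.field_context <- function(x, ...) {
  cat(sprintf("<field_context> 1H %.1f MHz, 15N %.2f MHz\n",
              x$proton_mhz, abs(x$omega_N) / (2 * pi * 1e6)))
  invisible(x)
}

# physical constants (SI)
.gamma_H <- 2.6752218744e8   # rad s^-1 T^-1
.gamma_N <- -2.7126189e7     # rad s^-1 T^-1 (15N, negative)
.gamma_C <- 6.728284e7       # rad s^-1 T^-1 (13C)
.hbar    <- 1.054571817e-34  # J s
.mu0     <- 4 * pi * 1e-7

as_field <- function(field) {
  if (inherits(field, "field_context")) field else field_context(field)
}

#' Convert a chemical-shift difference in ppm to rad/s
#'
#' @param dw_ppm shift difference in ppm.
#' @param field a [field_context()] (or MHz value).
#' @param nucleus `"N"` (15N, default), `"C"` (13C) or `"H"`.
#' @return angular frequency difference, rad/s (non-negative for
#'   non-negative input).
#' @export
ppm_to_rad <- function(dw_ppm, field, nucleus = c("N", "C", "H")) {
  nucleus <- match.arg(nucleus)
  f <- as_field(field)
  omega <- switch(nucleus,
                  N = abs(f$omega_N),
                  C = f$omega_H * (.gamma_C / .gamma_H),
                  H = f$omega_H)
  dw_ppm * 1e-6 * omega
}
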