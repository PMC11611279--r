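#' Linear absorption coefficients per material
#'
#' Coefficients are in inverse micrometres; the Beer--Lambert exponent for a
#' ray is the sum over materials of mu_m times the path length (in um)
#' through material m. Background (vacuum) is always 0 and cannot be
#' overridden.
#'
#' Presets carry the measured coefficients for the three reference samples at
#' their data-collection wavelengths:
#' \describe{
#'   \item{`insulin`}{3.10 A: crystal 0.00745, liquor 0.00720, loop 0.00690}
#'   \item{`thermolysin`}{3.53 A: crystal 0.01312, liquor 0.01583, loop 0.01172}
#'   \item{`thaumatin`}{4.13 A: crystal 0.01926, liquor 0.02019, loop 0.01864}
#' }
#'
#' @param crystal,liquor,loop Coefficients in um^-1 (non-negative).
#' @param ... Further named materials and their coefficients.
#' @param preset Optional preset name, one of `"insulin"`, `"thermolysin"`,
#'   `"thaumatin"`; overrides the individual arguments.
#' @return Named numeric vector of coefficients including `background = 0`,
#'   class `material_coefficients`.
#' @examples
#' material_coefficients(preset = "thaumatin")
#' material_coefficients(crystal = 0.01, liquor = 0.012, loop = 0.009)
#' @export
material_coefficients <- function(crystal = 0, liquor = 0, loop = 0, ...,
                                  preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("insulin", "thermolysin", "thaumatin"))
    mu <- switch(preset,
      insulin = c(crystal = 0.00745, liquor = 0.00720, loop = 0.00690),
      thermolysin = c(crystal = 0.01312, liquor = 0.01583, loop = 0.01172),
      thaumatin = c(crystal = 0.01926, liquor = 0.02019, loop = 0.01864)
    )
  } else {
    extra <- c(...)
    mu <- c(crystal = crystal, liquor = liquor, loop = loop, extra)
  }
  if ("background" %in% names(mu) && any(mu[names(mu) == "background"] != 0)) {
    stop("the background coefficient is fixed at 0")
  }
  mu <- mu[names(mu) != "background"]
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("absorption coefficients must be finite and >= 0")
  }
  structure(c(background = 0, mu), class = "material_coefficients")
}

# Coefficient vector indexed by label code (position code + 1), background 0,
# materials absent from `coeffs` treated as non-absorbing.
mu_by_code <- function(volume, coeffs) {
  mu <- numeric(max_code(volume) + 1L)
  for (m in names(volume$label_map)) {
    if (m %in% names(coeffs)) mu[volume$label_map[[m]] + 1L] <- coeffs[[m]]
  }
  mu
}

coeff_hash <- function(coeffs) {
  paste(names(coeffs), signif(unclass(coeffs), 12), sep = "=", collapse = ";")
}
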