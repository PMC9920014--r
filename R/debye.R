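#' Single-pole Debye medium
#'
#' Describes the dielectric response of a tissue with a single relaxation
#' pole plus a static-conductivity term,
#' \deqn{\varepsilon_r(\omega) = \varepsilon_\infty +
#'   \frac{\varepsilon_s - \varepsilon_\infty}{1 + j\omega\tau} +
#'   \frac{\sigma_s}{j\omega\varepsilon_0}.}
#'
#' @param eps_inf relative permittivity at infinite frequency (dimensionless,
#'   >= 1).
#' @param delta_eps dispersion magnitude \eqn{\varepsilon_s -
#'   \varepsilon_\infty} (dimensionless, >= 0).
#' @param sigma_s static conductivity in S/m (>= 0).
#' @param tau relaxation time in seconds (> 0). Defaults to 13 ps, the value
#'   tabulated for skin; the same relaxation constant is shared by all
#'   tissues in [tissue_library()].
#' @return An object of class `debye_medium`.
#' @seealso [debye_permittivity()], [tissue_library()]
#' @export
debye_medium <- function(eps_inf, delta_eps, sigma_s, tau = 13e-12) {
  stopifnot(is.numeric(eps_inf), is.numeric(delta_eps),
            is.numeric(sigma_s), is.numeric(tau))
  if (eps_inf < 1) stop("eps_inf must be >= 1")
  if (delta_eps < 0) stop("delta_eps must be >= 0")
  if (sigma_s < 0) stop("sigma_s must be >= 0")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(eps_inf = eps_inf, delta_eps = delta_eps,
                 sigma_s = sigma_s, tau = tau),
            class = "debye_medium")
}

#' @export
print.debye_medium <- function(x, ...) {
  cat(sprintf(
    "Debye medium: eps_inf = %.3g, delta_eps = %.3g, sigma_s = %.3g S/m, tau = %.3g ps\n",
    x$eps_inf, x$delta_eps, x$sigma_s, x$tau * 1e12))
  invisible(x)
}

#' Dielectric library for the axillary region
#'
#' Returns the Debye parameters of the tissues used in the axillary phantoms:
#' skin, adipose tissue, muscle, and the surface / cross-section values of
#' healthy and metastasized lymph nodes. The heterogeneous healthy background
#' tissue uses the adipose parameters. Any entry can be overridden by name.
#'
#' @param ... named `debye_medium` objects overriding individual entries.
#' @param tau relaxation time in seconds applied to every default entry
#'   (a single shared relaxation constant; only the skin value is tabulated
#'   in the literature source).
#' @return A named list of `debye_medium` objects with entries `skin`,
#'   `adipose`, `muscle`, `healthy_aln_surface`, `healthy_aln_cross`,
#'   `metastasized_aln_surface`, `metastasized_aln_cross`,
#'   `background_healthy`.
#' @export
tissue_library <- function(..., tau = 13e-12) {
  lib <- list(
    skin                     = debye_medium(15.93, 23.83, 0.83, tau),
    adipose                  = debye_medium( 3.12,  1.59, 0.05, tau),
    muscle                   = debye_medium(21.66, 33.24, 0.89, tau),
    healthy_aln_surface      = debye_medium( 3.60,  1.71, 0.19, tau),
    healthy_aln_cross        = debye_medium(10.34, 17.56, 0.57, tau),
    metastasized_aln_surface = debye_medium( 6.86, 12.37, 0.67, tau),
    metastasized_aln_cross   = debye_medium( 8.81, 38.82, 1.15, tau)
  )
  lib$background_healthy <- lib$adipose
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("overrides must be named")
    bad <- setdiff(names(dots), names(lib))
    if (length(bad)) stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (!inherits(dots[[nm]], "debye_medium"))
        stop("override for '", nm, "' is not a debye_medium")
      lib[[nm]] <- dots[[nm]]
    }
  }
  lib
}

#' Complex relative permittivity of a Debye medium
#'
#' Evaluates the single-pole Debye model at one or more frequencies under the
#' engineering \eqn{e^{+j\omega t}} time convention, so a lossy medium has a
#' negative imaginary part.
#'
#' @param medium a `debye_medium`.
#' @param frequency frequency in Hz (> 0); may be a vector.
#' @return Complex relative permittivity, same length as `frequency`.
#' @examples
#' sk <- tissue_library()$skin
#' debye_permittivity(sk, 7.5e9)
#' @export
debye_permittivity <- function(medium, frequency) {
  stopifnot(inherits(medium, "debye_medium"))
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be positive and finite; the static limit is eps_inf + delta_eps")
  eps0 <- 8.8541878128e-12
  w <- 2 * pi * frequency
  medium$eps_inf +
    medium$delta_eps / (1 + 1i * w * medium$tau) +
    medium$sigma_s / (1i * w * eps0)
}

#' Effective propagation speed in a Debye medium
#'
#' Phase speed \eqn{c_0 / \sqrt{\mathrm{Re}\,\varepsilon_r(f)}} used as the
#' single effective speed of the beamforming delay model.
#'
#' @inheritParams debye_permittivity
#' @return Speed in m/s.
#' @export
effective_speed <- function(medium, frequency) {
  299792458 / sqrt(Re(debye_permittivity(medium, frequency)))
}
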