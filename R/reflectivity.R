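# Specular reflectivity of a stratified medium by the Abeles characteristic
# matrix method, optional Nevot-Croce interfacial roughness, and Gaussian
# dq/q resolution smearing. All heavy lifting is in the compiled kernels.

#' Layer stack for the matrix engine
#'
#' @param thickness Interior layer thicknesses (\eqn{\mathrm{\AA}}); may be
#'   empty for a single interface.
#' @param sld SLDs (\eqn{\mathrm{\AA}^{-2}}) of fronting half-space, interior
#'   layers and backing half-space: `length(thickness) + 2` values.
#' @param roughness Optional Nevot-Croce interfacial widths
#'   (\eqn{\mathrm{\AA}}), one per interface (`length(thickness) + 1`);
#'   default 0 (sharp).
#' @return Object of class `layer_stack`.
#' @export
#' @examples
#' layer_stack(50, c(2.07e-6, 4e-6, 6.35e-6))
layer_stack <- function(thickness, sld, roughness = NULL) {
  thickness <- as.numeric(thickness)
  sld <- as.numeric(sld)
  if (length(sld) != length(thickness) + 2)
    stop("need length(thickness) + 2 SLD values (fronting, layers, backing)")
  if (length(thickness) && any(thickness <= 0))
    stop("interior layer thicknesses must be positive")
  if (is.null(roughness)) roughness <- rep(0, length(thickness) + 1)
  roughness <- rep_len(as.numeric(roughness), length(thickness) + 1)
  if (any(roughness < 0)) stop("roughness must be non-negative")
  structure(list(thickness = thickness, sld = sld, roughness = roughness),
            class = "layer_stack")
}

#' Neutron wavevector inside a medium
#'
#' \eqn{k_n = \{q^2/4 - 4\pi[\rho_n - \rho_0]\}^{1/2}} with the principal
#' branch taken so the imaginary part is non-negative (decaying evanescent
#' wave below the critical edge).
#'
#' @param q Momentum transfer (\eqn{\mathrm{\AA}^{-1}}), > 0.
#' @param sld SLD of the medium (\eqn{\mathrm{\AA}^{-2}}).
#' @param rho_fronting SLD of the fronting medium.
#' @return Complex vector.
#' @export
neutron_wavevector <- function(q, sld, rho_fronting) {
  if (any(q <= 0)) stop("q must be positive")
  rad <- q^2 / 4 - 4 * pi * (sld - rho_fronting)
  ifelse(rad >= 0, complex(real = sqrt(pmax(rad, 0))),
         complex(imaginary = sqrt(pmax(-rad, 0))))
}

#' Specular reflectivity of a sharp-interface stack
#'
#' Exact dynamical reflectivity from the ordered product of 2x2
#' characteristic matrices with Fresnel coefficients
#' \eqn{r_{n,n+1} = (k_n - k_{n+1})/(k_n + k_{n+1})}. Interfaces are sharp;
#' see [nevot_croce_reflectivity()] for Gaussian roughness.
#'
#' @param stack A [layer_stack()] (roughness ignored here).
#' @param q Momentum transfer grid (\eqn{\mathrm{\AA}^{-1}}), > 0.
#' @return Reflectivities in `[0, 1]`.
#' @export
#' @examples
#' s <- layer_stack(numeric(0), c(2.07e-6, 6.35e-6))
#' reflectivity(s, 0.01)  # below the critical edge: total reflection
reflectivity <- function(stack, q) {
  stopifnot(inherits(stack, "layer_stack"))
  if (any(q <= 0)) stop("q must be positive")
  abeles_cpp(as.numeric(q), stack$thickness, stack$sld,
             rep(0, length(stack$thickness) + 1))
}

#' Reflectivity with Nevot-Croce interfacial roughness
#'
#' As [reflectivity()] but each Fresnel coefficient is damped by
#' \eqn{\exp(-2 k_n k_{n+1} \sigma_r^2)} with \eqn{\sigma_r} the Gaussian
#' width of that interface. Identical to the sharp result at
#' \eqn{\sigma_r = 0}.
#'
#' @param stack A [layer_stack()] carrying the roughness values.
#' @param q Momentum transfer grid, > 0.
#' @return Reflectivities (not clamped; the Nevot-Croce factor is an
#'   approximation and is only used for data generation here).
#' @export
nevot_croce_reflectivity <- function(stack, q) {
  stopifnot(inherits(stack, "layer_stack"))
  if (any(q <= 0)) stop("q must be positive")
  if (any(stack$roughness < 0)) stop("roughness must be non-negative")
  abeles_cpp(as.numeric(q), stack$thickness, stack$sld, stack$roughness,
             clamp_unit = FALSE)
}

#' Gaussian instrumental resolution smearing
#'
#' Replaces each point of a tabulated theory curve by a `p`-point weighted
#' average spanning \eqn{\pm 2.5} standard deviations of a Gaussian whose
#' FWHM is `dq_over_q * q` (weights normalized to one; values between tabled
#' points obtained by linear interpolation, clamped at the ends).
#'
#' @param q Momentum transfer grid of the tabulated curve.
#' @param R Theory reflectivity on `q`.
#' @param dq_over_q Fractional resolution; scalar or one value per point;
#'   `0` returns the input unchanged.
#' @param p Odd number of points in the average (default 17).
#' @return Smeared reflectivity on `q`.
#' @export
smear_resolution <- function(q, R, dq_over_q = 0.1, p = 17L) {
  p <- as.integer(p)
  if (p < 3L || p %% 2L == 0L) stop("p must be an odd integer >= 3")
  if (length(R) != length(q)) stop("q and R lengths differ")
  if (any(dq_over_q < 0)) stop("dq_over_q must be non-negative")
  smear_cpp(as.numeric(q), as.numeric(R), as.numeric(dq_over_q), p)
}

#' One measured or simulated reflectivity curve
#'
#' Container for a single solvent contrast: the q-grid, reflectivities,
#' optional uncertainties, the fractional resolution, and the fronting and
#' solvent SLDs. Points with non-positive reflectivity cannot enter the
#' logarithmic part of the fit score and are dropped with a warning; q is
#' sorted ascending.
#'
#' @param q Momentum transfer (\eqn{\mathrm{\AA}^{-1}}), positive.
#' @param R Reflectivities.
#' @param dR Optional 1-sigma uncertainties.
#' @param dq_over_q Fractional resolution FWHM (default 0.10).
#' @param rho_fronting Fronting medium SLD (\eqn{\mathrm{\AA}^{-2}}).
#' @param rho_solvent Solvent (backing) SLD (\eqn{\mathrm{\AA}^{-2}}).
#' @param label Short name, e.g. `"D2O"`.
#' @return Object of class `contrast_curve`. Attribute `n_dropped` records
#'   how many non-positive-R rows were removed.
#' @export
contrast_curve <- function(q, R, dR = NULL, dq_over_q = 0.1,
                           rho_fronting, rho_solvent, label = "") {
  stopifnot(length(q) == length(R), is.numeric(q), is.numeric(R))
  if (!is.null(dR)) stopifnot(length(dR) == length(R))
  keep <- is.finite(q) & is.finite(R) & q > 0 & R > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    warning(sprintf("dropped %d point(s) with non-positive or non-finite q/R", n_dropped))
  q <- q[keep]; R <- R[keep]
  if (!is.null(dR)) dR <- dR[keep]
  if (length(q) < 2) stop("fewer than two usable data points")
  o <- order(q)
  if (anyDuplicated(q[o])) stop("duplicate q values")
  x <- structure(list(q = q[o], R = R[o], dR = if (is.null(dR)) NULL else dR[o],
                      dq_over_q = dq_over_q, rho_fronting = rho_fronting,
                      rho_solvent = rho_solvent, label = label),
                 class = "contrast_curve")
  attr(x, "n_dropped") <- n_dropped
  x
}

#' @export
print.contrast_curve <- function(x, ...) {
  cat(sprintf("Contrast curve '%s': %d points, q in [%.4g, %.4g] A^-1, rho_solvent = %.3g A^-2\n",
              x$label, length(x$q), min(x$q), max(x$q), x$rho_solvent))
  invisible(x)
}

#' Smeared model reflectivity on a contrast's q-grid
#'
#' Composition of [discretize_model()], [reflectivity()] and
#' [smear_resolution()]: the theoretical, resolution-smeared reflectivity of
#' an interfacial model evaluated exactly on the experimental grid of one
#' contrast.
#'
#' @param model An [interfacial_model()].
#' @param contrast A [contrast_curve()].
#' @param p Points in the smearing average (default 17).
#' @return Numeric vector `R(q)` on `contrast$q`.
#' @export
forward_curve <- function(model, contrast, p = 17L) {
  stopifnot(inherits(contrast, "contrast_curve"))
  dz <- discretize_model(model, contrast$rho_solvent, contrast$rho_fronting)
  st <- layer_stack(dz$thickness, dz$sld)
  smear_resolution(contrast$q, reflectivity(st, contrast$q),
                   contrast$dq_over_q, p)
}
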