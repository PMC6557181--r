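# The two-profile interfacial model: N equal sub-layers of total extension D,
# each carrying a non-solvent SLD rho_n and a hydration (solvent volume
# fraction) h_n, blended across layer boundaries by a Gaussian error function
# of width sigma. Virtual boundary layers pin h to 0 at the fronting side and
# 1 at the backing side; the non-solvent SLD plateaus are the fronting SLD and
# the solvent SLD of the contrast being evaluated.

#' Construct an interfacial profile model
#'
#' The unknowns of the reconstruction: `N` equally thick sub-layers spanning
#' a total extension `D`, each with a non-solvent scattering length density
#' `rho[n]` and a hydration fraction `h[n]`, plus a single smoothing length
#' `sigma` shared by both profiles. Hydration is pinned to 0 just before the
#' film (fronting side) and 1 just after it (backing side) by virtual
#' boundary layers that are not free parameters.
#'
#' @param D Total extension of the interfacial layer (\eqn{\mathrm{\AA}}), > 0.
#' @param N Number of sub-layers (default 50).
#' @param rho Numeric vector of `N` non-solvent SLDs (\eqn{\mathrm{\AA}^{-2}}).
#'   Scalar values are recycled.
#' @param h Numeric vector of `N` hydration fractions in `[0, 1]`. Scalars
#'   are recycled.
#' @param sigma Smoothing length (\eqn{\mathrm{\AA}}). Defaults to the lower
#'   resolution limit \eqn{\pi/(4 q_{max})}.
#' @param rho_min,rho_max Admissible SLD bounds. Default to the H2O and D2O
#'   values, the natural limits for non-deuterated aqueous systems.
#' @param q_max Maximum momentum transfer the model will be compared against
#'   (\eqn{\mathrm{\AA}^{-1}}); fixes the admissible range of `sigma`.
#' @return An object of class `interfacial_model`.
#' @export
#' @examples
#' m <- interfacial_model(D = 170, rho = 2e-6, h = 0)
#' m$d  # sub-layer thickness
interfacial_model <- function(D, N = 50L, rho = 0, h = 0, sigma = NULL,
                              rho_min = sld_registry()[["H2O"]],
                              rho_max = sld_registry()[["D2O"]],
                              q_max = 0.25) {
  stopifnot(is.numeric(D), length(D) == 1, is.finite(D))
  if (D <= 0) stop("total extension D must be positive")
  N <- as.integer(N)
  stopifnot(N >= 1, rho_min < rho_max, q_max > 0)
  rho <- rep_len(as.numeric(rho), N)
  h <- rep_len(as.numeric(h), N)
  slim <- sigma_limits(q_max)
  if (is.null(sigma)) sigma <- slim[1]
  stopifnot(is.numeric(sigma), length(sigma) == 1, is.finite(sigma))
  if (sigma < slim[1] - 1e-12 || sigma > slim[2] + 1e-12)
    stop(sprintf("sigma must lie in [%.4g, %.4g] A for q_max = %g", slim[1],
                 slim[2], q_max))
  if (any(!is.finite(rho)) || any(rho < rho_min - 1e-15) ||
      any(rho > rho_max + 1e-15))
    stop("rho values must be finite and inside [rho_min, rho_max]")
  if (any(!is.finite(h)) || any(h < 0) || any(h > 1))
    stop("hydration values must lie in [0, 1]")
  structure(list(D = D, N = N, d = D / N, rho = rho, h = h, sigma = sigma,
                 rho_min = rho_min, rho_max = rho_max, q_max = q_max,
                 sigma_min = slim[1], sigma_max = slim[2]),
            class = "interfacial_model")
}

#' @export
print.interfacial_model <- function(x, ...) {
  cat(sprintf("Interfacial model: D = %.6g A, N = %d (d = %.6g A), sigma = %.4g A\n",
              x$D, x$N, x$d, x$sigma))
  cat(sprintf("  rho in [%.3g, %.3g] A^-2; mean h = %.3f\n",
              min(x$rho), max(x$rho), mean(x$h)))
  invisible(x)
}

# step values of the two profiles including the virtual outer plateaus
profile_steps <- function(model, which, rho_fronting, rho_backing) {
  if (which == "hydration") c(0, model$h, 1)
  else c(rho_fronting, model$rho, rho_backing)
}

#' Evaluate one smeared profile component
#'
#' Returns the non-solvent SLD profile \eqn{\rho(z)} or the hydration profile
#' \eqn{h(z)} as the error-function-blended sum of steps across the `N + 1`
#' layer boundaries, including the virtual outer plateaus (`h = 0`/`1`;
#' fronting / backing SLDs).
#'
#' @param model An [interfacial_model()].
#' @param z Depths (\eqn{\mathrm{\AA}}); `z = 0` is the fronting/film boundary,
#'   increasing towards the backing (solvent). Tails extend into both media.
#' @param which `"sld"` or `"hydration"`.
#' @param rho_fronting,rho_backing Outer SLD plateaus, required for
#'   `which = "sld"`. `rho_backing` is normally the solvent SLD of the
#'   contrast under consideration.
#' @return Numeric vector, same length as `z`.
#' @export
smeared_component <- function(model, z, which = c("sld", "hydration"),
                              rho_fronting = NULL, rho_backing = NULL) {
  which <- match.arg(which)
  stopifnot(inherits(model, "interfacial_model"))
  if (any(!is.finite(z))) stop("z must be finite")
  if (which == "sld") {
    if (is.null(rho_fronting) || is.null(rho_backing))
      stop("rho_fronting and rho_backing are required for the SLD component")
  } else {
    rho_fronting <- 0; rho_backing <- 0
  }
  v <- profile_steps(model, which, rho_fronting, rho_backing)
  zb <- seq(0, model$D, length.out = model$N + 1)
  # the blending convention is erf((z - nd)/sigma): sigma equals sqrt(2)
  # times the width of the equivalent Gaussian interface, matching the
  # resolution-limit interpretation of the sigma bounds
  erf_profile_cpp(as.numeric(z), zb, v, model$sigma / sqrt(2))
}

#' Composite scattering length density profile
#'
#' Combines the smeared non-solvent SLD and hydration profiles with the
#' solvent SLD of one contrast:
#' \eqn{\rho'(z) = \rho(z)\,[1 - h(z)] + h(z)\,\rho_{solvent}}.
#'
#' @inheritParams smeared_component
#' @param rho_solvent Solvent (backing) SLD of the contrast
#'   (\eqn{\mathrm{\AA}^{-2}}).
#' @param rho_fronting Fronting medium SLD (\eqn{\mathrm{\AA}^{-2}}).
#' @return Numeric vector of composite SLDs.
#' @export
#' @examples
#' m <- interfacial_model(D = 100, N = 10, rho = 2e-6, h = 0.5)
#' composite_sld(m, 50, rho_solvent = 6.35e-6, rho_fronting = 2.07e-6)
composite_sld <- function(model, z, rho_solvent, rho_fronting) {
  r <- smeared_component(model, z, "sld", rho_fronting = rho_fronting,
                         rho_backing = rho_solvent)
  h <- smeared_component(model, z, "hydration")
  r * (1 - h) + h * rho_solvent
}

#' Discretize the composite profile for the reflectivity engine
#'
#' Samples the composite SLD at the centres of equal slabs of thickness
#' `d = D/N`, extended by `padding` on both sides of `[0, D]` so that the
#' smeared tails are captured, and brackets the result with the fronting and
#' backing half-spaces.
#'
#' @inheritParams composite_sld
#' @param padding Sampling extension beyond `[0, D]` on each side
#'   (\eqn{\mathrm{\AA}}); default three times the upper smoothing limit
#'   \eqn{\pi/(2 q_{max})}, rounded up to whole slabs.
#' @return List with `thickness` (interior slab thicknesses), `sld`
#'   (fronting, slabs, backing), `z` (slab centres) and `npad`.
#' @export
discretize_model <- function(model, rho_solvent, rho_fronting, padding = NULL) {
  stopifnot(inherits(model, "interfacial_model"))
  if (is.null(padding)) padding <- 3 * model$sigma_max
  if (padding < 0) stop("padding must be non-negative")
  npad <- as.integer(ceiling(padding / model$d))
  d <- model$d
  zc <- seq(-npad * d + d / 2, by = d, length.out = model$N + 2L * npad)
  sld <- composite_sld(model, zc, rho_solvent, rho_fronting)
  list(thickness = rep(d, length(zc)), sld = c(rho_fronting, sld, rho_solvent),
       z = zc, npad = npad)
}

#' Tabulate profiles for export
#'
#' Evaluates the non-solvent SLD, hydration and per-contrast composite SLD
#' profiles on a z-grid and returns them as a data frame (optionally written
#' as a plain-text table, see [write_profile_table()]).
#'
#' @inheritParams composite_sld
#' @param contrasts List of [contrast_curve()] objects (their fronting and
#'   solvent SLDs define the composite columns).
#' @param z Evaluation grid; default 1 \eqn{\mathrm{\AA}} spacing over
#'   `[-20, D + 20]`.
#' @return Data frame with columns `z`, `rho_nonsolvent`, `hydration` and one
#'   `rho_composite_<label>` per contrast.
#' @export
profile_table <- function(model, contrasts, z = NULL) {
  stopifnot(inherits(model, "interfacial_model"), length(contrasts) >= 1)
  if (is.null(z)) z <- seq(-20, model$D + 20, by = 1)
  rho0 <- contrasts[[1]]$rho_fronting
  out <- data.frame(
    z = z,
    rho_nonsolvent = smeared_component(model, z, "sld", rho_fronting = rho0,
                                       rho_backing = contrasts[[1]]$rho_solvent),
    hydration = smeared_component(model, z, "hydration"))
  for (ct in contrasts) {
    lab <- if (nzchar(ct$label)) ct$label else sprintf("solv%.3g", ct$rho_solvent)
    out[[paste0("rho_composite_", lab)]] <-
      composite_sld(model, z, ct$rho_solvent, ct$rho_fronting)
  }
  out
}
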