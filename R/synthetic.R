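# Ground-truth systems and rendering of multi-contrast reflectivity
# "measurements". Slab systems are rendered with Nevot-Croce roughness;
# continuous profiles are first discretized into slabs; model systems go
# through the same erf-profile forward pipeline the annealing uses. Output
# follows the usual desk conventions for simulated neutron data: q up to
# 0.25 A^-1, points below R = 1e-6 (the typical background level) removed,
# dq/q = 10%.

#' Define a ground-truth system
#'
#' @param name Short identifier.
#' @param type `"slab"` (Nevot-Croce stack), `"profile"` (continuous
#'   profile discretized into `n_layers` slabs) or `"model"` (an
#'   [interfacial_model()] rendered through the erf-profile engine).
#' @param thickness,rho_ns,h,roughness Slab description (`type = "slab"`):
#'   layer thicknesses, non-solvent SLDs, hydrations, and the
#'   `length(thickness) + 1` interfacial roughnesses.
#' @param profile For `type = "profile"`: `function(z)` returning a list or
#'   data.frame with `rho_ns` and `h` at depth `z`; support `[0, extent]`.
#' @param extent Total extent of a profile system (\eqn{\mathrm{\AA}}).
#' @param n_layers Slabs used to discretize a profile system.
#' @param model For `type = "model"`: the interfacial model itself.
#' @param fronting Name in [sld_registry()] or an SLD value.
#' @param contrasts Character names from [sld_registry()] or a named numeric
#'   vector of solvent SLDs.
#' @param q_max,R_floor,dq_over_q Truncation and resolution conventions.
#' @return Object of class `ground_truth_system`.
#' @export
ground_truth_system <- function(name, type = c("slab", "profile", "model"),
                                thickness = NULL, rho_ns = NULL, h = NULL,
                                roughness = NULL, profile = NULL,
                                extent = NULL, n_layers = 20L, model = NULL,
                                fronting = "Si",
                                contrasts = c("D2O", "SMW", "H2O"),
                                q_max = 0.25, R_floor = 1e-6,
                                dq_over_q = 0.1) {
  type <- match.arg(type)
  reg <- sld_registry()
  rho0 <- if (is.character(fronting)) unname(reg[[fronting]]) else fronting
  solv <- if (is.character(contrasts)) {
    stats::setNames(unname(reg[contrasts]), contrasts)
  } else contrasts
  if (any(is.na(solv))) stop("unknown contrast name")
  if (type == "slab") {
    stopifnot(length(thickness) >= 1,
              length(rho_ns) == length(thickness),
              length(h) == length(thickness))
    if (is.null(roughness)) roughness <- rep(0, length(thickness) + 1)
    stopifnot(length(roughness) == length(thickness) + 1)
    extent <- sum(thickness)
  } else if (type == "profile") {
    stopifnot(is.function(profile), extent > 0, n_layers >= 2)
  } else {
    stopifnot(inherits(model, "interfacial_model"))
    extent <- model$D
  }
  structure(list(name = name, type = type, thickness = thickness,
                 rho_ns = rho_ns, h = h, roughness = roughness,
                 profile = profile, extent = extent,
                 n_layers = as.integer(n_layers), model = model,
                 rho_fronting = rho0, solvents = solv, q_max = q_max,
                 R_floor = R_floor, dq_over_q = dq_over_q),
            class = "ground_truth_system")
}

#' The rough three-layer validation system
#'
#' Three 50 \eqn{\mathrm{\AA}} layers on silicon with 5 \eqn{\mathrm{\AA}}
#' interfacial roughness, non-solvent SLDs 5, 0 and 2
#' \eqn{\times 10^{-6}\,\mathrm{\AA}^{-2}} and a 50% solvent-penetrated
#' third layer, rendered at the D2O, SMW and H2O contrasts.
#'
#' @return A [ground_truth_system()].
#' @export
three_layer_system <- function() {
  ground_truth_system("three_layer", "slab",
                      thickness = c(50, 50, 50),
                      rho_ns = c(5e-6, 0, 2e-6),
                      h = c(0, 0, 0.5),
                      roughness = rep(5, 4))
}

#' Close-packed nanoparticle layer with a parabolic profile
#'
#' Spherical silica nanoparticles of the given radius in a close-packed
#' arrangement at the silicon surface produce a parabolic non-solvent
#' volume-fraction profile
#' \eqn{\phi(z) = \phi_{max}[1 - (z - R_p)^2/R_p^2]} over
#' \eqn{0 \le z \le 2R_p}, with hydration \eqn{h(z) = 1 - \phi(z)}. For
#' curve generation the profile is approximated by `n_layers` slabs with
#' Nevot-Croce roughness.
#'
#' @param radius Particle radius \eqn{R_p} (\eqn{\mathrm{\AA}}).
#' @param sld Particle material SLD (silica, \eqn{3.5\times10^{-6}}).
#' @param phi_max Peak volume fraction; default 0.9069, the packing
#'   fraction of a hexagonal layer cross-section at the equator.
#' @param n_layers Slabs in the discretization (default 20).
#' @param roughness Interfacial roughness of the slabs (default 10).
#' @return A [ground_truth_system()].
#' @export
parabolic_nanoparticle_system <- function(radius = 250, sld = 3.5e-6,
                                          phi_max = 0.9069, n_layers = 20L,
                                          roughness = 10) {
  stopifnot(radius > 0, phi_max > 0, phi_max <= 1)
  prof <- function(z) {
    phi <- phi_max * (1 - (z - radius)^2 / radius^2)
    phi <- pmax(phi, 0)
    phi[z < 0 | z > 2 * radius] <- 0
    list(rho_ns = rep(sld, length(z)), h = 1 - phi)
  }
  ground_truth_system("parabolic_nanoparticle", "profile", profile = prof,
                      extent = 2 * radius, n_layers = n_layers,
                      roughness = rep(roughness, n_layers + 1))
}

# slab decomposition (thickness, composite sld per contrast, roughness)
system_slabs <- function(system, rho_solvent) {
  if (system$type == "slab") {
    comp <- system$rho_ns * (1 - system$h) + system$h * rho_solvent
    list(thickness = system$thickness, sld = comp,
         roughness = system$roughness)
  } else if (system$type == "profile") {
    d <- system$extent / system$n_layers
    zc <- (seq_len(system$n_layers) - 0.5) * d
    pr <- system$profile(zc)
    comp <- pr$rho_ns * (1 - pr$h) + pr$h * rho_solvent
    list(thickness = rep(d, system$n_layers), sld = comp,
         roughness = system$roughness)
  } else stop("model systems have no slab decomposition")
}

#' True profiles of a ground-truth system
#'
#' Composite SLD and hydration of the generating model evaluated at depths
#' `z` for one solvent SLD, with the generation roughness applied as
#' erf-blended steps (slab/profile systems) or the model's own smoothing
#' (model systems). Used for plotting and truth-comparison metrics.
#'
#' @param system A [ground_truth_system()].
#' @param z Depths (\eqn{\mathrm{\AA}}).
#' @param rho_solvent Solvent SLD.
#' @return Data frame with `z`, `rho_composite`, `hydration`.
#' @export
system_truth <- function(system, z, rho_solvent) {
  if (system$type == "model") {
    m <- system$model
    return(data.frame(z = z,
                      rho_composite = composite_sld(m, z, rho_solvent,
                                                    system$rho_fronting),
                      hydration = smeared_component(m, z, "hydration")))
  }
  sl <- system_slabs(system, rho_solvent)
  nb <- length(sl$thickness) + 1
  zb <- c(0, cumsum(sl$thickness))
  sig <- pmax(sl$roughness, 1e-9)
  vr <- c(system$rho_fronting, sl$sld, rho_solvent)
  hsrc <- if (system$type == "slab") system$h
          else system$profile((zb[-nb] + zb[-1]) / 2)$h
  vh <- c(0, hsrc, 1)
  data.frame(z = z,
             rho_composite = erf_profile_cpp(z, zb, vr, sig),
             hydration = erf_profile_cpp(z, zb, vh, sig))
}

#' Default simulated q-grid
#'
#' 150 log-spaced points over `[0.005, q_max]` \eqn{\mathrm{\AA}^{-1}},
#' mimicking the coverage of a two-wavelength reflectometer.
#'
#' @param q_max Upper end (default 0.25).
#' @param n Number of points (default 150).
#' @return Numeric vector.
#' @export
default_q_grid <- function(q_max = 0.25, n = 150) {
  exp(seq(log(0.005), log(q_max), length.out = n))
}

#' Render the contrast series of a ground-truth system
#'
#' Computes the resolution-smeared reflectivity of the system at each of
#' its solvent contrasts, applies the truncation conventions
#' (`q <= q_max`, `R >= R_floor`), and optionally adds multiplicative
#' Gaussian noise with a matching `dR` column.
#'
#' @param system A [ground_truth_system()].
#' @param q Momentum transfer grid (default [default_q_grid()]).
#' @param noise Relative noise level (0 = exact curves); `dR = noise * R`.
#' @param seed Optional seed for the noise draw.
#' @return Named list of [contrast_curve()] objects, one per contrast.
#' @export
render_contrast_series <- function(system, q = default_q_grid(system$q_max),
                                   noise = 0, seed = NULL) {
  stopifnot(inherits(system, "ground_truth_system"),
            all(q > 0), !is.unsorted(q))
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- list()
  for (nm in names(system$solvents)) {
    rs <- system$solvents[[nm]]
    if (system$type == "model") {
      ct0 <- contrast_curve(q, rep(1, length(q)),
                            dq_over_q = system$dq_over_q,
                            rho_fronting = system$rho_fronting,
                            rho_solvent = rs, label = nm)
      R <- forward_curve(system$model, ct0)
    } else if (system$type == "slab") {
      # exact rendering of the roughened profile: erf-blended composite on
      # a fine 1 A slab grid through the dynamical engine. The Nevot-Croce
      # factor is avoided here because its error grows as q*roughness
      # approaches 1 and differs between solvent contrasts, which would
      # contaminate a multi-contrast ground truth.
      tr <- system_truth(system,
                         seq(-5 * max(system$roughness) + 0.5,
                             system$extent + 5 * max(system$roughness), 1),
                         rs)
      st <- layer_stack(rep(1, nrow(tr)),
                        c(system$rho_fronting, tr$rho_composite, rs))
      R <- smear_resolution(q, reflectivity(st, q), system$dq_over_q)
    } else {
      # published convention for the nanoparticle layer: n_layers slabs
      # under the Nevot-Croce roughness approximation
      sl <- system_slabs(system, rs)
      st <- layer_stack(sl$thickness,
                        c(system$rho_fronting, sl$sld, rs), sl$roughness)
      R <- smear_resolution(q, nevot_croce_reflectivity(st, q),
                            system$dq_over_q)
    }
    dR <- NULL
    if (noise > 0) {
      dR <- noise * R
      R <- R * (1 + noise * rnorm(length(R)))
      R <- pmax(R, 1e-7)  # absolute floor of the noise model
    }
    keep <- q <= system$q_max & R >= system$R_floor
    out[[nm]] <- contrast_curve(q[keep], R[keep], dR = dR[keep],
                                dq_over_q = system$dq_over_q,
                                rho_fronting = system$rho_fronting,
                                rho_solvent = rs, label = nm)
  }
  out
}
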