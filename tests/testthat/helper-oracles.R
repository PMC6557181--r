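# Independent closed-form oracles used across the tests. These deliberately
# re-derive textbook results (parratt-style interface formulas, numeric
# cosine transforms) without touching the package's own kernels.

# complex normal wavevector in a medium, referenced to the fronting SLD
oracle_k <- function(q, sld, rho0) {
  rad <- q^2 / 4 - 4 * pi * (sld - rho0)
  ifelse(rad >= 0, complex(real = sqrt(pmax(rad, 0))),
         complex(imaginary = sqrt(pmax(-rad, 0))))
}

# Fresnel reflectivity of a single interface, optional Gaussian roughness
oracle_fresnel <- function(q, rho0, rho1, rough = 0) {
  k0 <- oracle_k(q, rho0, rho0)
  k1 <- oracle_k(q, rho1, rho0)
  r <- (k0 - k1) / (k0 + k1)
  if (rough > 0) r <- r * exp(-2 * k0 * k1 * rough^2)
  Mod(r)^2
}

# analytic two-boundary (single slab) reflectance
oracle_slab <- function(q, rho0, rho1, rho2, t) {
  vapply(q, function(qi) {
    k0 <- oracle_k(qi, rho0, rho0)
    k1 <- oracle_k(qi, rho1, rho0)
    k2 <- oracle_k(qi, rho2, rho0)
    r01 <- (k0 - k1) / (k0 + k1)
    r12 <- (k1 - k2) / (k1 + k2)
    ph <- exp(2i * k1 * t)
    Mod((r01 + r12 * ph) / (1 + r01 * r12 * ph))^2
  }, numeric(1))
}

# kinematic |FT(drho/dz)|^2-based reflectivity of a sharp slab: two delta
# steps a1 at z = 0 and a2 at z = t
oracle_kinematic_slab <- function(q, a1, a2, t) {
  16 * pi^2 * (a1^2 + a2^2 + 2 * a1 * a2 * cos(q * t)) / q^4
}

# brute-force numeric cosine transform of an arbitrary p(z)
oracle_cosine_transform <- function(pfun, D, q, nz = 4001) {
  z <- seq(0, D, length.out = nz)
  w <- rep(z[2] - z[1], nz); w[c(1, nz)] <- w[1] / 2
  pz <- pfun(z)
  2 * drop(cos(outer(q, z)) %*% (pz * w))
}

# small three-contrast slab fixture used by several modules (not one of the
# published validation systems; kept cheap on purpose)
tiny_two_layer_system <- function(roughness = 4) {
  ground_truth_system("tiny_two_layer", "slab",
                      thickness = c(40, 30),
                      rho_ns = c(4e-6, 1e-6),
                      h = c(0, 0.3),
                      roughness = rep(roughness, 3))
}
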