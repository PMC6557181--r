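# Indirect Fourier transform of reflectivity in the kinematic (Born)
# approximation. p(z), the autocorrelation of dSLD/dz, is expanded in cubic
# B-splines on [0, D]; in that approximation
#     q^4 R(q) / 16 pi^2 = 2 * Integral_0^D p(z) cos(qz) dz,
# which is linear in the spline coefficients, so a weighted least-squares
# fit with a Lagrange-multiplier smoothness penalty Lambda * N_c gives the
# regularized curve. Scanning Lambda yields the stability plot from which
# Lambda is picked at the inflection of log N_c vs log Lambda; scanning
# trial D values yields the overall-extension estimate.

#' Cubic B-spline expansion of the correlation function p(z)
#'
#' @param D Overall extension (\eqn{\mathrm{\AA}}), > 0.
#' @param coefficients Spline coefficients.
#' @param n_splines Number of uniform cubic B-splines on `[0, D]`.
#' @return Object of class `spline_correlation`.
#' @export
spline_correlation <- function(D, coefficients, n_splines = length(coefficients)) {
  if (D <= 0) stop("D must be positive")
  stopifnot(n_splines >= 4, length(coefficients) == n_splines)
  structure(list(D = D, n_splines = n_splines,
                 coefficients = as.numeric(coefficients)),
            class = "spline_correlation")
}

# Uniform cubic B-spline design matrix on [0, D]; n basis functions, every
# one with support ending at or before z = D, so the expansion vanishes at
# D with cubic contact (p(D) = p'(D) = 0): the correlation function is
# forced to approach the z axis smoothly at the trial extension, which is
# what makes the trial-D diagnostics discriminating. p(0) stays free.
bspline_basis <- function(z, D, n_splines) {
  h <- D / n_splines
  knots <- seq(-3 * h, D, by = h)
  splines::splineDesign(knots, pmin(pmax(z, 0), D), ord = 4, outer.ok = TRUE)
}

#' Evaluate p(z)
#'
#' @param sp A [spline_correlation()].
#' @param z Depths in `[0, D]` (clamped).
#' @return Numeric vector.
#' @export
evaluate_p <- function(sp, z) {
  stopifnot(inherits(sp, "spline_correlation"))
  drop(bspline_basis(z, sp$D, sp$n_splines) %*% sp$coefficients)
}

# critical edge of the strongest known interface of a curve
critical_q <- function(curve) {
  drho <- abs(curve$rho_solvent - curve$rho_fronting)
  sqrt(16 * pi * max(drho, 1e-7))
}

# Linear model pieces for the kinematic fit of one curve at one trial D,
# for q >= q_cut_factor * q_c (the Born approximation fails near total
# reflection). Two fit bases are supported; both compare the cosine
# transform 2 Int p(z) cos(qz) dz with a rescaled reflectivity:
#   "fresnel": y = drho^2 R / R_F, the master-formula form with R_F the
#     Fresnel curve of the bare fronting/solvent step. Dividing by R_F
#     absorbs most of the dynamical distortion near the critical edge (the
#     same normalization used for stability-plot displays), which is
#     essential for trial-D scans: with raw q^4 weighting the smooth low-q
#     dynamical residue masquerades as long-range structure in p(z).
#   "q4": y = q^4 R / 16 pi^2, the plain Born weighting.
# The smearing operator is the same p-point Gaussian average used by the
# dynamical engine, assembled as a matrix so the prediction stays linear.
ift_design <- function(curve, D, n_splines = 25, q_cut_factor = 3,
                       p = 17L, nz = NULL, rel_sigma = 0.01,
                       fit_basis = c("fresnel", "q4")) {
  stopifnot(inherits(curve, "contrast_curve"))
  fit_basis <- match.arg(fit_basis)
  if (D <= 0) stop("D must be positive")
  qc <- critical_q(curve)
  keep <- curve$q >= q_cut_factor * qc
  if (sum(keep) < n_splines)
    stop(sprintf("only %d points above %g * q_c; reduce n_splines or the cut",
                 sum(keep), q_cut_factor))
  q <- curve$q[keep]
  R <- curve$R[keep]
  drho <- curve$rho_solvent - curve$rho_fronting
  if (fit_basis == "fresnel" && abs(drho) < 1e-8) {
    fit_basis <- "q4"  # contrast-matched solvent: no Fresnel curve to divide by
  }
  # envelope E(q): y = E * R and the design is E S E^-1 A0
  E <- if (fit_basis == "fresnel") {
    k0 <- q / 2
    k1 <- neutron_wavevector(q, curve$rho_solvent, curve$rho_fronting)
    RF <- Mod((k0 - k1) / (k0 + k1))^2
    drho^2 / RF
  } else {
    q^4 / (16 * pi^2)
  }
  y <- E * R
  sigma_y <- if (!is.null(curve$dR)) {
    E * pmax(curve$dR[keep], 1e-12 * R)
  } else {
    rel_sigma * pmax(abs(y), 1e-3 * mean(abs(y)))
  }
  w <- 1 / sigma_y^2

  if (is.null(nz)) nz <- max(600, ceiling(40 * D * max(q) / (2 * pi)))
  zg <- seq(0, D, length.out = nz)
  wz <- rep(zg[2] - zg[1], nz); wz[c(1, nz)] <- wz[1] / 2  # trapezoid
  B <- bspline_basis(zg, D, n_splines)                      # nz x ns
  C <- cos(outer(q, zg))                                    # nq x nz
  A0 <- 2 * (C %*% (B * wz))                                # cosine transform
  # smearing acts on the reflectivity itself: S[j, i] = d smeared_j / d R_i,
  # built by pushing unit vectors through the engine's smearing kernel
  S <- vapply(seq_along(q), function(i) {
    e <- numeric(length(q)); e[i] <- 1
    smear_cpp(q, e, curve$dq_over_q, as.integer(p))
  }, numeric(length(q)))
  A <- E * (S %*% (A0 / E))
  list(q = q, y = y, w = w, A = A, D = D, n_splines = n_splines,
       n = length(q), q_cut = q_cut_factor * qc, fit_basis = fit_basis)
}

penalty_matrix <- function(n, type = c("diff1", "diff2")) {
  type <- match.arg(type)
  Dm <- diff(diag(n), differences = if (type == "diff1") 1 else 2)
  crossprod(Dm)
}

#' Regularized spline fit at fixed Lambda
#'
#' Minimizes \eqn{\chi^2 + \Lambda N_c} in the spline coefficients, where
#' \eqn{\chi^2} is the weighted misfit of the smeared kinematic prediction
#' to \eqn{q^4 R/16\pi^2} and \eqn{N_c} is the smoothness penalty (sum of
#' squared first differences of the coefficients by default).
#'
#' @param curve A [contrast_curve()] (weights from `dR` when present,
#'   otherwise a constant relative error).
#' @param D Trial overall extension (\eqn{\mathrm{\AA}}).
#' @param lambda Lagrange multiplier, >= 0.
#' @param n_splines Number of cubic B-splines (default 25).
#' @param penalty `"diff1"` (default) or `"diff2"`.
#' @param design Optional precomputed design from the internal builder (used
#'   by the scans to avoid rebuilding).
#' @param ... Passed to the design builder (`q_cut_factor`, `p`, `nz`).
#' @return List with `spline` ([spline_correlation()]), `chi2` (weighted
#'   misfit), `chi2n` (per point), `Nc`, `lambda`, `fitted` (regularized
#'   \eqn{q^4R/16\pi^2} on the fitted grid) and `design`.
#' @export
fit_given_lambda <- function(curve, D, lambda, n_splines = 25,
                             penalty = "diff1", design = NULL, ...) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.null(design)) design <- ift_design(curve, D, n_splines, ...)
  A <- design$A; y <- design$y; w <- design$w
  P <- penalty_matrix(design$n_splines, penalty)
  M <- crossprod(A, w * A) + lambda * P
  # tiny ridge keeps the unregularized reference fit solvable when the
  # smeared cosine design is numerically rank-deficient
  diag(M) <- diag(M) + 1e-12 * mean(abs(diag(M)))
  cf <- tryCatch(solve(M, crossprod(A, w * y)),
                 error = function(e)
                   stop(sprintf("singular normal equations (rcond = %.3g): %s",
                                rcond(M), conditionMessage(e))))
  cf <- drop(cf)
  fitted <- drop(A %*% cf)
  chi2 <- sum(w * (y - fitted)^2)
  list(spline = spline_correlation(design$D, cf, design$n_splines),
       chi2 = chi2, chi2n = chi2 / design$n,
       Nc = drop(crossprod(cf, P %*% cf)), lambda = lambda,
       fitted = fitted, design = design)
}

#' Smeared kinematic prediction from a p(z) expansion
#'
#' Evaluates \eqn{2\int_0^D p(z)\cos(qz)\,dz}, i.e. the kinematic
#' \eqn{q^4 R/16\pi^2}, then applies the Gaussian resolution smearing (to
#' the implied reflectivity, as the engine does).
#'
#' @param sp A [spline_correlation()].
#' @param q Momentum transfer grid, > 0.
#' @param dq_over_q Fractional resolution (0 = no smearing).
#' @param p Points in the smearing average.
#' @return Predicted \eqn{q^4 R_{kin}/16\pi^2} on `q`.
#' @export
kinematic_transform <- function(sp, q, dq_over_q = 0, p = 17L) {
  stopifnot(inherits(sp, "spline_correlation"))
  if (any(q <= 0)) stop("q must be positive")
  nz <- max(600, ceiling(40 * sp$D * max(q) / (2 * pi)))
  zg <- seq(0, sp$D, length.out = nz)
  wz <- rep(zg[2] - zg[1], nz); wz[c(1, nz)] <- wz[1] / 2
  pz <- evaluate_p(sp, zg)
  u <- 2 * drop(cos(outer(q, zg)) %*% (pz * wz))
  if (dq_over_q > 0) {
    Rk <- 16 * pi^2 * u / q^4
    u <- q^4 * smear_cpp(as.numeric(q), Rk, dq_over_q, as.integer(p)) / (16 * pi^2)
  }
  u
}

#' Stability scan over the Lagrange multiplier
#'
#' Tabulates the smoothness penalty \eqn{N_c(\Lambda)} and misfit
#' \eqn{\chi^2(\Lambda)} over a log-spaced grid of Lambda values scaled by
#' the self-normalizing ratio \eqn{\chi^2(0)/N_c(0)}.
#'
#' @inheritParams fit_given_lambda
#' @param n_lambda Number of grid points (default 40).
#' @param lambda_rel Relative span of the grid (default `10^-4 .. 10^4`).
#' @return Object of class `stability_scan`: data frame fields `lambda`,
#'   `chi2`, `Nc` plus the coefficient matrix and design.
#' @export
stability_scan <- function(curve, D, n_lambda = 40,
                           lambda_rel = c(1e-4, 1e4), n_splines = 25,
                           penalty = "diff1", design = NULL, ...) {
  if (n_lambda < 20) stop("use at least 20 lambda values")
  if (is.null(design)) design <- ift_design(curve, D, n_splines, ...)
  f0 <- fit_given_lambda(curve, D, 0, design = design, penalty = penalty)
  scale <- if (f0$Nc > 0) f0$chi2 / f0$Nc else 1
  lambdas <- scale * 10^seq(log10(lambda_rel[1]), log10(lambda_rel[2]),
                            length.out = n_lambda)
  fits <- lapply(lambdas, function(l)
    fit_given_lambda(curve, D, l, design = design, penalty = penalty))
  structure(list(lambda = lambdas,
                 chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
                 Nc = vapply(fits, `[[`, numeric(1), "Nc"),
                 coefficients = vapply(fits, function(f) f$spline$coefficients,
                                       numeric(design$n_splines)),
                 D = D, design = design, penalty = penalty),
            class = "stability_scan")
}

#' Pick Lambda at the inflection of log Nc versus log Lambda
#'
#' Restricted to the region where \eqn{\chi^2} is within `eps` of its
#' left-plateau (small-Lambda) level, the selected Lambda is the last zero
#' crossing of the second derivative of a smoothing-spline fit of
#' \eqn{\log N_c} against \eqn{\log\Lambda} - the inflection "in the middle
#' of the plateau before \eqn{\chi^2} starts to increase". A featureless
#' scan falls back to the midpoint of the widest flat stretch and is
#' flagged.
#'
#' @param scan A [stability_scan()].
#' @param eps Allowed fractional rise of chi2 above its left-plateau median
#'   (default 0.10).
#' @return List with `lambda`, `index` (nearest grid point), `flagged`
#'   (TRUE when the fallback was used) and `method`.
#' @export
select_lambda <- function(scan, eps = 0.10) {
  stopifnot(inherits(scan, "stability_scan"))
  x <- log10(scan$lambda)
  yN <- log10(pmax(scan$Nc, 1e-300))
  n <- length(x)
  n_left <- max(3L, n %/% 5L)
  plateau <- median(scan$chi2[seq_len(n_left)])
  allowed <- scan$chi2 <= (1 + eps) * plateau
  if (!any(allowed)) allowed <- rep(TRUE, n)
  ss <- smooth.spline(x, yN, df = min(8, n - 2))
  d2 <- predict(ss, x, deriv = 2)$y
  d1 <- predict(ss, x, deriv = 1)$y
  # a real inflection needs the slope itself to vary; a featureless
  # (near-linear) decline only has numerical-noise curvature
  significant <- diff(range(d1)) > 0.5 * max(abs(d1))
  # zero crossings of the second derivative between consecutive grid
  # points, restricted to steep stretches (plateau-edge wiggles of the
  # smoother also cross zero, but with near-zero slope)
  cross <- which(d2[-n] * d2[-1] < 0)
  cross <- cross[allowed[cross] & allowed[cross + 1] &
                   abs(d1[cross]) >= 0.3 * max(abs(d1))]
  if (!significant) cross <- integer(0)
  if (length(cross)) {
    i <- cross[length(cross)]  # the one nearest the chi2 rise
    t <- d2[i] / (d2[i] - d2[i + 1])
    xc <- x[i] + t * (x[i + 1] - x[i])
    return(list(lambda = 10^xc, index = if (t < 0.5) i else i + 1L,
                flagged = FALSE, method = "inflection"))
  }
  # fallback: widest flat stretch of log Nc within the allowed region
  flat <- allowed & abs(d1) <= 0.15 * max(abs(d1))
  r <- rle(flat)
  if (any(r$values)) {
    ends <- cumsum(r$lengths)
    iw <- which.max(ifelse(r$values, r$lengths, 0))
    i2 <- ends[iw]; i1 <- i2 - r$lengths[iw] + 1L
    mid <- (i1 + i2) %/% 2L
  } else mid <- which(allowed)[sum(allowed) %/% 2L + 1L]
  list(lambda = scan$lambda[mid], index = mid, flagged = TRUE,
       method = "plateau_fallback")
}

# diagnostics of one regularized solution used by the trial-D scan
p_diagnostics <- function(sp, nz = 201) {
  z <- seq(0, sp$D, length.out = nz)
  pz <- evaluate_p(sp, z)
  pmax_abs <- max(abs(pz))
  tail_idx <- z >= 0.85 * sp$D
  list(tail = mean(abs(pz[tail_idx])) / pmax_abs,
       osc = sum(diff(sign(diff(pz))) != 0) / nz,
       p = pz, z = z)
}

# per-curve knee of log chi2 versus D: the smallest trial D from which the
# remaining per-Angstrom improvement of the regularized misfit stays below
# `slope_tol` for this and the following grid step. Underestimated D fits
# badly (steep improvement still ahead); once D covers the true extent only
# the slow absorption of the kinematic model error remains.
knee_D <- function(D_grid, chi2, slope_tol) {
  slope <- -diff(log(chi2)) / diff(D_grid)   # improvement per Angstrom
  ns <- length(slope)
  # sustained flatness: this and the next two grid steps all below tolerance
  # (a single flat step can be a local shelf on the way down)
  ok <- which(slope < slope_tol &
                c(slope[-1], Inf) < slope_tol &
                c(slope[-(1:2)], Inf, Inf) < slope_tol)
  if (length(ok)) list(D = D_grid[ok[1]], flagged = FALSE)
  else list(D = D_grid[which.min(chi2)], flagged = TRUE)
}

#' Estimate the overall layer extension D by trial IFT
#'
#' Runs a regularized IFT (stability scan + inflection-point Lambda) for
#' every trial `D` on every supplied curve. The spline basis pins
#' `p(D) = p'(D) = 0`, so each solution approaches the z axis smoothly by
#' construction and the discriminating signal is the fit quality: the
#' misfit falls steeply while `D` underestimates the true extent and flattens
#' once it is covered. Per curve, the selected `D` is the knee of
#' `log chi2` versus `D` (the smallest `D` from which the remaining
#' improvement per \eqn{\mathrm{\AA}} stays below `slope_tol`); the overall
#' estimate is the largest per-curve knee, since the extension must
#' accommodate every contrast. The full diagnostic table is returned for
#' audit.
#'
#' @param curves A single [contrast_curve()] or a list of them; following
#'   the usual practice the two most extreme contrasts (D2O and H2O) are
#'   scanned separately and combined.
#' @param D_grid Trial extensions (\eqn{\mathrm{\AA}}), increasing.
#' @param n_splines,penalty,... Passed to the fit (see [fit_given_lambda()]).
#' @param slope_tol Knee threshold on the per-\eqn{\mathrm{\AA}} decay rate
#'   of the misfit (default 0.025, i.e. a factor ~1.3 per 10
#'   \eqn{\mathrm{\AA}} step).
#' @return List with `D_best`, `flagged` (TRUE when any per-curve knee fell
#'   back to the misfit minimum), `per_curve_D`, `table` (one row per trial
#'   D: per-curve misfit, tail amplitude of p, oscillation count) and
#'   `per_curve` details (selected Lambda, chi2, the spline solutions).
#' @export
estimate_D <- function(curves, D_grid, n_splines = 25, penalty = "diff1",
                       slope_tol = 0.025, ...) {
  if (inherits(curves, "contrast_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1, length(D_grid) >= 4, !is.unsorted(D_grid))
  nD <- length(D_grid)
  chi2n <- matrix(NA_real_, nD, length(curves))
  tailm <- matrix(NA_real_, nD, length(curves))
  oscm <- matrix(NA_real_, nD, length(curves))
  per_curve <- vector("list", length(curves))
  for (ci in seq_along(curves)) {
    det <- vector("list", nD)
    for (di in seq_len(nD)) {
      D <- D_grid[di]
      sc <- stability_scan(curves[[ci]], D, n_splines = n_splines,
                           penalty = penalty, ...)
      sel <- select_lambda(sc)
      fit <- fit_given_lambda(curves[[ci]], D, sel$lambda,
                              design = sc$design, penalty = penalty)
      dg <- p_diagnostics(fit$spline)
      chi2n[di, ci] <- fit$chi2n
      tailm[di, ci] <- dg$tail
      oscm[di, ci] <- dg$osc
      det[[di]] <- list(D = D, lambda = sel$lambda,
                        lambda_flagged = sel$flagged, chi2n = fit$chi2n,
                        tail = dg$tail, osc = dg$osc,
                        spline = fit$spline)
    }
    per_curve[[ci]] <- det
  }
  knees <- lapply(seq_along(curves), function(ci)
    knee_D(D_grid, chi2n[, ci], slope_tol))
  per_curve_D <- vapply(knees, `[[`, numeric(1), "D")
  flagged <- any(vapply(knees, `[[`, logical(1), "flagged"))
  tab <- data.frame(D = D_grid, tail = rowMeans(tailm),
                    oscillations = rowMeans(oscm))
  for (ci in seq_along(curves))
    tab[[paste0("chi2n_", ci)]] <- chi2n[, ci]
  list(D_best = max(per_curve_D), flagged = flagged,
       per_curve_D = per_curve_D, table = tab, per_curve = per_curve)
}
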