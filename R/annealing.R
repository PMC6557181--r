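# Simulated-annealing reconstruction of the two interfacial profiles from
# all solvent contrasts simultaneously. The objective is the two-term score
#   f = (1/M_c) sum_c [ mean(((q^4R_exp - q^4R_th)/<q^4R_exp>)^2)
#                       + mean((ln R_exp - ln R_th)^2) ],
# which balances the q^4-weighted and logarithmic views of a reflectivity
# curve so that neither the high-q nor the low-q region dominates.

#' Score configuration: the set of contrasts fitted simultaneously
#'
#' @param contrasts List of [contrast_curve()] objects (at least one); all
#'   must share the same fronting medium type (their `rho_fronting` may
#'   differ between air and solid setups but is per-contrast).
#' @return Object of class `score_config`.
#' @export
score_config <- function(contrasts) {
  if (inherits(contrasts, "contrast_curve")) contrasts <- list(contrasts)
  if (length(contrasts) < 1) stop("need at least one contrast curve")
  ok <- vapply(contrasts, inherits, logical(1), "contrast_curve")
  if (!all(ok)) stop("all elements must be contrast_curve objects")
  structure(list(contrasts = contrasts), class = "score_config")
}

# contrasts in the plain-list form the C++ kernels expect
contrast_payload <- function(config, p = 17L) {
  lapply(config$contrasts, function(ct)
    list(q = ct$q, R = ct$R, rho_fronting = ct$rho_fronting,
         rho_solvent = ct$rho_solvent, dq_over_q = ct$dq_over_q,
         p = as.integer(p)))
}

npad_for <- function(model) as.integer(ceiling(3 * model$sigma_max / model$d))

#' Multi-contrast score of a model
#'
#' @param model An [interfacial_model()].
#' @param config A [score_config()].
#' @return Non-negative scalar; 0 iff the theoretical curves reproduce every
#'   kept experimental point exactly.
#' @export
score <- function(model, config) {
  stopifnot(inherits(model, "interfacial_model"),
            inherits(config, "score_config"))
  score_cpp(model$rho, model$h, model$sigma, model$D, npad_for(model),
            contrast_payload(config))
}

#' Region constraint on the profiles
#'
#' Freezes either the hydration or the non-solvent SLD of all sub-layers
#' whose centres fall in `[z_lo, z_hi)` at a fixed value; frozen parameters
#' are excluded from the annealing move set (for instance the native ~10 A
#' silicon oxide: `h = 0` and `rho = 3.5e-6`).
#'
#' @param z_range Numeric `c(z_lo, z_hi)` in \eqn{\mathrm{\AA}},
#'   `0 <= z_lo < z_hi`.
#' @param kind `"fix_hydration"` or `"fix_sld"`.
#' @param value The frozen hydration fraction or SLD.
#' @return Object of class `profile_constraint`.
#' @export
constraint <- function(z_range, kind = c("fix_hydration", "fix_sld"), value) {
  kind <- match.arg(kind)
  stopifnot(length(z_range) == 2, z_range[1] >= 0, z_range[1] < z_range[2])
  if (kind == "fix_hydration" && (value < 0 || value > 1))
    stop("fixed hydration must lie in [0, 1]")
  structure(list(z_range = as.numeric(z_range), kind = kind,
                 value = as.numeric(value)), class = "profile_constraint")
}

# apply constraints to a model: returns free/fixed masks and the model with
# constrained layers set to their fixed values
apply_constraints <- function(model, constraints) {
  rho_free <- rep(TRUE, model$N)
  h_free <- rep(TRUE, model$N)
  centres <- (seq_len(model$N) - 0.5) * model$d
  for (cn in constraints) {
    stopifnot(inherits(cn, "profile_constraint"))
    if (cn$z_range[2] > model$D + 1e-9)
      stop("constraint range exceeds the model extension D")
    sel <- centres >= cn$z_range[1] & centres < cn$z_range[2]
    if (cn$kind == "fix_hydration") {
      h_free[sel] <- FALSE
      model$h[sel] <- cn$value
    } else {
      if (cn$value < model$rho_min || cn$value > model$rho_max)
        stop("fixed SLD outside [rho_min, rho_max]")
      rho_free[sel] <- FALSE
      model$rho[sel] <- cn$value
    }
  }
  if (!any(rho_free) && !any(h_free))
    stop("model is fully constrained; nothing to anneal")
  list(model = model, rho_free = rho_free, h_free = h_free)
}

#' Annealing schedule
#'
#' Defaults follow the published schedule: start at `T0 = 1`, attempt
#' `100 N` trials per temperature, cool by `T' = 0.9 T`, stop after 100
#' consecutive rejections. The `fast` preset (`20 N` trials, cooling 0.85)
#' trades some refinement for a several-fold shorter run.
#'
#' @param T0 Starting temperature (score units).
#' @param trials_per_T Trials per temperature; `NULL` means `100 N`
#'   (or `20 N` when `fast`).
#' @param cooling Multiplicative cooling factor in (0, 1).
#' @param stop_rejections Consecutive rejections that end the run.
#' @param max_temps Safety cap on temperature decrements.
#' @param fast Use the reduced preset.
#' @param fresh_prob Probability that a move redraws the parameter uniformly
#'   over its whole admissible interval; otherwise a local step of
#'   half-width `max(step_min_frac, sqrt(T/T0))` times the interval is
#'   taken, reflected at the bounds.
#' @param step_min_frac Floor of the local step half-width (fraction of the
#'   interval).
#' @return Object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T0 = 1, trials_per_T = NULL, cooling = NULL,
                            stop_rejections = 100L, max_temps = 250L,
                            fast = FALSE, fresh_prob = 0.2,
                            step_min_frac = 0.02) {
  if (is.null(cooling)) cooling <- if (fast) 0.85 else 0.9
  stopifnot(T0 > 0, cooling > 0, cooling < 1, stop_rejections >= 1,
            max_temps >= 1, fresh_prob >= 0, fresh_prob <= 1,
            step_min_frac > 0, step_min_frac <= 1)
  structure(list(T0 = T0, trials_per_T = trials_per_T, cooling = cooling,
                 stop_rejections = as.integer(stop_rejections),
                 max_temps = as.integer(max_temps), fast = fast,
                 fresh_prob = fresh_prob, step_min_frac = step_min_frac),
            class = "anneal_schedule")
}

trials_for <- function(schedule, N) {
  if (!is.null(schedule$trials_per_T)) return(as.integer(schedule$trials_per_T))
  as.integer((if (schedule$fast) 20 else 100) * N)
}

#' Propose one annealing move
#'
#' Picks uniformly among the free parameters (each free `rho[n]`, each free
#' `h[n]`, and the single `sigma`) and redraws the chosen one uniformly
#' within its admissible interval; all bounds and constraints hold by
#' construction. This mirrors the move rule of the compiled annealing loop.
#'
#' @param model An [interfacial_model()].
#' @param rho_free,h_free Logical masks of movable sub-layers (default all).
#' @return The trial model, with attributes `move_kind`
#'   (`"rho"`/`"h"`/`"sigma"`) and `move_index`.
#' @export
propose_move <- function(model, rho_free = rep(TRUE, model$N),
                         h_free = rep(TRUE, model$N)) {
  ir <- which(rho_free); ih <- which(h_free)
  nmove <- length(ir) + length(ih) + 1L
  m <- floor(runif(1) * nmove) + 1L
  if (m <= length(ir)) {
    i <- ir[m]
    model$rho[i] <- runif(1, model$rho_min, model$rho_max)
    kind <- "rho"
  } else if (m <= length(ir) + length(ih)) {
    i <- ih[m - length(ir)]
    model$h[i] <- runif(1)
    kind <- "h"
  } else {
    model$sigma <- runif(1, model$sigma_min, model$sigma_max)
    kind <- "sigma"; i <- NA_integer_
  }
  attr(model, "move_kind") <- kind
  attr(model, "move_index") <- i
  model
}

#' One simulated-annealing run
#'
#' Starts from random profiles (uniform in the admissible intervals, with
#' `sigma` at its lower limit \eqn{\pi/4q_{max}}), then performs Metropolis
#' annealing: a trial is accepted when the score does not increase, or with
#' probability \eqn{\exp(-\Delta f/T)} otherwise; the temperature drops by
#' the cooling factor every `trials_per_T` trials and the run ends after
#' `stop_rejections` consecutive rejections.
#'
#' @param config A [score_config()].
#' @param D Overall extension (\eqn{\mathrm{\AA}}), typically from
#'   [estimate_D()].
#' @param constraints List of [constraint()] objects (may be empty).
#' @param schedule An [anneal_schedule()].
#' @param seed Integer RNG seed; runs are bitwise reproducible given the
#'   seed.
#' @param N Number of sub-layers (default 50).
#' @param rho_min,rho_max SLD search bounds; default H2O / D2O.
#' @param q_max Maximum q defining the sigma limits; default the largest q
#'   in the data.
#' @return Object of class `anneal_result`: `model` (best-so-far), `f`,
#'   `final_model`, `trace` (per-temperature T, current f, best f,
#'   acceptance ratio), counters, `seed` and `stopped_by`.
#' @export
anneal_run <- function(config, D, constraints = list(),
                       schedule = anneal_schedule(), seed = 1L, N = 50L,
                       rho_min = sld_registry()[["H2O"]],
                       rho_max = sld_registry()[["D2O"]], q_max = NULL) {
  stopifnot(inherits(config, "score_config"),
            inherits(schedule, "anneal_schedule"))
  if (is.null(q_max))
    q_max <- max(vapply(config$contrasts, function(ct) max(ct$q), numeric(1)))
  set.seed(as.integer(seed))
  model <- interfacial_model(D, N,
                             rho = runif(N, rho_min, rho_max),
                             h = runif(N), sigma = NULL,
                             rho_min = rho_min, rho_max = rho_max,
                             q_max = q_max)
  ac <- apply_constraints(model, constraints)
  model <- ac$model
  res <- anneal_cpp(contrast_payload(config), D, as.integer(N),
                    npad_for(model), model$rho, model$h, model$sigma,
                    rho_min, rho_max, model$sigma_min, model$sigma_max,
                    ac$rho_free, ac$h_free,
                    schedule$T0, trials_for(schedule, N), schedule$cooling,
                    schedule$stop_rejections, schedule$max_temps,
                    schedule$fresh_prob, schedule$step_min_frac)
  if (identical(res$stopped_by, "non_finite"))
    stop("non-finite score during annealing; trace returned in the condition")
  best <- interfacial_model(D, N, rho = res$rho, h = res$h,
                            sigma = res$sigma, rho_min = rho_min,
                            rho_max = rho_max, q_max = q_max)
  final <- interfacial_model(D, N, rho = res$final_rho, h = res$final_h,
                             sigma = res$final_sigma, rho_min = rho_min,
                             rho_max = rho_max, q_max = q_max)
  structure(list(model = best, f = res$f, final_model = final,
                 final_f = res$final_f, trace = res$trace,
                 n_trials = res$n_trials, n_accepted = res$n_accepted,
                 stopped_by = res$stopped_by, seed = as.integer(seed),
                 constraints = constraints, config = config,
                 schedule = schedule),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("Annealing run (seed %d): f = %.4g after %.0f trials (%.1f%% accepted), stopped by %s\n",
              x$seed, x$f, x$n_trials, 100 * x$n_accepted / x$n_trials,
              x$stopped_by))
  invisible(x)
}

#' Repeated annealing runs with best-run selection
#'
#' Executes `n_runs` independent annealing runs (distinct seeds) and keeps
#' the one with the lowest score as the solution; all runs are returned for
#' [average_profiles()].
#'
#' @inheritParams anneal_run
#' @param n_runs Number of runs (default 10).
#' @param seeds Integer seeds, one per run; default `seed + 0:(n_runs-1)`.
#' @param seed Base seed used when `seeds` is NULL.
#' @param ... Passed to [anneal_run()].
#' @return List with `best` (an `anneal_result`), `runs` (all results) and
#'   `f` (scores per run).
#' @export
multi_run <- function(config, D, constraints = list(),
                      schedule = anneal_schedule(), n_runs = 10L,
                      seeds = NULL, seed = 1L, ...) {
  n_runs <- as.integer(n_runs)
  stopifnot(n_runs >= 1)
  if (is.null(seeds)) seeds <- as.integer(seed) + seq_len(n_runs) - 1L
  stopifnot(length(seeds) == n_runs)
  runs <- lapply(seeds, function(s)
    anneal_run(config, D, constraints, schedule, seed = s, ...))
  f <- vapply(runs, `[[`, numeric(1), "f")
  list(best = runs[[which.min(f)]], runs = runs, f = f)
}

#' Average the low-score profile reconstructions
#'
#' Pointwise mean and standard deviation of the hydration and per-contrast
#' composite SLD profiles over all runs whose score is within
#' `f_threshold` of the best, reducing the truncation ripple and giving a
#' spread estimate.
#'
#' @param results A [multi_run()] result or a list of `anneal_result`s.
#' @param f_threshold Qualifying factor: runs with
#'   `f <= f_threshold * min(f)` enter the average (default 1.2).
#' @param z Common evaluation grid; default 1 \eqn{\mathrm{\AA}} spacing
#'   over `[-20, D + 20]`.
#' @return List with `z`, `hydration` (mean), `hydration_sd`,
#'   `rho_composite` (matrix, one column per contrast), `rho_composite_sd`,
#'   `n_used`, `used` (logical per run) and `single_run` (TRUE when fewer
#'   than two runs qualified).
#' @export
average_profiles <- function(results, f_threshold = 1.2, z = NULL) {
  runs <- if (!is.null(results$runs)) results$runs else results
  stopifnot(length(runs) >= 1)
  f <- vapply(runs, `[[`, numeric(1), "f")
  used <- f <= f_threshold * min(f)
  single <- sum(used) < 2
  if (single) {
    warning("fewer than two qualifying runs; returning the best run only")
    used <- seq_along(runs) == which.min(f)
  }
  sel <- runs[used]
  D <- sel[[1]]$model$D
  contrasts <- sel[[1]]$config$contrasts
  if (is.null(z)) z <- seq(-20, D + 20, by = 1)
  hmat <- vapply(sel, function(r)
    smeared_component(r$model, z, "hydration"), numeric(length(z)))
  rho_mean <- matrix(NA_real_, length(z), length(contrasts))
  rho_sd <- matrix(NA_real_, length(z), length(contrasts))
  colnames(rho_mean) <- colnames(rho_sd) <-
    vapply(contrasts, `[[`, character(1), "label")
  for (ci in seq_along(contrasts)) {
    m <- vapply(sel, function(r)
      composite_sld(r$model, z, contrasts[[ci]]$rho_solvent,
                    contrasts[[ci]]$rho_fronting), numeric(length(z)))
    rho_mean[, ci] <- rowMeans(m)
    rho_sd[, ci] <- apply(m, 1, sd)
  }
  list(z = z, hydration = rowMeans(hmat), hydration_sd = apply(hmat, 1, sd),
       rho_composite = rho_mean, rho_composite_sd = rho_sd,
       n_used = sum(used), used = used, single_run = single)
}
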