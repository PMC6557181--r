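# Small multi-contrast fixture rendered from a model the parameterization
# can represent exactly (no background floor, so scoring and generation see
# identical grids).
anneal_fixture <- function(D = 80, N = 16) {
  rho <- c(rep(4.5e-6, N / 2), rep(1e-6, N / 2))
  h <- c(rep(0, N / 2), rep(0.4, N / 2))
  m <- interfacial_model(D = D, N = N, rho = rho, h = h, sigma = 4)
  sys <- ground_truth_system("fixture", "model", model = m, R_floor = 0)
  list(model = m, config = score_config(render_contrast_series(sys)))
}

test_that("the score is zero for self-generated data and symmetric in contrasts", {
  fx <- anneal_fixture()
  expect_equal(score(fx$model, fx$config), 0, tolerance = 1e-10)
  perm <- score_config(rev(fx$config$contrasts))
  m2 <- interfacial_model(D = 80, N = 16, rho = 3e-6, h = 0.2, sigma = 4)
  expect_equal(score(m2, fx$config), score(m2, perm), tolerance = 1e-12)
  expect_error(score_config(list()), "at least one")
})

test_that("inflating the theoretical curve strictly increases the score", {
  # evaluate the two-term objective directly with the experiment fixed and
  # the theoretical curve doubled: both terms must grow when theory and
  # experiment already agree
  fx <- anneal_fixture()
  term_pair <- function(ct, Rth) {
    ye <- ct$q^4 * ct$R; yt <- ct$q^4 * Rth
    c(mean(((ye - yt) / mean(ye))^2), mean((log(ct$R) - log(Rth))^2))
  }
  f_of <- function(scale) {
    mean(vapply(fx$config$contrasts, function(ct)
      sum(term_pair(ct, scale * forward_curve(fx$model, ct))), numeric(1)))
  }
  expect_equal(f_of(1), 0, tolerance = 1e-12)
  expect_gt(f_of(2), f_of(1))
  expect_gt(f_of(2), f_of(1.5))
})

test_that("proposed moves respect bounds, constraints and the move mix", {
  set.seed(21)
  N <- 20
  m <- interfacial_model(D = 100, N = N, rho = 2e-6, h = 0.5)
  cons <- list(constraint(c(0, 25), "fix_hydration", 0),
               constraint(c(0, 10), "fix_sld", 3.5e-6))
  ac <- reflift:::apply_constraints(m, cons)
  frozen_h <- which(!ac$h_free)   # layers with centres < 25 A
  frozen_r <- which(!ac$rho_free)
  expect_equal(frozen_h, 1:5)
  expect_equal(frozen_r, 1:2)
  expect_equal(ac$model$rho[frozen_r], rep(3.5e-6, 2))

  kinds <- character(8000)
  violations <- 0L
  for (i in seq_along(kinds)) {
    tr <- propose_move(ac$model, ac$rho_free, ac$h_free)
    kinds[i] <- attr(tr, "move_kind")
    idx <- attr(tr, "move_index")
    ok <- switch(kinds[i],
      rho = !(idx %in% frozen_r) && tr$rho[idx] >= m$rho_min &&
        tr$rho[idx] <= m$rho_max,
      h = !(idx %in% frozen_h) && tr$h[idx] >= 0 && tr$h[idx] <= 1,
      sigma = tr$sigma >= m$sigma_min && tr$sigma <= m$sigma_max)
    one_change <- sum(tr$rho != ac$model$rho) + sum(tr$h != ac$model$h) +
      (tr$sigma != ac$model$sigma) == 1
    violations <- violations + !ok + !one_change
  }
  expect_equal(violations, 0L)
  # frequencies follow the free-parameter counts (chi-square on 3 bins)
  nfree <- c(rho = sum(ac$rho_free), h = sum(ac$h_free), sigma = 1)
  obs <- table(factor(kinds, levels = names(nfree)))
  chisq <- suppressWarnings(stats::chisq.test(obs, p = nfree / sum(nfree)))
  expect_gt(chisq$p.value, 1e-4)
})

test_that("a fully constrained model is rejected at construction", {
  m <- interfacial_model(D = 100, N = 4, rho = 2e-6, h = 0)
  cons <- list(constraint(c(0, 100), "fix_hydration", 0),
               constraint(c(0, 100), "fix_sld", 2e-6))
  expect_error(reflift:::apply_constraints(m, cons), "fully constrained")
})

test_that("greedy limit: the running score never increases at T ~ 0", {
  fx <- anneal_fixture(D = 60, N = 8)
  sch <- anneal_schedule(T0 = 1e-12, trials_per_T = 150, cooling = 0.5,
                         max_temps = 4)
  r <- anneal_run(fx$config, D = 60, schedule = sch, seed = 4, N = 8)
  expect_true(all(diff(r$trace$f) <= 1e-15))
  expect_true(all(diff(r$trace$f_best) <= 1e-15))
})

test_that("runs are reproducible and multi_run selects the best", {
  fx <- anneal_fixture(D = 60, N = 8)
  sch <- anneal_schedule(trials_per_T = 100, cooling = 0.7, max_temps = 12)
  r1 <- anneal_run(fx$config, D = 60, schedule = sch, seed = 9, N = 8)
  r2 <- anneal_run(fx$config, D = 60, schedule = sch, seed = 9, N = 8)
  expect_identical(r1$model$rho, r2$model$rho)
  expect_identical(r1$f, r2$f)

  mr <- multi_run(fx$config, D = 60, schedule = sch, n_runs = 3, seed = 9,
                  N = 8)
  expect_equal(mr$best$f, min(mr$f))
  expect_lte(mr$best$f, median(mr$f))
  expect_length(mr$runs, 3)
  one <- multi_run(fx$config, D = 60, schedule = sch, n_runs = 1, seed = 9,
                   N = 8)
  expect_identical(one$best$f, one$runs[[1]]$f)
  # best-so-far trace is non-increasing
  expect_true(all(diff(mr$best$trace$f_best) <= 1e-15))
})

test_that("profile averaging honours constraints and collapses for identical runs", {
  fx <- anneal_fixture(D = 60, N = 8)
  sch <- anneal_schedule(trials_per_T = 100, cooling = 0.7, max_temps = 10)
  cons <- list(constraint(c(0, 15), "fix_hydration", 0))
  r <- anneal_run(fx$config, D = 60, cons, sch, seed = 2, N = 8)
  avg <- average_profiles(list(r, r, r), f_threshold = 1.5)
  expect_equal(avg$n_used, 3)
  expect_true(all(avg$hydration_sd == 0))
  expect_true(all(avg$rho_composite_sd == 0))
  # deep inside the constrained region hydration stays at the fixed value
  expect_lt(max(abs(avg$hydration[avg$z > 2 & avg$z < 8])),
            0.5)  # erf tails from z > 15 only
  expect_equal(r$model$h[1], 0)

  # one good run plus one far-off run: only one qualifies -> warning
  r2 <- r; r2$f <- r$f * 10
  expect_warning(avg1 <- average_profiles(list(r, r2), f_threshold = 1.2),
                 "fewer than two")
  expect_true(avg1$single_run)
})
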