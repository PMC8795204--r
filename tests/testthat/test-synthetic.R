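test_that("ground-truth surfaces encode the time-varying cytokine regimes", {
  truth <- default_ground_truth()
  # early synergy: IL-3, TNFa and their interaction positive before day 7
  m0 <- truth[["proT.0"]]
  expect_gt(m0$linear[["IL3"]], 0)
  expect_gt(m0$linear[["TNFa"]], 0)
  expect_gt(m0$interaction[["IL3:TNFa"]], 0)
  expect_gt(m0$interaction[["SCF:TNFa"]], 0)
  expect_equal(m0$linear[["IL7"]], 0)     # unresponsive to IL-7 early
  # TNFa flips sign from day 21
  expect_lt(truth[["lateDP.21"]]$linear[["TNFa"]], 0)
  expect_lt(truth[["CD8SP.28"]]$linear[["TNFa"]], 0)
  # IL-3 inert from day 28 (linear and all interactions zero)
  for (key in c("CD4ISP.28", "earlyDP.35", "lateDP.28", "CD8SP.35")) {
    m <- truth[[key]]
    expect_equal(m$linear[["IL3"]], 0)
    il3_inter <- grepl("IL3", names(m$interaction))
    expect_true(all(m$interaction[il3_inter] == 0))
  }
  # Flt3L inert in every surface
  for (m in truth) expect_equal(m$linear[["Flt3L"]], 0)
  # interior optima: every active factor has a negative pure quadratic
  for (m in truth) expect_true(all(m$quadratic < 0))
})

test_that("population coverage follows the assay's developmental windows", {
  truth <- default_ground_truth()
  pops <- function(start)
    sort(unname(vapply(Filter(function(m) m$interval[1] == start, truth),
                       `[[`, "", "population")))
  expect_equal(pops(0), sort(c("proT", "CD4ISP", "earlyDP")))
  expect_equal(pops(7), sort(c("proT", "CD4ISP", "earlyDP")))
  expect_equal(pops(14), sort(c("CD4ISP", "earlyDP", "lateDP", "CD8SP")))
  expect_equal(pops(35), sort(c("CD4ISP", "earlyDP", "lateDP", "CD8SP")))
})

test_that("the generator demands the six campaign cytokines", {
  expect_error(default_ground_truth(make_factors(6)), "config error")
})

test_that("simulation is deterministic and noiseless at sd 0", {
  f <- default_factors()
  d <- generate_ccd(f, n_center = 4)
  truth <- default_ground_truth(f)
  one <- truth["proT.0"]
  a <- simulate_dataset(d, one, seed = 5)
  b <- simulate_dataset(d, one, seed = 5)
  expect_identical(a, b)
  c2 <- simulate_dataset(d, one, seed = 6)
  expect_false(identical(a, c2))
  # noiseless counts equal the squared clipped surface exactly
  clean <- simulate_dataset(d, one, seed = 1, noise_sd = 0, n_control = 0)
  mu <- predict_response(truth[["proT.0"]], d$coded, scale = "sqrt",
                         extrapolate = TRUE)
  expect_equal(clean$count, pmax(mu, 0)^2, tolerance = 1e-12)
})

test_that("donor offsets shift the sqrt-scale signal additively", {
  f <- default_factors()
  d <- generate_ccd(f, n_center = 2)
  truth <- default_ground_truth(f)["proT.0"]
  obs <- simulate_dataset(d, truth, seed = 8, noise_sd = 0,
                          donor_offsets = c(dA = 0, dB = 2),
                          n_control = 0)
  a <- sqrt(obs$count[obs$donor_id == "dA"])
  b <- sqrt(obs$count[obs$donor_id == "dB"])
  expect_equal(b, a + 2, tolerance = 1e-12)
})

test_that("control replicates support z-scoring of simulated screens", {
  f <- default_factors()
  d <- generate_ccd(f, n_center = 2)
  truth <- default_ground_truth(f)["proT.0"]
  obs <- simulate_dataset(d, truth, seed = 9, n_control = 3)
  z <- compute_zscores(obs)
  ctl <- z$z[z$is_control]
  expect_equal(mean(ctl), 0, tolerance = 1e-10)
  expect_equal(length(ctl), 3)
})

test_that("noiseless simulation round-trips through the RSM fit", {
  f <- default_factors()
  d <- generate_ccd(f, n_center = 8)
  truth <- default_ground_truth(f)
  obs <- simulate_dataset(d, truth, seed = 1, noise_sd = 0, n_control = 0)
  for (key in c("proT.0", "earlyDP.14", "CD8SP.35")) {
    sf <- truth[[key]]
    fit <- fit_rsm(d, obs, sf$population, sf$interval)
    expect_equal(cytokinedoe:::coef_vector(fit),
                 cytokinedoe:::coef_vector(sf), tolerance = 1e-8)
  }
})

test_that("null coefficients stay null and active signs are recovered", {
  # full-pipeline parameter recovery across seeds at the default noise
  f <- default_factors()
  d <- generate_ccd(f, n_center = 8)
  truth <- default_ground_truth(f, noise_sd = 0.5)
  terms <- cytokinedoe:::quad_terms(names(f), "full_quadratic")
  X <- cbind(1, cytokinedoe:::term_columns(d$coded, terms))
  se <- 0.5 * sqrt(diag(solve(crossprod(X))))
  keys <- c("proT.0", "CD4ISP.7", "lateDP.21", "CD8SP.28")
  null_ok <- 0L; null_n <- 0L; sign_ok <- 0L; sign_n <- 0L
  for (s in 1:50) {
    obs <- simulate_dataset(d, truth[keys], seed = 300 + s, n_control = 0)
    for (key in keys) {
      sf <- truth[[key]]
      fit <- fit_rsm(d, obs, sf$population, sf$interval)
      est <- cytokinedoe:::coef_vector(fit)
      tru <- cytokinedoe:::coef_vector(sf)
      nulls <- which(tru == 0)
      null_ok <- null_ok + sum(abs(est[nulls]) < 3 * se[nulls])
      null_n <- null_n + length(nulls)
      act <- which(tru != 0 & names(tru) %in% names(sf$linear))
      sign_ok <- sign_ok + sum(sign(est[act]) == sign(tru[act]))
      sign_n <- sign_n + length(act)
    }
  }
  expect_gte(null_ok / null_n, 0.95)
  expect_gte(sign_ok / sign_n, 0.95)
})

test_that("logistic dose-response fixtures hit their stated anchors", {
  cv <- simulate_dose_response_curve(0.3, hill = 2,
                                     doses = c(0, 0.1, 0.3, 1))
  expect_equal(cv$response[1], 100)
  expect_equal(cv$response[cv$dose_uM == 0.3], 50)
  expect_error(simulate_dose_response_curve(-1), "domain")
  expect_error(simulate_dose_response_curve(5, doses = c(0, 1)), "domain")
  noisy1 <- simulate_dose_response_curve(0.3, doses = c(0, 0.3, 1),
                                         seed = 3, noise_sd = 5)
  noisy2 <- simulate_dose_response_curve(0.3, doses = c(0, 0.3, 1),
                                         seed = 3, noise_sd = 5)
  expect_identical(noisy1, noisy2)
  expect_gte(min(noisy1$response), 0)
})

test_that("partition recovery degrades monotonically with noise", {
  rate <- vapply(c(0, 1, 2), function(nsd) {
    ok <- 0L
    for (s in 1:3) {
      f <- default_factors()
      truth <- default_ground_truth(f, noise_sd = nsd)
      models <- if (nsd == 0) truth else {
        d <- generate_ccd(f, n_center = 8)
        obs <- simulate_dataset(d, truth, seed = 700 + s, n_control = 0)
        stats::setNames(lapply(names(truth), function(key)
          fit_rsm(d, obs, truth[[key]]$population,
                  truth[[key]]$interval)), names(truth))
      }
      opt <- optimize_all_intervals(models, default_schedule(),
                                    lower = -2, upper = 2, n_iter = 15,
                                    seed = 700 + s)
      best <- select_best_partition(opt, models)
      if (best$t1 == 7 && best$t2 == 21) ok <- ok + 1L
    }
    ok / 3
  }, 0)
  expect_true(all(diff(rate) <= 0))
  expect_equal(rate[1], 1)
})
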