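noiseless_obs <- function(design, model) {
  mu <- predict_response(model, design$coded, scale = "sqrt",
                         extrapolate = TRUE)
  data.frame(run_id = design$run_id, donor_id = "d1",
             day_start = model$interval[1], day_end = model$interval[2],
             population = model$population, count = pmax(mu, 0)^2,
             is_control = FALSE)
}

test_that("noiseless CCD data reproduce the generating coefficients", {
  f <- default_factors()
  d <- generate_ccd(f, n_center = 8)
  truth <- default_ground_truth(f)[["proT.0"]]
  fit <- fit_rsm(d, noiseless_obs(d, truth), "proT", c(0, 7))
  expect_equal(fit$beta0, truth$beta0, tolerance = 1e-8)
  expect_equal(fit$linear, truth$linear, tolerance = 1e-8)
  expect_equal(fit$interaction, truth$interaction, tolerance = 1e-8)
  expect_equal(fit$quadratic, truth$quadratic, tolerance = 1e-8)
})

test_that("constant counts give a pure-intercept model with R2 = 0", {
  f <- make_factors(3)
  d <- generate_ccd(f, n_center = 4)
  obs <- data.frame(run_id = d$run_id, donor_id = "d1", day_start = 0,
                    day_end = 7, population = "proT", count = 25,
                    is_control = FALSE)
  fit <- fit_rsm(d, obs, "proT", c(0, 7))
  expect_equal(fit$beta0, 5, tolerance = 1e-10)
  expect_lt(max(abs(c(fit$linear, fit$interaction, fit$quadratic))), 1e-10)
  expect_equal(fit$diagnostics$r_squared, 0)
})

test_that("residuals are orthogonal to every model column", {
  f <- make_factors(4)
  d <- generate_ccd(f, n_center = 6)
  set.seed(9)
  obs <- data.frame(run_id = d$run_id, donor_id = "d1", day_start = 7,
                    day_end = 14, population = "CD4ISP",
                    count = (10 + rnorm(nrow(d$coded)))^2,
                    is_control = FALSE)
  fit <- fit_rsm(d, obs, "CD4ISP", c(7, 14))
  terms <- cytokinedoe:::quad_terms(names(f), "full_quadratic")
  X <- cbind(1, cytokinedoe:::term_columns(d$coded, terms))
  resid <- sqrt(obs$count) - predict_response(fit, d$coded, scale = "sqrt",
                                              extrapolate = TRUE)
  expect_lt(max(abs(crossprod(X, resid))), 1e-8)
})

test_that("coefficient noise is in line with the OLS covariance", {
  f <- default_factors()
  d <- generate_ccd(f, n_center = 8)
  truth <- default_ground_truth(f, noise_sd = 0.5)[["earlyDP.14"]]
  obs <- simulate_dataset(d, list(truth), seed = 21, n_control = 0)
  fit <- fit_rsm(d, obs, "earlyDP", c(14, 21))
  est <- cytokinedoe:::coef_vector(fit)
  tru <- cytokinedoe:::coef_vector(truth)
  terms <- cytokinedoe:::quad_terms(names(f), "full_quadratic")
  X <- cbind(1, cytokinedoe:::term_columns(d$coded, terms))
  se <- 0.5 * sqrt(diag(solve(crossprod(X))))
  expect_lt(sqrt(mean((est - tru)^2)), 3 * sqrt(mean(se^2)))
})

test_that("repeated fits are unbiased for every coefficient", {
  f <- make_factors(3)
  d <- generate_ccd(f, n_center = 6)
  truth <- rsm_model("proT", c(0, 7), f, beta0 = 12,
                     linear = c(x1 = 2, x2 = -1),
                     interaction = c(`x1:x2` = 0.8),
                     quadratic = c(x1 = -1.5, x2 = -1, x3 = -0.5),
                     hull = 2.5)
  truth$noise_sd <- 0.5
  tru <- cytokinedoe:::coef_vector(truth)
  ests <- vapply(1:200, function(s) {
    obs <- simulate_dataset(d, list(truth), seed = s, n_control = 0)
    cytokinedoe:::coef_vector(fit_rsm(d, obs, "proT", c(0, 7)))
  }, numeric(length(tru)))
  terms <- cytokinedoe:::quad_terms(names(f), "full_quadratic")
  X <- cbind(1, cytokinedoe:::term_columns(d$coded, terms))
  se_mean <- 0.5 * sqrt(diag(solve(crossprod(X)))) / sqrt(200)
  expect_true(all(abs(rowMeans(ests) - tru) < 3 * se_mean))
})

test_that("predictions evaluate the polynomial and clip on the count scale", {
  m <- vertex_model(beta0 = 2, b = c(1, 0), q = c(0, 0))
  expect_equal(predict_response(m, c(x1 = 0, x2 = 0), "sqrt"), 2)
  expect_equal(predict_response(m, c(x1 = 1), "sqrt"), 3)
  expect_equal(predict_response(m, c(x1 = 1), "count"), 9)
  neg <- vertex_model(beta0 = -1, b = c(0, 0), q = c(0, 0))
  expect_equal(predict_response(neg, c(x1 = 0.5), "count"), 0)
  expect_gte(min(predict_response(neg,
                                  matrix(runif(20, -2, 2), 10, 2,
                                         dimnames = list(NULL,
                                                         c("x1", "x2"))),
                                  "count")), 0)
})

test_that("points outside the coded hull need explicit extrapolation", {
  m <- vertex_model()
  expect_error(predict_response(m, c(x1 = 2.5)), "extrapolation")
  expect_silent(predict_response(m, c(x1 = 2.5), extrapolate = TRUE))
})

test_that("dose sweeps pin the other factors at the scaled center", {
  flat <- vertex_model(beta0 = 7, b = c(0, 2), q = c(0, -1))
  sw <- dose_sweep(flat, "x1", seq(-2, 2, length.out = 11))
  expect_equal(sw$count, rep(49, 11))           # no x1 dependence
  declining <- vertex_model(beta0 = 10, b = c(-2, 0), q = c(0, 0))
  sw2 <- dose_sweep(declining, "x1", seq(-2, 2, length.out = 21))
  expect_true(all(diff(sw2$count) < 0))         # late-interval TNFa shape
  bump <- vertex_model(beta0 = 5, b = c(0, 0), q = c(-1, 0))
  sw3 <- dose_sweep(bump, "x1", seq(-2, 2, length.out = 21))
  expect_equal(sw3$coded[which.max(sw3$count)], 0)
  expect_error(dose_sweep(flat, "nope"), "unknown factor")
})

test_that("models survive a JSON round trip", {
  f <- default_factors()
  d <- generate_ccd(f, n_center = 8)
  truth <- default_ground_truth(f)[["lateDP.21"]]
  fit <- fit_rsm(d, noiseless_obs(d, truth), "lateDP", c(21, 28))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_rsm_model(fit, path)
  back <- read_rsm_model(path)
  expect_equal(back$linear, fit$linear, tolerance = 1e-12)
  expect_equal(back$interaction, fit$interaction, tolerance = 1e-12)
  pts <- matrix(c(0.5, -1, 1.2, 0.3), 2, 2,
                dimnames = list(NULL, c("SCF", "TNFa")))
  expect_equal(predict_response(back, pts), predict_response(fit, pts),
               tolerance = 1e-10)
})

test_that("missing runs are reported by id", {
  f <- make_factors(3)
  d <- generate_ccd(f, n_center = 2)
  truth <- rsm_model("proT", c(0, 7), f, beta0 = 10, hull = 2)
  obs <- noiseless_obs(d, truth)
  expect_error(fit_rsm(d, obs[-3, ], "proT", c(0, 7)), "run_03")
})
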