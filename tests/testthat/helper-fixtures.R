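# shared fixtures: small factor sets and designs built in code

make_factors <- function(n, prefix = "x", low = 10, high = 30) {
  as_factor_list <- getFromNamespace("as_factor_list", "cytokinedoe")
  as_factor_list(lapply(paste0(prefix, seq_len(n)), doe_factor,
                        low = low, high = high))
}

# a 2-factor model with a known interior vertex on the sqrt scale
vertex_model <- function(beta0 = 10, b = c(1, -0.8), q = c(-1, -1),
                         population = "proT", interval = c(0, 7)) {
  f <- make_factors(2)
  rsm_model(population, interval, f, beta0 = beta0,
            linear = stats::setNames(b, names(f)),
            quadratic = stats::setNames(q, names(f)), hull = 2)
}

# analytic vertex of a separable quadratic: x* = -b / (2q)
separable_vertex <- function(b, q) -b / (2 * q)

expect_design_levels <- function(design, n_levels) {
  lv <- apply(design$coded, 2, function(x) length(unique(x)))
  expect_true(all(lv == n_levels))
}
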