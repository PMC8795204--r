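#' Validate an observation table of absolute cell counts
#'
#' The long-format table holds one absolute count per run, donor, 7-day
#' interval and cell population, with control wells flagged. Columns:
#' `run_id`, `donor_id`, `day_start`, `day_end`, `population`, `count`,
#' `is_control`.
#'
#' @param obs Data frame in the schema above.
#' @return The validated data frame (invisibly usable downstream).
#' @export
validate_observations <- function(obs) {
  need <- c("run_id", "donor_id", "day_start", "day_end", "population",
            "count", "is_control")
  missing <- setdiff(need, names(obs))
  if (length(missing))
    stop("observation table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (any(!is.finite(obs$count)) || any(obs$count < 0))
    stop("counts must be non-negative and finite", call. = FALSE)
  key <- do.call(paste, c(obs[c("run_id", "donor_id", "day_start",
                                "population")], sep = "\r"))
  if (anyDuplicated(key[!obs$is_control]))
    stop("duplicate (run, donor, interval, population) rows", call. = FALSE)
  obs
}

#' Standardize cell counts against the control condition
#'
#' For every (donor, interval, population) cell, control replicates define
#' a mean and n-1 sample standard deviation, and every row's count is
#' expressed as z = (count - mean_control) / sd_control — a
#' better-or-worse-than-control effect size on a common scale across
#' populations of very different absolute abundance.
#'
#' @param obs Observation table (see [validate_observations()]); at least 2
#'   control replicates per (donor, interval, population).
#' @return The table with a `z` column replacing `count`.
#' @examples
#' obs <- data.frame(run_id = c("c1", "c2", "c3", "r1"),
#'                   donor_id = 1, day_start = 0, day_end = 7,
#'                   population = "proT", count = c(8, 10, 12, 14),
#'                   is_control = c(TRUE, TRUE, TRUE, FALSE))
#' compute_zscores(obs)$z  # controls -1, 0, 1; test run 2
#' @export
compute_zscores <- function(obs) {
  obs <- validate_observations(obs)
  grp <- interaction(obs$donor_id, obs$day_start, obs$population, drop = TRUE)
  z <- numeric(nrow(obs))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    ctrl <- obs$count[idx][obs$is_control[idx]]
    if (length(ctrl) < 2)
      stop("insufficient-control: fewer than 2 control replicates for ",
           "group ", g, call. = FALSE)
    s <- stats::sd(ctrl)
    if (s == 0)
      stop("degenerate-control: zero control standard deviation for group ",
           g, call. = FALSE)
    z[idx] <- (obs$count[idx] - mean(ctrl)) / s
  }
  out <- obs
  out$z <- z
  out$count <- NULL
  out
}

#' Stepwise minimum-BIC regression for screening designs
#'
#' Forward selection from the intercept-only model over main effects and,
#' depending on `candidate_set`, pure quadratics and two-factor
#' interactions. Strong effect heredity is enforced by group entry: a
#' candidate is scored as the BIC of the model augmented by the term plus
#' any heredity parents it is missing, and the whole group enters together.
#' BIC uses the Gaussian profile form n log(RSS/n) + k log(n) with k
#' counting all coefficients including the intercept; selection stops when
#' no candidate lowers it. Candidates whose augmented model is
#' rank-deficient on the design are skipped.
#'
#' @param design A `doe_design` (typically a DSD).
#' @param response Numeric response aligned to runs. Length may be a
#'   multiple of the run count (e.g. per-donor z-scores pooled as
#'   independent observations), in which case design rows are recycled in
#'   blocks.
#' @param candidate_set `"main_only"`, `"main_quadratic"` (the default for
#'   screening designs) or `"full_quadratic"`.
#' @return A `screen_model`: selected `terms`, `coefficients`, `bic_trace`,
#'   an `effects` table with OLS t-test p-values, `n` and `rss`.
#' @export
stepwise_bic_fit <- function(design, response,
                             candidate_set = c("main_quadratic",
                                               "full_quadratic",
                                               "main_only")) {
  candidate_set <- match.arg(candidate_set)
  stopifnot(inherits(design, "doe_design"))
  nr <- nrow(design$coded)
  if (length(response) %% nr != 0)
    stop("response length (", length(response),
         ") is not a multiple of the run count (", nr, ")", call. = FALSE)
  reps <- length(response) / nr
  coded <- design$coded[rep(seq_len(nr), times = reps), , drop = FALSE]
  n <- length(response)
  fnames <- colnames(coded)

  candidates <- quad_terms(fnames, candidate_set)
  main_fit <- ols_qr(cbind(`(Intercept)` = 1, term_columns(coded, fnames)),
                     response)
  if (!main_fit$ok)
    stop("aliasing: main-effect columns are rank deficient; aliased: ",
         paste(main_fit$aliased, collapse = ", "), call. = FALSE)

  selected <- character()
  rss <- sum((response - mean(response))^2)
  bic_trace <- profile_bic(n, rss, 1L)
  fit <- list(coef = c(`(Intercept)` = mean(response)), rss = rss)

  repeat {
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    best <- NULL
    for (tm in pool) {
      group <- unique(c(setdiff(term_parents(tm), selected), tm))
      trial <- c(selected, group)
      X <- cbind(`(Intercept)` = 1, term_columns(coded, trial))
      f <- ols_qr(X, response)
      if (!f$ok) next
      bic <- profile_bic(n, f$rss, ncol(X))
      if (is.null(best) || bic < best$bic)
        best <- list(bic = bic, terms = trial, fit = f)
    }
    if (is.null(best) || best$bic >= bic_trace[length(bic_trace)]) break
    selected <- best$terms
    fit <- best$fit
    bic_trace <- c(bic_trace, best$bic)
  }

  # effect table from the final OLS fit
  X <- cbind(`(Intercept)` = 1, term_columns(coded, selected))
  p <- ncol(X)
  sigma2 <- if (n > p) fit$rss / (n - p) else NA_real_
  se <- if (is.finite(sigma2))
    sqrt(diag(chol2inv(chol(crossprod(X)))) * sigma2) else rep(NA_real_, p)
  tval <- fit$coef / se
  effects <- data.frame(
    term = colnames(X), coefficient = unname(fit$coef),
    std_error = unname(se), t_value = unname(tval),
    p_value = unname(2 * stats::pt(abs(tval), df = max(n - p, 1),
                                   lower.tail = FALSE)))

  structure(list(terms = c("(Intercept)", selected),
                 coefficients = fit$coef, bic_trace = bic_trace,
                 effects = effects, n = n, rss = fit$rss,
                 candidate_set = candidate_set),
            class = "screen_model")
}

#' @export
print.screen_model <- function(x, ...) {
  cat("<screen_model> ", length(x$terms), " term(s) selected in ",
      length(x$bic_trace) - 1L, " step(s); BIC ",
      signif(x$bic_trace[length(x$bic_trace)], 6), "\n", sep = "")
  print(x$effects, digits = 4)
  invisible(x)
}

#' Serialize a screening model to JSON
#' @param model A `screen_model`.
#' @param path Output path.
#' @export
write_screen_model <- function(model, path) {
  jsonlite::write_json(
    list(terms = model$terms, coefficients = as.list(model$coefficients),
         bic_trace = model$bic_trace, n = model$n, rss = model$rss,
         candidate_set = model$candidate_set),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
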