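#' Define a desirability objective for one cell population
#'
#' Larger-is-better Derringer-Suich desirability: predictions at or below
#' `L` score 0, at or above `T` score 1, with `((yhat - L)/(T - L))^s`
#' in between. Populations can also be excluded from an interval's
#' objective (e.g. not yet present developmentally).
#'
#' @param population Population label; must match an `rsm_model`.
#' @param direction `"maximize"` or `"exclude"`.
#' @param L Count-scale lower bound where desirability is 0 (default 0).
#' @param T Count-scale target where desirability reaches 1, or `"auto"`
#'   to take the maximum prediction found by a coarse axis-grid pre-pass
#'   over the optimization box (see [basin_hop_maximize()]).
#' @param s Shape exponent (> 0; 1 = linear ramp).
#' @param weight Positive weight in the overall-desirability geometric
#'   mean.
#' @return A `desirability_objective`.
#' @export
desirability_objective <- function(population,
                                   direction = c("maximize", "exclude"),
                                   L = 0, T = "auto", s = 1, weight = 1) {
  direction <- match.arg(direction)
  if (direction == "maximize") {
    if (!identical(T, "auto")) {
      if (!is.numeric(T) || L >= T)
        stop("invalid-objective: need L < T for a maximize objective",
             call. = FALSE)
    }
    if (s <= 0 || weight <= 0)
      stop("invalid-objective: s and weight must be positive",
           call. = FALSE)
  } else {
    L <- T <- s <- weight <- NULL
  }
  structure(list(population = population, direction = direction,
                 L = L, T = T, s = s, weight = weight),
            class = "desirability_objective")
}

#' Derringer-Suich larger-is-better desirability of a prediction
#'
#' @param yhat Count-scale prediction(s).
#' @param objective A `maximize` [desirability_objective()] with numeric
#'   bounds.
#' @return Desirability in \[0, 1\], vectorized over `yhat`.
#' @examples
#' obj <- desirability_objective("proT", L = 0, T = 100)
#' desirability_score(c(0, 50, 100, 150), obj)  # 0, 0.5, 1, 1
#' @export
desirability_score <- function(yhat, objective) {
  stopifnot(inherits(objective, "desirability_objective"),
            objective$direction == "maximize")
  if (identical(objective$T, "auto"))
    stop("objective target 'auto' has not been resolved; optimize via ",
         "basin_hop_maximize() or set a numeric T", call. = FALSE)
  d <- (yhat - objective$L) / (objective$T - objective$L)
  pmin(pmax(d, 0), 1)^objective$s
}

#' Overall desirability: weighted geometric mean
#'
#' @param ds Individual desirabilities in \[0, 1\].
#' @param weights Positive weights (default equal).
#' @return D = (prod d_i^w_i)^(1/sum w) in \[0, 1\]; 0 whenever any
#'   component is 0.
#' @export
overall_desirability <- function(ds, weights = rep(1, length(ds))) {
  if (!length(ds)) stop("no-objective: empty desirability list",
                        call. = FALSE)
  stopifnot(length(weights) == length(ds), all(weights > 0),
            all(ds >= 0 & ds <= 1))
  if (any(ds == 0)) return(0)
  exp(sum(weights * log(ds)) / sum(weights))
}

## coarse pre-pass for T = "auto": 9 points per marginal axis (others at
## center) plus the center point itself
auto_target <- function(model, lower, upper) {
  fnames <- names(model$factors)
  k <- length(fnames)
  pts <- matrix(0, 1 + 9 * k, k, dimnames = list(NULL, fnames))
  r <- 1
  for (i in seq_len(k)) {
    g <- seq(lower[i], upper[i], length.out = 9)
    pts[r + seq_len(9), i] <- g
    r <- r + 9
  }
  max(predict_response(model, pts, scale = "count", extrapolate = TRUE))
}

resolve_objectives <- function(models, objectives, lower, upper) {
  lapply(objectives, function(ob) {
    if (ob$direction == "maximize" && identical(ob$T, "auto")) {
      m <- models[[ob$population]]
      if (is.null(m))
        stop("schedule-model mismatch: no model for population ",
             ob$population, call. = FALSE)
      ob$T <- auto_target(m, lower, upper)
      if (ob$T <= ob$L) ob$T <- ob$L + 1  # flat surface; D will be ~0
    }
    ob
  })
}

## overall desirability of one coded point (or matrix of points)
eval_overall_D <- function(models, objectives, x) {
  maximize <- Filter(function(o) o$direction == "maximize", objectives)
  if (!length(maximize))
    stop("no-objective: schedule entry has no maximize objective",
         call. = FALSE)
  ds <- vapply(maximize, function(ob) {
    m <- models[[ob$population]]
    if (is.null(m))
      stop("schedule-model mismatch: no model for population ",
           ob$population, call. = FALSE)
    yhat <- predict_response(m, x, scale = "count", extrapolate = TRUE)
    if (any(is.na(yhat)))
      stop("model-domain error: NaN prediction for ", ob$population,
           call. = FALSE)
    desirability_score(yhat, ob)
  }, numeric(1))
  overall_desirability(ds, vapply(maximize, `[[`, 0, "weight"))
}

## run code under a temporary RNG state derived from `seed`, restoring the
## caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

## deterministic per-task seed stream derived from one root seed
split_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + index * 104729) %% 2147483647
}

#' Maximize overall desirability by basin-hopping
#'
#' Global maximization of the overall desirability D(x) over a coded box:
#' repeated cycles of a uniform random perturbation (magnitude at most
#' `step_size` per coordinate), a bounded derivative-free local search
#' (Nelder-Mead with boundary clipping), and Metropolis acceptance of the
#' local optimum at the given `temperature` on the D scale. Deterministic
#' given `seed`; iterations consume the random stream sequentially, so the
#' best value found is non-decreasing in `n_iter` for a fixed seed.
#'
#' @param models Named list of `rsm_model`s for one interval, keyed by
#'   population.
#' @param objectives List of [desirability_objective()] for that interval;
#'   `"auto"` targets are resolved by a coarse grid pre-pass over the box.
#' @param lower,upper Coded box bounds, scalar or per-factor vectors
#'   (default the models' hull).
#' @param n_iter Basin-hopping iterations (default 200).
#' @param step_size Perturbation half-width in coded units (default 0.5).
#' @param temperature Metropolis temperature on the D scale (default 1).
#' @param seed Integer seed.
#' @param k_top How many top solutions to retain (default 5).
#' @return A `doe_optimum`: `best` (coded and natural point, D), `top_k`,
#'   a spatially deduplicated view `top_k_dedup` (L-infinity separation
#'   > 0.05 coded), resolved `objectives`, seed/settings provenance and
#'   the acceptance trace.
#' @export
basin_hop_maximize <- function(models, objectives, lower = NULL,
                               upper = NULL, n_iter = 200, step_size = 0.5,
                               temperature = 1, seed = 1, k_top = 5) {
  stopifnot(n_iter >= 1)
  models <- as_model_list(models)
  fnames <- names(models[[1]]$factors)
  k <- length(fnames)
  hull <- models[[1]]$hull
  lower <- rep_len(if (is.null(lower)) -hull else lower, k)
  upper <- rep_len(if (is.null(upper)) hull else upper, k)
  stopifnot(all(lower < upper), all(is.finite(lower)), all(is.finite(upper)))
  objectives <- resolve_objectives(models, objectives, lower, upper)
  clip <- function(x) pmin(pmax(x, lower), upper)
  Dfun <- function(x) eval_overall_D(models, objectives,
                                     matrix(x, 1, k,
                                            dimnames = list(NULL, fnames)))
  local_max <- function(x0) {
    if (k == 1) {
      o <- stats::optim(x0, function(p) -Dfun(clip(p)), method = "Brent",
                        lower = lower, upper = upper)
    } else {
      o <- stats::optim(x0, function(p) -Dfun(clip(p)),
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    }
    x <- clip(o$par)
    list(x = x, D = Dfun(x))
  }

  with_seed(seed, {
    cur <- local_max(rep(0, k))
    evals <- list(cur)
    accepted <- logical(n_iter)
    for (i in seq_len(n_iter)) {
      prop <- clip(cur$x + stats::runif(k, -step_size, step_size))
      cand <- local_max(prop)
      evals[[length(evals) + 1L]] <- cand
      acc <- cand$D >= cur$D ||
        stats::runif(1) < exp((cand$D - cur$D) / temperature)
      accepted[i] <- acc
      if (acc) cur <- cand
    }
    Ds <- vapply(evals, `[[`, 0, "D")
    ord <- order(Ds, decreasing = TRUE)
    top <- evals[ord[seq_len(min(k_top, length(evals)))]]
    if (max(Ds) == 0)
      warning("flat-objective: all evaluations gave D = 0; returning the ",
              "best-effort point", call. = FALSE)
    dedup <- list()
    for (e in evals[ord]) {
      if (length(dedup) >= k_top) break
      if (!length(dedup) ||
          all(vapply(dedup, function(d) max(abs(d$x - e$x)) > 0.05, TRUE)))
        dedup[[length(dedup) + 1L]] <- e
    }
    best <- top[[1]]
    mk_tab <- function(lst) {
      pts <- do.call(rbind, lapply(lst, `[[`, "x"))
      colnames(pts) <- fnames
      cbind(as.data.frame(pts), D = vapply(lst, `[[`, 0, "D"))
    }
    structure(list(
      interval = models[[1]]$interval,
      best = list(
        coded = stats::setNames(best$x, fnames),
        natural = stats::setNames(vapply(seq_len(k), function(i)
          decode_one(best$x[i], models[[1]]$factors[[i]]), 0), fnames),
        D = best$D),
      top_k = mk_tab(top),
      top_k_dedup = mk_tab(dedup),
      objectives = objectives,
      seed = seed, n_iter = n_iter,
      settings = list(step_size = step_size, temperature = temperature,
                      lower = lower, upper = upper, k_top = k_top),
      n_accepted = sum(accepted),
      acceptance_trace = accepted),
      class = "doe_optimum")
  })
}

as_model_list <- function(models) {
  if (inherits(models, "rsm_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "rsm_model")))
  names(models) <- vapply(models, `[[`, "", "population")
  models
}

#' @export
print.doe_optimum <- function(x, ...) {
  cat(sprintf("<doe_optimum> days %g-%g: D = %.4f at\n",
              x$interval[1], x$interval[2], x$best$D))
  print(round(x$best$natural, 3))
  invisible(x)
}

#' Optimize every 7-day interval of the assay
#'
#' Runs [basin_hop_maximize()] for each interval of the objective schedule
#' in temporal order, using the models fitted for that interval. Each
#' interval gets its own seed derived deterministically from `seed`.
#'
#' @param models List of `rsm_model`s covering every (population,
#'   interval) the schedule maximizes.
#' @param schedule An objective schedule: list of entries
#'   `list(interval = c(start, end), objectives = list(...))`; see
#'   [default_schedule()].
#' @param ... Optimizer settings passed to [basin_hop_maximize()].
#' @param seed Root seed.
#' @return List of `doe_optimum`, one per interval in temporal order; see
#'   [optima_summary()] for the mean/sd of the top-k points.
#' @export
optimize_all_intervals <- function(models, schedule, ..., seed = 1) {
  starts <- vapply(schedule, function(e) e$interval[1], 0)
  ord <- order(starts)
  lapply(seq_along(ord), function(j) {
    entry <- schedule[[ord[j]]]
    mods <- models_for_interval(models, entry)
    basin_hop_maximize(mods, entry$objectives, ...,
                       seed = split_seed(seed, j))
  })
}

models_for_interval <- function(models, entry) {
  wanted <- vapply(Filter(function(o) o$direction == "maximize",
                          entry$objectives), `[[`, "", "population")
  hit <- Filter(function(m)
    m$interval[1] == entry$interval[1] && m$population %in% wanted, models)
  got <- vapply(hit, `[[`, "", "population")
  if (length(setdiff(wanted, got)))
    stop("schedule-model mismatch: interval [", entry$interval[1], ",",
         entry$interval[2], ") lacks model(s) for ",
         paste(setdiff(wanted, got), collapse = ", "), call. = FALSE)
  as_model_list(hit)
}

#' Mean and standard deviation of the top-k optima per interval
#'
#' @param optima List of `doe_optimum` from [optimize_all_intervals()].
#' @return Data frame: `day_start`, `factor`, `mean_coded`, `sd_coded`
#'   over each interval's retained top-k points.
#' @export
optima_summary <- function(optima) {
  do.call(rbind, lapply(optima, function(o) {
    pts <- o$top_k[, setdiff(names(o$top_k), "D"), drop = FALSE]
    data.frame(day_start = o$interval[1], factor = names(pts),
               mean_coded = vapply(pts, mean, 0),
               sd_coded = vapply(pts, stats::sd, 0), row.names = NULL)
  }))
}

#' Read or write an objective schedule as YAML
#'
#' Each document entry has `interval: [start, end]` and a list of
#' `objectives` with fields `population`, `direction`, and for maximize
#' objectives `L`, `T` (number or `"auto"`), `s`, `weight`.
#'
#' @param path YAML file path.
#' @param schedule Schedule structure as used by
#'   [optimize_all_intervals()].
#' @export
read_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(e)
    list(interval = as.numeric(unlist(e$interval)),
         objectives = lapply(e$objectives, function(o)
           desirability_objective(o$population,
                                  direction = o$direction %||% "maximize",
                                  L = o$L %||% 0, T = o$T %||% "auto",
                                  s = o$s %||% 1,
                                  weight = o$weight %||% 1))))
}

#' @rdname read_schedule
#' @export
write_schedule <- function(schedule, path) {
  yaml::write_yaml(lapply(schedule, function(e)
    list(interval = as.list(e$interval),
         objectives = lapply(e$objectives, function(o)
           Filter(Negate(is.null),
                  o[c("population", "direction", "L", "T", "s",
                      "weight")])))), path)
  invisible(path)
}

#' Default objective schedule for the 42-day assay
#'
#' Days 0-14 maximize the populations present early (proT, CD4ISP,
#' earlyDP); from day 14 the objectives shift to maturation (CD4ISP,
#' earlyDP, lateDP, CD8SP). All targets `"auto"`, shape 1, equal weights.
#'
#' @return A schedule list consumable by [optimize_all_intervals()].
#' @export
default_schedule <- function() {
  early <- c("proT", "CD4ISP", "earlyDP")
  late <- c("CD4ISP", "earlyDP", "lateDP", "CD8SP")
  lapply(seq(0, 35, by = 7), function(s) {
    pops <- if (s < 14) early else late
    list(interval = c(s, s + 7),
         objectives = lapply(pops, desirability_objective))
  })
}
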