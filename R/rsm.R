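#' Construct a response-surface model object from coefficients
#'
#' Holds a full second-order polynomial on the square-root cell-count scale
#' in coded factor units: intercept, linear, two-factor interaction and
#' pure-quadratic coefficients for one cell population over one 7-day
#' interval. Usually produced by [fit_rsm()]; the constructor is exposed so
#' coefficient tables (e.g. transcribed from an external fit) can be turned
#' into models directly.
#'
#' @param population Population label (e.g. `"proT"`, `"earlyDP"`).
#' @param interval Length-2 vector `c(day_start, day_end)`; a 7-day week.
#' @param factors List of [doe_factor()] fixing factor order and units.
#' @param beta0 Intercept on the sqrt-count scale.
#' @param linear,quadratic Named numeric vectors keyed by factor name
#'   (missing entries are 0).
#' @param interaction Named numeric vector keyed `"A:B"` with A before B in
#'   factor order (missing entries are 0).
#' @param hull Coded half-width of the region the model may be evaluated
#'   on without explicit extrapolation (the design's alpha).
#' @param diagnostics Optional list (R2, adj R2, RMSE, BIC).
#' @return An object of class `rsm_model`.
#' @export
rsm_model <- function(population, interval, factors, beta0,
                      linear = numeric(), interaction = numeric(),
                      quadratic = numeric(), hull = 2,
                      diagnostics = NULL) {
  factors <- as_factor_list(factors)
  fnames <- names(factors)
  stopifnot(length(interval) == 2, interval[2] - interval[1] == 7,
            interval[1] %% 7 == 0)
  fill <- function(x, keys) {
    out <- stats::setNames(numeric(length(keys)), keys)
    if (length(x)) {
      bad <- setdiff(names(x), keys)
      if (length(bad))
        stop("unknown coefficient key(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      out[names(x)] <- x
    }
    out
  }
  inter_keys <- if (length(fnames) >= 2) {
    ij <- utils::combn(length(fnames), 2)
    paste0(fnames[ij[1, ]], ":", fnames[ij[2, ]])
  } else character()
  structure(list(population = population,
                 interval = as.numeric(interval),
                 factors = factors,
                 beta0 = as.numeric(beta0),
                 linear = fill(linear, fnames),
                 interaction = fill(interaction, inter_keys),
                 quadratic = fill(quadratic, fnames),
                 hull = hull,
                 diagnostics = diagnostics,
                 transform = "sqrt"),
            class = "rsm_model")
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf("<rsm_model> %s, days %g-%g; %d factors; beta0 = %.4g\n",
              x$population, x$interval[1], x$interval[2],
              length(x$factors), x$beta0))
  if (!is.null(x$diagnostics))
    cat(sprintf("  R2 = %.3f, RMSE = %.3g\n",
                x$diagnostics$r_squared, x$diagnostics$rmse))
  invisible(x)
}

coef_vector <- function(model) {
  c(`(Intercept)` = model$beta0, model$linear, model$interaction,
    stats::setNames(model$quadratic,
                    paste0(names(model$quadratic), "^2")))
}

#' Fit a full-quadratic response-surface model to sqrt counts
#'
#' Ordinary least squares of the square-root-transformed absolute cell
#' count on the full second-order expansion of the coded design, for one
#' population and one 7-day interval. Replicate runs (multiple donors,
#' repeated center points) are pooled into the single fit.
#'
#' @param design A `doe_design`, normally a CCD (any design full-rank for
#'   the quadratic expansion works).
#' @param obs Observation table ([validate_observations()] schema); control
#'   rows are ignored.
#' @param population Population label to fit.
#' @param interval `c(day_start, day_end)`.
#' @return An `rsm_model` with diagnostics (R2, adjusted R2, RMSE, BIC).
#' @export
fit_rsm <- function(design, obs, population, interval) {
  stopifnot(inherits(design, "doe_design"))
  obs <- validate_observations(obs)
  sub <- obs[!obs$is_control & obs$population == population &
               obs$day_start == interval[1], , drop = FALSE]
  if (!nrow(sub))
    stop("incomplete-data: no observations for ", population, " in [",
         interval[1], ",", interval[2], ")", call. = FALSE)
  missing <- setdiff(design$run_id, sub$run_id)
  if (length(missing))
    stop("incomplete-data: missing run(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(sub$run_id, design$run_id)
  if (anyNA(idx))
    stop("observation run_id(s) not in design: ",
         paste(unique(sub$run_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  coded <- design$coded[idx, , drop = FALSE]
  y <- sqrt(sub$count)
  fnames <- colnames(design$coded)
  terms <- quad_terms(fnames, "full_quadratic")
  X <- cbind(`(Intercept)` = 1, term_columns(coded, terms))
  fit <- ols_qr(X, y)
  if (!fit$ok)
    stop("aliasing: quadratic expansion rank deficient; aliased terms: ",
         paste(fit$aliased, collapse = ", "), call. = FALSE)
  n <- length(y)
  p <- ncol(X)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - fit$rss / tss else 0
  adj <- if (tss > 0 && n > p) 1 - (1 - r2) * (n - 1) / (n - p) else 0
  cf <- fit$coef
  k <- length(fnames)
  rsm_model(population = population, interval = interval,
            factors = design$factors,
            beta0 = cf[1],
            linear = cf[1 + seq_len(k)],
            interaction = if (k >= 2)
              cf[1 + 2 * k + seq_len(k * (k - 1) / 2)] else numeric(),
            quadratic = stats::setNames(cf[1 + k + seq_len(k)], fnames),
            hull = max(abs(design$coded)),
            diagnostics = list(
              r_squared = r2, adj_r_squared = adj,
              rmse = sqrt(fit$rss / max(n - p, 1)),
              bic = profile_bic(n, fit$rss, p),
              n = n, rss = fit$rss))
}

#' Predict cell counts (or sqrt counts) from a response-surface model
#'
#' Evaluates the quadratic polynomial at coded points. On the count scale
#' negative sqrt-scale predictions are clipped to 0 before squaring, so
#' predicted counts are never negative.
#'
#' @param model An `rsm_model`.
#' @param point Named numeric vector, or a matrix/data frame with one row
#'   per point; names/columns are factor names (missing factors sit at
#'   coded 0).
#' @param scale `"count"` (default) or `"sqrt"`.
#' @param coded Is `point` in coded units (default) or natural ng/ml?
#' @param extrapolate Allow points outside the coded hull `[-alpha, alpha]`.
#' @return Numeric vector of predictions.
#' @export
predict_response <- function(model, point, scale = c("count", "sqrt"),
                             coded = TRUE, extrapolate = FALSE) {
  scale <- match.arg(scale)
  fnames <- names(model$factors)
  X <- point_matrix(point, fnames)
  if (!coded)
    for (nm in fnames) X[, nm] <- code_one(X[, nm], model$factors[[nm]])
  if (!extrapolate && any(abs(X) > model$hull + 1e-9))
    stop("extrapolation: point outside the coded hull [-",
         signif(model$hull, 6), ", ", signif(model$hull, 6),
         "]; set extrapolate = TRUE to override", call. = FALSE)
  yhat <- drop(model$beta0 +
                 X %*% model$linear +
                 X^2 %*% model$quadratic +
                 interaction_part(X, model$interaction))
  if (scale == "sqrt") yhat else pmax(yhat, 0)^2
}

point_matrix <- function(point, fnames) {
  if (is.null(dim(point))) {
    if (is.null(names(point)))
      stop("point must be named by factor", call. = FALSE)
    point <- matrix(point, nrow = 1, dimnames = list(NULL, names(point)))
  }
  point <- as.matrix(point)
  bad <- setdiff(colnames(point), fnames)
  if (length(bad))
    stop("unknown factor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  X <- matrix(0, nrow(point), length(fnames),
              dimnames = list(NULL, fnames))
  X[, colnames(point)] <- point
  X
}

interaction_part <- function(X, inter) {
  if (!length(inter)) return(0)
  out <- numeric(nrow(X))
  keys <- strsplit(names(inter), ":", fixed = TRUE)
  for (i in seq_along(inter)) {
    if (inter[i] != 0)
      out <- out + inter[i] * X[, keys[[i]][1]] * X[, keys[[i]][2]]
  }
  out
}

#' Single-factor dose sweep through the design center
#'
#' Sweeps one cytokine across a coded grid while all other cytokines are
#' held at their scaled center value (coded 0), returning count-scale
#' predictions in grid order.
#'
#' @param model An `rsm_model`.
#' @param factor Factor name to sweep.
#' @param grid Ascending coded levels within `[-alpha, alpha]`.
#' @return Data frame with `coded`, `ngml` and `count` columns.
#' @export
dose_sweep <- function(model, factor, grid = seq(-model$hull, model$hull,
                                                 length.out = 41)) {
  if (!factor %in% names(model$factors))
    stop("unknown factor: ", factor, call. = FALSE)
  if (is.unsorted(grid))
    stop("grid must be ascending", call. = FALSE)
  pts <- matrix(grid, ncol = 1, dimnames = list(NULL, factor))
  data.frame(coded = grid,
             ngml = decode_one(grid, model$factors[[factor]]),
             count = predict_response(model, pts, scale = "count"))
}

#' Write or read an `rsm_model` as JSON
#'
#' The schema — `population`, `interval`, `factors` (full definitions),
#' `beta0`, `linear`, `interaction`, `quadratic`, `hull`, `diagnostics` —
#' doubles as the import format for externally estimated coefficient
#' tables.
#'
#' @param model An `rsm_model`.
#' @param path File path.
#' @return `read_rsm_model()` returns an `rsm_model`.
#' @export
write_rsm_model <- function(model, path) {
  jsonlite::write_json(
    list(population = model$population, interval = model$interval,
         factors = lapply(model$factors, function(f)
           f[c("name", "low", "center", "high", "scale")]),
         beta0 = model$beta0, linear = as.list(model$linear),
         interaction = as.list(model$interaction),
         quadratic = as.list(model$quadratic),
         hull = model$hull, diagnostics = model$diagnostics),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rsm_model
#' @export
read_rsm_model <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  factors <- lapply(j$factors, function(f)
    doe_factor(f$name, low = f$low, high = f$high, center = f$center,
               scale = f$scale))
  rsm_model(population = j$population, interval = unlist(j$interval),
            factors = factors, beta0 = j$beta0,
            linear = unlist(j$linear),
            interaction = if (length(j$interaction))
              unlist(j$interaction) else numeric(),
            quadratic = unlist(j$quadratic), hull = j$hull,
            diagnostics = j$diagnostics)
}
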