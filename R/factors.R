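#' Define a cytokine factor for a coded experimental design
#'
#' A factor maps between coded design units and natural concentrations in
#' ng/ml. Under `scale = "linear"` the center must be the arithmetic midpoint
#' of `low` and `high`; under `scale = "log10"` it must be the geometric
#' midpoint (so the coding map is affine in log10 concentration). Coded -1,
#' 0 and +1 correspond to `low`, `center` and `high`; axial points of a
#' central composite design extend beyond +/-1.
#'
#' @param name Cytokine identifier (e.g. `"SCF"`, `"TNFa"`).
#' @param low,high Natural concentrations (ng/ml) at coded -1 and +1.
#' @param center Natural concentration at coded 0. Defaults to the midpoint
#'   implied by `scale`.
#' @param scale Coding map: `"linear"` or `"log10"`. Log coding requires
#'   strictly positive `low`.
#' @return An object of class `doe_factor`.
#' @examples
#' doe_factor("SCF", low = 10, high = 100)
#' doe_factor("IL7", low = 1, high = 100, scale = "log10")  # center = 10
#' @export
doe_factor <- function(name, low, high, center = NULL,
                       scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(low) || !is.numeric(high) || low < 0 || high < 0)
    stop("invalid-factor: concentrations must be non-negative numbers",
         call. = FALSE)
  if (low >= high)
    stop("invalid-factor: 'low' must be strictly less than 'high' for ",
         name, call. = FALSE)
  if (scale == "log10" && low <= 0)
    stop("invalid-factor: log10 coding requires strictly positive 'low'",
         call. = FALSE)
  mid <- if (scale == "linear") (low + high) / 2 else
    10 ^ ((log10(low) + log10(high)) / 2)
  if (is.null(center)) {
    center <- mid
  } else {
    if (center <= low || center >= high)
      stop("invalid-factor: 'center' must lie strictly between 'low' and ",
           "'high'", call. = FALSE)
    if (abs(center - mid) > 1e-8 * max(1, abs(mid)))
      stop("invalid-factor: 'center' must be the ", scale,
           " midpoint of 'low' and 'high' (expected ", signif(mid, 10), ")",
           call. = FALSE)
  }
  structure(list(name = name, low = low, center = center, high = high,
                 scale = scale),
            class = "doe_factor")
}

#' @export
print.doe_factor <- function(x, ...) {
  cat(sprintf("<doe_factor> %s: %g / %g / %g ng/ml (%s coding)\n",
              x$name, x$low, x$center, x$high, x$scale))
  invisible(x)
}

factor_names <- function(factors) vapply(factors, `[[`, "", "name")

as_factor_list <- function(factors) {
  if (inherits(factors, "doe_factor")) factors <- list(factors)
  if (!is.list(factors) || !all(vapply(factors, inherits, TRUE, "doe_factor")))
    stop("'factors' must be a list of doe_factor objects", call. = FALSE)
  nm <- factor_names(factors)
  if (anyDuplicated(nm))
    stop("duplicate factor names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(factors) <- nm
  factors
}

## coded <-> natural maps for a single factor (vectorized); domain checks
## on user-supplied naturals live in map_units()
code_one <- function(x, f) {
  if (f$scale == "linear") {
    (x - f$center) / ((f$high - f$low) / 2)
  } else {
    if (any(x == 0))
      stop("domain error: log10 coding undefined at 0 ng/ml for ", f$name,
           call. = FALSE)
    (log10(x) - log10(f$center)) / ((log10(f$high) - log10(f$low)) / 2)
  }
}

decode_one <- function(z, f) {
  if (f$scale == "linear") {
    f$center + z * (f$high - f$low) / 2
  } else {
    10 ^ (log10(f$center) + z * (log10(f$high) - log10(f$low)) / 2)
  }
}

#' Map design points between coded and natural concentration units
#'
#' The coded scale places the design center at 0 and the factorial levels at
#' -1 and +1; axial points extend to +/-alpha. The map is affine in natural
#' concentration (linear coding) or in log10 concentration (log10 coding),
#' and round-trips exactly to numerical precision.
#'
#' @param x A named numeric vector, matrix or data frame whose
#'   names/columns are factor names, or a `doe_design`.
#' @param factors List of [doe_factor()]; taken from the design when `x` is
#'   a `doe_design`.
#' @param direction `"to_natural"` or `"to_coded"`.
#' @return The same shape as `x` with values converted. For a `doe_design`,
#'   a data frame of the requested units.
#' @examples
#' f <- doe_factor("IL3", low = 0, high = 20)   # center 10 ng/ml
#' map_units(c(IL3 = 1), list(f), "to_natural") # 20 ng/ml
#' map_units(c(IL3 = 30), list(f), "to_coded")  # +2
#' @export
map_units <- function(x, factors = NULL,
                      direction = c("to_natural", "to_coded")) {
  direction <- match.arg(direction)
  if (inherits(x, "doe_design")) {
    factors <- x$factors
    x <- if (direction == "to_natural") x$coded else design_natural(x)
  }
  factors <- as_factor_list(factors)
  fun <- if (direction == "to_natural") decode_one else function(x, f) {
    if (any(x < 0))
      stop("domain error: natural concentration below 0 for ", f$name,
           call. = FALSE)
    code_one(x, f)
  }
  if (is.null(dim(x))) {
    if (is.null(names(x)))
      stop("point must be named by factor", call. = FALSE)
    missing <- setdiff(names(x), names(factors))
    if (length(missing))
      stop("unknown factor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    out <- x
    for (nm in names(x)) out[nm] <- fun(x[[nm]], factors[[nm]])
    return(out)
  }
  out <- as.data.frame(x)
  for (nm in intersect(colnames(out), names(factors)))
    out[[nm]] <- fun(out[[nm]], factors[[nm]])
  out
}

#' Read factor definitions from a YAML or JSON configuration file
#'
#' The file holds a list of records with fields `name`, `low`, `high`,
#' optional `center` and optional `scale` (default `"linear"`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of [doe_factor()] objects.
#' @export
read_factors <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  as_factor_list(lapply(raw, function(r)
    doe_factor(r$name, low = r$low, high = r$high,
               center = r$center %||% NULL,
               scale = r$scale %||% "linear")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
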