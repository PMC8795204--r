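#' Default cytokine factors for the 42-day response-surface campaign
#'
#' Six cytokines with linear coding on ng/ml ranges chosen so that axial
#' points of an orthogonal CCD (alpha ~ 2.1 for the half-fraction core)
#' stay at non-negative concentrations. Centers for IL-3 (10 ng/ml) and
#' TNFa (5 ng/ml) sit at their usual working concentrations; the remaining
#' cytokines span 30-70 ng/ml around a 50 ng/ml center.
#'
#' @return Named list of six [doe_factor()] objects.
#' @export
default_factors <- function() {
  as_factor_list(list(
    doe_factor("SCF", low = 30, high = 70),
    doe_factor("Flt3L", low = 30, high = 70),
    doe_factor("IL3", low = 6, high = 14),
    doe_factor("IL7", low = 30, high = 70),
    doe_factor("TNFa", low = 3, high = 7),
    doe_factor("CXCL12", low = 30, high = 70)))
}

norm_name <- function(x) toupper(gsub("[^A-Za-z0-9]", "", x))

#' Ground-truth dose-response surfaces with time-varying regimes
#'
#' Builds one full-quadratic surface (sqrt-count scale, coded units) per
#' population per 7-day interval, with three coefficient regimes that
#' change exactly at days 7 and 21:
#' \describe{
#'   \item{days 0-7}{SCF, IL-3 and TNFa active with positive IL-3 x TNFa
#'     and SCF x TNFa synergies; IL-7 unresponsive.}
#'   \item{days 7-21}{SCF and IL-7 drive expansion; the IL-3 effect has
#'     flattened to zero; TNFa weakly positive.}
#'   \item{days 21-42}{TNFa inhibits maturation (negative linear term);
#'     IL-3 inert (hence zero from day 28 onward as well).}
#' }
#' Flt3L is inert throughout and CXCL12 modestly positive. Every factor
#' carries a negative pure-quadratic term so each interval's optimum is an
#' interior point; within a regime, population surfaces are scaled copies
#' of each other, so all populations share the regime's optimum. The sharp
#' regime breaks are a fixture property that gives the stage-boundary
#' search a known correct answer (t1, t2) = (7, 21); coefficient
#' magnitudes are package defaults, not estimates.
#'
#' @param factors Factor list containing SCF, Flt3L, IL-3, IL-7, TNFa and
#'   CXCL12 (name matching ignores case and punctuation).
#' @param noise_sd Gaussian noise standard deviation on the sqrt-count
#'   scale attached to each surface (default 0.5).
#' @return Named list of surfaces (`rsm_model` objects with a `noise_sd`
#'   field), keyed `"<population>.<day_start>"`.
#' @export
default_ground_truth <- function(factors = default_factors(),
                                 noise_sd = 0.5) {
  factors <- as_factor_list(factors)
  need <- c("SCF", "FLT3L", "IL3", "IL7", "TNFA", "CXCL12")
  have <- norm_name(names(factors))
  if (length(setdiff(need, have)))
    stop("config error: ground truth requires factor(s) ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  nm <- stats::setNames(names(factors)[match(need, have)], need)

  lin <- function(...) {
    v <- c(...)
    stats::setNames(v, nm[names(v)])
  }
  regimes <- list(
    A = list(  # days 0-7: early IL-3/TNFa synergy, IL-7 inert
      linear = lin(SCF = 3, IL3 = 2.5, TNFA = 2.5, CXCL12 = 0.8),
      interaction = stats::setNames(
        c(1, 0.6),
        c(inter_key(nm[["IL3"]], nm[["TNFA"]], names(factors)),
          inter_key(nm[["SCF"]], nm[["TNFA"]], names(factors)))),
      quadratic = lin(SCF = -2, IL3 = -2, TNFA = -2, IL7 = -0.8,
                      FLT3L = -0.5, CXCL12 = -1)),
    B = list(  # days 7-21: SCF/IL-7 driven, IL-3 flattened
      linear = lin(SCF = 3, IL7 = 3, TNFA = 0.5, CXCL12 = 0.8),
      interaction = numeric(),
      quadratic = lin(SCF = -2, IL7 = -2, TNFA = -1, IL3 = -0.8,
                      FLT3L = -0.5, CXCL12 = -1)),
    C = list(  # days 21-42: TNFa inhibitory, IL-3 inert
      linear = lin(SCF = 2.5, IL7 = 3, TNFA = -2.5, CXCL12 = 0.8),
      interaction = numeric(),
      quadratic = lin(SCF = -2, IL7 = -2, TNFA = -1.5, IL3 = -0.5,
                      FLT3L = -0.5, CXCL12 = -1)))
  regime_of <- function(start) if (start < 7) "A" else
    if (start < 21) "B" else "C"

  # baselines (sqrt-count scale) large enough that every surface stays
  # positive over the whole design region, including factorial corners
  pops <- list(
    early = c(proT = 20, CD4ISP = 18, earlyDP = 16),
    late = c(CD4ISP = 17, earlyDP = 18, lateDP = 15, CD8SP = 13))
  scale_of <- c(proT = 1, CD4ISP = 0.9, earlyDP = 0.8, lateDP = 0.85,
                CD8SP = 0.7)

  surfaces <- list()
  for (start in seq(0, 35, by = 7)) {
    rg <- regimes[[regime_of(start)]]
    b0s <- if (start < 14) pops$early else pops$late
    for (pop in names(b0s)) {
      s <- scale_of[[pop]]
      m <- rsm_model(population = pop, interval = c(start, start + 7),
                     factors = factors, beta0 = b0s[[pop]],
                     linear = s * rg$linear,
                     interaction = if (length(rg$interaction))
                       s * rg$interaction else numeric(),
                     quadratic = s * rg$quadratic,
                     hull = 2.5)
      m$noise_sd <- noise_sd
      surfaces[[paste0(pop, ".", start)]] <- m
    }
  }
  surfaces
}

# "A:B" key with the two factors in canonical factor order
inter_key <- function(a, b, fnames) {
  i <- match(c(a, b), fnames)
  paste(fnames[sort(i)], collapse = ":")
}

#' Simulate an observation table from ground-truth surfaces
#'
#' For every design run, donor, population and interval with a surface,
#' the sqrt-count signal at the run's coded point gets the donor's offset
#' and Gaussian noise added, is floored at 0 and squared to an absolute
#' count. Control replicates (for z-scoring) are generated at a designated
#' control point, the design center by default.
#'
#' @param design A `doe_design` whose factors match the surfaces.
#' @param surfaces List of surfaces from [default_ground_truth()] (or any
#'   `rsm_model`s carrying a `noise_sd` field).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param noise_sd Overrides each surface's own `noise_sd` when not
#'   `NULL`.
#' @param donor_offsets Named (or unnamed) numeric vector of per-donor
#'   additive shifts on the sqrt scale; its length sets the donor count.
#'   Default one donor with no offset.
#' @param n_control Control replicates per (donor, population, interval);
#'   default 3, 0 to disable.
#' @param control_point Coded coordinates of the control condition
#'   (default all 0).
#' @return An observation table (see [validate_observations()]).
#' @export
simulate_dataset <- function(design, surfaces, seed = 1, noise_sd = NULL,
                             donor_offsets = 0, n_control = 3,
                             control_point = NULL) {
  stopifnot(inherits(design, "doe_design"))
  fnames <- colnames(design$coded)
  ndonor <- length(donor_offsets)
  donors <- names(donor_offsets) %||% paste0("donor_", seq_len(ndonor))
  if (is.null(names(donor_offsets))) names(donor_offsets) <- donors
  if (is.null(control_point))
    control_point <- stats::setNames(rep(0, length(fnames)), fnames)

  with_seed(seed, {
    rows <- list()
    for (key in seq_along(surfaces)) {
      sf <- surfaces[[key]]
      if (!setequal(names(sf$factors), fnames))
        stop("surface for ", sf$population, " [", sf$interval[1], ",",
             sf$interval[2], ") does not match the design factors",
             call. = FALSE)
      sd_use <- noise_sd %||% sf$noise_sd %||% 0
      mu <- predict_response(sf, design$coded, scale = "sqrt",
                             extrapolate = TRUE)
      mu_ctl <- predict_response(sf, control_point, scale = "sqrt",
                                 extrapolate = TRUE)
      for (d in donors) {
        s <- mu + donor_offsets[[d]] +
          stats::rnorm(length(mu), 0, sd_use)
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = design$run_id, donor_id = d,
          day_start = sf$interval[1], day_end = sf$interval[2],
          population = sf$population, count = pmax(s, 0)^2,
          is_control = FALSE)
        if (n_control > 0) {
          sc <- mu_ctl + donor_offsets[[d]] +
            stats::rnorm(n_control, 0, sd_use)
          rows[[length(rows) + 1L]] <- data.frame(
            run_id = sprintf("control_%02d", seq_len(n_control)),
            donor_id = d, day_start = sf$interval[1],
            day_end = sf$interval[2], population = sf$population,
            count = pmax(sc, 0)^2, is_control = TRUE)
        }
      }
    }
    validate_observations(do.call(rbind, rows))
  })
}

#' Simulate a logistic inhibitor dose-response curve
#'
#' response(d) = 100 / (1 + (d / ed50_true)^hill), plus optional seeded
#' Gaussian noise, floored at 0 — the fixture for testing ED50 recovery
#' by linear interpolation.
#'
#' @param ed50_true True midpoint dose (> 0, within the grid span).
#' @param hill Hill slope (> 0; large values approximate a step).
#' @param doses Dose grid including 0.
#' @param seed Seed for the noise draws (unused when `noise_sd = 0`).
#' @param noise_sd Gaussian noise standard deviation in percent units.
#' @return Data frame with `dose_uM` and `response` columns.
#' @export
simulate_dose_response_curve <- function(ed50_true, hill = 1,
                                         doses = c(0, 0.05, 0.1, 0.25,
                                                   0.5, 1, 2.5),
                                         seed = 1, noise_sd = 0) {
  if (ed50_true <= 0)
    stop("domain error: ed50_true must be positive", call. = FALSE)
  if (ed50_true > max(doses))
    stop("domain error: ed50_true outside the dose grid span",
         call. = FALSE)
  stopifnot(doses[1] == 0, hill > 0)
  resp <- 100 / (1 + (doses / ed50_true)^hill)
  if (noise_sd > 0)
    resp <- with_seed(seed,
                      pmax(resp + stats::rnorm(length(resp), 0, noise_sd),
                           0))
  data.frame(dose_uM = doses, response = resp)
}

#' Write or read an observation table as CSV
#' @param obs Observation table.
#' @param path CSV path.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(validate_observations(obs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  validate_observations(utils::read.csv(path, stringsAsFactors = FALSE))
}
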