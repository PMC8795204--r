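#' ED50 of an inhibitor dose-response curve by linear interpolation
#'
#' Responses are normalized to the vehicle (dose 0) value as 100%, and the
#' 50% effective dose is the linear interpolation on the dose axis between
#' the first adjacent dose pair bracketing 50%. Curves that never fall
#' below 50% are censored at the maximum dose. Non-monotone curves use the
#' first crossing and are flagged.
#'
#' @param doses Strictly ascending doses (same units as the result, e.g.
#'   uM), the first being 0 (vehicle control).
#' @param responses Non-negative responses aligned to `doses` (frequency
#'   %, fold change, ...); the dose-0 response must be positive.
#' @return List with `value` (dose units), `censored`, `nonmonotone` and
#'   `method = "linear-interpolation"`.
#' @examples
#' ed50_interpolate(c(0, 0.1, 0.5), c(100, 80, 40))$value  # 0.4
#' @export
ed50_interpolate <- function(doses, responses) {
  stopifnot(length(doses) >= 2, length(doses) == length(responses))
  if (doses[1] != 0)
    stop("first dose must be 0 (vehicle control)", call. = FALSE)
  if (any(diff(doses) <= 0))
    stop("doses must be strictly ascending", call. = FALSE)
  if (any(responses < 0))
    stop("responses must be non-negative", call. = FALSE)
  if (responses[1] == 0)
    stop("undefined-baseline: response at dose 0 is 0", call. = FALSE)
  pct <- 100 * responses / responses[1]
  nonmono <- any(diff(pct) > 0)
  cross <- which(pct[-length(pct)] >= 50 & pct[-1] < 50)
  if (!length(cross)) {
    # flat-at-50 tail or never below: censored unless it touches 50 exactly
    at50 <- which(pct == 50)
    if (length(at50))
      return(list(value = doses[at50[1]], censored = FALSE,
                  nonmonotone = nonmono, method = "linear-interpolation"))
    return(list(value = doses[length(doses)], censored = TRUE,
                nonmonotone = nonmono, method = "linear-interpolation"))
  }
  i <- cross[1]
  value <- doses[i] + (pct[i] - 50) / (pct[i] - pct[i + 1]) *
    (doses[i + 1] - doses[i])
  list(value = value, censored = FALSE, nonmonotone = nonmono,
       method = "linear-interpolation")
}

#' Per-donor ED50 estimates with a mean +/- standard error summary
#'
#' @param curve Data frame with columns `dose_uM`, `donor_id`, `response`.
#' @return List of per-donor estimates plus `mean`, `se` and `n_censored`.
#' @export
ed50_by_donor <- function(curve) {
  stopifnot(all(c("dose_uM", "donor_id", "response") %in% names(curve)))
  per <- lapply(split(curve, curve$donor_id), function(d) {
    d <- d[order(d$dose_uM), ]
    ed50_interpolate(d$dose_uM, d$response)
  })
  vals <- vapply(per, `[[`, 0, "value")
  list(per_donor = per, mean = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_censored = sum(vapply(per, `[[`, TRUE, "censored")))
}

#' Cumulative fold expansion across weekly passages
#'
#' Cells are counted at the end of each week and a fraction is carried
#' forward to seed the next week's plate. The cumulative fold is the
#' product of the weekly per-cell expansions (counted / seeded), so it is
#' split-adjusted: passaging only half the cells does not halve the
#' reported expansion.
#'
#' @param passages Data frame with columns `week`, `counted` (cells at the
#'   end of the week) and `fraction_carried` (in (0, 1\]; the last week's
#'   value is unused).
#' @param seed0 Cells seeded on day 0.
#' @return Cumulative fold expansion relative to `seed0`.
#' @examples
#' p <- data.frame(week = 1:2, counted = c(100, 500),
#'                 fraction_carried = c(0.5, 1))
#' cumulative_fold_expansion(p, seed0 = 10)  # 10 * (500/50) = 100
#' @export
cumulative_fold_expansion <- function(passages, seed0) {
  stopifnot(all(c("week", "counted", "fraction_carried") %in%
                  names(passages)))
  passages <- passages[order(passages$week), ]
  if (any(passages$counted <= 0))
    stop("counts must be positive", call. = FALSE)
  if (any(passages$fraction_carried <= 0 | passages$fraction_carried > 1))
    stop("fraction_carried must be in (0, 1]", call. = FALSE)
  if (seed0 <= 0) stop("division error: zero or negative seed",
                       call. = FALSE)
  seeded <- seed0
  fold <- 1
  for (i in seq_len(nrow(passages))) {
    fold <- fold * passages$counted[i] / seeded
    seeded <- passages$counted[i] * passages$fraction_carried[i]
  }
  fold
}

#' Surface density of a plate-coating protein
#'
#' @param concentration Coating solution concentration in ug/ml.
#' @param volume Coating volume in ul.
#' @param area Well growth area in mm^2 (a 96-well plate well is ~32 mm^2,
#'   i.e. 0.32 cm^2).
#' @return Surface density in ng/mm^2 (ug/ml x ul = ng).
#' @examples
#' coating_density(2.5, 50, 32)  # ~3.9 ng/mm^2
#' @export
coating_density <- function(concentration, volume, area = 32) {
  stopifnot(concentration > 0, volume > 0, area > 0)
  concentration * volume / area
}

#' Relative expression by the delta cycle threshold method
#'
#' @param ct_gene,ct_reference Positive, finite qPCR cycle thresholds for
#'   the target gene and the reference gene (e.g. beta-actin).
#' @return 2^-(ct_gene - ct_reference).
#' @export
delta_ct_expression <- function(ct_gene, ct_reference) {
  if (missing(ct_reference) || any(!is.finite(ct_reference)))
    stop("missing reference cycle threshold", call. = FALSE)
  stopifnot(all(is.finite(ct_gene)), all(ct_gene > 0),
            all(ct_reference > 0))
  2^(-(ct_gene - ct_reference))
}

#' Descriptive group summaries with a median ratio against a reference
#'
#' @param values Numeric vector.
#' @param group Grouping vector aligned to `values`.
#' @param reference Name of the reference group for the median ratio
#'   (default the first group).
#' @return Data frame per group: `n`, `median`, `iqr`, `q5`, `q95`,
#'   `mean`, `se`, `median_ratio` (group median / reference median).
#' @export
group_summary <- function(values, group, reference = NULL) {
  stopifnot(length(values) == length(group))
  sp <- split(values, group)
  if (any(!lengths(sp))) stop("empty group", call. = FALSE)
  if (is.null(reference)) reference <- names(sp)[1]
  if (!reference %in% names(sp))
    stop("unknown reference group: ", reference, call. = FALSE)
  ref_med <- stats::median(sp[[reference]])
  out <- do.call(rbind, lapply(names(sp), function(g) {
    v <- sp[[g]]
    data.frame(group = g, n = length(v), median = stats::median(v),
               iqr = stats::IQR(v),
               q5 = unname(stats::quantile(v, 0.05)),
               q95 = unname(stats::quantile(v, 0.95)),
               mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               median_ratio = stats::median(v) / ref_med)
  }))
  rownames(out) <- NULL
  out
}

#' Normality-gated multi-group comparison
#'
#' Each group is tested for normality with Shapiro-Wilk. If any group
#' rejects (p < 0.05), groups are compared by Kruskal-Wallis with Dunn's
#' post hoc z tests and Benjamini-Hochberg adjustment of the pairwise p
#' values; otherwise one-way ANOVA with Tukey's HSD. Groups with zero
#' variance cannot be tested for normality; the procedure then skips with
#' a warning and reports no test.
#'
#' @param values Numeric vector.
#' @param group Grouping vector (>= 2 groups, >= 3 values each).
#' @return List: `test_used` (`"kruskal-dunn"`, `"anova-tukey"` or
#'   `"none"`), `shapiro_p` per group, `statistic`, `p_value` (omnibus)
#'   and `pairwise` (comparison, statistic, adjusted p).
#' @export
adaptive_group_test <- function(values, group) {
  group <- as.factor(group)
  sp <- split(values, group)
  if (length(sp) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(lengths(sp) < 3))
    stop("each group needs at least 3 values", call. = FALSE)
  if (any(vapply(sp, function(v) stats::sd(v) == 0, TRUE))) {
    warning("zero-variance group; normality gate undefined, test skipped",
            call. = FALSE)
    return(list(test_used = "none", shapiro_p = NULL, statistic = NA_real_,
                p_value = NA_real_, pairwise = NULL))
  }
  shapiro_p <- vapply(sp, function(v) stats::shapiro.test(v)$p.value, 0)
  if (any(shapiro_p < 0.05)) {
    kw <- stats::kruskal.test(values, group)
    pw <- dunn_posthoc(values, group)
    pw$p_adjusted <- stats::p.adjust(pw$p_value, method = "BH")
    list(test_used = "kruskal-dunn", shapiro_p = shapiro_p,
         statistic = unname(kw$statistic), p_value = kw$p.value,
         pairwise = pw)
  } else {
    fit <- stats::aov(values ~ group)
    tk <- stats::TukeyHSD(fit)$group
    sm <- summary(fit)[[1]]
    list(test_used = "anova-tukey", shapiro_p = shapiro_p,
         statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
         pairwise = data.frame(comparison = rownames(tk),
                               statistic = tk[, "diff"],
                               p_adjusted = tk[, "p adj"],
                               row.names = NULL))
  }
}

# Dunn's rank-sum z statistics with tie correction; two-sided normal p
dunn_posthoc <- function(values, group) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rs <- tapply(r, group, mean)
  ns <- tapply(r, group, length)
  gs <- names(rs)
  cmb <- utils::combn(length(gs), 2)
  do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
    i1 <- cmb[1, j]; i2 <- cmb[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[i1] + 1 / ns[i2]))
    z <- (rs[i1] - rs[i2]) / se
    data.frame(comparison = paste(gs[i1], gs[i2], sep = "-"),
               statistic = unname(z),
               p_value = unname(2 * stats::pnorm(-abs(z))))
  }))
}
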