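#' Enumerate candidate three-stage boundaries
#'
#' Stage boundaries t1 < t2 are multiples of 7 in \[7, 42), splitting the
#' 42-day assay into \[0, t1), \[t1, t2) and \[t2, 42\].
#'
#' @return Data frame of the 10 `(t1, t2)` pairs in lexicographic order.
#' @export
enumerate_partitions <- function() {
  ts <- seq(7, 35, by = 7)
  pairs <- expand.grid(t2 = ts, t1 = ts)[, c("t1", "t2")]
  pairs <- pairs[pairs$t1 < pairs$t2, ]
  pairs <- pairs[order(pairs$t1, pairs$t2), ]
  rownames(pairs) <- NULL
  pairs
}

#' Evaluate a candidate three-stage protocol
#'
#' Each stage's cytokine concentration is the arithmetic mean, in natural
#' ng/ml units, of the per-interval optimal concentrations of the 7-day
#' intervals whose start day falls in that stage. Each interval's overall
#' desirability is then re-evaluated at its stage concentration (with the
#' interval's own resolved objectives), and the protocol is scored by the
#' mean of the six interval desirabilities.
#'
#' @param optima List of six `doe_optimum` from
#'   [optimize_all_intervals()], covering days 0-42.
#' @param models The `rsm_model`s used for the optimization.
#' @param t1,t2 Stage boundaries (multiples of 7, 7 <= t1 < t2 <= 35).
#' @param coded_average Average stage concentrations in coded rather than
#'   natural units (sensitivity analysis; default `FALSE`).
#' @return A `staged_protocol`: `t1`, `t2`, `stage_concentrations` (ng/ml),
#'   `average_D`, `per_interval_D`.
#' @export
evaluate_staged_protocol <- function(optima, models, t1, t2,
                                     coded_average = FALSE) {
  stopifnot(t1 %% 7 == 0, t2 %% 7 == 0, t1 >= 7, t1 < t2, t2 <= 35)
  starts <- vapply(optima, function(o) o$interval[1], 0)
  need <- seq(0, 35, by = 7)
  if (length(setdiff(need, starts)))
    stop("incomplete-optima: missing interval(s) starting at day ",
         paste(setdiff(need, starts), collapse = ", "), call. = FALSE)
  optima <- optima[match(need, starts)]
  factors <- models[[1]]$factors
  fnames <- names(factors)
  stage_of <- function(s) 1L + (s >= t1) + (s >= t2)
  stages <- vapply(need, stage_of, 0L)

  stage_conc <- matrix(NA_real_, 3, length(fnames),
                       dimnames = list(paste0("stage", 1:3), fnames))
  for (st in 1:3) {
    member <- which(stages == st)
    if (coded_average) {
      pts <- do.call(rbind, lapply(optima[member],
                                   function(o) o$best$coded))
      avg_coded <- colMeans(pts)
      stage_conc[st, ] <- vapply(fnames, function(nm)
        decode_one(avg_coded[[nm]], factors[[nm]]), 0)
    } else {
      pts <- do.call(rbind, lapply(optima[member],
                                   function(o) o$best$natural))
      stage_conc[st, ] <- colMeans(pts)
    }
  }

  per_D <- vapply(seq_along(need), function(i) {
    o <- optima[[i]]
    conc <- stage_conc[stages[i], ]
    coded <- vapply(fnames, function(nm) code_one(conc[[nm]], factors[[nm]]),
                    0)
    mods <- as_model_list(Filter(function(m)
      m$interval[1] == need[i] &&
        m$population %in% vapply(o$objectives, `[[`, "", "population"),
      models))
    eval_overall_D(mods, o$objectives,
                   matrix(coded, 1, dimnames = list(NULL, fnames)))
  }, 0)
  names(per_D) <- paste0("day", need)

  structure(list(t1 = t1, t2 = t2,
                 stage_concentrations = as.data.frame(stage_conc),
                 average_D = mean(per_D), per_interval_D = per_D),
            class = "staged_protocol")
}

#' @export
print.staged_protocol <- function(x, ...) {
  cat(sprintf("<staged_protocol> t1 = %d, t2 = %d; average D = %.4f\n",
              x$t1, x$t2, x$average_D))
  print(round(x$stage_concentrations, 2))
  invisible(x)
}

#' Exhaustive search for the best three-stage protocol
#'
#' Evaluates every enumerated `(t1, t2)` pair and returns the one with the
#' highest average overall desirability; exact ties go to the
#' lexicographically earliest pair.
#'
#' @inheritParams evaluate_staged_protocol
#' @return The best `staged_protocol`, with an `all_partitions` data frame
#'   (`t1`, `t2`, `average_D`) attached.
#' @export
select_best_partition <- function(optima, models, coded_average = FALSE) {
  pairs <- enumerate_partitions()
  evals <- lapply(seq_len(nrow(pairs)), function(i)
    evaluate_staged_protocol(optima, models, pairs$t1[i], pairs$t2[i],
                             coded_average = coded_average))
  pairs$average_D <- vapply(evals, `[[`, 0, "average_D")
  best <- evals[[which.max(pairs$average_D)]]
  best$all_partitions <- pairs
  best
}

#' Serialize a staged protocol to JSON
#' @param protocol A `staged_protocol`.
#' @param path Output path.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(
    list(t1 = protocol$t1, t2 = protocol$t2,
         stage_concentrations_ngml = protocol$stage_concentrations,
         average_D = protocol$average_D,
         per_interval_D = as.list(protocol$per_interval_D)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
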