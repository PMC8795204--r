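#' Generate a definitive screening design
#'
#' Builds the three-level screening design from a conference matrix C as the
#' row-block stack \[C; -C; 0\]: every non-center run has a mirror (negated)
#' run, each factor takes the coded levels \{-1, 0, +1\}, and main effects
#' are orthogonal to each other and to two-factor interactions. For m
#' factors the design uses the smallest shipped conference-matrix order
#' m' >= m (orders 6, 8, 10, 12, 14, 16) and drops trailing columns,
#' giving 2 m' + 1 runs.
#'
#' @param factors List of [doe_factor()] (between 4 and 16).
#' @return A `doe_design` of kind `"DSD"`.
#' @examples
#' f <- lapply(paste0("F", 1:6), doe_factor, low = 0, high = 20)
#' d <- generate_dsd(f)
#' nrow(d$coded)  # 13
#' @export
generate_dsd <- function(factors) {
  factors <- as_factor_list(factors)
  m <- length(factors)
  if (m < 4 || m > 16)
    stop("unsupported-size: definitive screening designs are supported for ",
         "4 to 16 factors, got ", m, call. = FALSE)
  orders <- as.integer(names(.conference_matrices))
  mp <- min(orders[orders >= m])
  C <- .conference_matrices[[as.character(mp)]][, seq_len(m), drop = FALSE]
  coded <- rbind(C, -C, matrix(0, 1, m))
  colnames(coded) <- names(factors)
  new_design(kind = "DSD", factors = factors, coded = coded,
             n_center = 1L, alpha = 1)
}

#' Generate a central composite design
#'
#' A two-level factorial core (full for up to 5 factors, a resolution-V or
#' better half-fraction for 6-8 factors, unless overridden), 2k axial runs
#' at coded +/-alpha, and `n_center` center runs. With
#' `alpha_mode = "orthogonal"`, alpha is chosen so that, after centering,
#' pure-quadratic model columns are orthogonal to the linear columns:
#' alpha = (((sqrt(N) - sqrt(F))^2 * F) / 4)^(1/4) with F the factorial run
#' count and N the total run count. `"rotatable"` gives alpha = F^(1/4);
#' `"face"` pins axial points to the factorial faces (alpha = 1, three
#' levels only).
#'
#' @param factors List of [doe_factor()] (between 2 and 8).
#' @param n_center Number of center runs (>= 1; default 8).
#' @param alpha_mode `"orthogonal"`, `"rotatable"` or `"face"`.
#' @param core `"auto"` (full for k <= 5, half-fraction for k >= 6),
#'   `"full"` or `"half"`.
#' @return A `doe_design` of kind `"CCD"` with the axial distance in
#'   `$alpha`.
#' @examples
#' f <- lapply(c("SCF", "Flt3L", "IL3", "IL7", "TNFa", "CXCL12"),
#'             doe_factor, low = 0, high = 100)
#' d <- generate_ccd(f, n_center = 8, alpha_mode = "orthogonal")
#' d$alpha
#' @export
generate_ccd <- function(factors, n_center = 8L,
                         alpha_mode = c("orthogonal", "rotatable", "face"),
                         core = c("auto", "full", "half")) {
  alpha_mode <- match.arg(alpha_mode)
  core <- match.arg(core)
  factors <- as_factor_list(factors)
  k <- length(factors)
  if (k < 2 || k > 8)
    stop("unsupported-size: central composite designs are supported for 2 ",
         "to 8 factors, got ", k, call. = FALSE)
  if (n_center < 1) stop("'n_center' must be >= 1", call. = FALSE)
  if (core == "auto") core <- if (k <= 5) "full" else "half"
  fac <- as.matrix(expand.grid(rep(list(c(-1, 1)),
                                   if (core == "full") k else k - 1)))
  if (core == "half") {
    # half-fraction generated by the product of all other columns
    # (I = +ABC...K), resolution >= V for k = 6-8
    fac <- cbind(fac, apply(fac, 1, prod))
  }
  Fn <- nrow(fac)
  N <- Fn + 2L * k + n_center
  alpha <- switch(alpha_mode,
    orthogonal = (((sqrt(N) - sqrt(Fn))^2 * Fn) / 4)^(1 / 4),
    rotatable  = Fn^(1 / 4),
    face       = 1)
  if (alpha_mode == "orthogonal" && alpha <= 1)
    stop("degenerate-design: orthogonal alpha = ", signif(alpha, 6),
         " <= 1; increase n_center or the factorial core", call. = FALSE)
  axial <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -alpha
    axial[2L * i, i] <- alpha
  }
  coded <- rbind(fac, axial, matrix(0, n_center, k))
  colnames(coded) <- names(factors)
  new_design(kind = "CCD", factors = factors, coded = coded,
             n_center = as.integer(n_center), alpha = alpha)
}

new_design <- function(kind, factors, coded, n_center, alpha) {
  coded <- as.matrix(coded)
  rownames(coded) <- NULL
  structure(list(kind = kind, factors = factors, coded = coded,
                 n_center = n_center, alpha = alpha,
                 run_id = sprintf("run_%02d", seq_len(nrow(coded)))),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("<doe_design> %s: %d runs x %d factors (%d center run%s",
              x$kind, nrow(x$coded), ncol(x$coded), x$n_center,
              if (x$n_center == 1) "" else "s"))
  if (x$kind == "CCD") cat(sprintf(", alpha = %.4f", x$alpha))
  cat(")\n")
  invisible(x)
}

#' Natural-unit (ng/ml) concentrations of a design's runs
#' @param design A `doe_design`.
#' @return Data frame, one column per factor, in ng/ml.
#' @export
design_natural <- function(design) {
  stopifnot(inherits(design, "doe_design"))
  out <- as.data.frame(design$coded)
  for (nm in names(design$factors))
    out[[nm]] <- decode_one(out[[nm]], design$factors[[nm]])
  out
}

is_center_run <- function(design) rowSums(abs(design$coded)) == 0

#' Write or read a design as CSV
#'
#' Columns: `run_id`, `kind`, `is_center`, then per factor `<name>.coded`
#' and `<name>.ngml`. Reading requires the factor definitions to rebuild
#' the coding maps; coded values are taken from the file and checked to
#' round-trip against the natural columns.
#'
#' @param design A `doe_design`.
#' @param path Output (or input) CSV path.
#' @param factors For [read_design()], the list of [doe_factor()].
#' @return `write_design()` returns `path` invisibly; `read_design()` a
#'   `doe_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "doe_design"))
  nat <- design_natural(design)
  df <- data.frame(run_id = design$run_id, kind = design$kind,
                   is_center = is_center_run(design))
  for (nm in names(design$factors)) {
    df[[paste0(nm, ".coded")]] <- design$coded[, nm]
    df[[paste0(nm, ".ngml")]] <- nat[[nm]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, factors) {
  factors <- as_factor_list(factors)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(factors)
  coded <- as.matrix(df[paste0(nm, ".coded")])
  colnames(coded) <- nm
  for (f in nm) {
    back <- code_one(df[[paste0(f, ".ngml")]], factors[[f]])
    if (max(abs(back - coded[, f])) > 1e-6)
      stop("design file inconsistent with factor definitions for ", f,
           call. = FALSE)
  }
  alpha <- max(abs(coded))
  d <- new_design(kind = df$kind[1], factors = factors, coded = coded,
                  n_center = sum(rowSums(abs(coded)) == 0), alpha = alpha)
  d$run_id <- df$run_id
  d
}

.onLoad <- function(libname, pkgname) {
  for (n in names(.conference_matrices)) {
    C <- .conference_matrices[[n]]
    n_i <- as.integer(n)
    stopifnot(all(diag(C) == 0),
              all(abs(C[row(C) != col(C)]) == 1),
              all(C %*% t(C) == (n_i - 1) * diag(n_i)))
  }
  invisible()
}
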