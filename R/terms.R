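# Term bookkeeping for quadratic response-surface expansions.
# Terms are strings over factor names: "A" (main effect), "A^2" (pure
# quadratic), "A:B" (two-factor interaction, names in factor order).

quad_terms <- function(fnames,
                       candidate_set = c("full_quadratic", "main_quadratic",
                                         "main_only")) {
  candidate_set <- match.arg(candidate_set)
  k <- length(fnames)
  terms <- fnames
  if (candidate_set != "main_only")
    terms <- c(terms, paste0(fnames, "^2"))
  if (candidate_set == "full_quadratic" && k >= 2) {
    ij <- utils::combn(k, 2)
    terms <- c(terms, paste0(fnames[ij[1, ]], ":", fnames[ij[2, ]]))
  }
  terms
}

# parents a term needs in the model under strong heredity
term_parents <- function(term) {
  if (grepl(":", term, fixed = TRUE)) strsplit(term, ":", fixed = TRUE)[[1]]
  else if (grepl("^2", term, fixed = TRUE)) sub("\\^2$", "", term)
  else character()
}

# model-matrix columns (no intercept) for terms over a coded run matrix
term_columns <- function(coded, terms) {
  if (!length(terms)) return(matrix(0, nrow(coded), 0))
  cols <- vapply(terms, function(tm) {
    if (grepl(":", tm, fixed = TRUE)) {
      p <- strsplit(tm, ":", fixed = TRUE)[[1]]
      coded[, p[1]] * coded[, p[2]]
    } else if (grepl("^2", tm, fixed = TRUE)) {
      coded[, sub("\\^2$", "", tm)]^2
    } else {
      coded[, tm]
    }
  }, numeric(nrow(coded)))
  matrix(cols, nrow = nrow(coded), dimnames = list(NULL, terms))
}

# OLS through the QR with rank reporting; X includes the intercept
ols_qr <- function(X, y) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))]]
    return(list(ok = FALSE, aliased = aliased))
  }
  coef <- qr.coef(qrx, y)
  res <- y - X %*% coef
  list(ok = TRUE, coef = drop(coef), rss = sum(res^2), resid = drop(res),
       qr = qrx)
}

profile_bic <- function(n, rss, k) {
  n * log(max(rss, 1e-300) / n) + k * log(n)
}
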