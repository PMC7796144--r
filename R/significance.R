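#' Permutation test for the significance of one effect
#'
#' Tests whether a term contributes more structure than expected by chance.
#' The test statistic is the sum of squares of the first `l` score columns
#' of the term's PCA sub-model,
#' \deqn{SS(f) = \sum_{i=1}^{n} \sum_{j=1}^{l} (T_f)_{i,j}^2,}
#' which for `l = "all"` equals the squared Frobenius norm of the effect
#' matrix. The null distribution is built by permuting whole rows of `X`
#' against the fixed design `N` times and recomputing the decomposition
#' under the same coding scheme; the p-value is the exact count
#' \deqn{p(f) = \#\{SS_r(f) \ge SS(f)\} / N.}
#' The observed data set is not counted among the permutations, so `p = 0`
#' is attainable.
#'
#' The design matrix is factored once and reused across permutations, so a
#' single test costs `N` least-squares solves against a cached QR
#' decomposition.
#'
#' @inheritParams asca_decompose
#' @param term Label of the tested term (e.g. `"A"` or `"A:B"`).
#' @param N Number of random permutations (the study default is 1000).
#' @param l Number of leading sub-model components entering the statistic,
#'   or `"all"` (default) for every component — equivalently the full
#'   effect-matrix norm.
#' @param seed Optional integer seed making the permutation stream
#'   reproducible.
#' @return An object of class `"asca_permutation"`: list with `term`,
#'   `ss_observed`, `null_ss` (length `N`), `p`, `N`, `l`, `seed`, `coding`.
#' @export
permutation_test <- function(X, design, model, term, N = 1000, l = "all",
                             seed = NULL) {
  if (is.character(model)) model <- model_spec(model)
  if (!is.numeric(N) || N < 1) stop("N must be at least 1")
  N <- as.integer(N)
  if (!term %in% model$labels) {
    stop("term '", term, "' is not in the model (",
         paste(model$labels, collapse = ", "), ")")
  }
  if (!identical(l, "all") && (!is.numeric(l) || l < 1)) {
    stop("l must be a positive integer or \"all\"")
  }
  X <- .as_response_matrix(X)

  dm <- build_design_matrix(design, model)
  qrd <- qr(dm$values)
  if (qrd$rank < ncol(dm$values)) {
    stop("aliased design: permutation test requires a full-rank design matrix")
  }
  idx <- dm$blocks[[term]]
  sub <- dm$values[, idx, drop = FALSE]

  term_ss <- function(Xr) {
    beta <- qr.coef(qrd, Xr)
    con <- sub %*% beta[idx, , drop = FALSE]
    if (identical(l, "all")) {
      .frob2(con)
    } else {
      d <- svd(con, nu = 0, nv = 0)$d
      sum(d[seq_len(min(l, length(d)))]^2)
    }
  }

  ss_observed <- term_ss(X)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  null_ss <- vapply(seq_len(N), function(r) term_ss(X[sample.int(n), ,
                                                      drop = FALSE]), 0)
  structure(
    list(term = term, ss_observed = ss_observed, null_ss = null_ss,
         p = sum(null_ss >= ss_observed) / N,
         N = N, l = l, seed = seed, coding = model$coding),
    class = "asca_permutation"
  )
}

#' Permutation tests for every term of a model
#'
#' Convenience wrapper running [permutation_test()] for each term with an
#' independent permutation stream per term (seed offset by the term's
#' position in the model). Mirrors a per-term p-value table.
#'
#' @inheritParams permutation_test
#' @param terms Term labels to test; defaults to all terms of the model.
#' @return A data.frame with columns `term`, `ss`, `p`.
#' @export
permutation_tests <- function(X, design, model, terms = NULL, N = 1000,
                              l = "all", seed = NULL) {
  if (is.character(model)) model <- model_spec(model)
  if (is.null(terms)) terms <- model$labels
  res <- lapply(seq_along(terms), function(i) {
    permutation_test(X, design, model, terms[i], N = N, l = l,
                     seed = if (is.null(seed)) NULL else seed + i - 1L)
  })
  data.frame(
    term = terms,
    ss = vapply(res, `[[`, 0, "ss_observed"),
    p = vapply(res, `[[`, 0, "p"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' @export
print.asca_permutation <- function(x, ...) {
  cat("Permutation test for term '", x$term, "' (", x$coding,
      " coding)\n", sep = "")
  cat("  SS(f) =", signif(x$ss_observed, 6),
      " N =", x$N, " l =", ifelse(identical(x$l, "all"), "all", x$l), "\n")
  cat("  p(f) =", format(x$p, digits = 4), "\n")
  invisible(x)
}
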