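#' @keywords internal
.frob2 <- function(M) sum(M * M)

.centered_ss <- function(X) {
  .frob2(sweep(X, 2, colMeans(X)))
}

.variance_table <- function(terms, ss, residual_ss, denom, method, coding) {
  # a response with identical rows has zero corrected total: report 0%, not 0/0
  pct_of_total <- function(s) if (denom > 0) 100 * s / denom else 0 * s
  percent <- pct_of_total(ss)
  residual_percent <- pct_of_total(residual_ss)
  table <- data.frame(
    term = c(terms, "residual"),
    ss = c(ss, residual_ss),
    percent = c(percent, residual_percent),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(table = table, total_ss = denom,
         percent_sum = sum(percent) + residual_percent,
         method = method, coding = coding),
    class = "asca_variance"
  )
}

#' Type III percentage of variance
#'
#' Quantifies each term's contribution after all other terms have been
#' accounted for. For every term \eqn{f} the model is refitted without that
#' term (all remaining columns of the coded design matrix are kept, including
#' an interaction whose main effect was dropped) and
#' \deqn{SS(f) = \|\hat E_f\|^2 - \|\hat E\|^2,}
#' the increase in residual sum of squares. Percentages are taken against
#' the corrected total \eqn{\|X - M_0\|^2}, where \eqn{M_0} is the
#' column-mean matrix of the mean model — the same denominator for every
#' coding scheme, so percentages are comparable across schemes. The residual
#' percentage is \eqn{\|\hat E\|^2 / \|X - M_0\|^2 \times 100}.
#'
#' On a balanced design the effect blocks are mutually orthogonal and the
#' percentages (terms plus residual) sum to exactly 100; on unbalanced
#' designs the sum generally differs from 100.
#'
#' @inheritParams asca_decompose
#' @return An object of class `"asca_variance"`: list with `table`
#'   (data.frame `term`, `ss`, `percent`; last row is the residual),
#'   `total_ss`, `percent_sum`, `method = "type3"`, `coding`.
#' @export
type3_percent_variance <- function(X, design, model, allow_deficient = FALSE) {
  if (is.character(model)) model <- model_spec(model)
  X <- .as_response_matrix(X)
  dm <- build_design_matrix(design, model)
  full <- fit_glm(X, dm, allow_deficient = allow_deficient)
  ss_full <- .frob2(full$residual)

  ss <- vapply(model$labels, function(lab) {
    reduced <- dm$values[, -dm$blocks[[lab]], drop = FALSE]
    fit <- .ols(X, reduced, allow_deficient)
    resid <- X - reduced %*% fit$beta
    max(.frob2(resid) - ss_full, 0)  # clamp floating round-off
  }, 0)

  .variance_table(model$labels, ss, ss_full, .centered_ss(X),
                  "type3", model$coding)
}

#' Naive percentage of variance of a decomposition
#'
#' The direct norm-ratio partition used by classical ASCA:
#' \eqn{\%Var_f = \|\mathrm{Con}_f\|^2 / \|X - M_0\|^2 \times 100} with the
#' column-mean matrix \eqn{M_0}. On a balanced design this coincides with
#' the type III partition; on unbalanced designs with non-orthogonal effect
#' matrices the percentages can sum to more than 100 (the classical-ASCA
#' overestimation).
#'
#' @param dec An [asca_decompose()] or [classical_asca_decompose()] result.
#' @return An `"asca_variance"` object (see [type3_percent_variance()]),
#'   with `method = "naive"`.
#' @export
naive_percent_variance <- function(dec) {
  stopifnot(inherits(dec, "asca_decomposition"))
  ss <- vapply(dec$contributions, .frob2, 0)
  .variance_table(names(ss), ss, .frob2(dec$residual),
                  .centered_ss(dec$X), "naive", dec$coding)
}

#' @export
print.asca_variance <- function(x, ...) {
  cat("Percentage of variance (", x$method, ", ", x$coding, " coding)\n",
      sep = "")
  tab <- x$table
  tab$ss <- signif(tab$ss, 6)
  tab$percent <- round(tab$percent, 2)
  print(tab, row.names = FALSE)
  cat("Sum (%):", round(x$percent_sum, 2), "\n")
  invisible(x)
}
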