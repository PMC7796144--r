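#' Build a coded design matrix
#'
#' Translates a factor design and a model specification into the numeric
#' model matrix of the multivariate general linear model. The matrix starts
#' with an intercept column of ones (labelled `M0`) followed by one
#' contiguous column block per term, in model order. A main effect with
#' \eqn{\alpha} levels occupies \eqn{\alpha - 1} columns and a two-way
#' interaction of \eqn{\alpha \times \beta} levels occupies
#' \eqn{(\alpha - 1)(\beta - 1)} columns, under every scheme.
#'
#' Under weighted-effect coding, the column for non-reference level \eqn{q}
#' of a factor holds \eqn{+1} at level \eqn{q}, \eqn{-n_q / n_{\mathrm{ref}}}
#' at the reference (last) level and 0 elsewhere. The interaction column for
#' the pair of non-reference levels \eqn{(p, q)} holds \eqn{+1} in cell
#' \eqn{(p, q)}, \eqn{-n_{p,q}/n_{p,\beta}} in \eqn{(p, \beta)},
#' \eqn{-n_{p,q}/n_{\alpha,q}} in \eqn{(\alpha, q)},
#' \eqn{+n_{p,q}/n_{\alpha,\beta}} in \eqn{(\alpha, \beta)} and 0 elsewhere.
#' Every such column sums to exactly zero over the observations, which keeps
#' all effect columns orthogonal to the intercept even in unbalanced designs.
#' Count ratios are formed from integer cell counts in a single floating
#' division, so printed fractions such as \eqn{-3/4} are reproduced exactly.
#'
#' Dummy and deviation interaction columns are the element-wise products of
#' the corresponding main-effect columns.
#'
#' @param design A [factor_design()].
#' @param model An [model_spec()] object (or a string passed through
#'   `model_spec()` with the default coding).
#' @return An object of class `"asca_design_matrix"`: list with `values`
#'   (n x p numeric matrix), `blocks` (named list mapping term label —
#'   including `"M0"` — to column indices), `coding`, `model`, `design`.
#' @seealso [sub_design_matrix()]
#' @examples
#' fx <- worked_example_fixture("unbalanced7")
#' dm <- build_design_matrix(fx$design, model_spec("A + B + A:B", "weighted"))
#' dm$values  # reproduces the printed weighted-effect matrix
#' @export
build_design_matrix <- function(design, model) {
  stopifnot(inherits(design, "factor_design"))
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "asca_model"))

  used <- unique(unlist(model$terms))
  unknown <- setdiff(used, names(design$factors))
  if (length(unknown)) {
    stop("model names factor(s) absent from the design: ",
         paste(unknown, collapse = ", "))
  }
  for (f in used) {
    cnt <- cell_counts(design, f)
    if (length(cnt) < 2L) {
      stop("factor '", f, "' has a single level and cannot be modelled")
    }
    if (any(cnt == 0L)) {
      stop("factor '", f, "' has empty level(s): ",
           paste(names(cnt)[cnt == 0L], collapse = ", "))
    }
  }

  n <- design$n
  cols <- list(M0 = matrix(1, n, 1, dimnames = list(NULL, "M0")))
  blocks <- list(M0 = 1L)
  p <- 1L

  for (i in seq_along(model$terms)) {
    term <- model$terms[[i]]
    label <- model$labels[i]
    block <- if (length(term) == 1L) {
      .main_effect_columns(design, term, model$coding)
    } else {
      .interaction_columns(design, term, model$coding)
    }
    blocks[[label]] <- p + seq_len(ncol(block))
    p <- p + ncol(block)
    cols[[label]] <- block
  }

  values <- do.call(cbind, cols)
  rownames(values) <- design$obs_ids
  structure(
    list(values = values, blocks = blocks, coding = model$coding,
         model = model, design = design),
    class = "asca_design_matrix"
  )
}

.main_effect_columns <- function(design, factor_name, coding) {
  f <- design$factors[[factor_name]]
  lev <- levels(f)
  alpha <- length(lev)
  ref <- lev[alpha]
  cnt <- cell_counts(design, factor_name)
  out <- matrix(0, design$n, alpha - 1L)
  colnames(out) <- paste0(factor_name, ".", lev[-alpha])
  for (q in seq_len(alpha - 1L)) {
    out[f == lev[q], q] <- 1
    out[f == ref, q] <- switch(coding,
      dummy     = 0,
      deviation = -1,
      weighted  = -cnt[[lev[q]]] / cnt[[ref]]
    )
  }
  out
}

.interaction_columns <- function(design, term, coding) {
  fa <- design$factors[[term[1]]]
  fb <- design$factors[[term[2]]]
  la <- levels(fa); lb <- levels(fb)
  alpha <- length(la); beta <- length(lb)
  ref_a <- la[alpha]; ref_b <- lb[beta]
  nab <- cell_counts(design, term)  # alpha x beta counts
  empty <- which(nab == 0L, arr.ind = TRUE)
  if (nrow(empty)) {
    cell <- paste0(term[1], "=", la[empty[1, 1]], ", ",
                   term[2], "=", lb[empty[1, 2]])
    stop("empty design cell in modelled interaction ",
         paste(term, collapse = ":"), ": ", cell)
  }

  out <- matrix(0, design$n, (alpha - 1L) * (beta - 1L))
  nm <- character(ncol(out))
  k <- 0L
  for (p in seq_len(alpha - 1L)) {
    for (q in seq_len(beta - 1L)) {
      k <- k + 1L
      nm[k] <- paste0(term[1], ".", la[p], ":", term[2], ".", lb[q])
      if (coding %in% c("dummy", "deviation")) {
        a_col <- .main_effect_columns(design, term[1], coding)[, p]
        b_col <- .main_effect_columns(design, term[2], coding)[, q]
        out[, k] <- a_col * b_col
      } else {
        in_cell <- function(a, b) fa == a & fb == b
        out[in_cell(la[p], lb[q]), k] <- 1
        out[in_cell(la[p], ref_b), k] <- -nab[p, q] / nab[p, beta]
        out[in_cell(ref_a, lb[q]), k] <- -nab[p, q] / nab[alpha, q]
        out[in_cell(ref_a, ref_b), k] <- nab[p, q] / nab[alpha, beta]
      }
    }
  }
  colnames(out) <- nm
  out
}

#' Sub-design matrix of a single term
#'
#' Returns a matrix of the same shape as `dm` in which the columns of `term`
#' are retained verbatim and *all* other columns — including the intercept —
#' are set to zero. Multiplying a sub-design matrix by the fitted parameter
#' matrix isolates that term's contribution to the reconstruction.
#'
#' @param dm An [build_design_matrix()] result.
#' @param term A term label present in `dm$blocks` (e.g. `"B"`, `"A:B"`,
#'   or `"M0"` for the intercept).
#' @return An `"asca_design_matrix"` whose `values` have zeros outside the
#'   requested block.
#' @export
sub_design_matrix <- function(dm, term) {
  stopifnot(inherits(dm, "asca_design_matrix"))
  if (!term %in% names(dm$blocks)) {
    stop("unknown term '", term, "'; available: ",
         paste(names(dm$blocks), collapse = ", "))
  }
  values <- dm$values
  keep <- dm$blocks[[term]]
  values[, -keep] <- 0
  out <- dm
  out$values <- values
  out$sub_of <- term
  out
}

#' @export
print.asca_design_matrix <- function(x, ...) {
  cat("Coded design matrix (", x$coding, "): ",
      nrow(x$values), " x ", ncol(x$values), "\n", sep = "")
  cat("Blocks:",
      paste(vapply(names(x$blocks), function(b) {
        paste0(b, " [", length(x$blocks[[b]]), "]")
      }, ""), collapse = ", "), "\n")
  invisible(x)
}
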