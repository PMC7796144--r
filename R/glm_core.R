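#' Fit the multivariate general linear model
#'
#' Ordinary least squares of every response column on the coded design
#' matrix, solved through a QR decomposition (numerically stable; the
#' normal-equation form \eqn{\hat\beta = (D^T D)^{-1} D^T X} is the contract,
#' not the algorithm). The residual matrix is orthogonal to every design
#' column.
#'
#' @param X Numeric response matrix, n observations in rows.
#' @param dm An [build_design_matrix()] result with matching row count.
#' @param allow_deficient If `TRUE`, a rank-deficient design is solved with
#'   the minimum-norm pseudo-inverse instead of raising an error. Off by
#'   default: aliasing is almost always a design mistake.
#' @return List with `beta` (p x m, rownames = design column names),
#'   `fitted` and `residual` (both n x m).
#' @export
fit_glm <- function(X, dm, allow_deficient = FALSE) {
  stopifnot(inherits(dm, "asca_design_matrix"))
  X <- .as_response_matrix(X)
  D <- dm$values
  if (nrow(X) != nrow(D)) {
    stop("response has ", nrow(X), " rows but the design matrix has ", nrow(D))
  }
  fit <- .ols(X, D, allow_deficient)
  list(beta = fit$beta, fitted = D %*% fit$beta,
       residual = X - D %*% fit$beta)
}

.ols <- function(X, D, allow_deficient = FALSE) {
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    if (!allow_deficient) {
      stop("aliased design: the coded design matrix has rank ", qrd$rank,
           " < ", ncol(D), " columns",
           if (nrow(D) < ncol(D)) " (fewer observations than parameters)",
           "; set allow_deficient = TRUE to use a pseudo-inverse")
    }
    s <- svd(D)
    pos <- s$d > max(dim(D)) * .Machine$double.eps * s$d[1]
    beta <- s$v[, pos, drop = FALSE] %*%
      ((t(s$u[, pos, drop = FALSE]) %*% X) / s$d[pos])
  } else {
    beta <- qr.coef(qrd, X)
  }
  rownames(beta) <- colnames(D)
  colnames(beta) <- colnames(X)
  list(beta = beta, qr = qrd)
}

.as_response_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("the response matrix must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  X
}

#' Decompose a response matrix into additive effect matrices (GLM route)
#'
#' The ASCA+/WE-ASCA decomposition: the model matrix is coded according to
#' `model$coding`, the parameter matrix is estimated by least squares, and
#' each term's contribution is isolated through its sub-design matrix,
#' \eqn{\mathrm{Con}_f = D_{/f}\,\hat\beta}. The result satisfies
#' \eqn{X = M_0 + \sum_f \mathrm{Con}_f + \hat E} exactly (up to floating
#' round-off).
#'
#' Under weighted-effect coding the effect matrices are column-centred over
#' the observations and `M0` equals the matrix of response column means;
#' under deviation coding on unbalanced data the fitted intercept differs
#' from the column means, and `M0` is taken from the fitted intercept term.
#'
#' @param X Numeric response matrix (n x m).
#' @param design A [factor_design()].
#' @param model A [model_spec()] (or model string; default coding applies).
#' @param allow_deficient Passed to [fit_glm()].
#' @return An object of class `"asca_decomposition"`: list with `X`, `M0`,
#'   `contributions` (named list of n x m matrices, one per term),
#'   `residual`, `beta`, `coding`, `model`, `design`, `dm`.
#' @examples
#' sim <- simulate_dataset(simulation_spec(
#'   factors = list(A = c("a1", "a2"), B = c("b1", "b2", "b3")),
#'   counts = c(3, 2, 4, 2, 3, 2), model = "A + B", m = 12, seed = 1))
#' dec <- asca_decompose(sim$X, sim$design, model_spec("A + B", "weighted"))
#' range(dec$M0 + Reduce(`+`, dec$contributions) + dec$residual - sim$X)
#' @export
asca_decompose <- function(X, design, model, allow_deficient = FALSE) {
  if (is.character(model)) model <- model_spec(model)
  X <- .as_response_matrix(X)
  dm <- build_design_matrix(design, model)
  fit <- fit_glm(X, dm, allow_deficient = allow_deficient)

  M0 <- dm$values[, dm$blocks$M0, drop = FALSE] %*%
    fit$beta[dm$blocks$M0, , drop = FALSE]
  contributions <- lapply(model$labels, function(lab) {
    idx <- dm$blocks[[lab]]
    con <- dm$values[, idx, drop = FALSE] %*% fit$beta[idx, , drop = FALSE]
    dimnames(con) <- dimnames(X)
    con
  })
  names(contributions) <- model$labels
  dimnames(M0) <- dimnames(X)

  structure(
    list(X = X, M0 = M0, contributions = contributions,
         residual = fit$residual, beta = fit$beta,
         coding = model$coding, model = model, design = design, dm = dm),
    class = "asca_decomposition"
  )
}

#' Classical ASCA decomposition (cell-mean estimator)
#'
#' The original ASCA estimator built from observation means: a main effect's
#' contribution for an observation at level \eqn{p} is the level-\eqn{p}
#' mean minus the grand mean, and a two-way interaction's contribution is
#' cell mean − both level means + grand mean, with all means taken over
#' observations. `M0` is the column-mean matrix. Applied as-is to unbalanced
#' designs, where the resulting effect matrices are generally
#' non-orthogonal and their summed percentages of variance can exceed 100%.
#'
#' @inheritParams asca_decompose
#' @return An `"asca_decomposition"` with `coding = "classical"` and no
#'   `beta`/`dm` elements.
#' @export
classical_asca_decompose <- function(X, design, model) {
  if (is.character(model)) model <- model_spec(model)
  X <- .as_response_matrix(X)
  if (nrow(X) != design$n) {
    stop("response has ", nrow(X), " rows but the design has ", design$n)
  }

  for (f in unique(unlist(model$terms))) {
    cnt <- cell_counts(design, f)
    if (length(cnt) < 2L) stop("factor '", f, "' has a single level")
    if (any(cnt == 0L)) {
      stop("factor '", f, "' has empty level(s): ",
           paste(names(cnt)[cnt == 0L], collapse = ", "))
    }
  }
  n <- nrow(X)
  grand <- colMeans(X)
  grand_mat <- matrix(grand, n, ncol(X), byrow = TRUE)
  M0 <- grand_mat
  dimnames(M0) <- dimnames(X)

  group_mean_rows <- function(g) {
    means <- t(vapply(levels(g),
                      function(l) colMeans(X[g == l, , drop = FALSE]),
                      numeric(ncol(X))))
    means[as.integer(g), , drop = FALSE]
  }
  level_dev <- function(f) {
    group_mean_rows(design$factors[[f]]) - grand_mat
  }
  cell_dev <- function(term) {
    nab <- cell_counts(design, term)
    if (any(nab == 0L)) {
      empty <- which(nab == 0L, arr.ind = TRUE)
      stop("empty design cell in modelled interaction ",
           paste(term, collapse = ":"), ": ",
           term[1], "=", rownames(nab)[empty[1, 1]], ", ",
           term[2], "=", colnames(nab)[empty[1, 2]])
    }
    g <- interaction(design$factors[[term[1]]], design$factors[[term[2]]],
                     drop = TRUE, lex.order = TRUE)
    # cell mean - A level mean - B level mean + grand mean, per observation
    group_mean_rows(g) - level_dev(term[1]) - level_dev(term[2]) - grand_mat
  }

  contributions <- lapply(model$terms, function(term) {
    con <- if (length(term) == 1L) level_dev(term) else cell_dev(term)
    dimnames(con) <- dimnames(X)
    con
  })
  names(contributions) <- model$labels

  residual <- X - M0 - Reduce(`+`, contributions)
  structure(
    list(X = X, M0 = M0, contributions = contributions,
         residual = residual, beta = NULL,
         coding = "classical", model = model, design = design, dm = NULL),
    class = "asca_decomposition"
  )
}

#' @export
print.asca_decomposition <- function(x, ...) {
  cat("ASCA decomposition (", x$coding, " coding)\n", sep = "")
  cat("  X: ", nrow(x$X), " x ", ncol(x$X),
      ";  terms: ", paste(x$model$labels, collapse = " + "), "\n", sep = "")
  denom <- sum(sweep(x$X, 2, colMeans(x$X))^2)
  pct <- vapply(x$contributions, function(con) 100 * sum(con^2) / denom, 0)
  cat("  naive %variance: ",
      paste0(names(pct), " = ", sprintf("%.2f", pct), collapse = ", "),
      "; residual = ", sprintf("%.2f", 100 * sum(x$residual^2) / denom),
      "\n", sep = "")
  invisible(x)
}
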