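#' PCA sub-model of a single effect matrix
#'
#' Scores and loadings of one effect matrix, obtained from its singular
#' value decomposition. The matrix is *not* re-centred: effect matrices of
#' weighted-effect fits are column-centred by construction, while deviation
#' coding on unbalanced data can leave a nonzero column mean — in that case
#' the sub-model describes the effect matrix as estimated, not a recentred
#' version of it.
#'
#' Each loading vector's largest-magnitude entry is made positive, so scores
#' are reproducible across runs and platforms. Components beyond the rank of
#' the matrix are returned with zero explained variance and flagged.
#'
#' @param con An n x m effect matrix (one element of
#'   `asca_decompose()$contributions`).
#' @param k Number of components to retain; defaults to the numerical rank.
#' @param term Optional term label carried along for printing.
#' @return An object of class `"asca_submodel"`: list with `term`, `scores`
#'   (n x k), `loadings` (m x k, orthonormal), `explained` (percent of
#'   \eqn{\|\mathrm{Con}\|^2} per component, non-increasing), `k`, `rank`,
#'   `total_ss`, `zero_variance` (logical per component).
#' @export
fit_effect_submodel <- function(con, k = NULL, term = NULL) {
  con <- as.matrix(con)
  s <- svd(con)
  tol <- max(dim(con)) * .Machine$double.eps * max(s$d[1], 0)
  rank <- sum(s$d > tol)
  if (is.null(k)) k <- max(rank, 1L)
  k <- as.integer(k)
  if (k < 1L || k > min(dim(con))) {
    stop("k must be between 1 and min(n, m) = ", min(dim(con)))
  }

  d <- s$d[seq_len(k)]
  d[seq_len(k) > rank] <- 0
  loadings <- s$v[, seq_len(k), drop = FALSE]
  scores <- s$u[, seq_len(k), drop = FALSE] %*% diag(d, k, k)
  for (j in seq_len(k)) {
    i_star <- which.max(abs(loadings[, j]))
    if (loadings[i_star, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total <- sum(s$d^2)
  explained <- if (total > 0) 100 * d^2 / total else rep(0, k)
  rownames(scores) <- rownames(con)
  rownames(loadings) <- colnames(con)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))

  structure(
    list(term = term, scores = scores, loadings = loadings,
         explained = explained, k = k, rank = rank, total_ss = total,
         zero_variance = seq_len(k) > rank),
    class = "asca_submodel"
  )
}

#' Sub-model of a term of a decomposition
#'
#' Convenience wrapper around [fit_effect_submodel()] that pulls the effect
#' matrix out of a decomposition and attaches the residual-augmented scores
#' together with the observation grouping implied by the term.
#'
#' @param dec An [asca_decompose()] result.
#' @param term A term label of the model.
#' @param k Components to retain (default 2, the usual score-plot choice).
#' @return An `"asca_submodel"` with extra elements `augmented` (see
#'   [augmented_scores()]) and `groups` (factor of term-level membership).
#' @export
effect_submodel <- function(dec, term, k = 2) {
  stopifnot(inherits(dec, "asca_decomposition"))
  if (!term %in% names(dec$contributions)) {
    stop("term '", term, "' is not part of the decomposition")
  }
  con <- dec$contributions[[term]]
  sm <- fit_effect_submodel(con, k = min(k, min(dim(con))), term = term)
  fs <- dec$model$terms[[match(term, dec$model$labels)]]
  groups <- if (length(fs) == 1L) {
    dec$design$factors[[fs]]
  } else {
    interaction(dec$design$factors[[fs[1]]], dec$design$factors[[fs[2]]],
                drop = TRUE, lex.order = TRUE)
  }
  sm$groups <- groups
  sm$augmented <- augmented_scores(sm, con, dec$residual, groups = groups)
  sm
}

#' Residual-augmented score points
#'
#' Projects the sum of an effect matrix and the residual matrix onto the
#' effect's loadings, giving one point per observation: the effect's score
#' plus the observation's residual variation along the same directions.
#' These are the points drawn in effect score plots, where the per-level
#' means ("bold points") recover the level scores and the per-level
#' covariances sketch the within-level scatter ellipses.
#'
#' @param sm An [fit_effect_submodel()] result.
#' @param con The effect matrix the sub-model was fitted to.
#' @param residual The residual matrix of the same decomposition.
#' @param groups Optional factor of length n; when supplied, per-level mean
#'   points and covariance matrices are returned as well.
#' @return List with `points` (n x k), and — when `groups` is given —
#'   `group_means` (levels x k) and `group_cov` (named list of k x k
#'   matrices).
#' @export
augmented_scores <- function(sm, con, residual, groups = NULL) {
  stopifnot(inherits(sm, "asca_submodel"))
  con <- as.matrix(con); residual <- as.matrix(residual)
  if (!all(dim(con) == dim(residual))) {
    stop("effect and residual matrices must have identical shape")
  }
  if (ncol(con) != nrow(sm$loadings)) {
    stop("matrix has ", ncol(con), " features but the sub-model loadings have ",
         nrow(sm$loadings))
  }
  points <- (con + residual) %*% sm$loadings
  rownames(points) <- rownames(con)
  out <- list(points = points)
  if (!is.null(groups)) {
    groups <- droplevels(as.factor(groups))
    if (length(groups) != nrow(points)) stop("groups length mismatch")
    out$group_means <- t(vapply(levels(groups), function(l) {
      colMeans(points[groups == l, , drop = FALSE])
    }, numeric(ncol(points))))
    out$group_cov <- lapply(levels(groups), function(l) {
      p <- points[groups == l, , drop = FALSE]
      if (nrow(p) > 1) stats::cov(p) else matrix(0, ncol(p), ncol(p))
    })
    names(out$group_cov) <- levels(groups)
  }
  out
}

#' Whole-data PCA summary
#'
#' PCA of the mean-centred response matrix — the "all data" reference column
#' of an explained-variance table. Scheme-independent by construction.
#'
#' @param X Numeric response matrix.
#' @param k Components to report (default 2).
#' @return An `"asca_submodel"` fitted to the column-centred `X`, with
#'   `term = "all data"`.
#' @export
whole_data_pca <- function(X, k = 2) {
  X <- .as_response_matrix(X)
  fit_effect_submodel(sweep(X, 2, colMeans(X)), k = k, term = "all data")
}

#' @export
print.asca_submodel <- function(x, ...) {
  cat("PCA sub-model",
      if (!is.null(x$term)) paste0(" of '", x$term, "'"), ":\n", sep = "")
  cat("  rank ", x$rank, ", retained ", x$k, " component(s)\n", sep = "")
  cat("  explained (% of effect SS): ",
      paste(sprintf("PC%d = %.2f", seq_len(x$k), x$explained),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
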