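#' Construct a factor design
#'
#' A factor design couples an ordered set of observation identifiers with one
#' or more categorical factors, each carrying an explicit ordered level list.
#' The level order matters: the *last* level of each factor acts as the
#' reference level under deviation and weighted-effect coding.
#'
#' @param factors A data.frame (or anything coercible) whose columns are the
#'   categorical factors, one row per observation. Character and factor
#'   columns are accepted.
#' @param obs_ids Optional character vector of observation identifiers. When
#'   omitted, non-trivial rownames of `factors` are used, else
#'   `"obs1" ... "obsn"`.
#' @param levels Optional named list giving an explicit level order for some
#'   or all factors. Factors not named here get their levels in order of
#'   first appearance in the table (not alphabetical).
#'
#' @return An object of class `"factor_design"`: a list with elements
#'   `obs_ids`, `factors` (a data.frame of factor columns with the declared
#'   level order), `levels` (named list) and `n`.
#'
#' @examples
#' d <- factor_design(data.frame(A = c("a1", "a1", "a2"), B = c("b1", "b2", "b1")))
#' cell_counts(d, "A")
#' cell_counts(d, c("A", "B"))
#' @export
factor_design <- function(factors, obs_ids = NULL, levels = NULL) {
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (ncol(factors) < 1L) stop("at least one factor column is required")
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    stop("every factor column must be named")
  }
  n <- nrow(factors)
  if (n < 1L) stop("the design has no observations")

  if (is.null(obs_ids)) {
    rn <- rownames(factors)
    obs_ids <- if (!is.null(rn) && !identical(rn, as.character(seq_len(n)))) {
      rn
    } else {
      paste0("obs", seq_len(n))
    }
  }
  obs_ids <- as.character(obs_ids)
  if (length(obs_ids) != n) stop("obs_ids length does not match the number of rows")
  if (anyDuplicated(obs_ids)) {
    stop("duplicate observation ids: ",
         paste(unique(obs_ids[duplicated(obs_ids)]), collapse = ", "))
  }

  lev <- list()
  for (f in names(factors)) {
    col <- factors[[f]]
    if (anyNA(col)) stop("factor '", f, "' contains missing level assignments")
    col <- as.character(col)
    declared <- if (!is.null(levels) && f %in% names(levels)) {
      as.character(levels[[f]])
    } else {
      unique(col)  # order of first appearance
    }
    if (!all(col %in% declared)) {
      stop("factor '", f, "' has values outside its declared levels: ",
           paste(setdiff(unique(col), declared), collapse = ", "))
    }
    lev[[f]] <- declared
    factors[[f]] <- factor(col, levels = declared)
  }
  rownames(factors) <- obs_ids

  structure(
    list(obs_ids = obs_ids, factors = factors, levels = lev, n = n),
    class = "factor_design"
  )
}

#' Cell counts of a factor design
#'
#' Counts of observations per level (one factor) or per level combination
#' (two factors) — the \eqn{n_{a_p}}, \eqn{n_{b_q}} and \eqn{n_{a_p,b_q}}
#' entering the weighted-effect coding.
#'
#' @param design A [factor_design()].
#' @param term Character vector of one or two factor names.
#' @return A named integer vector (one factor) or an integer matrix
#'   (two factors, first factor in rows).
#' @export
cell_counts <- function(design, term) {
  stopifnot(inherits(design, "factor_design"))
  missing <- setdiff(term, names(design$factors))
  if (length(missing)) {
    stop("unknown factor(s): ", paste(missing, collapse = ", "))
  }
  if (length(term) == 1L) {
    tab <- table(design$factors[[term]])
    stats::setNames(as.integer(tab), names(tab))
  } else if (length(term) == 2L) {
    tab <- table(design$factors[[term[1]]], design$factors[[term[2]]])
    m <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
    m
  } else {
    stop("term must name one or two factors")
  }
}

#' Restrict a design to a subset of observations
#'
#' Rows are selected and empty levels are dropped from every factor (the
#' level order of the surviving levels is preserved). Used internally by
#' [crossvalidate()] when the decomposition is refitted on a training fold.
#'
#' @param design A [factor_design()].
#' @param rows Integer or logical index, or character observation ids.
#' @return A new `factor_design`.
#' @export
subset_design <- function(design, rows) {
  stopifnot(inherits(design, "factor_design"))
  if (is.character(rows)) rows <- match(rows, design$obs_ids)
  fac <- design$factors[rows, , drop = FALSE]
  ids <- design$obs_ids[rows]
  lev <- lapply(names(fac), function(f) {
    keep <- design$levels[[f]] %in% unique(as.character(fac[[f]]))
    design$levels[[f]][keep]
  })
  names(lev) <- names(fac)
  factor_design(data.frame(lapply(fac, as.character),
                           check.names = FALSE, stringsAsFactors = FALSE),
                obs_ids = ids, levels = lev)
}

#' @export
print.factor_design <- function(x, ...) {
  cat("Factor design:", x$n, "observations,",
      ncol(x$factors), "factor(s)\n")
  for (f in names(x$levels)) {
    cnt <- cell_counts(x, f)
    cat("  ", f, ": ",
        paste0(names(cnt), " (", cnt, ")", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
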