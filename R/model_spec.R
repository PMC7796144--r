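#' Specify an ASCA model
#'
#' A model is an ordered list of terms — main effects and two-way
#' interactions — together with a coding scheme for the design matrix.
#' Terms are written in the usual statistical-formula mini-language:
#' `"A + B + A:B"` (a one-sided formula `~ A + B + A:B` is also accepted).
#'
#' Coding schemes:
#' \describe{
#'   \item{`"dummy"`}{0/1 reference coding; a factor with \eqn{\alpha} levels
#'     occupies \eqn{\alpha - 1} columns, the reference (last) level coded as
#'     all zeros.}
#'   \item{`"deviation"`}{sum-to-zero coding as used by ASCA+: 0/1 for the
#'     first \eqn{\alpha - 1} levels and \eqn{-1} for the last level.}
#'   \item{`"weighted"`}{weighted-effect coding (WE-ASCA): the reference
#'     level carries \eqn{-n_q / n_{\mathrm{ref}}} so that every column sums
#'     to zero over the observations even when the design is unbalanced.}
#' }
#'
#' @param terms A formula or a character string such as `"A + B + A:B"`.
#' @param coding One of `"weighted"`, `"deviation"`, `"dummy"`. Partial
#'   matching and the aliases `"we"`, `"weighted-effect"` and `"sum"` are
#'   accepted.
#' @return An object of class `"asca_model"` with elements `terms` (a list of
#'   character vectors of length 1 or 2), `labels` (e.g. `"A:B"`) and
#'   `coding`.
#' @examples
#' model_spec("A + B + A:B", coding = "weighted")
#' @export
model_spec <- function(terms, coding = c("weighted", "deviation", "dummy")) {
  coding <- .match_coding(coding)
  if (inherits(terms, "formula")) {
    terms <- paste(attr(stats::terms(terms), "term.labels"), collapse = " + ")
  }
  if (!is.character(terms) || length(terms) != 1L) {
    stop("terms must be a single string such as \"A + B + A:B\" or a formula")
  }
  pieces <- trimws(strsplit(terms, "+", fixed = TRUE)[[1]])
  pieces <- pieces[nzchar(pieces)]
  if (!length(pieces)) stop("the model has no terms")

  term_list <- lapply(pieces, function(p) {
    fs <- trimws(strsplit(p, ":", fixed = TRUE)[[1]])
    if (any(!nzchar(fs))) stop("malformed term: '", p, "'")
    if (length(fs) > 2L) {
      stop("term '", p, "': interactions of order > 2 are not supported")
    }
    fs
  })
  labels <- vapply(term_list, paste, "", collapse = ":")
  if (anyDuplicated(labels)) {
    stop("duplicate term(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  mains <- unlist(term_list[lengths(term_list) == 1L])
  for (t in term_list[lengths(term_list) == 2L]) {
    absent <- setdiff(t, mains)
    if (length(absent)) {
      stop("interaction ", paste(t, collapse = ":"),
           ": factor(s) ", paste(absent, collapse = ", "),
           " must also appear as main effects")
    }
  }

  structure(list(terms = term_list, labels = labels, coding = coding),
            class = "asca_model")
}

.match_coding <- function(coding) {
  coding <- tolower(coding[1])
  map <- c(weighted = "weighted", "weighted-effect" = "weighted",
           we = "weighted", deviation = "deviation", sum = "deviation",
           dummy = "dummy")
  hit <- pmatch(coding, names(map))
  if (is.na(hit)) {
    stop("unknown coding scheme '", coding,
         "' (use \"weighted\", \"deviation\" or \"dummy\")")
  }
  unname(map[hit])
}

#' @export
print.asca_model <- function(x, ...) {
  cat("ASCA model: ", paste(x$labels, collapse = " + "),
      "  [", x$coding, " coding]\n", sep = "")
  invisible(x)
}
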