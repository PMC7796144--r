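#' Read a response matrix and design table from CSV
#'
#' Both files carry a header and hold the observation identifier in their
#' first column. The response file's remaining columns are numeric features
#' (e.g. wavenumbers); the design file's remaining columns are categorical
#' factor levels. Observation ids must match one-to-one; design rows are
#' re-ordered to the response order, and factor levels are ordered by first
#' appearance unless `levels` overrides them.
#'
#' @param response_path Path to the response CSV.
#' @param design_path Path to the design CSV.
#' @param levels Optional named list of level orders (see [factor_design()]).
#' @return List with `X` (numeric matrix, rownames = ids) and `design`
#'   (a [factor_design()]).
#' @export
read_dataset <- function(response_path, design_path, levels = NULL) {
  resp <- utils::read.csv(response_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  des <- utils::read.csv(design_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(resp) < 2L) stop("response file needs an id column plus features")
  if (ncol(des) < 2L) stop("design file needs an id column plus factors")

  rid <- as.character(resp[[1]])
  did <- as.character(des[[1]])
  if (anyDuplicated(rid)) {
    stop("duplicate observation id(s) in the response file: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  }
  if (anyDuplicated(did)) {
    stop("duplicate observation id(s) in the design file: ",
         paste(unique(did[duplicated(did)]), collapse = ", "))
  }
  only_r <- setdiff(rid, did)
  only_d <- setdiff(did, rid)
  if (length(only_r) || length(only_d)) {
    stop("observation ids do not match one-to-one",
         if (length(only_r)) paste0("; response-only: ",
                                    paste(utils::head(only_r, 5), collapse = ", ")),
         if (length(only_d)) paste0("; design-only: ",
                                    paste(utils::head(only_d, 5), collapse = ", ")))
  }

  vals <- resp[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))) &
                     !is.na(vals[[j]]))[1]
      stop("non-numeric response value in column '", names(vals)[j],
           "', row id '", rid[if (is.na(bad)) 1 else bad], "'")
    }
  }
  X <- as.matrix(vals)
  rownames(X) <- rid

  des <- des[match(rid, did), , drop = FALSE]
  design <- factor_design(des[, -1, drop = FALSE], obs_ids = rid,
                          levels = levels)
  list(X = X, design = design)
}

#' Write a response matrix and design table as CSV
#'
#' Inverse of [read_dataset()]: first column `id`, then features / factors.
#'
#' @param X Numeric response matrix with rownames.
#' @param design A [factor_design()].
#' @param response_path,design_path Output paths.
#' @export
write_dataset <- function(X, design, response_path, design_path) {
  X <- .as_response_matrix(X)
  ids <- if (is.null(rownames(X))) design$obs_ids else rownames(X)
  utils::write.csv(data.frame(id = ids, X, check.names = FALSE),
                   response_path, row.names = FALSE)
  utils::write.csv(
    data.frame(id = design$obs_ids,
               lapply(design$factors, as.character), check.names = FALSE),
    design_path, row.names = FALSE)
  invisible(c(response_path, design_path))
}

#' Write a decomposition to disk
#'
#' One CSV per effect matrix (`M0.csv`, one per term, `residual.csv`) plus
#' a JSON summary holding the coding scheme, the model and the naive
#' percentage-of-variance table.
#'
#' @param dec An [asca_decompose()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_decomposition <- function(dec, dir) {
  stopifnot(inherits(dec, "asca_decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  dump <- function(M, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(data.frame(id = rownames(M), M, check.names = FALSE),
                     p, row.names = FALSE)
    p
  }
  paths <- c(paths, dump(dec$M0, "M0"))
  for (lab in names(dec$contributions)) {
    paths <- c(paths, dump(dec$contributions[[lab]], paste0("Con_", gsub(":", "_", lab))))
  }
  paths <- c(paths, dump(dec$residual, "residual"))

  vp <- naive_percent_variance(dec)
  summary <- list(coding = dec$coding,
                  model = paste(dec$model$labels, collapse = " + "),
                  n = nrow(dec$X), m = ncol(dec$X),
                  percent_variance = vp$table,
                  percent_sum = vp$percent_sum)
  sp <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, sp))
}

#' Write a run manifest
#'
#' Every output directory of the command-line interface carries exactly one
#' manifest recording input paths with content hashes, the model string,
#' coding scheme, seeds and tool version — enough to re-run the command and
#' reproduce all deterministic outputs bit-identically.
#'
#' @param dir Output directory.
#' @param inputs Character vector of input file paths (hashed with MD5).
#' @param params Named list of run parameters (model, coding, seeds, ...).
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, inputs = character(), params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "weasca",
    version = as.character(utils::packageVersion("weasca")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    params = params
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
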