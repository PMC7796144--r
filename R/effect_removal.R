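#' Remove a nuisance effect from a response matrix
#'
#' Subtracts one term's fitted effect matrix from the response,
#' \eqn{X_{\mathrm{corr}} = X - \mathrm{Con}_f}, with the decomposition
#' fitted on `X` itself. The workhorse of effect-removal preprocessing:
#' refitting the same model on the corrected matrix leaves essentially zero
#' variance attributable to the removed term.
#'
#' @inheritParams asca_decompose
#' @param term Label of the term to remove.
#' @return The corrected n x m response matrix.
#' @export
remove_effect <- function(X, design, model, term) {
  if (is.character(model)) model <- model_spec(model)
  if (!term %in% model$labels) {
    stop("term '", term, "' is not in the model")
  }
  dec <- asca_decompose(X, design, model)
  dec$X - dec$contributions[[term]]
}

#' Cross-validation configuration
#'
#' Settings for leave-one-group-out cross-validated classification with
#' optional effect-removal preprocessing of the training folds.
#'
#' @param group Name of the design factor whose levels define the folds
#'   (e.g. the individual/mouse); must have at least two levels.
#' @param label Name of the design factor holding the class labels.
#' @param nuisance_model Model (string or [model_spec()]) used for the
#'   training-fold decomposition; defaults to a weighted-effect main-effect
#'   model of `nuisance_term`.
#' @param nuisance_term Term whose contribution is subtracted from each
#'   training fold; defaults to `group`.
#' @param classifier `"pca-lda"` (linear discriminant on leading principal
#'   components of the training fold) or `"pls-da"` (linear discriminant on
#'   supervised partial-least-squares latent variables fitted to one-hot
#'   class targets).
#' @param ncomp Integer grid of component counts to evaluate (default 1:20).
#' @param ridge Ridge added to the pooled within-class covariance of the
#'   discriminant (fraction of its mean diagonal); 0 (default) uses plain
#'   LDA.
#' @param pooled If `TRUE`, sensitivities are also computed from the
#'   confusion matrix pooled over folds.
#' @param seed Optional integer recorded with the result (all steps are
#'   deterministic; the seed is kept for manifest completeness).
#' @return An object of class `"asca_cv_config"`.
#' @export
cv_config <- function(group, label, nuisance_model = NULL,
                      nuisance_term = group,
                      classifier = c("pca-lda", "pls-da"),
                      ncomp = 1:20, ridge = 0, pooled = FALSE, seed = NULL) {
  classifier <- match.arg(classifier)
  if (is.null(nuisance_model)) nuisance_model <- model_spec(nuisance_term, "weighted")
  if (is.character(nuisance_model)) nuisance_model <- model_spec(nuisance_model)
  if (!nuisance_term %in% nuisance_model$labels) {
    stop("nuisance_term '", nuisance_term, "' is not in the nuisance model")
  }
  ncomp <- sort(unique(as.integer(ncomp)))
  if (any(ncomp < 1L)) stop("ncomp must be positive")
  structure(
    list(group = group, label = label, nuisance_model = nuisance_model,
         nuisance_term = nuisance_term, classifier = classifier,
         ncomp = ncomp, ridge = ridge, pooled = pooled, seed = seed),
    class = "asca_cv_config"
  )
}

#' Leave-one-group-out cross-validated classification
#'
#' For every level of the grouping factor, all of its observations are held
#' out, the nuisance decomposition is fitted on the remaining (training)
#' rows only, and two classifiers are trained per component count: one on
#' the corrected training matrix (`corrected` arm, nuisance effect
#' subtracted) and one on the raw training matrix (`uncorrected` arm). The
#' held-out rows are never corrected — a new group's nuisance effect is
#' unobservable — and are predicted by both arms.
#'
#' "Mean sensitivity" is the unweighted mean of per-class recalls over the
#' classes present in a fold's test set; the reported band is the standard
#' deviation of fold sensitivities. A pooled-confusion alternative is
#' available via `cv_config(pooled = TRUE)`.
#'
#' All statistics a classifier uses (centering, principal directions,
#' latent variables, discriminants) are computed from training rows only.
#'
#' @param X Numeric response matrix.
#' @param design A [factor_design()] containing the grouping and label
#'   factors.
#' @param cfg An [cv_config()].
#' @return An object of class `"asca_cv"`: list with `curve` (data.frame
#'   `arm`, `ncomp`, `mean_sensitivity`, `sd_sensitivity`), `per_fold`
#'   (fold-level sensitivities), `predictions` (one row per observation,
#'   arm and component count), `pooled` (optional pooled-confusion curve),
#'   `folds`, `config`.
#' @export
crossvalidate <- function(X, design, cfg) {
  stopifnot(inherits(cfg, "asca_cv_config"), inherits(design, "factor_design"))
  X <- .as_response_matrix(X)
  if (nrow(X) != design$n) stop("response/design row mismatch")
  for (nm in c(cfg$group, cfg$label)) {
    if (!nm %in% names(design$factors)) stop("design lacks factor '", nm, "'")
  }
  grp <- design$factors[[cfg$group]]
  lab <- design$factors[[cfg$label]]
  folds <- levels(droplevels(grp))
  if (length(folds) < 2L) stop("the grouping factor needs at least 2 levels")
  classes <- levels(droplevels(lab))

  for (g in folds) {
    tr_classes <- unique(as.character(lab[grp != g]))
    lost <- setdiff(classes, tr_classes)
    if (length(lost)) {
      stop("fold '", g, "': training set loses class(es) ",
           paste(lost, collapse = ", "))
    }
  }

  kmax_req <- max(cfg$ncomp)
  pred_rows <- list()
  for (g in folds) {
    te <- which(grp == g)
    tr <- which(grp != g)
    d_tr <- subset_design(design, tr)
    dec <- asca_decompose(X[tr, , drop = FALSE], d_tr, cfg$nuisance_model)
    arms <- list(
      corrected = dec$X - dec$contributions[[cfg$nuisance_term]],
      uncorrected = X[tr, , drop = FALSE]
    )
    y_tr <- droplevels(lab[tr])
    for (arm in names(arms)) {
      scores <- .latent_scores(arms[[arm]], y_tr, X[te, , drop = FALSE],
                               kmax_req, cfg$classifier)
      for (k in cfg$ncomp[cfg$ncomp <= ncol(scores$train)]) {
        pred <- .lda_predict(scores$train[, seq_len(k), drop = FALSE], y_tr,
                             scores$test[, seq_len(k), drop = FALSE],
                             ridge = cfg$ridge)
        pred_rows[[length(pred_rows) + 1L]] <- data.frame(
          obs = design$obs_ids[te], fold = g, arm = arm, ncomp = k,
          truth = as.character(lab[te]), predicted = as.character(pred),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  predictions <- do.call(rbind, pred_rows)

  sens <- function(truth, predicted) {
    present <- unique(truth)
    mean(vapply(present, function(cl) {
      mean(predicted[truth == cl] == cl)
    }, 0))
  }
  per_fold <- do.call(rbind, lapply(split(
    predictions, predictions[c("arm", "ncomp", "fold")], drop = TRUE),
    function(d) data.frame(arm = d$arm[1], ncomp = d$ncomp[1], fold = d$fold[1],
                           sensitivity = sens(d$truth, d$predicted),
                           stringsAsFactors = FALSE)))
  rownames(per_fold) <- NULL
  curve <- do.call(rbind, lapply(split(
    per_fold, per_fold[c("arm", "ncomp")], drop = TRUE),
    function(d) data.frame(arm = d$arm[1], ncomp = d$ncomp[1],
                           mean_sensitivity = mean(d$sensitivity),
                           sd_sensitivity = stats::sd(d$sensitivity),
                           stringsAsFactors = FALSE)))
  curve <- curve[order(curve$arm, curve$ncomp), ]
  rownames(curve) <- NULL

  pooled <- NULL
  if (isTRUE(cfg$pooled)) {
    pooled <- do.call(rbind, lapply(split(
      predictions, predictions[c("arm", "ncomp")], drop = TRUE),
      function(d) data.frame(arm = d$arm[1], ncomp = d$ncomp[1],
                             mean_sensitivity = sens(d$truth, d$predicted),
                             stringsAsFactors = FALSE)))
    rownames(pooled) <- NULL
  }

  structure(
    list(curve = curve, per_fold = per_fold, predictions = predictions,
         pooled = pooled, folds = folds, config = cfg),
    class = "asca_cv"
  )
}

# Latent representations for the two classifier families. Everything is
# computed from training rows; test rows are only projected.
.latent_scores <- function(Xtr, ytr, Xte, kmax, classifier) {
  mu <- colMeans(Xtr)
  Xtr_c <- sweep(Xtr, 2, mu)
  Xte_c <- sweep(Xte, 2, mu)
  if (classifier == "pca-lda") {
    s <- svd(Xtr_c)
    tol <- max(dim(Xtr_c)) * .Machine$double.eps * max(s$d[1], 0)
    feasible <- sum(s$d > tol)
    if (kmax > feasible) {
      warning("component count truncated to the training-fold rank (",
              feasible, ")")
      kmax <- feasible
    }
    V <- s$v[, seq_len(kmax), drop = FALSE]
    list(train = Xtr_c %*% V, test = Xte_c %*% V)
  } else {
    if (!requireNamespace("mixOmics", quietly = TRUE)) {
      stop("the pls-da classifier requires the mixOmics package")
    }
    Y <- stats::model.matrix(~ ytr - 1)
    feasible <- min(nrow(Xtr) - 1L, ncol(Xtr))
    if (kmax > feasible) {
      warning("component count truncated to the feasible PLS rank (",
              feasible, ")")
      kmax <- feasible
    }
    colnames(Xtr) <- colnames(Xte) <- colnames(Xtr, do.NULL = FALSE)
    fit <- mixOmics::pls(Xtr, Y, ncomp = kmax, scale = FALSE,
                         mode = "regression")
    list(train = unname(fit$variates$X),
         test = unname(stats::predict(fit, Xte)$variates))
  }
}

.lda_predict <- function(S_tr, y_tr, S_te, ridge = 0) {
  if (ridge > 0) {
    return(.ridge_lda_predict(S_tr, y_tr, S_te, ridge))
  }
  tryCatch({
    fit <- MASS::lda(S_tr, grouping = y_tr)
    stats::predict(fit, S_te)$class
  }, error = function(e) {
    # degenerate within-class scatter (tiny folds, zero-variance directions):
    # fall back to a minimally ridged discriminant instead of aborting the CV
    .ridge_lda_predict(S_tr, y_tr, S_te, ridge = 1e-8)
  })
}

# Gaussian linear discriminant with a ridged pooled covariance, for
# degenerate within-class scatter that plain LDA rejects.
.ridge_lda_predict <- function(S_tr, y_tr, S_te, ridge) {
  classes <- levels(y_tr)
  k <- ncol(S_tr)
  means <- lapply(classes, function(cl) colMeans(S_tr[y_tr == cl, , drop = FALSE]))
  pooled <- matrix(0, k, k)
  for (i in seq_along(classes)) {
    rows <- S_tr[y_tr == classes[i], , drop = FALSE]
    dev <- sweep(rows, 2, means[[i]])
    pooled <- pooled + crossprod(dev)
  }
  pooled <- pooled / max(nrow(S_tr) - length(classes), 1)
  pooled <- pooled + diag(ridge * mean(diag(pooled)) + 1e-12, k)
  W <- solve(pooled)
  priors <- as.numeric(table(y_tr)[classes]) / length(y_tr)
  disc <- vapply(seq_along(classes), function(i) {
    m <- means[[i]]
    drop(S_te %*% W %*% m) - 0.5 * drop(t(m) %*% W %*% m) + log(priors[i])
  }, numeric(nrow(S_te)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = nrow(S_te))
  factor(classes[max.col(disc)], levels = classes)
}

#' @export
print.asca_cv <- function(x, ...) {
  cat("Leave-one-group-out CV (", x$config$classifier, "), ",
      length(x$folds), " folds\n", sep = "")
  for (arm in unique(x$curve$arm)) {
    d <- x$curve[x$curve$arm == arm, ]
    best <- d[which.max(d$mean_sensitivity), ]
    cat(sprintf("  %-11s max mean sensitivity %.3f at %d component(s)\n",
                paste0(arm, ":"), best$mean_sensitivity, best$ncomp))
  }
  invisible(x)
}
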