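# Small two-class, multi-group data set with an individual-like nuisance
# factor: every group contributes one observation per class.
nuisance_sim <- function(n_groups = 8, nuisance_size = 5, class_size = 1,
                         noise_sd = 0.5, m = 30, seed = NULL) {
  simulate_dataset(simulation_spec(
    factors = list(class = c("c1", "c2"),
                   indiv = paste0("g", seq_len(n_groups))),
    counts = 1, model = "class + indiv",
    effect_size = c(class = class_size, indiv = nuisance_size),
    m = m, noise_sd = noise_sd, seed = seed))
}

test_that("removing a term with zero true effect leaves X unchanged", {
  sim <- simulate_dataset(simulation_spec(
    factors = list(A = c("a1", "a2"), B = c("b1", "b2")),
    counts = c(3, 4, 2, 3), model = "A + B",
    effect_size = c(A = 1, B = 1), m = 10, noise_sd = 0.5, seed = 5))
  # a decomposition whose B effect is exactly zero: build X without B
  X0 <- sim$X - sim$truth$contributions$B
  Xc <- remove_effect(X0, sim$design, model_spec("A + B", "weighted"), "B")
  # the *fitted* B effect absorbs a little noise, so allow a small departure
  expect_lt(norm(Xc - X0, "F") / norm(X0, "F"), 0.15)
  # with zero noise the corrected matrix is exactly X
  sim0 <- simulate_dataset(simulation_spec(
    factors = list(A = c("a1", "a2"), B = c("b1", "b2")),
    counts = c(3, 4, 2, 3), model = "A + B",
    effect_size = c(A = 1, B = 0), m = 10, noise_sd = 0, seed = 5))
  Xc0 <- remove_effect(sim0$X, sim0$design, model_spec("A + B", "weighted"), "B")
  expect_lt(max(abs(Xc0 - sim0$X)), 1e-8)
})

test_that("refitting after removal leaves ~zero variance for the removed term", {
  sim <- nuisance_sim(n_groups = 6, seed = 31)
  model <- model_spec("class + indiv", "weighted")
  Xc <- remove_effect(sim$X, sim$design, model, "indiv")
  vp <- type3_percent_variance(Xc, sim$design, model)
  expect_lt(vp$table$percent[vp$table$term == "indiv"], 1e-6)
  vp_naive <- naive_percent_variance(asca_decompose(Xc, sim$design, model))
  expect_lt(vp_naive$table$percent[vp_naive$table$term == "indiv"], 1e-6)
})

test_that("removal shrinks the spread of per-class mean spectra across groups", {
  sim <- nuisance_sim(n_groups = 10, nuisance_size = 5, seed = 77)
  model <- model_spec("class + indiv", "weighted")
  Xc <- remove_effect(sim$X, sim$design, model, "indiv")
  spread <- function(X) {
    # sd across groups of the group-mean rows, averaged over features
    g <- sim$design$factors$indiv
    gm <- t(vapply(levels(g), function(l) colMeans(X[g == l, , drop = FALSE]),
                   numeric(ncol(X))))
    mean(apply(gm, 2, sd))
  }
  expect_lt(spread(Xc), spread(sim$X))
})

test_that("cross-validation folds partition the observations", {
  sim <- nuisance_sim(n_groups = 5, seed = 2)
  cfg <- cv_config(group = "indiv", label = "class", ncomp = 1:3)
  res <- crossvalidate(sim$X, sim$design, cfg)
  expect_identical(res$folds, paste0("g", 1:5))
  for (arm in c("corrected", "uncorrected")) {
    for (k in 1:3) {
      pred <- res$predictions[res$predictions$arm == arm &
                                res$predictions$ncomp == k, ]
      expect_setequal(pred$obs, sim$design$obs_ids)
      expect_identical(anyDuplicated(pred$obs), 0L)
    }
  }
  expect_true(all(res$per_fold$sensitivity >= 0 &
                    res$per_fold$sensitivity <= 1))
})

test_that("perfectly separable classes reach sensitivity 1 in both arms", {
  sim <- nuisance_sim(n_groups = 6, nuisance_size = 0.2, class_size = 8,
                      noise_sd = 0.05, seed = 13)
  cfg <- cv_config(group = "indiv", label = "class", ncomp = 1:2)
  res <- crossvalidate(sim$X, sim$design, cfg)
  best <- tapply(res$curve$mean_sensitivity, res$curve$arm, max)
  expect_identical(unname(best["corrected"]), 1)
  expect_identical(unname(best["uncorrected"]), 1)
})

test_that("a fold that loses a class is rejected with the fold named", {
  design <- factor_design(data.frame(
    class = c("c1", "c1", "c1", "c2", "c2"),
    indiv = c("g1", "g2", "g2", "g3", "g3")))
  X <- matrix(rnorm(5 * 6), 5, 6)
  cfg <- cv_config(group = "indiv", label = "class", ncomp = 1)
  expect_error(crossvalidate(X, design, cfg), "fold 'g3'.*c2")
})

test_that("no information leaks from test rows into training-side quantities", {
  set.seed(10)
  Xtr <- matrix(rnorm(20 * 8), 20, 8)
  ytr <- factor(rep(c("c1", "c2"), 10))
  Xte <- matrix(rnorm(4 * 8), 4, 8)
  Xte_garbled <- matrix(rnorm(4 * 8, sd = 100), 4, 8)
  for (clf in c("pca-lda", if (requireNamespace("mixOmics", quietly = TRUE)) "pls-da")) {
    s1 <- weasca:::.latent_scores(Xtr, ytr, Xte, 3, clf)
    s2 <- weasca:::.latent_scores(Xtr, ytr, Xte_garbled, 3, clf)
    expect_identical(s1$train, s2$train)
    # and the discriminant trained on those scores predicts identically
    fixed_te <- matrix(rnorm(2 * 3), 2, 3)
    expect_identical(weasca:::.lda_predict(s1$train, ytr, fixed_te),
                     weasca:::.lda_predict(s2$train, ytr, fixed_te))
  }
})

test_that("cross-validation results are reproducible", {
  sim <- nuisance_sim(n_groups = 4, seed = 3)
  cfg <- cv_config(group = "indiv", label = "class", ncomp = 1:2, seed = 1)
  expect_identical(crossvalidate(sim$X, sim$design, cfg)$curve,
                   crossvalidate(sim$X, sim$design, cfg)$curve)
})

test_that("the PLS-DA classifier runs and predicts every observation", {
  skip_if_not_installed("mixOmics")
  sim <- nuisance_sim(n_groups = 4, class_size = 4, seed = 21)
  cfg <- cv_config(group = "indiv", label = "class", classifier = "pls-da",
                   ncomp = 1:2)
  res <- crossvalidate(sim$X, sim$design, cfg)
  expect_setequal(
    res$predictions$obs[res$predictions$arm == "corrected" &
                          res$predictions$ncomp == 2],
    sim$design$obs_ids)
  expect_true(all(res$curve$mean_sensitivity >= 0 &
                    res$curve$mean_sensitivity <= 1))
})

test_that("ridged discriminants handle degenerate within-class scatter", {
  sim <- nuisance_sim(n_groups = 4, seed = 9)
  cfg <- cv_config(group = "indiv", label = "class", ncomp = 1:2, ridge = 0.1)
  res <- crossvalidate(sim$X, sim$design, cfg)
  expect_true(all(!is.na(res$curve$mean_sensitivity)))
})

test_that("component grids beyond the training rank are truncated with a warning", {
  sim <- nuisance_sim(n_groups = 3, m = 4, seed = 8)
  cfg <- cv_config(group = "indiv", label = "class", ncomp = 1:10)
  w <- capture_warnings(res <- crossvalidate(sim$X, sim$design, cfg))
  expect_true(any(grepl("truncated", w)))
  expect_lte(max(res$curve$ncomp), 4)
})

test_that("invalid configurations are rejected early", {
  expect_error(cv_config(group = "g", label = "y", ncomp = 0), "positive")
  expect_error(cv_config(group = "g", label = "y", nuisance_model = "g",
                         nuisance_term = "z"),
               "not in the nuisance model")
  sim <- nuisance_sim(n_groups = 3, seed = 1)
  cfg <- cv_config(group = "nope", label = "class", ncomp = 1)
  expect_error(crossvalidate(sim$X, sim$design, cfg), "lacks factor")
})
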