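test_that("the decomposition reconstructs X under every coding scheme", {
  set.seed(21)
  for (rep in 1:8) {
    design <- random_design(n_factors = 2, max_levels = 4)
    X <- random_response(design, m = 6)
    for (coding in c("dummy", "deviation", "weighted")) {
      dec <- asca_decompose(X, design, model_spec("A + B + A:B", coding))
      recon <- dec$M0 + Reduce(`+`, dec$contributions) + dec$residual
      expect_lt(norm(recon - X, "F") / norm(X, "F"), 1e-8)
    }
    dec_c <- classical_asca_decompose(X, design, model_spec("A + B + A:B"))
    recon <- dec_c$M0 + Reduce(`+`, dec_c$contributions) + dec_c$residual
    expect_lt(norm(recon - X, "F") / norm(X, "F"), 1e-8)
  }
})

test_that("residuals are orthogonal to the design columns", {
  set.seed(5)
  design <- random_design(n_factors = 2, max_levels = 4)
  X <- random_response(design, m = 4)
  dm <- build_design_matrix(design, model_spec("A + B + A:B", "weighted"))
  fit <- fit_glm(X, dm)
  expect_lt(max(abs(crossprod(dm$values, fit$residual))), 1e-8)
  expect_equal(dm$values %*% fit$beta + fit$residual, X, tolerance = 1e-12)
})

test_that("under weighted coding the intercept row equals the column means", {
  set.seed(9)
  for (rep in 1:5) {
    design <- random_design(n_factors = 2, max_levels = 4, max_count = 6)
    X <- random_response(design, m = 5)
    dm <- build_design_matrix(design, model_spec("A + B + A:B", "weighted"))
    fit <- fit_glm(X, dm)
    expect_lt(max(abs(fit$beta["M0", ] - colMeans(X))), 1e-8)
  }
})

test_that("weighted effect matrices are column-centred and cell-constant", {
  set.seed(13)
  design <- random_design(n_factors = 2, max_levels = 4)
  X <- random_response(design, m = 5)
  dec <- asca_decompose(X, design, model_spec("A + B + A:B", "weighted"))
  for (con in dec$contributions) {
    expect_lt(max(abs(colSums(con))), 1e-8)
  }
  # contributions are constant within the cells of their own term
  cell <- interaction(design$factors$A, design$factors$B)
  for (lv in levels(droplevels(cell))) {
    rows <- dec$contributions$`A:B`[cell == lv, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-10)
  }
  for (lv in levels(design$factors$A)) {
    rows <- dec$contributions$A[design$factors$A == lv, , drop = FALSE]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-10)
  }
})

test_that("a one-factor weighted fit recovers group means minus grand mean", {
  set.seed(31)
  design <- factor_design(data.frame(
    A = rep(c("a1", "a2", "a3"), times = c(5, 2, 9))))
  X <- random_response(design, m = 4)
  dec <- asca_decompose(X, design, model_spec("A", "weighted"))
  grand <- colMeans(X)
  for (lv in levels(design$factors$A)) {
    rows <- design$factors$A == lv
    oracle <- colMeans(X[rows, , drop = FALSE]) - grand
    expect_equal(unname(dec$contributions$A[which(rows)[1], ]),
                 unname(oracle), tolerance = 1e-10)
  }
})

test_that("saturated fits of cell-constant data leave zero residual", {
  fx <- worked_example_fixture("unbalanced7")
  cell_values <- matrix(rnorm(6 * 3), 6, 3)
  cell_of <- c(1, 2, 3, 4, 5, 6, 6)  # x6 and x7 share the (a2, b3) cell
  X <- cell_values[cell_of, ]
  rownames(X) <- fx$design$obs_ids
  for (coding in c("dummy", "deviation", "weighted")) {
    dec <- asca_decompose(X, fx$design, model_spec(fx$model, coding))
    expect_lt(max(abs(dec$residual)), 1e-10)
  }
  # classical estimator with one observation per cell: residual is zero too
  dec_c <- classical_asca_decompose(X[1:6, ],
                                    worked_example_fixture("balanced6")$design,
                                    model_spec("A + B + A:B"))
  expect_lt(max(abs(dec_c$residual)), 1e-10)
})

test_that("zero-effect data yields zero contributions everywhere", {
  fx <- worked_example_fixture("unbalanced7")
  X <- matrix(rep(rnorm(4), each = 7), 7, 4)
  rownames(X) <- fx$design$obs_ids
  for (decomp in list(
    asca_decompose(X, fx$design, model_spec(fx$model, "weighted")),
    classical_asca_decompose(X, fx$design, model_spec(fx$model)))) {
    for (con in decomp$contributions) expect_lt(max(abs(con)), 1e-10)
    expect_lt(max(abs(decomp$residual)), 1e-10)
  }
})

test_that("classical ASCA coincides with the GLM estimators when balanced", {
  set.seed(17)
  factors <- list(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  sim <- simulate_dataset(simulation_spec(
    factors = factors, counts = 4, model = "A + B + A:B",
    m = 10, noise_sd = 1, seed = 17))
  dec_c <- classical_asca_decompose(sim$X, sim$design,
                                    model_spec("A + B + A:B"))
  for (coding in c("deviation", "weighted")) {
    dec_g <- asca_decompose(sim$X, sim$design,
                            model_spec("A + B + A:B", coding))
    for (lab in names(dec_c$contributions)) {
      expect_equal(dec_g$contributions[[lab]], dec_c$contributions[[lab]],
                   tolerance = 1e-8)
    }
    expect_equal(dec_g$M0, dec_c$M0, tolerance = 1e-8)
  }
})

test_that("simulated effects are recovered as noise vanishes", {
  # noise at 1% of the effect scale: relative recovery error well under 5%
  sim <- simulate_dataset(simulation_spec(
    factors = list(A = c("a1", "a2", "a3"), B = c("b1", "b2")),
    counts = c(3, 5, 2, 4, 3, 6), model = "A + B",
    effect_size = 1, m = 40, noise_sd = 0.01, seed = 99))
  dec <- asca_decompose(sim$X, sim$design, model_spec("A + B", "weighted"))
  for (lab in c("A", "B")) {
    rel <- norm(dec$contributions[[lab]] - sim$truth$contributions[[lab]], "F") /
      norm(sim$truth$contributions[[lab]], "F")
    expect_lt(rel, 0.05)
  }
})

test_that("aliased designs raise an error unless a pseudo-inverse is allowed", {
  design <- factor_design(data.frame(A = c("a1", "a2"), B = c("b1", "b2")))
  # 2 observations, A and B perfectly aliased
  X <- matrix(rnorm(4), 2, 2)
  expect_error(asca_decompose(X, design, model_spec("A + B", "weighted")),
               "aliased design")
  dec <- asca_decompose(X, design, model_spec("A + B", "weighted"),
                        allow_deficient = TRUE)
  recon <- dec$M0 + Reduce(`+`, dec$contributions) + dec$residual
  expect_equal(unname(recon), unname(X), tolerance = 1e-10)
})

test_that("response/design shape mismatches are rejected", {
  fx <- worked_example_fixture("balanced6")
  X <- matrix(rnorm(10), 5, 2)
  expect_error(asca_decompose(X, fx$design, model_spec(fx$model, "weighted")),
               "5 rows")
  expect_error(classical_asca_decompose(X, fx$design, model_spec(fx$model)),
               "5 rows")
  expect_error(asca_decompose(matrix("a", 6, 2), fx$design,
                              model_spec(fx$model)), "numeric")
})
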