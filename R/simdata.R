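#' Specification of a synthetic spectra-like data set
#'
#' Describes a (possibly unbalanced) full-factorial design and the
#' ground-truth structure of the generated response: a smooth baseline
#' spectrum shared by all observations, one smooth effect profile per model
#' term, and i.i.d. Gaussian noise. Profiles are sums of Gaussian peaks
#' over the feature axis, mimicking the band structure of vibrational
#' spectra without any attempt at real Raman physics (no baselines drifts,
#' no cosmic spikes).
#'
#' Ground-truth effect matrices are built in the column space of the
#' weighted-effect coding of the realized design, so they satisfy the
#' weighted zero-sum constraint per term exactly and are identifiable: at
#' zero noise a weighted-effect decomposition recovers them to machine
#' precision.
#'
#' @param factors Named list of level vectors, e.g.
#'   `list(A = c("a1","a2"), B = c("b1","b2","b3"))`. The given order is the
#'   declared level order (last level = reference).
#' @param counts Observations per cell of the full factorial: a single
#'   integer (balanced) or a vector/array over the cells of
#'   `expand.grid(factors)` (first factor varying fastest).
#' @param model Model terms whose effects are generated, as a string or
#'   [model_spec()]; coding of the generator is always weighted-effect.
#' @param effect_size Effect magnitude per term: single number or named
#'   vector by term label. Magnitude 0 switches a term's effect off.
#' @param m Number of features (default 200).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param n_peaks Number of Gaussian peaks per profile (default 5).
#' @param baseline_size Amplitude of the shared baseline spectrum.
#' @param seed Optional integer seed; the whole data set is a deterministic
#'   function of the spec including the seed.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(factors, counts = 1, model, effect_size = 1,
                            m = 200, noise_sd = 1, n_peaks = 5,
                            baseline_size = 5, seed = NULL) {
  if (is.character(model)) model <- model_spec(model, coding = "weighted")
  stopifnot(is.list(factors), length(factors) >= 1)
  cells <- expand.grid(factors, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  counts <- as.integer(counts)
  if (length(counts) == 1L) counts <- rep(counts, nrow(cells))
  if (length(counts) != nrow(cells)) {
    stop("counts must have one entry per cell of the full factorial (",
         nrow(cells), ")")
  }
  if (any(counts < 0L)) stop("cell counts must be non-negative")
  if (any(counts == 0L) && any(lengths(model$terms) == 2L)) {
    stop("zero-count cell requested while the model contains an interaction")
  }
  if (any(counts == 0L)) {
    # main-effects-only models tolerate empty cells as long as every level
    # keeps at least one observation
    for (f in names(factors)) {
      lv <- tapply(counts, cells[[f]], sum)
      if (any(lv == 0)) stop("factor '", f, "' would lose level(s) ",
                             paste(names(lv)[lv == 0], collapse = ", "))
    }
  }
  if (sum(counts) < 2L) stop("the design needs at least 2 observations")

  es <- effect_size
  if (is.null(names(es))) {
    es <- stats::setNames(rep(es, length.out = length(model$labels)),
                          model$labels)
  } else {
    missing <- setdiff(model$labels, names(es))
    es[missing] <- 0
    es <- es[model$labels]
  }

  structure(
    list(factors = factors, cells = cells, counts = counts, model = model,
         effect_size = es, m = m, noise_sd = noise_sd, n_peaks = n_peaks,
         baseline_size = baseline_size, seed = seed),
    class = "simulation_spec"
  )
}

# smooth sum-of-Gaussian-peaks profile over m features
.peak_profile <- function(m, n_peaks, amplitude = 1) {
  x <- seq_len(m)
  centers <- stats::runif(n_peaks, 1, m)
  widths <- stats::runif(n_peaks, m / 60, m / 12)
  heights <- stats::rnorm(n_peaks)
  prof <- rowSums(vapply(seq_len(n_peaks), function(p) {
    heights[p] * exp(-0.5 * ((x - centers[p]) / widths[p])^2)
  }, numeric(m)))
  amplitude * prof
}

#' Generate a synthetic data set with known ground truth
#'
#' Realizes a [simulation_spec()]: expands the design table, draws the
#' baseline and per-term effect profiles, assembles
#' \eqn{X = M_0 + \sum_f \mathrm{Con}_f + E} and returns response, design
#' and the true decomposition.
#'
#' @param spec A [simulation_spec()].
#' @return List with `X` (n x m), `design` (a [factor_design()]), `truth`
#'   (list `M0`, `contributions`, `residual` — the exact generating
#'   matrices) and `spec`.
#' @examples
#' sim <- simulate_dataset(simulation_spec(
#'   factors = list(A = c("a1", "a2")), counts = c(5, 3),
#'   model = "A", m = 30, noise_sd = 0, seed = 7))
#' dec <- asca_decompose(sim$X, sim$design, model_spec("A", "weighted"))
#' max(abs(dec$contributions$A - sim$truth$contributions$A))  # ~1e-15
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)

  keep <- spec$counts > 0L
  tab <- spec$cells[rep(seq_len(nrow(spec$cells))[keep], spec$counts[keep]), ,
                    drop = FALSE]
  n <- nrow(tab)
  ids <- sprintf("obs%03d", seq_len(n))
  design <- factor_design(tab, obs_ids = ids, levels = spec$factors)

  m <- spec$m
  baseline <- .peak_profile(m, spec$n_peaks, spec$baseline_size)
  features <- sprintf("f%03d", seq_len(m))
  M0 <- matrix(baseline, n, m, byrow = TRUE,
               dimnames = list(ids, features))

  dm <- build_design_matrix(design,
                            model_spec(paste(spec$model$labels, collapse = " + "),
                                       coding = "weighted"))
  contributions <- list()
  for (lab in spec$model$labels) {
    idx <- dm$blocks[[lab]]
    beta <- t(vapply(idx, function(i) {
      .peak_profile(m, spec$n_peaks, spec$effect_size[[lab]])
    }, numeric(m)))
    con <- dm$values[, idx, drop = FALSE] %*% beta
    dimnames(con) <- list(ids, features)
    contributions[[lab]] <- con
  }

  E <- matrix(stats::rnorm(n * m, sd = spec$noise_sd), n, m,
              dimnames = list(ids, features))
  X <- M0 + Reduce(`+`, contributions, accumulate = FALSE) + E

  list(X = X, design = design,
       truth = list(M0 = M0, contributions = contributions, residual = E),
       spec = spec)
}

#' Printed worked-example designs and their coded matrices
#'
#' The two small two-factor crossed designs used throughout the package's
#' tests, together with the exact coded design matrices they must produce:
#' `"balanced6"` — six observations, one per cell of a 2 x 3 design;
#' `"unbalanced7"` — seven observations with a duplicated (a2, b3) cell, so
#' counts are a1:3, a2:4 and b1:2, b2:2, b3:3.
#'
#' The expected matrices carry exact fractional entries (e.g. −3/4 for the
#' weighted a2 rows, −2/3 for b3 rows, +1/2 for the duplicated-cell
#' interaction entries).
#'
#' @param name `"balanced6"` or `"unbalanced7"`.
#' @return List with `design` (a [factor_design()]), `model` (the term
#'   string `"A + B + A:B"`) and `expected`: named list of matrices `D`
#'   (deviation), `D_B` (deviation sub-matrix of B), `BD` (weighted),
#'   `BD_B` (weighted sub-matrix of B).
#' @export
worked_example_fixture <- function(name = c("balanced6", "unbalanced7")) {
  name <- match.arg(name)
  a_of <- function(k) c("a1", "a1", "a1", "a2", "a2", "a2", "a2")[k]
  b_of <- function(k) c("b1", "b2", "b3", "b1", "b2", "b3", "b3")[k]
  rows <- if (name == "balanced6") 1:6 else 1:7
  design <- factor_design(
    data.frame(A = a_of(rows), B = b_of(rows), stringsAsFactors = FALSE),
    obs_ids = paste0("x", rows),
    levels = list(A = c("a1", "a2"), B = c("b1", "b2", "b3"))
  )

  cn <- c("M0", "A.a1", "B.b1", "B.b2", "A.a1:B.b1", "A.a1:B.b2")
  rn <- paste0("x", rows)
  mk <- function(entries) {
    matrix(entries, nrow = length(rows), ncol = 6, byrow = TRUE,
           dimnames = list(rn, cn))
  }

  if (name == "balanced6") {
    D <- mk(c(1,  1,  1,  0,  1,  0,
              1,  1,  0,  1,  0,  1,
              1,  1, -1, -1, -1, -1,
              1, -1,  1,  0, -1,  0,
              1, -1,  0,  1,  0, -1,
              1, -1, -1, -1,  1,  1))
    BD <- D  # balanced: weighted-effect coincides with deviation coding
  } else {
    D <- mk(c(1,  1,  1,  0,  1,  0,
              1,  1,  0,  1,  0,  1,
              1,  1, -1, -1, -1, -1,
              1, -1,  1,  0, -1,  0,
              1, -1,  0,  1,  0, -1,
              1, -1, -1, -1,  1,  1,
              1, -1, -1, -1,  1,  1))
    BD <- mk(c(1,    1,    1,    0,    1,    0,
               1,    1,    0,    1,    0,    1,
               1,    1, -2/3, -2/3, -1/1, -1/1,
               1, -3/4,    1,    0, -1/1,    0,
               1, -3/4,    0,    1,    0, -1/1,
               1, -3/4, -2/3, -2/3,  1/2,  1/2,
               1, -3/4, -2/3, -2/3,  1/2,  1/2))
  }
  zero_but_B <- function(M) {
    out <- M
    out[, c("M0", "A.a1", "A.a1:B.b1", "A.a1:B.b2")] <- 0
    out
  }

  list(design = design, model = "A + B + A:B",
       expected = list(D = D, D_B = zero_but_B(D),
                       BD = BD, BD_B = zero_but_B(BD)))
}
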