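# Shared fixtures and independent oracle implementations used across tests.
# The oracles deliberately take a different computational route from the
# package: coding matrices are assembled per *cell* and expanded through
# indicator matrices, residual sums of squares come from qr residuals on
# explicitly concatenated blocks, and small-n permutation distributions are
# enumerated exhaustively.

# --- random designs ---------------------------------------------------------

random_design <- function(n_factors = 2, max_levels = 4, min_count = 1,
                          max_count = 4) {
  n_levels <- sample(2:max_levels, n_factors, replace = TRUE)
  factors <- lapply(seq_len(n_factors), function(i) {
    paste0(letters[i], seq_len(n_levels[i]))
  })
  names(factors) <- LETTERS[seq_len(n_factors)]
  cells <- expand.grid(factors, stringsAsFactors = FALSE)
  counts <- sample(min_count:max_count, nrow(cells), replace = TRUE)
  tab <- cells[rep(seq_len(nrow(cells)), counts), , drop = FALSE]
  tab <- tab[sample(nrow(tab)), , drop = FALSE]  # shuffle row order
  factor_design(tab, obs_ids = paste0("o", seq_len(nrow(tab))),
                levels = factors)
}

random_response <- function(design, m = 5, sd = 1) {
  matrix(rnorm(design$n * m, sd = sd), design$n, m,
         dimnames = list(design$obs_ids, paste0("v", seq_len(m))))
}

# --- independent weighted-effect coding (cell-level construction) -----------

# indicator matrix of a factor: n x (number of levels)
indicator <- function(f) {
  Z <- outer(as.integer(f), seq_along(levels(f)), `==`) * 1
  colnames(Z) <- levels(f)
  Z
}

# level-by-column coding matrix of a WE main effect, expanded through the
# indicator: a level x (alpha-1) matrix L with L[q, q] = 1,
# L[alpha, q] = -n_q / n_alpha.
oracle_we_main <- function(design, f) {
  fac <- design$factors[[f]]
  cnt <- as.integer(table(fac))
  alpha <- length(cnt)
  L <- diag(1, alpha, alpha - 1)
  L[alpha, ] <- -cnt[-alpha] / cnt[alpha]
  indicator(fac) %*% L
}

# cell-by-column coding matrix of a WE interaction: one row per (p, q) cell
# of the alpha x beta cross, columns over non-reference pairs.
oracle_we_interaction <- function(design, fa_name, fb_name) {
  fa <- design$factors[[fa_name]]
  fb <- design$factors[[fb_name]]
  alpha <- nlevels(fa); beta <- nlevels(fb)
  nab <- table(fa, fb)
  cell <- interaction(fa, fb, lex.order = TRUE)  # levels: a1.b1, a1.b2, ...
  L <- matrix(0, alpha * beta, (alpha - 1) * (beta - 1))
  col <- 0
  for (p in seq_len(alpha - 1)) {
    for (q in seq_len(beta - 1)) {
      col <- col + 1
      cell_row <- function(pp, qq) (pp - 1) * beta + qq
      L[cell_row(p, q), col] <- 1
      L[cell_row(p, beta), col] <- -nab[p, q] / nab[p, beta]
      L[cell_row(alpha, q), col] <- -nab[p, q] / nab[alpha, q]
      L[cell_row(alpha, beta), col] <- nab[p, q] / nab[alpha, beta]
    }
  }
  indicator(cell) %*% L
}

# deviation / dummy analogues via base-R contrasts (contr.sum puts -1 on the
# last level; contr.treatment with base = last level gives reference coding)
oracle_coded_main <- function(design, f, coding) {
  fac <- design$factors[[f]]
  alpha <- nlevels(fac)
  C <- switch(coding,
    deviation = contr.sum(alpha),
    dummy = contr.treatment(alpha, base = alpha),
    weighted = return(oracle_we_main(design, f)))
  indicator(fac) %*% C
}

oracle_coded_block <- function(design, term, coding) {
  if (length(term) == 1) return(oracle_coded_main(design, term, coding))
  if (coding == "weighted") {
    return(oracle_we_interaction(design, term[1], term[2]))
  }
  A <- oracle_coded_main(design, term[1], coding)
  B <- oracle_coded_main(design, term[2], coding)
  out <- matrix(0, design$n, ncol(A) * ncol(B))
  k <- 0
  for (p in seq_len(ncol(A))) {
    for (q in seq_len(ncol(B))) {
      k <- k + 1
      out[, k] <- A[, p] * B[, q]
    }
  }
  out
}

oracle_design_matrix <- function(design, terms, coding) {
  blocks <- lapply(terms, oracle_coded_block, design = design, coding = coding)
  labels <- vapply(terms, paste, "", collapse = ":")
  names(blocks) <- labels
  cbind(`(icpt)` = rep(1, design$n), do.call(cbind, blocks))
}

# residual sum of squares of X on an explicit column set
oracle_rss <- function(X, D) {
  sum(qr.resid(qr(D), X)^2)
}

# brute-force type III %variance: refit with each term's block left out
oracle_type3 <- function(X, design, terms, coding) {
  blocks <- lapply(terms, oracle_coded_block, design = design, coding = coding)
  ones <- matrix(1, design$n, 1)
  full <- oracle_rss(X, do.call(cbind, c(list(ones), blocks)))
  ss <- vapply(seq_along(terms), function(i) {
    reduced <- do.call(cbind, c(list(ones), blocks[-i]))
    oracle_rss(X, reduced) - full
  }, 0)
  denom <- sum(scale(X, scale = FALSE)^2)
  list(percent = 100 * ss / denom, residual_percent = 100 * full / denom)
}

# sequential (type I) sums of squares, for the balanced-agreement check
oracle_type1 <- function(X, design, terms, coding) {
  blocks <- lapply(terms, oracle_coded_block, design = design, coding = coding)
  D <- matrix(1, design$n, 1)
  rss_prev <- oracle_rss(X, D)
  ss <- numeric(length(terms))
  for (i in seq_along(blocks)) {
    D <- cbind(D, blocks[[i]])
    rss_now <- oracle_rss(X, D)
    ss[i] <- rss_prev - rss_now
    rss_prev <- rss_now
  }
  100 * ss / sum(scale(X, scale = FALSE)^2)
}

# --- exhaustive permutations ------------------------------------------------

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
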