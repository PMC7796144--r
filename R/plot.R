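#' Score plot of an effect sub-model
#'
#' Residual-augmented score points coloured by level, with level means
#' ("bold points") and 2-standard-deviation covariance ellipses. A
#' convenience layer over the tested computations in [effect_submodel()];
#' requires ggplot2.
#'
#' @param sm An [effect_submodel()] result (must carry `augmented` and
#'   `groups`).
#' @param components Two component indices to plot (default 1:2).
#' @param n_sd Ellipse radius in standard deviations (default 2).
#' @return A ggplot object.
#' @export
plot_effect_scores <- function(sm, components = 1:2, n_sd = 2) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_effect_scores requires ggplot2")
  }
  stopifnot(inherits(sm, "asca_submodel"), !is.null(sm$augmented))
  i <- components[1]; j <- components[2]
  pts <- data.frame(x = sm$augmented$points[, i],
                    y = sm$augmented$points[, j],
                    group = sm$groups)
  means <- data.frame(x = sm$augmented$group_means[, i],
                      y = sm$augmented$group_means[, j],
                      group = rownames(sm$augmented$group_means))

  theta <- seq(0, 2 * pi, length.out = 90)
  ell <- do.call(rbind, lapply(names(sm$augmented$group_cov), function(g) {
    S <- sm$augmented$group_cov[[g]][components, components, drop = FALSE]
    e <- eigen(S, symmetric = TRUE)
    ax <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2) * n_sd
    mu <- unlist(means[means$group == g, c("x", "y")])
    data.frame(x = mu[1] + ax[1, 1] * cos(theta) + ax[1, 2] * sin(theta),
               y = mu[2] + ax[2, 1] * cos(theta) + ax[2, 2] * sin(theta),
               group = g)
  }))

  lab <- function(idx) {
    sprintf("PC%d (%.1f%%)", idx, sm$explained[idx])
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.6, size = 1.5) +
    ggplot2::geom_path(data = ell, linewidth = 0.4) +
    ggplot2::geom_point(data = means, size = 4, shape = 18) +
    ggplot2::labs(x = lab(i), y = lab(j),
                  title = if (!is.null(sm$term)) {
                    paste("Effect sub-model:", sm$term)
                  },
                  colour = NULL) +
    ggplot2::theme_minimal()
}
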