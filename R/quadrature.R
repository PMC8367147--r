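#' Fixed quadrature grid over the latent trait
#'
#' Equally spaced nodes with standard-normal prior weights renormalized to
#' sum to one. This grid carries both the population prior used for EAP
#' scoring and the integration rule used by the EM calibration; equally
#' spaced rules on rapidly decaying smooth integrands are essentially
#' trapezoidal and converge very quickly, so 61 nodes on [-6, 6] is ample
#' for person-location work (see the fidelity checks in the test suite).
#'
#' @param n_nodes number of nodes (default 61).
#' @param bounds length-2 numeric, latent-trait range in logits.
#' @return an object of class `quad_grid`: list with `nodes` (strictly
#'   increasing numeric) and `weights` (nonnegative, summing to 1).
#' @examples
#' g <- quad_grid()
#' sum(g$weights)        # 1
#' sum(g$nodes * g$weights)  # 0 (symmetric grid)
#' @export
quad_grid <- function(n_nodes = 61L, bounds = c(-6, 6)) {
  stopifnot(length(n_nodes) == 1L, n_nodes >= 2, length(bounds) == 2L,
            is.finite(bounds), bounds[1] < bounds[2])
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)), class = "quad_grid")
}

#' @export
print.quad_grid <- function(x, ...) {
  cat(sprintf("Quadrature grid: %d nodes on [%g, %g], N(0,1) prior weights\n",
              length(x$nodes), min(x$nodes), max(x$nodes)))
  invisible(x)
}

as_quad_grid <- function(grid) {
  if (is.null(grid)) return(quad_grid())
  stopifnot(inherits(grid, "quad_grid"))
  grid
}
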