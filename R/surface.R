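#' Variance components across allele frequencies
#'
#' Holds the genotypic-value parameters of a model fixed and sweeps the
#' allele frequencies, returning one decomposition per grid point. This is
#' the surface behind the classic observation that for a (partially)
#' recessive or epistatic model `V_A / V_G` approaches 1 as the causal
#' allele frequencies approach 0.
#'
#' @param model A model object; its frequencies are ignored and replaced by
#'   the grid.
#' @param resolution Number of grid points per axis (default 99, giving
#'   frequencies 0.01 .. 0.99).
#' @param from,to Frequency range endpoints (open interval defaults 0.01 and
#'   0.99; the boundaries 0 and 1 are legal and give zero variance).
#' @param diagonal For two-locus models, sweep only the diagonal `p = q`
#'   instead of the full `p x q` grid.
#' @return A tibble with columns `p` (and `q` for two-locus models), `M`,
#'   `alpha_A`, `alpha_B`, `V_A`, `V_D`, `V_AA`, `V_AD`, `V_DD`, `V_G`, and
#'   `ratio_A` (`NA`, not 0, wherever `V_G = 0`).
#' @seealso [plot_surface()]
#' @export
#' @examples
#' frequency_surface(single_locus(4, 4, 0.5), resolution = 9)
frequency_surface <- function(model, resolution = 99, from = 0.01,
                              to = 0.99, diagonal = FALSE) {
  stopifnot(resolution >= 2)
  grid_p <- seq(from, to, length.out = resolution)
  if (inherits(model, "single_locus")) {
    rows <- purrr::map(grid_p, function(p) {
      glance(decompose_variance(single_locus(model$a, model$d, p)))
    })
    out <- dplyr::bind_rows(rows)
    out$alpha_B <- NULL
    return(dplyr::bind_cols(tibble::tibble(p = grid_p), out))
  }
  pq <- if (diagonal) {
    tibble::tibble(p = grid_p, q = grid_p)
  } else {
    tidyr::expand_grid(p = grid_p, q = grid_p)
  }
  rows <- purrr::map2(pq$p, pq$q, function(p, q) {
    m <- model
    m$p <- p
    m$q <- q
    glance(decompose_general(m))
  })
  dplyr::bind_cols(pq, dplyr::bind_rows(rows))
}
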