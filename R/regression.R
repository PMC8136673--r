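#' Falconer-style partition table for a single locus
#'
#' Splits each genotype's deviation from the population mean into a breeding
#' value (the fitted value of the frequency-weighted regression of genotypic
#' value on dosage, expressed as deviation from the mean: `alpha (x - 2p)`)
#' and a dominance deviation (the regression residual). Frequency-weighted
#' means of all three columns are zero; the weighted variance of the
#' breeding values is `V_A` and of the dominance deviations `V_D`.
#'
#' @param model A [single_locus()] model with `p` strictly inside (0, 1);
#'   a monomorphic locus has a single genotype and no regression.
#' @return A tibble with one row per genotype: `genotype`, `dosage`,
#'   `frequency`, `value`, `deviation`, `breeding_value`,
#'   `dominance_deviation`.
#' @export
#' @examples
#' partition_table(single_locus(a = 4, d = 4, p = 0.5))
partition_table <- function(model) {
  stopifnot(inherits(model, "single_locus"))
  if (model$p <= 0 || model$p >= 1) {
    stop("Partition table is undefined for a monomorphic locus ",
         "(p must be strictly between 0 and 1).", call. = FALSE)
  }
  p <- model$p
  alpha <- unname(average_effects(model))
  M <- pop_mean(model)
  tb <- tibble::tibble(
    genotype = c("A2A2", "A1A2", "A1A1"),
    dosage = 0:2,
    frequency = unname(hwe_frequencies(p)),
    value = unname(model$values)
  )
  tb <- dplyr::mutate(tb,
    deviation = .data$value - M,
    breeding_value = alpha * (.data$dosage - 2 * p),
    dominance_deviation = .data$deviation - .data$breeding_value
  )
  class(tb) <- c("partition_table", class(tb))
  tb
}

# marginal genotype means at locus A: frequency-weighted average over the
# locus-B genotypes (valid under linkage equilibrium)
marginal_means_A <- function(model) {
  fb <- unname(hwe_frequencies(model$q))
  as.vector(model$values %*% fb)
}

#' Per-background dosage regressions at locus A
#'
#' For each locus-B genotype (the "background"), fits the weighted
#' least-squares line of genotypic value on A1 dosage, weighting by the
#' conditional (HWE at locus A) genotype frequencies; also fits the marginal
#' line over the frequency-weighted marginal genotype means. Under linkage
#' equilibrium the marginal slope equals the average effect `alpha_A`.
#' Epistasis shows up as background-dependent slopes.
#'
#' @param model A `two_locus` model with `p` strictly inside (0, 1).
#' @return A tibble with one row per background plus a marginal row:
#'   `background`, `dosage_B` (`NA` for the marginal row), `intercept`,
#'   `slope`.
#' @seealso [plot_background_regressions()]
#' @export
#' @examples
#' background_regressions(two_locus_aa(4, 4, 4, 0.5, 0.5))
background_regressions <- function(model) {
  stopifnot(inherits(model, "two_locus"))
  if (model$p <= 0 || model$p >= 1) {
    stop("Background regressions need a polymorphic locus A ",
         "(p strictly between 0 and 1).", call. = FALSE)
  }
  w <- unname(hwe_frequencies(model$p))
  x <- 0:2
  wls <- function(y) {
    xb <- sum(w * x)
    slope <- sum(w * (x - xb) * y) / sum(w * (x - xb)^2)
    c(intercept = sum(w * y) - slope * xb, slope = slope)
  }
  fits <- rbind(
    wls(model$values[, 1]),
    wls(model$values[, 2]),
    wls(model$values[, 3]),
    wls(marginal_means_A(model))
  )
  tibble::tibble(
    background = c("B2B2", "B1B2", "B1B1", "marginal"),
    dosage_B = c(0, 1, 2, NA),
    intercept = fits[, "intercept"],
    slope = fits[, "slope"]
  )
}

#' Swap the roles of loci A and B
#'
#' Transposes the genotypic-value table and exchanges the allele
#' frequencies, so locus-B analyses can reuse the locus-A functions.
#'
#' @param model A `two_locus` model.
#' @return A `two_locus` model with loci exchanged.
#' @export
transpose_loci <- function(model) {
  stopifnot(inherits(model, "two_locus"))
  two_locus(t(model$values), p = model$q, q = model$p)
}
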