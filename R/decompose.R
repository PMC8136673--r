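# Orthogonal genetic contrasts and the least-squares variance partition.
#
# The additive score at a locus is the centered dosage (dosage - 2p); its
# weighted variance under HWE is the heterozygosity H = 2p(1-p). The
# dominance score is the heterozygote indicator orthogonalized (weighted
# Gram-Schmidt) against the intercept and the additive score. Interaction
# scores are products of single-locus scores; under HWE x LE all eight are
# mutually weighted-orthogonal, so the partition is unique and
# order-independent.

# single-locus scores under weights w = HWE(p): columns (add, dom)
locus_scores <- function(p) {
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  add <- (0:2) - 2 * p
  het <- c(0, 1, 0)
  het <- het - sum(w * het)
  va <- sum(w * add^2)
  # monomorphic locus: additive score has zero variance, skip the projection
  if (va > 1e-12) het <- het - sum(w * het * add) / va * add
  cbind(add = add, dom = het)
}

#' Orthogonal contrast design for one or two loci
#'
#' Builds the per-genotype predictor scores used by the least-squares
#' partition: additive (centered dosage) and dominance (orthogonalized
#' heterozygote indicator) scores per locus, and for two loci their four
#' pairwise products. Every score has weighted mean zero and, for
#' polymorphic loci under HWE and linkage equilibrium, all pairs are
#' weighted-orthogonal, which makes the variance partition unique.
#'
#' @param p Frequency of allele A1.
#' @param q Frequency of allele B1, or `NULL` for a single-locus design.
#' @return An object of class `contrast_design`: `scores` (genotypes x
#'   predictors matrix), `weights` (genotype frequencies), the frequencies,
#'   and `H_A`/`H_B`, the weighted variances of the additive scores
#'   (heterozygosities `2p(1-p)`).
#' @export
#' @examples
#' contrast_design(0.5, 0.5)
contrast_design <- function(p, q = NULL) {
  p <- check_freq(p, "p")
  sa <- locus_scores(p)
  if (is.null(q)) {
    w <- unname(hwe_frequencies(p))
    scores <- cbind(add_A = sa[, "add"], dom_A = sa[, "dom"])
    H_B <- NULL
  } else {
    q <- check_freq(q, "q")
    sb <- locus_scores(q)
    grid <- expand.grid(iA = 1:3, iB = 1:3)
    w <- as.vector(genotype_frequencies(p, q))
    scores <- cbind(
      add_A = sa[grid$iA, "add"],
      dom_A = sa[grid$iA, "dom"],
      add_B = sb[grid$iB, "add"],
      dom_B = sb[grid$iB, "dom"]
    )
    scores <- cbind(scores,
      add_A_add_B = scores[, "add_A"] * scores[, "add_B"],
      add_A_dom_B = scores[, "add_A"] * scores[, "dom_B"],
      dom_A_add_B = scores[, "dom_A"] * scores[, "add_B"],
      dom_A_dom_B = scores[, "dom_A"] * scores[, "dom_B"]
    )
    H_B <- 2 * q * (1 - q)
  }
  structure(
    list(scores = scores, weights = w, p = p, q = q,
         H_A = 2 * p * (1 - p), H_B = H_B),
    class = "contrast_design"
  )
}

# Project genotypic values onto a contrast design. Returns per-predictor
# coefficients and variance contributions b_k^2 * wvar(s_k); predictors with
# (numerically) zero score variance -- monomorphic loci -- contribute 0.
project_values <- function(values, design) {
  w <- design$weights
  y <- as.vector(values)
  ss <- colSums(w * design$scores^2)       # scores have weighted mean 0
  sy <- colSums(w * design$scores * y)
  b <- ifelse(ss > 1e-12, sy / ss, 0)
  list(coef = b, contribution = b^2 * ss, score_var = ss)
}

new_decomposition <- function(M, alpha_A, alpha_B, comps, V_G, model,
                              method) {
  V_sum <- sum(comps)
  structure(
    list(M = M, alpha_A = alpha_A, alpha_B = alpha_B,
         V_A = comps[["V_A"]], V_D = comps[["V_D"]], V_AA = comps[["V_AA"]],
         V_AD = comps[["V_AD"]], V_DD = comps[["V_DD"]],
         V_G = V_G,
         ratio_A = if (V_G > 0) comps[["V_A"]] / V_G else NA_real_,
         model = model, method = method),
    class = "variance_decomposition"
  )
}

#' Partition the genotypic variance of a genetic model
#'
#' Computes the population mean, average effect(s) of allele substitution,
#' and the orthogonal variance components of a model under Hardy-Weinberg
#' (and, for two loci, linkage) equilibrium:
#' \deqn{V_G = V_A + V_D + V_{AA} + V_{AD} + V_{DD}.}
#'
#' For a [single_locus()] model the closed forms are used:
#' `alpha = a + (1 - 2p) d`, `V_A = 2p(1-p) alpha^2`,
#' `V_D = (2p(1-p) d)^2`. For a [two_locus_aa()] model:
#' `alpha_A = a_A + (2q - 1) a_AB`, `alpha_B = a_B + (2p - 1) a_AB`,
#' `V_A = 2p(1-p) alpha_A^2 + 2q(1-q) alpha_B^2`,
#' `V_AA = 4p(1-p)q(1-q) a_AB^2`, all dominance components zero. Any
#' two-locus table is handled by [decompose_general()], the weighted
#' least-squares projection onto the eight orthogonal contrasts; with
#' `method = "least_squares"` the general route is forced, which must agree
#' with the closed forms.
#'
#' @param model A model from [single_locus()], [two_locus()] or its
#'   constructors.
#' @param method `"auto"` (closed form where one exists), `"closed_form"`,
#'   or `"least_squares"`.
#' @return A `variance_decomposition`: population mean `M`, average effects
#'   `alpha_A`/`alpha_B` (single-locus models report `alpha_A`), components
#'   `V_A`, `V_D`, `V_AA`, `V_AD`, `V_DD`, total `V_G`, and
#'   `ratio_A = V_A / V_G` (`NA` when `V_G = 0`). See [tidy()] / [glance()]
#'   for tabular views.
#' @seealso [decompose_general()], [frequency_surface()]
#' @export
#' @examples
#' decompose_variance(single_locus(a = 4, d = 4, p = 0.1))
#' glance(decompose_variance(duplicate_factor(c = 4, p = 0.5, q = 0.5)))
decompose_variance <- function(model,
                               method = c("auto", "closed_form",
                                          "least_squares")) {
  method <- match.arg(method)
  UseMethod("decompose_variance")
}

#' @export
decompose_variance.single_locus <- function(model,
                                            method = c("auto", "closed_form",
                                                       "least_squares")) {
  method <- match.arg(method)
  if (method == "least_squares") {
    # embed as a table constant in a dummy second locus fixed at q = 0
    tab <- two_locus(matrix(rep(model$values, 3), 3, 3), model$p, 0)
    dec <- decompose_general(tab)
    dec$alpha_B <- NULL
    dec$model <- model
    return(dec)
  }
  p <- model$p
  H <- 2 * p * (1 - p)
  alpha <- model$a + (1 - 2 * p) * model$d
  V_A <- H * alpha^2
  V_D <- (H * model$d)^2
  comps <- c(V_A = V_A, V_D = V_D, V_AA = 0, V_AD = 0, V_DD = 0)
  M <- (2 * p - 1) * model$a + H * model$d
  new_decomposition(M, alpha_A = alpha, alpha_B = NULL, comps,
                    V_G = V_A + V_D, model = model, method = "closed_form")
}

#' @export
decompose_variance.two_locus_aa <- function(model,
                                            method = c("auto", "closed_form",
                                                       "least_squares")) {
  method <- match.arg(method)
  if (method == "least_squares") return(decompose_general(model))
  p <- model$p; q <- model$q
  H_A <- 2 * p * (1 - p); H_B <- 2 * q * (1 - q)
  alpha_A <- model$a_A + (2 * q - 1) * model$a_AB
  alpha_B <- model$a_B + (2 * p - 1) * model$a_AB
  V_A <- H_A * alpha_A^2 + H_B * alpha_B^2
  V_AA <- H_A * H_B * model$a_AB^2
  comps <- c(V_A = V_A, V_D = 0, V_AA = V_AA, V_AD = 0, V_DD = 0)
  M <- model$a_A * (2 * p - 1) + model$a_B * (2 * q - 1) +
    model$a_AB * (1 - 2 * (p + q) + 4 * p * q)
  new_decomposition(M, alpha_A, alpha_B, comps, V_G = V_A + V_AA,
                    model = model, method = "closed_form")
}

#' @export
decompose_variance.two_locus <- function(model,
                                         method = c("auto", "closed_form",
                                                    "least_squares")) {
  method <- match.arg(method)
  if (method == "closed_form") {
    stop("No closed form for a general two-locus table; ",
         "use method = \"least_squares\".", call. = FALSE)
  }
  decompose_general(model)
}

#' General least-squares partition of a two-locus genotypic-value table
#'
#' Projects the nine genotypic values onto the eight orthogonal contrast
#' predictors of [contrast_design()] under the HWE x LE genotype-frequency
#' weights. `V_A` is the summed weighted variance of the two additive fitted
#' parts, `V_D` of the two dominance parts, `V_AA` of the additive-by-
#' additive part, `V_AD` of the two mixed parts, `V_DD` of the dominance-by-
#' dominance part. Because the predictors are weighted-orthogonal the
#' components sum to the frequency-weighted variance of the table. A
#' monomorphic locus (frequency 0 or 1) contributes nothing: every component
#' involving it is 0.
#'
#' @param model A `two_locus` model (any constructor).
#' @return A `variance_decomposition` (see [decompose_variance()]).
#' @export
#' @examples
#' decompose_general(complementary(c = 4, p = 0.5, q = 0.5))
decompose_general <- function(model) {
  stopifnot(inherits(model, "two_locus"))
  design <- contrast_design(model$p, model$q)
  pr <- project_values(model$values, design)
  co <- pr$contribution
  comps <- c(
    V_A = co[["add_A"]] + co[["add_B"]],
    V_D = co[["dom_A"]] + co[["dom_B"]],
    V_AA = co[["add_A_add_B"]],
    V_AD = co[["add_A_dom_B"]] + co[["dom_A_add_B"]],
    V_DD = co[["dom_A_dom_B"]]
  )
  V_G <- wvar(as.vector(model$values), design$weights)
  M <- wmean(as.vector(model$values), design$weights)
  new_decomposition(M, alpha_A = pr$coef[["add_A"]],
                    alpha_B = pr$coef[["add_B"]], comps, V_G,
                    model = model, method = "least_squares")
}

#' Population mean of a genetic model
#'
#' The genotype-frequency-weighted mean of the genotypic values. Closed
#' forms: `(2p - 1) a + 2p(1-p) d` for a single locus;
#' `a_A (2p - 1) + a_B (2q - 1) + a_AB (1 - 2(p + q) + 4pq)` for the
#' additive-by-additive model.
#'
#' @param model A model object.
#' @return The population mean, trait units.
#' @export
#' @examples
#' pop_mean(single_locus(4, 4, 0.5)) # 2
pop_mean <- function(model) {
  if (inherits(model, "single_locus")) {
    (2 * model$p - 1) * model$a + 2 * model$p * (1 - model$p) * model$d
  } else if (inherits(model, "two_locus_aa")) {
    p <- model$p; q <- model$q
    model$a_A * (2 * p - 1) + model$a_B * (2 * q - 1) +
      model$a_AB * (1 - 2 * (p + q) + 4 * p * q)
  } else {
    wmean(as.vector(model$values), as.vector(model_frequencies(model)))
  }
}

#' Average effect(s) of allele substitution
#'
#' The slope of the frequency-weighted least-squares regression of genotypic
#' value on allelic dosage — the quantity a GWAS dosage regression
#' estimates. Single locus: `alpha = a + (1 - 2p) d`. Additive-by-additive
#' model: `alpha_A = a_A + (2q - 1) a_AB`, `alpha_B = a_B + (2p - 1) a_AB`.
#' General tables use the least-squares projection.
#'
#' @param model A model object.
#' @return Named numeric: `alpha` for a single locus, `c(alpha_A, alpha_B)`
#'   for two loci.
#' @export
#' @examples
#' average_effects(single_locus(4, 4, 0.1)) # 7.2
average_effects <- function(model) {
  if (inherits(model, "single_locus")) {
    c(alpha = model$a + (1 - 2 * model$p) * model$d)
  } else if (inherits(model, "two_locus_aa")) {
    c(alpha_A = model$a_A + (2 * model$q - 1) * model$a_AB,
      alpha_B = model$a_B + (2 * model$p - 1) * model$a_AB)
  } else {
    dec <- decompose_general(model)
    c(alpha_A = dec$alpha_A, alpha_B = dec$alpha_B)
  }
}

#' @export
print.variance_decomposition <- function(x, digits = 2, ...) {
  cat("Genotypic variance partition (", x$method, ")\n", sep = "")
  cat("  M =", format(x$M), "\n")
  if (is.null(x$alpha_B)) {
    cat("  alpha =", format(x$alpha_A), "\n")
  } else {
    cat("  alpha_A =", format(x$alpha_A),
        " alpha_B =", format(x$alpha_B), "\n")
  }
  v <- round_half_up(
    c(V_A = x$V_A, V_D = x$V_D, V_AA = x$V_AA, V_AD = x$V_AD,
      V_DD = x$V_DD, V_G = x$V_G), digits)
  print(v)
  cat("  V_A/V_G =",
      if (is.na(x$ratio_A)) "undefined (V_G = 0)"
      else format(round_half_up(x$ratio_A, digits)), "\n")
  invisible(x)
}

#' Tidy a variance decomposition into a component-level tibble
#'
#' @param x A `variance_decomposition`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `variance`, `proportion`
#'   (of `V_G`; `NA` when `V_G = 0`).
#' @method tidy variance_decomposition
#' @export
tidy.variance_decomposition <- function(x, ...) {
  v <- c(V_A = x$V_A, V_D = x$V_D, V_AA = x$V_AA, V_AD = x$V_AD,
         V_DD = x$V_DD)
  tibble::tibble(
    component = names(v),
    variance = unname(v),
    proportion = if (x$V_G > 0) unname(v) / x$V_G else NA_real_
  )
}

#' One-row summary of a variance decomposition
#'
#' @param x A `variance_decomposition`.
#' @param ... Unused.
#' @return A one-row tibble: `M`, `alpha_A`, `alpha_B` (`NA` for a single
#'   locus), the five components, `V_G` and `ratio_A`.
#' @method glance variance_decomposition
#' @export
glance.variance_decomposition <- function(x, ...) {
  tibble::tibble(
    M = x$M,
    alpha_A = x$alpha_A,
    alpha_B = if (is.null(x$alpha_B)) NA_real_ else x$alpha_B,
    V_A = x$V_A, V_D = x$V_D, V_AA = x$V_AA, V_AD = x$V_AD, V_DD = x$V_DD,
    V_G = x$V_G, ratio_A = x$ratio_A
  )
}
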