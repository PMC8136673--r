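#' Simulate a random-mating population under a genetic model
#'
#' Draws individual allelic dosages independently per locus as
#' Binomial(2, allele frequency) — Hardy-Weinberg genotype proportions under
#' panmixia, linkage equilibrium across loci — and phenotypes as the
#' genotypic value plus independent Gaussian environmental noise with
#' variance `V_e`.
#'
#' @param model A model object from [single_locus()] or the two-locus
#'   constructors.
#' @param n Number of individuals (>= 1).
#' @param V_e Environmental variance, trait units squared (>= 0).
#' @param seed Integer seed making every draw reproducible; `NULL` leaves
#'   the RNG state alone.
#' @return An object of class `population_sample` with a tibble `$data`
#'   (`id`, dosage column(s), `genotypic_value`, `phenotype`) plus the
#'   model, `n`, `V_e` and `seed`.
#' @seealso [gwas_regression()], [empirical_components()]
#' @export
#' @examples
#' sample_population(single_locus(4, 4, 0.1), n = 100, V_e = 1, seed = 1)
sample_population <- function(model, n, V_e = 0, seed = NULL) {
  stopifnot(inherits(model, "quantvar_model"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a positive integer.", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.numeric(V_e) || length(V_e) != 1L || !is.finite(V_e) || V_e < 0) {
    stop("`V_e` must be a finite non-negative number.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (inherits(model, "single_locus")) {
    dosage <- stats::rbinom(n, 2, model$p)
    g <- unname(model$values)[dosage + 1]
    data <- tibble::tibble(id = seq_len(n), dosage_A = dosage,
                           genotypic_value = g)
  } else {
    dosage_A <- stats::rbinom(n, 2, model$p)
    dosage_B <- stats::rbinom(n, 2, model$q)
    g <- model$values[cbind(dosage_A + 1, dosage_B + 1)]
    data <- tibble::tibble(id = seq_len(n), dosage_A = dosage_A,
                           dosage_B = dosage_B, genotypic_value = g)
  }
  e <- if (V_e > 0) stats::rnorm(n, 0, sqrt(V_e)) else 0
  data$phenotype <- data$genotypic_value + e
  structure(list(data = data, model = model, n = n, V_e = V_e, seed = seed),
            class = "population_sample")
}

#' @export
print.population_sample <- function(x, ...) {
  cat("<population_sample> n =", x$n, " V_e =", x$V_e,
      if (!is.null(x$seed)) paste(" seed =", x$seed), "\n")
  print(utils::head(x$data, 5))
  invisible(x)
}

sample_dosage <- function(sample, locus = c("A", "B")) {
  locus <- match.arg(locus)
  col <- paste0("dosage_", locus)
  if (!col %in% names(sample$data)) {
    stop("Sample has no locus ", locus, " dosages.", call. = FALSE)
  }
  sample$data[[col]]
}

#' Single-variant GWAS dosage regression
#'
#' Ordinary least squares of individual phenotype on allelic dosage at one
#' locus, `y = mu + beta x + e` — the standard single-SNP GWAS model. The
#' slope estimates the average effect of allele substitution at the locus
#' (which already absorbs dominance and epistatic contributions through the
#' allele frequencies), so `beta` converges to `alpha` as n grows.
#'
#' @param sample A [sample_population()] result.
#' @param locus `"A"` or `"B"`.
#' @return An object of class `gwas_fit`: `beta_hat`, `se`, `intercept`,
#'   `n`, `locus`, and `alpha_theory`, the model's average effect at that
#'   locus. `tidy()` and `glance()` methods are provided.
#' @export
#' @examples
#' s <- sample_population(single_locus(4, 4, 0.1), 5000, V_e = 10, seed = 1)
#' gwas_regression(s)
gwas_regression <- function(sample, locus = c("A", "B")) {
  locus <- match.arg(locus)
  x <- sample_dosage(sample, locus)
  if (length(unique(x)) < 2L) {
    stop("Dosage at locus ", locus, " is monomorphic in this sample; ",
         "the regression slope is undefined.", call. = FALSE)
  }
  fit <- stats::lm(sample$data$phenotype ~ x)
  sm <- summary(fit)$coefficients
  al <- average_effects(sample$model)
  alpha_theory <- if (inherits(sample$model, "single_locus")) {
    al[["alpha"]]
  } else {
    al[[paste0("alpha_", locus)]]
  }
  structure(
    list(beta_hat = unname(sm["x", "Estimate"]),
         se = unname(sm["x", "Std. Error"]),
         intercept = unname(sm["(Intercept)", "Estimate"]),
         n = sample$n, locus = locus, alpha_theory = alpha_theory),
    class = "gwas_fit"
  )
}

#' @export
print.gwas_fit <- function(x, ...) {
  cat("GWAS dosage regression, locus", x$locus, " (n =", x$n, ")\n")
  cat("  beta_hat =", format(x$beta_hat), " se =", format(x$se),
      " alpha (theory) =", format(x$alpha_theory), "\n")
  invisible(x)
}

#' @rdname gwas_regression
#' @param x A `gwas_fit`.
#' @param ... Unused.
#' @method tidy gwas_fit
#' @export
tidy.gwas_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", paste0("dosage_", x$locus)),
    estimate = c(x$intercept, x$beta_hat),
    std.error = c(NA_real_, x$se)
  )
}

#' @rdname gwas_regression
#' @method glance gwas_fit
#' @export
glance.gwas_fit <- function(x, ...) {
  tibble::tibble(locus = x$locus, n = x$n, beta_hat = x$beta_hat,
                 se = x$se, alpha_theory = x$alpha_theory)
}

#' Empirical variance components from individual-level data
#'
#' The estimation counterpart of [decompose_general()]: contrast scores are
#' built from the *sample* allele frequencies (as with real data), then
#' orthogonalized in-sample against the observed genotype-class proportions
#' (weighted Gram-Schmidt in the fixed order additive A, additive B,
#' dominance A, dominance B, then the four products). Phenotypes are
#' regressed on the orthogonalized scores; each component is the variance of
#' its fitted part. By orthogonality the components sum to the variance
#' explained by the saturated genotype-class model, and they converge to the
#' theoretical components as n grows. A locus monomorphic in the sample
#' yields a reduced design and zero for every component involving it.
#'
#' @param sample A two-locus [sample_population()] result.
#' @return A `variance_decomposition` with `method = "empirical"`; `M` is
#'   the sample phenotype mean and the average effects are in-sample
#'   marginal slopes.
#' @export
#' @examples
#' s <- sample_population(duplicate_factor(4, 0.5, 0.5), 2000, seed = 1)
#' empirical_components(s)
empirical_components <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  if (inherits(sample$model, "single_locus")) {
    stop("Empirical components require a two-locus sample.", call. = FALSE)
  }
  dA <- sample$data$dosage_A
  dB <- sample$data$dosage_B
  y <- sample$data$phenotype
  phat <- mean(dA) / 2
  qhat <- mean(dB) / 2

  # class-level sufficient statistics: proportions and mean phenotypes
  cls <- interaction(factor(dA, 0:2), factor(dB, 0:2), drop = FALSE)
  w <- as.vector(table(cls)) / length(y)
  ybar <- as.vector(tapply(y, cls, mean))
  ybar[is.na(ybar)] <- 0 # empty classes carry zero weight

  grid <- expand.grid(iA = 0:2, iB = 0:2)
  raw <- cbind(
    add_A = grid$iA - 2 * phat,
    add_B = grid$iB - 2 * qhat,
    dom_A = as.numeric(grid$iA == 1),
    dom_B = as.numeric(grid$iB == 1)
  )
  raw <- cbind(raw,
    add_A_add_B = raw[, "add_A"] * raw[, "add_B"],
    add_A_dom_B = raw[, "add_A"] * raw[, "dom_B"],
    dom_A_add_B = raw[, "dom_A"] * raw[, "add_B"],
    dom_A_dom_B = raw[, "dom_A"] * raw[, "dom_B"]
  )
  # sequential weighted Gram-Schmidt under observed class proportions
  S <- raw
  for (k in seq_len(ncol(S))) {
    s <- S[, k] - sum(w * S[, k])
    if (k > 1) {
      for (j in seq_len(k - 1)) {
        ss <- sum(w * S[, j]^2)
        if (ss > 1e-12) s <- s - sum(w * s * S[, j]) / ss * S[, j]
      }
    }
    S[, k] <- s
  }
  ss <- colSums(w * S^2)
  b <- ifelse(ss > 1e-12, colSums(w * S * ybar) / ss, 0)
  co <- b^2 * ss
  comps <- c(
    V_A = co[["add_A"]] + co[["add_B"]],
    V_D = co[["dom_A"]] + co[["dom_B"]],
    V_AA = co[["add_A_add_B"]],
    V_AD = co[["add_A_dom_B"]] + co[["dom_A_add_B"]],
    V_DD = co[["dom_A_dom_B"]]
  )
  new_decomposition(M = mean(y), alpha_A = b[["add_A"]],
                    alpha_B = b[["add_B"]], comps,
                    V_G = sum(w * (ybar - sum(w * ybar))^2),
                    model = sample$model, method = "empirical")
}
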