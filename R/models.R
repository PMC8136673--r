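#' Single-locus additive/dominance model
#'
#' A biallelic locus with alleles A1 (frequency `p`) and A2. Genotypic values
#' are assigned `-a`, `d`, `a` to the genotypes A2A2, A1A2, A1A1, i.e. to A1
#' dosages 0, 1, 2. `d` is the dominance deviation of the heterozygote from
#' the homozygote midpoint; `d = 0` is pure additivity, `d = a` complete
#' dominance of A1, `|d| > |a|` overdominance.
#'
#' @param a Half the difference between the two homozygote values
#'   (trait units).
#' @param d Heterozygote value, as deviation from the homozygote midpoint
#'   (trait units).
#' @param p Frequency of the A1 allele, in `[0, 1]`.
#' @return An object of class `single_locus`, with fields `a`, `d`, `p` and
#'   `values` (the genotypic values for dosage 0, 1, 2).
#' @seealso [decompose_variance()], [partition_table()], [two_locus()]
#' @export
#' @examples
#' single_locus(a = 4, d = 4, p = 0.1) # complete dominance of A1
single_locus <- function(a, d, p) {
  a <- check_finite(a, "a")
  d <- check_finite(d, "d")
  p <- check_freq(p, "p")
  structure(
    list(a = a, d = d, p = p,
         values = stats::setNames(c(-a, d, a), 0:2)),
    class = c("single_locus", "quantvar_model")
  )
}

#' General two-locus model from a 3x3 genotypic-value table
#'
#' Two unlinked biallelic loci A and B, in Hardy-Weinberg and linkage
#' equilibrium. `values[i, j]` is the genotypic value of the genotype with
#' `i - 1` copies of A1 and `j - 1` copies of B1 (rows index locus A dosage
#' 0..2, columns locus B dosage 0..2).
#'
#' @param values A finite numeric 3x3 matrix of genotypic values, rows =
#'   A1 dosage 0..2, columns = B1 dosage 0..2.
#' @param p Frequency of allele A1.
#' @param q Frequency of allele B1.
#' @return An object of class `two_locus` with fields `values`, `p`, `q`.
#' @seealso [two_locus_aa()], [duplicate_factor()], [complementary()],
#'   [decompose_variance()]
#' @export
#' @examples
#' two_locus(matrix(c(0, 4, 4, 4, 4, 4, 4, 4, 4), 3, 3), p = 0.5, q = 0.5)
two_locus <- function(values, p, q) {
  p <- check_freq(p, "p")
  q <- check_freq(q, "q")
  values <- as.matrix(values)
  if (!is.numeric(values) || !identical(dim(values), c(3L, 3L)) ||
      any(!is.finite(values))) {
    stop("`values` must be a finite numeric 3x3 matrix ",
         "(rows = A1 dosage 0..2, columns = B1 dosage 0..2).", call. = FALSE)
  }
  dimnames(values) <- list(dosage_A = 0:2, dosage_B = 0:2)
  structure(list(values = values, p = p, q = q),
            class = c("two_locus", "quantvar_model"))
}

#' Two-locus model with additive and additive-by-additive effects
#'
#' The no-dominance epistatic model: the genotypic value at dosage pair
#' `(i, j)` is `a_A (i - 1) + a_B (j - 1) + a_AB (i - 1)(j - 1)`, so the
#' interaction term is `+a_AB` in the double-homozygote corners (0,0) and
#' (2,2), `-a_AB` in the opposing corners, and 0 wherever either locus is
#' heterozygous.
#'
#' @param a_A,a_B Additive effects (half homozygote difference) at loci A
#'   and B (trait units).
#' @param a_AB Additive-by-additive interaction effect (trait units).
#' @param p,q Allele frequencies of A1 and B1.
#' @return A `two_locus` model (subclass `two_locus_aa`) retaining the
#'   parameters `a_A`, `a_B`, `a_AB`.
#' @export
#' @examples
#' two_locus_aa(a_A = 4, a_B = 4, a_AB = 4, p = 0.5, q = 0.5)
two_locus_aa <- function(a_A, a_B, a_AB, p, q) {
  a_A <- check_finite(a_A, "a_A")
  a_B <- check_finite(a_B, "a_B")
  a_AB <- check_finite(a_AB, "a_AB")
  vals <- outer(0:2, 0:2, function(i, j) {
    a_A * (i - 1) + a_B * (j - 1) + a_AB * (i - 1) * (j - 1)
  })
  m <- two_locus(vals, p, q)
  m$a_A <- a_A
  m$a_B <- a_B
  m$a_AB <- a_AB
  class(m) <- c("two_locus_aa", class(m))
  m
}

#' Duplicate-factor epistatic model
#'
#' Classical two-locus duplicate gene action (Shull's shepherd's-purse
#' capsule shape): every genotype has value `c` except the double recessive
#' homozygote A2A2 B2B2, which has value 0. A single dominant allele at
#' either locus is sufficient for the full value.
#'
#' @param c Genotypic value of all non-double-recessive genotypes
#'   (trait units).
#' @param p,q Allele frequencies of A1 and B1.
#' @return A `two_locus` model (subclass `duplicate_factor`).
#' @export
#' @examples
#' decompose_variance(duplicate_factor(c = 4, p = 0.5, q = 0.5))
duplicate_factor <- function(c, p, q) {
  c <- check_finite(c, "c")
  vals <- matrix(c, 3, 3)
  vals[1, 1] <- 0
  m <- two_locus(vals, p, q)
  m$c <- c
  class(m) <- c("duplicate_factor", class(m))
  m
}

#' Complementary epistatic model
#'
#' Classical complementary gene action (Bateson's sweet-pea flower colour):
#' value `c` requires at least one dominant allele at *both* loci; any
#' recessive homozygote at either locus gives value 0.
#'
#' @param c Genotypic value of genotypes carrying A1 and B1 (trait units).
#' @param p,q Allele frequencies of A1 and B1.
#' @return A `two_locus` model (subclass `complementary`).
#' @export
#' @examples
#' decompose_variance(complementary(c = 4, p = 0.5, q = 0.5))
complementary <- function(c, p, q) {
  c <- check_finite(c, "c")
  vals <- outer(0:2, 0:2, function(i, j) ifelse(i >= 1 & j >= 1, c, 0))
  m <- two_locus(vals, p, q)
  m$c <- c
  class(m) <- c("complementary", class(m))
  m
}

#' Hardy-Weinberg genotype frequencies at one locus
#'
#' @param p Frequency of the counted (reference) allele.
#' @return Numeric vector of length 3: frequencies of dosage 0, 1, 2, i.e.
#'   `(1-p)^2`, `2p(1-p)`, `p^2`.
#' @export
#' @examples
#' hwe_frequencies(0.1)
hwe_frequencies <- function(p) {
  p <- check_freq(p, "p")
  stats::setNames(c((1 - p)^2, 2 * p * (1 - p), p^2), 0:2)
}

#' Joint two-locus genotype frequencies under HWE and linkage equilibrium
#'
#' With unlinked loci in linkage equilibrium the joint frequency of a
#' two-locus genotype is the product of its single-locus Hardy-Weinberg
#' frequencies.
#'
#' @param p,q Allele frequencies of A1 and B1.
#' @return A 3x3 matrix of genotype probabilities (rows = A1 dosage,
#'   columns = B1 dosage), summing to 1 with HWE marginals.
#' @export
#' @examples
#' genotype_frequencies(0.5, 0.5)
genotype_frequencies <- function(p, q) {
  f <- outer(hwe_frequencies(p), hwe_frequencies(q))
  dimnames(f) <- list(dosage_A = 0:2, dosage_B = 0:2)
  f
}

# frequencies belonging to a model object
model_frequencies <- function(model) {
  if (inherits(model, "single_locus")) {
    hwe_frequencies(model$p)
  } else {
    genotype_frequencies(model$p, model$q)
  }
}

#' @export
print.quantvar_model <- function(x, ...) {
  if (inherits(x, "single_locus")) {
    cat("<single_locus> a =", x$a, " d =", x$d, " p =", x$p, "\n")
    cat("genotypic values (dosage 0,1,2):", x$values, "\n")
  } else {
    cat("<", class(x)[1], "> p = ", x$p, "  q = ", x$q, "\n", sep = "")
    print(x$values)
  }
  invisible(x)
}

#' Tidy a genetic model into a genotype-level tibble
#'
#' @param x A `single_locus` or `two_locus` model.
#' @param ... Unused.
#' @return A tibble with one row per genotype: dosage column(s), `frequency`
#'   (HWE, and linkage equilibrium for two loci) and genotypic `value`.
#' @method tidy quantvar_model
#' @export
tidy.quantvar_model <- function(x, ...) {
  if (inherits(x, "single_locus")) {
    tibble::tibble(
      dosage = 0:2,
      frequency = unname(hwe_frequencies(x$p)),
      value = unname(x$values)
    )
  } else {
    grid <- tidyr::expand_grid(dosage_A = 0:2, dosage_B = 0:2)
    f <- genotype_frequencies(x$p, x$q)
    dplyr::mutate(grid,
      frequency = f[cbind(.data$dosage_A + 1, .data$dosage_B + 1)],
      value = x$values[cbind(.data$dosage_A + 1, .data$dosage_B + 1)]
    )
  }
}

#' Write a model's genotype table to TSV
#'
#' One row per genotype with dosage, frequency and genotypic value columns
#' (see [tidy.quantvar_model()]).
#'
#' @param model A model object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  utils::write.table(tidy(model), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
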