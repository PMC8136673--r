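# Independent oracles: stats::lm with frequency weights, kept deliberately
# separate from the package's explicit projection arithmetic.

# weighted least-squares slope/intercept of y on x
oracle_wls <- function(y, x, w) {
  fit <- lm(y ~ x, weights = w)
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# full two-locus partition via lm on the eight contrast predictors
oracle_decompose <- function(values, p, q) {
  grid <- expand.grid(dosA = 0:2, dosB = 0:2)
  hw <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)
  w <- hw(p)[grid$dosA + 1] * hw(q)[grid$dosB + 1]
  y <- values[cbind(grid$dosA + 1, grid$dosB + 1)]
  wproj <- function(v, u) {
    uu <- sum(w * u * u)
    if (uu < 1e-12) return(v)
    v - sum(w * v * u) / uu * u
  }
  xA <- grid$dosA - 2 * p
  xB <- grid$dosB - 2 * q
  hA <- wproj(as.numeric(grid$dosA == 1) -
                sum(w * (grid$dosA == 1)), xA)
  hB <- wproj(as.numeric(grid$dosB == 1) -
                sum(w * (grid$dosB == 1)), xB)
  S <- cbind(add_A = xA, add_B = xB, dom_A = hA, dom_B = hB,
             aa = xA * xB, ad = xA * hB, da = hA * xB, dd = hA * hB)
  keep <- colSums(w * S^2) > 1e-12
  df <- data.frame(y = y, S[, keep, drop = FALSE], w = w, check.names = FALSE)
  fit <- lm(y ~ . - w, data = df, weights = w)
  b <- coef(fit)[-1]
  names(b) <- gsub("`", "", names(b))
  contr <- setNames(numeric(ncol(S)), colnames(S))
  for (k in colnames(S)[keep]) {
    contr[k] <- unname(b[k])^2 * sum(w * S[, k]^2)
  }
  mu <- sum(w * y)
  list(M = mu,
       alpha_A = if (keep[["add_A"]]) unname(b["add_A"]) else 0,
       V_A = contr[["add_A"]] + contr[["add_B"]],
       V_D = contr[["dom_A"]] + contr[["dom_B"]],
       V_AA = contr[["aa"]],
       V_AD = contr[["ad"]] + contr[["da"]],
       V_DD = contr[["dd"]],
       V_G = sum(w * (y - mu)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random finite 3x3 genotypic-value table
random_table <- function() matrix(runif(9, -10, 10), 3, 3)

expect_decomp_equal <- function(dec, ref, tol = 1e-9) {
  for (f in c("M", "V_A", "V_D", "V_AA", "V_AD", "V_DD", "V_G")) {
    expect_equal(dec[[f]], ref[[f]], tolerance = tol,
                 ignore_attr = TRUE, label = f)
  }
}
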