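# Many-to-one (Dunnett) equicoordinate probabilities. For comparisons of
# k treatment means against a shared control after ANOVA, the statistics
# T_j = (Ybar_j - Ybar_0) / (S * sqrt(1/n_j + 1/n_0)) are, conditional on
# the control-mean deviate Z0 and the pooled-SD deviate S/sigma,
# independent normals. P(max_j |T_j| <= q) therefore factorizes under the
# integral and is evaluated by deterministic 2-D quadrature:
# Gauss-Hermite in Z0 and Gauss-Legendre in the probability transform of
# the chi distribution of S/sigma. Accuracy is well inside the 1e-3
# contract used for adjusted p-values (k = 1 reproduces the Student-t
# tail to ~1e-8).

.dunnett_cache <- new.env(parent = emptyenv())

gauss_hermite_nodes <- function(n) {
  key <- paste0("gh", n)
  if (is.null(.dunnett_cache[[key]])) {
    # Golub-Welsch: eigen decomposition of the Hermite Jacobi matrix
    J <- matrix(0, n, n)
    off <- sqrt(seq_len(n - 1) / 2)
    J[cbind(1:(n - 1), 2:n)] <- off
    J[cbind(2:n, 1:(n - 1))] <- off
    e <- eigen(J, symmetric = TRUE)
    .dunnett_cache[[key]] <- list(x = e$values,
                                  w = sqrt(pi) * e$vectors[1, ]^2)
  }
  .dunnett_cache[[key]]
}

gauss_legendre01 <- function(n) {
  key <- paste0("gl", n)
  if (is.null(.dunnett_cache[[key]])) {
    J <- matrix(0, n, n)
    i <- seq_len(n - 1)
    off <- i / sqrt(4 * i^2 - 1)
    J[cbind(i, i + 1)] <- off
    J[cbind(i + 1, i)] <- off
    e <- eigen(J, symmetric = TRUE)
    # nodes/weights on [-1, 1], mapped to [0, 1]
    .dunnett_cache[[key]] <- list(x = (e$values + 1) / 2,
                                  w = e$vectors[1, ]^2)
  }
  .dunnett_cache[[key]]
}

#' Dunnett equicoordinate probability
#'
#' `P(max_j |T_j| <= q)` for the two-sided many-to-one comparison of `k`
#' treatment groups (sizes `n_treat`) against a control of size `n0`,
#' with `df` error degrees of freedom. Deterministic quadrature; no
#' Monte Carlo.
#'
#' @param q non-negative quantile.
#' @param n_treat integer vector of treatment group sizes (length k).
#' @param n0 control group size.
#' @param df error degrees of freedom of the pooled variance.
#' @param nz,ns quadrature orders (control deviate / SD deviate).
#' @return probability in `[0, 1]`.
#' @export
pdunnett <- function(q, n_treat, n0, df, nz = 64L, ns = 48L) {
  if (q < 0) stop("q must be >= 0")
  if (q == 0) return(0)
  gh <- gauss_hermite_nodes(nz)
  gl <- gauss_legendre01(ns)
  z <- sqrt(2) * gh$x                       # N(0,1) nodes
  wz <- gh$w / sqrt(pi)
  s <- sqrt(stats::qchisq(gl$x, df) / df)   # chi_df/sqrt(df) nodes
  ws <- gl$w
  zc <- z / sqrt(n0)
  P <- matrix(1, length(s), length(z))
  for (j in seq_along(n_treat)) {
    cj <- q * s * sqrt(1 / n_treat[j] + 1 / n0)   # length ns
    sq <- sqrt(n_treat[j])
    upper <- stats::pnorm(sq * outer(cj, zc, `+`))
    lower <- stats::pnorm(sq * outer(-cj, zc, `+`))
    P <- P * (upper - lower)
  }
  min(max(as.numeric(ws %*% P %*% wz), 0), 1)
}

pooled_anova <- function(values, groups) {
  groups <- factor(groups)
  if (any(!is.finite(values))) stop("values must be finite")
  ns <- tapply(values, groups, length)
  if (any(ns < 2)) stop("every group needs at least 2 observations")
  means <- tapply(values, groups, mean)
  ss <- tapply(values, groups, function(v) sum((v - mean(v))^2))
  df <- length(values) - nlevels(groups)
  list(groups = levels(groups), n = as.numeric(ns),
       means = as.numeric(means), mse = sum(ss) / df, df = df)
}

#' Dunnett many-to-one comparisons against a control
#'
#' One-way ANOVA pooled error followed by two-sided Dunnett-adjusted
#' p-values for every treatment group against `control`. Adjusted
#' p-values are monotone in `|t|` and never below the unadjusted
#' two-sample p.
#'
#' @param values numeric outcome (one value per experimental unit,
#'   typically a well).
#' @param groups condition label per value.
#' @param control the control condition label (e.g. `"NTC"`).
#' @param alpha significance level recorded alongside the stars.
#' @return data frame with one row per treatment condition: `condition`,
#'   `n`, `mean`, `diff` (vs control), `t`, `p_adj`, `stars`.
#' @export
dunnett_vs_control <- function(values, groups, control = "NTC",
                               alpha = 0.05) {
  a <- pooled_anova(values, groups)
  if (!control %in% a$groups)
    stop("control group '", control, "' not present")
  ci <- match(control, a$groups)
  ti <- setdiff(seq_along(a$groups), ci)
  n0 <- a$n[ci]; nt <- a$n[ti]
  se <- sqrt(a$mse * (1 / nt + 1 / n0))
  diff <- a$means[ti] - a$means[ci]
  tval <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- vapply(abs(tval), function(q) {
    if (!is.finite(q)) return(0)
    1 - pdunnett(q, nt, n0, a$df)
  }, numeric(1))
  data.frame(condition = a$groups[ti], n = nt, mean = a$means[ti],
             diff = diff, t = tval, p_adj = p, stars = p_stars(p),
             stringsAsFactors = FALSE)
}

#' Two-factor Dunnett comparisons of treated cells against a control
#'
#' Cell-means formulation of the two-way layout: the error term pools
#' within-cell variation over every observed `(factor_a, factor_b)` cell
#' (full-interaction ANOVA error), and each treated cell is compared
#' against the pooled control cell(s) with Dunnett adjustment over the
#' whole family. With a single-level `factor_a` this reduces to
#' [dunnett_vs_control()].
#'
#' @param values numeric outcome per experimental unit.
#' @param factor_a blocking factor (e.g. SEC fraction).
#' @param factor_b treatment factor containing the control level.
#' @param control control level of `factor_b` (e.g. `"NTC"`).
#' @param alpha significance level recorded alongside the stars.
#' @return data frame with one row per treated cell: `factor_a`,
#'   `factor_b`, `n`, `mean`, `diff`, `t`, `p_adj`, `stars`.
#' @export
two_way_dunnett <- function(values, factor_a, factor_b, control = "NTC",
                            alpha = 0.05) {
  factor_a <- as.character(factor_a); factor_b <- as.character(factor_b)
  if (!any(factor_b == control))
    stop("control level '", control, "' not present in factor_b")
  cell <- paste(factor_a, factor_b, sep = "\r")
  ns <- tapply(values, cell, length)
  if (any(ns < 2)) stop("every cell needs at least 2 observations")
  ss <- tapply(values, cell, function(v) sum((v - mean(v))^2))
  df <- length(values) - length(ns)
  mse <- sum(ss) / df

  is_ctrl <- factor_b == control
  n0 <- sum(is_ctrl)
  mean0 <- mean(values[is_ctrl])
  treated <- sort(unique(cell[!is_ctrl]))
  nt <- as.numeric(ns[treated])
  meant <- as.numeric(tapply(values, cell, mean)[treated])
  se <- sqrt(mse * (1 / nt + 1 / n0))
  diff <- meant - mean0
  tval <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  p <- vapply(abs(tval), function(q) {
    if (!is.finite(q)) return(0)
    1 - pdunnett(q, nt, n0, df)
  }, numeric(1))
  parts <- strsplit(treated, "\r", fixed = TRUE)
  data.frame(factor_a = vapply(parts, `[`, "", 1),
             factor_b = vapply(parts, `[`, "", 2),
             n = nt, mean = meant, diff = diff, t = tval, p_adj = p,
             stars = p_stars(p), stringsAsFactors = FALSE)
}

#' Tukey all-pairs comparisons
#'
#' Studentized-range adjusted p-values for every pair of groups
#' (Tukey-Kramer for unequal sizes). Returns a symmetric matrix with
#' unit diagonal.
#'
#' @param values numeric outcome per experimental unit.
#' @param groups group label per value.
#' @return symmetric matrix of adjusted p-values.
#' @export
tukey_all_pairs <- function(values, groups) {
  a <- pooled_anova(values, groups)
  k <- length(a$groups)
  p <- matrix(1, k, k, dimnames = list(a$groups, a$groups))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(a$mse / 2 * (1 / a$n[i] + 1 / a$n[j]))
    d <- abs(a$means[i] - a$means[j])
    pij <- if (se > 0)
      stats::ptukey(d / se, nmeans = k, df = a$df, lower.tail = FALSE)
    else as.numeric(d > 0) * 0 + ifelse(d > 0, 0, 1)
    p[i, j] <- p[j, i] <- pij
  }
  p
}

#' Significance stars
#'
#' The tiers used in screening figure legends: `****` p <= 0.0001,
#' `**` p <= 0.01, `*` p <= 0.05, otherwise `ns`.
#'
#' @param p numeric vector of (adjusted) p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}
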