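# Inferential chain for subgroup comparison of the vulnerability index K:
# descriptive summaries with t confidence intervals, one-way ANOVA from the
# standard sums of squares, Hochberg's GT2 post hoc procedure built on the
# studentized maximum modulus (SMM) distribution, Hartley's F-max
# homogeneity screen with Monte-Carlo calibration for unequal group sizes,
# and the pooled two-proportion z-test.

# Normalize (x, g) / list-of-groups input into a named list of numeric vectors.
as_group_list <- function(x, g = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    groups <- lapply(x, as.numeric)
    if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  } else {
    if (is.null(g)) stop("supply either a list of groups or values plus 'g'")
    g <- if (is.factor(g)) droplevels(g) else factor(g, levels = unique(g))
    groups <- split(as.numeric(x), g)
  }
  if (any(vapply(groups, anyNA, logical(1)))) stop("missing values in groups")
  groups
}

#' Per-subgroup mean and confidence interval of K
#'
#' Arithmetic mean of K per subgroup with a symmetric Student-t confidence
#' interval, mean +/- t(1-alpha/2, n-1) * sd/sqrt(n).
#'
#' @param x Numeric K values, or a named list of numeric vectors (one per
#'   group, in which case `g` is ignored).
#' @param g Grouping vector aligned with `x`.
#' @param confidence Confidence level (default 0.95).
#' @return Data frame with columns `group_id`, `n`, `k_mean`, `ci_low`,
#'   `ci_high`.
#' @export
subgroup_summary <- function(x, g = NULL, confidence = 0.95) {
  stopifnot(confidence > 0, confidence < 1)
  groups <- as_group_list(x, g)
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(groups)[n < 2], collapse = ", "))
  }
  m <- vapply(groups, mean, numeric(1))
  sdv <- vapply(groups, stats::sd, numeric(1))
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * sdv / sqrt(n)
  data.frame(group_id = names(groups), n = n, k_mean = m,
             ci_low = m - half, ci_high = m + half,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-way analysis of variance
#'
#' Single-factor fixed-effects ANOVA computed from the standard between- and
#' within-group sums of squares; the p-value comes from the upper tail of
#' the F distribution with (g-1, N-g) degrees of freedom. The within-group
#' mean square (`mse`) and residual degrees of freedom feed the GT2 post hoc
#' procedure.
#'
#' @inheritParams subgroup_summary
#' @return Object of class `anova_k`: list with `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `mse`, `group_means`, `group_n`,
#'   `grand_mean`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4)))  # F = 1.5 on (1, 4) df
#' @export
one_way_anova <- function(x, g = NULL) {
  groups <- as_group_list(x, g)
  if (length(groups) < 2) stop("ANOVA needs at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(groups)[n < 2], collapse = ", "))
  }
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  dfb <- length(groups) - 1L
  dfw <- N - length(groups)
  if (ssw == 0 && ssb == 0) {
    stop("degenerate input: zero variance within and between groups (F = 0/0)")
  }
  msb <- ssb / dfb
  mse <- ssw / dfw
  f <- msb / mse
  structure(list(
    f_stat = f, df_between = dfb, df_within = dfw,
    p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE),
    mse = mse, group_means = means, group_n = n, grand_mean = grand
  ), class = "anova_k")
}

#' @export
print.anova_k <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4f, p = %.4g, MSE = %.6g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value, x$mse))
  invisible(x)
}

#' Upper tail of the studentized maximum modulus distribution
#'
#' Survival function of M = max_i |Z_i| / (S/sigma), the maximum absolute
#' value of `k_star` independent standard normals studentized by a shared
#' chi estimate on `nu` degrees of freedom. The CDF is the scale mixture
#' F(m) = E_U[(2*Phi(m U) - 1)^k_star] with U = sqrt(chi^2_nu / nu),
#' evaluated by adaptive quadrature on the probability scale (substituting
#' U by its quantile function), which stays accurate at large `nu` where
#' the chi density is sharply peaked.
#'
#' @param m Threshold(s), non-negative.
#' @param k_star Number of comparisons (>= 1).
#' @param nu Residual degrees of freedom (>= 1).
#' @param rel_tol Relative quadrature tolerance (default 1e-8).
#' @return P(M >= m), vectorized over `m`.
#' @export
smm_sf <- function(m, k_star, nu, rel_tol = 1e-8) {
  if (any(!is.finite(m)) || any(m < 0)) stop("m must be finite and >= 0")
  if (k_star < 1 || k_star != round(k_star)) stop("k_star must be an integer >= 1")
  if (nu < 1) stop("nu must be >= 1")
  vapply(m, function(mi) {
    if (mi == 0) return(1)
    cdf <- stats::integrate(
      function(q) (2 * stats::pnorm(mi * sqrt(stats::qchisq(q, nu) / nu)) - 1)^k_star,
      lower = 0, upper = 1, rel.tol = rel_tol, subdivisions = 400L
    )$value
    min(max(1 - cdf, 0), 1)
  }, numeric(1))
}

#' Hochberg GT2 post hoc comparisons
#'
#' All pairwise comparisons of group means after a one-way ANOVA, for
#' unequal group sizes: for groups i and j the statistic is
#' t_ij = |mean_i - mean_j| / sqrt(MSE * (1/n_i + 1/n_j)) and the adjusted
#' p-value is the SMM upper-tail probability at t_ij with k* = g(g-1)/2
#' comparisons and the ANOVA residual degrees of freedom. A pair is
#' significant at `alpha` when its adjusted p is below `alpha`.
#'
#' @inheritParams subgroup_summary
#' @param alpha Familywise significance level (default 0.05).
#' @return Object of class `posthoc_gt2`: list with `pairs` (data frame:
#'   `group_i`, `group_j`, `mean_diff`, `standard_error`, `t`,
#'   `adjusted_p`, `significant`), `alpha`, `k_star`, `nu`, `anova`.
#' @export
hochberg_gt2 <- function(x, g = NULL, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  groups <- as_group_list(x, g)
  if (length(groups) < 2) stop("post hoc comparison needs at least 2 groups")
  aov_res <- one_way_anova(groups)
  gnames <- names(groups)
  ng <- length(groups)
  k_star <- ng * (ng - 1L) / 2L
  pairs <- utils::combn(ng, 2)
  means <- aov_res$group_means
  n <- aov_res$group_n
  diff <- means[pairs[1, ]] - means[pairs[2, ]]
  se <- sqrt(aov_res$mse * (1 / n[pairs[1, ]] + 1 / n[pairs[2, ]]))
  tstat <- abs(diff) / se
  adj_p <- smm_sf(tstat, k_star, aov_res$df_within)
  tab <- data.frame(
    group_i = gnames[pairs[1, ]], group_j = gnames[pairs[2, ]],
    mean_diff = unname(diff), standard_error = unname(se),
    t = unname(tstat), adjusted_p = adj_p,
    significant = adj_p < alpha,
    stringsAsFactors = FALSE
  )
  structure(list(pairs = tab, alpha = alpha, k_star = k_star,
                 nu = aov_res$df_within, anova = aov_res),
            class = "posthoc_gt2")
}

#' @export
print.posthoc_gt2 <- function(x, ...) {
  cat(sprintf("Hochberg GT2 post hoc: %d pairwise comparisons, nu = %d, alpha = %g\n",
              x$k_star, x$nu, x$alpha))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Upper-triangular p-value matrix from a GT2 result
#'
#' Formats the pairwise adjusted p-values as a square matrix with the upper
#' triangle populated (publication-table shape); values at or above the cap
#' print as `">.99"` when rounding.
#'
#' @param x A `posthoc_gt2` object.
#' @param digits Decimals to round to, or `NULL` for full precision.
#' @return Matrix of adjusted p-values (numeric when `digits` is `NULL`,
#'   character otherwise).
#' @export
posthoc_matrix <- function(x, digits = NULL) {
  gnames <- union(x$pairs$group_i, x$pairs$group_j)
  m <- matrix(NA_real_, length(gnames), length(gnames),
              dimnames = list(gnames, gnames))
  for (r in seq_len(nrow(x$pairs))) {
    m[x$pairs$group_i[r], x$pairs$group_j[r]] <- x$pairs$adjusted_p[r]
    m[x$pairs$group_j[r], x$pairs$group_i[r]] <- x$pairs$adjusted_p[r]
  }
  diag(m) <- 1
  if (is.null(digits)) return(m)
  out <- matrix("-", nrow(m), ncol(m), dimnames = dimnames(m))
  up <- upper.tri(m, diag = TRUE)
  rounded <- round(m, digits)
  out[up] <- ifelse(rounded[up] > 0.99, ">.99",
                    sub("^0\\.", ".", formatC(rounded[up], digits = digits,
                                              format = "f")))
  out
}

#' Hartley's F-max homogeneity-of-variance screen
#'
#' Ratio of the largest to the smallest sample variance across groups, with
#' a Monte-Carlo p-value simulated under normality at the observed group
#' sizes (the classical tables assume equal n). The p-value uses the
#' add-one estimator (1 + #{sim >= observed}) / (n_rep + 1).
#'
#' @inheritParams subgroup_summary
#' @param n_rep Monte-Carlo replicates (default 10000).
#' @param seed Optional integer seed for the simulation (local to the call).
#' @return Object of class `hartley_fmax`: list with `f_max`, `p_value`,
#'   `group_variances`, `degenerate` (TRUE when a group variance is zero,
#'   making `f_max` infinite).
#' @export
hartley_fmax <- function(x, g = NULL, n_rep = 10000, seed = NULL) {
  groups <- as_group_list(x, g)
  if (length(groups) < 2) stop("F-max needs at least 2 groups")
  n <- vapply(groups, length, integer(1))
  if (any(n < 2)) {
    stop("group(s) with fewer than 2 observations: ",
         paste(names(groups)[n < 2], collapse = ", "))
  }
  v <- vapply(groups, stats::var, numeric(1))
  if (min(v) == 0) {
    return(structure(list(f_max = Inf, p_value = NA_real_,
                          group_variances = v, degenerate = TRUE),
                     class = "hartley_fmax"))
  }
  fmax <- max(v) / min(v)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  sim_v <- matrix(NA_real_, nrow = n_rep, ncol = length(groups))
  for (j in seq_along(groups)) {
    z <- matrix(stats::rnorm(n_rep * n[j]), nrow = n_rep)
    sim_v[, j] <- (rowSums(z^2) - n[j] * rowMeans(z)^2) / (n[j] - 1)
  }
  sim_fmax <- apply(sim_v, 1, max) / apply(sim_v, 1, min)
  p <- (1 + sum(sim_fmax >= fmax)) / (n_rep + 1)
  structure(list(f_max = fmax, p_value = p, group_variances = v,
                 degenerate = FALSE),
            class = "hartley_fmax")
}

#' @export
print.hartley_fmax <- function(x, ...) {
  if (x$degenerate) {
    cat("Hartley F-max: infinite (a group has zero variance)\n")
  } else {
    cat(sprintf("Hartley F-max = %.4f, Monte-Carlo p = %.4f\n",
                x$f_max, x$p_value))
  }
  invisible(x)
}

#' Two-proportion z-test
#'
#' Compares two binomial proportions. The default pooled statistic is
#' z = (p1 - p2) / sqrt(p_hat (1 - p_hat) (1/n1 + 1/n2)) with
#' p_hat = (a1 + a2)/(n1 + n2); two-tailed p = 2 (1 - Phi(|z|)). Set
#' `pooled = FALSE` for the unpooled-variance variant.
#'
#' @param a1,n1 Successes and trials in the first sample.
#' @param a2,n2 Successes and trials in the second sample.
#' @param pooled Use the pooled variance estimate (default TRUE).
#' @return Object of class `ztest_result`: list with `p1`, `p2`, `z`,
#'   `p_value`, `pooled`, `degenerate` (TRUE when the pooled proportion is
#'   0 or 1, leaving z undefined).
#' @export
two_prop_ztest <- function(a1, n1, a2, n2, pooled = TRUE) {
  if (n1 < 1 || n2 < 1) stop("both samples need at least one trial")
  if (a1 < 0 || a1 > n1 || a2 < 0 || a2 > n2) {
    stop("successes must lie in [0, trials]")
  }
  p1 <- a1 / n1
  p2 <- a2 / n2
  if (pooled) {
    phat <- (a1 + a2) / (n1 + n2)
    if (phat == 0 || phat == 1) {
      return(structure(list(p1 = p1, p2 = p2, z = NA_real_,
                            p_value = NA_real_, pooled = pooled,
                            degenerate = TRUE),
                       class = "ztest_result"))
    }
    se <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
    if (se == 0) {
      return(structure(list(p1 = p1, p2 = p2, z = NA_real_,
                            p_value = NA_real_, pooled = pooled,
                            degenerate = TRUE),
                       class = "ztest_result"))
    }
  }
  z <- (p1 - p2) / se
  structure(list(p1 = p1, p2 = p2, z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 pooled = pooled, degenerate = FALSE),
            class = "ztest_result")
}

#' @export
print.ztest_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Two-proportion z-test: degenerate (pooled proportion is 0 or 1)\n")
  } else {
    cat(sprintf("Two-proportion z-test (%s): p1 = %.4f, p2 = %.4f, z = %.3f, p = %.4g\n",
                if (x$pooled) "pooled" else "unpooled", x$p1, x$p2, x$z,
                x$p_value))
  }
  invisible(x)
}
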