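#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computed from first principles: conditioning on the table margins, the
#' count in cell (1,1) follows a hypergeometric distribution over its
#' feasible range. The two-sided p-value is the sum of the point
#' probabilities of every margin-preserving table whose probability does
#' not exceed that of the observed table, with a relative tolerance factor
#' of `1 + 1e-7` absorbing floating-point ties — the convention of
#' mainstream statistical software. Point probabilities are evaluated in
#' log space via `lgamma` so cohort-scale tables cannot overflow.
#'
#' @param x 2x2 matrix (or something coercible) of non-negative integer
#'   counts; rows are the levels of one factor, columns of the other.
#' @return Object of class `assoc_result`: a list with `p_value`,
#'   `odds_ratio` (see [odds_ratio()]), `method` and the `table`.
#' @examples
#' fisher_exact(matrix(c(12, 0, 2, 3), 2, byrow = TRUE))$p_value  # 0.0147
#' @export
fisher_exact <- function(x) {
  m <- as_2x2(x)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (n == 0) stop("all-zero contingency table", call. = FALSE)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  k <- lo:hi
  # log hypergeometric point probability for each feasible (1,1) cell
  logp <- lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1)
  log_obs <- logp[k == a]
  p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  structure(
    list(p_value = min(p, 1), odds_ratio = odds_ratio(m),
         method = "Fisher exact test (two-sided, point-probability)",
         table = m),
    class = "assoc_result"
  )
}

#' Sample odds ratio of a 2x2 table
#'
#' `(a * d) / (b * c)`. When only the numerator is positive the odds ratio
#' is reported as `Inf`; when both products are zero it is undefined and
#' reported as `NaN`.
#'
#' @inheritParams fisher_exact
#' @return A single number (possibly `Inf` or `NaN`).
#' @export
odds_ratio <- function(x) {
  m <- as_2x2(x)
  num <- m[1, 1] * m[2, 2]
  den <- m[1, 2] * m[2, 1]
  if (den == 0 && num == 0) return(NaN)
  if (den == 0) return(Inf)
  num / den
}

as_2x2 <- function(x) {
  m <- as.matrix(x)
  if (!all(dim(m) == c(2, 2))) stop("expected a 2x2 table", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Mann-Whitney U test
#'
#' Ranks the pooled sample with average ranks for ties and computes
#' `U = R_x - n_x (n_x + 1) / 2`. For small problems
#' (`n_x + n_y <= exact_limit`) the two-sided p-value is exact: every
#' assignment of the pooled ranks to the two groups is enumerated and the
#' p-value is the fraction whose U deviates from its mean `n_x n_y / 2` at
#' least as much as observed. Larger problems use the normal approximation
#' with the tie-corrected variance and the standard 0.5 continuity
#' correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param exact_limit Largest pooled size for which enumeration is used.
#' @return Object of class `mwu_result`: list with `U`, `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(10, 11, 12))$p_value  # exact: 0.1
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  if (n <= exact_limit) {
    idx <- utils::combn(n, nx)
    u_all <- colSums(matrix(rk[idx], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(rk)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sqrt(v)
      p <- 2 * stats::pnorm(-max(z, 0))
    }
    method <- "normal approximation, tie-corrected"
  }
  structure(list(U = u_obs, p_value = min(p, 1), method = method),
            class = "mwu_result")
}

#' Multiple-testing adjustment of p-values
#'
#' Bonferroni: `min(1, m * p)`. Benjamini-Hochberg: the standard step-up
#' procedure — sort ascending, scale the i-th smallest by `m / i`, enforce
#' monotonicity by a cumulative minimum from the largest down, and map back
#' to the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- sum(ok)
  out <- rep(NA_real_, length(p))
  if (m == 0) return(out)
  pv <- p[ok]
  if (method == "bonferroni") {
    out[ok] <- pmin(1, m * pv)
  } else {
    o <- order(pv)
    ranked <- pv[o] * m / seq_len(m)
    ranked <- rev(cummin(rev(ranked)))
    adj <- numeric(m)
    adj[o] <- pmin(1, ranked)
    out[ok] <- adj
  }
  out
}

#' Pairwise association tests over a table of binary sample factors
#'
#' Tabulates each requested pair of logical factors into a 2x2 table and
#' applies [fisher_exact()].
#'
#' @param factors Data frame with one row per sample and logical columns.
#' @param pairs Character vector of `"factor1:factor2"` pairs.
#' @return Tibble: one row per pair with counts, `odds_ratio`, `p_value`.
#' @export
associate_factors <- function(factors, pairs) {
  purrr::map_dfr(pairs, function(pair) {
    nm <- strsplit(pair, ":", fixed = TRUE)[[1]]
    if (length(nm) != 2 || !all(nm %in% names(factors))) {
      stop("pair '", pair, "' does not name two factor columns", call. = FALSE)
    }
    f1 <- factors[[nm[1]]]; f2 <- factors[[nm[2]]]
    m <- matrix(c(sum(f1 & f2), sum(f1 & !f2),
                  sum(!f1 & f2), sum(!f1 & !f2)), 2, byrow = TRUE)
    res <- fisher_exact(m)
    tibble::tibble(
      factor1 = nm[1], factor2 = nm[2],
      a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
      odds_ratio = res$odds_ratio, p_value = res$p_value
    )
  })
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(x$method, "\n")
  print(x$table)
  cat(sprintf("p = %.4g, odds ratio = %.4g\n", x$p_value, x$odds_ratio))
  invisible(x)
}

#' @export
print.mwu_result <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n", sep = "")
  cat(sprintf("U = %g, two-sided p = %.4g\n", x$U, x$p_value))
  invisible(x)
}
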