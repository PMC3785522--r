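#' Expected aCGH log2 ratio under the two-component purity mixture
#'
#' A tumor specimen is modeled as a mixture of a tumor-cell fraction `f`
#' (purity) carrying integer copy state `c` at a locus and a stromal fraction
#' `1 - f` carrying the normal two copies. Relative to a diploid reference the
#' expected probe log2 ratio is
#' \deqn{L = \log_2\frac{(1-f)\,2 + f\,c}{2}.}
#' A hemizygous loss (`c = 1`) in a pure tumor gives -1; a homozygous deletion
#' (`c = 0`) at purity 0.75 gives -2, the stromal cells contributing the only
#' remaining template.
#'
#' @param copies Non-negative integer copy state(s) in the tumor fraction.
#' @param purity Tumor-cell fraction(s) in `(0, 1]`.
#' @return Numeric vector of expected log2 ratios.
#' @examples
#' expected_log2(0, 0.75)  # -2: homozygous deletion at 75% purity
#' expected_log2(1, 1.0)   # -1: one remaining allele, pure tumor
#' @seealso [infer_purity()] for the exact inverse.
#' @export
expected_log2 <- function(copies, purity) {
  stopifnot(is.numeric(copies), is.numeric(purity))
  if (any(copies < 0)) {
    stop("`copies` must be a non-negative copy state", call. = FALSE)
  }
  check_purity(purity)
  log2(((1 - purity) * 2 + purity * copies) / 2)
}

#' Tumor purity implied by a probe log2 ratio at a known copy state
#'
#' Exact algebraic inverse of [expected_log2()]:
#' `f = (2 - 2^(L + 1)) / (2 - c)`. The diploid state `c = 2` is
#' unidentifiable (every purity gives `L = 0`) and is rejected.
#'
#' @param log2_ratio Observed probe log2 ratio(s).
#' @param copies Assumed integer copy state(s), anything but 2.
#' @param tol Numerical slack allowed before an implied purity just outside
#'   `(0, 1]` is treated as an error rather than clipped.
#' @return Implied purity in `(0, 1]`.
#' @examples
#' infer_purity(-2, 0)  # 0.75
#' infer_purity(-1, 1)  # 1
#' @export
infer_purity <- function(log2_ratio, copies, tol = 1e-9) {
  stopifnot(is.numeric(log2_ratio), is.numeric(copies))
  if (any(copies == 2)) {
    stop("purity is unidentifiable at the diploid copy state (c = 2)",
         call. = FALSE)
  }
  if (any(copies < 0)) {
    stop("`copies` must be a non-negative copy state", call. = FALSE)
  }
  n <- max(length(log2_ratio), length(copies))
  L <- rep_len(log2_ratio, n)
  cc <- rep_len(copies, n)
  f <- (2 - 2^(L + 1)) / (2 - cc)
  bad <- f < tol | f > 1 + tol
  if (any(bad)) {
    stop(sprintf(
      "log2 ratio %.4g implies purity %.4g outside (0, 1] for copy state %d",
      L[bad][1], f[bad][1], as.integer(cc[bad][1])
    ), call. = FALSE)
  }
  pmin(f, 1)
}

check_purity <- function(purity) {
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("`purity` must lie in (0, 1]", call. = FALSE)
  }
  invisible(purity)
}
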