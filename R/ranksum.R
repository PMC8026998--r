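#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Shared rank-sum engine used for the response-ratio group comparison and
#' the nonparametric qPCR/puncta comparisons. Ties are handled by midranks.
#' The two-sided p value is computed by three routes:
#'
#' * exact null distribution (`stats::pwilcox`) when there are no ties and
#'   both groups have at most `exact_limit` observations;
#' * full enumeration of all group assignments when there are ties but the
#'   assignment space is small enough to enumerate (`choose(n1+n2, n1) <=
#'   enum_limit`), which also yields p = 1 for identical samples;
#' * tie-corrected normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_limit largest per-group size for the exact no-ties route.
#' @param enum_limit largest assignment-space size for the enumeration route.
#' @return list with `statistic` (Mann-Whitney U of `x`), `p.value`, and
#'   `method`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))$p.value  # exact 2/6 = 0.3333
#' @export
rank_sum_test <- function(x, y, exact_limit = 25, enum_limit = 2e5) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && n1 <= exact_limit && n2 <= exact_limit) {
    p_less <- stats::pwilcox(U, n1, n2)
    p_greater <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_less, p_greater))
    return(list(statistic = U, p.value = p, method = "exact"))
  }
  if (ties && choose(N, n1) <= enum_limit) {
    combos <- utils::combn(N, n1)
    U_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
    return(list(statistic = U, p.value = p, method = "enumeration"))
  }
  tie_tab <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = U, p.value = 1, method = "normal"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  if (U == mu) z <- 0
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = U, p.value = p, method = "normal")
}

#' @rdname rank_sum_test
#' @export
mann_whitney <- function(x, y, ...) rank_sum_test(x, y, ...)
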