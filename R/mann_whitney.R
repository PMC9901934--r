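#' Mann-Whitney U comparison of two samples
#'
#' Used to ask whether epistasis or activity values of two structural
#' element classes could come from one distribution. The statistic is
#' `U = #\{x_i > y_j\} + 0.5 * #\{x_i = y_j\}`. The two-sided p-value is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))` under the permutation null.
#'
#' Three regimes:
#' * full enumeration of all `choose(m+n, m)` group assignments when that
#'   count is at most `enum_limit` (handles ties exactly; identical samples
#'   give p = 1);
#' * the exact tie-free Mann-Whitney distribution ([stats::pwilcox]) when
#'   there are no ties and `m * n <= 10^4`;
#' * otherwise the normal approximation with tie correction and continuity
#'   correction.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param enum_limit Largest number of assignments enumerated exactly.
#' @param method `"auto"` (the regime rules above) or one of
#'   `"enumeration"`, `"exact"`, `"normal"` to force a regime.
#' @return List with `u`, `p`, and `method` (`"enumeration"`, `"exact"`,
#'   or `"normal"`).
#' @export
compare_distributions <- function(x, y, enum_limit = 2e4,
                                  method = c("auto", "enumeration",
                                             "exact", "normal")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  m <- length(x); n <- length(y); N <- m + n
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- any(duplicated(pooled))

  if (method == "exact" && ties) {
    stop("the exact tie-free distribution does not apply to tied samples",
         call. = FALSE)
  }
  if (method == "enumeration" ||
      (method == "auto" && choose(N, m) <= enum_limit)) {
    comb <- utils::combn(N, m)
    u_all <- colSums(matrix(r[comb], nrow = m)) - m * (m + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                        mean(u_all >= u_obs - eps)))
    return(list(u = u_obs, p = p, method = "enumeration"))
  }
  if (method == "exact" || (method == "auto" && !ties && m * n <= 1e4)) {
    p <- min(1, 2 * min(stats::pwilcox(u_obs, m, n),
                        1 - stats::pwilcox(u_obs - 1, m, n)))
    return(list(u = u_obs, p = p, method = "exact"))
  }
  mu <- m * n / 2
  tie_tab <- table(pooled)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(u = u_obs, p = p, method = "normal")
}
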