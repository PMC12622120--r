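#' Hotelling's T-squared test of a component vector
#'
#' Combines the k correlated per-transition estimates of one variant pair
#' into a single test via `T2 = theta' solve(Sigma) theta`, with `Sigma`
#' the EIC-based estimator covariance (already on the estimator scale, see
#' [component_covariance()]). The p-value uses the exact Hotelling F
#' reference, `((n - k) / (k (n - 1))) T2 ~ F(k, n - k)`, which matches
#' the chi-squared reference at biobank sample sizes but keeps the test
#' exact at small n; the chi-squared p-value is reported alongside. A
#' numerically singular covariance falls back to the Moore-Penrose
#' pseudo-inverse with the effective rank as the test dimension.
#'
#' @param theta Numeric k-vector of component estimates.
#' @param sigma k x k estimator covariance matrix.
#' @param n Sample count the components were estimated on.
#' @param reference `"F"` (default) or `"chisq"` for the reported `p_H`.
#' @return List with `T2`, `p_H`, `p_chisq`, `k` (effective test
#'   dimension), `rank_deficient`, and `reference`.
#' @export
hotelling_test <- function(theta, sigma, n, reference = c("F", "chisq")) {
  reference <- match.arg(reference)
  k <- length(theta)
  if (k == 0L) stop("no components to test", call. = FALSE)
  sigma <- unclass(sigma)
  stopifnot(is.matrix(sigma), nrow(sigma) == k, ncol(sigma) == k)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  tol <- max(ev) * k * .Machine$double.eps
  rank <- sum(ev > tol)
  rank_deficient <- rank < k
  if (rank_deficient) {
    warning(sprintf("singular component covariance: rank %d < k = %d; %s",
                    rank, k, "using the pseudo-inverse"))
    t2 <- drop(t(theta) %*% MASS::ginv(sigma) %*% theta)
    k_eff <- rank
  } else {
    t2 <- drop(t(theta) %*% solve(sigma, theta))
    k_eff <- k
  }
  p_chisq <- stats::pchisq(t2, df = k_eff, lower.tail = FALSE)
  p_f <- if (n > k_eff) {
    f_stat <- (n - k_eff) / (k_eff * (n - 1)) * t2
    stats::pf(f_stat, k_eff, n - k_eff, lower.tail = FALSE)
  } else p_chisq
  list(T2 = t2, p_H = if (reference == "F") p_f else p_chisq,
       p_chisq = p_chisq, k = k_eff, rank_deficient = rank_deficient,
       reference = reference)
}

#' Grouped Benjamini-Hochberg adjustment of Hotelling p-values
#'
#' Applies the BH step-up procedure independently within each group
#' (default: trait crossed with transcription factor, so discoveries are
#' controlled per trait per TF) and flags results whose adjusted value
#' `q_H` falls below the FDR threshold.
#'
#' @param results data.frame with a `p_H` column.
#' @param group_cols Character vector of grouping columns present in
#'   `results` (ignored if absent).
#' @param threshold FDR threshold (default 0.05).
#' @return `results` with added columns `q_H` and `significant`.
#' @export
bh_adjust <- function(results, group_cols = c("trait", "tf"),
                      threshold = 0.05) {
  stopifnot("p_H" %in% names(results), threshold > 0, threshold < 1)
  if (nrow(results) == 0L) {
    results$q_H <- numeric(0)
    results$significant <- logical(0)
    return(results)
  }
  group_cols <- intersect(group_cols, names(results))
  grp <- if (length(group_cols)) {
    interaction(results[group_cols], drop = TRUE)
  } else factor(rep(1L, nrow(results)))
  results$q_H <- stats::ave(results$p_H, grp,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  results$significant <- !is.na(results$q_H) & results$q_H < threshold
  results
}
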