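#' Unpaired two-sample t test
#'
#' Two-sided unpaired t test between two groups; Student's pooled-variance
#' variant by default, Welch by flag. When both groups have zero variance
#' the test is degenerate: equal means give p = 1 by convention, unequal
#' means p = 0.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param equal_variance Use Student's pooled test (default `TRUE`);
#'   `FALSE` for Welch.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
unpaired_t_test <- function(a, b, equal_variance = TRUE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (equal) 0 else sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2L,
                p = if (equal) 1 else 0))
  }
  # a single zero-variance group breaks the pooled assumption: fall back
  # to Welch, which stays defined
  if ((va == 0 || vb == 0) && equal_variance) equal_variance <- FALSE
  tt <- stats::t.test(a, b, var.equal = equal_variance,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' `d_signed = (mean(a) - mean(b)) / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`.
#' The conventionally reported value is the absolute d; the signed value
#' is retained.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `d` (absolute) and `d_signed`.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  d_signed <- (mean(a) - mean(b)) / sqrt(sp2)
  list(d = abs(d_signed), d_signed = d_signed)
}

#' Conventional effect-size bands for Cohen's d
#'
#' d > 0.8 is large, 0.5 to 0.8 medium, 0.2 to 0.5 small, below 0.2
#' negligible.
#'
#' @param d Absolute Cohen's d (>= 0).
#' @return One of `"negligible"`, `"small"`, `"medium"`, `"large"`.
#' @export
classify_effect_size <- function(d) {
  stopifnot(d >= 0)
  if (d > 0.8) "large"
  else if (d >= 0.5) "medium"
  else if (d >= 0.2) "small"
  else "negligible"
}
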