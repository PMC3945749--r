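# Two-sample test for equality of proportions with Yates' correction.

#' Upper-tail probability of the 1-df chi-square distribution
#'
#' @param x Non-negative statistic value.
#' @return `P(X >= x)` for `X ~ chi-square(1)`.
#' @export
chi2_sf_1df <- function(x) {
  if (any(x < 0)) abort("chi-square statistic must be non-negative")
  pchisq(x, df = 1, lower.tail = FALSE)
}

#' Two-sample proportion test with Yates' continuity correction
#'
#' Compares the proportions `x1/n1` and `x2/n2` via the corrected chi-square
#' statistic on the 2x2 table `a = x1, b = n1 - x1, c = x2, d = n2 - x2`:
#' `chi2 = N (max(|ad - bc| - N/2, 0))^2 / (r1 r2 c1 c2)` with `N = n1 + n2`
#' and row/column sums `r1, r2, c1, c2`. The two-sided p-value is the 1-df
#' chi-square upper tail. Equivalent to `stats::prop.test` with
#' `correct = TRUE`.
#'
#' @param x1,n1 Successes and trials of the first sample.
#' @param x2,n2 Successes and trials of the second sample.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return A `prop_test_result` with fields `x1`, `n1`, `x2`, `n2`,
#'   `estimate` (the two proportions), `chi2`, `p_value`, `corrected`.
#' @export
yates_prop_test <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 <= 0 || n2 <= 0) abort("sample sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    abort("counts must satisfy 0 <= x <= n")
  }
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- n1 + n2
  margins <- c(n1, n2, a + c, b + d)
  if (any(margins == 0)) {
    abort("test undefined: a row or column sum of the 2x2 table is zero")
  }
  cc <- if (correct) N / 2 else 0
  chi2 <- N * max(abs(a * d - b * c) - cc, 0)^2 / prod(margins)
  structure(
    list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
         estimate = c(p1 = x1 / n1, p2 = x2 / n2),
         chi2 = chi2, p_value = chi2_sf_1df(chi2), corrected = correct),
    class = "prop_test_result"
  )
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat("Two-sample test for equality of proportions",
      if (x$corrected) "with Yates' continuity correction" else "(uncorrected)",
      "\n")
  cat(sprintf("  p1 = %d/%d = %.3f, p2 = %d/%d = %.3f\n",
              x$x1, x$n1, x$estimate[1], x$x2, x$n2, x$estimate[2]))
  cat(sprintf("  X-squared = %.4f (df = 1), p-value = %.4f\n",
              x$chi2, x$p_value))
  invisible(x)
}

#' @rdname yates_prop_test
#' @param x A `prop_test_result`.
#' @param ... Ignored.
#' @export
tidy.prop_test_result <- function(x, ...) {
  tibble(
    estimate1 = unname(x$estimate[1]), estimate2 = unname(x$estimate[2]),
    statistic = x$chi2, p.value = x$p_value, parameter = 1,
    method = paste0("2-sample test for equality of proportions",
                    if (x$corrected) " with continuity correction" else "")
  )
}

#' @rdname yates_prop_test
#' @export
glance.prop_test_result <- function(x, ...) tidy.prop_test_result(x, ...)
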