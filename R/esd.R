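#' Generalized extreme studentized deviate (Rosner) outlier test
#'
#' Iteratively tests for up to `k_max` outliers in a univariate sample. At
#' step `i` the most extreme studentized deviate
#' \eqn{R_i = \max_j |x_j - \bar x| / s} is computed over the points still in
#' play, the extreme point is set aside, and \eqn{R_i} is compared with the
#' critical value
#' \deqn{\lambda_i = \frac{(n-i)\, t_{p,\,n-i-1}}{\sqrt{(n-i-1+t^2_{p,\,n-i-1})(n-i+1)}},
#'   \quad p = 1 - \frac{\alpha}{2(n-i+1)}.}
#' The number of outliers is the largest `i` with \eqn{R_i > \lambda_i}; the
#' flagged observations are the first `i` points removed. Ties at the argmax
#' are broken by lowest index. If the remaining points have zero standard
#' deviation the iteration stops and the remaining \eqn{R_i} are zero.
#'
#' @param values Numeric vector (finite).
#' @param k_max Maximum number of outliers to test for.
#' @param alpha Significance level.
#' @return An object of class `nap_esd`: a list with `n`, `k_max`, `alpha`,
#'   `stats` (tibble with `i`, `R`, `lambda`, `removed_index`), `n_outliers`
#'   and `flagged` (integer indices into `values`).
#' @seealso [tidy.nap_esd()], [glance.nap_esd()]
#' @export
#' @examples
#' esd_outliers(c(1, 2, 3, 4, 5, 100), k_max = 2)
esd_outliers <- function(values, k_max, alpha = 0.05) {
  if (any(!is.finite(values))) {
    abort("values must be finite", class = "napscan_validation_error")
  }
  n <- length(values)
  if (k_max < 1) abort("k_max must be >= 1", class = "napscan_validation_error")
  if (n < k_max + 2) {
    abort(paste0("need at least k_max + 2 = ", k_max + 2,
                 " observations, got ", n),
          class = "napscan_validation_error")
  }
  remaining <- seq_len(n)
  R <- numeric(k_max)
  lambda <- numeric(k_max)
  removed <- integer(k_max)
  degenerate <- FALSE
  for (i in seq_len(k_max)) {
    xi <- values[remaining]
    s <- sd(xi)
    if (!degenerate && s > 0) {
      dev <- abs(xi - mean(xi)) / s
      j <- which.max(dev)  # which.max takes the lowest index on ties
      R[i] <- dev[j]
      removed[i] <- remaining[j]
      remaining <- remaining[-j]
    } else {
      degenerate <- TRUE
      R[i] <- 0
      removed[i] <- NA_integer_
    }
    p <- 1 - alpha / (2 * (n - i + 1))
    tcrit <- qt(p, df = n - i - 1)
    lambda[i] <- (n - i) * tcrit /
      sqrt((n - i - 1 + tcrit^2) * (n - i + 1))
  }
  exceed <- which(R > lambda)
  n_out <- if (length(exceed) == 0) 0L else max(exceed)
  structure(
    list(n = n, k_max = k_max, alpha = alpha,
         stats = tibble(i = seq_len(k_max), R = R, lambda = lambda,
                        removed_index = removed),
         n_outliers = n_out,
         flagged = if (n_out > 0) removed[seq_len(n_out)] else integer()),
    class = "nap_esd"
  )
}

#' @export
print.nap_esd <- function(x, ...) {
  cat("<generalized ESD test>  n =", x$n, " k_max =", x$k_max,
      " alpha =", x$alpha, "\n")
  cat("  outliers:", x$n_outliers,
      if (x$n_outliers > 0) paste0("(indices ",
                                   paste(x$flagged, collapse = ", "), ")") else "",
      "\n")
  invisible(x)
}
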