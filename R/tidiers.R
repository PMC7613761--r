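#' Tidiers for package result objects
#'
#' broom-style [generics::tidy()] and [generics::glance()] methods.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name napscan-tidiers
NULL

#' @rdname napscan-tidiers
#' @export
tidy.nap_esd <- function(x, ...) {
  dplyr::mutate(x$stats, outlier = .data$i <= x$n_outliers)
}

#' @rdname napscan-tidiers
#' @export
glance.nap_esd <- function(x, ...) {
  tibble(n = x$n, k_max = x$k_max, alpha = x$alpha,
         n_outliers = x$n_outliers)
}

#' @rdname napscan-tidiers
#' @export
tidy.nap_ols <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std_error = unname(s[, 2]), statistic = unname(s[, 3]),
         p_value = unname(s[, 4]))
}

#' @rdname napscan-tidiers
#' @export
glance.nap_ols <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         residual_se = x$residual_se, n = x$n, df = x$df,
         r_squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' @rdname napscan-tidiers
#' @export
tidy.nap_pgls <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std_error = c(NA_real_, x$slope_se),
         p_value = c(NA_real_, x$slope_p))
}

#' @rdname napscan-tidiers
#' @export
glance.nap_pgls <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, sigma2_bm = x$sigma2_bm,
         loglik = x$loglik, slope_p = x$slope_p, n = x$n,
         log_transform = x$log_transform)
}

#' @rdname napscan-tidiers
#' @export
tidy.nap_enrichment <- function(x, ...) {
  as_tibble(x)
}

#' @rdname napscan-tidiers
#' @export
glance.nap_enrichment <- function(x, ...) {
  tibble(n_proteins = nrow(x), d0 = attr(x, "d0"), s0_sq = attr(x, "s0_sq"),
         n_significant = sum(x$q_value < 0.05))
}

#' @rdname napscan-tidiers
#' @export
glance.nap_screen <- function(x, ...) {
  tibble(n_features = nrow(x), nap_class = attr(x, "nap_class"),
         nap_rank = attr(x, "nap_rank"))
}
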