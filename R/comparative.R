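#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho on average ranks. The two-sided p-value is exact
#' (full enumeration of rank permutations) for `n <= exact_max` and uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` df
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @param exact_max Largest `n` for exact enumeration.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `method`.
#' @export
spearman <- function(x, y, exact_max = 7) {
  n <- length(x)
  if (n != length(y)) abort("x and y must have equal length",
                            class = "napscan_validation_error")
  if (n < 3) abort("need at least 3 observations",
                   class = "napscan_validation_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("rho undefined for a constant vector",
          class = "napscan_validation_error")
  }
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(ryy) {
    stats::cor(rx, ryy)
  }
  rho <- rho_of(ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(idx) rho_of(ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  tibble(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n is small by construction
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1))
  }
  do.call(rbind, out)
}

#' Correlation screen of domain-class abundances against growth temperature
#'
#' For every domain class (plus the aggregate NAP class) quantified in at
#' least `min_species` species, computes the Spearman correlation between
#' its per-species relative abundance and optimal growth temperature, and
#' reports the rank of the NAP class among all retained features (by rho,
#' descending).
#'
#' @param abundances Long tibble with columns `species_id`, `class`,
#'   `percent` (from [aggregate_by_class()] stacked across species, plus the
#'   NAP aggregate as its own class).
#' @param ogt Tibble with `species_id` and `ogt` (degrees C).
#' @param min_species Minimum number of species in which a class must be
#'   quantified (non-zero) to be retained.
#' @param nap_class Name of the NAP aggregate class.
#' @return A tibble of class `nap_screen` with columns `class`, `rho`,
#'   `p_value`, `n_species`; attribute `nap_rank` gives the NAP class rank.
#' @export
domain_ogt_screen <- function(abundances, ogt, min_species = 5,
                              nap_class = "NAP") {
  joined <- dplyr::inner_join(abundances, ogt, by = "species_id")
  res <- joined |>
    dplyr::group_by(.data$class) |>
    dplyr::filter(sum(.data$percent > 0) >= min_species) |>
    dplyr::summarise(
      rho = spearman(.data$percent, .data$ogt)$rho,
      p_value = spearman(.data$percent, .data$ogt)$p_value,
      n_species = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$rho))
  nap_rank <- if (nap_class %in% res$class) {
    which(res$class == nap_class)
  } else {
    NA_integer_
  }
  class(res) <- c("nap_screen", class(res))
  attr(res, "nap_rank") <- nap_rank
  attr(res, "nap_class") <- nap_class
  res
}

#' Linear prediction of NAP investment at a new growth temperature
#'
#' Fits ordinary least squares of NAP investment (percent of proteome) on
#' optimal growth temperature and predicts the investment expected at a new
#' temperature `x0`, with both the 95% confidence interval of the mean
#' response and the 95% prediction interval for a new observation (the two
#' intervals answer different questions; both are reported).
#'
#' @param x Growth temperatures (degrees C).
#' @param y NAP investments (percent).
#' @param x0 Temperature(s) at which to predict.
#' @param level Interval coverage.
#' @return An object of class `nap_ols`: list with `slope`, `intercept`,
#'   `residual_se`, `n`, `df`, `fit` (the `lm` object) and `prediction`, a
#'   tibble with `x0`, `estimate`, `ci_lower`, `ci_upper`, `pi_lower`,
#'   `pi_upper`.
#' @export
ols_predict <- function(x, y, x0, level = 0.95) {
  n <- length(x)
  if (n < 3) {
    abort("need at least 3 points for interval computation (df = n - 2 > 0)",
          class = "napscan_validation_error")
  }
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  nd <- data.frame(x = x0)
  ci <- predict(fit, nd, interval = "confidence", level = level)
  pi <- suppressWarnings(predict(fit, nd, interval = "prediction", level = level))
  structure(
    list(slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         residual_se = suppressWarnings(summary(fit)$sigma),
         n = n, df = n - 2, level = level, fit = fit,
         prediction = tibble(
           x0 = x0,
           estimate = unname(ci[, "fit"]),
           ci_lower = unname(ci[, "lwr"]), ci_upper = unname(ci[, "upr"]),
           pi_lower = unname(pi[, "lwr"]), pi_upper = unname(pi[, "upr"]))),
    class = "nap_ols"
  )
}

#' @export
print.nap_ols <- function(x, ...) {
  cat("<OLS fit>  slope =", signif(x$slope, 4), " intercept =",
      signif(x$intercept, 4), " n =", x$n, "\n")
  print(x$prediction)
  invisible(x)
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Regresses a tip trait on another accounting for phylogenetic
#' non-independence: residuals are assumed to covary proportionally to
#' shared root-to-tip branch length (the Brownian-motion covariance `C`).
#' Coefficients are the GLS estimate
#' \eqn{\hat\beta = (X^\top C^{-1} X)^{-1} X^\top C^{-1} y}; the BM rate
#' \eqn{\sigma^2} is the maximum-likelihood estimate
#' \eqn{r^\top C^{-1} r / n}; the slope p-value is a t test on `n - 2` df.
#' Optional parametric bootstrap confidence intervals are obtained by
#' simulating BM residuals on the tree and refitting.
#'
#' @param data Tibble with a `species_id` column matching the tree's tip
#'   labels plus the predictor and response columns.
#' @param tree A rooted `phylo` object with branch lengths; tips must match
#'   `data$species_id` exactly.
#' @param x,y Column names (strings) of predictor and response.
#' @param log_transform Natural-log-transform both variables first (requires
#'   positive values; non-positive rows are dropped with a warning).
#' @param n_boot Number of parametric bootstrap replicates (0 = none).
#' @param level Bootstrap interval coverage.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `nap_pgls`: list with `slope`, `intercept`,
#'   `sigma2_bm`, `loglik`, `slope_se`, `slope_p`, `n`, `bootstrap_ci`
#'   (tibble or `NULL`) and `C`.
#' @export
pgls_bm <- function(data, tree, x, y, log_transform = FALSE,
                    n_boot = 0, level = 0.95, seed = NULL) {
  miss <- setdiff(tree$tip.label, data$species_id)
  extra <- setdiff(data$species_id, tree$tip.label)
  if (length(miss) > 0 || length(extra) > 0) {
    abort(paste0("tree/data tip mismatch; missing from data: ",
                 paste(miss, collapse = ", "), "; not in tree: ",
                 paste(extra, collapse = ", ")),
          class = "napscan_validation_error")
  }
  df <- data[match(tree$tip.label, data$species_id), ]
  xv <- df[[x]]; yv <- df[[y]]
  keep <- rep(TRUE, length(xv))
  if (log_transform) {
    keep <- xv > 0 & yv > 0
    if (any(!keep)) {
      warn(paste0(sum(!keep), " tip(s) with non-positive values dropped ",
                  "before log transform"))
    }
  }
  tips <- tree$tip.label[keep]
  if (sum(keep) < 3) abort("fewer than 3 usable tips",
                           class = "napscan_validation_error")
  tr <- ape::keep.tip(tree, tips)
  xv <- xv[keep]; yv <- yv[keep]
  names(xv) <- names(yv) <- tips
  if (log_transform) { xv <- log(xv); yv <- log(yv) }
  C <- ape::vcv(tr)[tips, tips]
  n <- length(tips)
  L <- tryCatch(chol(C), error = function(e)
    abort("singular BM covariance matrix", class = "napscan_validation_error"))
  Ci <- chol2inv(L)
  X <- cbind(intercept = 1, slope = xv)
  XtCi <- t(X) %*% Ci
  beta_cov_unscaled <- solve(XtCi %*% X)
  beta <- drop(beta_cov_unscaled %*% (XtCi %*% yv))
  r <- yv - drop(X %*% beta)
  quad <- drop(t(r) %*% Ci %*% r)
  sigma2_ml <- quad / n
  logdetC <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2_ml) + logdetC + n)
  s2 <- quad / (n - 2)
  slope_se <- sqrt(s2 * beta_cov_unscaled["slope", "slope"])
  tstat <- beta[["slope"]] / slope_se
  slope_p <- 2 * pt(-abs(tstat), df = n - 2)

  boot_ci <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    Lt <- t(L)  # lower-triangular factor: C = Lt %*% t(Lt)
    slopes <- purrr::map_dbl(seq_len(n_boot), function(b) {
      eps <- drop(Lt %*% rnorm(n)) * sqrt(sigma2_ml)
      yb <- drop(X %*% beta) + eps
      drop(beta_cov_unscaled %*% (XtCi %*% yb))[2]
    })
    a <- (1 - level) / 2
    boot_ci <- tibble(level = level, n_boot = n_boot,
                      lower = unname(quantile(slopes, a)),
                      upper = unname(quantile(slopes, 1 - a)))
  }
  structure(
    list(slope = beta[["slope"]], intercept = beta[["intercept"]],
         sigma2_bm = sigma2_ml, loglik = loglik,
         slope_se = slope_se, slope_p = slope_p, n = n,
         log_transform = log_transform,
         bootstrap_ci = boot_ci, C = C),
    class = "nap_pgls"
  )
}

#' @export
print.nap_pgls <- function(x, ...) {
  cat("<PGLS (Brownian motion)>  n =", x$n, "\n")
  cat("  slope =", signif(x$slope, 4), " (se", signif(x$slope_se, 3),
      ", p", format.pval(x$slope_p, digits = 3), ")\n")
  cat("  intercept =", signif(x$intercept, 4),
      " sigma2_bm =", signif(x$sigma2_bm, 4), "\n")
  if (!is.null(x$bootstrap_ci)) {
    cat("  bootstrap", x$bootstrap_ci$level * 100, "% CI for slope: [",
        signif(x$bootstrap_ci$lower, 4), ",",
        signif(x$bootstrap_ci$upper, 4), "] (", x$bootstrap_ci$n_boot,
        "replicates )\n")
  }
  invisible(x)
}

#' Cross-species abundance correlation over ortholog pairs
#'
#' Given reciprocal-best-hit (or otherwise precomputed) ortholog pairs
#' between two species, correlates the log10 fractional abundances of the
#' paired proteins. Pairs not detected in both species are dropped.
#'
#' @param fpA,fpB Fractional-abundance tibbles of the two species.
#' @param pairs Tibble with columns `id_a`, `id_b`.
#' @return A one-row tibble: `rho`, `p_value`, `n_pairs`.
#' @export
rbh_abundance_correlation <- function(fpA, fpB, pairs) {
  a <- setNames(fpA$fraction, fpA$protein_id)[pairs$id_a]
  b <- setNames(fpB$fraction, fpB$protein_id)[pairs$id_b]
  usable <- !is.na(a) & !is.na(b) & a > 0 & b > 0
  if (sum(usable) < 3) {
    abort("fewer than 3 ortholog pairs detected in both species",
          class = "napscan_validation_error")
  }
  res <- spearman(log10(a[usable]), log10(b[usable]))
  tibble(rho = res$rho, p_value = res$p_value, n_pairs = sum(usable))
}

#' Mean number of genes per transcription unit
#'
#' @param om Operon tibble (see [read_operon_table()]).
#' @return Numeric scalar: the arithmetic mean operon size.
#' @export
genes_per_tu <- function(om) {
  sizes <- operon_sizes(om)
  if (nrow(sizes) == 0) {
    abort("operon map is empty", class = "napscan_validation_error")
  }
  mean(sizes$n_genes)
}
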