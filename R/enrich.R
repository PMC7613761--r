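#' Build a log2 intensity matrix from quantification tables
#'
#' Stacks replicate quantification tibbles (one per replicate of a fraction)
#' into a proteins-by-replicates matrix of log2 intensities, with `NA` for
#' proteins missing from a replicate. Zero intensities are treated as
#' missing.
#'
#' @param quants A list of quantification tibbles, or one long tibble with a
#'   `replicate_id` column.
#' @param value Column to use (`"raw_intensity"` or `"lfq_intensity"`).
#' @return A numeric matrix with protein ids as rownames and replicate ids
#'   as colnames.
#' @export
quant_to_log2_matrix <- function(quants, value = "raw_intensity") {
  long <- if (is.data.frame(quants)) quants else dplyr::bind_rows(quants)
  wide <- long |>
    dplyr::mutate(v = ifelse(.data[[value]] > 0, log2(.data[[value]]), NA_real_)) |>
    dplyr::select("protein_id", "replicate_id", "v") |>
    tidyr::pivot_wider(names_from = "replicate_id", values_from = "v")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$protein_id
  m
}

#' Impute left-censored missing values
#'
#' Fills missing cells of a log2 intensity matrix by drawing from a narrow
#' normal distribution shifted below each sample's observed distribution
#' (the usual convention for label-free proteomics, where missingness
#' concentrates at low abundance): missing values in sample `j` are drawn
#' from Normal(mean_j - shift * sd_j, (width * sd_j)^2).
#'
#' @param mat Proteins-by-replicates matrix of log2 intensities with `NA`s.
#' @param shift Downshift of the imputation distribution, in sample-sd units.
#' @param width Width of the imputation distribution, in sample-sd units.
#' @param seed Optional integer seed for reproducible draws.
#' @return The completed matrix.
#' @export
impute_missing <- function(mat, shift = 1.8, width = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j][!is.na(mat[, j])]
    nmiss <- sum(is.na(mat[, j]))
    if (nmiss == 0) next
    if (length(obs) < 2) {
      abort(paste0("sample ", colnames(mat)[j] %||% j,
                   " has fewer than 2 observed values; cannot impute"),
            class = "napscan_validation_error")
    }
    mu <- mean(obs); s <- sd(obs)
    mat[is.na(mat[, j]), j] <- rnorm(nmiss, mu - shift * s, width * s)
  }
  mat
}

# moment-match the scaled-F marginal of per-protein sample variances:
# s_g^2 ~ s0^2 F(d, d0). Returns prior df d0 and prior variance s0^2.
fit_variance_prior <- function(s2, d) {
  m <- mean(s2)
  v <- var(s2)
  cv2 <- v / m^2
  denom <- cv2 * d - 2
  if (!is.finite(denom) || denom <= 1e-8) {
    return(list(d0 = Inf, s0_sq = m))
  }
  d0 <- (2 * d - 4 + 4 * cv2 * d) / denom
  if (!is.finite(d0) || d0 <= 4) {
    # moment solution invalid (needs d0 > 4); fall back to heavy shrinkage
    return(list(d0 = Inf, s0_sq = m))
  }
  list(d0 = d0, s0_sq = m * (d0 - 2) / d0)
}

#' Moderated two-sample test for nucleoid enrichment
#'
#' Compares per-protein log2 intensities between the nucleoid and top
#' fractions with an empirical-Bayes moderated t-test. Per-protein pooled
#' variances \eqn{s_g^2} (on \eqn{d_g} residual df) are shrunk toward a
#' prior variance \eqn{s_0^2} with prior df \eqn{d_0}:
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},}
#' with \eqn{d_0} and \eqn{s_0^2} fitted by moment-matching the marginal
#' scaled-F distribution of the \eqn{s_g^2}. P-values come from a t
#' distribution with \eqn{d_0 + d_g} df and are BH-adjusted across proteins.
#' Positive `log2fc` means nucleoid-enriched.
#'
#' @param nucleoid,top Proteins-by-replicates matrices of imputed log2
#'   intensities, same rownames.
#' @param prior_df Override for \eqn{d_0}: `NULL` (estimate), `0` (ordinary
#'   two-sample t) or `Inf` (fully pooled variance).
#' @return A tibble of class `nap_enrichment` with columns `protein_id`,
#'   `mean_log2_nucleoid`, `mean_log2_top`, `log2fc`, `s2`, `moderated_t`,
#'   `df_total`, `p_value`, `q_value`; attributes `d0` and `s0_sq` hold the
#'   fitted prior.
#' @export
moderated_test <- function(nucleoid, top, prior_df = NULL) {
  if (!identical(rownames(nucleoid), rownames(top))) {
    abort("nucleoid and top matrices must share rownames",
          class = "napscan_validation_error")
  }
  if (any(is.na(nucleoid)) || any(is.na(top))) {
    abort("matrices contain missing values; impute first (impute_missing)",
          class = "napscan_validation_error")
  }
  nA <- ncol(nucleoid); nB <- ncol(top)
  if (nA < 2 || nB < 2) {
    abort("need >= 2 replicates per fraction", class = "napscan_validation_error")
  }
  d <- nA + nB - 2
  mA <- unname(rowMeans(nucleoid)); mB <- unname(rowMeans(top))
  s2 <- unname(rowSums((nucleoid - mA)^2) + rowSums((top - mB)^2)) / d
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else if (prior_df == 0) {
    prior <- list(d0 = 0, s0_sq = 0)
  } else if (is.infinite(prior_df)) {
    prior <- list(d0 = Inf, s0_sq = mean(s2))
  } else {
    prior <- list(d0 = prior_df, s0_sq = fit_variance_prior(s2, d)$s0_sq)
  }
  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
    df_total <- rep(1e6, length(s2))  # effectively normal
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
    df_total <- rep(prior$d0 + d, length(s2))
  }
  tt <- (mA - mB) / sqrt(s2_post * (1 / nA + 1 / nB))
  p <- 2 * pt(-abs(tt), df = df_total)
  out <- tibble(
    protein_id = rownames(nucleoid),
    mean_log2_nucleoid = mA,
    mean_log2_top = mB,
    log2fc = mA - mB,
    s2 = s2,
    moderated_t = tt,
    df_total = df_total,
    p_value = p,
    q_value = p.adjust(p, method = "BH")
  )
  class(out) <- c("nap_enrichment", class(out))
  attr(out, "d0") <- prior$d0
  attr(out, "s0_sq") <- prior$s0_sq
  out
}

#' Rank-sum test for collective enrichment of a protein class
#'
#' Tests whether the nucleoid/top log2 fold changes of proteins carrying a
#' DNA-binding domain (or any other membership set) differ from those of the
#' remaining proteins. The statistic is the rank sum `W` of the member group
#' (average ranks for ties). The two-sided p-value is exact (full
#' enumeration of group assignments) when both groups have at most
#' `exact_max` members, and uses the normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param et An enrichment tibble (see [moderated_test()]), or any tibble
#'   with `protein_id` and `log2fc`.
#' @param members Character vector of protein ids in the class.
#' @param exact_max Group-size bound for exact enumeration.
#' @return A one-row tibble: `statistic` (W), `p_value`, `n_members`,
#'   `n_others`, `method`.
#' @export
domain_class_enrichment <- function(et, members, exact_max = 10) {
  is_member <- et$protein_id %in% members
  x <- et$log2fc[is_member]
  y <- et$log2fc[!is_member]
  if (length(x) == 0 || length(y) == 0) {
    abort("both member and non-member groups must be non-empty",
          class = "napscan_validation_error")
  }
  r <- rank(c(x, y))
  m <- length(x); k <- length(y); n <- m + k
  W <- sum(r[seq_len(m)])
  if (m <= exact_max && k <= exact_max) {
    combos <- utils::combn(n, m)
    Ws <- colSums(matrix(r[combos], nrow = m))
    eps <- 1e-9
    p_hi <- mean(Ws >= W - eps)
    p_lo <- mean(Ws <= W + eps)
    p <- min(1, 2 * min(p_hi, p_lo))
    method <- "exact enumeration"
  } else {
    mu <- m * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- m * k / 12 * ((n + 1) - tie_term)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(statistic = W, p_value = p, n_members = m, n_others = k,
         method = method)
}
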