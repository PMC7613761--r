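#' Candidate-NAP size filter
#'
#' Known NAPs are small; a protein qualifies only if strictly shorter than
#' `max_len` amino acids. The default of 290 is 110% the length of the
#' largest characterized chromatin protein considered (TrmBL2).
#'
#' @param length Protein length(s), amino acids.
#' @param max_len Exclusive upper bound.
#' @return Logical vector.
#' @export
size_filter <- function(length, max_len = 290) {
  length < max_len
}

#' Candidate-NAP DNA-binding filter
#'
#' A protein qualifies if it carries at least one hit to a known DNA-binding
#' domain model, or its external DNA-binding predictor score is strictly
#' positive (OR semantics). Missing scores count as non-positive.
#'
#' @param protein_id Character vector of protein ids.
#' @param hits Domain-hit tibble.
#' @param cls A [domain_classification()].
#' @param scores Score tibble (see [read_dnabinding_scores()]) or named
#'   numeric vector.
#' @return Logical vector, one element per protein id.
#' @export
dna_binding_filter <- function(protein_id, hits, cls, scores) {
  binder_ids <- unique(hits$protein_id[hits_in_models(hits, cls$dna_binding_domains)])
  if (is.data.frame(scores)) {
    scores <- setNames(scores$score, scores$protein_id)
  }
  sc <- scores[protein_id]
  has_score <- !is.na(sc) & sc > 0
  protein_id %in% binder_ids | has_score
}

#' Abundance-outlier filter against the transcription-factor background
#'
#' Tests whether candidate proteins are high-abundance outliers relative to
#' the abundances of predicted transcription factors, using the generalized
#' ESD (Rosner) test. In the default `"leave_one_in"` mode each candidate is
#' appended alone to the TF background and tested, so one extreme candidate
#' cannot mask another; `"pooled"` runs a single test on TFs plus all
#' candidates. A candidate passes if it is ESD-flagged and lies above the
#' median TF abundance (high side only).
#'
#' @param candidate_fractions Named numeric vector (or tibble with
#'   `protein_id`, `fraction`) of candidate abundances, percent of proteome.
#' @param tf_fractions Numeric vector of TF abundances, percent.
#' @param k_max Maximum outliers for the ESD test; default
#'   `max(5, ceiling(0.05 * n))` with `n` the pooled sample size.
#' @param alpha ESD significance level.
#' @param log_transform Log10-transform abundances before testing (protein
#'   abundances are roughly log-normal, so this is the default).
#' @param mode `"leave_one_in"` or `"pooled"`.
#' @return A tibble with columns `protein_id`, `fraction`, `esd_flagged`,
#'   `above_tf_median`, `pass`.
#' @export
abundance_outlier_filter <- function(candidate_fractions, tf_fractions,
                                     k_max = NULL, alpha = 0.05,
                                     log_transform = TRUE,
                                     mode = c("leave_one_in", "pooled")) {
  mode <- match.arg(mode)
  if (is.data.frame(candidate_fractions)) {
    candidate_fractions <- setNames(candidate_fractions$fraction,
                                    candidate_fractions$protein_id)
  }
  if (length(tf_fractions) == 0) {
    abort("tf_fractions must be non-empty", class = "napscan_validation_error")
  }
  tf_med <- median(tf_fractions)
  trans <- if (log_transform) log10 else identity
  ids <- names(candidate_fractions)
  if (mode == "leave_one_in") {
    flagged <- purrr::map_lgl(seq_along(candidate_fractions), function(i) {
      bg <- tf_fractions
      if (!is.null(names(bg)) && !is.null(ids)) {
        bg <- bg[names(bg) != ids[[i]]]
      }
      pool <- c(unname(bg), candidate_fractions[[i]])
      km <- k_max %||% max(5, ceiling(0.05 * length(pool)))
      res <- esd_outliers(trans(pool), k_max = km, alpha = alpha)
      length(pool) %in% res$flagged
    })
  } else {
    pool <- c(tf_fractions, unname(candidate_fractions))
    km <- k_max %||% max(5, ceiling(0.05 * length(pool)))
    res <- esd_outliers(trans(pool), k_max = km, alpha = alpha)
    cand_idx <- length(tf_fractions) + seq_along(candidate_fractions)
    flagged <- cand_idx %in% res$flagged
  }
  above <- unname(candidate_fractions) > tf_med
  tibble(protein_id = ids,
         fraction = unname(candidate_fractions),
         esd_flagged = flagged,
         above_tf_median = above,
         pass = flagged & above)
}

#' Single-gene-operon filter
#'
#' A protein qualifies only if its operon contains exactly one gene.
#' Proteins absent from the operon map fail, with a warning (the
#' conservative default: no evidence of monocistronic organisation).
#'
#' @param protein_id Character vector of protein ids.
#' @param om Operon tibble (see [read_operon_table()]).
#' @return Logical vector.
#' @export
single_operon_filter <- function(protein_id, om) {
  sizes <- operon_sizes(om)
  idx <- operon_index(om)
  op <- idx[protein_id]
  missing <- is.na(op)
  if (any(missing)) {
    warn(paste0(sum(missing), " protein(s) not assigned to any operon; ",
                "treated as failing the single-operon filter"))
  }
  n_genes <- setNames(sizes$n_genes, sizes$operon_id)[op]
  !missing & !is.na(n_genes) & n_genes == 1
}

#' Predict candidate NAPs from a quantified proteome
#'
#' Runs the four-filter prediction pipeline over all detected proteins,
#' excluding known NAPs: (1) length strictly below `max_len`; (2) known
#' DNA-binding domain or positive DNA-binding predictor score; (3)
#' high-abundance outlier relative to predicted transcription factors
#' (generalized ESD test on log10 abundances, high side only); (4) encoded
#' as a single-gene operon (droppable via `relax_operon`). Predicted
#' transcription factors are the detected proteins with at least one hit to
#' the classification's TF domain set.
#'
#' @param fp Fractional-abundance tibble (see [fractional_abundances()]).
#' @param lengths Tibble with `protein_id`, `length` (amino acids), or a
#'   named numeric vector.
#' @param hits Domain-hit tibble.
#' @param cls A [domain_classification()].
#' @param scores DNA-binding predictor scores (tibble or named vector).
#' @param om Operon tibble.
#' @param known_nap_ids Protein ids of known NAPs (excluded from the output
#'   and from the TF background).
#' @param max_len Size-filter bound, amino acids.
#' @param alpha,k_max,log_transform,mode Passed to
#'   [abundance_outlier_filter()].
#' @param relax_operon Drop the single-gene-operon requirement.
#' @param sequences Optional tibble with `protein_id`, `sequence`; when
#'   given, the pI of each candidate is computed.
#' @param keep_all Return the full per-protein filter table rather than
#'   candidates only.
#' @return A tibble of candidates (rows with all four filters passed),
#'   ranked by `fraction` descending, with columns `protein_id`, `length`,
#'   `fraction`, `pI`, the four `pass_*` flags and `rank`. With
#'   `keep_all = TRUE`, one row per assessed protein (`rank` is `NA` for
#'   non-candidates).
#' @export
predict_candidates <- function(fp, lengths, hits, cls, scores, om,
                               known_nap_ids = character(),
                               max_len = 290, alpha = 0.05, k_max = NULL,
                               log_transform = TRUE,
                               mode = c("leave_one_in", "pooled"),
                               relax_operon = FALSE,
                               sequences = NULL,
                               keep_all = FALSE) {
  mode <- match.arg(mode)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$protein_id)
  }
  tab <- fp |>
    dplyr::filter(!.data$protein_id %in% known_nap_ids) |>
    dplyr::arrange(.data$protein_id)
  tab$length <- unname(lengths[tab$protein_id])
  if (any(is.na(tab$length))) {
    warn(paste0(sum(is.na(tab$length)),
                " detected protein(s) without a length; they fail the size filter"))
  }
  tab$pass_size <- !is.na(tab$length) & size_filter(tab$length, max_len)
  tab$pass_dna_binding <- dna_binding_filter(tab$protein_id, hits, cls, scores)

  eligible <- tab$pass_size & tab$pass_dna_binding & tab$fraction > 0
  # background population: predicted TFs (excluding known NAPs); each
  # candidate is dropped from the background when it is itself tested
  tf_ids <- setdiff(
    unique(hits$protein_id[hits_in_models(hits, cls$tf_domains)]),
    known_nap_ids)
  in_tf <- tab$protein_id %in% tf_ids
  tf_fr <- setNames(tab$fraction[in_tf], tab$protein_id[in_tf])
  tab$pass_abundance_outlier <- FALSE
  if (any(eligible) && length(tf_fr) > 0) {
    out <- abundance_outlier_filter(
      setNames(tab$fraction[eligible], tab$protein_id[eligible]),
      tf_fr, k_max = k_max, alpha = alpha,
      log_transform = log_transform, mode = mode)
    tab$pass_abundance_outlier[eligible] <- out$pass
  }

  tab$pass_single_operon <- if (relax_operon) {
    TRUE
  } else {
    single_operon_filter(tab$protein_id, om)
  }

  tab$candidate <- tab$pass_size & tab$pass_dna_binding &
    tab$pass_abundance_outlier & tab$pass_single_operon
  tab$pI <- NA_real_
  if (!is.null(sequences)) {
    seq_map <- setNames(sequences$sequence, sequences$protein_id)
    has_seq <- tab$candidate & tab$protein_id %in% names(seq_map)
    tab$pI[has_seq] <- purrr::map_dbl(seq_map[tab$protein_id[has_seq]],
                                      compute_isoelectric_point)
  }
  tab <- dplyr::arrange(tab, dplyr::desc(.data$fraction))
  tab$rank <- NA_integer_
  tab$rank[tab$candidate] <- seq_len(sum(tab$candidate))
  cols <- c("species_id", "protein_id", "length", "fraction", "pI",
            "pass_size", "pass_dna_binding", "pass_abundance_outlier",
            "pass_single_operon", "candidate", "rank")
  tab <- dplyr::select(tab, dplyr::all_of(cols))
  if (keep_all) tab else dplyr::filter(tab, .data$candidate)
}
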