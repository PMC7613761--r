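#' Fractional proteome abundances
#'
#' Converts per-protein intensities to percentages of the summed intensity of
#' all quantified proteins in the sample. When `prefer_lfq` is set and any
#' LFQ intensities are present, LFQ values are used and rows lacking an LFQ
#' value are dropped from the basis (with a message); otherwise raw
#' intensities are used. The result always sums to 100.
#'
#' @param q A quantification tibble (see [read_quant_table()]).
#' @param prefer_lfq Use LFQ intensities when available.
#' @return A tibble with columns `species_id`, `condition`, `protein_id`,
#'   `fraction` (percent of proteome), carrying attributes
#'   `intensity_basis` (`"raw"` or `"lfq"`) and `n_detected`.
#' @export
#' @examples
#' q <- tibble::tibble(
#'   species_id = "sp1", condition = "whole_cell", replicate_id = "r1",
#'   protein_id = c("A", "B", "C"), raw_intensity = c(50, 30, 20),
#'   lfq_intensity = NA_real_, aliases = NA_character_
#' )
#' fractional_abundances(q)
fractional_abundances <- function(q, prefer_lfq = TRUE) {
  validate_quant_table(q)
  use_lfq <- prefer_lfq && any(!is.na(q$lfq_intensity))
  if (use_lfq) {
    dropped <- sum(is.na(q$lfq_intensity))
    if (dropped > 0) {
      inform(paste0(dropped, " row(s) without LFQ intensity dropped from basis"))
    }
    q <- dplyr::filter(q, !is.na(.data$lfq_intensity))
    x <- q$lfq_intensity
  } else {
    x <- q$raw_intensity
  }
  total <- sum(x)
  if (!is.finite(total) || total <= 0) {
    abort("total intensity is zero; cannot form fractional abundances",
          class = "napscan_validation_error")
  }
  fp <- tibble(
    species_id = q$species_id,
    condition = q$condition,
    protein_id = q$protein_id,
    fraction = 100 * x / total
  )
  attr(fp, "intensity_basis") <- if (use_lfq) "lfq" else "raw"
  attr(fp, "n_detected") <- nrow(fp)
  fp
}

#' Proteome-level quality control
#'
#' A quantified proteome enters the cross-species analysis only if it was
#' measured from whole-cell extract, without size selection, and identified
#' strictly more than `min_proteins` proteins.
#'
#' @param q A quantification tibble.
#' @param meta One row of species metadata (see [read_species_meta()]).
#' @param min_proteins Minimum identified-protein count (exclusive).
#' @return A one-row tibble: `species_id`, `n_proteins`, `pass`, `reasons`.
#' @export
qc_filter <- function(q, meta, min_proteins = 500) {
  n <- length(unique(q$protein_id))
  reasons <- character()
  if (!isTRUE(meta$whole_cell_extract)) reasons <- c(reasons, "not whole-cell extract")
  if (isTRUE(meta$size_selected)) reasons <- c(reasons, "size-selected sample")
  if (n <= min_proteins) {
    reasons <- c(reasons, paste0("only ", n, " identified proteins (need > ",
                                 min_proteins, ")"))
  }
  tibble(species_id = meta$species_id[[1]], n_proteins = n,
         pass = length(reasons) == 0,
         reasons = paste(reasons, collapse = "; "))
}

#' Aggregate NAP investment
#'
#' The summed fractional abundance (percent of proteome) of all detected
#' members of a protein set; the canonical use is the set of known plus
#' candidate NAPs of one species. Proteins in the set that were not detected
#' contribute nothing.
#'
#' @param fp A fractional-abundance tibble (see [fractional_abundances()]).
#' @param nap_ids Character vector of protein ids.
#' @return Summed percent (numeric scalar).
#' @export
investment <- function(fp, nap_ids) {
  sum(fp$fraction[fp$protein_id %in% nap_ids])
}

#' NAP investment normalized by a reference protein class
#'
#' Divides summed NAP abundance by the summed abundance of a reference class
#' expected to scale with ploidy/genome copy number: proteins carrying class
#' I/II tRNA-synthetase domains, or the RNA polymerase largest
#' (second-largest) subunit domain.
#'
#' @inheritParams investment
#' @param hits Domain-hit tibble (see [read_hmm_tblout()]).
#' @param cls A [domain_classification()].
#' @param reference `"trna_synth"`, `"rnap_rpb1"` or `"rnap_rpb2"`.
#' @return Ratio of NAP percent to reference percent (numeric scalar).
#' @export
reference_normalize <- function(fp, nap_ids, hits, cls,
                                reference = c("trna_synth", "rnap_rpb1", "rnap_rpb2")) {
  reference <- match.arg(reference)
  models <- switch(reference,
                   trna_synth = cls$trna_synth_models,
                   rnap_rpb1 = cls$rnap_models[1],
                   rnap_rpb2 = cls$rnap_models[2])
  ref_ids <- unique(hits$protein_id[hits_in_models(hits, models)])
  ref_ab <- investment(fp, ref_ids)
  if (ref_ab <= 0) {
    abort(paste0("no detected abundance for reference class '", reference, "'"),
          class = "napscan_validation_error")
  }
  investment(fp, nap_ids) / ref_ab
}

#' Aggregate abundance by domain class
#'
#' Sums fractional abundance over proteins carrying at least one hit to each
#' class's model set. A protein matching several classes contributes its full
#' fraction to each (no splitting); classes with no detected member get 0.
#'
#' @inheritParams reference_normalize
#' @param classes Named list mapping class name to a character vector of
#'   model names.
#' @return A tibble with columns `class` and `percent`, one row per class.
#' @export
aggregate_by_class <- function(fp, hits, classes) {
  map <- tibble(
    class = rep(names(classes), lengths(classes)),
    model = unlist(classes, use.names = FALSE)
  )
  matched <- hits |>
    dplyr::select("protein_id", "model", "model_accession") |>
    tidyr::pivot_longer(c("model", "model_accession"),
                        values_to = "model", names_to = NULL) |>
    dplyr::inner_join(map, by = "model", relationship = "many-to-many") |>
    dplyr::distinct(.data$class, .data$protein_id)
  sums <- matched |>
    dplyr::inner_join(dplyr::select(fp, "protein_id", "fraction"),
                      by = "protein_id") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(percent = sum(.data$fraction), .groups = "drop")
  tibble(class = names(classes)) |>
    dplyr::left_join(sums, by = "class") |>
    dplyr::mutate(percent = dplyr::coalesce(.data$percent, 0))
}

#' Per-species investment records
#'
#' Convenience wrapper assembling, for one species, the quantities used in
#' the cross-species comparison: total NAP investment (known + candidate),
#' investment in known NAPs only, the two reference-normalized ratios, and
#' proteome coverage.
#'
#' @inheritParams reference_normalize
#' @param known_nap_ids,candidate_nap_ids Character vectors of protein ids.
#' @param predicted_proteome_size Number of proteins encoded in the genome.
#' @return A one-row tibble: `species_id`, `nap_percent`,
#'   `nap_percent_known_only`, `normalized_by_trna_synth`,
#'   `normalized_by_rnap`, `coverage`, `n_detected`.
#' @export
investment_record <- function(fp, known_nap_ids, candidate_nap_ids, hits, cls,
                              predicted_proteome_size) {
  nap_ids <- union(known_nap_ids, candidate_nap_ids)
  n_det <- attr(fp, "n_detected") %||% nrow(fp)
  cov <- min(1, n_det / predicted_proteome_size)
  by_trna <- tryCatch(
    reference_normalize(fp, nap_ids, hits, cls, "trna_synth"),
    error = function(e) NA_real_)
  by_rnap <- tryCatch(
    reference_normalize(fp, nap_ids, hits, cls, "rnap_rpb1"),
    error = function(e) NA_real_)
  tibble(
    species_id = fp$species_id[[1]],
    nap_percent = investment(fp, nap_ids),
    nap_percent_known_only = investment(fp, known_nap_ids),
    normalized_by_trna_synth = by_trna,
    normalized_by_rnap = by_rnap,
    coverage = cov,
    n_detected = n_det
  )
}

#' EMBOSS-style pKa values for isoelectric-point calculation
#'
#' @return Named list with `positive` and `negative` pKa sets (including the
#'   termini).
#' @export
pka_emboss <- function() {
  list(
    positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
    negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
  )
}

#' Isoelectric point of a protein sequence
#'
#' Computes the pH at which the net charge of the sequence is zero. Charge is
#' the Henderson-Hasselbalch sum over ionizable side chains and the two
#' termini; since that function is strictly decreasing in pH, the root is
#' found by bisection.
#'
#' @param sequence Amino-acid string (standard 20 one-letter codes).
#' @param pka pKa set; see [pka_emboss()].
#' @param tol Bisection tolerance (pH units).
#' @return The pI (numeric scalar, pH units).
#' @export
#' @examples
#' compute_isoelectric_point("KKKKK") > 7
#' compute_isoelectric_point("DDDDD") < 7
compute_isoelectric_point <- function(sequence, pka = pka_emboss(), tol = 1e-6) {
  if (length(sequence) != 1 || is.na(sequence) || !nzchar(sequence)) {
    abort("sequence must be a non-empty string",
          class = "napscan_validation_error")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aa %in% standard)) {
    abort(paste0("non-standard residue(s): ",
                 paste(unique(setdiff(aa, standard)), collapse = ", ")),
          class = "napscan_validation_error")
  }
  counts <- table(factor(aa, levels = standard))
  net_charge <- function(ph) {
    pos <- pka$positive
    neg <- pka$negative
    n_pos <- c(Nterm = 1, K = counts[["K"]], R = counts[["R"]], H = counts[["H"]])
    n_neg <- c(Cterm = 1, D = counts[["D"]], E = counts[["E"]],
               C = counts[["C"]], Y = counts[["Y"]])
    sum(n_pos / (1 + 10^(ph - pos[names(n_pos)]))) -
      sum(n_neg / (1 + 10^(neg[names(n_neg)] - ph)))
  }
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
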