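#' Presence/absence of NAP families across genomes
#'
#' Calls each known NAP family present in a genome if the genome has at least
#' one qualifying hit to any of the family's models. Hit tables are assumed
#' to have been produced with per-model gathering thresholds, so every
#' PFAM/TIGR hit row counts; an optional stricter e-value cutoff can be
#' layered on top. Hits from iterative profile searches (`JACKHMMER` source,
#' used for families without a curated model, e.g. CC1) additionally require
#' `e_value <= jackhmmer_cutoff`.
#'
#' @param hits_by_genome Named list mapping genome id to a domain-hit tibble
#'   (see [read_hmm_tblout()]); a `NULL` entry yields an all-absent row with
#'   a warning.
#' @param cls A [domain_classification()].
#' @param evalue_cutoff Optional stricter e-value threshold applied to every
#'   hit (`NULL` = gathering thresholds only).
#' @param jackhmmer_cutoff E-value threshold for `JACKHMMER`-source hits.
#' @return A tibble with one row per genome: a `genome` column plus one
#'   logical column per NAP family, of class `nap_presence`.
#' @export
call_presence <- function(hits_by_genome, cls, evalue_cutoff = NULL,
                          jackhmmer_cutoff = 1e-5) {
  families <- names(cls$nap_family_models)
  rows <- purrr::imap(hits_by_genome, function(hits, genome) {
    if (is.null(hits) || nrow(hits) == 0) {
      if (is.null(hits)) {
        warn(paste0("no hit table for genome ", genome, "; calling all families absent"))
      }
      pres <- rep(FALSE, length(families))
    } else {
      ok <- rep(TRUE, nrow(hits))
      if (!is.null(evalue_cutoff)) ok <- ok & hits$e_value <= evalue_cutoff
      ok <- ok & (hits$source != "JACKHMMER" | hits$e_value <= jackhmmer_cutoff)
      pres <- purrr::map_lgl(cls$nap_family_models, function(models) {
        any(ok & hits_in_models(hits, models))
      })
    }
    tibble(genome = genome, !!!setNames(as.list(pres), families))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nap_presence", class(out))
  attr(out, "families") <- families
  out
}

#' Pairwise co-occurrence of NAP families
#'
#' Counts, for every pair of families, the number of genomes carrying both.
#' The diagonal (`family_a == family_b`) is each family's prevalence.
#'
#' @param pa A presence/absence tibble from [call_presence()].
#' @return A tibble with columns `family_a`, `family_b`, `n_genomes`, of
#'   class `nap_cooccurrence` (symmetric: both orientations present).
#' @export
cooccurrence <- function(pa) {
  families <- attr(pa, "families") %||% setdiff(names(pa), "genome")
  m <- as.matrix(as.data.frame(pa)[, families, drop = FALSE]) * 1L
  cc <- t(m) %*% m
  out <- as_tibble(as.data.frame.table(cc, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(out) <- c("family_a", "family_b", "n_genomes")
  out$n_genomes <- as.integer(out$n_genomes)
  class(out) <- c("nap_cooccurrence", class(out))
  out
}

#' Number of NAP families per genome
#'
#' @inheritParams cooccurrence
#' @return A tibble with columns `genome` and `n_naps`.
#' @export
naps_per_genome <- function(pa) {
  families <- attr(pa, "families") %||% setdiff(names(pa), "genome")
  tibble(
    genome = pa$genome,
    n_naps = as.integer(rowSums(as.data.frame(pa)[, families, drop = FALSE]))
  )
}
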