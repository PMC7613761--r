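#' Column-name dialect for protein quantification tables
#'
#' Upstream quantification tools differ in how they label the protein-id and
#' intensity columns of their per-sample output (`proteinGroups`-style tables
#' being the most common). A dialect maps those labels onto the columns
#' [read_quant_table()] expects. The defaults follow the MaxQuant convention.
#'
#' @param protein_id Name of the protein-id column.
#' @param raw_intensity Name of the raw-intensity column.
#' @param lfq_intensity Name of the (optional) label-free-quantification
#'   intensity column.
#' @return A named list of class `quant_dialect`.
#' @export
#' @examples
#' quant_dialect()
#' quant_dialect(protein_id = "Accession", raw_intensity = "iBAQ")
quant_dialect <- function(protein_id = "Protein IDs",
                          raw_intensity = "Intensity",
                          lfq_intensity = "LFQ intensity") {
  structure(
    list(protein_id = protein_id,
         raw_intensity = raw_intensity,
         lfq_intensity = lfq_intensity),
    class = "quant_dialect"
  )
}

#' Read a per-sample protein quantification table
#'
#' Reads a tab-separated table of protein intensities (one row per protein
#' group) into the tidy quantification format used throughout the package:
#' one row per protein with `species_id`, `condition`, `replicate_id`,
#' `protein_id`, `raw_intensity` and `lfq_intensity` columns. Protein-group
#' rows listing several ids separated by `;` are reduced to their first id;
#' the remainder is kept in an `aliases` column.
#'
#' Zero-intensity rows are retained; duplicated protein ids and negative
#' intensities are errors. The LFQ column is optional (filled with `NA` when
#' absent).
#'
#' @param path Path to a tab-separated file with a header row.
#' @param species_id,condition,replicate_id Sample annotation attached to
#'   every row.
#' @param dialect A [quant_dialect()] mapping column names.
#' @return A tibble with columns `species_id`, `condition`, `replicate_id`,
#'   `protein_id`, `raw_intensity`, `lfq_intensity`, `aliases`.
#' @export
read_quant_table <- function(path, species_id, condition = "whole_cell",
                             replicate_id = "r1",
                             dialect = quant_dialect()) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c(dialect$protein_id, dialect$raw_intensity)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("quant table ", path, " lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "napscan_format_error")
  }
  has_lfq <- dialect$lfq_intensity %in% names(raw)
  ids_full <- as.character(raw[[dialect$protein_id]])
  first_id <- sub(";.*$", "", ids_full)
  aliases <- ifelse(grepl(";", ids_full), sub("^[^;]*;", "", ids_full), NA_character_)
  q <- tibble(
    species_id = species_id,
    condition = condition,
    replicate_id = replicate_id,
    protein_id = first_id,
    raw_intensity = as.numeric(raw[[dialect$raw_intensity]]),
    lfq_intensity = if (has_lfq) as.numeric(raw[[dialect$lfq_intensity]]) else NA_real_,
    aliases = aliases
  )
  validate_quant_table(q)
  q
}

#' @rdname read_quant_table
#' @param q A quantification tibble as returned by [read_quant_table()].
#' @export
write_quant_table <- function(q, path, dialect = quant_dialect()) {
  validate_quant_table(q)
  id <- ifelse(is.na(q$aliases), q$protein_id,
               paste(q$protein_id, q$aliases, sep = ";"))
  out <- tibble(!!dialect$protein_id := id,
                !!dialect$raw_intensity := q$raw_intensity,
                !!dialect$lfq_intensity := q$lfq_intensity)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

validate_quant_table <- function(q) {
  if (nrow(q) == 0) {
    abort("quant table has no rows", class = "napscan_validation_error")
  }
  if (anyDuplicated(q$protein_id)) {
    dups <- unique(q$protein_id[duplicated(q$protein_id)])
    abort(paste0("duplicated protein id(s): ",
                 paste(head(dups, 5), collapse = ", ")),
          class = "napscan_validation_error")
  }
  bad <- q$raw_intensity < 0 | (!is.na(q$lfq_intensity) & q$lfq_intensity < 0)
  if (any(bad, na.rm = TRUE)) {
    abort("negative intensities are not allowed",
          class = "napscan_validation_error")
  }
  invisible(q)
}

#' Read an hmmer3 `--tblout` domain hit table
#'
#' Parses the per-sequence tabular output of `hmmsearch`/`jackhmmer`
#' (`--tblout`). The layout is whitespace-delimited with 18 fixed fields
#' followed by a free-text description that may itself contain spaces; lines
#' starting with `#` are comments. One row is produced per non-comment line.
#'
#' The model is identified by the query accession when present, falling back
#' to the query name (jackhmmer runs usually have no accession). The query
#' name is always kept in `model`, which is what the curated domain sets in
#' [domain_classification()] are keyed on.
#'
#' @param path Path to a `--tblout` file.
#' @param source One of `"PFAM"`, `"TIGR"`, `"JACKHMMER"`: which model
#'   collection produced the hits.
#' @return A tibble with columns `protein_id`, `model`, `model_accession`,
#'   `source`, `e_value`, `bit_score`, `description`.
#' @export
read_hmm_tblout <- function(path, source = c("PFAM", "TIGR", "JACKHMMER")) {
  source <- match.arg(source)
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(protein_id = character(), model = character(),
                  model_accession = character(), source = character(),
                  e_value = numeric(), bit_score = numeric(),
                  description = character()))
  }
  line_no <- which(keep)
  parsed <- purrr::map2(lines, line_no, function(ln, no) {
    fields <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(fields) < 18) {
      abort(paste0("malformed tblout line ", no, " in ", path,
                   ": expected >= 18 fields, got ", length(fields)),
            class = "napscan_parse_error")
    }
    desc <- if (length(fields) > 18) paste(fields[-(1:18)], collapse = " ") else ""
    list(protein_id = fields[1],
         query_name = fields[3],
         query_acc = fields[4],
         e_value = as.numeric(fields[5]),
         bit_score = as.numeric(fields[6]),
         description = desc)
  })
  hits <- tibble(
    protein_id = purrr::map_chr(parsed, "protein_id"),
    model = purrr::map_chr(parsed, "query_name"),
    model_accession = purrr::map_chr(parsed, "query_acc"),
    source = source,
    e_value = purrr::map_dbl(parsed, "e_value"),
    bit_score = purrr::map_dbl(parsed, "bit_score"),
    description = purrr::map_chr(parsed, "description")
  )
  hits$model_accession <- ifelse(hits$model_accession %in% c("-", ""),
                                 hits$model, hits$model_accession)
  if (any(!is.finite(hits$e_value)) || any(hits$e_value <= 0)) {
    abort(paste0("non-positive or non-numeric e-value in ", path),
          class = "napscan_validation_error")
  }
  hits
}

#' @rdname read_hmm_tblout
#' @param hits A hit tibble as returned by [read_hmm_tblout()].
#' @export
write_hmm_tblout <- function(hits, path) {
  header <- c(
    "#                                                               --- full sequence ---",
    "# target name        accession  query name           accession    E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
    "#------------------- ---------- -------------------- ---------- --------- ------ ----- ----- --- --- --- --- --- --- --- --- ---------------------"
  )
  body <- sprintf("%s - %s %s %.6g %.1f 0.0 %.6g %.1f 0.0 1.0 1 0 0 1 1 1 1 %s",
                  hits$protein_id, hits$model, hits$model_accession,
                  hits$e_value, hits$bit_score,
                  hits$e_value, hits$bit_score,
                  ifelse(nzchar(hits$description), hits$description, "-"))
  readr::write_lines(c(header, body, "#"), path)
  invisible(path)
}

#' Read an operon membership table
#'
#' Reads a TSV with columns `operon_id`, `position`, `protein_id` (the format
#' distilled from external operon predictors such as Operon Mapper). Gene
#' order within each operon is preserved via `position`. A protein assigned
#' to two different operons is an error.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `operon_id`, `position`, `protein_id`,
#'   sorted by operon and position.
#' @export
read_operon_table <- function(path) {
  om <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          operon_id = readr::col_character(),
                          position = readr::col_integer(),
                          protein_id = readr::col_character()))
  validate_operon_table(om)
  dplyr::arrange(om, .data$operon_id, .data$position)
}

#' @rdname read_operon_table
#' @param om An operon tibble.
#' @export
write_operon_table <- function(om, path) {
  validate_operon_table(om)
  readr::write_tsv(om, path, progress = FALSE)
  invisible(path)
}

validate_operon_table <- function(om) {
  need <- c("operon_id", "position", "protein_id")
  if (!all(need %in% names(om))) {
    abort("operon table must have columns operon_id, position, protein_id",
          class = "napscan_format_error")
  }
  multi <- om |>
    dplyr::distinct(.data$protein_id, .data$operon_id) |>
    dplyr::count(.data$protein_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("protein(s) assigned to more than one operon: ",
                 paste(head(multi$protein_id, 5), collapse = ", ")),
          class = "napscan_validation_error")
  }
  invisible(om)
}

#' Sizes of operons and protein-to-operon index
#'
#' @param om An operon tibble (see [read_operon_table()]).
#' @return `operon_sizes()`: a tibble with `operon_id` and `n_genes`.
#'   `operon_index()`: a named character vector mapping protein id to
#'   operon id.
#' @export
operon_sizes <- function(om) {
  dplyr::count(om, .data$operon_id, name = "n_genes")
}

#' @rdname operon_sizes
#' @export
operon_index <- function(om) {
  setNames(om$operon_id, om$protein_id)
}

#' Read a species metadata table
#'
#' Reads a TSV with one row per species: `species_id`, `ogt` (optimal growth
#' temperature, degrees Celsius), optional `ph`, `doubling_time` (hours),
#' `genome_size` (bp), `predicted_proteome_size` (protein count), and the
#' sample flags `whole_cell_extract` and `size_selected`.
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per species.
#' @export
read_species_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("species_id", "ogt") %in% names(meta))) {
    abort("species metadata must have species_id and ogt columns",
          class = "napscan_format_error")
  }
  if (!is.numeric(meta$ogt)) {
    abort("non-numeric OGT in species metadata",
          class = "napscan_validation_error")
  }
  bad <- !is.na(meta$ogt) & (meta$ogt < 0 | meta$ogt > 130)
  if (any(bad)) {
    abort("OGT outside the plausible range [0, 130] degrees C",
          class = "napscan_validation_error")
  }
  if ("predicted_proteome_size" %in% names(meta) &&
      any(meta$predicted_proteome_size <= 0, na.rm = TRUE)) {
    abort("predicted_proteome_size must be positive",
          class = "napscan_validation_error")
  }
  for (col in c("ph", "doubling_time", "genome_size", "predicted_proteome_size")) {
    if (!col %in% names(meta)) meta[[col]] <- NA_real_
  }
  for (col in c("whole_cell_extract", "size_selected")) {
    if (!col %in% names(meta)) {
      meta[[col]] <- col == "whole_cell_extract"
    }
  }
  meta
}

#' @rdname read_species_meta
#' @param meta A species metadata tibble.
#' @export
write_species_meta <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a species tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Tip labels must be
#' unique and branch lengths non-negative; polytomies are allowed.
#' Zero-length branches (common in large reference trees) are tolerated but
#' reported.
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_nap_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) {
    abort(paste0("could not parse Newick file ", path),
          class = "napscan_parse_error")
  }
  validate_nap_tree(tree)
}

#' @rdname read_nap_tree
#' @param tree A `phylo` object.
#' @export
write_nap_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_nap_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    abort("tree tip labels are not unique", class = "napscan_validation_error")
  }
  if (!is.null(tree$edge.length)) {
    if (any(tree$edge.length < 0)) {
      abort("tree has negative branch lengths",
            class = "napscan_validation_error")
    }
    if (any(tree$edge.length == 0)) {
      inform("tree contains zero-length branches")
    }
  }
  tree
}

#' Read a DNA-binding predictor score table
#'
#' Reads a TSV with columns `protein_id` and `score` holding per-protein
#' scores from an external DNA-binding predictor (an SVM decision value;
#' positive scores are taken downstream as predicted binders). Scores may be
#' any real number.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `protein_id` and `score`.
#' @export
read_dnabinding_scores <- function(path) {
  sc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("protein_id", "score") %in% names(sc))) {
    abort("score table must have protein_id and score columns",
          class = "napscan_format_error")
  }
  if (!is.numeric(sc$score)) {
    abort("non-numeric DNA-binding scores", class = "napscan_validation_error")
  }
  sc
}

#' @rdname read_dnabinding_scores
#' @param scores A score tibble.
#' @export
write_dnabinding_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}

#' Curated domain sets used across the package
#'
#' Bundles the domain-model sets the analyses rely on: models diagnostic of
#' DNA binding, the transcription-factor set (the DNA-binding list plus the
#' sequence-specific DNA-binding GO category), one model set per known NAP
#' family (Alba, CC1, Cren7, Histone, HU, MC1, Sul7), and the reference sets
#' used for normalization (class I/II tRNA synthetases; RNA polymerase
#' largest/second-largest subunit domains).
#'
#' The default lists are curated from public model collections and are
#' intentionally editable: model collections evolve between releases, so
#' treat the defaults as a reasonable starting point, not a canonical
#' registry. Sets are keyed on model names (as they appear in the `model`
#' column of [read_hmm_tblout()] output); matching also falls back to
#' accessions.
#'
#' @param dna_binding_domains Character vector of DNA-binding model names.
#' @param tf_domains Character vector of transcription-factor model names.
#' @param nap_family_models Named list mapping NAP family name to a character
#'   vector of model names.
#' @param trna_synth_models Character vector of tRNA-synthetase model names.
#' @param rnap_models Character vector of RNA-polymerase subunit model names.
#' @return An object of class `domain_classification`.
#' @export
domain_classification <- function(dna_binding_domains,
                                  tf_domains,
                                  nap_family_models,
                                  trna_synth_models = c("tRNA-synth_1", "tRNA-synth_2"),
                                  rnap_models = c("RNA_pol_Rpb1_3", "RNA_pol_Rpb2_3")) {
  stopifnot(length(dna_binding_domains) > 0, length(tf_domains) > 0,
            length(nap_family_models) > 0, length(trna_synth_models) > 0,
            length(rnap_models) > 0)
  if (is.null(names(nap_family_models)) ||
      anyDuplicated(names(nap_family_models))) {
    abort("nap_family_models must be a uniquely named list",
          class = "napscan_validation_error")
  }
  if (any(lengths(nap_family_models) == 0)) {
    abort("every NAP family needs at least one model",
          class = "napscan_validation_error")
  }
  structure(
    list(dna_binding_domains = unique(dna_binding_domains),
         tf_domains = unique(tf_domains),
         nap_family_models = lapply(nap_family_models, unique),
         trna_synth_models = unique(trna_synth_models),
         rnap_models = unique(rnap_models)),
    class = "domain_classification"
  )
}

#' @rdname domain_classification
#' @export
default_domain_classification <- function() {
  nap_families <- list(
    Alba    = c("Alba", "PF01918"),
    CC1     = c("CC1", "G4RKF6_jackhmmer"),
    Cren7   = c("Cren7", "PF11520"),
    Histone = c("CBFD_NFYB_HMF", "PF00808"),
    HU      = c("Bac_DNA_binding", "PF00216"),
    MC1     = c("MC1", "PF07382"),
    Sul7    = c("7kD_DNA_binding", "PF02294")
  )
  tf_pool <- c("HTH_1", "HTH_3", "TrmB", "PadR", "AsnC_trans_reg", "MarR",
               "ArsR", "Fe_dep_repress", "CopG_Arc_RHH", "Rrf2", "PhoU",
               "HrcA_DNA-bdg", "TFB", "TBP")
  dna_binding <- unique(c(
    unlist(nap_families, use.names = FALSE),
    tf_pool,
    c("HMG_box", "ribbon_helix_helix", "SSB", "zf-C2H2_archaeal",
      "Arg_repressor", "LexA_DNA_bind", "ParB_like")
  ))
  domain_classification(
    dna_binding_domains = dna_binding,
    tf_domains = unique(c(dna_binding, tf_pool)),
    nap_family_models = nap_families
  )
}

#' @export
print.domain_classification <- function(x, ...) {
  cat("<domain_classification>\n")
  cat("  DNA-binding models:", length(x$dna_binding_domains), "\n")
  cat("  TF models:         ", length(x$tf_domains), "\n")
  cat("  NAP families:      ", paste(names(x$nap_family_models), collapse = ", "), "\n")
  cat("  tRNA-synth models: ", paste(x$trna_synth_models, collapse = ", "), "\n")
  cat("  RNAP models:       ", paste(x$rnap_models, collapse = ", "), "\n")
  invisible(x)
}

# match hit rows against a model set (by name or accession)
hits_in_models <- function(hits, models) {
  hits$model %in% models | hits$model_accession %in% models
}
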