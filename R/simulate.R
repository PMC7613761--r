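#' Parameters of the synthetic study generator
#'
#' Collects the generator's tunable parameters with defaults chosen to
#' emulate the statistical structure of a cross-archaea quantitative
#' proteomics study: NAP investment is linear in optimal growth temperature,
#' `beta0 + beta1 * OGT + noise`, truncated below at 0.01%. The default
#' linear coefficients put the expected investment at 37 degrees C near
#' 0.75% and the maximum across a 24-98 degree span near 5.4%, the regime of
#' real archaeal proteomes; they are a calibration, not ground truth.
#'
#' @param beta0 Intercept of the investment-vs-OGT line (percent).
#' @param beta1 Slope (percent per degree C).
#' @param noise_sd Residual sd of investment (percent).
#' @param root_ogt OGT at the tree root (degrees C).
#' @param bm_rate Brownian-motion rate of OGT evolution (degrees C squared
#'   per unit branch length; trees are scaled to unit depth).
#' @param ogt_bounds Reflecting bounds for OGT (degrees C).
#' @param proteome_size Number of detected proteins per species.
#' @param abundance_log_sd Log10 sd of the long-tailed abundance
#'   distribution.
#' @param tf_fraction Fraction of proteins that are transcription factors.
#' @param enrichment_effect Nucleoid-vs-top shift of true NAPs (log2 units).
#' @param rep_sd Replicate noise sd of enrichment intensities (log2 units).
#' @param missing_rate Overall missingness rate of enrichment intensities
#'   (missing-at-low-abundance).
#' @param n_reps Replicates per fraction in the enrichment assay.
#' @param n_background_domains Number of non-NAP background domain families.
#' @return A named list of class `study_params`.
#' @export
study_params <- function(beta0 = -2.0, beta1 = 0.075, noise_sd = 0.6,
                         root_ogt = 70, bm_rate = 2500,
                         ogt_bounds = c(24, 98),
                         proteome_size = 2000, abundance_log_sd = 1.2,
                         tf_fraction = 0.05, enrichment_effect = 2.5,
                         rep_sd = 0.5, missing_rate = 0.1, n_reps = 3,
                         n_background_domains = 150) {
  p <- list(beta0 = beta0, beta1 = beta1, noise_sd = noise_sd,
            root_ogt = root_ogt, bm_rate = bm_rate, ogt_bounds = ogt_bounds,
            proteome_size = proteome_size, abundance_log_sd = abundance_log_sd,
            tf_fraction = tf_fraction, enrichment_effect = enrichment_effect,
            rep_sd = rep_sd, missing_rate = missing_rate, n_reps = n_reps,
            n_background_domains = n_background_domains)
  stopifnot(p$proteome_size > 10, p$noise_sd >= 0, p$bm_rate >= 0,
            p$ogt_bounds[1] < p$ogt_bounds[2], p$tf_fraction > 0,
            p$missing_rate >= 0, p$missing_rate < 1, p$n_reps >= 2)
  structure(p, class = "study_params")
}

#' Simulate a species tree
#'
#' Draws a pure-birth (Yule) tree, rescales it to unit root-to-tip depth and
#' labels tips `sp01 ... spNN`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object of unit depth.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (n_tips < 3) abort("n_tips must be >= 3", class = "napscan_validation_error")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Simulate optimal growth temperatures on a tree
#'
#' Evolves OGT along the tree by Brownian motion from `root_ogt`, reflecting
#' excursions back into `bounds` (so the trait stays in the physiologically
#' plausible range while retaining phylogenetic covariance on short
#' branches).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param root_ogt Root state (degrees C).
#' @param bm_rate BM rate (degrees C squared per unit branch length).
#' @param bounds Reflecting bounds.
#' @param seed Integer seed.
#' @return A tibble with columns `species_id` and `ogt`.
#' @export
simulate_ogt <- function(tree, root_ogt = 70, bm_rate = 2500,
                         bounds = c(24, 98), seed = 1) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  tr <- stats::reorder(tree, "cladewise")
  val <- numeric(n + tr$Nnode)
  val[n + 1] <- root_ogt
  reflect <- function(v) {
    w <- bounds[2] - bounds[1]
    z <- (v - bounds[1]) %% (2 * w)
    bounds[1] + ifelse(z > w, 2 * w - z, z)
  }
  for (k in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[k, 1]; child <- tr$edge[k, 2]
    val[child] <- reflect(val[parent] +
                            rnorm(1, 0, sqrt(bm_rate * tr$edge.length[k])))
  }
  tibble(species_id = tr$tip.label, ogt = val[seq_len(n)])
}

# internal domain pools used by the generator (all drawn from the default
# classification so generated hit tables resolve against it)
generator_pools <- function(params) {
  cls <- default_domain_classification()
  list(
    cls = cls,
    tf_pool = c("HTH_1", "HTH_3", "TrmB", "PadR", "AsnC_trans_reg", "MarR",
                "ArsR", "Fe_dep_repress", "CopG_Arc_RHH", "Rrf2",
                "HrcA_DNA-bdg", "TFB", "TBP"),
    novel_binding_pool = c("HMG_box", "ribbon_helix_helix", "SSB",
                           "zf-C2H2_archaeal", "HrcA_DNA-bdg"),
    background_pool = sprintf("BG_dom_%03d", seq_len(params$n_background_domains))
  )
}

#' Simulate one quantified proteome with spiked NAPs
#'
#' Generates, for one species, everything the prediction pipeline consumes:
#' a quantification table with long-tailed (log-normal) abundances, protein
#' lengths, domain hits, an operon map, DNA-binding predictor scores and the
#' ground-truth NAP labels. One to three true NAPs (60-120 aa, DNA-binding
#' evidence, single-gene operons) are spiked in and the remaining abundances
#' renormalized so the NAPs' summed fractional abundance equals the target
#' `beta0 + beta1 * ogt + noise`, truncated to at least 0.01%. With
#' probability 1/2 the first NAP belongs to a known NAP family (carrying the
#' family's domain model and listed in `known_nap_ids`); the rest are novel
#' candidates. Transcription factors (a `tf_fraction` share of the proteome)
#' get mid-range abundances and TF domains, and decoy proteins failing
#' exactly one filter each (abundant non-binder; abundant binder in a
#' two-gene operon; large abundant binder) exercise every filter.
#'
#' @param species_id Species label.
#' @param ogt Optimal growth temperature (degrees C).
#' @param params A [study_params()] list.
#' @param seed Integer seed.
#' @return A list with elements `quant`, `lengths`, `hits`, `operons`,
#'   `dnabind`, `known_nap_ids`, `novel_nap_ids`, `true_nap_ids`,
#'   `target_percent`.
#' @export
simulate_proteome <- function(species_id, ogt, params = study_params(),
                              seed = 1) {
  set.seed(seed)
  pools <- generator_pools(params)
  size <- params$proteome_size
  target <- max(params$beta0 + params$beta1 * ogt +
                  rnorm(1, 0, params$noise_sd), 0.01)
  if (target >= 100) {
    abort("target NAP percent >= 100; check generator parameters",
          class = "napscan_validation_error")
  }
  n_nap <- min(3L, max(1L, as.integer(round(target / 1.2)) + 1L))
  ids <- sprintf("%s_p%04d", species_id, seq_len(size))
  nap_idx <- seq_len(n_nap)
  n_tf <- max(3L, round(params$tf_fraction * size))
  tf_idx <- n_nap + seq_len(n_tf)
  # decoys: 2 abundant non-binders, 2 abundant binders in 2-gene operons,
  # 2 large abundant binders
  dec_b <- max(tf_idx) + 1:2
  dec_c <- max(dec_b) + 1:2
  dec_d <- max(dec_c) + 1:2
  bg_idx <- (max(dec_d) + 1):size

  # abundance weights (relative); background long-tailed, TFs mid-range
  w <- numeric(size)
  w[bg_idx] <- 10^rnorm(length(bg_idx), 0, params$abundance_log_sd)
  w[tf_idx] <- 10^rnorm(n_tf, 0, 0.25)
  w[c(dec_b, dec_c, dec_d)] <- 10^runif(6, 1.5, 2.5)
  w_other_sum <- sum(w[-nap_idx])
  total_w <- w_other_sum / (1 - target / 100)
  props <- runif(n_nap, 0.5, 1.5)
  w[nap_idx] <- total_w * (target / 100) * props / sum(props)

  lengths <- integer(size)
  lengths[nap_idx] <- sample(60:120, n_nap, replace = TRUE)
  lengths[tf_idx] <- sample(90:280, n_tf, replace = TRUE)
  lengths[dec_b] <- sample(60:150, 2, replace = TRUE)
  lengths[dec_c] <- sample(60:150, 2, replace = TRUE)
  lengths[dec_d] <- sample(300:600, 2, replace = TRUE)
  lengths[bg_idx] <- sample(80:600, length(bg_idx), replace = TRUE)

  # domain hits
  known_first <- runif(1) < 0.5
  hit_rows <- list()
  add_hits <- function(idx, models, source = "PFAM") {
    if (length(idx) == 0) return(NULL)
    tibble(protein_id = ids[idx], model = models,
           model_accession = models, source = source,
           e_value = 10^runif(length(idx), -30, -6),
           bit_score = runif(length(idx), 30, 300),
           description = "")
  }
  known_ids <- character()
  novel_idx <- nap_idx
  if (known_first) {
    fam <- sample(names(pools$cls$nap_family_models), 1)
    hit_rows <- c(hit_rows, list(add_hits(1L, pools$cls$nap_family_models[[fam]][1])))
    known_ids <- ids[1]
    novel_idx <- setdiff(nap_idx, 1L)
  }
  # novel NAPs: half carry a generic DNA-binding domain, half rely on the
  # external predictor score alone
  nv_dom <- novel_idx[seq_along(novel_idx) %% 2 == 1]
  nv_score_only <- setdiff(novel_idx, nv_dom)
  hit_rows <- c(hit_rows, list(
    add_hits(nv_dom, sample(pools$novel_binding_pool, length(nv_dom), replace = TRUE)),
    add_hits(tf_idx, sample(pools$tf_pool, n_tf, replace = TRUE)),
    add_hits(dec_c, sample(pools$novel_binding_pool, 2, replace = TRUE)),
    add_hits(dec_d, sample(pools$novel_binding_pool, 2, replace = TRUE))
  ))
  # background domains (non-binding), ~1 hit per protein on average
  n_bg_hits <- stats::rbinom(1, length(bg_idx), 0.8)
  bg_carriers <- sample(bg_idx, n_bg_hits, replace = TRUE)
  hit_rows <- c(hit_rows, list(
    add_hits(bg_carriers, sample(pools$background_pool, n_bg_hits, replace = TRUE))
  ))
  # reference classes for normalization
  ref_trna <- sample(bg_idx, 20)
  ref_rnap1 <- sample(setdiff(bg_idx, ref_trna), 2)
  ref_rnap2 <- sample(setdiff(bg_idx, c(ref_trna, ref_rnap1)), 2)
  hit_rows <- c(hit_rows, list(
    add_hits(ref_trna, sample(c("tRNA-synth_1", "tRNA-synth_2"), 20, replace = TRUE)),
    add_hits(ref_rnap1, "RNA_pol_Rpb1_3"),
    add_hits(ref_rnap2, "RNA_pol_Rpb2_3")
  ))
  hits <- dplyr::bind_rows(hit_rows)

  # DNA-binding predictor scores: non-binders strictly negative (binding
  # evidence is carried only by designated proteins, so the filters'
  # discriminating work falls on the constructed decoys); positive for
  # score-only novel NAPs
  score <- -abs(rnorm(size, 1, 0.5))
  score[nv_score_only] <- runif(length(nv_score_only), 0.5, 2)
  dnabind <- tibble(protein_id = ids, score = score)

  # operons: NAPs and abundant-non-binder decoys single-gene; dec_c in
  # 2-gene operons; everything else chunked into units of mean size ~1.8
  op_rows <- list(
    tibble(operon_id = paste0(species_id, "_opN", seq_len(n_nap)),
           position = 1L, protein_id = ids[nap_idx]),
    tibble(operon_id = paste0(species_id, "_opB", 1:2),
           position = 1L, protein_id = ids[dec_b]),
    {
      partners <- sample(bg_idx, 2)
      tibble(operon_id = rep(paste0(species_id, "_opC", 1:2), each = 2),
             position = rep(1:2, 2),
             protein_id = c(ids[dec_c[1]], ids[partners[1]],
                            ids[dec_c[2]], ids[partners[2]]))
    }
  )
  assigned <- unlist(purrr::map(op_rows, "protein_id"))
  rest <- setdiff(ids, assigned)
  rest <- sample(rest)
  sizes <- integer()
  while (sum(sizes) < length(rest)) {
    sizes <- c(sizes, 1L + stats::rpois(200, 0.8))
  }
  sizes <- sizes[cumsum(sizes) - sizes < length(rest)]
  op_id <- rep(seq_along(sizes), sizes)[seq_along(rest)]
  pos <- stats::ave(seq_along(rest), op_id, FUN = seq_along)
  op_rows <- c(op_rows, list(
    tibble(operon_id = sprintf("%s_op%04d", species_id, op_id),
           position = as.integer(pos), protein_id = rest)))
  operons <- dplyr::bind_rows(op_rows)

  raw <- w * 1e7
  quant <- tibble(species_id = species_id, condition = "whole_cell",
                  replicate_id = "r1", protein_id = ids,
                  raw_intensity = raw, lfq_intensity = raw,
                  aliases = NA_character_)
  list(quant = quant,
       lengths = tibble(protein_id = ids, length = lengths),
       hits = hits,
       operons = operons,
       dnabind = dnabind,
       known_nap_ids = known_ids,
       novel_nap_ids = ids[novel_idx],
       true_nap_ids = ids[nap_idx],
       target_percent = target)
}

#' Simulate a two-fraction nucleoid enrichment experiment
#'
#' Generates replicated nucleoid- and top-fraction intensities for every
#' protein of a simulated proteome. Log2 intensities are the proteome's
#' base abundance plus replicate noise; true NAPs get an `effect` log2 shift
#' in the nucleoid fraction. Missingness is concentrated at low abundance
#' (censoring probability decreasing in rank), with overall rate
#' `missing_rate`.
#'
#' @param quant A quantification tibble (one replicate, e.g. from
#'   [simulate_proteome()]).
#' @param true_nap_ids Protein ids receiving the enrichment effect.
#' @param effect Log2 shift of true NAPs in the nucleoid fraction.
#' @param n_reps Replicates per fraction.
#' @param rep_sd Replicate noise sd (log2 units).
#' @param missing_rate Overall missingness rate.
#' @param seed Integer seed.
#' @return A list with `nucleoid` and `top`, each a long quantification
#'   tibble (conditions `"nucleoid"`/`"top"`, replicates `r1..rK`; missing
#'   values appear as dropped rows).
#' @export
simulate_enrichment <- function(quant, true_nap_ids, effect = 2.5,
                                n_reps = 3, rep_sd = 0.5,
                                missing_rate = 0.1, seed = 1) {
  if (!is.finite(effect)) abort("effect must be finite",
                                class = "napscan_validation_error")
  set.seed(seed)
  base <- log2(quant$raw_intensity)
  ok <- is.finite(base)
  base <- base[ok]
  ids <- quant$protein_id[ok]
  is_nap <- ids %in% true_nap_ids
  one_fraction <- function(condition, shift) {
    purrr::map(seq_len(n_reps), function(r) {
      v <- base + shift + rnorm(length(base), 0, rep_sd)
      pr <- rank(v) / (length(v) + 1)
      miss <- runif(length(v)) < pmin(1, 2 * missing_rate * (1 - pr))
      tibble(species_id = quant$species_id[[1]], condition = condition,
             replicate_id = paste0("r", r), protein_id = ids[!miss],
             raw_intensity = 2^v[!miss], lfq_intensity = 2^v[!miss],
             aliases = NA_character_)
    }) |> dplyr::bind_rows()
  }
  list(nucleoid = one_fraction("nucleoid", ifelse(is_nap, effect, 0)),
       top = one_fraction("top", 0))
}

#' Simulate a complete synthetic study
#'
#' Composes the generator: a species tree, OGT evolving on it, one quantified
#' proteome per species (with spiked NAPs whose summed abundance follows the
#' linear-in-OGT target), species metadata, and two-fraction enrichment
#' experiments for the first two species. Optionally writes the whole bundle
#' to a directory in the exact external formats the package readers consume
#' (TSV, hmmer tblout, Newick, JSON); [read_study()] loads it back.
#'
#' @param n_species Number of species.
#' @param params A [study_params()] list.
#' @param seed Integer seed; every stage's sub-seed derives from it.
#' @param dir Optional output directory.
#' @param enrichment Simulate enrichment assays for the first two species.
#' @return A list of class `nap_study`: `tree`, `meta`, `truth` (per-species
#'   tibble with list-columns of NAP ids), `proteomes` (named list from
#'   [simulate_proteome()]), `enrichment`, `params`, `seed`,
#'   `classification`.
#' @export
simulate_study <- function(n_species = 19, params = study_params(), seed = 1,
                           dir = NULL, enrichment = TRUE) {
  tree <- simulate_tree(n_species, seed = seed)
  ogt <- simulate_ogt(tree, root_ogt = params$root_ogt,
                      bm_rate = params$bm_rate,
                      bounds = params$ogt_bounds, seed = seed + 1031L)
  proteomes <- purrr::map(seq_len(n_species), function(i) {
    simulate_proteome(ogt$species_id[i], ogt$ogt[i], params,
                      seed = seed + 7919L * i)
  })
  names(proteomes) <- ogt$species_id
  set.seed(seed + 523L)
  meta <- tibble(
    species_id = ogt$species_id,
    ogt = ogt$ogt,
    ph = NA_real_,
    doubling_time = NA_real_,
    genome_size = round(rnorm(n_species, 2.2e6, 4e5)),
    predicted_proteome_size = round(params$proteome_size /
                                      runif(n_species, 0.62, 0.75)),
    whole_cell_extract = TRUE,
    size_selected = FALSE
  )
  truth <- tibble(
    species_id = ogt$species_id,
    ogt = ogt$ogt,
    target_percent = purrr::map_dbl(proteomes, "target_percent"),
    true_nap_ids = purrr::map(proteomes, "true_nap_ids"),
    known_nap_ids = purrr::map(proteomes, "known_nap_ids"),
    novel_nap_ids = purrr::map(proteomes, "novel_nap_ids")
  )
  enr <- NULL
  if (enrichment && n_species >= 2) {
    enr <- purrr::map(ogt$species_id[1:2], function(sp) {
      simulate_enrichment(proteomes[[sp]]$quant,
                          proteomes[[sp]]$true_nap_ids,
                          effect = params$enrichment_effect,
                          n_reps = params$n_reps, rep_sd = params$rep_sd,
                          missing_rate = params$missing_rate,
                          seed = seed + 211L * match(sp, ogt$species_id))
    })
    names(enr) <- ogt$species_id[1:2]
  }
  study <- structure(
    list(tree = tree, meta = meta, truth = truth, proteomes = proteomes,
         enrichment = enr, params = params, seed = seed,
         classification = default_domain_classification()),
    class = "nap_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @rdname simulate_study
#' @param study A `nap_study` object.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_nap_tree(study$tree, file.path(dir, "tree.nwk"))
  write_species_meta(study$meta, file.path(dir, "species_meta.tsv"))
  for (sp in names(study$proteomes)) {
    pr <- study$proteomes[[sp]]
    write_quant_table(pr$quant, file.path(dir, paste0(sp, "_quant.tsv")))
    write_hmm_tblout(pr$hits, file.path(dir, paste0(sp, "_hits.tblout")))
    write_operon_table(pr$operons, file.path(dir, paste0(sp, "_operons.tsv")))
    write_dnabinding_scores(pr$dnabind, file.path(dir, paste0(sp, "_dnabind.tsv")))
    readr::write_tsv(pr$lengths, file.path(dir, paste0(sp, "_lengths.tsv")),
                     progress = FALSE)
  }
  for (sp in names(study$enrichment)) {
    for (fr in c("nucleoid", "top")) {
      long <- study$enrichment[[sp]][[fr]]
      for (r in unique(long$replicate_id)) {
        write_quant_table(dplyr::filter(long, .data$replicate_id == r),
                          file.path(dir, paste0(sp, "_", fr, "_", r, ".tsv")))
      }
    }
  }
  truth_json <- study$truth
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"))
  jsonlite::write_json(
    c(study$params, list(seed = study$seed,
                         enrichment_species = names(study$enrichment))),
    file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a written synthetic-study bundle
#'
#' Reads back a directory produced by [simulate_study()] (or assembled by
#' hand in the same layout) through the package's format readers.
#'
#' @param dir Bundle directory.
#' @return A list of class `nap_study_files` with `tree`, `meta`, and
#'   per-species `quant`, `hits`, `operons`, `dnabind`, `lengths`,
#'   `enrichment`.
#' @export
read_study <- function(dir) {
  meta <- read_species_meta(file.path(dir, "species_meta.tsv"))
  tree <- read_nap_tree(file.path(dir, "tree.nwk"))
  pars <- jsonlite::read_json(file.path(dir, "params.json"),
                              simplifyVector = TRUE)
  species <- meta$species_id
  proteomes <- purrr::map(species, function(sp) {
    list(
      quant = read_quant_table(file.path(dir, paste0(sp, "_quant.tsv")),
                               species_id = sp),
      hits = read_hmm_tblout(file.path(dir, paste0(sp, "_hits.tblout")), "PFAM"),
      operons = read_operon_table(file.path(dir, paste0(sp, "_operons.tsv"))),
      dnabind = read_dnabinding_scores(file.path(dir, paste0(sp, "_dnabind.tsv"))),
      lengths = readr::read_tsv(file.path(dir, paste0(sp, "_lengths.tsv")),
                                show_col_types = FALSE, progress = FALSE)
    )
  })
  names(proteomes) <- species
  enr_species <- pars$enrichment_species
  enrichment <- NULL
  if (length(enr_species) > 0) {
    enrichment <- purrr::map(enr_species, function(sp) {
      purrr::map(c(nucleoid = "nucleoid", top = "top"), function(fr) {
        files <- list.files(dir, pattern = paste0("^", sp, "_", fr, "_r\\d+\\.tsv$"),
                            full.names = TRUE)
        dplyr::bind_rows(purrr::map(files, function(f) {
          r <- sub("^.*_(r\\d+)\\.tsv$", "\\1", f)
          read_quant_table(f, species_id = sp, condition = fr, replicate_id = r)
        }))
      })
    })
    names(enrichment) <- enr_species
  }
  structure(list(tree = tree, meta = meta, proteomes = proteomes,
                 enrichment = enrichment, params = pars),
            class = "nap_study_files")
}

#' @export
print.nap_study <- function(x, ...) {
  cat("<synthetic NAP study>  seed =", x$seed, "\n")
  cat(" ", nrow(x$meta), "species;", x$params$proteome_size,
      "proteins each; OGT range",
      paste(round(range(x$meta$ogt), 1), collapse = "-"), "C\n")
  cat("  total NAP investment targets:",
      paste(round(range(x$truth$target_percent), 2), collapse = "-"), "%\n")
  invisible(x)
}
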