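#' Run configuration for an end-to-end study analysis
#'
#' Assembles and validates the configuration consumed by
#' [run_nap_study()]. Unknown fields are rejected so that typos in batch
#' configs fail loudly. The configuration round-trips to JSON via
#' [write_run_config()] / [read_run_config()].
#'
#' @param out_dir Output directory for stage results.
#' @param seed Integer seed driving every stochastic stage.
#' @param input_dir Optional directory with an existing study bundle (as
#'   written by [simulate_study()]); when `NULL` a synthetic study is
#'   generated.
#' @param n_species Species count for the synthetic study.
#' @param params Generator parameters ([study_params()]).
#' @param predict_at Temperature (degrees C) at which to predict NAP
#'   investment from the fitted line.
#' @param alpha ESD significance level for the prediction pipeline.
#' @param n_boot PGLS bootstrap replicates.
#' @param min_species Minimum species for the domain screen.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, input_dir = NULL, n_species = 19,
                       params = study_params(), predict_at = 37,
                       alpha = 0.05, n_boot = 1000, min_species = 5) {
  structure(
    list(out_dir = out_dir, seed = seed, input_dir = input_dir,
         n_species = n_species, params = params, predict_at = predict_at,
         alpha = alpha, n_boot = n_boot, min_species = min_species),
    class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), c(known, "params"))
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
          class = "napscan_validation_error")
  }
  if (!is.null(raw$params)) {
    pk <- setdiff(names(raw$params), names(formals(study_params)))
    if (length(pk) > 0) {
      abort(paste0("unknown generator parameter(s): ",
                   paste(pk, collapse = ", ")),
            class = "napscan_validation_error")
    }
    raw$params <- do.call(study_params, raw$params)
  }
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full analysis pipeline on a (synthetic or loaded) study
#'
#' Chains every stage with one configuration and deterministic seeds:
#' simulate (or load) the study bundle, quality-control and quantify each
#' proteome, survey NAP-family presence/absence and co-occurrence, predict
#' candidate NAPs, score nucleoid enrichment where assays exist, and run the
#' comparative statistics (investment-vs-OGT Spearman, OLS prediction with
#' intervals, domain screen, PGLS under BM, genes per transcription unit).
#' Stage outputs are written as TSV under `config$out_dir` together with a
#' JSON report recording every parameter used.
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a named list; also written to
#'   `report.json`).
#' @export
run_nap_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cls <- default_domain_classification()

  if (is.null(config$input_dir)) {
    study <- simulate_study(config$n_species, config$params,
                            seed = config$seed)
    known_by_sp <- setNames(purrr::map(study$proteomes, "known_nap_ids"),
                            names(study$proteomes))
  } else {
    files <- read_study(config$input_dir)
    study <- list(tree = files$tree, meta = files$meta,
                  proteomes = files$proteomes, enrichment = files$enrichment)
    # known NAPs from the survey: proteins hitting NAP family models
    known_by_sp <- purrr::map(files$proteomes, function(pr) {
      fam_models <- unlist(cls$nap_family_models, use.names = FALSE)
      unique(pr$hits$protein_id[hits_in_models(pr$hits, fam_models)])
    })
  }
  species <- study$meta$species_id

  # quantification + prediction per species
  per_species <- purrr::map(species, function(sp) {
    pr <- study$proteomes[[sp]]
    fp <- fractional_abundances(pr$quant)
    qc <- qc_filter(pr$quant, study$meta[study$meta$species_id == sp, ])
    cand <- suppressWarnings(predict_candidates(
      fp, pr$lengths, pr$hits, cls, pr$dnabind, pr$operons,
      known_nap_ids = known_by_sp[[sp]], alpha = config$alpha))
    rec <- investment_record(
      fp, known_by_sp[[sp]], cand$protein_id, pr$hits, cls,
      study$meta$predicted_proteome_size[study$meta$species_id == sp])
    list(fp = fp, qc = qc, candidates = cand, record = rec,
         gptu = genes_per_tu(pr$operons))
  })
  names(per_species) <- species

  records <- dplyr::bind_rows(purrr::map(per_species, "record"))
  candidates <- dplyr::bind_rows(purrr::map(per_species, "candidates"))
  qc <- dplyr::bind_rows(purrr::map(per_species, "qc"))
  readr::write_tsv(records, file.path(config$out_dir, "investment.tsv"),
                   progress = FALSE)
  readr::write_tsv(candidates, file.path(config$out_dir, "candidates.tsv"),
                   progress = FALSE)
  readr::write_tsv(qc, file.path(config$out_dir, "qc.tsv"), progress = FALSE)

  # survey
  hits_by_genome <- purrr::map(study$proteomes, "hits")
  pa <- call_presence(hits_by_genome, cls)
  cc <- cooccurrence(pa)
  readr::write_tsv(as_tibble(pa), file.path(config$out_dir, "presence.tsv"),
                   progress = FALSE)
  readr::write_tsv(cc, file.path(config$out_dir, "cooccurrence.tsv"),
                   progress = FALSE)

  # enrichment
  enrichment_summary <- NULL
  if (!is.null(study$enrichment)) {
    enrichment_summary <- purrr::imap(study$enrichment, function(enr, sp) {
      mats <- purrr::map(enr, quant_to_log2_matrix)
      shared <- intersect(rownames(mats$nucleoid), rownames(mats$top))
      # align on union so one-fraction proteins are retained via imputation
      all_ids <- union(rownames(mats$nucleoid), rownames(mats$top))
      pad <- function(m) {
        out <- matrix(NA_real_, length(all_ids), ncol(m),
                      dimnames = list(all_ids, colnames(m)))
        out[rownames(m), ] <- m
        out
      }
      nuc <- impute_missing(pad(mats$nucleoid), seed = config$seed + 1)
      top <- impute_missing(pad(mats$top), seed = config$seed + 2)
      et <- moderated_test(nuc, top)
      binders <- unique(study$proteomes[[sp]]$hits$protein_id[
        hits_in_models(study$proteomes[[sp]]$hits, cls$dna_binding_domains)])
      wtest <- domain_class_enrichment(et, binders)
      readr::write_tsv(et, file.path(config$out_dir,
                                     paste0(sp, "_enrichment.tsv")),
                       progress = FALSE)
      list(species = sp, n_shared = length(shared),
           dna_binding_W = wtest$statistic, dna_binding_p = wtest$p_value)
    })
  }

  # comparative statistics
  inv_ogt <- dplyr::inner_join(records,
                               dplyr::select(study$meta, "species_id", "ogt"),
                               by = "species_id")
  rho <- spearman(inv_ogt$nap_percent, inv_ogt$ogt)
  rho_known <- tryCatch(
    spearman(inv_ogt$nap_percent_known_only, inv_ogt$ogt),
    error = function(e) tibble(rho = NA_real_, p_value = NA_real_))
  ols <- ols_predict(inv_ogt$ogt, inv_ogt$nap_percent, config$predict_at)
  abund <- dplyr::bind_rows(purrr::map(species, function(sp) {
    bg <- aggregate_by_class(
      per_species[[sp]]$fp, study$proteomes[[sp]]$hits,
      as.list(setNames(generator_pools(config$params)$background_pool,
                       generator_pools(config$params)$background_pool)))
    nap_ids <- union(known_by_sp[[sp]],
                     candidates$protein_id[candidates$species_id == sp])
    dplyr::bind_rows(bg, tibble(class = "NAP",
                                percent = investment(per_species[[sp]]$fp,
                                                     nap_ids))) |>
      dplyr::mutate(species_id = sp)
  }))
  screen <- domain_ogt_screen(abund, dplyr::select(study$meta, "species_id", "ogt"),
                              min_species = config$min_species)
  readr::write_tsv(screen, file.path(config$out_dir, "screen.tsv"),
                   progress = FALSE)
  pgls <- pgls_bm(inv_ogt, study$tree, x = "ogt", y = "nap_percent",
                  log_transform = TRUE, n_boot = config$n_boot,
                  seed = config$seed)
  gptu <- tibble(species_id = species,
                 genes_per_tu = purrr::map_dbl(per_species, "gptu"))
  readr::write_tsv(gptu, file.path(config$out_dir, "genes_per_tu.tsv"),
                   progress = FALSE)

  report <- list(
    seed = config$seed,
    n_species = length(species),
    parameters = c(unclass(config$params),
                   list(alpha = config$alpha, n_boot = config$n_boot,
                        predict_at = config$predict_at,
                        min_species = config$min_species)),
    qc_passed = sum(qc$pass),
    n_candidates = nrow(candidates),
    investment_range = range(records$nap_percent),
    spearman_rho = rho$rho, spearman_p = rho$p_value,
    spearman_rho_known_only = rho_known$rho,
    ols_slope = ols$slope, ols_intercept = ols$intercept,
    prediction = as.list(ols$prediction[1, ]),
    pgls_slope = pgls$slope, pgls_slope_p = pgls$slope_p,
    pgls_bootstrap_ci = if (!is.null(pgls$bootstrap_ci))
      as.list(pgls$bootstrap_ci[1, ]) else NULL,
    nap_screen_rank = attr(screen, "nap_rank"),
    mean_genes_per_tu = mean(gptu$genes_per_tu),
    enrichment = enrichment_summary
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}
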