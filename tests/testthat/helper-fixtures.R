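# Small in-code fixtures shared across test files.

make_quant <- function(ids, raw, lfq = NA_real_, species = "spX",
                       condition = "whole_cell", replicate = "r1") {
  tibble::tibble(
    species_id = species, condition = condition, replicate_id = replicate,
    protein_id = ids, raw_intensity = raw,
    lfq_intensity = if (length(lfq) == 1 && all(is.na(lfq))) NA_real_ else lfq,
    aliases = NA_character_
  )
}

make_hits <- function(ids, models, source = "PFAM", e_value = 1e-10,
                      bit_score = 100) {
  tibble::tibble(protein_id = ids, model = models, model_accession = models,
                 source = source, e_value = e_value, bit_score = bit_score,
                 description = "")
}

make_operons <- function(sizes, prefix = "op") {
  if (length(sizes) == 0) {
    return(tibble::tibble(operon_id = character(), position = integer(),
                          protein_id = character()))
  }
  op <- rep(paste0(prefix, seq_along(sizes)), sizes)
  tibble::tibble(operon_id = op,
                 position = as.integer(unlist(lapply(sizes, seq_len))),
                 protein_id = paste0("g", seq_along(op)))
}

# independent brute-force generalized ESD: explicit loop recomputing
# mean/sd at each step, straight from the definition
esd_brute <- function(x, k_max, alpha = 0.05) {
  n <- length(x)
  remaining <- x
  orig_idx <- seq_len(n)
  R <- lambda <- numeric(k_max)
  removed <- integer(k_max)
  for (i in seq_len(k_max)) {
    s <- stats::sd(remaining)
    if (is.na(s) || s == 0) {
      R[i] <- 0
      removed[i] <- NA_integer_
    } else {
      dev <- abs(remaining - mean(remaining)) / s
      j <- which.max(dev)
      R[i] <- dev[j]
      removed[i] <- orig_idx[j]
      remaining <- remaining[-j]
      orig_idx <- orig_idx[-j]
    }
    p <- 1 - alpha / (2 * (n - i + 1))
    tc <- stats::qt(p, n - i - 1)
    lambda[i] <- (n - i) * tc / sqrt((n - i - 1 + tc^2) * (n - i + 1))
  }
  n_out <- if (any(R > lambda)) max(which(R > lambda)) else 0L
  list(n_outliers = n_out,
       flagged = if (n_out > 0) removed[seq_len(n_out)] else integer())
}
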