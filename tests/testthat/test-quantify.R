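test_that("fractional abundances sum to 100 and honor the LFQ preference", {
  fp <- fractional_abundances(make_quant(c("A", "B", "C"), c(50, 30, 20)))
  expect_equal(fp$fraction, c(50, 30, 20))
  expect_equal(sum(fp$fraction), 100, tolerance = 1e-6)
  expect_equal(attr(fp, "intensity_basis"), "raw")

  one <- fractional_abundances(make_quant("A", 42))
  expect_equal(one$fraction, 100)

  # LFQ replaces raw for the whole basis
  q <- make_quant(c("A", "B"), c(90, 10), lfq = c(10, 90))
  fp2 <- fractional_abundances(q, prefer_lfq = TRUE)
  expect_equal(fp2$fraction, c(10, 90))
  expect_equal(attr(fp2, "intensity_basis"), "lfq")
  fp3 <- fractional_abundances(q, prefer_lfq = FALSE)
  expect_equal(fp3$fraction, c(90, 10))

  # rows lacking LFQ are dropped from the basis, with a message
  q_mix <- make_quant(c("A", "B"), c(50, 50), lfq = c(40, NA))
  expect_message(fp4 <- fractional_abundances(q_mix), "dropped")
  expect_equal(fp4$fraction, 100)

  expect_error(fractional_abundances(make_quant(c("A", "B"), c(0, 0))),
               class = "napscan_validation_error")
})

test_that("fractional abundances are scale invariant", {
  set.seed(7)
  q <- make_quant(paste0("p", 1:40), rlnorm(40, 0, 2))
  q10 <- dplyr::mutate(q, raw_intensity = raw_intensity * 1234.5)
  expect_equal(fractional_abundances(q)$fraction,
               fractional_abundances(q10)$fraction)
})

test_that("QC requires whole-cell, unselected samples with >500 proteins", {
  meta <- tibble::tibble(species_id = "sp1", whole_cell_extract = TRUE,
                         size_selected = FALSE)
  q500 <- make_quant(paste0("p", 1:500), rep(1, 500))
  expect_false(qc_filter(q500, meta)$pass)
  q501 <- make_quant(paste0("p", 1:501), rep(1, 501))
  expect_true(qc_filter(q501, meta)$pass)

  big <- make_quant(paste0("p", 1:10000), rep(1, 10000))
  meta_ss <- dplyr::mutate(meta, size_selected = TRUE)
  res <- qc_filter(big, meta_ss)
  expect_false(res$pass)
  expect_match(res$reasons, "size-selected")
  meta_frac <- dplyr::mutate(meta, whole_cell_extract = FALSE)
  expect_false(qc_filter(big, meta_frac)$pass)
})

test_that("investment sums detected members and is additive", {
  fp <- fractional_abundances(make_quant(c("A", "B", "C"), c(50, 30, 20)))
  expect_equal(investment(fp, character()), 0)
  expect_equal(investment(fp, c("A", "B", "C")), 100)
  expect_equal(investment(fp, c("B", "C")), 50)
  # undetected ids contribute nothing
  expect_equal(investment(fp, c("B", "ghost")), 30)
  # additivity over disjoint sets; monotone under union
  expect_equal(investment(fp, c("A", "C")),
               investment(fp, "A") + investment(fp, "C"))
  expect_gte(investment(fp, c("A", "B")), investment(fp, "A"))
})

test_that("reference normalization divides by the reference class", {
  fp <- fractional_abundances(make_quant(c("nap", "ref1", "ref2", "bulk"),
                                         c(2, 3, 1, 94)))
  hits <- make_hits(c("ref1", "ref2"), c("tRNA-synth_1", "tRNA-synth_2"))
  cls <- default_domain_classification()
  expect_equal(reference_normalize(fp, "nap", hits, cls, "trna_synth"), 0.5)
  expect_equal(reference_normalize(fp, character(), hits, cls, "trna_synth"), 0)
  expect_error(reference_normalize(fp, "nap", hits, cls, "rnap_rpb1"),
               "rnap_rpb1", class = "napscan_validation_error")
})

test_that("class aggregation assigns full fractions without splitting", {
  fp <- fractional_abundances(make_quant(c("A", "B"), c(5, 95)))
  hits <- make_hits(c("A", "A"), c("X", "Y"))
  out <- aggregate_by_class(fp, hits, list(X = "X", Y = "Y", Z = "Z"))
  expect_equal(out$percent[out$class == "X"], 5)
  expect_equal(out$percent[out$class == "Y"], 5)
  expect_equal(out$percent[out$class == "Z"], 0)

  # disjoint classes covering everything sum to 100
  hits2 <- make_hits(c("A", "B"), c("X", "Y"))
  out2 <- aggregate_by_class(fp, hits2, list(X = "X", Y = "Y"))
  expect_equal(sum(out2$percent), 100)
})

test_that("isoelectric point matches an independent root finder", {
  # glycine homopolymer: only the termini ionize, so the pI solves a
  # two-term charge balance; solve it independently with uniroot
  pka <- pka_emboss()
  charge <- function(ph) {
    1 / (1 + 10^(ph - pka$positive[["Nterm"]])) -
      1 / (1 + 10^(pka$negative[["Cterm"]] - ph))
  }
  expected <- stats::uniroot(charge, c(0, 14), tol = 1e-9)$root
  expect_equal(compute_isoelectric_point("GGGG"), expected, tolerance = 1e-4)

  # adding a lysine can only raise the pI
  set.seed(1)
  for (s in c("GGGG", "ACDEFG", "MNPQRS")) {
    expect_gte(compute_isoelectric_point(paste0(s, "K")),
               compute_isoelectric_point(s) - 1e-6)
  }
  expect_lt(compute_isoelectric_point("DDDDDD"), 7)
  expect_gt(compute_isoelectric_point("KKKKKK"), 7)
  expect_error(compute_isoelectric_point(""), class = "napscan_validation_error")
  expect_error(compute_isoelectric_point("ABZ"), class = "napscan_validation_error")
})

test_that("investment records assemble coverage and normalizations", {
  fp <- fractional_abundances(make_quant(c("k1", "c1", "ref", "bulk"),
                                         c(1, 2, 2, 95)))
  hits <- make_hits("ref", "tRNA-synth_1")
  cls <- default_domain_classification()
  rec <- investment_record(fp, "k1", "c1", hits, cls,
                           predicted_proteome_size = 8)
  expect_equal(rec$nap_percent, 3)
  expect_equal(rec$nap_percent_known_only, 1)
  expect_equal(rec$normalized_by_trna_synth, 1.5)
  expect_true(is.na(rec$normalized_by_rnap))
  expect_equal(rec$coverage, 0.5)
  expect_lte(rec$nap_percent_known_only, rec$nap_percent)
})
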