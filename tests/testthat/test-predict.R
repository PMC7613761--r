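cls <- default_domain_classification()

test_that("size filter is strictly below the bound", {
  expect_true(size_filter(289))
  expect_false(size_filter(290))
  expect_true(size_filter(74))
  expect_equal(size_filter(c(100, 290, 500)), c(TRUE, FALSE, FALSE))
})

test_that("DNA-binding filter is domain OR strictly positive score", {
  hits <- make_hits("withdom", "Bac_DNA_binding")
  scores <- tibble::tibble(protein_id = c("zero", "small", "withdom"),
                           score = c(0, 0.01, -5))
  expect_false(dna_binding_filter("zero", hits, cls, scores))
  expect_true(dna_binding_filter("small", hits, cls, scores))
  expect_true(dna_binding_filter("withdom", hits, cls, scores))
  # missing score and no domain
  expect_false(dna_binding_filter("unknown", hits, cls, scores))
})

test_that("abundance outlier filter keeps only high-side ESD outliers", {
  set.seed(5)
  tf <- rnorm(50, 1, 0.1)
  res <- abundance_outlier_filter(
    c(at_median = median(tf), spike = mean(tf) + 6 * sd(tf)),
    tf, log_transform = FALSE)
  expect_false(res$pass[res$protein_id == "at_median"])
  expect_true(res$pass[res$protein_id == "spike"])

  # a low-side extreme is never returned even though ESD flags it
  tf_low <- c(tf, 0.01)
  res_low <- abundance_outlier_filter(c(low = 0.005), tf,
                                      log_transform = FALSE)
  expect_false(res_low$pass)
  expect_true(all(res_low$fraction[res_low$pass] > median(tf)))
})

test_that("single-operon filter requires exactly one gene", {
  om <- make_operons(c(1, 2))   # g1 alone; g2,g3 together
  expect_true(single_operon_filter("g1", om))
  expect_false(single_operon_filter("g2", om))
  expect_warning(res <- single_operon_filter("ghost", om), "not assigned")
  expect_false(res)
})

test_that("a constructed proteome yields exactly the spiked candidate", {
  # 60 TFs at moderate abundance, one spiked small DNA-binder at 10x the
  # TF maximum in a single-gene operon, bulk proteins failing size/binding
  set.seed(9)
  n_tf <- 60
  tf_ids <- paste0("tf", seq_len(n_tf))
  bulk_ids <- paste0("bulk", 1:40)
  ids <- c("spike", tf_ids, bulk_ids)
  tf_ab <- rlnorm(n_tf, 0, 0.3)
  raw <- c(10 * max(tf_ab), tf_ab, rlnorm(40, 2, 1))
  q <- make_quant(ids, raw)
  fp <- fractional_abundances(q)
  lengths <- tibble::tibble(protein_id = ids,
                            length = c(70, rep(150, n_tf), rep(400, 40)))
  hits <- dplyr::bind_rows(
    make_hits("spike", "HMG_box"),
    make_hits(tf_ids, sample(c("TrmB", "MarR", "ArsR"), n_tf, replace = TRUE)))
  scores <- tibble::tibble(protein_id = ids, score = -1)
  om <- tibble::tibble(operon_id = c("op_spike", paste0("op", seq_len(n_tf + 40))),
                       position = 1L, protein_id = ids)

  cand <- predict_candidates(fp, lengths, hits, cls, scores, om)
  expect_equal(cand$protein_id, "spike")
  expect_equal(cand$rank, 1L)
  expect_true(all(cand[, c("pass_size", "pass_dna_binding",
                           "pass_abundance_outlier", "pass_single_operon")] == TRUE))

  # spiked protein listed as a known NAP is excluded
  none <- predict_candidates(fp, lengths, hits, cls, scores, om,
                             known_nap_ids = "spike")
  expect_equal(nrow(none), 0)

  # an otherwise identical 300-aa protein fails the size filter
  lengths300 <- dplyr::mutate(lengths,
                              length = ifelse(protein_id == "spike", 300L, length))
  expect_equal(nrow(predict_candidates(fp, lengths300, hits, cls, scores, om)), 0)

  # relaxing the operon criterion never removes candidates
  cand_rel <- predict_candidates(fp, lengths, hits, cls, scores, om,
                                 relax_operon = TRUE)
  expect_true(all(cand$protein_id %in% cand_rel$protein_id))

  # row-order permutation stability
  set.seed(33)
  perm <- sample(nrow(fp))
  cand_perm <- predict_candidates(fp[perm, ], lengths, hits, cls, scores, om)
  expect_equal(cand_perm, cand)

  # monotonicity: raising the candidate's abundance keeps it a candidate
  for (mult in c(2, 10, 100)) {
    raw_up <- raw; raw_up[1] <- raw_up[1] * mult
    fp_up <- fractional_abundances(make_quant(ids, raw_up))
    cand_up <- predict_candidates(fp_up, lengths, hits, cls, scores, om)
    expect_true("spike" %in% cand_up$protein_id)
  }

  # pI is attached when sequences are supplied
  seqs <- tibble::tibble(protein_id = "spike",
                         sequence = strrep("K", 70))
  cand_pi <- predict_candidates(fp, lengths, hits, cls, scores, om,
                                sequences = seqs)
  expect_gt(cand_pi$pI, 7)
})

test_that("keep_all returns the full filter table", {
  set.seed(10)
  ids <- c("a", paste0("tf", 1:30))
  q <- make_quant(ids, c(100, rlnorm(30, 0, 0.3)))
  fp <- fractional_abundances(q)
  lengths <- tibble::tibble(protein_id = ids, length = rep(100L, 31))
  hits <- make_hits(ids, c("HMG_box", rep("TrmB", 30)))
  scores <- tibble::tibble(protein_id = ids, score = -1)
  om <- tibble::tibble(operon_id = paste0("op", seq_along(ids)),
                       position = 1L, protein_id = ids)
  full <- predict_candidates(fp, lengths, hits, cls, scores, om,
                             keep_all = TRUE)
  expect_equal(nrow(full), 31)
  expect_true(all(full$candidate == !is.na(full$rank)))
})
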