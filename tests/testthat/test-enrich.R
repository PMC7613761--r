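test_that("imputation fills only missing cells, deterministically", {
  set.seed(2)
  m <- matrix(rnorm(60, 20, 2), 20, 3,
              dimnames = list(paste0("p", 1:20), paste0("r", 1:3)))
  expect_identical(impute_missing(m), m)

  m2 <- m; m2[cbind(c(1, 5, 9), c(1, 2, 3))] <- NA
  f1 <- impute_missing(m2, seed = 7)
  f2 <- impute_missing(m2, seed = 7)
  expect_identical(f1, f2)
  expect_false(any(is.na(f1)))
  expect_identical(f1[!is.na(m2)], m2[!is.na(m2)])

  m3 <- matrix(c(1, NA, NA, NA), 4, 1)
  expect_error(impute_missing(m3), class = "napscan_validation_error")
})

test_that("imputed values sit below the observed distribution", {
  # with shift 1.8 and width 0.3 a draw exceeds the observed mean only if
  # its z-score exceeds 1.8/0.3 = 6; check the empirical mass below the mean
  set.seed(3)
  obs <- rnorm(5000, 25, 1.5)
  m <- matrix(c(obs, rep(NA, 10000)), ncol = 1)
  filled <- impute_missing(m, seed = 11)
  imputed <- filled[5001:15000, 1]
  expect_gt(mean(imputed < mean(obs)), pnorm(6) - 1e-3)
  expect_equal(mean(imputed), mean(obs) - 1.8 * sd(obs), tolerance = 0.02)
  expect_equal(sd(imputed), 0.3 * sd(obs), tolerance = 0.02)
})

test_that("with no prior the moderated statistic is the ordinary t", {
  set.seed(4)
  A <- matrix(rnorm(300, 10, 1), 100, 3, dimnames = list(paste0("p", 1:100)))
  B <- matrix(rnorm(300, 10, 1), 100, 3, dimnames = list(paste0("p", 1:100)))
  et <- moderated_test(A, B, prior_df = 0)
  # closed-form pooled-variance two-sample t
  d <- 4
  s2 <- (rowSums((A - rowMeans(A))^2) + rowSums((B - rowMeans(B))^2)) / d
  t_ref <- (rowMeans(A) - rowMeans(B)) / sqrt(s2 * (2 / 3))
  expect_equal(et$moderated_t, unname(t_ref), tolerance = 1e-8)
  expect_equal(et$p_value, unname(2 * pt(-abs(t_ref), d)), tolerance = 1e-8)
})

test_that("identical group means give zero fold change and p near 1", {
  m <- matrix(rep(c(5, 6, 7), each = 4), 4, 3,
              dimnames = list(paste0("p", 1:4)))
  et <- moderated_test(m, m)
  expect_equal(et$log2fc, rep(0, 4))
  expect_true(all(et$p_value > 0.99))
})

test_that("spiked proteins dominate the ranking with small q-values", {
  set.seed(6)
  n <- 400; spiked <- 1:20
  base <- rnorm(n, 20, 2)
  mk <- function(shift) {
    matrix(base + shift, n, 3, dimnames = list(paste0("p", 1:n))) +
      matrix(rnorm(n * 3, 0, 0.3), n, 3)
  }
  shift <- rep(0, n); shift[spiked] <- 3
  nuc <- mk(shift); top <- mk(0)
  et <- moderated_test(nuc, top)
  expect_true(all(et$q_value[spiked] < 0.05))
  expect_gt(min(et$moderated_t[spiked]), max(et$moderated_t[-spiked]))
})

test_that("swapping fraction labels negates fold changes, keeps p-values", {
  set.seed(8)
  A <- matrix(rnorm(150, 15, 1), 50, 3, dimnames = list(paste0("p", 1:50)))
  B <- matrix(rnorm(150, 15, 1), 50, 3, dimnames = list(paste0("p", 1:50)))
  e1 <- moderated_test(A, B)
  e2 <- moderated_test(B, A)
  expect_equal(e1$log2fc, -e2$log2fc)
  expect_equal(e1$p_value, e2$p_value)
})

test_that("moderated results agree with limma's on the same data", {
  set.seed(12)
  n <- 500
  sd_g <- exp(rnorm(n, log(0.4), 0.4))
  A <- matrix(rnorm(n * 3, 0, sd_g), n, 3, dimnames = list(paste0("p", 1:n)))
  B <- matrix(rnorm(n * 3, 0, sd_g), n, 3, dimnames = list(paste0("p", 1:n)))
  B[1:10, ] <- B[1:10, ] + 4
  et <- moderated_test(A, B)
  fit <- limma::lmFit(cbind(A, B), design = cbind(1, rep(c(1, 0), each = 3)))
  eb <- limma::eBayes(fit)
  # same fold changes; strongly concordant moderated statistics
  expect_equal(et$log2fc, unname(eb$coefficients[, 2]), tolerance = 1e-8)
  expect_gt(cor(et$moderated_t, eb$t[, 2]), 0.99)
  # the two prior-df estimators (moment matching vs profile fitting) agree
  # to within a small factor
  expect_lt(abs(log(attr(et, "d0") / eb$df.prior)), log(4))
})

test_that("BH q-values reject the same set as the step-up definition", {
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(sample(20:200, 1))^sample(1:3, 1)
    q <- p.adjust(p, "BH")
    for (alpha in c(0.01, 0.05, 0.1)) {
      # step-up: largest k with p_(k) <= k/m * alpha; reject smallest k p's
      o <- order(p); m <- length(p)
      ks <- which(p[o] <= seq_len(m) / m * alpha)
      rejected_stepup <- if (length(ks)) o[seq_len(max(ks))] else integer()
      expect_setequal(which(q <= alpha), rejected_stepup)
    }
  }
})

test_that("class-enrichment p-values: exact enumeration and approximation", {
  et <- tibble::tibble(protein_id = paste0("p", 1:6),
                       log2fc = c(10, 11, 12, 1, 2, 3))
  res <- domain_class_enrichment(et, paste0("p", 1:3))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact enumeration")

  # symmetric configuration: identical member/non-member values
  et2 <- tibble::tibble(protein_id = paste0("p", 1:6),
                        log2fc = rep(c(1, 2, 3), 2))
  expect_equal(domain_class_enrichment(et2, paste0("p", 1:3))$p_value, 1)

  # exact vs normal approximation agree for moderate sizes
  set.seed(14)
  for (rep in 1:5) {
    vals <- rnorm(20)
    et3 <- tibble::tibble(protein_id = paste0("p", 1:20), log2fc = vals)
    members <- paste0("p", sample(20, 10))
    exact <- domain_class_enrichment(et3, members, exact_max = 10)
    approx <- domain_class_enrichment(et3, members, exact_max = 0)
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
  }

  expect_error(domain_class_enrichment(et, character()),
               class = "napscan_validation_error")
})

test_that("null type-I error of the moderated test is calibrated", {
  set.seed(15)
  fr <- replicate(4, {
    n <- 1000
    sd_g <- exp(rnorm(n, log(0.3), 0.3))
    A <- matrix(rnorm(n * 3, 0, sd_g), n, 3, dimnames = list(paste0("p", 1:n)))
    B <- matrix(rnorm(n * 3, 0, sd_g), n, 3, dimnames = list(paste0("p", 1:n)))
    mean(moderated_test(A, B)$p_value < 0.05)
  })
  expect_lt(abs(mean(fr) - 0.05), 0.012)
})
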