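test_that("spearman handles monotone data, ties and validation", {
  up <- spearman(1:8, (1:8)^3)
  expect_equal(up$rho, 1)
  down <- spearman(1:8, -(1:8))
  expect_equal(down$rho, -1)

  # average-rank formula checked against direct rank computation
  x <- c(1, 2, 3, 4); y <- c(1, 2, 2, 4)
  res <- spearman(x, y)
  rx <- rank(x); ry <- rank(y)
  rho_direct <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(res$rho, rho_direct)

  expect_error(spearman(rep(1, 5), 1:5), class = "napscan_validation_error")
  expect_error(spearman(1:2, 1:2), class = "napscan_validation_error")
})

test_that("spearman agrees with cor.test", {
  set.seed(21)
  # exact regime
  x <- rnorm(6); y <- rnorm(6)
  res <- spearman(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(res$rho, unname(ref$estimate))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  # approximate regime
  x2 <- rnorm(25); y2 <- x2 + rnorm(25)
  res2 <- spearman(x2, y2)
  ref2 <- suppressWarnings(cor.test(x2, y2, method = "spearman"))
  expect_equal(res2$rho, unname(ref2$estimate))
  expect_equal(res2$p_value, ref2$p.value, tolerance = 0.02)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(22)
  x <- rlnorm(15); y <- rlnorm(15)
  base <- spearman(x, y)$rho
  expect_equal(spearman(log(x), y)$rho, base)
  expect_equal(spearman(x, sqrt(y))$rho, base)
  expect_equal(spearman(exp(x / max(x)), y^3)$rho, base)
})

test_that("domain screen retains quantified features and ranks the NAP class", {
  set.seed(23)
  sp <- paste0("s", 1:12)
  ogt <- tibble::tibble(species_id = sp, ogt = seq(25, 95, length.out = 12))
  ab <- dplyr::bind_rows(
    tibble::tibble(species_id = sp, class = "NAP",
                   percent = 0.05 * ogt$ogt + rnorm(12, 0, 0.2)),
    tibble::tibble(species_id = sp, class = "noise",
                   percent = runif(12, 0, 2)),
    tibble::tibble(species_id = sp, class = "rare",
                   percent = c(1, 1, rep(0, 10)))
  )
  scr <- domain_ogt_screen(ab, ogt, min_species = 5)
  expect_false("rare" %in% scr$class)
  expect_equal(attr(scr, "nap_rank"), 1L)
  expect_true(all(scr$rho >= -1 & scr$rho <= 1))
  expect_equal(glance(scr)$nap_rank, 1L)

  # shuffled OGT decorrelates the NAP class
  set.seed(24)
  rhos <- replicate(100, {
    ogt_s <- dplyr::mutate(ogt, ogt = sample(ogt))
    scr_s <- domain_ogt_screen(ab, ogt_s, min_species = 5)
    scr_s$rho[scr_s$class == "NAP"]
  })
  expect_lt(abs(mean(rhos)), 0.12)
})

test_that("OLS prediction reproduces the closed-form intervals", {
  # perfect collinearity: point prediction with zero-width intervals
  fit0 <- ols_predict(c(0, 10, 20), c(0, 10, 20), x0 = 5)
  expect_equal(fit0$prediction$estimate, 5)
  expect_equal(fit0$prediction$ci_upper - fit0$prediction$ci_lower, 0)

  set.seed(25)
  x <- runif(19, 20, 100)
  y <- -2 + 0.08 * x + rnorm(19, 0, 0.5)
  x0 <- 37
  fit <- ols_predict(x, y, x0)
  # textbook half-widths
  n <- 19
  b <- coef(lm(y ~ x)); res <- y - b[1] - b[2] * x
  s <- sqrt(sum(res^2) / (n - 2))
  sxx <- sum((x - mean(x))^2)
  half_ci <- qt(0.975, n - 2) * s * sqrt(1 / n + (x0 - mean(x))^2 / sxx)
  half_pi <- qt(0.975, n - 2) * s * sqrt(1 + 1 / n + (x0 - mean(x))^2 / sxx)
  expect_equal((fit$prediction$ci_upper - fit$prediction$ci_lower) / 2,
               half_ci, tolerance = 1e-10)
  expect_equal((fit$prediction$pi_upper - fit$prediction$pi_lower) / 2,
               half_pi, tolerance = 1e-10)
  expect_equal(fit$slope, unname(b[2]))
  expect_equal(tidy(fit)$estimate, unname(b), tolerance = 1e-12)
  expect_error(ols_predict(c(1, 2), c(1, 2), 1.5),
               class = "napscan_validation_error")
})

test_that("PGLS matches a hand-inverted three-taxon oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  df <- tibble::tibble(species_id = c("A", "B", "C"),
                       x = c(1, 2, 4), y = c(1.2, 2.1, 3.7))
  fit <- pgls_bm(df, tree, "x", "y")
  C <- rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2))
  Ci <- solve(C)
  X <- cbind(1, df$x)
  beta <- solve(t(X) %*% Ci %*% X) %*% t(X) %*% Ci %*% df$y
  expect_equal(fit$intercept, beta[1, 1], tolerance = 1e-10)
  expect_equal(fit$slope, beta[2, 1], tolerance = 1e-10)
  r <- df$y - X %*% beta
  expect_equal(fit$sigma2_bm, drop(t(r) %*% Ci %*% r) / 3, tolerance = 1e-10)

  # exact linear data recovers the line on any tree
  df2 <- tibble::tibble(species_id = c("A", "B", "C"), x = c(1, 5, 9),
                        y = c(1, 5, 9))
  fit2 <- pgls_bm(df2, tree, "x", "y")
  expect_equal(fit2$slope, 1, tolerance = 1e-10)
  expect_equal(fit2$intercept, 0, tolerance = 1e-10)
})

test_that("PGLS equals OLS on a star tree and ignores branch rescaling", {
  set.seed(26)
  n <- 10
  star <- ape::stree(n, type = "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", 1:n)
  df <- tibble::tibble(species_id = star$tip.label,
                       x = rnorm(n), y = rnorm(n))
  fit <- pgls_bm(df, star, "x", "y")
  ols <- lm(y ~ x, df)
  expect_lt(abs(fit$slope - coef(ols)[2]), 1e-8)
  expect_lt(abs(fit$intercept - coef(ols)[1]), 1e-8)

  tree <- ape::rcoal(8)
  tree$tip.label <- paste0("t", 1:8)
  df2 <- tibble::tibble(species_id = tree$tip.label,
                        x = rnorm(8), y = rnorm(8))
  f1 <- pgls_bm(df2, tree, "x", "y")
  tree10 <- tree; tree10$edge.length <- tree10$edge.length * 10
  f2 <- pgls_bm(df2, tree10, "x", "y")
  expect_equal(f1$slope, f2$slope, tolerance = 1e-10)
  expect_equal(f1$intercept, f2$intercept, tolerance = 1e-10)
})

test_that("PGLS agrees with an independent GLS implementation", {
  set.seed(27)
  tree <- ape::rcoal(12)
  tree$tip.label <- paste0("t", 1:12)
  df <- tibble::tibble(species_id = tree$tip.label,
                       x = rnorm(12), y = rnorm(12))
  fit <- pgls_bm(df, tree, "x", "y")
  gd <- as.data.frame(df[match(tree$tip.label, df$species_id), ])
  rownames(gd) <- gd$species_id
  ref <- nlme::gls(y ~ x, data = gd,
                   correlation = ape::corBrownian(1, tree, form = ~species_id),
                   method = "ML")
  expect_equal(fit$slope, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(fit$slope_p,
               summary(ref)$tTable["x", "p-value"], tolerance = 1e-4)
})

test_that("PGLS validates tips, handles log transform and bootstraps", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  df_bad <- tibble::tibble(species_id = c("A", "B", "D"), x = 1:3, y = 1:3)
  expect_error(pgls_bm(df_bad, tree, "x", "y"), "D",
               class = "napscan_validation_error")

  set.seed(28)
  tr <- ape::rcoal(10); tr$tip.label <- paste0("t", 1:10)
  df <- tibble::tibble(species_id = tr$tip.label,
                       x = rlnorm(10, 3, 0.3), y = rlnorm(10, 0, 0.5))
  fit <- pgls_bm(df, tr, "x", "y", log_transform = TRUE,
                 n_boot = 200, seed = 1)
  expect_false(is.null(fit$bootstrap_ci))
  expect_lt(fit$bootstrap_ci$lower, fit$bootstrap_ci$upper)
  # bootstrap interval brackets the point estimate for well-behaved data
  expect_gte(fit$slope, fit$bootstrap_ci$lower - 5 * fit$slope_se)
  expect_lte(fit$slope, fit$bootstrap_ci$upper + 5 * fit$slope_se)
  expect_equal(glance(fit)$n, 10)
})

test_that("ortholog-pair abundance correlation", {
  set.seed(29)
  ids <- paste0("p", 1:30)
  fpA <- fractional_abundances(make_quant(ids, rlnorm(30, 0, 1), species = "A"))
  fpB <- fpA |> dplyr::mutate(species_id = "B")
  pairs <- tibble::tibble(id_a = ids, id_b = ids)
  res <- rbh_abundance_correlation(fpA, fpB, pairs)
  expect_equal(res$rho, 1)
  expect_equal(res$n_pairs, 30)

  # unmatched pairs are dropped and counted
  pairs2 <- dplyr::bind_rows(pairs,
                             tibble::tibble(id_a = "ghost", id_b = "p1"))
  expect_equal(rbh_abundance_correlation(fpA, fpB, pairs2)$n_pairs, 30)

  # independent abundances give near-zero correlation
  rhos <- replicate(30, {
    fpC <- fractional_abundances(make_quant(ids, rlnorm(30, 0, 1), species = "C"))
    rbh_abundance_correlation(fpA, fpC, pairs)$rho
  })
  expect_lt(abs(mean(rhos)), 0.12)

  expect_error(rbh_abundance_correlation(
    fpA, fpB, tibble::tibble(id_a = "p1", id_b = "p1")),
    class = "napscan_validation_error")
})

test_that("genes per transcription unit is the mean operon size", {
  expect_equal(genes_per_tu(make_operons(c(1, 2, 3))), 2)
  expect_equal(genes_per_tu(make_operons(rep(1, 7))), 1)
  expect_equal(genes_per_tu(make_operons(5)), 5)
  expect_error(genes_per_tu(make_operons(integer())),
               class = "napscan_validation_error")
})
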