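test_that("K=1 collapses to the closed-form frequency MLE", {
  gm <- toy_gm(list(c("AA", "AG", "GG", "AG"), c("AA", "AA", "AG", "AA")))
  fit <- fit_admixture(gm, K = 1, n_restarts = 1, seed = 4)
  dos <- gt_dosage(gm)
  expect_equal(as.vector(fit$P), unname(colMeans(dos) / 2),
               tolerance = 1e-4)
  expect_equal(as.vector(fit$Q), rep(1, 4))
})

test_that("a single heterozygous call at K=1 gives LL = 2 ln 0.5", {
  calls <- matrix("AG", 1, 1, dimnames = list("s1", NULL))
  gm <- genotype_matrix(calls, toy_markers(1))
  fit <- fit_admixture(gm, K = 1, n_restarts = 1, seed = 1)
  expect_equal(fit$loglik, 2 * log(0.5), tolerance = 1e-6)
})

test_that("two fixed opposite populations are recovered at K=2", {
  calls <- rbind(matrix("AA", 10, 20), matrix("GG", 10, 20))
  rownames(calls) <- paste0("s", 1:20)
  gm <- genotype_matrix(calls, toy_markers(20))
  fit <- fit_admixture(gm, K = 2, n_restarts = 3, seed = 6)
  Q_true <- rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
                  matrix(c(0, 1), 10, 2, byrow = TRUE))
  err <- match_ancestry_labels(fit$Q, Q_true)$mean_row_max_err
  expect_lt(err, 0.02)
})

test_that("Q rows stay on the simplex and the fit is seed-reproducible", {
  m <- population_model(n_pops = 3, n_loci = 24, n_samples = 40, seed = 9)
  gm <- simulate_panel(m)$genotypes
  fit <- fit_admixture(gm, K = 3, n_restarts = 2, seed = 5)
  expect_equal(unname(rowSums(fit$Q)), rep(1, 40), tolerance = 1e-6)
  expect_true(all(fit$P > 0 & fit$P < 1))
  fit2 <- fit_admixture(gm, K = 3, n_restarts = 2, seed = 5)
  expect_identical(fit$loglik, fit2$loglik)
  expect_identical(fit$Q, fit2$Q)
})

test_that("the likelihood is invariant to joint label permutation", {
  m <- population_model(n_pops = 3, n_loci = 20, n_samples = 30, seed = 14)
  gm <- simulate_panel(m)$genotypes
  fit <- fit_admixture(gm, K = 3, n_restarts = 1, seed = 2)
  G <- gt_dosage(gm)
  ll_of <- function(Q, P) {
    f <- pmin(pmax(Q %*% P, 1e-6), 1 - 1e-6)
    sum(G * log(f) + (2 - G) * log(1 - f), na.rm = TRUE)
  }
  perm <- c(3, 1, 2)
  expect_equal(ll_of(fit$Q[, perm], fit$P[perm, ]), ll_of(fit$Q, fit$P),
               tolerance = 1e-8)
})

test_that("K greater than the sample count is rejected", {
  gm <- toy_gm(list(c("AA", "AG")))
  expect_error(fit_admixture(gm, K = 5), "exceeds")
})

test_that("Evanno table matches hand arithmetic and flags zero sd", {
  ll <- list(`2` = c(-1000, -1000), `3` = c(-501, -499), `4` = c(-491, -489))
  ev <- evanno_delta_k(ll)
  # delta K(3) = |-490 - 2(-500) + (-1000)| / sd = 490 / sd
  expect_equal(ev$table$Lpp_abs[2], 490)
  expect_equal(ev$table$delta_K[2], 490 / stats::sd(c(-501, -499)))
  expect_equal(ev$best_K, 3L)

  flat <- list(`2` = c(-30, -30), `3` = c(-20, -20), `4` = c(-10, -10))
  evf <- evanno_delta_k(flat)
  expect_true(evf$table$flagged[2])
  expect_true(is.na(evf$best_K))     # all interior K flagged
})

test_that("log-likelihoods linear in K have zero second difference", {
  ll <- lapply(stats::setNames(seq(-500, -100, by = 100), 2:6),
               function(m) m + c(-0.5, 0.5))
  ev <- evanno_delta_k(ll)
  expect_equal(ev$table$Lpp_abs[2:4], rep(0, 3), tolerance = 1e-9)
})

test_that("Evanno input validation catches short or sparse designs", {
  expect_error(evanno_delta_k(list(`2` = c(-1, -2), `3` = c(-1, -2))),
               "consecutive")
  expect_error(evanno_delta_k(list(`2` = -1, `3` = c(-1, -2),
                                   `4` = c(-1, -2))), "replicates")
})

test_that("PCA separates diverged populations on PC1", {
  m <- population_model(n_pops = 2, n_loci = 32, n_samples = 60,
                        freq_prior = c(0.2, 0.2), admix_alpha = 0.05,
                        missing_rate = 0.02, seed = 18)
  panel <- simulate_panel(m)
  pca <- suppressWarnings(genotype_pca(panel$genotypes, 2))
  pop <- max.col(panel$true_Q)
  pc1 <- pca$scores[, 1]
  between <- (mean(pc1[pop == 1]) - mean(pc1[pop == 2]))^2
  within <- stats::var(pc1[pop == 1]) + stats::var(pc1[pop == 2])
  expect_gt(between, within)
})

test_that("duplicated samples receive identical PCA scores", {
  m <- population_model(n_pops = 2, n_loci = 20, n_samples = 20,
                        missing_rate = 0, seed = 19)
  panel <- plant_duplicates(simulate_panel(m), list(c(1L, 2L)))
  pca <- suppressWarnings(genotype_pca(panel$genotypes, 3))
  expect_equal(pca$scores[1, ], pca$scores[2, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("explained-variance fractions are non-increasing and sum to <= 1", {
  m <- population_model(n_pops = 3, n_loci = 25, n_samples = 30, seed = 20)
  pca <- suppressWarnings(genotype_pca(simulate_panel(m)$genotypes, 5))
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_lte(sum(pca$explained), 1 + 1e-9)
})

test_that("monomorphic markers are dropped from PCA with a warning", {
  calls <- cbind(rep("AA", 6), sample(c("AA", "AG", "GG"), 6, TRUE),
                 sample(c("AA", "AG", "GG"), 6, TRUE))
  rownames(calls) <- paste0("s", 1:6)
  gm <- genotype_matrix(calls, toy_markers(3))
  expect_warning(genotype_pca(gm, 2), "zero-variance")
})
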