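test_that("Nei DA matches hand-evaluated cases", {
  gm <- toy_gm(list(c("AA", "AA")))
  expect_equal(unname(nei_da_dist(gm)[1, 2]), 0)

  opp <- toy_gm(list(c("AA", "GG"), c("AA", "GG")))
  expect_equal(unname(nei_da_dist(opp)[1, 2]), 1)

  # one locus, AA vs AG: 1 - sqrt(1 * 0.5) = 0.29289
  het <- toy_gm(list(c("AA", "AG")))
  expect_equal(unname(nei_da_dist(het)[1, 2]), 1 - sqrt(0.5),
               tolerance = 1e-9)
})

test_that("modified Rogers and Cavalli-Sforza-Edwards hit their extremes", {
  same <- toy_gm(list(c("AA", "AA"), c("AG", "AG")))
  expect_equal(unname(rogers_dist(same)[1, 2]), 0)
  expect_equal(unname(cavalli_dist(same)[1, 2]), 0)
  opp <- toy_gm(list(c("AA", "GG"), c("AA", "GG"), c("AA", "GG")))
  expect_equal(unname(rogers_dist(opp)[1, 2]), 1)
  expect_equal(unname(cavalli_dist(opp)[1, 2]), 1)
})

test_that("profile distances agree with the locus-frequency definition", {
  px <- rbind(c(1, 0), c(0.5, 0.5))
  py <- rbind(c(0, 1), c(0.5, 0.5))
  expect_equal(profile_distance(px, py, "mr"), sqrt(2 / 4))
  expect_equal(profile_distance(px, px, "ce"), 0)
})

test_that("distances are symmetric, zero-diagonal and locus-order invariant", {
  m <- population_model(n_pops = 2, n_loci = 16, n_samples = 12,
                        missing_rate = 0.1, seed = 33)
  gm <- simulate_panel(m)$genotypes
  for (fn in list(nei_da_dist, rogers_dist, cavalli_dist)) {
    d <- fn(gm)
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 12))
    expect_true(all(is.finite(d)))
    perm <- sample(16)
    expect_equal(fn(gm[, perm]), d, tolerance = 1e-12)
  }
})

test_that("pairs sharing no loci raise an informative error", {
  calls <- rbind(c("AA", NA), c(NA, "AG"))
  rownames(calls) <- c("x", "y")
  gm <- genotype_matrix(calls, toy_markers(2))
  expect_error(nei_da_dist(gm), "share no non-missing loci")
})

test_that("within-population DA is below between-population DA", {
  m <- population_model(n_pops = 2, n_loci = 32, n_samples = 40,
                        freq_prior = c(0.2, 0.2), admix_alpha = 0.05,
                        missing_rate = 0, seed = 35)
  panel <- simulate_panel(m)
  pop <- max.col(panel$true_Q)
  d <- nei_da_dist(panel$genotypes)
  same <- outer(pop, pop, "==") & upper.tri(d)
  diff_ <- outer(pop, pop, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff_]))
})

test_that("neighbor joining solves the three-point closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- neighbor_joining(d)
  bl <- setNames(tree$edge.length[tree$edge[, 2] <= 3],
                 tree$tip.label[tree$edge[tree$edge[, 2] <= 3, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("neighbor joining exactly recovers additive trees", {
  # tree ((A:1,B:2):1,(C:1,D:1)): path lengths below
  d <- matrix(c(0, 3, 3, 3,
                3, 0, 4, 4,
                3, 4, 0, 2,
                3, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- neighbor_joining(d)
  path <- ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(path, d, tolerance = 1e-9)
})

test_that("equidistant matrices reproduce their path lengths despite ties", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tree <- neighbor_joining(d)
  path <- ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]]
  expect_equal(path, d, tolerance = 1e-9)
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("Newick output re-parses to the same leaves and path lengths", {
  m <- population_model(n_pops = 3, n_loci = 20, n_samples = 8,
                        missing_rate = 0, seed = 39)
  gm <- simulate_panel(m)$genotypes
  tree <- neighbor_joining(nei_da_dist(gm))
  f <- tempfile(fileext = ".nwk")
  write_newick(tree, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tree$tip.label)
  ids <- tree$tip.label
  expect_equal(ape::cophenetic.phylo(back)[ids, ids],
               ape::cophenetic.phylo(tree)[ids, ids], tolerance = 1e-4)
  bad <- tree; bad$tip.label[1] <- ""
  expect_error(write_newick(bad), "labelled")
})
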