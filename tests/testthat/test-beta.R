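test_that("decomposition reproduces hand-worked triplets", {
  # a = 2 shared, b = 1 only-x, c = 3 only-y
  x <- c(1, 1, 1, 0, 0, 0)
  y <- c(1, 1, 0, 1, 1, 1)
  j <- decompose_beta(x, y, "jaccard")
  expect_equal(c(j$similarity, j$replacement, j$richness_difference),
               c(1, 1, 1) / 3)
  s <- decompose_beta(x, y, "sorensen")
  expect_equal(c(s$similarity, s$replacement, s$richness_difference),
               c(0.5, 0.25, 0.25))
  same <- decompose_beta(c(2, 3, 0), c(9, 1, 0))
  expect_equal(c(same$similarity, same$replacement, same$richness_difference),
               c(1, 0, 0))
  disj <- decompose_beta(c(1, 1, 0, 0), c(0, 0, 1, 1), "jaccard")
  expect_equal(c(disj$similarity, disj$replacement, disj$richness_difference),
               c(0, 1, 0))
  expect_error(decompose_beta(c(0, 0), c(0, 0)), class = "passar_empty_sample")
  expect_error(decompose_beta(c(1, 0), c(1, 0, 1)), class = "passar_bad_spec")
})

test_that("triplet identities hold over random presence pairs", {
  set.seed(8)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    if (sum(x | y) == 0) x[1] <- 1
    for (fam in c("jaccard", "sorensen")) {
      tr <- decompose_beta(x, y, fam)
      expect_equal(tr$similarity + tr$replacement + tr$richness_difference, 1,
                   tolerance = 1e-12)
      expect_equal(tr$replacement + tr$richness_difference, tr$dissimilarity,
                   tolerance = 1e-12)
    }
    dj <- decompose_beta(x, y, "jaccard")$dissimilarity
    ds <- decompose_beta(x, y, "sorensen")$dissimilarity
    expect_gte(dj, ds - 1e-12)
    if (dj > 0 && dj < 1) expect_gt(dj, ds)
  }
  # nestedness limit: subset communities show pure richness difference
  nest <- decompose_beta(c(1, 1, 1, 1), c(1, 1, 0, 0), "sorensen")
  expect_equal(nest$replacement, 0)
  expect_equal(nest$richness_difference, nest$dissimilarity)
})

test_that("summaries aggregate contributions over pairs", {
  one <- list(structure(list(similarity = 0.5, replacement = 0.4,
                             richness_difference = 0.1, dissimilarity = 0.5,
                             family = "jaccard"), class = "beta_triplet"))
  s <- summarize_decomposition(one)
  expect_equal(s$replacement_contribution_pct, 80)
  expect_equal(s$richness_difference_contribution_pct, 20)
  ident <- beta_triplets(make_table(rbind(c(1, 1), c(2, 2), c(5, 5))))
  sd0 <- summarize_decomposition(ident)
  expect_true(is.na(sd0$replacement_contribution_pct))
  mixed <- rbind(beta_triplets(make_table(rbind(c(1, 0), c(0, 1)))),
                 beta_triplets(make_table(rbind(c(1, 0), c(0, 1))), "sorensen"))
  expect_error(summarize_decomposition(mixed), class = "passar_mixed_families")
})

test_that("rare-dominated passive sampling makes replacement dominate", {
  pool <- generate_pool(pool_spec(n_species = 3000,
                                  total_individuals = 30000, alpha = 2000,
                                  seed = 81))
  pl <- placement_spec(areas = setNames(rep(0.36, 8), sprintf("tw%d", 1:8)),
                       seed = 82)
  tab <- simulate_passive_sampling(pool, pl)
  tab <- abundance_table(unclass(tab)[, colSums(tab) > 0, drop = FALSE])
  for (fam in c("sorensen", "jaccard")) {
    s <- summarize_decomposition(beta_triplets(tab, fam))
    expect_equal(s$n_pairs, 28)
    expect_gt(s$replacement_contribution_pct, 50)
  }
})

test_that("UniFrac special cases and invariances", {
  tree <- ape::read.tree(text = "((L1:1,L2:1):1,L3:1);")
  x <- c(L1 = 3, L2 = 1, L3 = 0)
  expect_equal(unweighted_unifrac(tree, x, x), 0)
  expect_equal(weighted_unifrac(tree, x, x), 0)
  expect_equal(weighted_unifrac(tree, x, x, normalized = FALSE), 0)
  two <- ape::read.tree(text = "(A:1,B:1);")
  a <- c(A = 5, B = 0); b <- c(A = 0, B = 2)
  expect_equal(unweighted_unifrac(two, a, b), 1)
  expect_equal(weighted_unifrac(two, a, b), 1)
  expect_equal(weighted_unifrac(two, a, b, normalized = FALSE), 2)
  # composition invariance of weighted UniFrac
  y <- c(L1 = 1, L2 = 2, L3 = 4)
  expect_equal(weighted_unifrac(tree, x, y), weighted_unifrac(tree, x * 10, y),
               tolerance = 1e-12)
  # multifurcating trees are fine
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  # shared branch A, unique branches B and C, D untouched: 2/3
  expect_equal(unweighted_unifrac(star, c(A = 1, B = 1, C = 0, D = 0),
                                  c(A = 1, B = 0, C = 1, D = 0)), 2 / 3)
  expect_error(unweighted_unifrac(two, c(A = 1, Z = 1), b),
               class = "passar_taxon_not_in_tree")
  expect_error(weighted_unifrac(two, c(A = 0, B = 0), b),
               class = "passar_empty_sample")
})

test_that("UniFrac matches the path-enumeration oracle on small trees", {
  set.seed(12)
  for (i in 1:30) {
    n <- sample(2:6, 1)
    tree <- random_tree(sprintf("L%d", 1:n), seed = 1000 + i)
    x <- setNames(rpois(n, 2), tree$tip.label)
    y <- setNames(rpois(n, 2), tree$tip.label)
    if (sum(x) == 0) x[1] <- 1
    if (sum(y) == 0) y[n] <- 1
    expect_equal(unweighted_unifrac(tree, x, y),
                 oracle_unifrac(tree, x, y, "unweighted"), tolerance = 1e-12)
    expect_equal(weighted_unifrac(tree, x, y),
                 oracle_unifrac(tree, x, y, "weighted"), tolerance = 1e-12)
  }
})

test_that("UniFrac behaves as a metric on random triples", {
  set.seed(13)
  for (i in 1:50) {
    tree <- random_tree(sprintf("L%d", 1:6), seed = 2000 + i)
    cs <- lapply(1:3, function(j) {
      v <- setNames(rpois(6, 1.5), tree$tip.label)
      if (sum(v) == 0) v[j] <- 1
      v
    })
    for (f in list(unweighted_unifrac, weighted_unifrac)) {
      dxy <- f(tree, cs[[1]], cs[[2]])
      dyx <- f(tree, cs[[2]], cs[[1]])
      dxz <- f(tree, cs[[1]], cs[[3]])
      dzy <- f(tree, cs[[3]], cs[[2]])
      expect_equal(dxy, dyx, tolerance = 1e-12)
      expect_lte(dxy, dxz + dzy + 1e-12)
      expect_equal(f(tree, cs[[1]], cs[[1]]), 0, tolerance = 1e-12)
    }
  }
})

test_that("distance matrices are symmetric with zero diagonal and round-trip trees", {
  tab <- random_table(4, 12, lambda = 1, seed = 90)
  tree <- random_tree(colnames(tab), seed = 91)
  for (m in c("unweighted", "weighted")) {
    d <- unifrac_matrix(tab, tree, m)
    expect_equal(d, t(d), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(unname(diag(d)), rep(0, 4))
    expect_true(all(d >= 0 & d <= 1))
  }
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(tree$tip.label))
  expect_error(read_newick("no/tree.nwk"), class = "passar_missing_file")
})
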