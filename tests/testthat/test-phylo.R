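test_that("prepare_tips averages samples, drops strays, collapses zero pairs", {
  tree <- ape::read.tree(text = "((jal:1,mac:1):1,(spe:1,syr:1):1);")
  counts <- c(j1 = 140, j2 = 165, m1 = 76, s1 = 50, x1 = 999)
  tip_map <- c(j1 = "jal", j2 = "jal", m1 = "mac", s1 = "spe",
               x1 = "notintree")
  pt <- prepare_tips(tree, counts, tip_map)
  expect_equal(unname(pt$values["jal"]), 152.5)   # mean of 140, 165
  expect_equal(unname(pt$values["mac"]), 76)
  expect_false("notintree" %in% names(pt$values))
  expect_equal(ape::Ntip(pt$tree), 3L)

  # two tips at zero patristic distance collapse into one carrying the
  # mean of all four contributing samples
  tree0 <- ape::read.tree(text = "((a:0,b:0):1,c:1);")
  counts0 <- c(s1 = 10, s2 = 20, s3 = 30, s4 = 40, s5 = 7)
  map0 <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b", s5 = "c")
  pt0 <- prepare_tips(tree0, counts0, map0)
  expect_equal(ape::Ntip(pt0$tree), 2L)
  expect_equal(unname(pt0$values["a"]), 25)       # mean of 10, 20, 30, 40

  expect_error(prepare_tips(tree, c(z = 1), c(z = "nowhere")), "map onto")
})

test_that("squared-change parsimony matches closed forms", {
  # two tips on unit branches: root at the midpoint, score (a-b)^2 / 2
  two <- ape::read.tree(text = "(a:1,b:1);")
  r2 <- scp_ancestral_states(phylo_trait(two, c(a = 3, b = 8)))
  expect_equal(unname(r2$node_states), 5.5)
  expect_equal(r2$scp_length, (3 - 8)^2 / 2)

  # three-tip star, unit branches, tips (0, 0, 3): root at the mean
  star <- ape::read.tree(text = "(a:1,b:1,c:1);")
  r3 <- scp_ancestral_states(phylo_trait(star, c(a = 0, b = 0, c = 3)))
  expect_equal(unname(r3$node_states), 1)
  expect_equal(r3$scp_length, 1 + 1 + 4)

  # constant tips: every node equal, zero length
  rc <- scp_ancestral_states(phylo_trait(star, c(a = 2, b = 2, c = 2)))
  expect_true(all(rc$node_states == 2))
  expect_equal(rc$scp_length, 0)
})

test_that("SCP equals numeric minimization on random trees up to 8 tips", {
  for (seed in 1:6) {
    n <- sample(4:8, 1)
    tree <- random_tree(n, seed)
    values <- setNames(runif(n, 0, 100), tree$tip.label)
    for (weighted in c(FALSE, TRUE)) {
      got <- scp_ancestral_states(phylo_trait(tree, values), weighted)
      want <- oracle_scp(tree, values, weighted)
      expect_equal(got$scp_length, want$scp_length, tolerance = 1e-6)
      expect_equal(unname(got$node_states), want$node_states,
                   tolerance = 1e-4)
    }
  }
})

test_that("SCP length is invariant under value-preserving relabeling", {
  tree <- random_tree(6, 99)
  values <- setNames(c(5, 5, 9, 9, 2, 2), tree$tip.label)
  base <- scp_ancestral_states(phylo_trait(tree, values))$scp_length
  # swap labels of tips carrying equal values
  swapped <- values
  names(swapped)[1:2] <- names(values)[2:1]
  expect_equal(scp_ancestral_states(phylo_trait(tree, swapped))$scp_length,
               base)
})

test_that("weighted SCP rejects zero branch lengths", {
  tree <- ape::read.tree(text = "((a:0,b:1):1,c:1);")
  pt <- phylo_trait(tree, c(a = 1, b = 2, c = 3))
  expect_error(scp_ancestral_states(pt, weighted = TRUE), "collapse")
  expect_silent(scp_ancestral_states(pt, weighted = FALSE))
})

test_that("permutation test detects built-in signal", {
  set.seed(1)
  tree <- ape::stree(16, "balanced")
  tree$edge.length <- rep(1, nrow(tree$edge))
  hits <- vapply(1:20, function(s) {
    # values perfectly sorted onto the two halves of the balanced tree
    values <- setNames(c(rnorm(8, 0, 1), rnorm(8, 20, 1)), tree$tip.label)
    permutation_signal_test(phylo_trait(tree, values), n_perm = 2000,
                            seed = s)$perm_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(2)
  tree <- random_tree(12, 7)
  ps <- vapply(1:500, function(s) {
    values <- setNames(rnorm(12), tree$tip.label)
    permutation_signal_test(phylo_trait(tree, values), n_perm = 200,
                            seed = s)$perm_p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate constant traits yield zero shorter permutations", {
  tree <- random_tree(8, 3)
  values <- setNames(rep(4, 8), tree$tip.label)
  res <- permutation_signal_test(phylo_trait(tree, values), n_perm = 100,
                                 seed = 1)
  expect_equal(res$n_shorter, 0L)
  expect_output(print(res), "< 0.01")
})

test_that("lambda transform rescales covariances but not variances", {
  tree <- random_tree(10, 11)
  V <- ape::vcv(tree)
  expect_equal(ape::vcv(lambda_transform(tree, 1)), V, tolerance = 1e-12)
  V0 <- ape::vcv(lambda_transform(tree, 0))
  expect_equal(diag(V0), diag(V), tolerance = 1e-12)
  expect_true(all(abs(V0[upper.tri(V0)]) < 1e-12))
  Vh <- ape::vcv(lambda_transform(tree, 0.5))
  expect_equal(Vh[upper.tri(Vh)], 0.5 * V[upper.tri(V)], tolerance = 1e-12)
  expect_equal(diag(Vh), diag(V), tolerance = 1e-12)
  expect_error(lambda_transform(tree, 1.2), "lambda")
})

test_that("lambda estimation recovers the generating value", {
  lam_hat_1 <- vapply(1:60, function(s) {
    pt <- make_tree_and_traits(200, lambda = 1, sigma2 = 1, root_state = 1000,
                               seed = 1000 + s)
    fit_lambda(pt)$lambda_hat
  }, numeric(1))
  expect_lt(abs(mean(lam_hat_1) - 1), 0.05)

  lam_hat_0 <- vapply(1:30, function(s) {
    tree <- random_tree(50, 2000 + s)
    values <- setNames(rnorm(50, 100, 5), tree$tip.label)
    fit_lambda(phylo_trait(tree, values))$lambda_hat
  }, numeric(1))
  expect_lt(mean(lam_hat_0), 0.15)
})

test_that("lambda log-likelihood agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  pt <- make_tree_and_traits(60, lambda = 0.6, sigma2 = 2, root_state = 500,
                             seed = 77)
  ours <- fit_lambda(pt)
  ref <- phytools::phylosig(pt$tree, pt$values, method = "lambda", test = TRUE)
  expect_equal(ours$lambda_hat, ref$lambda, tolerance = 0.01)
  expect_equal(ours$logL_lambda, ref$logL, tolerance = 1e-3)
  expect_equal(ours$logL_zero, ref$logL0, tolerance = 1e-3)
})

test_that("the unconstrained lambda likelihood is never below the null", {
  for (s in 1:10) {
    tree <- random_tree(20, 300 + s)
    values <- setNames(rnorm(20, 50, 10), tree$tip.label)
    f <- fit_lambda(phylo_trait(tree, values))
    expect_gte(f$logL_lambda, f$logL_zero - 1e-9)
  }
})

test_that("LRT arithmetic reproduces published log-likelihood pairs", {
  a <- lrt_lambda(-594.192, -597.863)
  expect_equal(a$lrt_stat, 7.342, tolerance = 1e-9)
  expect_equal(round(a$lrt_p, 4), 0.0067)
  b <- lrt_lambda(-587.547, -590.765)
  expect_equal(round(b$lrt_p, 4), 0.0112)
  z <- lrt_lambda(-10, -10)
  expect_equal(z$lrt_stat, 0)
  expect_equal(z$lrt_p, 1)
  expect_error(lrt_lambda(-11, -10), "nested")
})

test_that("Brownian-motion fitting recovers rate and root", {
  s2_hat <- vapply(1:40, function(s) {
    pt <- make_tree_and_traits(200, lambda = 1, sigma2 = 2, root_state = 1000,
                               seed = 5000 + s)
    fit_bm(pt, n_starts = 20, seed = s)$sigma2_hat
  }, numeric(1))
  expect_lt(abs(mean(s2_hat) - 2), 0.2)

  tree <- random_tree(10, 9)
  const <- phylo_trait(tree, setNames(rep(7, 10), tree$tip.label))
  fit <- fit_bm(const, seed = 1)
  expect_equal(fit$sigma2_hat, 0)
  expect_equal(fit$root_hat, 7)
})

test_that("multi-start optimization never falls below the analytic start", {
  for (s in 1:5) {
    tree <- random_tree(30, 400 + s)
    values <- setNames(rnorm(30, 200, 20), tree$tip.label)
    pt <- phylo_trait(tree, values)
    V <- ape::vcv(tree)
    analytic <- copyvar:::.bm_profile(V, unname(pt$values))
    fit <- fit_bm(pt, n_starts = 10, seed = s)
    expect_gte(fit$logL, analytic$logL - 1e-6)
  }
})

test_that("bounded BM simulation respects bounds and degenerate rates", {
  tree <- random_tree(12, 13)
  z <- simulate_bm_bounded(tree, 0, 5, n_sims = 50, seed = 1)
  expect_true(all(z == 5))
  sims <- simulate_bm_bounded(tree, 4, 1, n_sims = 500, seed = 2)
  expect_true(all(sims >= 0))
  a <- simulate_bm_bounded(tree, 4, 1, n_sims = 100, seed = 3)
  b <- simulate_bm_bounded(tree, 4, 1, n_sims = 100, seed = 3)
  expect_identical(a, b)
  expect_error(simulate_bm_bounded(tree, 4, -1), "bounds")
})

test_that("clade extremeness counts simulations in the observed direction", {
  tree <- random_tree(16, 17)
  values <- setNames(rnorm(16, 50, 10), tree$tip.label)
  pt <- phylo_trait(tree, values)
  sims <- simulate_bm_bounded(tree, 5, 50, n_sims = 400, seed = 4)
  ce <- clade_extremeness(pt, sims)
  expect_equal(nrow(ce), pt$tree$Nnode)
  expect_true(all(ce$n_more_extreme >= 0 & ce$n_more_extreme <= 400))
  # brute-force recount for a few nodes
  sys <- copyvar:::.scp_system(pt$tree)
  obs <- drop(sys$R %*% pt$values)
  sim_states <- sys$R %*% sims[pt$tree$tip.label, ]
  for (k in c(1, 5, 10)) {
    expected <- if (ce$direction[k] == "high") sum(sim_states[k, ] > obs[k])
    else sum(sim_states[k, ] < obs[k])
    expect_equal(ce$n_more_extreme[k], expected)
  }
  # observed equal to every simulation -> zero more extreme
  flat <- matrix(50, 16, 10, dimnames = list(tree$tip.label, NULL))
  pt_flat <- phylo_trait(tree, setNames(rep(50, 16), tree$tip.label))
  ce_flat <- clade_extremeness(pt_flat, flat)
  expect_true(all(ce_flat$n_more_extreme == 0L))

  bad <- sims
  rownames(bad) <- paste0("x", seq_len(16))
  expect_error(clade_extremeness(pt, bad), "tips")
})

test_that("Bonferroni critical counts follow floor(n alpha / clades)", {
  expect_equal(bonferroni_critical(10000, 0.05, 53), 9L)
  expect_equal(bonferroni_critical(100, 0.05, 1), 5L)
  tree <- random_tree(10, 23)
  pt <- phylo_trait(tree, setNames(rnorm(10), tree$tip.label))
  sims <- simulate_bm_bounded(tree, 1, 0, n_sims = 100, seed = 5)
  ce <- clade_extremeness(pt, sims, alpha = 0.05)
  expect_equal(attr(ce, "bonferroni_critical"),
               bonferroni_critical(100, 0.05, attr(ce, "n_clades")))
})
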