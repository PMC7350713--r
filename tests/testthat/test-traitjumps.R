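test_that("BM pruning matches the dense matrix oracle", {
  set.seed(51)
  for (i in 1:5) {
    tr <- random_ultra_tree(8)
    x <- setNames(rnorm(8), tr$tip.label)
    s2 <- runif(1, 0.3, 3)
    expect_equal(bm_loglik(tr, x, s2, "ml"), dense_bm_loglik(tr, x, s2),
                 tolerance = 1e-10)
  }
})

test_that("BM likelihood identities hold", {
  tr <- random_ultra_tree(10, seed = 52)
  x <- setNames(rnorm(10), tr$tip.label)
  # scaling branch lengths by c and sigma2 by 1/c changes nothing
  tr2 <- tr; tr2$edge.length <- tr2$edge.length * 4
  expect_equal(bm_loglik(tr, x, 1, "reml"), bm_loglik(tr2, x, 0.25, "reml"),
               tolerance = 1e-10)
  # an identical-valued cherry contributes its maximal contrast term
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  same <- bm_loglik(cherry, c(A = 1, B = 1), 1, "reml")
  off <- bm_loglik(cherry, c(A = 1, B = 1.5), 1, "reml")
  expect_gt(same, off)
  expect_equal(same, dnorm(0, 0, sqrt(2), log = TRUE), tolerance = 1e-12)
})

test_that("augmented Levy likelihood reduces and stretches correctly", {
  set.seed(53)
  tr <- random_ultra_tree(8)
  x <- setNames(rnorm(8), tr$tip.label)
  m <- levy_model(sigma2 = 0.7, jump_rate = 0, alpha = 5)
  zero <- integer(nrow(tr$edge))
  expect_equal(levy_loglik_given_jumps(tr, x, m, zero),
               bm_loglik(tr, x, 0.7, "ml"), tolerance = 1e-12)
  # one jump on a terminal branch == stretching that branch by alpha
  e <- which(tr$edge[, 2] <= 8)[1]
  cnt <- zero; cnt[e] <- 1L
  tr2 <- tr; tr2$edge.length[e] <- tr2$edge.length[e] + 5
  expect_equal(levy_loglik_given_jumps(tr, x, m, cnt),
               dense_bm_loglik(tr2, x, 0.7), tolerance = 1e-10)
  # arbitrary counts against the dense-covariance oracle
  set.seed(54)
  cnt2 <- rpois(nrow(tr$edge), 0.5)
  tr3 <- tr; tr3$edge.length <- tr3$edge.length + cnt2 * 5
  expect_equal(levy_loglik_given_jumps(tr, x, m, cnt2),
               dense_bm_loglik(tr3, x, 0.7), tolerance = 1e-10)
  expect_error(levy_loglik_given_jumps(tr, x, m, zero - 1L), "negative")
})

test_that("the C++ mixture pruning matches the R reference implementation", {
  set.seed(49)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    tr <- random_ultra_tree(n)
    x <- rnorm(n)
    po <- carapace:::.postorder(tr)
    s2 <- runif(1, 0.2, 2); jr <- runif(1, 0, 0.1); al <- runif(1, 1, 50)
    expect_equal(carapace:::.levy_marginal_loglik(po, x, s2, jr, al, 2L, 16L),
                 carapace:::.levy_marginal_loglik_r(po, x, s2, jr, al, 2L, 16L),
                 tolerance = 1e-4)
  }
})

test_that("zero-count reduction holds across many random trees", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    tr <- random_ultra_tree(n)
    x <- setNames(rnorm(n), tr$tip.label)
    expect_equal(levy_loglik_given_jumps(tr, x, levy_model(1, 0, 3),
                                         integer(nrow(tr$edge))),
                 bm_loglik(tr, x, 1, "ml"), tolerance = 1e-12)
  }
})

test_that("jump MCMC is deterministic and permutation-equivariant", {
  set.seed(56)
  tr <- random_ultra_tree(20)
  sim <- simulate_levy_trait(tr, levy_model(1, 0.01, 40), seed = 57)
  a <- sample_jump_vectors(tr, sim$tip_values, 40, n_vectors = 300,
                           burnin = 100, seed = 58)
  b <- sample_jump_vectors(tr, sim$tip_values, 40, n_vectors = 300,
                           burnin = 100, seed = 58)
  expect_identical(a$pp, b$pp)
  # relabeling tips (with the matching trait relabeling) leaves PPs unchanged
  perm <- sample(20)
  tr2 <- tr; tr2$tip.label <- paste0("sp_", perm)
  x2p <- setNames(unname(sim$tip_values[tr$tip.label]), tr2$tip.label)
  c2 <- sample_jump_vectors(tr2, x2p, 40, n_vectors = 300, burnin = 100,
                            seed = 58)
  expect_equal(unname(a$pp), unname(c2$pp), tolerance = 1e-12)
  expect_error(sample_jump_vectors(tr, setNames(rep(1, 20), tr$tip.label), 40),
               "zero variance")
})

test_that("jump calling uses a strict threshold", {
  post <- structure(list(pp = c(`3` = 0.9, `7` = 0.85, `9` = 0.2)),
                    class = "jump_posterior")
  expect_identical(call_jumps(post, 0.85), "3")
  expect_setequal(call_jumps(post, 0), c("3", "7", "9"))
  empty <- structure(list(pp = setNames(numeric(0), character(0))),
                     class = "jump_posterior")
  expect_length(call_jumps(empty), 0L)
  expect_error(call_jumps(post, 1.2), "threshold")
})

test_that("planted large jumps are recovered; null data yield no calls", {
  set.seed(60)
  tr <- ape::rphylo(50, 0.1, 0)
  alpha <- 25 * mean(tr$edge.length)
  hits <- 0L
  for (rep in 1:8) {
    pj <- simulate_planted_jump(tr, alpha, seed = 600 + rep)
    j <- sample_jump_vectors(tr, pj$tip_values, alpha, n_vectors = 1200,
                             burnin = 300, seed = rep)
    hits <- hits + (j$pp[pj$branch_key] > 0.85)
  }
  expect_gte(hits, 6L)  # >= 75% in this short run; acceptance runs 20 reps
  false_calls <- 0L
  for (rep in 1:5) {
    sim <- simulate_levy_trait(tr, levy_model(1, 0, alpha), seed = 700 + rep,
                               jump_counts = integer(nrow(tr$edge)))
    j <- sample_jump_vectors(tr, sim$tip_values, alpha, n_vectors = 1200,
                             burnin = 300, seed = rep)
    false_calls <- false_calls + (max(j$pp) > 0.85)
  }
  expect_equal(false_calls, 0L)
})

test_that("alpha grid is log10-spaced and the search reports its size", {
  set.seed(61)
  tr <- ape::rphylo(30, 0.1, 0)
  sim <- simulate_levy_trait(tr, levy_model(1, 0.015, 30), seed = 62)
  pk <- alpha_peak_search(tr, sim$tip_values, n_optimizations = 2,
                          max_comp = 8L)
  expect_equal(unique(round(diff(pk$profile$log10_alpha), 6)), 0.5)
  expect_gte(pk$n_evaluated, 3L)
  expect_equal(pk$n_evaluated, nrow(pk$profile))
  expect_true(is.finite(pk$alpha_hat))
  # flat-likelihood (pure BM) data set the multimodality/flat flag
  bm <- simulate_levy_trait(tr, levy_model(1, 0, 30), seed = 63,
                            jump_counts = integer(nrow(tr$edge)))
  pk0 <- alpha_peak_search(tr, bm$tip_values, n_optimizations = 1,
                           max_comp = 8L)
  expect_true(pk0$flat_profile || pk0$multimodal)
})

test_that("the LRT is non-negative, exact at zero, and conservative under BM", {
  set.seed(64)
  tr <- ape::rphylo(25, 0.1, 0)
  bm <- simulate_levy_trait(tr, levy_model(1, 0, 30), seed = 65,
                            jump_counts = integer(nrow(tr$edge)))
  # pinned jump rate: profile at jump_rate = 0 equals BM exactly
  po <- carapace:::.postorder(tr)
  x <- unname(bm$tip_values[tr$tip.label])
  s2 <- carapace:::.bm_sigma2_reml(tr, bm$tip_values)
  expect_equal(carapace:::.levy_marginal_loglik(po, x, s2, 0, 10),
               bm_loglik(tr, bm$tip_values, s2, "reml"), tolerance = 1e-12)
  # null calibration: boundary makes p conservative, never anti-conservative
  ps <- vapply(1:10, function(rep) {
    sim <- simulate_levy_trait(tr, levy_model(1, 0, 30), seed = 650 + rep,
                               jump_counts = integer(nrow(tr$edge)))
    lrt <- lrt_jump_vs_bm(tr, sim$tip_values, n_optimizations = 2,
                          max_comp = 8L)
    expect_gte(lrt$D, 0)
    lrt$p_value
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(median(ps), 0.2)
})

test_that("strongly jumping data give a decisive LRT", {
  set.seed(66)
  tr <- ape::rphylo(40, 0.1, 0)
  alpha <- 50 * mean(tr$edge.length)
  sig <- 0L
  for (rep in 1:5) {
    cnt <- integer(nrow(tr$edge))
    cnt[sample(which(tr$edge[, 2] <= 40), 3)] <- 1L
    sim <- simulate_levy_trait(tr, levy_model(1, 0, alpha), seed = 660 + rep,
                               jump_counts = cnt)
    lrt <- lrt_jump_vs_bm(tr, sim$tip_values, n_optimizations = 2,
                          max_comp = 8L)
    sig <- sig + (lrt$p_value < 0.001)
  }
  expect_gte(sig, 4L)
})

test_that("sigma2 is recovered within tolerance under plain BM", {
  set.seed(67)
  est <- vapply(1:50, function(i) {
    tr <- ape::rphylo(100, 0.1, 0)
    sim <- simulate_levy_trait(tr, levy_model(sigma2 = 1))
    carapace:::.bm_sigma2_reml(tr, sim$tip_values)
  }, numeric(1))
  expect_lt(abs(median(est) - 1), 0.2)
})

test_that("BM imputation fills missing tips sensibly", {
  set.seed(68)
  tr <- random_ultra_tree(10)
  sim <- simulate_levy_trait(tr, levy_model(1), seed = 69)
  x <- sim$tip_values
  # no missing values: returned unchanged
  out0 <- impute_tips_bm(tr, x)
  expect_identical(out0$traits, x[tr$tip.label])
  # missing tip in a cherry: imputed value between sister and the tree mean
  ntip <- ape::Ntip(tr)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  cherry <- Filter(function(k) all(k <= ntip), kids)[[1]]
  drop <- tr$tip.label[cherry[1]]; sis <- tr$tip.label[cherry[2]]
  x1 <- x; x1[drop] <- NA
  out <- impute_tips_bm(tr, x1)
  lo <- min(x[sis], mean(x[setdiff(names(x), drop)]))
  hi <- max(x[sis], mean(x[setdiff(names(x), drop)]))
  expect_gte(out$traits[drop], lo - 1e-9)
  expect_lte(out$traits[drop], hi + 1e-9)
  expect_gt(out$se[drop], 0)
  expect_equal(unname(out$se[sis]), 0)
  # sister branch length -> 0: imputed value -> sister's value
  tr2 <- tr
  es <- which(tr2$edge[, 2] %in% cherry)
  tr2$edge.length[es] <- 1e-9
  # re-ultrametrize: extend the cherry stem
  stem <- which(tr2$edge[, 2] == tr$edge[es[1], 1])
  tr2$edge.length[stem] <- tr2$edge.length[stem] + tr$edge.length[es[1]] - 1e-9
  out2 <- impute_tips_bm(tr2, x1)
  expect_equal(unname(out2$traits[drop]), unname(x1[sis]), tolerance = 1e-3)
  expect_error(impute_tips_bm(tr, setNames(rep(NA_real_, 10), tr$tip.label)),
               "at least 2 observed")
})
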