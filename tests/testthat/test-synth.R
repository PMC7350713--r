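test_that("Yule simulations match the closed-form tip-count expectation", {
  lambda <- 0.07; crown <- 25
  cfg <- sim_config(lambda0 = lambda, mu0 = 0, crown_age = crown)
  set.seed(1)
  n <- replicate(1000, ape::Ntip(simulate_bd_tree(cfg)$tree))
  expected <- 2 * exp(lambda * crown)
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("a survival-1 mass extinction is an exact no-op", {
  base <- sim_config(lambda0 = 0.1, mu0 = 0.02, crown_age = 30, seed = 42)
  noop <- sim_config(lambda0 = 0.1, mu0 = 0.02, crown_age = 30,
                     mass_extinctions = list(list(time = 15, survival = 1)),
                     seed = 42)
  t1 <- simulate_bd_tree(base); t2 <- simulate_bd_tree(noop)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
})

test_that("a survival-0.05 mass extinction kills about 95% of lineages", {
  # pure-birth background so that conditioning on crown survival barely
  # perturbs the realized kill fraction
  cfg <- sim_config(lambda0 = 0.2, mu0 = 0, crown_age = 40,
                    mass_extinctions = list(list(time = 15, survival = 0.05)))
  set.seed(7)
  fr <- replicate(120, {
    ev <- simulate_bd_tree(cfg)$events
    me <- ev[ev$type == "mass_extinction", ]
    me$n_killed / me$n_alive
  })
  expect_lt(abs(mean(fr) - 0.95), 3 * sd(fr) / sqrt(length(fr)) + 0.003)
})

test_that("total-extinction retry cap is an explicit error", {
  cfg <- sim_config(lambda0 = 0.02, mu0 = 0.0199, crown_age = 200, seed = 3)
  expect_error(simulate_bd_tree(cfg, max_retries = 2L), "2 retries")
})

test_that("posterior emulation preserves topology and ultrametricity", {
  set.seed(2)
  tr <- random_ultra_tree(15)
  same <- simulate_posterior_set(tr, 1, age_jitter_cv = 0)[[1]]
  expect_equal(same$edge.length, tr$edge.length, tolerance = 1e-12)
  post <- simulate_posterior_set(tr, 100, age_jitter_cv = 0.05, seed = 4)
  for (p in post) {
    expect_true(validate_ultrametric(p, tol = 1e-8)$ok)
    expect_true(ape::all.equal.phylo(p, tr, use.edge.length = FALSE))
  }
})

test_that("median jittered node ages track the input ages", {
  set.seed(6)
  tr <- random_ultra_tree(10)
  post <- simulate_posterior_set(tr, 2000, age_jitter_cv = 0.05, seed = 8)
  ntip <- ape::Ntip(tr)
  ages0 <- node_ages(tr)[-seq_len(ntip)]
  med <- apply(vapply(post, function(p) node_ages(p)[-seq_len(ntip)],
                      numeric(tr$Nnode)), 1, median)
  expect_true(all(abs(med - ages0) / ages0 < 0.01))
})

test_that("Levy trait generator reduces to BM and obeys closed forms", {
  # cherry with equal branches: difference of tips has variance 2 sigma2 t
  cherry <- ape::read.tree(text = "(A:2,B:2);")
  set.seed(9)
  d <- replicate(2000, {
    s <- simulate_levy_trait(cherry, levy_model(sigma2 = 0.5))
    diff(s$tip_values)
  })
  expect_equal(var(d), 2 * 0.5 * 2, tolerance = 0.15)
  # tip covariance equals sigma2 x shared path length under jump_rate = 0
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  set.seed(10)
  X <- t(replicate(2000, simulate_levy_trait(tr, levy_model(1))$tip_values))
  S <- cov(X)
  expect_equal(S["A", "B"], 1, tolerance = 0.15)
  expect_equal(S["A", "A"], 2, tolerance = 0.3)
  expect_lt(abs(S["A", "C"]), 0.2)
})

test_that("a forced large jump displaces its clade detectably", {
  set.seed(11)
  tr <- random_ultra_tree(16)
  e <- which(tr$edge[, 2] <= 16)[1]
  tip <- tr$tip.label[tr$edge[e, 1 + 1]]
  hits <- replicate(50, {
    cnt <- integer(nrow(tr$edge)); cnt[e] <- 1L
    sim <- simulate_levy_trait(tr, levy_model(1, alpha = 100),
                               jump_counts = cnt)
    base <- simulate_levy_trait(tr, levy_model(1),
                                jump_counts = integer(nrow(tr$edge)))
    t_len <- tr$edge.length[e]
    abs(sim$tip_values[tip] - mean(sim$tip_values[-match(tip, names(sim$tip_values))]))
  })
  # offset typically exceeds 3 * sigma * sqrt(branch length)
  expect_gt(mean(hits > 3 * sqrt(tr$edge.length[e])), 0.5)
})

test_that("generators are reproducible given the seed", {
  cfg <- sim_config(lambda0 = 0.1, mu0 = 0.02, crown_age = 25, seed = 21)
  a <- simulate_bd_tree(cfg); b <- simulate_bd_tree(cfg)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  set.seed(1); tr <- random_ultra_tree(30)
  r1 <- simulate_ranges(30, seed = 5, species = tr$tip.label)
  r2 <- simulate_ranges(30, seed = 5, species = tr$tip.label)
  expect_identical(r1$grid$occupancy, r2$grid$occupancy)
  t1 <- simulate_species_table(tr, r1$centroids, r1$areas, seed = 6)
  t2 <- simulate_species_table(tr, r2$centroids, r2$areas, seed = 6)
  expect_identical(t1, t2)
})

test_that("range blobs are contiguous and areas/centroids are consistent", {
  set.seed(12)
  r <- simulate_ranges(40, grid_dims = c(15L, 25L), mean_cells = 10,
                       cell_area = 100, seed = 13)
  nr <- 15L
  for (i in seq_len(40)) {
    cells <- which(r$grid$occupancy[i, ])
    expect_gte(length(cells), 1L)
    # connected under 4-neighbour adjacency
    rr <- (cells - 1L) %% nr + 1L; cc <- (cells - 1L) %/% nr + 1L
    seen <- 1L; frontier <- 1L
    while (length(frontier)) {
      nxt <- which(vapply(seq_along(cells), function(j)
        any(abs(rr[j] - rr[frontier]) + abs(cc[j] - cc[frontier]) == 1L),
        logical(1)))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    expect_length(seen, length(cells))
    expect_equal(unname(r$areas[i]), length(cells) * 100)
  }
  # single-cell species: centroid at the cell centre
  one <- simulate_ranges(1, grid_dims = c(5L, 5L), mean_cells = 1,
                         cell_area = 100, seed = 14)
  expect_equal(sum(one$grid$occupancy), 1L)
  expect_equal(one$areas[[1]], 100)
  cell <- which(one$grid$occupancy[1, ])
  expect_equal(unname(one$centroids[1, ]),
               c((cell - 1L) %/% 5L + 0.5, (cell - 1L) %% 5L + 0.5))
})

test_that("status generator honours its degenerate and default regimes", {
  set.seed(15)
  tr <- ape::rphylo(400, 0.07, 0.03)
  r <- simulate_ranges(400, seed = 16, species = tr$tip.label)
  # no effects, symmetric thresholds: near-uniform categories
  cfg0 <- status_gen_config(beta_area = 0, beta_other = numeric(0),
                            phylo_signal_sd = 0, spatial_signal_sd = 0,
                            thresholds = qnorm(seq_len(5) / 6),
                            mask_fraction = 0)
  t0 <- simulate_species_table(tr, r$centroids, r$areas, cfg0, seed = 17)
  tab <- table(factor(t0$true_status_code, levels = 1:6))
  expect_gt(chisq.test(tab, p = rep(1 / 6, 6))$p.value, 0.01)
  # defaults: dominant negative area effect and exact masking count
  td <- simulate_species_table(tr, r$centroids, r$areas, status_gen_config(),
                               seed = 18)
  expect_lt(cor(log(td$range_area), td$true_status_code, method = "spearman"),
            -0.5)
  expect_equal(sum(td$masked), round(0.3 * 400))
  expect_equal(sum(is.na(td$status_code)), 120L)
  expect_setequal(unique(td$true_status_code), 1:6)
})

test_that("phylogenetic signal makes sister species more alike in status", {
  set.seed(19)
  tr <- ape::rphylo(400, 0.07, 0.03)
  r <- simulate_ranges(400, seed = 20, species = tr$tip.label)
  cfg <- status_gen_config(beta_area = 0, beta_other = numeric(0),
                           phylo_signal_sd = 2, spatial_signal_sd = 0,
                           mask_fraction = 0)
  tb <- simulate_species_table(tr, r$centroids, r$areas, cfg, seed = 21)
  code <- setNames(tb$true_status_code, tb$species)
  # cherries: internal nodes with two tip children
  ntip <- ape::Ntip(tr)
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  cherries <- Filter(function(k) all(k <= ntip), kids)
  sis_diff <- mean(vapply(cherries, function(k)
    abs(code[tr$tip.label[k[1]]] - code[tr$tip.label[k[2]]]), numeric(1)))
  set.seed(22)
  perm <- replicate(999, {
    s <- sample(code)
    mean(vapply(cherries, function(k) abs(s[k[1]] - s[k[2]]), numeric(1)))
  })
  p <- (sum(perm <= sis_diff) + 1) / 1000
  expect_lt(p, 0.05)
})
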