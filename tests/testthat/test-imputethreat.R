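make_raw <- function(n = 30, seed = 81) {
  set.seed(seed)
  data.frame(species = sprintf("s%02d", 1:n),
             body_length = exp(rnorm(n, 3.5, 0.4)),
             body_mass = exp(rnorm(n, 1, 0.8)),
             range_area = exp(rnorm(n, 10, 1.5)),
             hei = runif(n), climate_pc1 = rnorm(n), climate_pc2 = rnorm(n),
             aet = exp(rnorm(n, 6.5, 0.3)), npp = exp(rnorm(n, 6, 0.4)),
             microhabitat = factor(sample(c("aquatic", "semiaquatic",
                                            "terrestrial"), n, TRUE)),
             endemicity = factor(sample(c("endemic", "widespread"), n, TRUE)),
             ecoregion = factor(sample(c("Nearctic", "Oriental"), n, TRUE)),
             stringsAsFactors = FALSE)
}

test_that("predictor encoding is deterministic and scheme-faithful", {
  raw <- make_raw()
  z <- encode_predictors(raw, "pglm")
  expect_false(anyNA(z$X))
  # z-scheme: continuous columns have mean 0, sd 1
  for (nm in c("body_length", "range_area", "hei")) {
    expect_equal(mean(z$X[, nm]), 0, tolerance = 1e-12)
    expect_equal(sd(z$X[, nm]), 1, tolerance = 1e-12)
  }
  # one-hot blocks sum to 1 per species
  mh <- z$X[, grep("^microhabitat_", colnames(z$X))]
  expect_true(all(rowSums(mh) == 1))
  mm <- encode_predictors(raw, "minmax")
  expect_true(all(mm$X >= 0 & mm$X <= 1))
  toy <- raw[1:3, ]; toy$hei <- c(2, 4, 6) / 10
  expect_equal(unname(encode_predictors(toy, "minmax")$X[, "hei"]),
               c(0, 0.5, 1))
  # stored parameters reproduce the training transform on new rows
  again <- encode_predictors(raw[5:10, ], params = z$params)
  expect_equal(again$X, z$X[5:10, ])
  bad <- raw; bad$range_area[1] <- 0
  expect_error(encode_predictors(bad, "pglm"), "non-positive")
  new_lvl <- raw[1:2, ]; new_lvl$ecoregion <- factor(c("Afrotropic", "Oriental"))
  expect_error(encode_predictors(new_lvl, params = z$params), "unseen")
})

test_that("PCoA axes recover simple geometries", {
  # collinear points at distances 0-1-2: axis 1 is the line, axis 2 zero
  D <- as.matrix(dist(c(0, 1, 2)))
  ax <- pcoa_axes(D, 2)
  expect_equal(order(ax[, 1]), order(c(0, 1, 2)) |> (\(o) if (ax[1, 1] < ax[3, 1]) o else rev(o))())
  expect_lt(max(abs(ax[, 2])), 1e-6)
  # planar configurations are reproduced exactly by 2 axes
  set.seed(82)
  P <- cbind(rnorm(12), rnorm(12))
  D2 <- as.matrix(dist(P))
  ax2 <- pcoa_axes(D2, 2)
  expect_equal(as.matrix(dist(ax2)), D2, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(pcoa_axes(matrix(0, 4, 4), 2) == 0))
  A <- D2; A[1, 2] <- A[1, 2] + 1
  expect_error(pcoa_axes(A), "symmetric")
})

test_that("the PGLM reduces to OLS under identity covariance", {
  raw <- make_raw(40, seed = 83)
  enc <- encode_predictors(raw, "pglm")
  X <- enc$X
  y_full <- setNames(3 - 0.8 * X[, "range_area"], raw$species)
  rownames(X) <- raw$species
  I40 <- diag(40); dimnames(I40) <- list(raw$species, raw$species)
  y <- y_full; y[39:40] <- NA
  fit <- fit_pglm(X, y, I40, I40, select = FALSE)
  expect_equal(unname(fit$beta["range_area"]), -0.8, tolerance = 1e-6)
  expect_equal(unname(fit$beta["(Intercept)"]), 3, tolerance = 1e-6)
  expect_lt(fit$sigma2, 1e-12)
  # a species identical to a training row gets that row's prediction
  X2 <- rbind(X, twin = X[1, ]); rownames(X2)[41] <- "twin"
  I41 <- diag(41); dimnames(I41) <- list(rownames(X2), rownames(X2))
  y2 <- c(y_full, twin = NA)
  fit2 <- fit_pglm(X2, y2, I41, I41, select = FALSE)
  expect_equal(unname(fit2$predictions["twin"]), unname(y_full[1]),
               tolerance = 1e-6)
})

test_that("the PGLM finds the dominant area effect on synthetic data", {
  set.seed(84)
  tr <- ape::rphylo(150, 0.07, 0.03)
  rng <- simulate_ranges(150, seed = 85, species = tr$tip.label)
  tab <- simulate_species_table(tr, rng$centroids, rng$areas,
                                status_gen_config(), seed = 86)
  B <- build_predictor_matrix(tab, tr, "pglm")
  y <- setNames(as.numeric(tab$status_code), tab$species)
  fit <- fit_pglm(B$X, y, B$phylo_cor, B$spatial_cor)
  expect_equal(names(fit$importance)[1], "range_area")
  expect_true(all(fit$predictions >= 1 & fit$predictions <= 6))
  expect_true(is.finite(fit$condition_number))
})

test_that("the random forest calibrates on noise and finds real signal", {
  raw <- make_raw(60, seed = 87)
  enc <- encode_predictors(raw, "pglm")
  X <- enc$X; rownames(X) <- raw$species
  set.seed(88)
  y_noise <- setNames(sample(1:6, 60, TRUE), raw$species)
  fit <- fit_rf(X, y_noise, n_trees = 300, seed = 89)
  acc <- mean(pmin(pmax(floor(fit$oob_predictions + 0.5), 1), 6) == y_noise)
  ci <- binom.test(round(acc * 60), 60, p = 1 / 6)$conf.int
  expect_lt(ci[1], 1 / 6 + 0.12)
  # duplicate of a training row predicts near its training code
  y_sig <- setNames(round(pmin(pmax(4 - 0.9 *
                                      scale(log(raw$range_area))[, 1], 1), 6)),
                    raw$species)
  X2 <- rbind(X, dup = X[5, ]); rownames(X2)[61] <- "dup"
  y2 <- c(y_sig, dup = NA)
  fit2 <- fit_rf(X2, y2, n_trees = 300, seed = 90)
  expect_lt(abs(unname(fit2$predictions["dup"]) - y_sig[5]), 0.5)
  expect_equal(names(sort(fit2$importance, decreasing = TRUE))[1],
               "range_area")
  expect_error(fit_rf(X, y_noise, n_trees = 0), "n_trees")
})

test_that("the neural net fits linear structure and validates its inputs", {
  set.seed(91)
  n <- 80
  X <- cbind(a = runif(n), b = runif(n))
  rownames(X) <- sprintf("s%02d", 1:n)
  y <- setNames(1 + 4 * X[, "a"], rownames(X))
  fit <- fit_ann(X, y, hidden_sizes = 4L, decays = 1e-4, k_folds = 4L,
                 repeats = 1L, seed = 92)
  rmse <- sqrt(mean((predict(fit$model, X) - y)^2))
  expect_lt(rmse, 0.1)
  fit2 <- fit_ann(X, y, hidden_sizes = 4L, decays = 1e-4, k_folds = 4L,
                  repeats = 1L, seed = 92)
  expect_identical(fit$model$wts, fit2$model$wts)
  expect_error(fit_ann(X, y, hidden_sizes = 0L), "size must be")
  expect_error(fit_ann(X * 3, y, hidden_sizes = 2L), "min-max")
})

test_that("cross-validation tabulates known versus predicted categories", {
  set.seed(93)
  n <- 60
  y <- rep(1:6, each = 10)
  X <- matrix(y + rnorm(n, 0, 1e-6), ncol = 1,
              dimnames = list(sprintf("s%02d", 1:n), "x"))
  perfect <- function(Xtr, ytr, Xte) Xte[, 1]
  cv <- crossvalidate(perfect, X, y, "loocv")
  expect_equal(cv$accuracy, 1)
  expect_true(all(cv$confusion == diag(10, 6)))
  expect_equal(cv$mean_abs_error, 0)
  # uniform random predictor: accuracy near chance (1/6)
  unif <- function(Xtr, ytr, Xte) runif(nrow(Xte), 0.5, 6.5)
  cvu <- crossvalidate(unif, X, y, "loocv", seed = 94)
  ci <- binom.test(sum(cvu$categories == y), n, p = 1 / 6)$conf.int
  expect_true(ci[1] <= 1 / 6 && 1 / 6 <= ci[2])
  # constant predictor on balanced classes: accuracy 1/6, one-hot sensitivity
  const <- function(Xtr, ytr, Xte) rep(3, nrow(Xte))
  cvc <- crossvalidate(const, X, y, "loocv")
  expect_equal(cvc$accuracy, 1 / 6)
  expect_equal(unname(cvc$per_class["VU", "sensitivity"]), 1)
  expect_equal(unname(cvc$per_class["LC", "sensitivity"]), 0)
  # repeated k-fold records folds whose training part lacks a class
  y_rare <- c(rep(1, 59), 6)
  cvr <- crossvalidate(perfect, X, y_rare, "repeated_kfold", k = 5,
                       repeats = 1, seed = 95)
  expect_gte(cvr$folds_missing_class, 1L)
})

test_that("pooling implements clamp-then-mean with half-up rounding", {
  p <- pool_predictions(2, 3, 4)
  expect_equal(p$pooled, 3); expect_equal(p$category, 3L)
  expect_equal(pool_predictions(3, 3, 3)$pooled, 3)
  pc <- pool_predictions(1.0, 1.0, 6.9)
  expect_equal(pc$pooled, 8 / 3, tolerance = 1e-12)
  expect_equal(pc$category, 3L)
  # x.5 rounds toward the more-threatened class
  expect_equal(pool_predictions(2, 2.5, 3)$category, 3L)
  # permutation invariance
  expect_equal(pool_predictions(1.2, 4.4, 3.3)$pooled,
               pool_predictions(3.3, 1.2, 4.4)$pooled)
  expect_error(pool_predictions(NA, 1, 2), "missing prediction")
})

test_that("concordance counts match the pairwise definitions", {
  S <- 114
  M <- matrix(3, S, 3)
  cc <- concordance(M)
  expect_equal(cc$total_pairwise, 342L)
  expect_equal(cc$n_all_identical, S)
  expect_equal(cc$pct_identical, 100)
  one <- concordance(matrix(c(1, 2, 3), 1, 3))
  expect_equal(one$pairwise_identical, 0)
  expect_equal(one$pairwise_adjacent, 2)
  expect_equal(one$total_pairwise - one$pairwise_identical -
                 one$pairwise_adjacent, 1)
  two <- concordance(matrix(c(2, 2, 5), 1, 3))
  expect_equal(two$n_two_agree, 1)
  expect_error(concordance(matrix(1, 2, 2)), "one column per model")
})
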