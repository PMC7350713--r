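# Threat-status imputation ensemble: PGLM + random forest + neural net ---

.iucn_codes <- c(LC = 1L, NT = 2L, VU = 3L, EN = 4L, CR = 5L, EX = 6L)

#' Encode raw predictors for modelling
#'
#' Continuous predictors on a ratio scale (`body_length`, `body_mass`,
#' `range_area`, `aet`, `npp`) are log-transformed; all continuous columns
#' are then centered and scaled (`scheme = "pglm"`) or min-max scaled to
#' `[0, 1]` (`scheme = "minmax"`). Categorical predictors become full binary
#' one-hot blocks (each block sums to 1 per species). Transformation
#' parameters are stored so prediction rows can be encoded identically.
#'
#' @param raw data.frame with the predictor columns (see
#'   [simulate_species_table()]).
#' @param scheme `"pglm"` (z-scores) or `"minmax"`.
#' @param params encoding parameters from a previous call, to reuse.
#' @return list with `X` (numeric matrix, rows named by species) and
#'   `params`.
#' @export
encode_predictors <- function(raw, scheme = c("pglm", "minmax"), params = NULL) {
  scheme <- match.arg(scheme)
  cont <- intersect(c("body_length", "body_mass", "range_area", "hei",
                      "climate_pc1", "climate_pc2", "aet", "npp"),
                    names(raw))
  logged <- intersect(c("body_length", "body_mass", "range_area", "aet", "npp"),
                      cont)
  cats <- intersect(c("microhabitat", "endemicity", "ecoregion"), names(raw))
  if (is.null(params)) {
    params <- list(scheme = scheme, cont = cont, logged = logged, cats = cats,
                   center = list(), scale = list(), min = list(), max = list(),
                   levels = lapply(raw[cats], function(v) levels(factor(v))))
    fresh <- TRUE
  } else {
    scheme <- params$scheme; cont <- params$cont
    logged <- params$logged; cats <- params$cats
    fresh <- FALSE
  }
  Xc <- sapply(cont, function(nm) {
    v <- raw[[nm]]
    if (nm %in% logged) {
      if (any(v <= 0))
        stop("non-positive values in log-transformed predictor: ", nm,
             call. = FALSE)
      v <- log(v)
    }
    v
  })
  if (is.null(dim(Xc))) Xc <- matrix(Xc, nrow = nrow(raw), dimnames = list(NULL, cont))
  for (nm in cont) {
    v <- Xc[, nm]
    if (scheme == "pglm") {
      if (fresh) {
        params$center[[nm]] <- mean(v)
        params$scale[[nm]] <- max(sd(v), .Machine$double.eps)
      }
      Xc[, nm] <- (v - params$center[[nm]]) / params$scale[[nm]]
    } else {
      if (fresh) {
        params$min[[nm]] <- min(v); params$max[[nm]] <- max(v)
      }
      rng <- max(params$max[[nm]] - params$min[[nm]], .Machine$double.eps)
      Xc[, nm] <- pmin(pmax((v - params$min[[nm]]) / rng, 0), 1)
    }
  }
  blocks <- lapply(cats, function(nm) {
    lev <- params$levels[[nm]]
    v <- as.character(raw[[nm]])
    unseen <- setdiff(unique(v), lev)
    if (length(unseen))
      stop("unseen category level(s) in ", nm, ": ",
           paste(unseen, collapse = ", "), call. = FALSE)
    B <- outer(v, lev, "==") * 1
    colnames(B) <- paste(nm, lev, sep = "_")
    B
  })
  X <- do.call(cbind, c(list(Xc), blocks))
  rownames(X) <- if (!is.null(raw$species)) raw$species else rownames(raw)
  list(X = X, params = params)
}

#' Principal-coordinate axes of a distance matrix
#'
#' Classical multidimensional scaling: eigendecomposition of the
#' double-centered squared-distance matrix, axes ordered by eigenvalue.
#' Axes beyond the matrix's positive-eigenvalue rank are zero-padded.
#'
#' @param distance_matrix symmetric matrix with zero diagonal.
#' @param k number of axes (default 2).
#' @return n x k matrix of coordinates.
#' @export
pcoa_axes <- function(distance_matrix, k = 2L) {
  D <- as.matrix(distance_matrix)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(D)) > 1e-8))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  n <- nrow(D)
  out <- matrix(0, n, k, dimnames = list(rownames(D), paste0("axis", seq_len(k))))
  if (all(D == 0)) return(out)
  cs <- suppressWarnings(cmdscale(D, k = min(k, n - 1)))
  if (NCOL(cs) > 0) out[, seq_len(ncol(cs))] <- cs
  out
}

#' Assemble the full predictor matrix with phylogenetic and spatial axes
#'
#' Encoded predictors plus two phylogenetic PCoA axes (from the patristic
#' distance matrix) and two spatial PCoA axes (from range-centroid
#' distances).
#'
#' @param table species table from [simulate_species_table()] (or with the
#'   same columns).
#' @param tree ultrametric `phylo` covering the table's species.
#' @param scheme encoding scheme, see [encode_predictors()].
#' @return list with `X`, `params`, `phylo_cor`, `spatial_cor` (correlation
#'   matrices for the PGLM).
#' @export
build_predictor_matrix <- function(table, tree, scheme = c("pglm", "minmax")) {
  scheme <- match.arg(scheme)
  enc <- encode_predictors(table, scheme)
  sp <- rownames(enc$X)
  Dp <- ape::cophenetic.phylo(tree)[sp, sp]
  Ds <- centroid_distance_matrix(cbind(table$centroid_x, table$centroid_y,
                                       deparse.level = 0) |>
                                   `rownames<-`(sp))
  P <- pcoa_axes(Dp, 2); colnames(P) <- c("phylo_pcoa1", "phylo_pcoa2")
  S <- pcoa_axes(Ds, 2); colnames(S) <- c("spatial_pcoa1", "spatial_pcoa2")
  if (scheme == "minmax") {
    mm <- function(M) apply(M, 2, function(v) {
      rng <- max(max(v) - min(v), .Machine$double.eps)
      (v - min(v)) / rng
    })
    P <- mm(P); S <- mm(S)
  }
  X <- cbind(enc$X, P, S)
  phylo_cor <- stats::cov2cor(ape::vcv(tree)[sp, sp])
  spatial_cor <- exp(-Ds / max(stats::median(Ds[upper.tri(Ds)]),
                               .Machine$double.eps))
  list(X = X, params = enc$params, phylo_cor = phylo_cor,
       spatial_cor = spatial_cor)
}

# GLS machinery shared by fit and LOOCV --------------------------------

.gls_fit <- function(X, y, V) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e)
    stop("combined correlation matrix is not positive definite", call. = FALSE))
  Xi <- backsolve(ch, X, transpose = TRUE)
  colnames(Xi) <- colnames(X)
  yi <- backsolve(ch, y, transpose = TRUE)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi))
    stop("singular design matrix (condition number ",
         format(kappa(Xi), digits = 3), "); drop aliased predictors",
         call. = FALSE)
  beta <- qr.coef(qrX, yi)
  resid <- yi - Xi %*% beta
  s2 <- sum(resid^2) / n
  ll <- -0.5 * n * (log(2 * pi * s2) + 1) - sum(log(diag(ch)))
  XtVX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtVX_inv) * s2, 0))
  list(beta = beta, se = se, sigma2 = s2, loglik = ll,
       kappa = kappa(Xi))
}

# Drop exactly collinear columns (keeps the first of each aliased group).
.drop_aliased <- function(X) {
  q <- qr(X)
  keep <- sort(q$pivot[seq_len(q$rank)])
  X[, keep, drop = FALSE]
}

#' Phylogenetic-spatial generalized least squares for ordinal status
#'
#' Fits status codes (treated as continuous 1-6) by GLS with residual
#' correlation `w * C_phylo + (1 - w) * C_spatial`, `w` estimated by profile
#' likelihood on a grid. Optional preliminary feature selection keeps
#' predictors whose full-model |z| exceeds 1.96 (the intercept is always
#' kept). Predictions for unassessed species are best linear unbiased
#' predictions (universal-kriging form), clamped to `[1, 6]`.
#'
#' @param X predictor matrix for all species (rows named).
#' @param y_known named numeric vector of status codes with `NA` for species
#'   to impute.
#' @param phylo_cov,spatial_cov correlation (or covariance) matrices over all
#'   species.
#' @param select run preliminary feature selection.
#' @param w_grid candidate mixing weights.
#' @return a `pglm_fit`: coefficients, selected features, `w`, importance
#'   (absolute standardized coefficient), predictions for missing species,
#'   fitted values, and the design condition number.
#' @export
fit_pglm <- function(X, y_known, phylo_cov, spatial_cov, select = TRUE,
                     w_grid = seq(0, 1, by = 0.1)) {
  sp <- rownames(X)
  stopifnot(!is.null(sp), all(sp %in% names(y_known)))
  y <- y_known[sp]
  obs <- which(!is.na(y)); mis <- which(is.na(y))
  Cp <- stats::cov2cor(as.matrix(phylo_cov)[sp, sp])
  Cs <- stats::cov2cor(as.matrix(spatial_cov)[sp, sp])
  Xd <- .drop_aliased(cbind(`(Intercept)` = 1, X))
  Xo <- Xd[obs, , drop = FALSE]
  best <- NULL
  for (w in w_grid) {
    V <- w * Cp[obs, obs] + (1 - w) * Cs[obs, obs]
    diag(V) <- diag(V) + 1e-8
    f <- .gls_fit(Xo, y[obs], V)
    if (is.null(best) || f$loglik > best$fit$loglik)
      best <- list(w = w, fit = f)
  }
  w <- best$w
  feats <- colnames(Xo)
  if (select) {
    z <- best$fit$beta / pmax(best$fit$se, .Machine$double.eps)
    keep <- abs(z) > 1.96 | feats == "(Intercept)"
    if (sum(keep) < 2) keep <- rep(TRUE, length(keep))
    feats <- feats[keep]
    V <- w * Cp[obs, obs] + (1 - w) * Cs[obs, obs]
    diag(V) <- diag(V) + 1e-8
    best$fit <- .gls_fit(Xo[, feats, drop = FALSE], y[obs], V)
  }
  V_all <- w * Cp + (1 - w) * Cs
  diag(V_all) <- diag(V_all) + 1e-8
  beta <- best$fit$beta
  mu_all <- as.numeric(Xd[, feats, drop = FALSE] %*% beta)
  pred <- setNames(numeric(0), character(0))
  if (length(mis)) {
    K <- V_all[mis, obs, drop = FALSE] %*% solve(V_all[obs, obs])
    raw <- mu_all[mis] + as.numeric(K %*% (y[obs] - mu_all[obs]))
    pred <- setNames(pmin(pmax(raw, 1), 6), sp[mis])
  }
  imp <- abs(beta[setdiff(feats, "(Intercept)")])
  structure(list(beta = beta, se = best$fit$se, w = w,
                 selected_features = feats,
                 importance = sort(imp, decreasing = TRUE),
                 predictions = pred,
                 fitted = setNames(pmin(pmax(mu_all, 1), 6), sp),
                 sigma2 = best$fit$sigma2, loglik = best$fit$loglik,
                 condition_number = best$fit$kappa,
                 obs_species = sp[obs]),
            class = "pglm_fit")
}

#' Random-forest regression on status codes
#'
#' 500-tree regression forest over all predictors with `mtry` tuned by
#' out-of-bag error; permutation importance is returned. Predictors are used
#' on their encoded scale without further transformation.
#'
#' @param X predictor matrix (all species, rows named).
#' @param y_known named status codes with `NA` for species to impute.
#' @param n_trees number of trees.
#' @param tune_mtry tune `mtry` over a small grid by OOB error.
#' @param seed integer seed.
#' @return an `rf_fit` with the model, `mtry`, importance (permutation),
#'   predictions for missing species (clamped to `[1, 6]`), and OOB
#'   predictions.
#' @export
fit_rf <- function(X, y_known, n_trees = 500L, tune_mtry = TRUE, seed = NULL) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sp <- rownames(X)
  y <- y_known[sp]
  obs <- which(!is.na(y)); mis <- which(is.na(y))
  p <- ncol(X)
  cands <- if (tune_mtry)
    sort(unique(pmax(1, c(floor(sqrt(p)), floor(p / 3), floor(2 * p / 3))))) else
      max(floor(p / 3), 1)
  best <- NULL
  for (m in cands) {
    fit <- randomForest::randomForest(X[obs, , drop = FALSE], y[obs],
                                      ntree = n_trees, mtry = m,
                                      importance = TRUE)
    oob <- mean((fit$predicted - y[obs])^2)
    if (is.null(best) || oob < best$oob) best <- list(fit = fit, mtry = m, oob = oob)
  }
  imp <- randomForest::importance(best$fit, type = 1)[, 1]
  pred <- setNames(numeric(0), character(0))
  if (length(mis))
    pred <- setNames(pmin(pmax(predict(best$fit, X[mis, , drop = FALSE]), 1), 6),
                     sp[mis])
  structure(list(model = best$fit, mtry = best$mtry,
                 importance = sort(imp, decreasing = TRUE),
                 predictions = pred,
                 oob_predictions = setNames(best$fit$predicted, sp[obs]),
                 oob_mse = best$oob),
            class = "rf_fit")
}

#' Single-hidden-layer neural network on status codes
#'
#' Feed-forward perceptron with one hidden layer trained by backpropagation
#' under a squared-error cost, tuned by repeated k-fold cross-validation over
#' hidden-layer size and weight decay. Inputs must be min-max scaled to
#' `[0, 1]`. Importance is the Olden connection-weight product: the absolute
#' sum over hidden units of input-hidden times hidden-output weights.
#'
#' @param X_minmax predictor matrix on `[0, 1]` (all species, rows named).
#' @param y_known named status codes with `NA` for species to impute.
#' @param hidden_sizes candidate hidden-layer sizes (all >= 1).
#' @param decays candidate weight-decay values.
#' @param k_folds,repeats repeated k-fold settings for tuning.
#' @param maxit training iterations per fit.
#' @param seed integer seed (fixes fold draws and weight initialization).
#' @return an `ann_fit` with the model, chosen size/decay, importance,
#'   predictions for missing species (clamped), and CV RMSE table.
#' @export
fit_ann <- function(X_minmax, y_known, hidden_sizes = c(4L, 8L),
                    decays = c(0.1, 0.01), k_folds = 10L, repeats = 5L,
                    maxit = 200L, seed = NULL) {
  if (any(hidden_sizes < 1))
    stop("hidden-layer size must be >= 1", call. = FALSE)
  if (any(X_minmax < -1e-9 | X_minmax > 1 + 1e-9))
    stop("inputs must be min-max scaled to [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sp <- rownames(X_minmax)
  y <- y_known[sp]
  obs <- which(!is.na(y)); mis <- which(is.na(y))
  Xo <- X_minmax[obs, , drop = FALSE]; yo <- y[obs]
  n <- length(obs)
  grid <- expand.grid(size = hidden_sizes, decay = decays)
  grid$rmse <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    errs <- numeric(0)
    for (r in seq_len(repeats)) {
      fold <- sample(rep_len(seq_len(k_folds), n))
      for (f in seq_len(k_folds)) {
        te <- fold == f
        fit <- nnet::nnet(Xo[!te, , drop = FALSE], yo[!te],
                          size = grid$size[gi], decay = grid$decay[gi],
                          linout = TRUE, maxit = maxit, trace = FALSE)
        ph <- predict(fit, Xo[te, , drop = FALSE])
        errs <- c(errs, (ph - yo[te])^2)
      }
    }
    grid$rmse[gi] <- sqrt(mean(errs))
  }
  bi <- which.min(grid$rmse)
  model <- nnet::nnet(Xo, yo, size = grid$size[bi], decay = grid$decay[bi],
                      linout = TRUE, maxit = maxit, trace = FALSE)
  # Olden connection-weight importance: |sum_h w_ih * w_ho| per input
  wts <- nnet_weight_matrices(model, ncol(Xo), grid$size[bi])
  contrib <- abs(wts$W1 %*% wts$W2)  # p x 1
  imp <- setNames(as.numeric(contrib) / sum(contrib), colnames(Xo))
  pred <- setNames(numeric(0), character(0))
  if (length(mis))
    pred <- setNames(pmin(pmax(as.numeric(
      predict(model, X_minmax[mis, , drop = FALSE])), 1), 6), sp[mis])
  structure(list(model = model, size = grid$size[bi], decay = grid$decay[bi],
                 importance = sort(imp, decreasing = TRUE),
                 predictions = pred, cv_table = grid),
            class = "ann_fit")
}

# Unpack nnet's flat weight vector into input-hidden and hidden-output
# matrices (single hidden layer, linear output, bias rows dropped).
nnet_weight_matrices <- function(model, p, size) {
  w <- model$wts
  W1 <- matrix(0, p, size)
  for (h in seq_len(size)) {
    off <- (h - 1) * (p + 1)
    W1[, h] <- w[(off + 2):(off + p + 1)]
  }
  off <- size * (p + 1)
  W2 <- matrix(w[(off + 2):(off + size + 1)], size, 1)
  list(W1 = W1, W2 = W2)
}

#' Cross-validate a status model
#'
#' Runs leave-one-out or repeated k-fold cross-validation of a fitting
#' routine, rounds the continuous predictions to categories (half-up, toward
#' the more-threatened class), and tabulates a 6 x 6 confusion matrix with
#' accuracy, per-class sensitivity/specificity, and the distribution of
#' absolute category errors. Folds whose training part lacks a class are
#' recorded, never dropped.
#'
#' @param fit_fun function `(X_train, y_train, X_test) -> numeric predictions`.
#' @param X predictor matrix of assessed species.
#' @param y integer status codes (1-6).
#' @param scheme `"loocv"` or `"repeated_kfold"`.
#' @param k,repeats k-fold settings.
#' @param seed integer seed for fold assignment.
#' @return list with `confusion`, `accuracy`, `per_class` (sensitivity,
#'   specificity), `abs_error_table`, `mean_abs_error`, `predictions`,
#'   `folds_missing_class`.
#' @export
crossvalidate <- function(fit_fun, X, y, scheme = c("loocv", "repeated_kfold"),
                          k = 10L, repeats = 5L, seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  stopifnot(nrow(X) == n)
  preds <- rep(NA_real_, n)
  folds_missing_class <- 0L
  run_fold <- function(te) {
    if (length(unique(y[-which(te)])) < length(unique(y)))
      folds_missing_class <<- folds_missing_class + 1L
    fit_fun(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE])
  }
  if (scheme == "loocv") {
    for (i in seq_len(n)) {
      te <- seq_len(n) == i
      preds[i] <- run_fold(te)
    }
    pred_mat <- matrix(preds, ncol = 1)
  } else {
    pred_mat <- matrix(NA_real_, n, repeats)
    for (r in seq_len(repeats)) {
      fold <- sample(rep_len(seq_len(k), n))
      for (f in seq_len(k)) {
        te <- fold == f
        pred_mat[te, r] <- run_fold(te)
      }
    }
    preds <- rowMeans(pred_mat)
  }
  cat_pred <- pmin(pmax(floor(preds + 0.5), 1), 6)
  lev <- 1:6
  confusion <- table(known = factor(y, levels = lev),
                     predicted = factor(cat_pred, levels = lev))
  acc <- mean(cat_pred == y)
  per_class <- t(vapply(lev, function(cl) {
    tp <- sum(y == cl & cat_pred == cl)
    fn <- sum(y == cl & cat_pred != cl)
    tn <- sum(y != cl & cat_pred != cl)
    fp <- sum(y != cl & cat_pred == cl)
    c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  }, numeric(2)))
  rownames(per_class) <- names(.iucn_codes)
  abs_err <- abs(cat_pred - y)
  list(confusion = confusion, accuracy = acc, per_class = per_class,
       abs_error_table = table(factor(abs_err, levels = 0:5)),
       mean_abs_error = mean(abs_err),
       predictions = preds, categories = cat_pred,
       folds_missing_class = folds_missing_class)
}

#' Pool three model predictions
#'
#' Clamps each continuous prediction to `[1, 6]`, averages them, and rounds
#' the mean to the nearest category with ties (x.5) rounded up toward the
#' more-threatened class.
#'
#' @param p_pglm,p_rf,p_ann numeric predictions (equal length, no `NA`).
#' @return data.frame with `pooled` (continuous) and `category` (1-6).
#' @export
pool_predictions <- function(p_pglm, p_rf, p_ann) {
  if (anyNA(p_pglm) || anyNA(p_rf) || anyNA(p_ann))
    stop("missing prediction passed to pooling", call. = FALSE)
  stopifnot(length(p_pglm) == length(p_rf), length(p_rf) == length(p_ann))
  cl <- function(p) pmin(pmax(p, 1), 6)
  pooled <- (cl(p_pglm) + cl(p_rf) + cl(p_ann)) / 3
  data.frame(pooled = pooled,
             category = pmin(pmax(floor(pooled + 0.5), 1L), 6L))
}

#' Concordance of per-model categorical predictions
#'
#' For S species and three models there are 3S unordered model pairs;
#' a pair is identical when the categories match and adjacent when they
#' differ by exactly one class.
#'
#' @param per_model_categories S x 3 matrix (or data.frame) of categories.
#' @return list of counts and percentages.
#' @export
concordance <- function(per_model_categories) {
  M <- as.matrix(per_model_categories)
  if (ncol(M) != 3L) stop("expected one column per model (3)", call. = FALSE)
  if (anyNA(M)) stop("missing categories", call. = FALSE)
  S <- nrow(M)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  d <- sapply(pairs, function(p) abs(M[, p[1]] - M[, p[2]]))
  if (is.null(dim(d))) d <- matrix(d, nrow = S)
  ident_pairs <- rowSums(d == 0)
  n_all_identical <- sum(ident_pairs == 3)
  n_two_agree <- sum(ident_pairs == 1)
  total_pairs <- 3L * S
  pairwise_identical <- sum(d == 0)
  pairwise_adjacent <- sum(d == 1)
  list(n_species = S,
       n_all_identical = n_all_identical,
       n_two_agree = n_two_agree,
       total_pairwise = total_pairs,
       pairwise_identical = pairwise_identical,
       pairwise_adjacent = pairwise_adjacent,
       pct_identical = 100 * pairwise_identical / total_pairs,
       pct_adjacent = 100 * pairwise_adjacent / total_pairs,
       pct_identical_or_adjacent =
         100 * (pairwise_identical + pairwise_adjacent) / total_pairs)
}

#' Run the full three-model imputation ensemble
#'
#' Builds the PGLM (z-scored) and network (min-max) predictor matrices with
#' phylogenetic and spatial PCoA axes, fits the PGLM, random forest, and
#' neural network to the assessed species, predicts the masked species with
#' each, and pools the three predictions.
#'
#' @param table species table (see [simulate_species_table()]), with
#'   `status_code` `NA` for species to impute.
#' @param tree ultrametric `phylo` over the table's species.
#' @param seed integer seed.
#' @param ann_args,rf_args optional lists of extra arguments.
#' @return list with the three fits, `predictions` (per model, pooled
#'   continuous and category, per missing species), and `concordance`.
#' @export
impute_threat_ensemble <- function(table, tree, seed = 1L,
                                   ann_args = list(), rf_args = list()) {
  y <- setNames(as.numeric(table$status_code), table$species)
  Bz <- build_predictor_matrix(table, tree, "pglm")
  Bm <- build_predictor_matrix(table, tree, "minmax")
  set.seed(seed)
  pg <- fit_pglm(Bz$X, y, Bz$phylo_cor, Bz$spatial_cor)
  rf <- do.call(fit_rf, c(list(X = Bz$X, y_known = y, seed = seed + 1L),
                          rf_args))
  ann <- do.call(fit_ann, c(list(X_minmax = Bm$X, y_known = y,
                                 seed = seed + 2L), ann_args))
  mis <- names(which(is.na(y)))
  pooled <- pool_predictions(pg$predictions[mis], rf$predictions[mis],
                             ann$predictions[mis])
  cats <- cbind(pglm = pmin(pmax(floor(pg$predictions[mis] + 0.5), 1), 6),
                rf = pmin(pmax(floor(rf$predictions[mis] + 0.5), 1), 6),
                ann = pmin(pmax(floor(ann$predictions[mis] + 0.5), 1), 6))
  preds <- data.frame(species = mis,
                      pglm = pg$predictions[mis], rf = rf$predictions[mis],
                      ann = ann$predictions[mis],
                      pooled = pooled$pooled, category = pooled$category,
                      row.names = mis, stringsAsFactors = FALSE)
  list(pglm = pg, rf = rf, ann = ann, predictions = preds,
       per_model_categories = cats,
       concordance = concordance(cats))
}
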