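# Synthetic ranges, predictors, and ordinal threat statuses --------------

#' Simulate species ranges on an abstract equal-area grid
#'
#' Each species occupies one contiguous blob of grid cells, grown from a
#' random seed cell by repeatedly annexing a random 4-neighbour of the
#' current blob. The grid is an abstract equal-area plane: area is cell count
#' times `cell_area`, and the centroid is the mean of occupied cell centers.
#'
#' @param n_species number of species.
#' @param grid_dims `c(nrow, ncol)` of the grid.
#' @param mean_cells mean blob size (cells); sizes are `1 + Poisson(mean-1)`.
#' @param cell_area area of one cell (km^2).
#' @param seed optional integer seed.
#' @param species optional character vector of species labels.
#' @return list with `grid` (a `range_grid`: dims, cell_area, occupancy
#'   species x cells), `centroids` (n x 2 matrix, x/y in cell units), and
#'   `areas` (km^2).
#' @export
simulate_ranges <- function(n_species, grid_dims = c(20L, 40L), mean_cells = 12,
                            cell_area = 2500, seed = NULL, species = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- grid_dims[1]; nc <- grid_dims[2]; ncell <- nr * nc
  if (mean_cells > ncell)
    stop("mean_cells exceeds the number of grid cells", call. = FALSE)
  if (is.null(species)) species <- sprintf("t%d", seq_len(n_species))
  occ <- matrix(FALSE, n_species, ncell,
                dimnames = list(species, NULL))
  cell_id <- function(r, c) (c - 1L) * nr + r
  for (i in seq_len(n_species)) {
    size <- min(1L + rpois(1, max(mean_cells - 1, 0)), ncell)
    r <- sample.int(nr, 1L); c <- sample.int(nc, 1L)
    blob_r <- r; blob_c <- c
    while (length(blob_r) < size) {
      j <- sample.int(length(blob_r), 1L)
      dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
      k <- sample.int(4L, 1L)
      nr2 <- blob_r[j] + dr[k]; nc2 <- blob_c[j] + dc[k]
      if (nr2 < 1L || nr2 > nr || nc2 < 1L || nc2 > nc) next
      if (any(blob_r == nr2 & blob_c == nc2)) next
      blob_r <- c(blob_r, nr2); blob_c <- c(blob_c, nc2)
    }
    occ[i, cell_id(blob_r, blob_c)] <- TRUE
  }
  centroids <- t(vapply(seq_len(n_species), function(i) {
    cells <- which(occ[i, ])
    rr <- (cells - 1L) %% nr + 1L
    cc <- (cells - 1L) %/% nr + 1L
    c(x = mean(cc) - 0.5, y = mean(rr) - 0.5)
  }, numeric(2)))
  rownames(centroids) <- species
  areas <- rowSums(occ) * cell_area
  grid <- structure(list(dims = c(nr, nc), cell_area = cell_area, occupancy = occ),
                    class = "range_grid")
  list(grid = grid, centroids = centroids, areas = areas)
}

#' Configuration for the ordinal threat-status generator
#'
#' The latent threat score is a sum of a dominant (negative) log-range-area
#' effect, minor predictor effects, a Brownian latent effect on the tree
#' (phylogenetic signal), a spatially autocorrelated effect (exponential-decay
#' kernel on range-centroid distance), and unit residual noise. Five
#' increasing cutpoints map the score to the six ordered IUCN-style
#' categories LC < NT < VU < EN < CR < EX.
#'
#' @param beta_area coefficient on standardized log range area (negative:
#'   small ranges are threatened).
#' @param beta_other named vector of minor coefficients on the standardized
#'   continuous predictors (any of `hei`, `climate_pc1`, `climate_pc2`,
#'   `aet`, `npp`, `body_length`, `body_mass`).
#' @param phylo_signal_sd SD of the Brownian latent effect at the tips.
#' @param spatial_signal_sd SD of the spatial Gaussian-process effect.
#' @param spatial_range e-folding distance of the exponential spatial kernel
#'   (grid-cell units).
#' @param thresholds five strictly increasing cutpoints on the latent scale.
#' @param mask_fraction fraction of species whose status is masked (DD/UA).
#' @param mask_bias_area if `TRUE`, masking probability is weighted toward
#'   small-range species.
#' @return a `status_gen_config` list.
#' @export
status_gen_config <- function(beta_area = -1.5,
                              beta_other = c(hei = 0.4, climate_pc1 = 0.2),
                              phylo_signal_sd = 0.75,
                              spatial_signal_sd = 0.75,
                              spatial_range = 6,
                              thresholds = c(-2.2, -1.1, 0.2, 1.3, 2.6),
                              mask_fraction = 0.3,
                              mask_bias_area = FALSE) {
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  if (length(thresholds) != 5L)
    stop("exactly 5 thresholds are required for 6 categories", call. = FALSE)
  if (mask_fraction < 0 || mask_fraction >= 1)
    stop("mask_fraction must be in [0, 1)", call. = FALSE)
  structure(list(beta_area = beta_area, beta_other = beta_other,
                 phylo_signal_sd = phylo_signal_sd,
                 spatial_signal_sd = spatial_signal_sd,
                 spatial_range = spatial_range,
                 thresholds = thresholds, mask_fraction = mask_fraction,
                 mask_bias_area = mask_bias_area),
            class = "status_gen_config")
}

.status_levels <- c("LC", "NT", "VU", "EN", "CR", "EX")

#' Simulate a species table with predictors and ordinal threat statuses
#'
#' Builds the predictor inventory used throughout the pipeline (body length
#' and mass, microhabitat, endemicity, ecoregion, range area, human
#' encroachment, two climate components, AET, NPP) and draws threat
#' statuses from a latent score with a dominant negative range-area effect,
#' phylogenetic and spatial signal. A fixed fraction of statuses is masked
#' (recorded as `DD`), exactly `round(mask_fraction * n)` species.
#'
#' @param tree ultrametric `phylo`; tips define the species set.
#' @param centroids n x 2 matrix of range centroids (rows named by species).
#' @param areas named vector of range areas (km^2).
#' @param cfg a [status_gen_config()].
#' @param seed optional integer seed.
#' @return data.frame, one row per species: predictors, `status` (factor with
#'   levels LC..EX, `NA` where masked), `status_code` (1-6 or `NA`),
#'   `true_status_code` (unmasked truth), `masked` flag, centroid and area.
#' @export
simulate_species_table <- function(tree, centroids, areas, cfg = status_gen_config(),
                                   seed = NULL) {
  stopifnot(inherits(cfg, "status_gen_config"))
  if (!is.null(seed)) set.seed(seed)
  sp <- tree$tip.label
  n <- length(sp)
  stopifnot(all(sp %in% rownames(centroids)), all(sp %in% names(areas)))
  centroids <- centroids[sp, , drop = FALSE]
  areas <- areas[sp]

  # continuous predictors; body size has phylogenetic signal via BM
  bl <- simulate_levy_trait(tree, levy_model(sigma2 = 0.01, root_state = log(40)))
  body_length <- exp(bl$tip_values)               # cm
  body_mass <- exp(1.1 * log(body_length) + rnorm(n, 0, 0.3))  # allometric, kg-ish
  hei <- pmin(pmax(rnorm(n, 0.35, 0.18), 0), 1)
  climate_pc1 <- rnorm(n)
  climate_pc2 <- rnorm(n)
  aet <- exp(rnorm(n, 6.5, 0.4))
  npp <- exp(rnorm(n, 6.0, 0.5))
  microhabitat <- factor(sample(c("aquatic", "semiaquatic", "terrestrial"),
                                n, TRUE, prob = c(0.45, 0.3, 0.25)))
  endemicity <- factor(sample(c("endemic", "widespread"), n, TRUE,
                              prob = c(0.3, 0.7)))
  ecoregion <- factor(sample(c("Nearctic", "Neotropic", "Afrotropic", "Oriental"),
                             n, TRUE))

  z <- function(v) as.numeric(scale(v))
  minors <- cbind(hei = z(hei), climate_pc1 = z(climate_pc1),
                  climate_pc2 = z(climate_pc2), aet = z(log(aet)),
                  npp = z(log(npp)), body_length = z(log(body_length)),
                  body_mass = z(log(body_mass)))
  bo <- cfg$beta_other
  minor_eff <- if (length(bo)) minors[, names(bo), drop = FALSE] %*% bo else 0

  phylo_eff <- if (cfg$phylo_signal_sd > 0) {
    g <- simulate_levy_trait(tree, levy_model(sigma2 = 1))$tip_values
    cfg$phylo_signal_sd * (g - mean(g)) / max(sd(g), .Machine$double.eps)
  } else rep(0, n)

  spatial_eff <- if (cfg$spatial_signal_sd > 0) {
    D <- as.matrix(dist(centroids))
    K <- exp(-D / cfg$spatial_range)
    L <- chol(K + diag(1e-8, n))
    g <- as.numeric(t(L) %*% rnorm(n))
    cfg$spatial_signal_sd * (g - mean(g)) / max(sd(g), .Machine$double.eps)
  } else rep(0, n)

  latent <- cfg$beta_area * z(log(areas)) + as.numeric(minor_eff) +
    phylo_eff + spatial_eff + rnorm(n)
  code <- findInterval(latent, cfg$thresholds) + 1L
  status <- factor(.status_levels[code], levels = .status_levels)

  n_mask <- round(cfg$mask_fraction * n)
  w <- if (cfg$mask_bias_area) 1 / sqrt(areas) else rep(1, n)
  masked_idx <- sample.int(n, n_mask, prob = w)
  masked <- seq_len(n) %in% masked_idx

  out <- data.frame(species = sp, body_length = body_length,
                    body_mass = body_mass, microhabitat = microhabitat,
                    endemicity = endemicity, ecoregion = ecoregion,
                    range_area = as.numeric(areas), hei = hei,
                    climate_pc1 = climate_pc1, climate_pc2 = climate_pc2,
                    aet = aet, npp = npp,
                    centroid_x = centroids[, 1], centroid_y = centroids[, 2],
                    true_status_code = code,
                    status_code = ifelse(masked, NA_integer_, code),
                    status = status, masked = masked,
                    stringsAsFactors = FALSE, row.names = sp)
  out$status[masked] <- NA
  out
}
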