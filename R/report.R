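# Summary statistics, hypothesis tests, and pipeline orchestration -------

#' Threat-status breakdown
#'
#' Counts per category with the headline fractions: threatened is VU+EN+CR,
#' reported relative to species with a (final) status; threatened-or-extinct
#' adds EX and is reported relative to all species. Display percentages are
#' rounded to the nearest integer; raw fractions are retained.
#'
#' @param status character vector (or factor) of final categories
#'   (LC/NT/VU/EN/CR/EX).
#' @param assessed optional logical vector: `TRUE` for originally assessed
#'   species, `FALSE` for imputed ones.
#' @param groups optional grouping factor (e.g., clade).
#' @return data.frame, one row per group plus `overall`.
#' @export
status_summary <- function(status, assessed = NULL, groups = NULL) {
  status <- as.character(status)
  bad <- !(status %in% names(.iucn_codes))
  if (any(bad))
    stop("unknown status label(s): ", paste(unique(status[bad]), collapse = ", "),
         call. = FALSE)
  if (is.null(assessed)) assessed <- rep(TRUE, length(status))
  one <- function(st, asd) {
    counts <- table(factor(st, levels = names(.iucn_codes)))
    n <- length(st)
    thr <- sum(counts[c("VU", "EN", "CR")])
    thr_ex <- thr + counts[["EX"]]
    data.frame(n = n, n_assessed = sum(asd),
               frac_assessed = sum(asd) / n,
               pct_assessed = round(100 * sum(asd) / n),
               LC = counts[["LC"]], NT = counts[["NT"]], VU = counts[["VU"]],
               EN = counts[["EN"]], CR = counts[["CR"]], EX = counts[["EX"]],
               n_threatened = thr,
               frac_threatened = thr / n,
               pct_threatened = round(100 * thr / n),
               frac_threatened_or_extinct = thr_ex / n,
               pct_threatened_or_extinct = round(100 * thr_ex / n))
  }
  out <- cbind(group = "overall", one(status, assessed))
  if (!is.null(groups)) {
    for (g in unique(as.character(groups))) {
      sel <- groups == g
      out <- rbind(out, cbind(group = g, one(status[sel], assessed[sel])))
    }
  }
  rownames(out) <- out$group
  out
}

#' Two-sample t-test of ED between threatened and non-threatened species
#'
#' Non-threatened (LC, NT) is the first group and threatened (VU, EN, CR)
#' the second, so a negative t means non-threatened species have lower ED.
#' Extinct species are excluded. Welch's unequal-variance test by default.
#'
#' @param ed_values numeric ED values.
#' @param statuses matching category labels.
#' @param var_equal use the pooled-variance test instead of Welch.
#' @return list with `t`, `p_value`, `df`, `median_nonthreatened`,
#'   `median_threatened`, `n`.
#' @export
ed_threat_ttest <- function(ed_values, statuses, var_equal = FALSE) {
  statuses <- as.character(statuses)
  g1 <- ed_values[statuses %in% c("LC", "NT")]
  g2 <- ed_values[statuses %in% c("VU", "EN", "CR")]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs at least 2 species", call. = FALSE)
  tt <- t.test(g1, g2, var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       median_nonthreatened = median(g1), median_threatened = median(g2),
       n = c(nonthreatened = length(g1), threatened = length(g2)))
}

#' Notch-overlap comparison of ED across categories
#'
#' Boxplot notches are `median +/- 1.58 * IQR / sqrt(n)`; two categories
#' whose notches do not overlap differ at roughly the 5% level.
#'
#' @param ed_values numeric ED values.
#' @param statuses matching category labels.
#' @return symmetric logical matrix: `TRUE` where notches overlap.
#' @export
notch_test <- function(ed_values, statuses) {
  statuses <- factor(as.character(statuses),
                     levels = intersect(names(.iucn_codes), unique(statuses)))
  lev <- levels(statuses)
  lims <- t(vapply(lev, function(l) {
    v <- ed_values[statuses == l]
    md <- median(v)
    half <- 1.58 * IQR(v) / sqrt(length(v))
    c(lo = md - half, hi = md + half)
  }, numeric(2)))
  ov <- outer(seq_along(lev), seq_along(lev), Vectorize(function(i, j)
    lims[i, "lo"] <= lims[j, "hi"] && lims[j, "lo"] <= lims[i, "hi"]))
  dimnames(ov) <- list(lev, lev)
  ov
}

#' Histogram and mode locations of an ED distribution
#'
#' Kernel-density local maxima, ordered by height; degenerate (constant)
#' input yields a single mode.
#'
#' @param ed_values numeric vector.
#' @param bin_width histogram bin width (default: Sturges breaks).
#' @return list with `histogram` (breaks, counts), `modes` (positions,
#'   ordered by density height), `density`.
#' @export
ed_distribution <- function(ed_values, bin_width = NULL) {
  if (!length(ed_values)) stop("empty input", call. = FALSE)
  if (sd(ed_values) == 0) {
    return(list(histogram = list(breaks = NULL, counts = length(ed_values)),
                modes = ed_values[1], density = NULL))
  }
  breaks <- if (is.null(bin_width)) "Sturges" else
    seq(min(ed_values), max(ed_values) + bin_width, by = bin_width)
  h <- hist(ed_values, breaks = breaks, plot = FALSE)
  d <- density(ed_values)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(locmax)) locmax <- which.max(y)
  modes <- d$x[locmax][order(y[locmax], decreasing = TRUE)]
  list(histogram = list(breaks = h$breaks, counts = h$counts),
       modes = modes, density = d)
}

#' Default pipeline configuration
#'
#' Laptop-scale defaults: 200 species, 100 posterior trees, 10,000 MCMC
#' generations.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir run directory for outputs.
#' @param ... overrides for any configuration entry.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("carapace_run_"),
                            ...) {
  cfg <- list(seed = seed, out_dir = out_dir,
              n_species = 200L, lambda = 0.07, mu = 0.03,
              n_posterior_trees = 100L, age_jitter_cv = 0.05,
              grid_dims = c(20L, 40L), mean_cells = 12, cell_area = 2500,
              status = status_gen_config(),
              mcmc_n_gen = 10000L, mcmc_burnin = 0.25,
              levy_alpha = NULL, levy_n_vectors = 500L, levy_burnin = 100L,
              ann_args = list(hidden_sizes = c(4L, 8L), decays = c(0.1, 0.01),
                              k_folds = 5L, repeats = 2L),
              top_n = 10L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full synthetic-data pipeline
#'
#' Generates a tree, posterior set, ranges, traits, and statuses; runs the
#' diversification MCMC, the jump analysis, ED/EDGE scoring, the imputation
#' ensemble, and the spatial and summary reports; writes every output under
#' the run directory and returns a manifest. Reruns with the same
#' configuration are reproducible stage by stage.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (list), invisibly written as JSON too.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  save_tsv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  seed <- config$seed

  tree <- .stage("synth_tree", {
    set.seed(seed)
    ape::rphylo(config$n_species, config$lambda, config$mu)
  })
  write_trees(tree, file.path(config$out_dir, "tree.nwk"))
  paths[["tree.nwk"]] <- file.path(config$out_dir, "tree.nwk")

  post <- .stage("posterior_set",
                 simulate_posterior_set(tree, config$n_posterior_trees,
                                        config$age_jitter_cv, seed = seed + 1L))
  write_trees(post, file.path(config$out_dir, "posterior.nwk"))
  paths[["posterior.nwk"]] <- file.path(config$out_dir, "posterior.nwk")

  rng <- .stage("ranges",
                simulate_ranges(config$n_species, config$grid_dims,
                                config$mean_cells, config$cell_area,
                                seed = seed + 2L, species = tree$tip.label))
  tab <- .stage("species_table",
                simulate_species_table(tree, rng$centroids, rng$areas,
                                       config$status, seed = seed + 3L))
  save_tsv(tab, "species_table.tsv")

  fit_bd <- .stage("divrates_fit", fit_constant_bd(tree))
  comet <- .stage("divrates_mcmc",
                  comet_mcmc(tree, n_gen = config$mcmc_n_gen,
                             burnin_frac = config$mcmc_burnin,
                             seed = seed + 4L))
  rtt <- .stage("rates_through_time", rates_through_time(comet))
  save_tsv(rtt, "rates_through_time.tsv")
  bf <- .stage("bayes_factors", bayes_factors(comet))
  save_tsv(bf$me, "bayes_factors_me.tsv")

  trait <- .stage("levy_trait", {
    simulate_levy_trait(tree, levy_model(sigma2 = 0.05, jump_rate = 0.002,
                                         alpha = 30, root_state = log(40)),
                        seed = seed + 5L)
  })
  alpha_hat <- config$levy_alpha
  if (is.null(alpha_hat)) alpha_hat <- 30
  jumps <- .stage("jump_mcmc",
                  sample_jump_vectors(tree, trait$tip_values, alpha_hat,
                                      n_vectors = config$levy_n_vectors,
                                      burnin = config$levy_burnin,
                                      seed = seed + 6L))
  save_tsv(data.frame(branch = names(jumps$pp), pp = jumps$pp),
           "jump_pp.tsv")

  ed <- .stage("median_ed", median_ed(post))
  save_tsv(ed, "ed.tsv")

  ens <- .stage("imputation",
                impute_threat_ensemble(tab, tree, seed = seed + 7L,
                                       ann_args = config$ann_args))
  save_tsv(ens$predictions, "imputed_status.tsv")

  final_code <- tab$status_code
  names(final_code) <- tab$species
  final_code[rownames(ens$predictions)] <- ens$predictions$category
  final_status <- names(.iucn_codes)[final_code]
  names(final_status) <- tab$species

  edt <- .stage("edge", {
    et <- edge_table(ed, final_status)
    et$rank <- rank(-et$edge, ties.method = "first")
    et
  })
  save_tsv(edt, "edge.tsv")
  top <- rank_edge(edt, config$top_n)
  save_tsv(top, "edge_top.tsv")

  maps <- .stage("spatial", {
    thr <- richness_map(rng$grid, final_code, "threatened")
    non <- richness_map(rng$grid, final_code, "nonthreatened")
    ew <- edge_weighted_richness(rng$grid, edt)
    write.table(thr, file.path(config$out_dir, "richness_threatened.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(non, file.path(config$out_dir, "richness_nonthreatened.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(ew, file.path(config$out_dir, "richness_edge_weighted.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    list(threatened = thr, nonthreatened = non, edge_weighted = ew)
  })
  paths[["richness_threatened.tsv"]] <-
    file.path(config$out_dir, "richness_threatened.tsv")
  paths[["richness_nonthreatened.tsv"]] <-
    file.path(config$out_dir, "richness_nonthreatened.tsv")
  paths[["richness_edge_weighted.tsv"]] <-
    file.path(config$out_dir, "richness_edge_weighted.tsv")

  summ <- .stage("report", {
    ss <- status_summary(final_status, assessed = !tab$masked)
    tt <- ed_threat_ttest(ed[tab$species, "ed"], final_status)
    list(status_summary = ss, ed_ttest = tt,
         lambda_hat = fit_bd$lambda_hat, mu_hat = fit_bd$mu_hat,
         me_overall_2lnbf = bf$me_overall$two_ln_bf,
         concordance = ens$concordance)
  })
  save_tsv(summ$status_summary, "status_summary.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("carapace")),
    seed = seed,
    config = config[setdiff(names(config), c("status"))],
    outputs = lapply(paths, normalizePath),
    md5 = as.list(tools::md5sum(unlist(paths))),
    summary = list(n_species = config$n_species,
                   lambda_hat = summ$lambda_hat, mu_hat = summ$mu_hat,
                   pct_threatened_or_extinct =
                     summ$status_summary["overall", "pct_threatened_or_extinct"],
                   ed_ttest_t = summ$ed_ttest$t,
                   concordance_pct_identical = summ$concordance$pct_identical),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, force = TRUE)
  writeLines(json, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}
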