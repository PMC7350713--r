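# Birth-death tree simulation with rate shifts and mass extinctions -----

#' Configuration for birth-death tree simulation
#'
#' Time runs backward from the present: tips are at age 0 and the crown node
#' at `crown_age` Myr. `rate_shifts` are (age, new lambda, new mu) triples:
#' `lambda0`/`mu0` apply from the crown toward the present until the oldest
#' shift age is crossed, after which the shifted rates apply. Mass extinctions
#' are (age, survival) pairs: at that instant every lineage survives
#' independently with the given probability (default survival 0.05, i.e. 95%
#' extinction, the conventional severity for mass-extinction scans).
#'
#' @param n_species target richness; used to derive `crown_age` when the
#'   latter is `NULL` (so that the crown expectation `2*exp((lambda-mu)*t)`
#'   equals `n_species`).
#' @param lambda0 speciation rate (events/lineage/Myr).
#' @param mu0 extinction rate (events/lineage/Myr).
#' @param crown_age crown age in Myr (optional if `n_species` given).
#' @param rate_shifts list of `list(time=, lambda=, mu=)`.
#' @param mass_extinctions list of `list(time=, survival=)`.
#' @param seed integer seed or `NULL`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = NULL, lambda0 = 0.07, mu0 = 0.03,
                       crown_age = NULL, rate_shifts = list(),
                       mass_extinctions = list(), seed = NULL) {
  if (!(lambda0 > mu0 && mu0 >= 0))
    stop("need lambda0 > mu0 >= 0", call. = FALSE)
  if (is.null(crown_age)) {
    if (is.null(n_species))
      stop("supply crown_age or n_species", call. = FALSE)
    crown_age <- log(n_species / 2) / (lambda0 - mu0)
  }
  stopifnot(crown_age > 0)
  for (s in rate_shifts) {
    if (!(s$time > 0 && s$time < crown_age))
      stop("rate-shift times must lie strictly inside (0, crown_age)", call. = FALSE)
    if (!(s$lambda >= 0 && s$mu >= 0))
      stop("shifted rates must be non-negative", call. = FALSE)
  }
  for (m in mass_extinctions) {
    if (!(m$time > 0 && m$time < crown_age))
      stop("mass-extinction times must lie strictly inside (0, crown_age)", call. = FALSE)
    if (!(m$survival > 0 && m$survival <= 1))
      stop("mass-extinction survival must be in (0, 1]", call. = FALSE)
  }
  structure(list(n_species = n_species, lambda0 = lambda0, mu0 = mu0,
                 crown_age = crown_age, rate_shifts = rate_shifts,
                 mass_extinctions = mass_extinctions, seed = seed),
            class = "sim_config")
}

# One forward pass; returns NULL on total (or single-crown-lineage) extinction.
.bd_forward_once <- function(cfg) {
  T_end <- cfg$crown_age
  # breakpoints in forward time (since crown)
  brk <- data.frame(t = numeric(0), type = character(0),
                    lambda = numeric(0), mu = numeric(0), survival = numeric(0))
  for (s in cfg$rate_shifts)
    brk <- rbind(brk, data.frame(t = T_end - s$time, type = "shift",
                                 lambda = s$lambda, mu = s$mu, survival = NA))
  for (m in cfg$mass_extinctions) {
    if (m$survival >= 1) next  # survival-1 events are exact no-ops
    brk <- rbind(brk, data.frame(t = T_end - m$time, type = "me",
                                 lambda = NA, mu = NA, survival = m$survival))
  }
  brk <- brk[order(brk$t), , drop = FALSE]

  nmax <- 64L
  parent <- integer(nmax); t_birth <- numeric(nmax); t_end <- numeric(nmax)
  fate <- character(nmax); child1 <- integer(nmax); child2 <- integer(nmax)
  n_lin <- 2L
  parent[1:2] <- 0L; t_birth[1:2] <- 0; fate[1:2] <- "alive"
  alive <- c(1L, 2L)
  grow <- function() {
    nmax <<- nmax * 2L
    length(parent) <<- nmax; length(t_birth) <<- nmax; length(t_end) <<- nmax
    length(fate) <<- nmax; length(child1) <<- nmax; length(child2) <<- nmax
  }
  lam <- cfg$lambda0; mu <- cfg$mu0
  cur <- 0; ib <- 1L
  log_rows <- list()
  while (length(alive) > 0 && cur < T_end) {
    next_brk <- if (ib <= nrow(brk)) brk$t[ib] else T_end
    total <- length(alive) * (lam + mu)
    dt <- if (total > 0) rexp(1, total) else Inf
    if (cur + dt < min(next_brk, T_end)) {
      cur <- cur + dt
      i <- alive[sample.int(length(alive), 1L)]
      if (runif(1) < lam / (lam + mu)) {
        while (n_lin + 2L > nmax) grow()
        a <- n_lin + 1L; b <- n_lin + 2L; n_lin <- n_lin + 2L
        parent[c(a, b)] <- i; t_birth[c(a, b)] <- cur; fate[c(a, b)] <- "alive"
        t_end[i] <- cur; fate[i] <- "speciated"; child1[i] <- a; child2[i] <- b
        alive <- c(setdiff(alive, i), a, b)
      } else {
        t_end[i] <- cur; fate[i] <- "extinct"
        alive <- setdiff(alive, i)
      }
    } else if (next_brk < T_end) {
      cur <- next_brk
      if (brk$type[ib] == "shift") {
        lam <- brk$lambda[ib]; mu <- brk$mu[ib]
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(type = "shift", time_bp = T_end - cur, lambda = lam,
                     mu = mu, survival = NA, n_alive = length(alive),
                     n_killed = NA)
      } else {
        killed <- alive[runif(length(alive)) > brk$survival[ib]]
        t_end[killed] <- cur; fate[killed] <- "extinct"
        alive <- setdiff(alive, killed)
        log_rows[[length(log_rows) + 1L]] <-
          data.frame(type = "mass_extinction", time_bp = T_end - cur,
                     lambda = NA, mu = NA, survival = brk$survival[ib],
                     n_alive = length(alive) + length(killed),
                     n_killed = length(killed))
      }
      ib <- ib + 1L
    } else {
      cur <- T_end
    }
  }
  if (!length(alive)) return(NULL)
  t_end[alive] <- T_end; fate[alive] <- "extant"

  # keep lineages with extant descendants; both crown lineages must be kept
  keep <- logical(n_lin)
  ord <- order(t_birth[seq_len(n_lin)], decreasing = TRUE)
  for (i in ord) {
    keep[i] <- fate[i] == "extant" ||
      (fate[i] == "speciated" && (keep[child1[i]] || keep[child2[i]]))
  }
  if (!(keep[1] && keep[2])) return(NULL)

  # build the reconstructed (pruned) phylo ------------------------------
  n_tip <- sum(fate[seq_len(n_lin)] == "extant" & keep[seq_len(n_lin)])
  if (n_tip < 2L) return(NULL)
  edge <- matrix(0L, 2L * n_tip - 2L, 2L)
  elen <- numeric(2L * n_tip - 2L)
  tip_i <- 0L; node_i <- n_tip + 1L; edge_i <- 0L
  # resolve lineage i (started at t0) to its pruned node id + its start time
  resolve <- function(i, t0) {
    repeat {
      if (fate[i] == "extant") {
        tip_i <<- tip_i + 1L
        return(list(id = tip_i, t0 = t0, len = T_end - t0))
      }
      kids <- c(child1[i], child2[i])
      kk <- kids[keep[kids]]
      if (length(kk) == 2L) {
        node_i <<- node_i + 1L
        my <- node_i
        t_split <- t_end[i]
        for (k in kk) {
          r <- resolve(k, t_split)
          edge_i <<- edge_i + 1L
          edge[edge_i, ] <<- c(my, r$id)
          elen[edge_i] <<- r$len
        }
        return(list(id = my, t0 = t0, len = t_split - t0))
      }
      i <- kk  # unifurcation: pass through
    }
  }
  root <- n_tip + 1L
  for (i in 1:2) {
    r <- resolve(i, 0)
    edge_i <- edge_i + 1L
    edge[edge_i, ] <- c(root, r$id)
    elen[edge_i] <- r$len
  }
  tree <- structure(list(edge = edge, edge.length = elen,
                         tip.label = sprintf("t%d", seq_len(n_tip)),
                         Nnode = n_tip - 1L),
                    class = "phylo", order = "cladewise")
  tree <- ape::reorder.phylo(tree, "cladewise")
  list(tree = tree,
       events = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(type = character(0), time_bp = numeric(0),
                    lambda = numeric(0), mu = numeric(0), survival = numeric(0),
                    n_alive = integer(0), n_killed = integer(0)))
}

#' Simulate a dated tree under an episodic birth-death process
#'
#' Forward simulation from two crown lineages at `crown_age`, with
#' piecewise-constant rates and instantaneous mass-extinction events; extinct
#' lineages are pruned, so the result is the reconstructed, ultrametric tree.
#' Conditioning is on survival of both crown lineages (which preserves the
#' crown age), via rejection with a retry cap.
#'
#' @param config a [sim_config()].
#' @param max_retries rejection cap; exceeded is an explicit error.
#' @return list with `tree` (ultrametric `phylo`), `events` (realized
#'   shift/mass-extinction log), and `config`.
#' @export
simulate_bd_tree <- function(config, max_retries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  for (try in seq_len(max_retries)) {
    out <- .bd_forward_once(config)
    if (!is.null(out)) {
      out$config <- config
      out$retries <- try - 1L
      return(out)
    }
  }
  stop("no surviving crown after ", max_retries,
       " retries; increase the retry cap or the net diversification rate",
       call. = FALSE)
}

#' Emulate a dating posterior by jittering node ages
#'
#' Produces `n_trees` copies of a tree with identical topology and node ages
#' perturbed multiplicatively (normal with coefficient of variation
#' `age_jitter_cv`). A jitter that would make a node older than its parent
#' (or non-positive) is resampled, never clamped, so every output tree is a
#' valid ultrametric dated tree.
#'
#' @param tree ultrametric `phylo`.
#' @param n_trees number of trees to generate.
#' @param age_jitter_cv coefficient of variation of the age perturbation.
#' @param seed optional integer seed.
#' @return a `multiPhylo` of length `n_trees`.
#' @export
simulate_posterior_set <- function(tree, n_trees, age_jitter_cv = 0.05,
                                   seed = NULL) {
  stopifnot(n_trees >= 1, age_jitter_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  stopifnot_ultrametric(tree)
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  # root-to-tip order: a node's parent always precedes it
  ord <- order(ages[-seq_len(ntip)], decreasing = TRUE) + ntip
  out <- vector("list", n_trees)
  for (k in seq_len(n_trees)) {
    new_ages <- ages
    if (age_jitter_cv > 0) {
      for (nd in ord) {
        pa <- parent_of[nd]
        amax <- if (pa > 0) new_ages[pa] else Inf
        # symmetric truncated jitter: Z is resampled (never clamped) into
        # (-U, U), so the median of the jittered age is the input age
        U <- min((amax / ages[nd] - 1) / age_jitter_cv, 1 / age_jitter_cv)
        if (U <= 0) {  # parent drawn below this node's original age
          new_ages[nd] <- runif(1, 0.99, 1) * amax
          next
        }
        repeat {
          z <- rnorm(1)
          if (abs(z) < U) break
        }
        new_ages[nd] <- ages[nd] * (1 + age_jitter_cv * z)
      }
    }
    tr <- tree
    tr$edge.length <- new_ages[tr$edge[, 1]] - new_ages[tr$edge[, 2]]
    out[[k]] <- tr
  }
  structure(out, class = "multiPhylo")
}
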