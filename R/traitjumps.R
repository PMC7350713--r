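# Levy jump-diffusion trait model: likelihoods, jump MCMC, alpha search --
#
# Two likelihood routes are used:
#  * the augmented (jump-counts-given) Gaussian likelihood, computed by
#    Felsenstein pruning with per-branch effective lengths
#    len + n_jumps * alpha (a jump of variance alpha*sigma2 is exactly a
#    branch-length extension of alpha in sigma2 units);
#  * the marginal likelihood with jump counts integrated out, computed by
#    Gaussian-mixture pruning: per-branch counts are summed over a capped,
#    normalized Poisson, so each node's partial likelihood is a Gaussian
#    mixture, reduced deterministically to a bounded component count by
#    weight-preserving moment matching.
# Root handling is REML (contrast) conditioning throughout the Levy
# machinery; plain BM likelihoods expose both REML and ML-root conventions.

.postorder <- function(tree) {
  idx <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  list(edge = tree$edge[idx, , drop = FALSE],
       elen = tree$edge.length[idx],
       ntip = ape::Ntip(tree), nnode = tree$Nnode,
       perm = idx)
}

.check_traits <- function(tree, traits) {
  if (is.null(names(traits)))
    stopifnot(length(traits) == ape::Ntip(tree))
  else {
    miss <- setdiff(tree$tip.label, names(traits))
    if (length(miss))
      stop("traits missing for tips: ", paste(head(miss, 5), collapse = ", "),
           call. = FALSE)
    traits <- traits[tree$tip.label]
  }
  if (anyNA(traits))
    stop("trait vector contains missing values; run impute_tips_bm() first",
         call. = FALSE)
  unname(traits)
}

#' Brownian-motion log-likelihood by pruning
#'
#' @param tree binary ultrametric `phylo`.
#' @param traits named numeric vector of tip values (complete).
#' @param sigma2 Brownian rate > 0.
#' @param root_handling `"ml"` (root state at its conditional ML value,
#'   default) or `"reml"` (contrast likelihood, no root term).
#' @return log-likelihood (scalar).
#' @export
bm_loglik <- function(tree, traits, sigma2, root_handling = c("ml", "reml")) {
  root_handling <- match.arg(root_handling)
  stopifnot_binary(tree); stopifnot_ultrametric(tree)
  x <- .check_traits(tree, traits)
  po <- .postorder(tree)
  c_bm_loglik(po$edge, po$elen, po$ntip, po$nnode, x, sigma2,
              reml = root_handling == "reml")$loglik
}

#' Augmented Levy log-likelihood given per-branch jump counts
#'
#' Gaussian likelihood in which branch `i` has variance
#' `sigma2 * (length_i + jump_counts_i * alpha)`.
#'
#' @param tree binary ultrametric `phylo`.
#' @param traits named numeric tip vector.
#' @param model a [levy_model()].
#' @param jump_counts non-negative integer vector, one per edge in
#'   `tree$edge` order.
#' @param root_handling as in [bm_loglik()].
#' @return log-likelihood (scalar).
#' @export
levy_loglik_given_jumps <- function(tree, traits, model, jump_counts,
                                    root_handling = c("ml", "reml")) {
  root_handling <- match.arg(root_handling)
  stopifnot(inherits(model, "levy_model"))
  if (any(jump_counts < 0)) stop("negative jump counts", call. = FALSE)
  stopifnot(length(jump_counts) == nrow(tree$edge))
  stopifnot_binary(tree); stopifnot_ultrametric(tree)
  x <- .check_traits(tree, traits)
  po <- .postorder(tree)
  eff <- po$elen + jump_counts[po$perm] * model$alpha
  c_bm_loglik(po$edge, eff, po$ntip, po$nnode, x, model$sigma2,
              reml = root_handling == "reml")$loglik
}

# REML estimate of the BM rate from standardized contrasts.
.bm_sigma2_reml <- function(tree, x) {
  if (!is.null(names(x))) x <- x[tree$tip.label]
  pics <- ape::pic(x, tree)
  mean(pics^2)
}

.logsumexp <- function(lw) {
  m <- max(lw)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lw - m)))
}

# weight-preserving moment-matching reduction of a Gaussian mixture
.reduce_mix <- function(m, v, lw, max_comp) {
  finite <- is.finite(lw)
  if (!all(finite) && any(finite)) {
    m <- m[finite]; v <- v[finite]; lw <- lw[finite]
  }
  if (length(lw) <= max_comp) return(list(m = m, v = v, lw = lw))
  o <- order(lw, decreasing = TRUE)
  keep <- o[seq_len(max_comp)]
  for (d in o[-seq_len(max_comp)]) {
    k <- keep[which.min(abs(m[keep] - m[d]))]
    lw_new <- .logsumexp(c(lw[k], lw[d]))
    wk <- exp(lw[k] - lw_new)
    mu <- wk * m[k] + (1 - wk) * m[d]
    v[k] <- wk * (v[k] + m[k]^2) + (1 - wk) * (v[d] + m[d]^2) - mu^2
    m[k] <- mu
    lw[k] <- lw_new
  }
  list(m = m[keep], v = v[keep], lw = lw[keep])
}

# Marginal REML log-likelihood of the Levy jump-diffusion model
# (jump counts summed out over 0..cap per branch, normalized). Dispatches to
# the C++ implementation; the R reference below is kept as the oracle the
# test suite compares against.
.levy_marginal_loglik <- function(po, x, sigma2, jump_rate, alpha,
                                  cap = 2L, max_comp = 16L) {
  c_levy_marginal_loglik(po$edge, po$elen, po$ntip, po$nnode, x,
                         sigma2, jump_rate, alpha, as.integer(cap),
                         as.integer(max_comp))
}

.levy_marginal_loglik_r <- function(po, x, sigma2, jump_rate, alpha,
                                    cap = 2L, max_comp = 16L) {
  ntot <- po$ntip + po$nnode
  mix <- vector("list", ntot)
  for (i in seq_len(po$ntip)) mix[[i]] <- list(m = x[i], v = 0, lw = 0)
  stash <- vector("list", ntot)
  n_counts <- cap + 1L
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]; len <- po$elen[e]
    cc <- mix[[ch]]
    lw_n <- dpois(0:cap, jump_rate * len, log = TRUE)
    lw_n <- lw_n - .logsumexp(lw_n)
    nc <- length(cc$m)
    m <- rep(cc$m, times = n_counts)
    v <- rep(cc$v, times = n_counts) + sigma2 * len +
      sigma2 * alpha * rep(0:cap, each = nc)
    lw <- rep(cc$lw, times = n_counts) + rep(lw_n, each = nc)
    br <- .reduce_mix(m, v, lw, max_comp)
    if (is.null(stash[[par]])) {
      stash[[par]] <- br
    } else {
      s <- stash[[par]]
      vs <- outer(s$v, br$v, "+")
      vs[vs <= 0] <- 1e-12
      d <- outer(s$m, br$m, "-")
      lwp <- outer(s$lw, br$lw, "+") + dnorm(d, 0, sqrt(vs), log = TRUE)
      # combined mean/variance of the product of two Gaussians
      m1 <- matrix(s$m, nrow = length(s$m), ncol = length(br$m))
      m2 <- matrix(br$m, nrow = length(s$m), ncol = length(br$m), byrow = TRUE)
      v1 <- matrix(s$v, nrow = length(s$v), ncol = length(br$v))
      v2 <- matrix(br$v, nrow = length(s$v), ncol = length(br$v), byrow = TRUE)
      mnew <- (m1 * v2 + m2 * v1) / vs
      vnew <- v1 * v2 / vs
      red <- .reduce_mix(as.numeric(mnew), as.numeric(vnew), as.numeric(lwp),
                         max_comp)
      mix[[par]] <- red
      stash[par] <- list(NULL)
    }
  }
  root <- po$ntip + 1L
  .logsumexp(mix[[root]]$lw)
}

# Profile (over sigma2 and jump_rate) marginal log-likelihood at fixed alpha.
.levy_profile_at_alpha <- function(po, x, alpha, n_optimizations = 5,
                                   cap = 2L, max_comp = 16L, tree = NULL) {
  s2_bm <- max(mean(x^2) * 1e-6, .bm_sigma2_reml(tree, x))
  total_len <- sum(po$elen)
  obj <- function(p) {
    ll <- .levy_marginal_loglik(po, x, exp(p[1]), exp(p[2]), alpha,
                                cap = cap, max_comp = max_comp)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- list(c(log(s2_bm), log(1 / total_len)),
                 c(log(s2_bm / (1 + alpha / 10)), log(2 / total_len)),
                 c(log(s2_bm), log(0.2 / total_len)),
                 c(log(s2_bm / 2), log(4 / total_len)),
                 c(log(s2_bm * 2), log(1 / total_len)))
  best <- NULL
  for (i in seq_len(min(n_optimizations, length(starts)))) {
    f <- optim(starts[[i]], obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-9))
    if (is.null(best) || f$value < best$value) best <- f
  }
  list(loglik = -best$value, sigma2 = exp(best$par[1]),
       jump_rate = exp(best$par[2]))
}

#' Expanding-grid search for the jump-size ratio alpha
#'
#' Profiles the marginal Levy likelihood over `sigma2` and `jump_rate` on an
#' expanding grid of `alpha` values spaced by `step` on the log10 scale,
#' starting at `log10_start`, until the likelihood peak is bracketed by the
#' grid (or the grid limits are reached). Reports the number of alpha values
#' evaluated and flags flat or multimodal profiles.
#'
#' @param tree binary ultrametric `phylo`.
#' @param traits named numeric tip vector.
#' @param log10_start,step starting value and step of log10(alpha).
#' @param n_optimizations restarts of the per-alpha profile optimization.
#' @param cap per-branch jump-count cap in the marginalization.
#' @param max_comp mixture-component bound in the pruning.
#' @param limits log10(alpha) search limits.
#' @return list with `alpha_hat`, `loglik`, `profile` (data.frame alpha,
#'   log10_alpha, loglik, sigma2, jump_rate), `n_evaluated`, `flat_profile`,
#'   `multimodal`.
#' @export
alpha_peak_search <- function(tree, traits, log10_start = 0.5, step = 0.5,
                              n_optimizations = 5, cap = 2L, max_comp = 16L,
                              limits = c(-1.5, 7)) {
  stopifnot_binary(tree); stopifnot_ultrametric(tree)
  x <- .check_traits(tree, traits)
  if (sd(x) == 0)
    stop("trait has zero variance; jump model is unidentifiable", call. = FALSE)
  po <- .postorder(tree)
  evaluated <- new.env()
  eval_at <- function(la) {
    key <- sprintf("%.6f", la)
    if (!is.null(evaluated[[key]])) return(evaluated[[key]])
    r <- .levy_profile_at_alpha(po, x, 10^la, n_optimizations, cap, max_comp,
                                tree = tree)
    r$log10_alpha <- la
    evaluated[[key]] <- r
    r
  }
  grid <- log10_start
  eval_at(log10_start)
  repeat {
    vals <- vapply(grid, function(g) eval_at(g)$loglik, numeric(1))
    i_best <- which.max(vals)
    at_low <- i_best == 1L && min(grid) > limits[1]
    at_high <- i_best == length(grid) && max(grid) < limits[2]
    if (!at_low && !at_high) break
    if (at_high) grid <- c(grid, max(grid) + step)
    if (at_low) grid <- c(min(grid) - step, grid)
    grid <- sort(grid)
  }
  prof <- do.call(rbind, lapply(sort(grid), function(g) {
    r <- eval_at(g)
    data.frame(log10_alpha = g, alpha = 10^g, loglik = r$loglik,
               sigma2 = r$sigma2, jump_rate = r$jump_rate)
  }))
  i_best <- which.max(prof$loglik)
  rng <- diff(range(prof$loglik))
  # interior local maxima above (global max - 2) beyond the global one
  is_locmax <- vapply(seq_len(nrow(prof)), function(i) {
    lo <- if (i > 1) prof$loglik[i] >= prof$loglik[i - 1] else TRUE
    hi <- if (i < nrow(prof)) prof$loglik[i] >= prof$loglik[i + 1] else TRUE
    lo && hi
  }, logical(1))
  n_modes <- sum(is_locmax & prof$loglik > prof$loglik[i_best] - 2)
  list(alpha_hat = prof$alpha[i_best],
       loglik = prof$loglik[i_best],
       sigma2 = prof$sigma2[i_best],
       jump_rate = prof$jump_rate[i_best],
       profile = prof,
       n_evaluated = nrow(prof),
       flat_profile = rng < 2,
       multimodal = n_modes > 1 || rng < 2)
}

#' Likelihood-ratio test of the jump-diffusion model against Brownian motion
#'
#' `D = 2 * (max log-likelihood of the Levy model - max log-likelihood of
#' BM)`, with the p-value from a chi-squared distribution with 2 degrees of
#' freedom (the extra parameters `jump_rate` and `alpha`). Because
#' `jump_rate >= 0` sits on the boundary of the parameter space under the
#' null, this p-value is conservative; `boundary_conservative` flags it.
#'
#' @param tree binary ultrametric `phylo`.
#' @param traits named numeric tip vector.
#' @param ... passed to [alpha_peak_search()].
#' @return list with `D`, `p_value`, `alpha_hat`, `df`,
#'   `boundary_conservative`.
#' @export
lrt_jump_vs_bm <- function(tree, traits, ...) {
  x <- .check_traits(tree, traits)
  names(x) <- tree$tip.label
  s2 <- .bm_sigma2_reml(tree, x)
  ll_bm <- bm_loglik(tree, x, s2, root_handling = "reml")
  peak <- alpha_peak_search(tree, x, ...)
  D <- max(2 * (peak$loglik - ll_bm), 0)
  list(D = D, p_value = pchisq(D, df = 2, lower.tail = FALSE),
       alpha_hat = peak$alpha_hat, df = 2, boundary_conservative = TRUE,
       loglik_bm = ll_bm, loglik_levy = peak$loglik)
}

#' Sample per-branch jump vectors by MCMC
#'
#' With `alpha` fixed (from [alpha_peak_search()]), samples per-branch jump
#' counts jointly with `sigma2` and `jump_rate`. The posterior probability of
#' a jump on a branch is the frequency of a non-zero count across sampled
#' vectors. Defaults follow the screening preset (5000 sampled vectors, 1000
#' burnin, thinning 2); final analyses conventionally raise `n_vectors` to
#' 25000.
#'
#' @param tree binary ultrametric `phylo`.
#' @param traits named numeric tip vector.
#' @param alpha fixed jump-size ratio.
#' @param n_vectors number of sampled jump vectors retained.
#' @param burnin number of recorded vectors discarded.
#' @param thin record every `thin`-th sweep.
#' @param seed integer seed (identical seeds give identical posteriors).
#' @param rate_prior Gamma prior `c(shape, rate)` on `jump_rate`. The
#'   default, `c(1, total tree length)`, encodes the rare-jumps assumption
#'   (one jump expected per tree a priori), which keeps the null
#'   false-call rate controlled across the whole tree.
#' @return a `jump_posterior`: `pp` (per edge, named by child node),
#'   `mean_counts`, posterior means and traces of `sigma2` and `jump_rate`,
#'   and the settings used.
#' @export
sample_jump_vectors <- function(tree, traits, alpha, n_vectors = 5000L,
                                burnin = 1000L, thin = 2L, seed = NULL,
                                rate_prior = NULL) {
  stopifnot_binary(tree); stopifnot_ultrametric(tree)
  x <- .check_traits(tree, traits)
  if (sd(x) == 0)
    stop("trait has zero variance; jump model is unidentifiable", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  po <- .postorder(tree)
  if (is.null(rate_prior)) rate_prior <- c(1, sum(po$elen))
  s2_init <- .bm_sigma2_reml(tree, setNames(x, tree$tip.label))
  res <- c_jump_mcmc(po$edge, po$elen, po$ntip, po$nnode, x, alpha,
                     as.integer(n_vectors), as.integer(burnin),
                     as.integer(thin), s2_init, 1 / sum(po$elen),
                     rate_prior[1], rate_prior[2], TRUE)
  # map back to tree$edge order
  pp <- numeric(nrow(tree$edge)); mc <- numeric(nrow(tree$edge))
  pp[po$perm] <- res$pp
  mc[po$perm] <- res$mean_counts
  names(pp) <- names(mc) <- as.character(tree$edge[, 2])
  structure(list(pp = pp, mean_counts = mc,
                 sigma2 = mean(res$sigma2_trace),
                 jump_rate = mean(res$jump_rate_trace),
                 sigma2_trace = res$sigma2_trace,
                 jump_rate_trace = res$jump_rate_trace,
                 n_sampled_vectors = res$n_sampled_vectors,
                 settings = list(alpha = alpha, n_vectors = n_vectors,
                                 burnin = burnin, thin = thin)),
            class = "jump_posterior")
}

#' Call jump branches from a posterior
#'
#' Branches whose posterior jump probability strictly exceeds the threshold
#' (default 0.85).
#'
#' @param posterior a `jump_posterior`.
#' @param threshold in `[0, 1]`.
#' @return character vector of branch keys (child-node ids).
#' @export
call_jumps <- function(posterior, threshold = 0.85) {
  if (threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]", call. = FALSE)
  pp <- posterior$pp
  names(pp)[pp > threshold]
}

#' Impute missing tip values under Brownian motion
#'
#' Missing tips are filled with the conditional mean of the BM multivariate
#' normal given the observed tips, with the BM rate estimated by REML from
#' the observed tips alone; standard errors come from the conditional
#' variance.
#'
#' @param tree ultrametric `phylo`.
#' @param partial_traits named numeric vector with `NA` for missing tips.
#' @return list with `traits` (completed, named), `se` (0 for observed tips),
#'   `sigma2`.
#' @export
impute_tips_bm <- function(tree, partial_traits) {
  stopifnot_ultrametric(tree)
  x <- partial_traits[tree$tip.label]
  obs <- which(!is.na(x)); mis <- which(is.na(x))
  if (length(obs) < 2L)
    stop("need at least 2 observed values to impute", call. = FALSE)
  se <- setNames(numeric(length(x)), tree$tip.label)
  if (!length(mis))
    return(list(traits = x, se = se, sigma2 = NA_real_))
  sub <- ape::keep.tip(tree, tree$tip.label[obs])
  sub <- ape::multi2di(sub)
  s2 <- .bm_sigma2_reml(sub, x[obs])
  C <- ape::vcv(tree) * s2
  Coo <- C[obs, obs, drop = FALSE]
  Cmo <- C[mis, obs, drop = FALSE]
  Cmm <- C[mis, mis, drop = FALSE]
  ones <- rep(1, length(obs))
  Ki <- solve(Coo)
  mu <- as.numeric((ones %*% Ki %*% x[obs]) / (ones %*% Ki %*% ones))
  w <- Cmo %*% Ki
  x[mis] <- mu + as.numeric(w %*% (x[obs] - mu))
  cv <- Cmm - w %*% t(Cmo)
  se[mis] <- sqrt(pmax(diag(cv), 0))
  list(traits = x, se = se, sigma2 = s2)
}
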