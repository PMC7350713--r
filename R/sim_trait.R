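# Levy jump-diffusion trait simulation ----------------------------------

#' Levy jump-diffusion model parameters
#'
#' Brownian motion with rate `sigma2` plus compound-Poisson jumps: jumps
#' arrive on a branch at rate `jump_rate` per Myr and each adds a
#' `Normal(0, alpha * sigma2)` displacement, so `alpha` is the per-jump
#' variance in units of the Brownian rate.
#'
#' @param sigma2 Brownian rate (trait-units^2/Myr), > 0.
#' @param jump_rate jumps/Myr/branch, >= 0.
#' @param alpha per-jump variance ratio, > 0.
#' @param root_state trait value at the root.
#' @return a `levy_model` list.
#' @export
levy_model <- function(sigma2 = 1, jump_rate = 0, alpha = 1, root_state = 0) {
  if (!(sigma2 > 0)) stop("sigma2 must be > 0", call. = FALSE)
  if (jump_rate < 0) stop("jump_rate must be >= 0", call. = FALSE)
  if (!(alpha > 0)) stop("alpha must be > 0", call. = FALSE)
  structure(list(sigma2 = sigma2, jump_rate = jump_rate, alpha = alpha,
                 root_state = root_state), class = "levy_model")
}

#' Simulate a continuous trait under Brownian motion plus jumps
#'
#' Walks the tree root-to-tip; each branch adds a Brownian increment of
#' variance `sigma2 * length` and `Poisson(jump_rate * length)` jumps each of
#' variance `alpha * sigma2`. The realized per-branch jump counts are
#' returned so recovery experiments can score detection against truth.
#'
#' @param tree ultrametric `phylo`.
#' @param model a [levy_model()].
#' @param seed optional integer seed.
#' @param jump_counts optional integer vector (one per edge, in `tree$edge`
#'   order) forcing the jump counts instead of drawing them.
#' @return list with `tip_values` (named), `node_values`, `jump_counts`
#'   per edge, and `jump_displacements` (realized summed jump displacement
#'   per edge, for recovery scoring).
#' @export
simulate_levy_trait <- function(tree, model, seed = NULL, jump_counts = NULL) {
  stopifnot(inherits(model, "levy_model"))
  stopifnot_ultrametric(tree)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nedge <- nrow(tree$edge)
  if (is.null(jump_counts)) {
    jump_counts <- rpois(nedge, model$jump_rate * tree$edge.length)
  } else {
    stopifnot(length(jump_counts) == nedge, all(jump_counts >= 0))
  }
  x <- numeric(ntip + tree$Nnode)
  x[ntip + 1L] <- model$root_state
  jump_disp <- numeric(nedge)
  # preorder traversal: parents before children
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]; len <- tree$edge.length[e]
    incr <- rnorm(1, 0, sqrt(model$sigma2 * len))
    if (jump_counts[e] > 0) {
      jump_disp[e] <- sum(rnorm(jump_counts[e], 0,
                                sqrt(model$alpha * model$sigma2)))
      incr <- incr + jump_disp[e]
    }
    x[ch] <- x[p] + incr
  }
  tips <- x[seq_len(ntip)]
  names(tips) <- tree$tip.label
  list(tip_values = tips, node_values = x, jump_counts = jump_counts,
       jump_displacements = jump_disp)
}

#' Plant a single large jump for a recovery experiment
#'
#' Simulates Brownian motion on the tree, then adds one jump on a randomly
#' chosen terminal branch of intermediate length (between the 10th and 50th
#' length percentiles, where a jump is uniquely localizable). The jump
#' displacement is drawn from the model's own jump distribution
#' `Normal(0, alpha * sigma2)` conditioned on being at least one jump
#' standard deviation in magnitude, i.e. a large jump rather than one lost
#' in the diffusion.
#'
#' @param tree ultrametric `phylo`.
#' @param alpha per-jump variance in units of `sigma2`.
#' @param sigma2 Brownian rate.
#' @param seed optional integer seed.
#' @return list with `tip_values`, `edge` (index of the planted edge),
#'   `branch_key` (child-node id as used in jump posteriors), and
#'   `displacement`.
#' @export
simulate_planted_jump <- function(tree, alpha, sigma2 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  len <- tree$edge.length
  pool <- which(tree$edge[, 2] <= ntip &
                  len >= quantile(len, 0.1) & len <= median(len))
  if (!length(pool)) pool <- which(tree$edge[, 2] <= ntip)
  e <- pool[sample.int(length(pool), 1L)]
  sim <- simulate_levy_trait(tree, levy_model(sigma2 = sigma2, jump_rate = 0,
                                              alpha = alpha),
                             jump_counts = integer(nrow(tree$edge)))
  sdj <- sqrt(alpha * sigma2)
  repeat {
    d <- rnorm(1, 0, sdj)
    if (abs(d) >= sdj) break
  }
  tip <- tree$tip.label[tree$edge[e, 2]]
  x <- sim$tip_values
  x[tip] <- x[tip] + d
  list(tip_values = x, edge = e, branch_key = as.character(tree$edge[e, 2]),
       displacement = d)
}
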