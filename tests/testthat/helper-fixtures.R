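# Shared fixtures: small trees and generators used across test files.

three_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# random ultrametric tree with given tip count (coalescent shape)
random_ultra_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ape::rcoal(n)
}

# dense multivariate-normal BM log-likelihood with ML (GLS) root -- the
# matrix oracle for pruning implementations
dense_bm_loglik <- function(tree, x, sigma2) {
  x <- x[tree$tip.label]
  C <- ape::vcv(tree) * sigma2
  Ki <- solve(C)
  ones <- rep(1, length(x))
  mu <- as.numeric((ones %*% Ki %*% x) / (ones %*% Ki %*% ones))
  r <- x - mu
  as.numeric(-0.5 * (length(x) * log(2 * pi) +
                       determinant(C)$modulus + t(r) %*% Ki %*% r))
}

# closed-form Yule log-likelihood conditioned on the crown age (same
# labelled-history convention as the package: constants omitted)
yule_loglik <- function(tree, lambda) {
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  internal <- setdiff(seq.int(ntip + 1L, ntip + tree$Nnode), root)
  sum(log(lambda) - lambda * ages[internal]) - 2 * lambda * ages[root]
}
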