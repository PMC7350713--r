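# Dated-tree input/output, validation, and taxonomic imputation ----------

#' Read a set of dated trees
#'
#' Reads one or more rooted trees from a Newick or Nexus file (Nexus translate
#' tables are handled) and validates them: tip labels must be unique within a
#' tree and branch lengths non-negative. The result is always a `multiPhylo`,
#' even for a single tree, so downstream posterior-set operations have a
#' uniform container.
#'
#' @param path file to read.
#' @param format `"newick"` or `"nexus"`.
#' @return a `multiPhylo` whose trees all share the same tip set.
#' @export
read_trees <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  trees <- tryCatch(
    switch(format,
           newick = ape::read.tree(path),
           nexus  = ape::read.nexus(path)),
    error = function(e) stop("unreadable file: ", path, " (", conditionMessage(e), ")",
                             call. = FALSE))
  if (is.null(trees)) stop("unreadable file: ", path, call. = FALSE)
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    if (length(dup))
      stop("duplicate tip label(s): ", paste(dup, collapse = ", "), call. = FALSE)
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
      stop("negative branch length(s) in tree ", i, call. = FALSE)
  }
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(trees) > 1L && !all(vapply(tipsets, identical, logical(1), tipsets[[1]])))
    stop("trees in the set do not share an identical tip set", call. = FALSE)
  trees
}

#' Write trees to Newick or Nexus
#'
#' @param trees a `phylo` or `multiPhylo`.
#' @param path output file.
#' @param format `"newick"` or `"nexus"`.
#' @param digits significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_trees <- function(trees, path, format = c("newick", "nexus"), digits = 12) {
  format <- match.arg(format)
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  if (format == "newick") {
    ape::write.tree(trees, file = path, digits = digits)
  } else {
    ape::write.nexus(trees, file = path, translate = TRUE)
  }
  invisible(path)
}

#' Check ultrametricity of a dated tree
#'
#' A dated tree is ultrametric when every tip sits at the same distance from
#' the root. The report is diagnostic, never an error: it returns the maximum
#' absolute deviation of tip depth from the mean tip depth and whether it is
#' within tolerance.
#'
#' @param tree a `phylo` with branch lengths.
#' @param tol absolute tolerance in Myr; default `1e-6 * tree height`.
#' @return list with `ok`, `max_deviation`, `tol`.
#' @export
validate_ultrametric <- function(tree, tol = NULL) {
  depth <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  height <- max(depth)
  tol <- tol %||% (1e-6 * max(height, .Machine$double.eps))
  dev <- max(abs(depth - mean(depth)))
  list(ok = dev <= tol, max_deviation = dev, tol = tol)
}

#' Constraint for taxonomic imputation
#'
#' Describes a species absent from a tree and the clade (a set of existing tip
#' labels) it must attach within.
#'
#' @param missing_taxon label of the taxon to add.
#' @param clade character vector of tip labels spanning the constraint clade.
#' @return a `taxon_constraint` object.
#' @export
taxon_constraint <- function(missing_taxon, clade) {
  stopifnot(is.character(missing_taxon), length(missing_taxon) == 1L,
            is.character(clade), length(clade) >= 1L)
  structure(list(missing_taxon = missing_taxon, clade = clade),
            class = "taxon_constraint")
}

# Edges of the subtree spanned by `node` (all edges whose parent is in the
# clade), plus the clade's stem edge if the clade is not the whole tree.
.clade_edges <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  desc <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% desc, 2]
    new <- setdiff(kids, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  idx <- which(tree$edge[, 1] %in% desc)
  stem <- which(tree$edge[, 2] == node)
  sort(unique(c(idx, stem)))
}

#' Attach missing taxa into constraint clades
#'
#' Adds each missing taxon to a dated tree under a pure-birth-flavoured
#' attachment rule: the attachment branch is drawn within the constraint clade
#' (including its stem) with probability proportional to branch length, and
#' the attachment age uniformly along that branch. The output stays
#' ultrametric and the induced subtree on the original tips is unchanged.
#'
#' @param tree ultrametric `phylo`.
#' @param constraints list of [taxon_constraint()] objects.
#' @param seed optional integer seed.
#' @return the enlarged `phylo`.
#' @export
impute_missing_taxa <- function(tree, constraints, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(constraints)) return(tree)
  for (con in constraints) {
    if (!inherits(con, "taxon_constraint"))
      stop("constraints must be taxon_constraint objects", call. = FALSE)
    if (con$missing_taxon %in% tree$tip.label)
      stop("taxon already present in tree: ", con$missing_taxon, call. = FALSE)
    miss <- setdiff(con$clade, tree$tip.label)
    if (length(miss))
      stop("constraint clade tips not in tree: ", paste(miss, collapse = ", "),
           call. = FALSE)
    tips <- match(con$clade, tree$tip.label)
    if (length(tips) == 1L) {
      mrca <- tips
    } else {
      mrca <- ape::getMRCA(tree, tips)
      below <- ape::extract.clade(tree, mrca)$tip.label
      if (!setequal(below, con$clade))
        stop("constraint clade is not monophyletic: ", con$missing_taxon,
             call. = FALSE)
    }
    ages <- node_ages(tree)
    eidx <- .clade_edges(tree, mrca)
    len <- tree$edge.length[eidx]
    pick <- eidx[sample.int(length(eidx), 1L, prob = len)]
    child <- tree$edge[pick, 2]
    parent <- tree$edge[pick, 1]
    a_child <- ages[child]
    a_parent <- ages[parent]
    attach_age <- runif(1, a_child, a_parent)
    tree <- phytools::bind.tip(tree, con$missing_taxon,
                               edge.length = attach_age,
                               where = child,
                               position = attach_age - a_child)
  }
  tree
}

#' Stable identifiers for tree edges
#'
#' Node numbers are not preserved across Newick round-trips, so results that
#' must be matched across separately loaded copies of a tree (e.g. true
#' versus inferred jump branches) need a stable branch key: the sorted
#' descendant tip labels of each edge's child, collapsed with `"|"`.
#'
#' @param tree a `phylo`.
#' @return character vector, one key per row of `tree$edge`.
#' @export
edge_clade_keys <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in po) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[[par]] <- c(below[[par]], below[[ch]])
  }
  vapply(tree$edge[, 2], function(ch)
    paste(sort(below[[ch]]), collapse = "|"), character(1))
}
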