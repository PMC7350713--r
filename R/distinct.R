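# Fair-proportion evolutionary distinctiveness and EDGE scoring ----------

#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch's length is divided equally among the tips it subtends; a
#' tip's ED is the sum of its shares along its root-to-tip path. ED therefore
#' sums over tips to the total branch length of the tree.
#'
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @return named numeric vector of ED values (Myr), one per tip.
#' @export
fair_proportion <- function(tree) {
  # the tree is apportioned from its root node; polytomies (including star
  # trees, which ape flags as unrooted) are fine for fair proportion
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  ntip <- ape::Ntip(tree)
  ed <- setNames(numeric(ntip), tree$tip.label)
  # postorder: count tips under each edge, then preorder accumulate shares
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  ntips_below <- integer(ntip + tree$Nnode)
  ntips_below[seq_len(ntip)] <- 1L
  for (e in po) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    ntips_below[par] <- ntips_below[par] + ntips_below[ch]
  }
  share <- setNames(numeric(ntip + tree$Nnode), NULL)  # ED accumulated at node
  for (e in rev(po)) {  # preorder
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    share[ch] <- share[par] + tree$edge.length[e] / ntips_below[ch]
  }
  ed[] <- share[seq_len(ntip)]
  ed
}

#' Median ED across a posterior set of trees
#'
#' @param posterior `multiPhylo` whose trees share an identical tip set.
#' @return data.frame with per-species median ED and the tree count.
#' @export
median_ed <- function(posterior) {
  if (inherits(posterior, "phylo"))
    posterior <- structure(list(posterior), class = "multiPhylo")
  tipset <- sort(posterior[[1]]$tip.label)
  eds <- vapply(posterior, function(tr) {
    if (!setequal(tr$tip.label, tipset))
      stop("tip sets differ across posterior trees", call. = FALSE)
    fair_proportion(tr)[tipset]
  }, numeric(length(tipset)))
  if (is.null(dim(eds))) eds <- matrix(eds, nrow = length(tipset))
  data.frame(species = tipset,
             ed = apply(eds, 1, median),
             n_trees = length(posterior),
             row.names = tipset, stringsAsFactors = FALSE)
}

#' GE weight of an IUCN category
#'
#' LC = 0, NT = 1, VU = 2, EN = 3, CR = 4. EX and unknown categories have no
#' GE weight (extinct species cannot be prioritized) and are an error.
#'
#' @param status character vector of categories.
#' @return integer vector of GE weights.
#' @export
ge_weight <- function(status) {
  map <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L)
  status <- as.character(status)
  bad <- is.na(status) | !(status %in% names(map))
  if (any(bad))
    stop("no GE weight for status: ",
         paste(unique(status[bad]), collapse = ", "), call. = FALSE)
  unname(map[status])
}

#' EDGE score
#'
#' `EDGE = ln(1 + ED) + GE * ln(2)`. With GE = 0 (Least Concern) the score
#' reduces to the log-transformed ED, so an all-LC assemblage has identical
#' ED and EDGE orderings.
#'
#' @param ed ED in Myr, >= 0.
#' @param ge integer GE weight (0-4).
#' @return numeric EDGE score.
#' @export
edge_score <- function(ed, ge) {
  if (any(ed < 0)) stop("ED must be non-negative", call. = FALSE)
  stopifnot(all(ge %in% 0:4))
  log1p(ed) + ge * log(2)
}

#' Rank species by EDGE score
#'
#' Descending EDGE with deterministic tie-breaks: higher ED first, then
#' species label.
#'
#' @param table data.frame with columns `species`, `ed`, `ge`, `edge`.
#' @param n number of top species to return.
#' @return the top-`n` rows, ranked.
#' @export
rank_edge <- function(table, n = 10L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  o <- order(-table$edge, -table$ed, table$species)
  out <- table[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  head(out, n)
}

#' Build an EDGE table from ED values and statuses
#'
#' Extinct (EX) species are dropped from EDGE ranking; species with missing
#' status are an error (impute first).
#'
#' @param ed_table data.frame from [median_ed()] (columns species, ed).
#' @param status named character vector (or factor) of final categories.
#' @return data.frame with species, ed, status, ge, edge.
#' @export
edge_table <- function(ed_table, status) {
  status <- setNames(as.character(status), names(status))
  st <- status[ed_table$species]
  if (anyNA(st))
    stop("missing final status for: ",
         paste(head(ed_table$species[is.na(st)], 5), collapse = ", "),
         call. = FALSE)
  keep <- st != "EX"
  out <- data.frame(species = ed_table$species[keep], ed = ed_table$ed[keep],
                    status = st[keep], stringsAsFactors = FALSE)
  out$ge <- ge_weight(out$status)
  out$edge <- edge_score(out$ed, out$ge)
  out
}
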