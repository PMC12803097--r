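#' Split a large tree into analysis-sized clades
#'
#' Large supertrees are decomposed into disjoint monophyletic clades so that
#' ancestral range estimation can run per clade.  Extraction is greedy and
#' deepest-first: walking from the root, every maximal clade whose size does
#' not exceed `max_tips` is emitted (a clade is emitted as soon as it fits;
#' otherwise its daughters are visited).  The resulting clades partition the
#' tip set.  Clades smaller than `min_tips` are flagged `below_min`; on most
#' topologies at most one such remainder occurs, but strongly pectinate trees
#' can produce several.
#'
#' The branch subtending each clade's MRCA is retained as the clade's root
#' edge (`root.edge`), so stem lengths are not lost.
#'
#' @param tree a `phylo`.
#' @param min_tips,max_tips clade size bounds (default 10 and 100).
#' @return A list of `phylo` objects, each with attributes `below_min`
#'   (logical) and `root_age`.
#' @examples
#' tr <- ape::rphylo(250, 1, 0)
#' cl <- split_into_clades(tr, 10, 100)
#' sum(vapply(cl, ape::Ntip, integer(1)))  # 250
#' @export
split_into_clades <- function(tree, min_tips = 10L, max_tips = 100L) {
  stopifnot(min_tips >= 2L, max_tips >= min_tips)
  ntip <- ape::Ntip(tree)
  if (ntip <= max_tips) {
    out <- list(flag_clade(tree, ntip < min_tips))
    return(out)
  }
  # clade sizes per node
  sizes <- clade_sizes(tree)
  stems <- tree$edge.length[match(seq_along(sizes), tree$edge[, 2])]
  picked <- integer(0)
  visit <- ntip + 1L  # root
  while (length(visit)) {
    nd <- visit[1]; visit <- visit[-1]
    if (sizes[nd] <= max_tips) {
      picked <- c(picked, nd)
    } else {
      visit <- c(visit, tree$edge[tree$edge[, 1] == nd, 2])
    }
  }
  lapply(picked, function(nd) {
    sub <- if (nd <= ntip) single_tip_clade(tree, nd) else ape::extract.clade(tree, nd)
    if (!is.na(stems[nd])) sub$root.edge <- stems[nd]
    flag_clade(sub, ape::Ntip(sub) < min_tips)
  })
}

flag_clade <- function(tr, below) {
  attr(tr, "below_min") <- below
  if (ape::Ntip(tr) >= 2) attr(tr, "root_age") <- max(node_depths(tr)[seq_len(ape::Ntip(tr))])
  tr
}

single_tip_clade <- function(tree, tip) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2),
                 edge.length = tree$edge.length[match(tip, tree$edge[, 2])],
                 tip.label = tree$tip.label[tip], Nnode = 1L),
            class = "phylo")
}

clade_sizes <- function(tree) {
  ntip <- ape::Ntip(tree)
  sizes <- integer(ntip + tree$Nnode)
  sizes[seq_len(ntip)] <- 1L
  ord <- reorder(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    sizes[ord$edge[k, 1]] <- sizes[ord$edge[k, 1]] + sizes[ord$edge[k, 2]]
  }
  sizes
}
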