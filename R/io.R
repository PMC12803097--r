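#' Read a dated phylogeny from a newick file
#'
#' Reads a rooted, dated (ultrametric) tree with branch lengths in Myr and
#' validates it: all branch lengths must be positive and all root-to-tip path
#' lengths equal within a relative tolerance, since downstream models place
#' nodes on an absolute time axis (ages in Ma).
#'
#' @param path path to a newick file (or a newick string ending in ";").
#' @param tol relative ultrametricity tolerance: the spread of tip depths may
#'   not exceed `tol * root age`.
#' @param allow_non_ultrametric if `TRUE`, a non-ultrametric tree raises a
#'   warning instead of an error.
#' @return An [ape::read.tree()] `phylo` object with an added `root_age`
#'   attribute (max root-to-tip path length, Ma).
#' @export
read_newick <- function(path, tol = 1e-6, allow_non_ultrametric = FALSE) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("could not parse newick input: ", path)
  validate_phylogeny(tr, tol = tol, allow_non_ultrametric = allow_non_ultrametric)
}

validate_phylogeny <- function(tr, tol = 1e-6, allow_non_ultrametric = FALSE) {
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length <= 0)) stop("tree has zero or negative branch lengths")
  depths <- node_depths(tr)[seq_len(ape::Ntip(tr))]
  root_age <- max(depths)
  spread <- diff(range(depths))
  if (spread > tol * root_age) {
    msg <- sprintf("tree is not ultrametric: tip depth spread %.3g exceeds %.3g", spread, tol * root_age)
    if (allow_non_ultrametric) warning(msg) else stop(msg)
  }
  attr(tr, "root_age") <- root_age
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
root_age <- function(tree) {
  ra <- attr(tree, "root_age")
  if (is.null(ra)) ra <- max(node_depths(tree)[seq_len(ape::Ntip(tree))])
  ra
}

# distance from the root to every node (tips first, then internals)
node_depths <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  d <- numeric(n_node)
  # edges in preorder: parents appear before children
  ord <- reorder(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    d[ord$edge[k, 2]] <- d[ord$edge[k, 1]] + ord$edge.length[k]
  }
  d
}

# age (Ma before present) of every node, taking the deepest tip as the present
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

#' Read and write lagrange/PHYLIP-style geography files
#'
#' The geography dialect used by the DEC model family: a header line
#' `"ntaxa nareas (L1 L2 ...)"` followed by one row per taxon,
#' `"name<ws>binarystring"`, where the binary string gives realm occupancy in
#' the canonical realm order.
#'
#' @param path file path.
#' @param realms a [realm_set()]; its labels must match the header when the
#'   header carries labels.
#' @return `read_geography()`: a named integer vector of range-state bitmasks,
#'   one per taxon.  `write_geography()`: the path, invisibly.
#' @export
read_geography <- function(path, realms) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- strsplit(lines[1], "[[:space:]]+")[[1]]
  ntax <- as.integer(hdr[1])
  nare <- as.integer(hdr[2])
  if (nare != length(realms)) {
    stop("geography header declares ", nare, " areas but realm set has ", length(realms))
  }
  labs <- gsub("[()]", "", hdr[-(1:2)])
  labs <- labs[nzchar(labs)]
  if (length(labs) && !identical(labs, as.character(unclass(realms)))) {
    stop("geography header labels do not match the realm set")
  }
  body <- lines[-1]
  if (length(body) != ntax) stop("geography header declares ", ntax, " taxa, found ", length(body))
  parts <- strsplit(body, "[[:space:]]+")
  nm <- vapply(parts, `[`, character(1), 1L)
  bin <- vapply(parts, `[`, character(1), 2L)
  if (anyDuplicated(nm)) stop("duplicate taxon in geography file: ", nm[duplicated(nm)][1])
  if (any(nchar(bin) != length(realms))) stop("range string length does not match realm count")
  if (any(grepl("[^01]", bin))) stop("range strings must be binary")
  bits <- vapply(strsplit(bin, ""), function(ch) {
    as.integer(sum(bitwShiftL(1L, which(ch == "1") - 1L)))
  }, integer(1))
  if (any(bits == 0L)) stop("empty range for taxon: ", nm[bits == 0L][1])
  names(bits) <- nm
  bits
}

#' @rdname read_geography
#' @param ranges named integer vector of range-state bitmasks.
#' @export
write_geography <- function(ranges, realms, path) {
  n <- length(realms)
  bin <- vapply(ranges, function(b) {
    paste(ifelse(has_bit(b, seq_len(n)), "1", "0"), collapse = "")
  }, character(1))
  lines <- c(sprintf("%d %d (%s)", length(ranges), n, paste(unclass(realms), collapse = " ")),
             paste(names(ranges), bin, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read realm occupancy from a long-format CSV
#'
#' Alternative to the PHYLIP-style dialect: a CSV with columns `taxon` and
#' `realm`, one row per presence.
#'
#' @inheritParams read_geography
#' @return named integer vector of range-state bitmasks.
#' @export
read_geography_csv <- function(path, realms) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "realm") %in% names(df))) stop("CSV needs 'taxon' and 'realm' columns")
  sp <- split(df$realm, df$taxon)
  vapply(sp, range_state, integer(1), realms = realms)
}

#' Bundle a phylogeny with tip ranges
#'
#' A clade dataset is the unit of analysis: one dated clade plus the range
#' state of each tip (all non-empty), optionally labeled with a group name.
#'
#' @param tree a validated `phylo` (see [read_newick()]).
#' @param ranges named integer vector of range-state bitmasks covering every
#'   tip label.
#' @param realms a [realm_set()].
#' @param group optional group label (e.g. "cetacean").
#' @return An object of class `clade_data`.
#' @export
clade_data <- function(tree, ranges, realms, group = NA_character_) {
  missing <- setdiff(tree$tip.label, names(ranges))
  if (length(missing)) stop("tips without ranges: ", paste(utils::head(missing, 3), collapse = ", "))
  ranges <- ranges[tree$tip.label]
  if (any(ranges == 0L)) stop("empty tip range: ", tree$tip.label[ranges == 0L][1])
  structure(list(tree = tree, ranges = ranges, realms = realms, group = group),
            class = "clade_data")
}

#' @export
print.clade_data <- function(x, ...) {
  cat("Clade dataset", if (!is.na(x$group)) paste0(" [", x$group, "]"), ": ",
      ape::Ntip(x$tree), " tips, root age ", signif(root_age(x$tree), 4), " Ma, ",
      length(x$realms), " realms\n", sep = "")
  invisible(x)
}

#' Read and write stratified dispersal multiplier matrix stacks
#'
#' Plain-text stack format: per stratum a header line `"EPOCH <start> <end>"`
#' (ages in Ma, youngest stratum first) followed by an N x N whitespace-
#' separated matrix in canonical realm order.
#'
#' @param path file path.
#' @param realms a [realm_set()].
#' @return `read_dmm_stack()` returns a `stratified_dmm`; see
#'   [stratified_dmm()].
#' @export
read_dmm_stack <- function(path, realms) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^EPOCH", lines)
  if (!length(hdr)) stop("no EPOCH headers in DMM stack")
  n <- length(realms)
  mats <- list(); bounds <- numeric(0)
  for (k in seq_along(hdr)) {
    h <- strsplit(lines[hdr[k]], "[[:space:]]+")[[1]]
    bounds[k] <- as.numeric(h[3])
    rows <- lines[(hdr[k] + 1):(hdr[k] + n)]
    m <- do.call(rbind, lapply(strsplit(rows, "[[:space:]]+"), as.numeric))
    dimnames(m) <- list(unclass(realms), unclass(realms))
    mats[[k]] <- m
  }
  stratified_dmm(mats, bounds, realms)
}

#' @rdname read_dmm_stack
#' @param dmm a `stratified_dmm`.
#' @export
write_dmm_stack <- function(dmm, path) {
  starts <- c(0, dmm$boundaries[-length(dmm$boundaries)])
  out <- character(0)
  for (k in seq_along(dmm$M)) {
    out <- c(out,
             sprintf("EPOCH %g %g", starts[k], dmm$boundaries[k]),
             apply(dmm$M[[k]], 1, function(r) paste(sprintf("%.12g", r), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
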