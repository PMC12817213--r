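#' Read and validate a rooted phylogeny from Newick
#'
#' Parses a Newick string or file (plain or gzipped) into an [ape::read.tree]
#' `phylo` object and validates it for downstream comparative analyses:
#' the tree must be rooted, every branch must carry a strictly positive
#' length, and tip labels must be unique.  Branch lengths are interpreted as
#' time (e.g. million years) throughout the package.
#'
#' @param file path to a Newick file (`.gz` accepted), or `NULL`.
#' @param text a literal Newick string, or `NULL`.  Exactly one of `file`
#'   and `text` must be given.
#' @param collapse_zero if `TRUE`, zero-length branches (occasionally present
#'   in time-tree exports) are replaced by `1e-8` times the tree height
#'   instead of being rejected.
#' @return a validated `phylo` object.
#' @examples
#' tr <- read_newick(text = "((A:1,B:1):1,C:2);")
#' phylo_vcv(tr)
#' @export
read_newick <- function(file = NULL, text = NULL, collapse_zero = FALSE) {
  if (is.null(text) == is.null(file))
    stopf("supply exactly one of 'file' or 'text'")
  if (is.null(text)) {
    con <- if (grepl("\\.gz$", file)) gzfile(file, "rt") else file(file, "rt")
    on.exit(close(con))
    text <- paste(readLines(con, warn = FALSE), collapse = "")
  }
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) {
    # locate the first structurally suspicious character for the message
    bad <- regexpr("[^][(),:;A-Za-z0-9_.'\" \t-]", text)
    pos <- if (bad > 0) bad else nchar(text)
    stopf("malformed Newick string (near position %d)", pos)
  }
  if (inherits(phy, "multiPhylo")) stopf("expected a single tree, found several")
  validate_phylogeny(phy, collapse_zero = collapse_zero)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param phy a `phylo` object.
#' @param collapse_zero replace zero-length branches by `1e-8` x tree height
#'   instead of rejecting them.
#' @return the (possibly repaired) `phylo` object, invisibly classed as-is.
#' @export
validate_phylogeny <- function(phy, collapse_zero = FALSE) {
  if (!inherits(phy, "phylo")) stopf("not a 'phylo' object")
  if (is.null(phy$edge.length))
    stopf("tree has no branch lengths; time-calibrated branch lengths are required")
  if (anyNA(phy$edge.length) || any(!is.finite(phy$edge.length)))
    stopf("tree has missing or non-finite branch lengths")
  if (any(phy$edge.length < 0)) stopf("tree has negative branch lengths")
  zero <- phy$edge.length == 0
  if (any(zero)) {
    if (!collapse_zero)
      stopf("%d zero-length branch(es); rerun with collapse_zero = TRUE to replace them",
            sum(zero))
    h <- max(node_depths(phy))
    phy$edge.length[zero] <- 1e-8 * h
  }
  if (anyDuplicated(phy$tip.label))
    stopf("duplicated tip labels: %s",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  # basal multifurcations are legitimate (ape's is.rooted would reject a
  # star tree); parsing from Newick always yields a designated root node
  phy
}

#' Write a phylogeny to Newick
#'
#' @param phy a `phylo` object.
#' @param file optional output path (`.gz` writes gzipped); when `NULL` the
#'   Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(phy, file = NULL, digits = 12) {
  txt <- ape::write.tree(phy, digits = digits)
  if (is.null(file)) return(txt)
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wt") else file(file, "wt")
  on.exit(close(con))
  writeLines(txt, con)
  invisible(txt)
}

# Length of the retained stem below the root (set by pruning), or 0.
root_stem <- function(phy) {
  re <- phy$root.edge
  if (is.null(re) || is.na(re)) 0 else re
}

# root-to-node distances in ape node numbering (tips first, then internals),
# measured from the bottom of any retained stem edge
node_depths <- function(phy) ape::node.depth.edgelength(phy) + root_stem(phy)

tree_height <- function(phy) max(node_depths(phy)[seq_along(phy$tip.label)])

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the branch length shared by tips i and j on their paths
#' from the root (the root-to-MRCA distance); the diagonal holds root-to-tip
#' distances.  Rows and columns follow sorted tip-label order, so the result
#' is independent of how the Newick string was rotated.
#'
#' @param phy a `phylo` object.
#' @return an n x n symmetric matrix with tip labels as dimnames.
#' @export
phylo_vcv <- function(phy) {
  phy <- validate_phylogeny(phy)
  V <- ape::vcv.phylo(phy) + root_stem(phy)
  ord <- sort(rownames(V))
  V[ord, ord, drop = FALSE]
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips outside `taxa`; suppressed degree-two nodes have their
#' branch lengths merged additively so the root-to-tip distance of every
#' retained tip is unchanged.
#'
#' @param phy a `phylo` object.
#' @param taxa character vector of tip labels to keep (at least one).
#' @return the induced subtree as a `phylo` object.
#' @export
prune_to_taxa <- function(phy, taxa) {
  taxa <- unique(as.character(taxa))
  missing <- setdiff(taxa, phy$tip.label)
  if (length(missing))
    stopf("taxa not in tree: %s", paste(missing, collapse = ", "))
  if (length(taxa) < 1) stopf("at least one taxon must be retained")
  if (length(taxa) == length(phy$tip.label)) return(phy)
  stem <- root_stem(phy)
  if (length(taxa) == 1) {
    d <- node_depths(phy)[match(taxa, phy$tip.label)]
    out <- ape::read.tree(text = sprintf("(%s:%.15g);", taxa, d))
    return(out)
  }
  # keep the collapsed basal path as a stem so root-to-tip depths (and hence
  # covariance submatrices) are conserved exactly: the stem is the original
  # depth of the induced subtree's root
  out <- ape::keep.tip(phy, taxa)
  out$root.edge <- NULL
  d_orig <- ape::node.depth.edgelength(phy)[match(out$tip.label[1], phy$tip.label)]
  d_sub <- ape::node.depth.edgelength(out)[1L]
  out$root.edge <- stem + max(d_orig - d_sub, 0)
  out
}

#' Test whether a tree is ultrametric
#'
#' @param phy a `phylo` object.
#' @param rel_tol maximum allowed spread of root-to-tip depths, as a fraction
#'   of the maximum depth.
#' @return `TRUE` if all tips are (numerically) equidistant from the root.
#' @export
is_ultrametric <- function(phy, rel_tol = 1e-6) {
  d <- node_depths(phy)[seq_along(phy$tip.label)]
  (max(d) - min(d)) <= rel_tol * max(d)
}

#' Simulate a birth-death tree with a fixed number of extant tips
#'
#' Wraps [ape::rphylo] (conditioned on `n_tips` species surviving to the
#' present), yielding an ultrametric tree with tips labelled `t1 ... tn`.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0).
#' @param seed optional integer seed; the same seed reproduces the same tree.
#' @return an ultrametric `phylo` object.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  if (n_tips < 2) stopf("n_tips must be >= 2")
  if (!(birth > death && death >= 0))
    stopf("rates must satisfy birth > death >= 0")
  phy <- local_seed(seed, ape::rphylo(n_tips, birth = birth, death = death))
  phy$tip.label <- paste0("t", seq_len(n_tips))
  phy
}

# Rescale a tree so its height (max root-to-tip distance) equals `height`.
rescale_tree_height <- function(phy, height = 1) {
  f <- height / tree_height(phy)
  phy$edge.length <- phy$edge.length * f
  if (!is.null(phy$root.edge)) phy$root.edge <- phy$root.edge * f
  phy
}

# Precomputed postorder representation consumed by the C++ likelihood kernel.
as_ptree <- function(phy) {
  po <- ape::reorder.phylo(phy, "postorder")
  d <- node_depths(phy)
  ntip <- length(phy$tip.label)
  list(parent = po$edge[, 1L], child = po$edge[, 2L], elen = po$edge.length,
       dpar = d[po$edge[, 1L]], dchild = d[po$edge[, 2L]],
       ntip = ntip, nnode = phy$Nnode, height = max(d[seq_len(ntip)]),
       root_edge = root_stem(phy), tip.label = phy$tip.label)
}

# Align a named per-tip vector to ape tip numbering (1..ntip).  Unnamed
# vectors are taken to follow sorted tip-label order, the package-wide
# convention for matrices and trait vectors.
align_to_tips <- function(phy, x, what = "trait") {
  n <- length(phy$tip.label)
  if (length(x) != n)
    stopf("%s has length %d but the tree has %d tips", what, length(x), n)
  if (!is.null(names(x))) {
    missing <- setdiff(phy$tip.label, names(x))
    if (length(missing))
      stopf("%s is missing values for: %s", what, paste(missing, collapse = ", "))
    x <- x[phy$tip.label]
  } else {
    x <- x[match(phy$tip.label, sort(phy$tip.label))]
  }
  unname(x)
}
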