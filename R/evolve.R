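#' Evolve a family of sequences from a root protein along a tree
#'
#' Simulates amino-acid substitution along the branches of a tree under a
#' simple Poisson process.  Each site accumulates `Poisson(branch length)`
#' substitution events per branch; a site with at least one event is redrawn
#' uniformly among its allowed residues other than the current one.  Sites
#' whose template mask fixes a single residue never change; class-constrained
#' sites (e.g. `[T/S]`) substitute only within their class; free background
#' sites substitute over the remaining 19 residues.  Branch lengths are in
#' expected substitutions per (free) site.
#'
#' @param root root protein sequence (character scalar)
#' @param tree either an integer number of leaves (a rescaled coalescent tree
#'   of that size is simulated with root-to-tip depth `rate`), the string
#'   `"star"` together with `n_leaves`, or an [ape::phylo] tree with branch
#'   lengths in substitutions/site (in which case `rate` is ignored)
#' @param rate root-to-tip expected substitutions per site (>= 0); used when
#'   `tree` is a leaf count or `"star"`
#' @param n_leaves number of leaves when `tree == "star"`
#' @param mask optional per-position allowed-set list as produced by
#'   [realize_template()]; `NULL` treats every site as free
#' @param label_prefix prefix for leaf names
#' @return list with `sequences` (named character vector, one per leaf) and
#'   `tree` (the [ape::phylo] tree actually used, leaf labels matching
#'   sequence names)
#' @export
evolve_family <- function(root, tree, rate = 0.1, n_leaves = NULL,
                          mask = NULL, label_prefix = "t") {
  stopifnot(is.character(root), length(root) == 1L, rate >= 0)
  if (is.numeric(tree) && length(tree) == 1L) {
    n <- as.integer(tree)
    stopifnot(n >= 1L)
    phy <- sim_family_tree(n, rate)
    phy$tip.label <- paste0(label_prefix, seq_along(phy$tip.label))
  } else if (identical(tree, "star")) {
    stopifnot(!is.null(n_leaves), n_leaves >= 1L)
    phy <- star_tree(as.integer(n_leaves), rate)
    phy$tip.label <- paste0(label_prefix, seq_along(phy$tip.label))
  } else if (inherits(tree, "phylo")) {
    phy <- tree  # caller-supplied tree: leaf labels kept as-is
  } else {
    stop("tree must be a leaf count, \"star\", or a phylo object")
  }
  res <- strsplit(root, "")[[1]]
  if (!is.null(mask) && length(mask) != length(res)) {
    stop("mask length does not match root sequence length")
  }
  n_tip <- length(phy$tip.label)
  seqs <- vector("list", n_tip + phy$Nnode)
  root_node <- n_tip + 1L
  seqs[[root_node]] <- res
  # preorder traversal so parents are evolved before children
  edges <- reorder_preorder(phy)
  for (k in seq_len(nrow(edges$edge))) {
    parent <- edges$edge[k, 1L]
    child <- edges$edge[k, 2L]
    seqs[[child]] <- mutate_branch(seqs[[parent]], edges$length[k], mask)
  }
  out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(out) <- phy$tip.label
  list(sequences = out, tree = phy)
}

# Coalescent-shaped family tree rescaled so every root-to-tip path length
# equals `depth` substitutions/site.
sim_family_tree <- function(n, depth) {
  if (n == 1L) {
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          edge.length = depth, tip.label = "t1",
                          Nnode = 1L), class = "phylo"))
  }
  if (n == 2L) {
    phy <- ape::read.tree(text = "(t1:1,t2:1);")
    phy$edge.length <- rep(depth, 2L)
    return(phy)
  }
  phy <- ape::rcoal(n)
  d <- max(ape::node.depth.edgelength(phy))
  if (d > 0) phy$edge.length <- phy$edge.length / d * depth
  phy
}

# Star (polytomy) tree with every pendant branch of length `depth`.
star_tree <- function(n, depth) {
  tips <- paste0("t", seq_len(n))
  txt <- paste0("(", paste0(tips, ":", depth, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Edges of a phylo tree in parent-before-child order, with lengths.
reorder_preorder <- function(phy) {
  if (nrow(phy$edge) <= 1L) {
    return(list(edge = phy$edge,
                length = if (is.null(phy$edge.length)) rep(0, nrow(phy$edge))
                         else phy$edge.length))
  }
  phy2 <- ape::reorder.phylo(phy, order = "cladewise")
  list(edge = phy2$edge,
       length = if (is.null(phy2$edge.length)) rep(0, nrow(phy2$edge))
                else phy2$edge.length)
}

# Apply Poisson substitutions along one branch.
mutate_branch <- function(res, b, mask) {
  if (b <= 0) return(res)
  hits <- which(stats::rpois(length(res), b) > 0L)
  for (i in hits) {
    allowed <- if (is.null(mask)) AA20 else mask[[i]]
    if (is.null(allowed)) allowed <- AA20
    if (length(allowed) <= 1L) next  # invariant site
    cand <- setdiff(allowed, res[i])
    if (length(cand) == 0L) next
    res[i] <- if (length(cand) == 1L) cand else sample(cand, 1L)
  }
  res
}
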