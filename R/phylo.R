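#' Poisson-corrected pairwise distances from a protein alignment
#'
#' For each pair, the p-distance is computed over columns where both
#' sequences are ungapped, then Poisson-corrected as `d = -ln(1 - p)`.
#' Saturated pairs (`p >= 0.95`) are capped at `d(0.95)` with a warning.
#' A pair with zero comparable columns is an error.
#'
#' @param alignment named character vector of aligned sequences (>= 2,
#'   equal lengths)
#' @return symmetric numeric distance matrix (substitutions/site) with ids
#'   as dimnames
#' @export
aln_distances <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 2L)
  if (length(unique(nchar(alignment))) > 1L) {
    stop("aligned sequences have unequal lengths")
  }
  m <- do.call(rbind, strsplit(alignment, ""))
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  capped <- FALSE
  cap <- -log(1 - 0.95)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L) {
        stop(sprintf("no comparable columns between %s and %s",
                     names(alignment)[i], names(alignment)[j]))
      }
      p <- sum(m[i, ok] != m[j, ok]) / nc
      if (p >= 0.95) {
        capped <- TRUE
        dij <- cap
      } else {
        dij <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  if (capped) warning("saturated pair(s) capped at d(p = 0.95)")
  d
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining (Saitou-Nei Q-criterion, via [ape::nj()]) with
#' negative branch lengths clamped to zero.  Internal edges of zero length
#' (no separating signal, e.g. between identical sequences) are collapsed
#' into polytomies so that arbitrary resolutions never contribute
#' bipartitions.  Exact on additive distance matrices, whose internal edges
#' are strictly positive.
#'
#' @param dm symmetric distance matrix with ids as dimnames
#' @return unrooted [ape::phylo] tree
#' @export
nj_tree <- function(dm) {
  if (nrow(dm) < 3L) stop("neighbor joining requires >= 3 taxa")
  phy <- ape::nj(stats::as.dist(dm))
  phy$edge.length[phy$edge.length < 0] <- 0
  ape::di2multi(phy, tol = 1e-12)
}

#' Bootstrap neighbor-joining with majority-rule consensus
#'
#' Resamples alignment columns with replacement `n_replicates` times,
#' builds an NJ tree per replicate, and returns the strict (>50%)
#' majority-rule consensus with per-edge support values (the fraction of
#' replicates containing each consensus bipartition).  Deterministic for a
#' fixed seed.
#'
#' @param alignment named character vector of aligned sequences (>= 3)
#' @param n_replicates number of bootstrap replicates (>= 1)
#' @param seed mandatory integer seed
#' @return list of class `tree_summary`: `consensus` ([ape::phylo] with
#'   supports as node labels), `supports` (per internal edge, in [0,1]),
#'   `n_replicates`, `replicate_trees`
#' @export
bootstrap_consensus <- function(alignment, n_replicates = 100L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_replicates >= 1L, length(alignment) >= 3L)
  set.seed(as.integer(seed))
  L <- nchar(alignment[[1L]])
  chars <- do.call(rbind, strsplit(alignment, ""))
  trees <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- setNames(apply(chars[, cols, drop = FALSE], 1L, paste,
                              collapse = ""), names(alignment))
    trees[[r]] <- nj_tree(aln_distances(rep_aln))
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, check.labels = TRUE)
  # support = fraction of replicates containing each consensus bipartition
  rep_splits <- lapply(trees, bipartitions)
  cons_splits <- bipartitions(cons)
  supports <- vapply(cons_splits, function(s) {
    mean(vapply(rep_splits, function(rs) any(vapply(rs, identical, TRUE, s)),
                TRUE))
  }, 0)
  # enforce strictly-greater-than-half majority rule
  weak <- which(supports <= 0.5)
  if (length(weak) > 0L) {
    cons <- drop_splits(cons, cons_splits[weak])
    cons_splits <- bipartitions(cons)
    supports <- supports[-weak]
  }
  cons$node.label <- c("", formatC(supports, format = "f", digits = 2))
  structure(list(consensus = cons, supports = supports,
                 n_replicates = as.integer(n_replicates),
                 replicate_trees = trees),
            class = "tree_summary")
}

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of the unrooted tree defines a bipartition of the
#' leaf set; bipartitions are canonicalized as the sorted side not
#' containing the alphabetically first leaf, so equal splits compare
#' `identical()`.
#'
#' @param tree an [ape::phylo] tree
#' @return list of character vectors (one per nontrivial bipartition)
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  if (n < 4L) return(list())
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  anchor <- sort(labs)[1L]
  out <- list()
  for (p in parts) {
    side <- labs[p]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= n - 1L) next
    out[[length(out) + 1L]] <- sort(side)
  }
  unique(out)
}

# Collapse the internal edges of `tree` that induce the given splits.
drop_splits <- function(tree, splits) {
  tree <- ape::unroot(tree)
  repeat {
    found <- FALSE
    n_tip <- length(tree$tip.label)
    internal <- which(tree$edge[, 2L] > n_tip)
    for (e in internal) {
      node <- tree$edge[e, 2L]
      tips <- sort(tree$tip.label[phangorn::Descendants(tree, node,
                                                        "tips")[[1L]]])
      anchor <- sort(tree$tip.label)[1L]
      side <- if (anchor %in% tips) sort(setdiff(tree$tip.label, tips)) else tips
      if (any(vapply(splits, identical, TRUE, side))) {
        tree$edge.length <- NULL
        tree <- collapse_edge(tree, e)
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  tree
}

# Collapse one internal edge into a polytomy.
collapse_edge <- function(tree, e) {
  child <- tree$edge[e, 2L]
  parent <- tree$edge[e, 1L]
  tree$edge[tree$edge[, 1L] == child, 1L] <- parent
  tree$edge <- tree$edge[-e, , drop = FALSE]
  # renumber internal nodes above the removed one
  tree$edge[tree$edge > child] <- tree$edge[tree$edge > child] - 1L
  tree$Nnode <- tree$Nnode - 1L
  tree
}

#' Topological equality of unrooted trees
#'
#' @param t1,t2 [ape::phylo] trees on the same leaf set
#' @return TRUE when the nontrivial bipartition sets are equal
#' @export
same_topology <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  s1 <- bipartitions(t1)
  s2 <- bipartitions(t2)
  length(s1) == length(s2) &&
    all(vapply(s1, function(s) any(vapply(s2, identical, TRUE, s)), TRUE))
}

#' Coupled-tree coevolution congruence
#'
#' Operationalizes visual clade matching between a GTPase tree and its
#' partner MglB tree: both trees are restricted to mapped leaves; each
#' internal bipartition `{S, S-bar}` of the GTPase tree is matched when some
#' bipartition `{T, T-bar}` of the MglB tree has, for every GTPase in `S`,
#' at least one partner inside `T` and, for every GTPase outside `S`, at
#' least one partner inside `T-bar` (for 1:2 systems the satisfying partner
#' is the "coevolving-clade" choice and is recorded).  The congruence
#' fraction is `matched / total internal bipartitions`; it is invariant to
#' rerooting of either tree.
#'
#' @param tree_g GTPase tree ([ape::phylo])
#' @param tree_b MglB tree ([ape::phylo])
#' @param partner_map named list: GTPase leaf -> character vector of 1 or 2
#'   MglB leaves
#' @return list of class `congruence_report`: `fraction`, `n_bipartitions`,
#'   `n_matched`, `matches` (per-bipartition data.frame), `chosen_partners`
#' @export
congruence <- function(tree_g, tree_b, partner_map) {
  if (length(partner_map) == 0L) stop("empty partner map")
  g_leaves <- intersect(tree_g$tip.label, names(partner_map))
  if (length(g_leaves) == 0L) stop("no mapped leaves present in tree_g")
  b_leaves <- intersect(tree_b$tip.label, unique(unlist(partner_map[g_leaves])))
  partner_map <- lapply(partner_map[g_leaves], intersect, b_leaves)
  keep_g <- g_leaves[lengths(partner_map) > 0L]
  partner_map <- partner_map[keep_g]
  tg <- ape::keep.tip(tree_g, keep_g)
  tb <- ape::keep.tip(tree_b, unique(unlist(partner_map)))
  sg <- bipartitions(tg)
  sb <- bipartitions(tb)
  nb <- length(tb$tip.label)
  # membership matrix of tree_b splits (rows) over its leaves
  if (length(sb) > 0L) {
    Mb <- do.call(rbind, lapply(sb, function(s) tb$tip.label %in% s))
    colnames(Mb) <- tb$tip.label
  } else {
    Mb <- matrix(FALSE, 0L, nb, dimnames = list(NULL, tb$tip.label))
  }
  gt <- names(partner_map)
  in_T <- function(row) {
    vapply(partner_map, function(p) any(row[p]), TRUE)  # >=1 partner in T
  }
  if (length(sb) > 0L) {
    has_in <- t(apply(Mb, 1L, in_T))
    has_out <- t(apply(!Mb, 1L, in_T))
    if (length(sb) == 1L) {  # apply() drops dims for single rows
      has_in <- matrix(has_in, nrow = 1L, dimnames = list(NULL, gt))
      has_out <- matrix(has_out, nrow = 1L, dimnames = list(NULL, gt))
    }
  }
  matched <- logical(length(sg))
  chosen <- list()
  for (k in seq_along(sg)) {
    S <- sg[[k]]
    inS <- gt %in% S
    if (length(sb) == 0L) break
    ok_fwd <- rowSums(has_in[, inS, drop = FALSE]) == sum(inS) &
      rowSums(has_out[, !inS, drop = FALSE]) == sum(!inS)
    # also accept the complementary orientation of T
    ok_rev <- rowSums(has_out[, inS, drop = FALSE]) == sum(inS) &
      rowSums(has_in[, !inS, drop = FALSE]) == sum(!inS)
    hit <- which(ok_fwd | ok_rev)
    matched[k] <- length(hit) > 0L
    if (matched[k]) {
      r <- hit[1L]
      row <- if (ok_fwd[r]) Mb[r, ] else !Mb[r, ]
      chosen[[length(chosen) + 1L]] <- data.frame(
        gtpase = S,
        partner = vapply(S, function(g) {
          p <- partner_map[[g]]
          p[row[p]][1L]
        }, ""),
        stringsAsFactors = FALSE)
    }
  }
  frac <- if (length(sg) == 0L) NA_real_ else mean(matched)
  matches <- data.frame(
    bipartition = vapply(sg, paste, "", collapse = ","),
    matched = matched, stringsAsFactors = FALSE)
  structure(list(fraction = frac, n_bipartitions = length(sg),
                 n_matched = sum(matched), matches = matches,
                 chosen_partners = if (length(chosen) > 0L)
                   unique(do.call(rbind, chosen)) else NULL),
            class = "congruence_report")
}
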