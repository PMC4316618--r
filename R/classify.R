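#' Family assignment from tree, coupling and motif evidence
#'
#' Assigns each candidate leaf to the MglA or Rup family.  Primary evidence
#' is the tree: a leaf belongs to a family when it falls inside the minimal
#' clade (on the midpoint-rooted tree) containing all of that family's
#' reference leaves and no reference of the other family.  When the tree is
#' ambiguous for a leaf (inside neither pure reference clade, or inside
#' both), a vote decides: coupled-to-MglB and a present G1-G2 insertion
#' each count toward MglA; a Ras-like mechanism call (`RAS_LIKE_Q` /
#' `RAS_LIKE_NO_Q`) counts toward Rup; ties give family `none` with
#' evidence `ambiguous`.
#'
#' @param tree [ape::phylo] covering all candidates plus reference leaves
#' @param reference_families named character vector: reference leaf id ->
#'   `"MglA"` or `"Rup"`
#' @param lengths named integer vector of protein lengths
#' @param coupled character vector of leaf ids coupled to an MglB
#' @param mechanisms optional `mechanism_calls` data.frame
#' @param insertions optional [detect_insertion()] data.frame
#' @param roco_flags character vector of leaf ids flagged as Roco-like
#'   (N-terminal LRRs); a Roco flag forces `small = FALSE`
#' @param small_band inclusive length band for the "small GTPase" flag
#' @return data.frame of class `family_assignments`: `protein_id`,
#'   `family`, `small`, `coupled`, `roco`, `evidence`
#' @export
assign_family <- function(tree, reference_families, lengths,
                          coupled = character(0), mechanisms = NULL,
                          insertions = NULL, roco_flags = character(0),
                          small_band = c(150L, 240L)) {
  refs <- reference_families[names(reference_families) %in% tree$tip.label]
  if (length(refs) == 0L) stop("no reference leaves present in tree")
  rooted <- midpoint_root(tree)
  clade_tips <- function(fam) {
    ids <- names(refs)[refs == fam]
    if (length(ids) == 0L) return(character(0))
    tips <- mrca_tips(rooted, ids)
    other <- names(refs)[refs != fam]
    if (any(other %in% tips)) return(character(0))  # impure reference clade
    tips
  }
  in_mgla <- clade_tips("MglA")
  in_rup <- clade_tips("Rup")
  mech <- if (!is.null(mechanisms)) {
    setNames(mechanisms$call, mechanisms$protein_id)
  } else character(0)
  ins <- if (!is.null(insertions)) {
    setNames(insertions$insertion_present, insertions$protein_id)
  } else logical(0)
  out <- lapply(tree$tip.label, function(id) {
    evidence <- character(0)
    if (id %in% names(refs)) {
      fam <- unname(refs[[id]])
      evidence <- "reference"
    } else {
      clade_m <- id %in% in_mgla
      clade_r <- id %in% in_rup
      if (xor(clade_m, clade_r)) {
        fam <- if (clade_m) "MglA" else "Rup"
        evidence <- "clade"
      } else {
        vote_m <- 0L
        vote_r <- 0L
        if (id %in% coupled) {
          vote_m <- vote_m + 1L
          evidence <- c(evidence, "coupling")
        }
        if (isTRUE(ins[id])) {
          vote_m <- vote_m + 1L
          evidence <- c(evidence, "insertion")
        }
        mid <- if (length(mech) > 0L) unname(mech[id]) else NA_character_
        if (!is.na(mid) && mid %in% c("RAS_LIKE_Q", "RAS_LIKE_NO_Q")) {
          vote_r <- vote_r + 1L
          evidence <- c(evidence, "motif")
        }
        fam <- if (vote_m > vote_r) "MglA"
               else if (vote_r > vote_m) "Rup"
               else "none"
        if (fam == "none") evidence <- "ambiguous"
      }
    }
    len <- unname(lengths[id])
    roco <- id %in% roco_flags
    data.frame(protein_id = id, family = fam,
               small = !roco & !is.na(len) & len >= small_band[1L] &
                 len <= small_band[2L],
               coupled = id %in% coupled, roco = roco,
               evidence = paste(evidence, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("family_assignments", class(res))
  res
}

# `%||%` for possibly-missing named lookups
midpoint_root <- function(tree) {
  if (!is.null(tree$edge.length)) phangorn::midpoint(tree) else tree
}

mrca_tips <- function(rooted, ids) {
  if (length(ids) == 1L) return(ids)
  node <- ape::getMRCA(rooted, ids)
  if (is.null(node)) return(rooted$tip.label)
  rooted$tip.label[phangorn::Descendants(rooted, node, "tips")[[1L]]]
}

#' Group assignment from reference-anchored clades
#'
#' Groups are the maximal clades (on the midpoint-rooted tree) whose
#' reference leaves all carry one group label; members inherit the label.
#' Leaves outside any pure reference clade, and leaves whose assigned
#' family contradicts the group's family, stay `unclassified`.
#'
#' @param assignments a `family_assignments` data.frame
#' @param tree the tree used for assignment
#' @param group_refs named character vector: reference leaf id -> group
#'   label (e.g. `"MglA_G1"`); group labels are expected to start with the
#'   family name
#' @return `assignments` with a `group` column added
#' @export
assign_group <- function(assignments, tree, group_refs) {
  refs <- group_refs[names(group_refs) %in% tree$tip.label]
  if (length(refs) == 0L) stop("no group references present in tree")
  rooted <- midpoint_root(tree)
  n_tip <- length(rooted$tip.label)
  nodes <- n_tip + seq_len(rooted$Nnode)
  tips_below <- phangorn::Descendants(rooted, nodes, "tips")
  groups_below <- lapply(tips_below, function(t)
    unique(refs[intersect(rooted$tip.label[t], names(refs))]))
  pure <- lengths(groups_below) == 1L
  parent_of <- setNames(rooted$edge[, 1L], rooted$edge[, 2L])
  group <- setNames(rep("unclassified", n_tip), rooted$tip.label)
  for (k in seq_along(nodes)) {
    if (!pure[k]) next
    par <- parent_of[as.character(nodes[k])]
    if (!is.na(par) && pure[par - n_tip]) next  # not maximal
    tips <- rooted$tip.label[tips_below[[k]]]
    group[tips] <- groups_below[[k]][[1L]]
  }
  # single references are their own (leaf) clades when no internal node is pure
  for (id in names(refs)) {
    if (group[id] == "unclassified") group[id] <- unname(refs[id])
  }
  out <- assignments
  out$group <- unname(group[out$protein_id])
  mismatch <- out$group != "unclassified" &
    !startsWith(out$group, out$family)
  out$group[mismatch] <- "unclassified"
  out
}

#' Census report (family table and per-group breakdown)
#'
#' Per family the four census rows: all sequences, small sequences,
#' sequences coupled to MglB, and small sequences coupled to MglB; plus a
#' per-group breakdown.  Invariants `small <= all` and
#' `small_coupled <= min(small, coupled)` hold by construction.
#'
#' @param assignments a `family_assignments` data.frame (with or without a
#'   `group` column)
#' @return list of class `census_report`: `family_table`, `group_table`
#' @export
census_report <- function(assignments) {
  fams <- c("MglA", "Rup")
  family_table <- do.call(rbind, lapply(fams, function(f) {
    a <- assignments[assignments$family == f, , drop = FALSE]
    data.frame(family = f,
               all_sequences = nrow(a),
               small_sequences = sum(a$small),
               coupled_to_mglb = sum(a$coupled),
               small_coupled = sum(a$small & a$coupled),
               stringsAsFactors = FALSE)
  }))
  group_table <- NULL
  if ("group" %in% names(assignments)) {
    grp <- assignments[assignments$family %in% fams, , drop = FALSE]
    tab <- split(grp, grp$group)
    group_table <- do.call(rbind, lapply(names(tab), function(g) {
      a <- tab[[g]]
      data.frame(group = g, n = nrow(a), n_small = sum(a$small),
                 n_coupled = sum(a$coupled), stringsAsFactors = FALSE)
    }))
    rownames(group_table) <- NULL
  }
  structure(list(family_table = family_table, group_table = group_table),
            class = "census_report")
}
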