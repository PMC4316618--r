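#' Gene-index distance on a replicon
#'
#' Ordinal distance between two gene indices: `|i - j|` on a linear
#' replicon, `min(|i - j|, N - |i - j|)` on a circular replicon of `N`
#' genes.
#'
#' @param i,j 0-based gene indices
#' @param n_genes number of genes on the replicon
#' @param topology `"circular"` or `"linear"`
#' @return integer distance
#' @export
gene_distance <- function(i, j, n_genes, topology = "linear") {
  d <- abs(i - j)
  if (topology == "circular") d <- pmin(d, n_genes - d)
  as.integer(d)
}

# Internal: per-protein gene lookup table keyed by "genome|locus".
gene_lookup <- function(genes) {
  ids <- protein_id(genes$genome_id, genes$locus_tag)
  n_per_replicon <- table(genes$replicon_id)
  data.frame(protein_id = ids, replicon_id = genes$replicon_id,
             topology = genes$topology, gene_index = genes$gene_index,
             n_genes = as.integer(n_per_replicon[genes$replicon_id]),
             stringsAsFactors = FALSE)
}

#' Find GTPase-MglB gene couplings
#'
#' A GTPase and an MglB gene are coupled when they lie on the same replicon
#' within `window` genes of each other (ordinal gene-index distance,
#' strand-agnostic, circular-aware).  Every qualifying pair is reported.
#'
#' @param gtpases,mglbs character vectors of protein ids (`"genome|locus"`)
#' @param genes gene-table data.frame (see [read_gene_table()])
#' @param window maximum ordinal distance (default 4, "encoded within four
#'   genes")
#' @return data.frame of class `coupling_records`: `gtpase`, `mglb`,
#'   `distance`, `replicon_id`
#' @export
find_couplings <- function(gtpases, mglbs, genes, window = 4L) {
  lut <- gene_lookup(genes)
  missing <- setdiff(c(gtpases, mglbs), lut$protein_id)
  if (length(missing) > 0L) {
    stop("id(s) missing from gene table: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  ga <- lut[match(gtpases, lut$protein_id), , drop = FALSE]
  gb <- lut[match(mglbs, lut$protein_id), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ga))) {
    same <- which(gb$replicon_id == ga$replicon_id[i] &
                    gb$protein_id != ga$protein_id[i])
    if (length(same) == 0L) next
    d <- gene_distance(ga$gene_index[i], gb$gene_index[same],
                       ga$n_genes[i], ga$topology[i])
    hit <- which(d <= window & d >= 1L)
    if (length(hit) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      gtpase = ga$protein_id[i], mglb = gb$protein_id[same][hit],
      distance = d[hit], replicon_id = ga$replicon_id[i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(data.frame(
    gtpase = character(0), mglb = character(0), distance = integer(0),
    replicon_id = character(0), stringsAsFactors = FALSE))))
  res <- res[order(res$gtpase, res$distance, res$mglb), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("coupling_records", class(res))
  res
}

#' Stoichiometry and orphan classification
#'
#' Labels every GTPase by the number of MglB partners within the window
#' (`1:1`, `1:2`, or `1:k` recorded verbatim) and lists orphans on both
#' sides: GTPases with no MglB partner and MglBs with no GTPase partner.
#'
#' @param couplings output of [find_couplings()]
#' @param gtpases,mglbs the full id sets that were searched (needed to list
#'   orphans)
#' @return list of class `context_summary`: `stoichiometry` (data.frame
#'   `gtpase`, `n_partners`, `class`), `orphan_gtpases`, `orphan_mglbs`,
#'   `coupled_gtpases`, `coupled_mglbs`
#' @export
classify_stoichiometry <- function(couplings, gtpases, mglbs) {
  cnt <- table(factor(couplings$gtpase, levels = unique(couplings$gtpase)))
  stoich <- data.frame(gtpase = as.character(names(cnt) %||% character(0)),
                       n_partners = as.integer(cnt),
                       stringsAsFactors = FALSE)
  stoich$class <- if (nrow(stoich) > 0L) paste0("1:", stoich$n_partners)
                  else character(0)
  coupled_g <- unique(couplings$gtpase)
  coupled_b <- unique(couplings$mglb)
  structure(list(
    stoichiometry = stoich,
    coupled_gtpases = coupled_g,
    coupled_mglbs = coupled_b,
    orphan_gtpases = setdiff(gtpases, coupled_g),
    orphan_mglbs = setdiff(mglbs, coupled_b)
  ), class = "context_summary")
}

#' Gene-neighborhood composition around a system
#'
#' Collects the product labels of all genes within `window` gene indices of
#' any gene of the system, excluding the system's own genes, ordered by
#' gene index (a label multiset for neighborhood surveys, e.g. PATAN- or
#' histidine-kinase-annotated neighbors).
#'
#' @param system character vector of the system's protein ids
#' @param genes gene-table data.frame
#' @param window ordinal window (default 4); `window = 0` yields an empty
#'   multiset
#' @return character vector of neighbor product labels (ordered by index)
#' @export
neighborhood_composition <- function(system, genes, window = 4L) {
  if (window <= 0L || length(system) == 0L) return(character(0))
  lut <- gene_lookup(genes)
  sys <- lut[match(system, lut$protein_id), , drop = FALSE]
  if (anyNA(sys$gene_index)) {
    stop("system id(s) missing from gene table")
  }
  ids <- protein_id(genes$genome_id, genes$locus_tag)
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(sys))) {
    on_rep <- genes$replicon_id == sys$replicon_id[i]
    d <- gene_distance(sys$gene_index[i], genes$gene_index,
                       sys$n_genes[i], sys$topology[i])
    keep <- keep | (on_rep & d <= window & d >= 1L)
  }
  keep[ids %in% system] <- FALSE
  nb <- genes[keep, , drop = FALSE]
  nb <- nb[order(nb$replicon_id, nb$gene_index), , drop = FALSE]
  nb$product
}

#' Brute-force coupling oracle
#'
#' All-pairs O(n^2) re-derivation of [find_couplings()], used as an
#' independent correctness oracle in tests.
#'
#' @inheritParams find_couplings
#' @return data.frame in the same shape as [find_couplings()]
#' @export
find_couplings_bruteforce <- function(gtpases, mglbs, genes, window = 4L) {
  lut <- gene_lookup(genes)
  out <- list()
  for (a in gtpases) {
    ia <- match(a, lut$protein_id)
    if (is.na(ia)) stop("id missing from gene table: ", a)
    for (b in mglbs) {
      ib <- match(b, lut$protein_id)
      if (is.na(ib)) stop("id missing from gene table: ", b)
      if (a == b) next
      if (lut$replicon_id[ia] != lut$replicon_id[ib]) next
      raw <- abs(lut$gene_index[ia] - lut$gene_index[ib])
      d <- if (lut$topology[ia] == "circular") {
        min(raw, lut$n_genes[ia] - raw)
      } else raw
      if (d >= 1L && d <= window) {
        out[[length(out) + 1L]] <- data.frame(
          gtpase = a, mglb = b, distance = as.integer(d),
          replicon_id = lut$replicon_id[ia], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, c(out, list(data.frame(
    gtpase = character(0), mglb = character(0), distance = integer(0),
    replicon_id = character(0), stringsAsFactors = FALSE))))
  res <- res[order(res$gtpase, res$distance, res$mglb), , drop = FALSE]
  rownames(res) <- NULL
  res
}
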