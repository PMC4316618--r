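#' Resolve overlapping domain hits into a domain architecture
#'
#' Greedy resolution: repeatedly keep the highest-scoring remaining hit and
#' discard every hit overlapping it (sharing at least one residue, or at
#' least `min_overlap_frac` of the shorter interval when configured), until
#' no hits remain.  Score ties are broken by lower e-value, then longer
#' interval, then domain name lexicographically, for determinism.
#'
#' @param hits domain-hit data.frame for a single protein (see
#'   [read_domain_hits()])
#' @param min_overlap_frac minimum overlap, as a fraction of the shorter
#'   interval, for two hits to conflict; default 0 (any shared residue)
#' @return list of class `domain_architecture` with `protein_id`, `kept`
#'   (data.frame ordered by `ali_from`) and `discarded` (data.frame with a
#'   `displaced_by` column)
#' @export
resolve_architecture <- function(hits, min_overlap_frac = 0) {
  if (nrow(hits) == 0L) {
    return(structure(list(protein_id = NA_character_,
                          kept = hits, discarded = cbind(hits,
                            displaced_by = character(0))),
                     class = "domain_architecture"))
  }
  if (length(unique(hits$protein_id)) != 1L) {
    stop("resolve_architecture expects hits for a single protein")
  }
  ord <- order(-hits$bit_score, hits$e_value,
               -(hits$ali_to - hits$ali_from), hits$domain_name)
  hits <- hits[ord, , drop = FALSE]
  kept <- logical(nrow(hits))
  displaced_by <- rep(NA_character_, nrow(hits))
  alive <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    if (i < nrow(hits)) {
      for (j in seq(i + 1L, nrow(hits))) {
        if (!alive[j]) next
        if (intervals_conflict(hits$ali_from[i], hits$ali_to[i],
                               hits$ali_from[j], hits$ali_to[j],
                               min_overlap_frac)) {
          alive[j] <- FALSE
          displaced_by[j] <- hits$domain_name[i]
        }
      }
    }
  }
  k <- hits[kept, , drop = FALSE]
  k <- k[order(k$ali_from), , drop = FALSE]
  d <- hits[!kept, , drop = FALSE]
  d$displaced_by <- displaced_by[!kept]
  rownames(k) <- rownames(d) <- NULL
  structure(list(protein_id = hits$protein_id[1L], kept = k, discarded = d),
            class = "domain_architecture")
}

intervals_conflict <- function(a1, a2, b1, b2, min_frac = 0) {
  ov <- min(a2, b2) - max(a1, b1) + 1L
  if (ov < 1L) return(FALSE)
  if (min_frac <= 0) return(TRUE)
  shorter <- min(a2 - a1, b2 - b1) + 1L
  ov / shorter >= min_frac
}

#' Resolve architectures for a whole domain-hit table
#'
#' @param domain_hits domain-hit data.frame covering any number of proteins
#' @inheritParams resolve_architecture
#' @return named list of `domain_architecture` objects, one per protein
#' @export
resolve_architectures <- function(domain_hits, min_overlap_frac = 0) {
  if (nrow(domain_hits) == 0L) return(list())
  by_prot <- split(domain_hits, domain_hits$protein_id)
  lapply(by_prot, resolve_architecture, min_overlap_frac = min_overlap_frac)
}

architecture_domains <- function(architectures, id) {
  a <- architectures[[id]]
  if (is.null(a)) character(0) else a$kept$domain_name
}

#' Domain-frequency census over seed-hit subjects
#'
#' Tallies, over the subjects of the seed similarity search, how often each
#' domain occurs in the resolved architectures; the ranked table guides the
#' choice of collection domains.  Subjects with no resolved domains are
#' listed separately (proteins that match the seed but no domain model).
#'
#' @param seed_hits similarity-hit data.frame from the seed search
#' @param architectures named list from [resolve_architectures()]
#' @return list with `table` (data.frame `domain_name`, `count`, descending)
#'   and `no_domain_subjects` (character vector)
#' @export
census_domains <- function(seed_hits, architectures) {
  subjects <- unique(seed_hits$subject_id)
  doms <- lapply(subjects, function(s)
    unique(architecture_domains(architectures, s)))
  no_dom <- subjects[lengths(doms) == 0L]
  tab <- table(unlist(doms))
  if (length(tab) == 0L) {
    df <- data.frame(domain_name = character(0), count = integer(0),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(domain_name = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$domain_name), , drop = FALSE]
    rownames(df) <- NULL
  }
  list(table = df, no_domain_subjects = no_dom)
}

#' Extract a 1-based inclusive region from a protein sequence
#'
#' @param sequence protein sequence (character scalar)
#' @param ali_from,ali_to 1-based inclusive residue coordinates
#' @return the subsequence
#' @export
extract_region <- function(sequence, ali_from, ali_to) {
  n <- nchar(sequence)
  if (ali_from < 1L || ali_to > n || ali_from > ali_to) {
    stop(sprintf("region [%d, %d] out of range for sequence of length %d",
                 ali_from, ali_to, n))
  }
  substr(sequence, ali_from, ali_to)
}

#' Harvest configuration
#'
#' @param seeds character vector of seed protein ids (must be present in the
#'   proteome)
#' @param e_value_threshold significance cutoff for similarity hits
#' @param min_length sequences shorter than this are excluded (truncations
#'   lacking conserved regions)
#' @param max_length sequences longer than this are flagged not-small but
#'   retained for tree context
#' @param mglb_mode when `TRUE`, the length band is only annotated, never
#'   used for exclusion or flagging (Roadblock/LC7 fusion proteins are
#'   retained), and the MglB band [129, 179] is reported
#' @param excluded_architecture_domains architectures containing any of
#'   these domains are excluded as decoys (ABC-transporter-like)
#' @param selected_domains optional explicit collection-domain set; by
#'   default the top `n_collect_domains` of the seed-hit domain census
#' @param n_collect_domains number of top census domains used for collection
#' @param expansion_rounds number of region-query expansion passes
#' @param max_expansion_queries cap on expansion queries per round (regions
#'   chosen deterministically, spread over the selected domains)
#' @return an object of class `harvest_config`
#' @export
harvest_config <- function(seeds,
                           e_value_threshold = 1e-4,
                           min_length = 150L, max_length = 240L,
                           mglb_mode = FALSE,
                           excluded_architecture_domains =
                             c("ABC_tran", "ABC_tran_2", "AAA_21"),
                           selected_domains = NULL,
                           n_collect_domains = 4L,
                           expansion_rounds = 1L,
                           max_expansion_queries = 16L) {
  if (min_length >= max_length) stop("min_length must be < max_length")
  if (e_value_threshold <= 0) stop("e_value_threshold must be > 0")
  structure(list(seeds = seeds, e_value_threshold = e_value_threshold,
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length), mglb_mode = mglb_mode,
                 excluded_architecture_domains = excluded_architecture_domains,
                 selected_domains = selected_domains,
                 n_collect_domains = as.integer(n_collect_domains),
                 expansion_rounds = as.integer(expansion_rounds),
                 max_expansion_queries = as.integer(max_expansion_queries)),
            class = "harvest_config")
}

#' Iterative homolog collection
#'
#' The census harvesting algorithm: (i) seed similarity search at the
#' significance threshold; (ii) domain-frequency census of the seed-hit
#' subjects and selection of collection domains; (iii) collection of every
#' protein whose resolved architecture contains a selected domain; (iv)
#' extraction of the domain regions and expansion similarity search with
#' those regions as queries; (v) union of all three sources.  Exclusion
#' rules are then applied: architectures containing an excluded
#' (ABC-transporter-like) domain, and sequences shorter than `min_length`.
#' Sequences longer than `max_length` are flagged not-small but retained
#' for tree context (unless `mglb_mode`).
#'
#' @param config a [harvest_config()]
#' @param proteome named character vector of all protein sequences
#' @param domain_hits domain-hit data.frame (synthetic annotation or a real
#'   domtblout)
#' @param similarity_hits optional precomputed similarity-hit data.frame;
#'   when supplied it replaces the built-in search for the seed and
#'   expansion queries it covers (backend interchangeability)
#' @param params [search_params()] for the built-in search
#' @return list of class `harvest_result` with `candidates` (data.frame:
#'   `protein_id`, `provenance`, `length`, `small`), `excluded` (data.frame:
#'   `protein_id`, `reason`), `domain_census`, `selected_domains` and
#'   `architectures`
#' @export
iterative_collect <- function(config, proteome, domain_hits,
                              similarity_hits = NULL,
                              params = search_params()) {
  stopifnot(inherits(config, "harvest_config"))
  missing_seeds <- setdiff(config$seeds, names(proteome))
  if (length(missing_seeds) > 0L || length(config$seeds) == 0L) {
    stop("configuration error: seeds not found in proteome: ",
         paste(missing_seeds, collapse = ", "))
  }
  params$e_value_threshold <- config$e_value_threshold
  architectures <- resolve_architectures(domain_hits)
  run_search <- function(queries) {
    if (!is.null(similarity_hits)) {
      h <- similarity_hits[similarity_hits$query_id %in% names(queries) &
                             similarity_hits$e_value <= config$e_value_threshold, ,
                           drop = FALSE]
      covered <- unique(similarity_hits$query_id)
      rest <- queries[!(names(queries) %in% covered)]
      if (length(rest) > 0L) {
        h <- rbind(h, search_all(rest, proteome, params))
      }
      h
    } else {
      search_all(queries, proteome, params)
    }
  }

  ## (i) seed search
  seed_hits <- run_search(proteome[config$seeds])
  provenance <- setNames(rep("seed-hit", length(unique(seed_hits$subject_id))),
                         unique(seed_hits$subject_id))

  ## (ii) domain census & selection
  dcensus <- census_domains(seed_hits, architectures)
  selected <- config$selected_domains
  if (is.null(selected)) {
    pool <- setdiff(dcensus$table$domain_name,
                    config$excluded_architecture_domains)
    selected <- utils::head(pool, config$n_collect_domains)
  }

  ## (iii) domain-member collection
  member_of <- vapply(names(architectures), function(id)
    any(architecture_domains(architectures, id) %in% selected), TRUE)
  members <- names(architectures)[member_of]
  members <- intersect(members, names(proteome))
  new_members <- setdiff(members, names(provenance))
  provenance[new_members] <- "domain-member"

  ## (iv) expansion rounds
  frontier <- members
  for (round in seq_len(config$expansion_rounds)) {
    queries <- expansion_queries(frontier, architectures, selected, proteome,
                                 config$max_expansion_queries)
    if (length(queries) == 0L) break
    exp_hits <- run_search(queries)
    found <- unique(exp_hits$subject_id)
    new_ids <- setdiff(found, names(provenance))
    if (length(new_ids) == 0L) break
    provenance[new_ids] <- "expansion-hit"
    frontier <- new_ids
  }

  ## (v) exclusions
  ids <- names(provenance)
  lens <- nchar(proteome[ids])
  arch_doms <- lapply(ids, function(id) architecture_domains(architectures, id))
  is_decoy <- vapply(arch_doms, function(d)
    any(d %in% config$excluded_architecture_domains), TRUE)
  is_short <- !is_decoy & lens < config$min_length & !config$mglb_mode
  keep <- !is_decoy & !is_short
  excluded <- data.frame(
    protein_id = ids[!keep],
    reason = ifelse(is_decoy[!keep], "decoy-architecture", "short"),
    stringsAsFactors = FALSE)
  candidates <- data.frame(
    protein_id = ids[keep], provenance = unname(provenance[keep]),
    length = unname(lens[keep]),
    small = if (config$mglb_mode) NA else
      unname(lens[keep] <= config$max_length),
    stringsAsFactors = FALSE)
  if (config$mglb_mode) {
    candidates$in_mglb_band <- candidates$length >= 129L &
      candidates$length <= 179L
  }
  candidates <- candidates[order(candidates$protein_id), , drop = FALSE]
  excluded <- excluded[order(excluded$protein_id), , drop = FALSE]
  rownames(candidates) <- rownames(excluded) <- NULL
  structure(list(candidates = candidates, excluded = excluded,
                 domain_census = dcensus, selected_domains = selected,
                 architectures = architectures),
            class = "harvest_result")
}

# Deterministic choice of expansion query regions: for each selected domain,
# take the region of up to ceiling(cap / n_domains) member proteins (sorted
# by id), favouring distinct proteins.
expansion_queries <- function(members, architectures, selected, proteome, cap) {
  if (length(members) == 0L || length(selected) == 0L || cap <= 0L) {
    return(setNames(character(0), character(0)))
  }
  per_dom <- max(1L, ceiling(cap / length(selected)))
  queries <- character(0)
  for (dom in selected) {
    has <- vapply(members, function(id)
      dom %in% architecture_domains(architectures, id), TRUE)
    take <- utils::head(sort(members[has]), per_dom)
    for (id in take) {
      k <- architectures[[id]]$kept
      k <- k[k$domain_name == dom, , drop = FALSE]
      if (nrow(k) == 0L || !(id %in% names(proteome))) next
      to <- min(k$ali_to[1L], nchar(proteome[[id]]))
      queries[[paste0(id, ":", dom)]] <-
        extract_region(proteome[[id]], k$ali_from[1L], to)
    }
  }
  utils::head(queries, cap)
}
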