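#' Run the full census pipeline on a synthetic (or ingested) genome set
#'
#' End-to-end driver: harvests GTPase candidates from a seed (iterative
#' similarity + domain collection with exclusion rules), harvests MglB
#' candidates in MglB mode, computes gene-neighborhood couplings and
#' stoichiometry, aligns the small-GTPase candidates and builds an NJ tree,
#' assigns families and groups against the reference leaves, projects
#' G1-G5 motifs per family, calls catalytic mechanisms, measures G1-G2
#' insertions, and emits the census report.
#'
#' @param census a `synthetic_census` (or a compatible list with elements
#'   `proteome`, `genes`, `domain_hits`, `references`, `motif_offsets`)
#' @param window coupling window in gene indices (default 4)
#' @param params [search_params()] for the similarity searches
#' @param expansion_rounds expansion passes for the harvests
#' @param gtpase_seed,mglb_seed seed protein ids; default: the planted
#'   MglA Group 1 reference and its MglB partner
#' @return list of class `census_run` with all intermediate and final
#'   results (see Details in the package vignette)
#' @export
run_census_pipeline <- function(census, window = 4L,
                                params = search_params(),
                                expansion_rounds = 1L,
                                gtpase_seed = NULL, mglb_seed = NULL) {
  proteome <- census$proteome
  refs <- census$references
  if (is.null(gtpase_seed)) {
    gtpase_seed <- refs$protein_id[refs$group == "MglA_G1"]
    if (length(gtpase_seed) == 0L) {
      gtpase_seed <- refs$protein_id[refs$family == "MglA"][1L]
    }
    gtpase_seed <- gtpase_seed[1L]
  }
  if (is.null(mglb_seed)) {
    mglb_seed <- refs$protein_id[refs$family == "MglB"][1L]
  }
  if (is.na(gtpase_seed)) stop("no GTPase seed available")

  ## --- harvest -----------------------------------------------------------
  h_g <- iterative_collect(
    harvest_config(seeds = gtpase_seed, expansion_rounds = expansion_rounds),
    proteome, census$domain_hits, params = params)
  h_b <- if (!is.na(mglb_seed)) {
    iterative_collect(
      harvest_config(seeds = mglb_seed, mglb_mode = TRUE,
                     n_collect_domains = 1L,
                     expansion_rounds = expansion_rounds),
      proteome, census$domain_hits, params = params)
  } else NULL

  gtpase_ids <- h_g$candidates$protein_id
  mglb_ids <- if (!is.null(h_b)) {
    setdiff(h_b$candidates$protein_id, gtpase_ids)
  } else character(0)

  ## --- genome context ----------------------------------------------------
  couplings <- find_couplings(gtpase_ids, mglb_ids, census$genes,
                              window = window)
  context <- classify_stoichiometry(couplings, gtpase_ids, mglb_ids)

  ## --- tree of GTPase candidates ----------------------------------------
  aln <- align_proteins(proteome[gtpase_ids])
  tree <- nj_tree(aln_distances(aln))

  ## --- motifs (projected through the candidate alignment) ---------------
  ref_map_key <- if ("mgla_g1" %in% names(census$motif_offsets)) "mgla_g1"
                 else names(census$motif_offsets)[1L]
  motifs <- NULL
  insertions <- NULL
  mechanisms <- NULL
  if (!is.null(ref_map_key)) {
    map <- tryCatch(motif_map_from_truth(census, ref_map_key),
                    error = function(e) NULL)
    if (!is.null(map) && map$reference_id %in% names(aln)) {
      motifs <- project_motifs(aln, map)
      mechanisms <- call_mechanism(motifs)
      off <- census$motif_offsets[[ref_map_key]]
      base_spacing <- off$spacing_g1_g2 - off$insertion
      insertions <- detect_insertion(motifs, base_spacing)
    }
  }

  ## --- classification ----------------------------------------------------
  ref_fams <- setNames(refs$family, refs$protein_id)
  ref_fams <- ref_fams[ref_fams %in% c("MglA", "Rup")]
  ref_groups <- setNames(refs$group, refs$protein_id)
  ref_groups <- ref_groups[names(ref_fams)]
  lengths <- setNames(nchar(proteome), names(proteome))
  roco_flags <- names(Filter(function(a) any(grepl("^LRR", a$kept$domain_name)),
                             h_g$architectures))
  roco_flags <- intersect(roco_flags, gtpase_ids)
  assignments <- assign_family(tree, ref_fams, lengths,
                               coupled = context$coupled_gtpases,
                               mechanisms = mechanisms,
                               insertions = insertions,
                               roco_flags = roco_flags)
  assignments <- assign_group(assignments, tree, ref_groups)
  report <- census_report(assignments)

  structure(list(harvest_gtpase = h_g, harvest_mglb = h_b,
                 gtpase_ids = gtpase_ids, mglb_ids = mglb_ids,
                 couplings = couplings, context = context,
                 alignment = aln, tree = tree,
                 motifs = motifs, mechanisms = mechanisms,
                 insertions = insertions,
                 assignments = assignments, report = report),
            class = "census_run")
}

#' Score a pipeline run against the planted ground truth
#'
#' Recovery metrics for a [run_census_pipeline()] result on a
#' `synthetic_census`: harvest sensitivity/precision, family-label
#' accuracy, coupling-status accuracy, stoichiometry accuracy, group
#' recovery, and decoy-exclusion bookkeeping.
#'
#' @param run a `census_run`
#' @param census the `synthetic_census` it was run on
#' @return list of metrics (all fractions in [0, 1])
#' @export
evaluate_against_truth <- function(run, census) {
  truth <- census$truth
  planted <- truth[truth$family %in% c("MglA", "Rup") &
                     truth$decoy_class == "none", , drop = FALSE]
  planted_ids <- planted$protein_id
  cand <- run$gtpase_ids
  decoy_ids <- truth$protein_id[truth$decoy_class != "none"]

  ## harvest
  sens <- if (length(planted_ids) > 0L) {
    mean(planted_ids %in% cand)
  } else NA_real_
  allowed <- c(planted_ids, decoy_ids[truth$decoy_class[match(decoy_ids,
    truth$protein_id)] == "roco"])
  prec <- if (length(cand) > 0L) mean(cand %in% allowed) else NA_real_

  ## family accuracy over recovered planted GTPases
  asg <- run$assignments
  fam_of <- setNames(asg$family, asg$protein_id)
  rec <- intersect(planted_ids, asg$protein_id)
  family_acc <- if (length(rec) > 0L) {
    mean(fam_of[rec] == planted$family[match(rec, planted$protein_id)])
  } else NA_real_

  ## coupling status over recovered planted GTPases
  coupled_truth <- setNames(planted$coupled, planted$protein_id)
  coupled_call <- setNames(asg$coupled, asg$protein_id)
  coupling_acc <- if (length(rec) > 0L) {
    mean(coupled_call[rec] == coupled_truth[rec])
  } else NA_real_

  ## stoichiometry (1:1 vs 1:2) over recovered coupled GTPases
  st <- run$context$stoichiometry
  st_call <- setNames(st$class, st$gtpase)
  coup <- planted[planted$coupled, , drop = FALSE]
  rec_c <- intersect(coup$protein_id, names(st_call))
  stoich_acc <- if (length(rec_c) > 0L) {
    mean(st_call[rec_c] == coup$stoichiometry[match(rec_c, coup$protein_id)])
  } else NA_real_

  ## group recovery over recovered planted GTPases
  grp_call <- setNames(asg$group, asg$protein_id)
  group_acc <- if (length(rec) > 0L) {
    mean(grp_call[rec] == planted$group[match(rec, planted$protein_id)])
  } else NA_real_

  ## decoy handling
  small_set <- asg$protein_id[asg$small]
  excl <- run$harvest_gtpase$excluded
  reason_of <- setNames(excl$reason, excl$protein_id)
  abc_ids <- truth$protein_id[truth$decoy_class == "abc"]
  trunc_ids <- truth$protein_id[truth$decoy_class == "truncation"]
  roco_ids <- truth$protein_id[truth$decoy_class == "roco"]
  decoys_excluded_from_small <- !any(decoy_ids %in% small_set)
  abc_ledger_ok <- all(abc_ids %in% names(reason_of)) &&
    all(reason_of[abc_ids] == "decoy-architecture")
  trunc_ledger_ok <- all(trunc_ids %in% names(reason_of)) &&
    all(reason_of[trunc_ids] == "short")
  roco_flagged_not_small <- all(!(roco_ids %in% small_set))

  list(harvest_sensitivity = sens, harvest_precision = prec,
       family_accuracy = family_acc, coupling_accuracy = coupling_acc,
       stoichiometry_accuracy = stoich_acc, group_accuracy = group_acc,
       decoys_excluded_from_small = decoys_excluded_from_small,
       abc_ledger_ok = abc_ledger_ok, trunc_ledger_ok = trunc_ledger_ok,
       roco_flagged_not_small = roco_flagged_not_small,
       n_planted = length(planted_ids), n_candidates = length(cand))
}
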