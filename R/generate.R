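#' Simulation configuration for the synthetic census
#'
#' Defines the composition of the synthetic genome set: how many genomes,
#' how many GTPase systems of each planted group, the coupling-distance
#' distribution, orphan and 1:2-stoichiometry fractions, decoy counts and
#' the substitution rate of the simulated family histories.  Group counts
#' are totals across the whole genome set; systems are distributed
#' round-robin over genomes.
#'
#' @param n_genomes number of genomes (each a single replicon)
#' @param genes_per_replicon genes per replicon (every ordinal index 0..n-1
#'   is occupied; positions not used by planted systems carry filler genes)
#' @param replicon_topology `"circular"` or `"linear"`
#' @param mgla_g1,mgla_g2,mgla_g3,mgla_g4,mgla_g5 MglA system counts per group
#' @param rup_g1,rup_g2 Rup system counts per group
#' @param frac_orphan_gtpase fraction of each group's GTPases planted without
#'   an MglB partner (orphans, SofG-like)
#' @param frac_orphan_mglb orphan MglB count as a fraction of the coupled
#'   MglB count; orphan MglBs are placed at least 5 gene indices from any
#'   GTPase so orphanhood is unambiguous under the 4-gene window
#' @param frac_1to2_systems fraction of coupled MglA systems given a second
#'   MglB partner (1:2 MglA:MglB stoichiometry)
#' @param coupling_distance_weights weights over gene-index distances 1..4
#' @param n_decoy_abc,n_truncations,n_roco decoy counts (ABC-transporter-like
#'   architectures, <150 aa truncations, >240 aa Roco-like LRR proteins)
#' @param substitution_rate expected substitutions/site from family root to
#'   tip
#' @param frac_no_domain fraction of planted family members emitted without
#'   domain hits (emulating divergent members below the domain-model
#'   gathering threshold, recoverable only by similarity search)
#' @param seed mandatory integer master seed
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(n_genomes = 30L,
                              genes_per_replicon = 110L,
                              replicon_topology = c("circular", "linear"),
                              mgla_g1 = 40L, mgla_g2 = 30L, mgla_g3 = 30L,
                              mgla_g4 = 20L, mgla_g5 = 20L,
                              rup_g1 = 25L, rup_g2 = 15L,
                              frac_orphan_gtpase = 0.1,
                              frac_orphan_mglb = 0.15,
                              frac_1to2_systems = 0.15,
                              coupling_distance_weights = c(0.4, 0.3, 0.2, 0.1),
                              n_decoy_abc = 10L, n_truncations = 8L,
                              n_roco = 8L,
                              substitution_rate = 0.1,
                              frac_no_domain = 0.1,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  replicon_topology <- match.arg(replicon_topology)
  counts <- c(n_genomes = n_genomes, genes_per_replicon = genes_per_replicon,
              mgla_g1 = mgla_g1, mgla_g2 = mgla_g2, mgla_g3 = mgla_g3,
              mgla_g4 = mgla_g4, mgla_g5 = mgla_g5,
              rup_g1 = rup_g1, rup_g2 = rup_g2,
              n_decoy_abc = n_decoy_abc, n_truncations = n_truncations,
              n_roco = n_roco)
  if (any(counts < 0)) stop("all counts must be >= 0")
  fracs <- c(frac_orphan_gtpase, frac_orphan_mglb, frac_1to2_systems,
             frac_no_domain)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0, 1]")
  if (substitution_rate < 0) stop("substitution_rate must be >= 0")
  if (length(coupling_distance_weights) != 4L ||
      any(coupling_distance_weights < 0) ||
      sum(coupling_distance_weights) <= 0) {
    stop("coupling_distance_weights must be 4 non-negative weights over distances 1..4")
  }
  structure(list(
    n_genomes = as.integer(n_genomes),
    genes_per_replicon = as.integer(genes_per_replicon),
    replicon_topology = replicon_topology,
    group_counts = c(mgla_g1 = as.integer(mgla_g1), mgla_g2 = as.integer(mgla_g2),
                     mgla_g3 = as.integer(mgla_g3), mgla_g4 = as.integer(mgla_g4),
                     mgla_g5 = as.integer(mgla_g5),
                     rup_g1 = as.integer(rup_g1), rup_g2 = as.integer(rup_g2)),
    frac_orphan_gtpase = frac_orphan_gtpase,
    frac_orphan_mglb = frac_orphan_mglb,
    frac_1to2_systems = frac_1to2_systems,
    coupling_distance_weights = coupling_distance_weights / sum(coupling_distance_weights),
    n_decoy_abc = as.integer(n_decoy_abc),
    n_truncations = as.integer(n_truncations),
    n_roco = as.integer(n_roco),
    substitution_rate = substitution_rate,
    frac_no_domain = frac_no_domain,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a synthetic prokaryotic genome census with ground truth
#'
#' Plants MglA-family systems (five groups), Rup-family proteins (two
#' groups), coupled and orphan MglB (Roadblock/LC7) partners, 1:2
#' MglA:MglB systems, and three decoy classes into synthetic genomes, and
#' returns the per-genome gene tables, the proteome, synthetic domain-hit
#' annotations, the true family trees, and a ground-truth manifest covering
#' every emitted protein exactly once.  MglB partners of coupled systems
#' evolve along the same tree topology as their GTPases, so the planted
#' families are genuinely coevolved.  Deterministic for a fixed config.
#'
#' @param config a [simulation_config()]
#' @return an object of class `synthetic_census`: a list with elements
#'   `config`, `genes` (gene-table data.frame), `proteome` (named character
#'   vector of protein sequences), `truth` (manifest data.frame),
#'   `motif_offsets` (per-group motif start positions and widths),
#'   `domain_hits` (data.frame), `trees` (named character vector of Newick
#'   strings, including `coupled_mgla` / `coupled_mglb` combined trees) and
#'   `references` (data.frame of planted reference proteins per group)
#' @export
generate_census <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  templates <- default_templates()
  empty <- empty_census(config)
  if (config$n_genomes == 0L) return(empty)

  ## ---- realize group roots and evolve families -------------------------
  proteins <- list()   # keyed records, placement added later
  systems <- list()
  trees <- character(0)
  motif_offsets <- list()
  rate <- config$substitution_rate

  add_protein <- function(key, group, family, mechanism, decoy_class, seq,
                          role, system_id = NA_character_,
                          is_reference = FALSE, has_domain = TRUE) {
    proteins[[key]] <<- list(key = key, group = group, family = family,
                             mechanism = mechanism, decoy_class = decoy_class,
                             sequence = seq, role = role, system_id = system_id,
                             is_reference = is_reference,
                             has_domain = has_domain)
  }

  group_trees_mgla <- list()   # per MglA group: coupled-GTPase true subtree
  group_trees_mglb <- list()

  # hierarchical background pools: MglA and Rup group roots descend from a
  # common ancestral G-domain background, so the planted families are
  # genuinely homologous (seed searches recover both families, and the
  # GTPase tree shows within-family clades).  The pools are segmented by
  # homologous region (lead, inter-motif spacers, the G1-G2 insertion, tail)
  # so that group layouts with different spacer lengths stay in register.
  # MglB groups share their own Roadblock/LC7 pool.
  s_pools <- ancestral_segment_pools()
  a_pools <- lapply(s_pools, mutate_branch, b = 0.3, mask = NULL)  # MglA
  r_pools <- lapply(s_pools, mutate_branch, b = 0.3, mask = NULL)  # Rup
  b_pool <- sample_background(300L)            # MglB superfamily

  for (gname in names(config$group_counts)) {
    k <- config$group_counts[[gname]]
    if (k == 0L) next
    tmpl <- templates[[gname]]
    root <- realize_template(
      tmpl,
      background = build_background(
        tmpl, if (startsWith(gname, "mgla")) a_pools else r_pools),
      background_divergence = 0.25)
    motif_offsets[[gname]] <- list(
      offsets = root$offsets,
      widths = vapply(tmpl$parsed, length, 1L),
      spacing_g1_g2 = unname(root$offsets["g2"] - (root$offsets["g1"] +
        length(tmpl$parsed[["g1"]]) - 1L) - 1L),
      insertion = tmpl$g1_g2_insertion_length)
    fam <- evolve_family(root$sequence, k, rate = rate, mask = root$mask,
                         label_prefix = paste0(gname, "_"))
    ids <- names(fam$sequences)
    n_orphan <- if (tmpl$family == "MglA") round(config$frac_orphan_gtpase * k) else 0L
    orphan_ids <- utils::head(ids, n_orphan)
    coupled_ids <- setdiff(ids, orphan_ids)
    no_dom <- ids[seq_along(ids) %% max(1L, round(1 / max(config$frac_no_domain,
                                                          1e-9))) == 0L]
    if (config$frac_no_domain == 0) no_dom <- character(0)
    ref_id <- ids[length(ids)]   # last leaf: always domain-annotated reference
    no_dom <- setdiff(no_dom, ref_id)
    for (i in seq_along(ids)) {
      id <- ids[i]
      add_protein(id, tmpl$group, tmpl$family, tmpl$mechanism, "none",
                  fam$sequences[[id]], role = "gtpase", system_id = id,
                  is_reference = id == ref_id,
                  has_domain = !(id %in% no_dom))
    }
    trees[[paste0(gname, "_true")]] <- ape::write.tree(fam$tree)

    if (tmpl$family == "MglA") {
      ## coevolved MglB partners on the same (pruned) topology
      btmpl <- templates[[sub("mgla", "mglb", gname)]]
      broot <- realize_template(btmpl, background = b_pool,
                                background_divergence = 0.3)
      if (length(coupled_ids) >= 1L) {
        btree <- if (length(coupled_ids) >= 2L) {
          ape::keep.tip(fam$tree, coupled_ids)
        } else {
          star_tree(1L, rate)
        }
        bfam <- evolve_family(broot$sequence, btree, mask = broot$mask)
        # relabel partner leaves to match system ids
        partner_of <- setNames(paste0(sub("mgla", "mglb", gname), "_",
                                      seq_along(btree$tip.label)),
                               if (length(coupled_ids) >= 2L) btree$tip.label
                               else coupled_ids)
        names(bfam$sequences) <- unname(partner_of[
          if (length(coupled_ids) >= 2L) btree$tip.label else coupled_ids])
        n12 <- round(config$frac_1to2_systems * length(coupled_ids))
        twin_systems <- utils::head(sort(coupled_ids), n12)
        for (sid in coupled_ids) {
          pkey <- unname(partner_of[[sid]])
          add_protein(pkey, btmpl$group, "MglB", "none", "none",
                      bfam$sequences[[pkey]], role = "mglb", system_id = sid,
                      has_domain = TRUE)
          partners <- pkey
          if (sid %in% twin_systems) {
            p2 <- paste0(pkey, "b")
            seq2 <- paste(mutate_branch(strsplit(bfam$sequences[[pkey]], "")[[1]],
                                        rate * 0.3, broot$mask), collapse = "")
            add_protein(p2, btmpl$group, "MglB", "none", "none", seq2,
                        role = "mglb", system_id = sid, has_domain = TRUE)
            partners <- c(partners, p2)
          }
          systems[[sid]] <- list(system_id = sid, group = tmpl$group,
                                 type = "coupled", gtpase = sid,
                                 partners = partners)
        }
        # true MglB tree: partner topology with 1:2 twins as sister cherries
        bt <- bfam$tree
        bt$tip.label <- unname(partner_of[bt$tip.label])
        for (sid in twin_systems) {
          bt <- add_sister_tip(bt, unname(partner_of[[sid]]),
                               paste0(unname(partner_of[[sid]]), "b"),
                               eps = rate * 0.3)
        }
        group_trees_mglb[[gname]] <- bt
        group_trees_mgla[[gname]] <- if (length(coupled_ids) >= 2L) {
          ape::keep.tip(fam$tree, coupled_ids)
        } else NULL
      }
      for (sid in orphan_ids) {
        systems[[sid]] <- list(system_id = sid, group = tmpl$group,
                               type = "orphan_gtpase", gtpase = sid,
                               partners = character(0))
      }
    } else {
      for (sid in ids) {
        systems[[sid]] <- list(system_id = sid, group = tmpl$group,
                               type = "orphan_gtpase", gtpase = sid,
                               partners = character(0))
      }
    }
  }

  ## ---- orphan MglBs ----------------------------------------------------
  n_coupled_mglb <- sum(vapply(proteins, function(p) p$role == "mglb", TRUE))
  n_orphan_b <- round(config$frac_orphan_mglb * n_coupled_mglb)
  if (n_orphan_b > 0L) {
    btmpl <- templates$mglb_orphan
    broot <- realize_template(btmpl, background = b_pool,
                              background_divergence = 0.4)
    ofam <- evolve_family(broot$sequence, n_orphan_b, rate = rate,
                          mask = broot$mask, label_prefix = "mglb_orphan_")
    for (id in names(ofam$sequences)) {
      add_protein(id, "MglB_orphan", "MglB", "none", "none",
                  ofam$sequences[[id]], role = "orphan_mglb", system_id = id)
      systems[[id]] <- list(system_id = id, group = "MglB_orphan",
                            type = "orphan_mglb", gtpase = NA_character_,
                            partners = id)
    }
  }

  ## ---- decoys ----------------------------------------------------------
  decoy_plan <- c(rep("decoy_abc", config$n_decoy_abc),
                  rep("decoy_truncation", config$n_truncations),
                  rep("decoy_roco", config$n_roco))
  for (i in seq_along(decoy_plan)) {
    tname <- decoy_plan[i]
    tmpl <- templates[[tname]]
    real <- switch(tname,
      decoy_truncation = realize_template(
        tmpl, background = build_background(tmpl, a_pools),
        background_divergence = 0.25),
      decoy_roco = realize_template(
        tmpl, background = build_background(tmpl, r_pools),
        background_divergence = 0.25),
      realize_template(tmpl))
    key <- sprintf("%s_%02d", tname, i)
    add_protein(key, tmpl$group, tmpl$family, tmpl$mechanism,
                tmpl$decoy_class, real$sequence, role = "decoy",
                system_id = key)
    systems[[key]] <- list(system_id = key, group = tmpl$group,
                           type = "decoy", gtpase = NA_character_,
                           partners = character(0), decoy_key = key)
    if (tname == "decoy_truncation" && !("decoy_truncation" %in% names(motif_offsets))) {
      motif_offsets[["decoy_truncation"]] <- list(
        offsets = real$offsets,
        widths = vapply(tmpl$parsed, length, 1L),
        spacing_g1_g2 = unname(real$offsets["g2"] - (real$offsets["g1"] +
          length(tmpl$parsed[["g1"]]) - 1L) - 1L),
        insertion = tmpl$g1_g2_insertion_length)
    }
  }

  ## ---- placement -------------------------------------------------------
  placed <- place_systems(config, proteins, systems)
  genes <- placed$genes
  proteins <- placed$proteins
  systems <- placed$systems

  ## ---- combined true coupled trees ------------------------------------
  mgla_sub <- Filter(Negate(is.null), group_trees_mgla)
  if (length(mgla_sub) >= 1L) {
    trees[["coupled_mgla"]] <- join_trees(mgla_sub)
    trees[["coupled_mglb"]] <- join_trees(group_trees_mglb[names(mgla_sub)])
  }

  ## ---- manifest --------------------------------------------------------
  truth <- build_manifest(proteins, systems, genes)
  # the first MglB partner of each group's reference system is itself a
  # reference (the characterized GAP of a characterized GTPase)
  for (sid in truth$key[truth$is_reference & truth$family == "MglA" &
                          truth$coupled]) {
    pkey <- systems[[sid]]$partners[1L]
    truth$is_reference[truth$key == pkey] <- TRUE
  }
  domain_hits <- build_domain_hits(proteins, motif_offsets, truth)
  # tree leaves -> protein ids
  key2id <- setNames(truth$protein_id, truth$key)
  trees <- vapply(trees, function(nwk) relabel_newick(nwk, key2id), "")
  refs <- truth[truth$is_reference, c("protein_id", "family", "group")]
  rownames(refs) <- NULL
  structure(list(config = config, genes = genes,
                 proteome = setNames(truth$sequence, truth$protein_id),
                 truth = truth, motif_offsets = motif_offsets,
                 domain_hits = domain_hits, trees = trees,
                 references = refs),
            class = "synthetic_census")
}

# Segment pools for the ancestral G-domain background: one residue pool per
# homologous region of the canonical small-GTPase layout.
ancestral_segment_pools <- function() {
  list(lead = sample_background(20L),   # N-terminal lead, right-aligned at G1
       s1 = sample_background(30L),     # G1-G2 spacer (insertion-free part)
       ins = sample_background(15L),    # the bacterial-MglA G1-G2 insertion
       s2 = sample_background(20L),     # G2-G3 spacer
       s3 = sample_background(60L),     # G3-G4 spacer
       s4 = sample_background(25L),     # G4-G5 spacer
       tail = sample_background(60L))   # C-terminal tail
}

# Lay a template's background out of the segment pools so that homologous
# regions occupy the same pool residues across group layouts: leads are
# right-aligned at G1, spacers left-aligned at their upstream motif, the
# insertion drawn from its own pool just before G2, and the tail (or a
# truncated template's end) continued from the appropriate pool.  Regions
# with no ancestral counterpart (e.g. Roco LRR leads) stay random.
build_background <- function(template, pools) {
  n <- template$total_length
  bg <- sample_background(n)
  nm <- names(template$motifs)
  widths <- vapply(template$parsed, length, 1L)
  pos <- template$lead + 1L
  if (nm[1L] == "g1" && template$lead > 0L) {
    stopifnot(template$lead <= length(pools$lead))
    bg[seq_len(template$lead)] <- utils::tail(pools$lead, template$lead)
  }
  spacer_pool <- c(g1 = "s1", g2 = "s2", g3 = "s3", g4 = "s4")
  for (k in seq_along(nm)) {
    pos <- pos + widths[k]                       # skip the motif itself
    seg_len <- if (k < length(nm)) template$spacers[k] else
      n - pos + 1L                               # tail
    if (seg_len <= 0L) next
    key <- if (k < length(nm)) unname(spacer_pool[nm[k]])
           else if (nm[k] == "g5") "tail"
           else if (nm[k] == "g3") "s3"          # truncated layouts
           else NA_character_
    if (!is.na(key) && !is.null(pools[[key]])) {
      take <- min(seg_len, length(pools[[key]]))
      bg[pos:(pos + take - 1L)] <- pools[[key]][seq_len(take)]
    }
    if (k < length(nm)) {
      # the G1-G2 insertion sits at the end of the first spacer
      if (nm[k] == "g1" && template$g1_g2_insertion_length > 0L) {
        ins <- template$g1_g2_insertion_length
        stopifnot(ins <= length(pools$ins))
        bg[(pos + seg_len):(pos + seg_len + ins - 1L)] <-
          pools$ins[seq_len(ins)]
        pos <- pos + ins
      }
      pos <- pos + seg_len
    }
  }
  bg
}

empty_census <- function(config) {
  structure(list(config = config,
                 genes = empty_gene_table(),
                 proteome = setNames(character(0), character(0)),
                 truth = empty_manifest(),
                 motif_offsets = list(),
                 domain_hits = empty_domain_hits(),
                 trees = character(0),
                 references = data.frame(protein_id = character(0),
                                         family = character(0),
                                         group = character(0))),
            class = "synthetic_census")
}

# Attach a sister tip next to `tip` at distance eps (a cherry).
add_sister_tip <- function(phy, tip, new_label, eps) {
  i <- match(tip, phy$tip.label)
  if (is.na(i)) stop("tip not found: ", tip)
  if (length(phy$tip.label) == 1L) {
    return(ape::read.tree(text = sprintf("(%s:%g,%s:%g);", tip, eps,
                                         new_label, eps)))
  }
  cherry <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", "XPLACEHOLDERX",
                                          eps, new_label, eps))
  out <- ape::bind.tree(phy, cherry, where = i)
  out$tip.label[out$tip.label == "XPLACEHOLDERX"] <- tip
  out
}

# Join several phylo trees on a ladder backbone; returns Newick text.
join_trees <- function(tree_list) {
  sub <- vapply(tree_list, function(t) {
    txt <- ape::write.tree(t)
    sub(";$", "", txt)
  }, "")
  if (length(sub) == 1L) return(paste0(sub, ";"))
  acc <- sub[1L]
  for (i in 2:length(sub)) {
    acc <- sprintf("(%s:0.05,%s:0.05)", acc, sub[i])
  }
  paste0(acc, ";")
}

# Replace leaf labels in a Newick string via a named map (keys -> ids).
relabel_newick <- function(nwk, map) {
  phy <- ape::read.tree(text = nwk)
  hit <- phy$tip.label %in% names(map)
  phy$tip.label[hit] <- unname(map[phy$tip.label[hit]])
  ape::write.tree(phy)
}

FILLER_PRODUCTS <- c("hypothetical protein", "hypothetical protein",
                     "hypothetical protein", "hypothetical protein",
                     "histidine kinase", "PATAN-domain response regulator",
                     "diguanylate cyclase", "MFS transporter")

PRODUCT_BY_ROLE <- c(gtpase_MglA = "MglA-family small GTPase",
                     gtpase_Rup = "Rup-family small GTPase",
                     mglb = "MglB Roadblock/LC7 family protein",
                     orphan_mglb = "MglB Roadblock/LC7 family protein",
                     decoy_abc = "ABC transporter ATP-binding protein",
                     decoy_truncation = "GTPase fragment",
                     decoy_roco = "Roco-family LRR GTPase")

# Place system blocks on genomes (round-robin), fill remaining indices with
# filler genes, and return the gene table plus placement-annotated records.
place_systems <- function(config, proteins, systems) {
  sys_ids <- names(systems)
  n_gen <- config$n_genomes
  G <- config$genes_per_replicon
  genome_ids <- sprintf("GEN%03d", seq_len(n_gen))
  # fixed per-genome substreams: placing genome g is unaffected by later ones
  genome_seeds <- sample.int(.Machine$integer.max - 1L, n_gen)
  # round-robin assignment of systems to genomes (master stream order)
  assignment <- split(sys_ids, rep_len(seq_len(n_gen), length(sys_ids)))
  rows <- list()
  for (g in seq_len(n_gen)) {
    set.seed(genome_seeds[g])
    gid <- genome_ids[g]
    slots <- rep(NA_character_, G)       # protein key per index
    cursor <- sample(0:3, 1L)
    for (sid in assignment[[as.character(g)]] %||% character(0)) {
      sys <- systems[[sid]]
      if (sys$type == "coupled") {
        d1 <- sample(1:4, 1L, prob = config$coupling_distance_weights)
        dd <- c(d1)
        if (length(sys$partners) == 2L) {
          w <- config$coupling_distance_weights
          w[d1] <- 0
          dd <- c(d1, sample(1:4, 1L, prob = w))
        }
        width <- max(dd) + 1L
        if (cursor + width > G) stop_sizing(gid, G)
        slots[cursor + 1L] <- sys$gtpase
        for (j in seq_along(sys$partners)) {
          slots[cursor + 1L + dd[j]] <- sys$partners[j]
        }
        systems[[sid]]$distances <- dd
        systems[[sid]]$genome <- gid
      } else {
        key <- if (sys$type == "orphan_mglb") sys$partners[1L]
               else if (sys$type == "decoy") sys$decoy_key
               else sys$gtpase
        if (cursor + 1L > G) stop_sizing(gid, G)
        slots[cursor + 1L] <- key
        systems[[sid]]$distances <- integer(0)
        systems[[sid]]$genome <- gid
        width <- 1L
      }
      cursor <- cursor + width + 5L + sample(0:2, 1L)
    }
    # filler genes everywhere else
    fill_idx <- which(is.na(slots))
    fill_lens <- sample(60:140, length(fill_idx), replace = TRUE)
    fill_prod <- sample(FILLER_PRODUCTS, length(fill_idx), replace = TRUE)
    start <- 101L
    for (i in seq_len(G)) {
      idx <- i - 1L
      locus <- sprintf("ORF_%04d", i)
      if (is.na(slots[i])) {
        j <- match(i, fill_idx)
        key <- sprintf("%s_filler_%04d", gid, i)
        proteins[[key]] <- list(key = key, group = "none", family = "none",
                                mechanism = "none", decoy_class = "none",
                                sequence = paste(sample_background(fill_lens[j]),
                                                 collapse = ""),
                                role = "filler", system_id = NA_character_,
                                is_reference = FALSE, has_domain = FALSE)
        product <- fill_prod[j]
      } else {
        key <- slots[i]
        p <- proteins[[key]]
        product <- switch(p$role,
          gtpase = PRODUCT_BY_ROLE[[paste0("gtpase_", p$family)]],
          mglb = PRODUCT_BY_ROLE[["mglb"]],
          orphan_mglb = PRODUCT_BY_ROLE[["orphan_mglb"]],
          decoy = PRODUCT_BY_ROLE[[paste0("decoy_", p$decoy_class)]])
      }
      plen <- nchar(proteins[[key]]$sequence)
      nt <- 3L * (plen + 1L)
      proteins[[key]]$genome_id <- gid
      proteins[[key]]$locus_tag <- locus
      proteins[[key]]$gene_index <- idx
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = gid, replicon_id = paste0(gid, "_chr"),
        topology = config$replicon_topology, locus_tag = locus,
        gene_index = idx, start = start, end = start + nt - 1L,
        strand = sample(c("+", "-"), 1L), product = product,
        stringsAsFactors = FALSE)
      start <- start + nt + 80L
    }
  }
  genes <- do.call(rbind, rows)
  list(genes = genes, proteins = proteins, systems = systems)
}

stop_sizing <- function(gid, G) {
  stop(sprintf(paste0("sizing error: planted systems do not fit on %s ",
                      "(genes_per_replicon = %d); increase genes_per_replicon ",
                      "or reduce system counts"), gid, G))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_manifest <- function(proteins, systems, genes) {
  recs <- lapply(proteins, function(p) {
    sys <- if (!is.na(p$system_id)) systems[[p$system_id]] else NULL
    coupled <- FALSE
    partner_keys <- character(0)
    dists <- integer(0)
    if (!is.null(sys) && sys$type == "coupled") {
      coupled <- TRUE
      if (p$role == "gtpase") {
        partner_keys <- sys$partners
        dists <- sys$distances
      } else {
        partner_keys <- sys$gtpase
        dists <- sys$distances[match(p$key, sys$partners)]
      }
    }
    stoich <- if (!is.null(sys) && sys$type == "coupled") {
      paste0("1:", length(sys$partners))
    } else ""
    data.frame(
      key = p$key,
      protein_id = protein_id(p$genome_id, p$locus_tag),
      genome_id = p$genome_id, locus_tag = p$locus_tag,
      gene_index = p$gene_index,
      family = p$family, group = p$group, mechanism = p$mechanism,
      decoy_class = p$decoy_class, role = p$role,
      length = nchar(p$sequence), coupled = coupled,
      stoichiometry = stoich,
      partner_locus_tags = paste(vapply(partner_keys, function(k)
        proteins[[k]]$locus_tag, ""), collapse = ","),
      coupling_distances = paste(dists, collapse = ","),
      is_reference = p$is_reference, has_domain = p$has_domain,
      sequence = p$sequence,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$genome_id, out$gene_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_manifest <- function() {
  data.frame(key = character(0), protein_id = character(0),
             genome_id = character(0), locus_tag = character(0),
             gene_index = integer(0), family = character(0),
             group = character(0), mechanism = character(0),
             decoy_class = character(0), role = character(0),
             length = integer(0), coupled = logical(0),
             stoichiometry = character(0),
             partner_locus_tags = character(0),
             coupling_distances = character(0),
             is_reference = logical(0), has_domain = logical(0),
             sequence = character(0), stringsAsFactors = FALSE)
}

# Synthetic domain-hit table consistent with the planted truth.  ABC decoys
# carry a spurious (disjoint) Miro match in addition to their transporter
# domains, truncations a partial Ras match, Roco proteins LRR + Ras + COR.
build_domain_hits <- function(proteins, motif_offsets, truth) {
  id_of <- setNames(truth$protein_id, truth$key)
  hits <- list()
  add <- function(pid, dom, clan, from, to, score, evalue) {
    hits[[length(hits) + 1L]] <<- data.frame(
      protein_id = pid, domain_name = dom, clan_name = clan,
      ali_from = as.integer(from), ali_to = as.integer(to),
      bit_score = score, e_value = evalue, stringsAsFactors = FALSE)
  }
  for (p in proteins) {
    if (!p$has_domain) next
    pid <- id_of[[p$key]]
    len <- nchar(p$sequence)
    grp <- p$group
    if (p$role == "gtpase" && p$family == "MglA") {
      off <- motif_offsets[[tolower(sub("MglA_G", "mgla_g", grp))]]
      from <- max(1L, off$offsets[["g1"]] - 5L)
      to <- min(len, off$offsets[["g5"]] + off$widths[["g5"]] + 4L)
      add(pid, "Miro", "P-loop_NTPase", from, to, 180, 1e-40)
      add(pid, "Ras", "P-loop_NTPase", from + 3L, to - 10L, 120, 1e-25)
    } else if (p$role == "gtpase" && p$family == "Rup") {
      off <- motif_offsets[[tolower(sub("Rup_G", "rup_g", grp))]]
      from <- max(1L, off$offsets[["g1"]] - 4L)
      to <- min(len, off$offsets[["g5"]] + off$widths[["g5"]] + 4L)
      add(pid, "Ras", "P-loop_NTPase", from, to, 160, 1e-35)
      add(pid, "GTP_EFTU", "P-loop_NTPase", from + 2L, to - 5L, 90, 1e-15)
    } else if (p$role %in% c("mglb", "orphan_mglb")) {
      add(pid, "Robl_LC7", "Profilin-like", 10L, min(len, 120L), 140, 1e-30)
    } else if (p$decoy_class == "abc") {
      add(pid, "ABC_tran", "P-loop_NTPase", 1L, 150L, 250, 1e-60)
      add(pid, "AAA_21", "P-loop_NTPase", 20L, 140L, 200, 1e-45)
      add(pid, "Miro", "P-loop_NTPase", 160L, min(len, 300L), 60, 1e-8)
    } else if (p$decoy_class == "roco") {
      add(pid, "LRR_8", "LRR", 5L, 60L, 80, 1e-12)
      add(pid, "Ras", "P-loop_NTPase", 65L, min(len, 230L), 150, 1e-32)
      add(pid, "COR", "none", min(len - 10L, 240L), len, 90, 1e-16)
    } else if (p$decoy_class == "truncation") {
      add(pid, "Ras", "P-loop_NTPase", 10L, min(len, 110L), 70, 1e-10)
    }
  }
  if (length(hits) == 0L) return(empty_domain_hits())
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(0), domain_name = character(0),
             clan_name = character(0), ali_from = integer(0),
             ali_to = integer(0), bit_score = numeric(0),
             e_value = numeric(0), stringsAsFactors = FALSE)
}

#' True motif windows for planted proteins
#'
#' Reads the planted motif windows directly from the manifest sequences at
#' the template-recorded offsets (evolution preserves positions because no
#' indels are simulated).
#'
#' @param census a `synthetic_census`
#' @param ids protein ids (default: all planted GTPase-family members)
#' @return data.frame with one row per protein and one column per motif
#'   (`g1`..`g5`, `NA` when the template lacks the motif)
#' @export
truth_motif_windows <- function(census, ids = NULL) {
  truth <- census$truth
  sel <- truth[truth$group %in% c(paste0("MglA_G", 1:5), paste0("Rup_G", 1:2),
                                  "Roco_decoy", "Truncation_decoy"), ,
               drop = FALSE]
  if (!is.null(ids)) sel <- sel[sel$protein_id %in% ids, , drop = FALSE]
  grp_key <- c(MglA_G1 = "mgla_g1", MglA_G2 = "mgla_g2", MglA_G3 = "mgla_g3",
               MglA_G4 = "mgla_g4", MglA_G5 = "mgla_g5",
               Rup_G1 = "rup_g1", Rup_G2 = "rup_g2",
               Truncation_decoy = "decoy_truncation")
  out <- data.frame(protein_id = sel$protein_id, stringsAsFactors = FALSE)
  for (m in c("g1", "g2", "g3", "g4", "g5")) {
    out[[m]] <- vapply(seq_len(nrow(sel)), function(i) {
      key <- unname(grp_key[sel$group[i]])
      if (is.na(key) || is.null(census$motif_offsets[[key]])) return(NA_character_)
      off <- census$motif_offsets[[key]]
      if (!(m %in% names(off$offsets))) return(NA_character_)
      substr(sel$sequence[i], off$offsets[[m]],
             off$offsets[[m]] + off$widths[[m]] - 1L)
    }, "")
  }
  out
}
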