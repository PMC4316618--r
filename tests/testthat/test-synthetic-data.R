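test_that("an all-zero configuration yields an empty census", {
  cfg <- simulation_config(n_genomes = 0L, genes_per_replicon = 0L,
                           mgla_g1 = 0L, mgla_g2 = 0L, mgla_g3 = 0L,
                           mgla_g4 = 0L, mgla_g5 = 0L, rup_g1 = 0L,
                           rup_g2 = 0L, n_decoy_abc = 0L, n_truncations = 0L,
                           n_roco = 0L, seed = 1L)
  cen <- generate_census(cfg)
  expect_length(cen$proteome, 0L)
  expect_equal(nrow(cen$truth), 0L)
  expect_equal(nrow(cen$genes), 0L)
})

test_that("the generator is deterministic for a fixed seed and config", {
  c1 <- generate_census(small_config())
  c2 <- generate_census(small_config())
  expect_identical(c1, c2)
  # and byte-identical on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_census(c1, d1)
  write_census(c2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_gt(length(f1), 2L)
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(mgla_g1 = -1L, seed = 1L), "counts")
  expect_error(simulation_config(frac_orphan_mglb = 1.5, seed = 1L),
               "fractions")
  expect_error(simulation_config(substitution_rate = -0.1, seed = 1L),
               "substitution_rate")
  # planting more systems than gene slots is a sizing error
  expect_error(generate_census(simulation_config(
    n_genomes = 1L, genes_per_replicon = 10L, mgla_g1 = 10L, seed = 1L)),
    "sizing")
})

test_that("planted couplings sit at the configured gene-index distance", {
  cfg <- simulation_config(n_genomes = 3L, genes_per_replicon = 60L,
                           mgla_g1 = 5L, mgla_g2 = 0L, mgla_g3 = 0L,
                           mgla_g4 = 0L, mgla_g5 = 0L, rup_g1 = 0L,
                           rup_g2 = 0L, frac_orphan_gtpase = 0,
                           frac_1to2_systems = 0,
                           coupling_distance_weights = c(0, 1, 0, 0),
                           n_decoy_abc = 0L, n_truncations = 0L, n_roco = 0L,
                           seed = 7L)
  cen <- generate_census(cfg)
  coup <- cen$truth[cen$truth$family == "MglA", , drop = FALSE]
  expect_equal(nrow(coup), 5L)
  expect_true(all(coup$coupled))
  expect_true(all(coup$coupling_distances == "2"))
  # brute-force scan of the emitted gene table confirms the distances
  for (i in seq_len(nrow(coup))) {
    g <- cen$genes[cen$genes$genome_id == coup$genome_id[i], ]
    ia <- g$gene_index[g$locus_tag == coup$locus_tag[i]]
    ib <- g$gene_index[g$locus_tag == coup$partner_locus_tags[i]]
    expect_equal(abs(ia - ib), 2L)
  }
})

test_that("planted-distance fidelity holds for every coupling in a census", {
  cen <- small_census()
  truth <- cen$truth
  coup <- truth[truth$coupled & truth$role == "gtpase", , drop = FALSE]
  expect_gt(nrow(coup), 0L)
  for (i in seq_len(nrow(coup))) {
    g <- cen$genes[cen$genes$genome_id == coup$genome_id[i], ]
    n <- nrow(g)
    ia <- g$gene_index[g$locus_tag == coup$locus_tag[i]]
    partners <- strsplit(coup$partner_locus_tags[i], ",")[[1]]
    dists <- as.integer(strsplit(coup$coupling_distances[i], ",")[[1]])
    for (j in seq_along(partners)) {
      ib <- g$gene_index[g$locus_tag == partners[j]]
      raw <- abs(ia - ib)
      d <- if (g$topology[1] == "circular") min(raw, n - raw) else raw
      expect_equal(d, dists[j])
    }
  }
})

test_that("orphan MglBs have no GTPase within four genes", {
  cen <- small_census()
  truth <- cen$truth
  orphans <- truth[truth$role == "orphan_mglb", , drop = FALSE]
  gtp <- truth[truth$role == "gtpase", , drop = FALSE]
  expect_gt(nrow(orphans), 0L)
  for (i in seq_len(nrow(orphans))) {
    same <- gtp[gtp$genome_id == orphans$genome_id[i], , drop = FALSE]
    if (nrow(same) == 0L) next
    n <- sum(cen$genes$genome_id == orphans$genome_id[i])
    raw <- abs(same$gene_index - orphans$gene_index[i])
    d <- pmin(raw, n - raw)
    expect_true(all(d > 4L))
  }
})

test_that("manifest covers every emitted protein exactly once", {
  cen <- small_census()
  expect_equal(nrow(cen$truth), length(cen$proteome))
  expect_false(anyDuplicated(cen$truth$protein_id) > 0L)
  expect_setequal(cen$truth$protein_id, names(cen$proteome))
})

test_that("planted lengths respect the family bands", {
  cen <- small_census()
  truth <- cen$truth
  small_gtp <- truth[truth$family %in% c("MglA", "Rup") &
                       truth$decoy_class == "none", ]
  expect_true(all(small_gtp$length >= 150L & small_gtp$length <= 240L))
  mglb <- truth[truth$family == "MglB", ]
  expect_true(all(mglb$length >= 129L & mglb$length <= 179L))
  expect_true(all(truth$length[truth$decoy_class == "roco"] > 240L))
  expect_true(all(truth$length[truth$decoy_class == "truncation"] < 150L))
})

test_that("realized templates carry the group-specific motif signatures", {
  tmpl <- default_templates()
  set.seed(11)
  g1 <- realize_template(tmpl$mgla_g1)
  expect_identical(unname(g1$windows["g3"]), "TVPGQ")
  expect_match(g1$windows["g1"], "^G....GK[TS]$")
  expect_match(g1$windows["g2"], "TR$")
  g2 <- realize_template(tmpl$mgla_g2)
  expect_match(g2$windows["g4"], "^N.FD$")
  expect_identical(unname(g2$windows["g5"]), "DAR")
  rup1 <- realize_template(tmpl$rup_g1)
  expect_match(rup1$windows["g3"], "^DTAG[^Q]$")
  # 120 aa truncations lack at least one of G1-G5
  tr <- realize_template(tmpl$decoy_truncation)
  expect_false(all(c("g4", "g5") %in% names(tr$windows)))
  expect_equal(nchar(tr$sequence), 120L)
})

test_that("motifs plus spacers exceeding total_length is a sizing error", {
  expect_error(motif_template("bad", "Rup", "none",
                              list(g1 = "GxxxxGK[TS]", g2 = "xTx"),
                              lead = 50, spacers = c(100), total_length = 120),
               "exceed")
})

test_that("zero-rate evolution returns identical leaves", {
  set.seed(3)
  root <- random_protein(80)
  fam <- evolve_family(root, 5L, rate = 0)
  expect_true(all(fam$sequences == root))
  two <- evolve_family(root, 2L, rate = 0)
  s <- strsplit(two$sequences, "")
  expect_equal(mean(s[[1]] != s[[2]]), 0)
})

test_that("substitution counts follow the Poisson expectation on a star tree", {
  set.seed(17)
  rate <- 0.3
  root <- random_protein(300)
  fam <- evolve_family(root, "star", n_leaves = 8L, rate = rate)
  root_chars <- strsplit(root, "")[[1]]
  diffs <- vapply(fam$sequences, function(s)
    mean(strsplit(s, "")[[1]] != root_chars), 0)
  p_exp <- 1 - exp(-rate)
  se <- sqrt(p_exp * (1 - p_exp) / (8 * 300))
  expect_lt(abs(mean(diffs) - p_exp), 3 * se)
})

test_that("evolution never touches invariant motif positions", {
  set.seed(5)
  tmpl <- default_templates()$mgla_g1
  root <- realize_template(tmpl)
  fam <- evolve_family(root$sequence, 10L, rate = 0.5, mask = root$mask)
  fixed <- which(vapply(root$mask, function(m)
    !is.null(m) && length(m) == 1L, TRUE))
  root_chars <- strsplit(root$sequence, "")[[1]]
  for (s in fam$sequences) {
    expect_identical(strsplit(s, "")[[1]][fixed], root_chars[fixed])
  }
})
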