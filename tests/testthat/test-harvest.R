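test_that("architecture resolution handles empty and disjoint hit sets", {
  empty <- rasprok:::empty_domain_hits()
  arch <- resolve_architecture(empty)
  expect_equal(nrow(arch$kept), 0L)
  two <- data.frame(protein_id = "p", domain_name = c("B", "A"),
                    clan_name = NA, ali_from = c(50L, 1L),
                    ali_to = c(90L, 40L), bit_score = c(10, 200),
                    e_value = c(1e-3, 1e-30), stringsAsFactors = FALSE)
  arch <- resolve_architecture(two)
  expect_equal(arch$kept$domain_name, c("A", "B"))  # coordinate order
  expect_equal(nrow(arch$discarded), 0L)
})

test_that("greedy resolution matches the recursive elimination oracle", {
  set.seed(41)
  for (trial in 1:300) {
    hits <- random_hitset(sample(1:8, 1L))
    got <- resolve_architecture(hits)$kept
    want <- oracle_resolve(hits)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, names(want)], want)
  }
})

test_that("every discarded hit overlaps a kept hit of at least its score", {
  set.seed(43)
  for (trial in 1:50) {
    hits <- random_hitset(8)
    arch <- resolve_architecture(hits)
    for (i in seq_len(nrow(arch$discarded))) {
      d <- arch$discarded[i, ]
      over <- arch$kept[arch$kept$ali_from <= d$ali_to &
                          arch$kept$ali_to >= d$ali_from, ]
      expect_gt(nrow(over), 0L)
      expect_true(any(over$bit_score >= d$bit_score))
    }
  }
})

test_that("domain census counts equal a brute-force tally", {
  cen <- small_census()
  arch <- resolve_architectures(cen$domain_hits)
  seed <- cen$references$protein_id[cen$references$group == "MglA_G1"]
  hits <- search_all(cen$proteome[seed], cen$proteome, search_params())
  dc <- census_domains(hits, arch)
  # brute force
  subj <- unique(hits$subject_id)
  tally <- table(unlist(lapply(subj, function(s) {
    a <- arch[[s]]
    if (is.null(a)) character(0) else unique(a$kept$domain_name)
  })))
  for (i in seq_len(nrow(dc$table))) {
    expect_equal(dc$table$count[i],
                 as.integer(tally[[dc$table$domain_name[i]]]))
  }
  expect_true(all(diff(dc$table$count) <= 0))
  # subjects with no resolved domains are flagged, not silently dropped
  no_dom_truth <- cen$truth$protein_id[!cen$truth$has_domain &
                                         cen$truth$family == "MglA"]
  expect_true(all(no_dom_truth %in% dc$no_domain_subjects))
})

test_that("extract_region slices 1-based inclusive coordinates", {
  expect_equal(extract_region("MGDT", 1, 4), "MGDT")
  expect_equal(extract_region("MGDT", 2, 4), "GDT")
  expect_error(extract_region("MGDT", 0, 2), "out of range")
  expect_error(extract_region("MGDT", 3, 5), "out of range")
  set.seed(45)
  for (trial in 1:20) {
    s <- random_protein(50)
    a <- sample(1:50, 1)
    b <- a + sample.int(51 - a, 1) - 1L
    expect_equal(nchar(extract_region(s, a, b)), b - a + 1L)
  }
})

test_that("a proteome containing only the seed harvests only the seed", {
  set.seed(47)
  prot <- setNames(random_protein(180), "G1|ORF_0001")
  res <- iterative_collect(harvest_config(seeds = "G1|ORF_0001"), prot,
                           rasprok:::empty_domain_hits())
  expect_equal(res$candidates$protein_id, "G1|ORF_0001")
  expect_equal(res$candidates$provenance, "seed-hit")
  expect_error(iterative_collect(harvest_config(seeds = "missing"), prot,
                                 rasprok:::empty_domain_hits()),
               "configuration error")
})

test_that("harvest recovers planted families and excludes decoys with reasons", {
  cen <- small_census()
  truth <- cen$truth
  seed <- cen$references$protein_id[cen$references$group == "MglA_G1"]
  res <- iterative_collect(harvest_config(seeds = seed), cen$proteome,
                           cen$domain_hits)
  planted <- truth$protein_id[truth$family %in% c("MglA", "Rup") &
                                truth$decoy_class == "none"]
  expect_true(all(planted %in% res$candidates$protein_id))
  # every excluded id carries exactly one reason
  expect_false(anyDuplicated(res$excluded$protein_id) > 0L)
  expect_length(intersect(res$candidates$protein_id,
                          res$excluded$protein_id), 0L)
  reasons <- setNames(res$excluded$reason, res$excluded$protein_id)
  trunc <- truth$protein_id[truth$decoy_class == "truncation"]
  expect_true(all(trunc %in% names(reasons)))
  expect_true(all(reasons[trunc] == "short"))
  abc <- truth$protein_id[truth$decoy_class == "abc"]
  expect_true(all(abc %in% names(reasons)))
  expect_true(all(reasons[abc] == "decoy-architecture"))
  # Roco proteins are retained but flagged not-small
  roco <- truth$protein_id[truth$decoy_class == "roco"]
  cand <- res$candidates
  expect_true(all(roco %in% cand$protein_id))
  expect_true(all(!cand$small[cand$protein_id %in% roco]))
  # no candidate flagged small violates the length band
  expect_true(all(cand$length[cand$small] >= 150L &
                    cand$length[cand$small] <= 240L))
})

test_that("an extra expansion round never shrinks the candidate set", {
  cen <- small_census()
  seed <- cen$references$protein_id[cen$references$group == "MglA_G1"]
  r1 <- iterative_collect(harvest_config(seeds = seed, expansion_rounds = 1L),
                          cen$proteome, cen$domain_hits)
  r2 <- iterative_collect(harvest_config(seeds = seed, expansion_rounds = 2L),
                          cen$proteome, cen$domain_hits)
  expect_true(all(r1$candidates$protein_id %in% r2$candidates$protein_id))
})

test_that("ingested hit tables are interchangeable with the built-in search", {
  cen <- small_census()
  seed <- cen$references$protein_id[cen$references$group == "MglA_G1"]
  res_builtin <- iterative_collect(harvest_config(seeds = seed),
                                   cen$proteome, cen$domain_hits)
  # precompute every similarity query the harvest will issue, write to TSV,
  # read back, and rerun on the file-based hits
  arch <- resolve_architectures(cen$domain_hits)
  all_q <- cen$proteome[seed]
  members <- names(arch)[vapply(names(arch), function(id)
    any(arch[[id]]$kept$domain_name %in% res_builtin$selected_domains), TRUE)]
  regions <- rasprok:::expansion_queries(
    intersect(members, names(cen$proteome)), arch,
    res_builtin$selected_domains, cen$proteome, 16L)
  hits <- search_all(c(all_q, regions), cen$proteome, search_params())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_hits(hits, path)
  res_file <- iterative_collect(harvest_config(seeds = seed), cen$proteome,
                                cen$domain_hits,
                                similarity_hits = read_similarity_hits(path))
  expect_equal(res_file$candidates, res_builtin$candidates)
  expect_equal(res_file$excluded, res_builtin$excluded)
})

test_that("MglB harvest mode annotates the band without excluding", {
  cen <- small_census()
  bseed <- cen$references$protein_id[cen$references$family == "MglB"][1]
  res <- iterative_collect(harvest_config(seeds = bseed, mglb_mode = TRUE,
                                          n_collect_domains = 1L),
                           cen$proteome, cen$domain_hits)
  truth <- cen$truth
  mglb <- truth$protein_id[truth$family == "MglB"]
  expect_true(all(mglb %in% res$candidates$protein_id))
  expect_true(all(res$candidates$in_mglb_band[
    res$candidates$protein_id %in% mglb]))
  expect_equal(nrow(res$excluded), 0L)
})
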