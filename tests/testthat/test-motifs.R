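# A tiny hand-built alignment with a known reference layout:
# ref ungapped:  ABCDEFGHIJKLMNOPQRST (as arbitrary residues)
toy_map <- function() {
  motif_map("ref", list(g1 = c(3, 5), g2 = c(9, 10), g3 = c(14, 16)))
}

toy_alignment <- function() {
  c(ref = "MGARNDCQEGHILKMFPSTWY",   # 21 residues, no gaps
    s1  = "MGARNDCQEGHILKMFPSTWY",
    s2  = "MGARNDCQEGHILKMFPSTWY")
}

test_that("projection through an identical-sequence alignment reproduces the reference windows", {
  aln <- toy_alignment()
  ms <- project_motifs(aln, toy_map())
  expect_equal(ms$g1, rep(substr(aln[["ref"]], 3, 5), 3))
  expect_equal(ms$g2, rep(substr(aln[["ref"]], 9, 10), 3))
  expect_equal(ms$g1_start, rep(3L, 3))
})

test_that("a deletion spanning a window records the motif as absent, never empty", {
  aln <- c(ref = "MGARNDCQEGHILKMFPSTWY",
           del = "MGARNDCQEGHIL---PSTWY")   # gaps over columns 14-16
  ms <- project_motifs(aln, toy_map())
  expect_true(is.na(ms$g3[ms$protein_id == "del"]))
  expect_false(identical(ms$g3[ms$protein_id == "del"], ""))
  expect_equal(ms$g3[ms$protein_id == "ref"], "KMF")
})

test_that("projection is invariant to all-gap columns", {
  aln <- toy_alignment()
  spiked <- vapply(aln, function(s)
    paste0(substr(s, 1, 7), "---", substr(s, 8, nchar(s))), "")
  ms1 <- project_motifs(aln, toy_map())
  ms2 <- project_motifs(spiked, toy_map())
  expect_equal(ms1, ms2)
})

test_that("projection errors are informative", {
  aln <- toy_alignment()
  expect_error(project_motifs(aln[-1], toy_map()), "reference")
  bad_map <- motif_map("ref", list(g1 = c(30, 35)))
  expect_error(project_motifs(aln, bad_map), "outside reference")
  expect_error(motif_map("r", list(g1 = c(5, 3))), "from > to")
  expect_error(motif_map("r", list(g1 = c(1, 5), g2 = c(4, 8))),
               "non-overlapping")
})

test_that("profiles compute consensus, frequencies and information content", {
  prof <- motif_profile(rep("TVPGQ", 40))
  expect_equal(prof$consensus, "TVPGQ")
  expect_equal(rowSums(prof$freq), rep(1, 5))
  expect_equal(prof$information, rep(log2(20), 5))
  prof2 <- motif_profile(c(rep("GTPGQ", 10), NA))
  expect_equal(prof2$consensus, "GTPGQ")
  expect_equal(prof2$n_windows, 10L)
  expect_error(motif_profile(c(NA_character_, NA_character_)), "zero present")
})

test_that("uniform random windows give an all-x consensus with near-zero information", {
  set.seed(61)
  wins <- vapply(1:500, function(i) random_protein(5), "")
  prof <- motif_profile(wins)
  expect_equal(prof$consensus, "xxxxx")
  expect_lt(mean(prof$information), 0.3)
})

test_that("profiles are permutation-invariant in input order", {
  set.seed(63)
  wins <- vapply(1:50, function(i) random_protein(4), "")
  p1 <- motif_profile(wins)
  p2 <- motif_profile(sample(wins))
  expect_equal(p1$freq, p2$freq)
  expect_equal(p1$consensus, p2$consensus)
})

test_that("mechanism rules reproduce the characterized catalytic types", {
  ms <- data.frame(
    protein_id = c("mgla1", "mgla2", "rup2", "rup1", "odd"),
    g2 = c("STR", "ATT", "GTA", "CTD", "AAA"),
    g3 = c("TVPGQ", "GTPGQ", "DTAGQ", "DTAGT", "PPPPP"),
    g4 = c("NKDD", "NSFD", "NKAD", "NKLD", NA),
    g5 = c("SAK", "DAR", "SAL", "SAK", NA),
    stringsAsFactors = FALSE)
  calls <- call_mechanism(ms)
  expect_equal(calls$call, c("INTRINSIC_ARG", "G2THR_GTPGQ", "RAS_LIKE_Q",
                             "RAS_LIKE_NO_Q", "UNCALLED"))
  # evidence is non-empty unless UNCALLED
  expect_true(all(nzchar(calls$evidence[calls$call != "UNCALLED"])))
  # G4/G5 signatures are annotated as evidence
  expect_match(calls$evidence[2], "G4:NxFD")
  expect_match(calls$evidence[2], "G5:DAR")
  # absent windows propagate to UNCALLED, not errors
  calls_na <- call_mechanism(data.frame(protein_id = "x", g2 = NA_character_,
                                        g3 = NA_character_))
  expect_equal(calls_na$call, "UNCALLED")
})

test_that("mechanism calls on planted motif windows match the manifest exactly", {
  cen <- small_census()
  wins <- truth_motif_windows(cen)
  truth <- cen$truth
  planted <- truth[truth$family %in% c("MglA", "Rup") &
                     truth$decoy_class == "none", ]
  wins <- wins[wins$protein_id %in% planted$protein_id, ]
  calls <- call_mechanism(wins)
  want <- planted$mechanism[match(calls$protein_id, planted$protein_id)]
  expect_equal(calls$call, want)
})

test_that("insertion detection separates MglA from Rup layouts", {
  # equal spacing: zero insertion, flag false
  ms <- data.frame(protein_id = "a", g1 = "GAAAAGKT", g1_start = 13L,
                   g2 = "STR", g2_start = 45L, stringsAsFactors = FALSE)
  det <- detect_insertion(ms, reference_spacing = 24L)
  expect_equal(det$insertion_length, 0L)
  expect_false(det$insertion_present)
  # planted MglA group 1 members carry the 12-residue insertion
  cen <- small_census()
  aln_ids <- cen$truth$protein_id[cen$truth$group == "MglA_G1"]
  aln <- align_proteins(cen$proteome[aln_ids])
  map <- motif_map_from_truth(cen, "mgla_g1")
  ms2 <- project_motifs(aln, map)
  off <- cen$motif_offsets[["mgla_g1"]]
  base <- off$spacing_g1_g2 - off$insertion
  det2 <- detect_insertion(ms2, base)
  expect_true(all(det2$insertion_present))
  expect_true(all(det2$insertion_length == off$insertion))
  # Rup sequences do not carry the insertion; measured on the full
  # candidate alignment, where the G1/G2 columns are well anchored
  run <- small_run()
  det3 <- run$insertions
  rup_ids <- cen$truth$protein_id[cen$truth$family == "Rup"]
  rup_rows <- det3$protein_id %in% rup_ids
  expect_gt(sum(rup_rows), 0L)
  expect_true(all(!det3$insertion_present[rup_rows] |
                    is.na(det3$insertion_length[rup_rows])))
  # while MglA candidates carry it
  mgla_rows <- det3$protein_id %in%
    cen$truth$protein_id[cen$truth$family == "MglA"]
  expect_gt(mean(det3$insertion_present[mgla_rows]), 0.9)
})
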