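test_that("pairwise distances follow the Poisson-corrected closed form", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA")
  expect_equal(aln_distances(aln)["a", "b"], 0)
  # p = k/n  =>  d = -ln(1 - k/n), computed over shared ungapped columns
  set.seed(71)
  for (k in c(1, 3, 5)) {
    s <- strsplit(random_protein(20), "")[[1]]
    s2 <- s
    s2[1:k] <- vapply(s[1:k], function(r) setdiff(c("A", "R", "W"), r)[1], "")
    aln <- c(x = paste(s, collapse = ""), y = paste(s2, collapse = ""))
    expect_equal(aln_distances(aln)["x", "y"], -log(1 - k / 20))
  }
  # gapped columns are excluded from the comparison (brute-force recount)
  aln <- c(x = "AR-NDAAAAA", y = "ARW-DAAAAG")
  m <- do.call(rbind, strsplit(aln, ""))
  ok <- m[1, ] != "-" & m[2, ] != "-"
  p <- sum(m[1, ok] != m[2, ok]) / sum(ok)
  expect_equal(aln_distances(aln)["x", "y"], -log(1 - p))
  # saturated pairs cap with a warning
  sat <- c(x = paste(rep("A", 40), collapse = ""),
           y = paste(rep("R", 40), collapse = ""))
  expect_warning(d <- aln_distances(sat), "capped")
  expect_equal(d["x", "y"], -log(1 - 0.95))
  # zero comparable columns is an error
  expect_error(aln_distances(c(x = "A-", y = "-A")), "comparable")
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(73)
  for (trial in 1:10) {
    n <- sample(4:10, 1L)
    phy <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    dm <- ape::cophenetic.phylo(phy)
    got <- nj_tree(dm[phy$tip.label, phy$tip.label])
    expect_true(same_topology(got, phy))
    expect_equal(ape::cophenetic.phylo(got)[phy$tip.label, phy$tip.label],
                 dm, tolerance = 1e-9)
  }
})

test_that("three taxa resolve with closed-form branch lengths", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.4,
                 0.5, 0.4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(dm)
  bl <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(unname(bl["a"]), (0.3 + 0.5 - 0.4) / 2)
  expect_equal(unname(bl["b"]), (0.3 + 0.4 - 0.5) / 2)
  expect_equal(unname(bl["c"]), (0.5 + 0.4 - 0.3) / 2)
  expect_error(nj_tree(dm[1:2, 1:2]), ">= 3 taxa")
})

test_that("input order does not change the unrooted NJ topology", {
  set.seed(75)
  phy <- ape::rtree(8, br = function(k) stats::runif(k, 0.1, 1))
  dm <- ape::cophenetic.phylo(phy)
  perm <- sample(rownames(dm))
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_true(same_topology(t1, t2))
})

test_that("bootstrap consensus is deterministic and sane in the limits", {
  set.seed(77)
  aln <- setNames(vapply(1:5, function(i) random_protein(60), ""),
                  paste0("t", 1:5))
  # random unrelated sequences saturate some resampled pairs; the cap
  # warning is expected
  ts1 <- suppressWarnings(bootstrap_consensus(aln, n_replicates = 20L,
                                              seed = 5L))
  ts2 <- suppressWarnings(bootstrap_consensus(aln, n_replicates = 20L,
                                              seed = 5L))
  expect_identical(ts1, ts2)
  expect_identical(ape::write.tree(ts1$consensus),
                   ape::write.tree(ts2$consensus))
  expect_error(bootstrap_consensus(aln, 10L), "seed")
  # n = 1: consensus is that replicate's tree with full support
  one <- suppressWarnings(bootstrap_consensus(aln, n_replicates = 1L,
                                              seed = 9L))
  expect_true(same_topology(one$consensus, one$replicate_trees[[1]]))
  expect_true(all(one$supports == 1))
  # identical sequences: no resolvable signal, star consensus
  flat <- setNames(rep(random_protein(50), 4), paste0("t", 1:4))
  star <- bootstrap_consensus(flat, n_replicates = 10L, seed = 11L)
  expect_length(bipartitions(star$consensus), 0L)
})

test_that("well-separated planted clades receive high bootstrap support", {
  set.seed(79)
  rootA <- strsplit(random_protein(120), "")[[1]]
  rootB <- rootA
  flip <- sample(120, 60)
  rootB[flip] <- vapply(rootB[flip], function(r)
    sample(setdiff(rasprok:::AA20, r), 1), "")
  mutate <- function(root, k) {
    i <- sample(120, k)
    root[i] <- vapply(root[i], function(r)
      sample(setdiff(rasprok:::AA20, r), 1), "")
    paste(root, collapse = "")
  }
  aln <- c(a1 = mutate(rootA, 6), a2 = mutate(rootA, 6), a3 = mutate(rootA, 6),
           b1 = mutate(rootB, 6), b2 = mutate(rootB, 6), b3 = mutate(rootB, 6))
  ts <- bootstrap_consensus(aln, n_replicates = 100L, seed = 13L)
  splits <- bipartitions(ts$consensus)
  target <- sort(c("a1", "a2", "a3"))
  hit <- vapply(splits, function(s)
    identical(s, target) || identical(sort(setdiff(names(aln), s)), target),
    TRUE)
  expect_true(any(hit))
  expect_gte(ts$supports[which(hit)[1]], 0.95)
})

test_that("congruence is 1 for identical histories under a bijection and reroot-invariant", {
  set.seed(81)
  tg <- ape::rtree(12)
  tb <- tg
  tb$tip.label <- paste0("b_", tb$tip.label)
  pm <- setNames(as.list(paste0("b_", tg$tip.label)), tg$tip.label)
  cr <- congruence(tg, tb, pm)
  expect_equal(cr$fraction, 1)
  expect_equal(cr$n_bipartitions, length(bipartitions(tg)))
  # rerooting either tree changes nothing
  tg2 <- ape::root(tg, tg$tip.label[5], resolve.root = TRUE)
  tb2 <- ape::root(tb, tb$tip.label[9], resolve.root = TRUE)
  expect_equal(congruence(tg2, tb2, pm)$fraction, 1)
  expect_error(congruence(tg, tb, list()), "empty partner map")
})

test_that("permuted partner maps score near the shuffle null", {
  set.seed(83)
  tg <- ape::rtree(16)
  tb <- ape::rtree(16)
  tb$tip.label <- paste0("b_", sample(tg$tip.label))
  pm <- setNames(as.list(paste0("b_", tg$tip.label)), tg$tip.label)
  obs <- congruence(tg, tb, pm)$fraction
  null <- vapply(1:30, function(i) {
    shuf <- setNames(sample(pm), names(pm))
    congruence(tg, tb, shuf)$fraction
  }, 0)
  expect_lte(obs, max(null) + 0.16)   # obs is itself a draw from the null
  expect_lt(mean(null), 0.3)
  expect_lt(obs, 0.4)
})

test_that("planted coevolved families are congruent, shuffles are not", {
  cen <- small_census()
  tg <- ape::read.tree(text = cen$trees[["coupled_mgla"]])
  tb <- ape::read.tree(text = cen$trees[["coupled_mglb"]])
  pm <- truth_partner_map(cen)
  cr <- congruence(tg, tb, pm)
  expect_gte(cr$fraction, 0.9)
  # 1:2 systems record which partner sits in the coevolving clade
  two <- names(pm)[lengths(pm) == 2]
  if (length(two) > 0 && !is.null(cr$chosen_partners)) {
    expect_true(all(cr$chosen_partners$partner[
      cr$chosen_partners$gtpase %in% two] %in% unlist(pm[two])))
  }
  set.seed(85)
  shuf <- setNames(sample(pm), names(pm))
  expect_lt(congruence(tg, tb, shuf)$fraction, cr$fraction)
})
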