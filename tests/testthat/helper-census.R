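# Shared fixtures: a small planted census for fast module tests, and the
# default-size census (the study conditions) for end-to-end checks.  Both
# are generated once per test run and cached.

small_config <- function(seed = 101L, ...) {
  simulation_config(
    n_genomes = 6L, genes_per_replicon = 60L,
    mgla_g1 = 6L, mgla_g2 = 4L, mgla_g3 = 3L, mgla_g4 = 0L, mgla_g5 = 0L,
    rup_g1 = 4L, rup_g2 = 3L,
    n_decoy_abc = 2L, n_truncations = 2L, n_roco = 2L,
    seed = seed, ...)
}

small_census <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_census(small_config())
    cache
  }
})

default_census <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_census(simulation_config(seed = 2014L))
    cache
  }
})

small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_census_pipeline(small_census())
    cache
  }
})

default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_census_pipeline(default_census())
    cache
  }
})

# Partner map (GTPase protein id -> MglB protein ids) from a census manifest.
truth_partner_map <- function(census, family = "MglA") {
  truth <- census$truth
  coup <- truth[truth$family == family & truth$coupled, , drop = FALSE]
  pm <- lapply(seq_len(nrow(coup)), function(i) {
    lt <- strsplit(coup$partner_locus_tags[i], ",", fixed = TRUE)[[1]]
    protein_id(coup$genome_id[i], lt)
  })
  setNames(pm, coup$protein_id)
}

# Random protein sequence for search tests.
random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# Random gene table with marked GTPase/MglB genes, for coupling oracles.
random_gene_table <- function(n_genes, topology = c("linear", "circular"),
                              genome = "G1") {
  topology <- match.arg(topology)
  data.frame(genome_id = genome, replicon_id = paste0(genome, "_chr"),
             topology = topology,
             locus_tag = sprintf("ORF_%04d", seq_len(n_genes)),
             gene_index = seq_len(n_genes) - 1L,
             start = seq_len(n_genes) * 1000L - 999L,
             end = seq_len(n_genes) * 1000L - 400L,
             strand = sample(c("+", "-"), n_genes, replace = TRUE),
             product = "hypothetical protein",
             stringsAsFactors = FALSE)
}
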