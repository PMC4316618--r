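# Independent oracles shared by the module and acceptance tests.

# Recursive re-derivation of greedy domain-overlap resolution (highest score
# kept, overlapping hits eliminated), independent of the iterative
# implementation in the package.
oracle_resolve <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(-hits$bit_score, hits$e_value,
               -(hits$ali_to - hits$ali_from), hits$domain_name)
  best <- hits[ord[1L], , drop = FALSE]
  rest <- hits[-ord[1L], , drop = FALSE]
  ok <- rest$ali_to < best$ali_from | rest$ali_from > best$ali_to
  out <- rbind(best, oracle_resolve(rest[ok, , drop = FALSE]))
  out[order(out$ali_from), , drop = FALSE]
}

# Random domain-hit set with continuous scores (ties improbable).
random_hitset <- function(n, protein = "p1") {
  from <- sample(1:150, n, replace = TRUE)
  data.frame(protein_id = protein,
             domain_name = sample(paste0("D", 1:5), n, replace = TRUE),
             clan_name = NA_character_,
             ali_from = from,
             ali_to = from + sample(5:60, n, replace = TRUE),
             bit_score = round(stats::runif(n, 10, 300), 3),
             e_value = 10^(-stats::runif(n, 1, 50)),
             stringsAsFactors = FALSE)
}
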