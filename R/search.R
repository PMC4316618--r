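#' Similarity-search parameters
#'
#' Parameters for the desk-scale Smith-Waterman similarity search that fills
#' the role of a full BLASTP run.  E-values use the Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with fixed ungapped BLOSUM62 constants
#' (`lambda = 0.3176`, `K = 0.134`); this is a monotone surrogate for the
#' BLAST statistic, adequate for ranking and for the 1e-4 significance
#' cutoff semantics, not for BLAST parity.
#'
#' @param substitution_matrix name of a scoring matrix available in
#'   Biostrings (default `"BLOSUM62"`), or a 20x20 integer matrix
#' @param gap_open,gap_extend positive gap penalties
#' @param e_value_threshold significance cutoff (default 1e-4)
#' @param database_size total residues in the search database, used for
#'   e-value scaling; set automatically by [search_all()]
#' @return an object of class `search_params`
#' @export
search_params <- function(substitution_matrix = "BLOSUM62",
                          gap_open = 11, gap_extend = 1,
                          e_value_threshold = 1e-4,
                          database_size = 1e6) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  if (e_value_threshold <= 0) stop("e_value_threshold must be > 0")
  if (is.character(substitution_matrix)) {
    mat <- get_scoring_matrix(substitution_matrix)
  } else {
    mat <- substitution_matrix
  }
  structure(list(substitution_matrix = mat, gap_open = gap_open,
                 gap_extend = gap_extend,
                 e_value_threshold = e_value_threshold,
                 database_size = database_size,
                 lambda = 0.3176, K = 0.134),
            class = "search_params")
}

get_scoring_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  get(name, envir = env)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gap penalties.  Coordinates
#' are 1-based inclusive on the optimal path.
#'
#' @param query,subject protein sequences (character scalars)
#' @param params a [search_params()]
#' @return list with `score` (raw), `q_from`, `q_to`, `s_from`, `s_to`,
#'   `pct_identity`; an all-negative comparison yields score 0 and empty
#'   (NA) coordinates
#' @export
align_local <- function(query, subject, params = search_params()) {
  stopifnot(nchar(query) > 0L, nchar(subject) > 0L)
  check_protein_alphabet(c(q = query, s = subject))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(subject), Biostrings::AAString(query),
    type = "local", substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(score = 0, q_from = NA_integer_, q_to = NA_integer_,
                s_from = NA_integer_, s_to = NA_integer_,
                pct_identity = NA_real_))
  }
  list(score = sc,
       q_from = Biostrings::start(Biostrings::subject(aln)),
       q_to = Biostrings::end(Biostrings::subject(aln)),
       s_from = Biostrings::start(Biostrings::pattern(aln)),
       s_to = Biostrings::end(Biostrings::pattern(aln)),
       pct_identity = Biostrings::pid(aln))
}

#' Karlin-Altschul e-value surrogate
#'
#' `E = K * m * n * exp(-lambda * S)` with fixed ungapped BLOSUM62
#' constants; strictly decreasing in the raw score `S` and linear in the
#' database size.
#'
#' @param score raw alignment score (>= 0)
#' @param query_len query length `m` in residues
#' @param subject_len subject length; used as `n` only when
#'   `params$database_size` is `NULL`
#' @param params a [search_params()]
#' @return e-value (dimensionless)
#' @export
evalue <- function(score, query_len, subject_len, params = search_params()) {
  stopifnot(all(score >= 0))
  n <- if (is.null(params$database_size)) subject_len else params$database_size
  params$K * query_len * n * exp(-params$lambda * score)
}

#' Search queries against a protein database
#'
#' Smith-Waterman search of every query against every database sequence,
#' retaining hits with `e_value <= params$e_value_threshold`.  Self-hits are
#' retained (harvest logic deduplicates).  Output ordering is deterministic:
#' by query, then e-value, then subject id.
#'
#' @param queries named character vector of query sequences
#' @param database named character vector of database sequences
#' @param params a [search_params()]; `database_size` is overridden with the
#'   total residue count of `database`
#' @return similarity-hit data.frame (see [read_similarity_hits()])
#' @export
search_all <- function(queries, database, params = search_params()) {
  if (length(database) == 0L) stop("empty database")
  if (length(queries) == 0L) return(empty_similarity_hits())
  if (is.null(names(queries)) || is.null(names(database))) {
    stop("queries and database must be named")
  }
  check_protein_alphabet(queries)
  check_protein_alphabet(database)
  params$database_size <- sum(nchar(database))
  db_set <- Biostrings::AAStringSet(database)
  out <- vector("list", length(queries))
  for (qi in seq_along(queries)) {
    qseq <- queries[[qi]]
    scores <- Biostrings::pairwiseAlignment(
      db_set, Biostrings::AAString(qseq), type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
    ev <- evalue(pmax(scores, 0), nchar(qseq), nchar(database), params)
    keep <- which(ev <= params$e_value_threshold & scores > 0)
    if (length(keep) == 0L) next
    aln <- Biostrings::pairwiseAlignment(
      db_set[keep], Biostrings::AAString(qseq), type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    df <- data.frame(
      query_id = names(queries)[qi],
      subject_id = names(database)[keep],
      pct_identity = Biostrings::pid(aln),
      ali_length = Biostrings::nchar(aln),
      q_from = Biostrings::start(Biostrings::subject(aln)),
      q_to = Biostrings::end(Biostrings::subject(aln)),
      s_from = Biostrings::start(Biostrings::pattern(aln)),
      s_to = Biostrings::end(Biostrings::pattern(aln)),
      e_value = ev[keep],
      bit_score = scores[keep],
      stringsAsFactors = FALSE)
    df <- df[order(df$e_value, df$subject_id), , drop = FALSE]
    out[[qi]] <- df
  }
  res <- do.call(rbind, c(out[!vapply(out, is.null, TRUE)],
                          list(empty_similarity_hits())))
  rownames(res) <- NULL
  res
}
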