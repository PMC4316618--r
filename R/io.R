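#' @name io_formats
#' @title On-disk formats
#' @description Strict readers and writers for the formats the pipeline
#'   touches: gene tables (TSV), protein FASTA, similarity hits (12-column,
#'   outfmt-6 compatible), domain hits (domtblout-compatible columns), and
#'   single-tree Newick.  Readers reject malformed input rather than repair
#'   it; errors name the file and offending line where possible.
NULL

GENE_TABLE_COLS <- c("genome_id", "replicon_id", "topology", "locus_tag",
                     "gene_index", "start", "end", "strand", "product")

empty_gene_table <- function() {
  out <- data.frame(genome_id = character(0), replicon_id = character(0),
                    topology = character(0), locus_tag = character(0),
                    gene_index = integer(0), start = integer(0),
                    end = integer(0), strand = character(0),
                    product = character(0), stringsAsFactors = FALSE)
  out
}

#' Read a gene table
#'
#' Gene tables are TSV files with the exact header
#' `genome_id, replicon_id, topology, locus_tag, gene_index, start, end,
#' strand, product`.  `gene_index` is a 0-based ordinal per replicon and
#' must be consecutive; coordinates are 1-based inclusive.
#'
#' @param path file path
#' @return validated gene-table data.frame, grouped by genome and replicon,
#'   sorted by `gene_index`
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!identical(names(df), GENE_TABLE_COLS)) {
    stop(sprintf("%s: gene table header must be exactly: %s", path,
                 paste(GENE_TABLE_COLS, collapse = ", ")))
  }
  for (col in c("gene_index", "start", "end")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (nrow(df) > 0 && anyNA(v)) {
      stop(sprintf("%s: unparsable integer in column '%s' (line %d)", path,
                   col, which(is.na(v))[1L] + 1L))
    }
    df[[col]] <- v
  }
  validate_gene_table(df, path)
}

validate_gene_table <- function(df, source = "<gene table>") {
  if (nrow(df) == 0L) return(empty_gene_table())
  if (any(df$locus_tag == "")) stop(source, ": empty locus_tag")
  if (!all(df$topology %in% c("circular", "linear"))) {
    stop(source, ": topology must be 'circular' or 'linear'")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop(source, ": strand must be '+' or '-'")
  }
  if (any(df$start > df$end)) stop(source, ": start > end")
  dup <- duplicated(df[, c("genome_id", "locus_tag")])
  if (any(dup)) {
    stop(sprintf("%s: duplicate locus_tag '%s' in genome %s", source,
                 df$locus_tag[dup][1L], df$genome_id[dup][1L]))
  }
  df <- df[order(df$genome_id, df$replicon_id, df$gene_index), , drop = FALSE]
  for (rep_id in unique(df$replicon_id)) {
    idx <- df$gene_index[df$replicon_id == rep_id]
    if (!identical(idx, seq_along(idx) - 1L)) {
      stop(sprintf("%s: gene_index not consecutive from 0 on replicon %s",
                   source, rep_id))
    }
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_gene_table
#' @param genes gene-table data.frame
#' @export
write_gene_table <- function(genes, path) {
  genes <- validate_gene_table(genes)
  utils::write.table(genes[, GENE_TABLE_COLS, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path file path
#' @return named character vector (id -> uppercased sequence); duplicate ids
#'   and empty sequences are rejected
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop(sprintf("%s: duplicate FASTA id '%s'", path, ids[duplicated(ids)][1L]))
  }
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf("%s: empty sequence for id '%s'", path,
                 ids[nchar(seqs) == 0L][1L]))
  }
  setNames(seqs, ids)
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences
#' @param width line width for wrapping
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

SIMILARITY_COLS <- c("query_id", "subject_id", "pct_identity", "ali_length",
                     "q_from", "q_to", "s_from", "s_to", "e_value",
                     "bit_score")

#' Read a similarity-hit table (12-column, outfmt-6 compatible)
#'
#' Columns: `qseqid sseqid pident length qstart qend sstart send evalue
#' bitscore` plus two reserved columns (ignored on read, written as `.`).
#' Hits with negative e-values or inverted coordinates are rejected.
#'
#' @param path file path
#' @return data.frame of similarity hits
#' @export
read_similarity_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_similarity_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    stop(sprintf("%s: line %d has %d columns, expected 12", path,
                 which(nc != 12L)[1L], nc[nc != 12L][1L]))
  }
  m <- do.call(rbind, parts)
  df <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                   pct_identity = as_num(m[, 3L], path, "pident"),
                   ali_length = as_int(m[, 4L], path, "length"),
                   q_from = as_int(m[, 5L], path, "qstart"),
                   q_to = as_int(m[, 6L], path, "qend"),
                   s_from = as_int(m[, 7L], path, "sstart"),
                   s_to = as_int(m[, 8L], path, "send"),
                   e_value = as_num(m[, 9L], path, "evalue"),
                   bit_score = as_num(m[, 10L], path, "bitscore"),
                   stringsAsFactors = FALSE)
  validate_similarity_hits(df, path)
}

validate_similarity_hits <- function(df, source = "<similarity hits>") {
  if (any(df$e_value < 0)) stop(source, ": negative e_value")
  if (any(df$q_from > df$q_to) || any(df$s_from > df$s_to)) {
    stop(source, ": inverted alignment coordinates")
  }
  if (any(df$q_from < 1L) || any(df$s_from < 1L)) {
    stop(source, ": alignment coordinates must be 1-based")
  }
  df
}

empty_similarity_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), ali_length = integer(0),
             q_from = integer(0), q_to = integer(0), s_from = integer(0),
             s_to = integer(0), e_value = numeric(0), bit_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' @rdname read_similarity_hits
#' @param hits similarity-hit data.frame
#' @export
write_similarity_hits <- function(hits, path) {
  m <- cbind(hits$query_id, hits$subject_id,
             formatC(hits$pct_identity, format = "f", digits = 2),
             hits$ali_length, hits$q_from, hits$q_to, hits$s_from, hits$s_to,
             format(hits$e_value, digits = 6, scientific = TRUE),
             formatC(hits$bit_score, format = "f", digits = 1), ".", ".")
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

as_int <- function(x, path, col) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) stop(sprintf("%s: unparsable integer in column '%s'", path, col))
  v
}

as_num <- function(x, path, col) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) stop(sprintf("%s: unparsable number in column '%s'", path, col))
  v
}

#' Read a domain-hit table (domtblout-compatible)
#'
#' Accepts either the package's native 7-column TSV (header `protein_id,
#' domain_name, clan_name, ali_from, ali_to, bit_score, e_value`) or a
#' whitespace-separated HMMER domtblout file, from which only the target
#' name, query (domain) name, bit score, independent e-value and alignment
#' coordinates are consumed.
#'
#' @param path file path
#' @return data.frame of domain hits
#' @export
read_domain_hits <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && startsWith(first, "protein_id\t")) {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character")
    need <- c("protein_id", "domain_name", "clan_name", "ali_from", "ali_to",
              "bit_score", "e_value")
    if (!all(need %in% names(df))) {
      stop(path, ": native domain-hit table must have columns: ",
           paste(need, collapse = ", "))
    }
    out <- data.frame(protein_id = df$protein_id,
                      domain_name = df$domain_name,
                      clan_name = df$clan_name,
                      ali_from = as_int(df$ali_from, path, "ali_from"),
                      ali_to = as_int(df$ali_to, path, "ali_to"),
                      bit_score = as_num(df$bit_score, path, "bit_score"),
                      e_value = as_num(df$e_value, path, "e_value"),
                      stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) return(empty_domain_hits())
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    nc <- lengths(parts)
    if (any(nc < 23L)) {
      stop(sprintf("%s: line %d has %d fields; domtblout requires >= 23",
                   path, which(nc < 23L)[1L], nc[nc < 23L][1L]))
    }
    m <- do.call(rbind, lapply(parts, `[`, 1:23))
    # domtblout: 1 target, 4 query(domain), 8 full-seq score, 13 i-Evalue,
    # 14 dom score, 18-19 ali coords
    out <- data.frame(protein_id = m[, 1L], domain_name = m[, 4L],
                      clan_name = NA_character_,
                      ali_from = as_int(m[, 18L], path, "ali_from"),
                      ali_to = as_int(m[, 19L], path, "ali_to"),
                      bit_score = as_num(m[, 14L], path, "dom_score"),
                      e_value = as_num(m[, 13L], path, "i_evalue"),
                      stringsAsFactors = FALSE)
  }
  validate_domain_hits(out, path)
}

validate_domain_hits <- function(df, source = "<domain hits>") {
  if (any(df$e_value < 0)) stop(source, ": negative e_value")
  if (any(df$ali_from > df$ali_to)) stop(source, ": ali_from > ali_to")
  if (any(df$ali_from < 1L)) stop(source, ": coordinates must be 1-based")
  if (any(!is.finite(df$bit_score))) stop(source, ": non-finite bit_score")
  df
}

#' @rdname read_domain_hits
#' @param hits domain-hit data.frame
#' @export
write_domain_hits <- function(hits, path) {
  utils::write.table(hits[, c("protein_id", "domain_name", "clan_name",
                              "ali_from", "ali_to", "bit_score", "e_value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a single-tree Newick file
#'
#' @param path file path
#' @return an [ape::phylo] tree; duplicate leaf labels are rejected
#' @export
read_newick <- function(path) {
  phy <- tryCatch(ape::read.tree(path),
                  error = function(e) stop(path, ": ", conditionMessage(e)))
  if (is.null(phy)) stop(path, ": could not parse Newick tree")
  if (inherits(phy, "multiPhylo")) stop(path, ": multi-tree Newick not supported")
  if (anyDuplicated(phy$tip.label)) {
    stop(sprintf("%s: duplicate leaf label '%s'", path,
                 phy$tip.label[duplicated(phy$tip.label)][1L]))
  }
  phy
}

#' @rdname read_newick
#' @param tree an [ape::phylo] tree
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a synthetic census to a directory
#'
#' Emits one proteome FASTA per genome (headers `genomeID|locusTag`), the
#' combined gene table TSV, the domain-hit table, the ground-truth manifest
#' as JSON, and the true trees as Newick files.
#'
#' @param census a `synthetic_census` from [generate_census()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_census <- function(census, dir) {
  stopifnot(inherits(census, "synthetic_census"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_table(census$genes, file.path(dir, "genes.tsv"))
  for (gid in unique(census$truth$genome_id)) {
    ids <- census$truth$protein_id[census$truth$genome_id == gid]
    write_fasta(census$proteome[ids], file.path(dir, paste0(gid, ".faa")))
  }
  write_domain_hits(census$domain_hits, file.path(dir, "domain_hits.tsv"))
  manifest <- census$truth[, setdiff(names(census$truth), "sequence")]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (length(census$trees) > 0L) {
    dir.create(file.path(dir, "trees"), showWarnings = FALSE)
    for (nm in names(census$trees)) {
      writeLines(census$trees[[nm]], file.path(dir, "trees",
                                               paste0(nm, ".nwk")))
    }
  }
  invisible(dir)
}
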