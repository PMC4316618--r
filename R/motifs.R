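#' Motif coordinate map
#'
#' Anchors the G1-G5 motif windows (and optionally a core region used for
#' phylogenetics) to ungapped residue coordinates of a reference sequence.
#' Windows must be ordered, non-overlapping and inside the core range.
#'
#' @param reference_id id of the reference sequence (must appear in any
#'   alignment the map is projected through)
#' @param windows named list of `c(from, to)` 1-based inclusive residue
#'   ranges on the ungapped reference (e.g. `list(g1 = c(14, 21), ...)`)
#' @param core optional `c(from, to)` core range on the reference
#' @return object of class `motif_map`
#' @export
motif_map <- function(reference_id, windows, core = NULL) {
  stopifnot(length(windows) >= 1L, !is.null(names(windows)))
  froms <- vapply(windows, `[`, 0, 1L)
  tos <- vapply(windows, `[`, 0, 2L)
  if (any(froms > tos)) stop("motif window with from > to")
  ord <- order(froms)
  if (any(utils::head(tos[ord], -1L) >= froms[ord][-1L])) {
    stop("motif windows must be non-overlapping")
  }
  if (!is.null(core) && (any(froms < core[1L]) || any(tos > core[2L]))) {
    stop("motif windows must lie inside the core range")
  }
  structure(list(reference_id = reference_id,
                 windows = windows[ord], core = core),
            class = "motif_map")
}

#' Build a motif map from a synthetic census
#'
#' Uses the planted template offsets of a group's reference protein.
#'
#' @param census a `synthetic_census`
#' @param group_key template key (e.g. `"mgla_g1"`)
#' @return a [motif_map()] anchored at the group's reference protein
#' @export
motif_map_from_truth <- function(census, group_key) {
  off <- census$motif_offsets[[group_key]]
  if (is.null(off)) stop("no motif offsets recorded for ", group_key)
  grp <- gsub("mgla_g", "MglA_G", gsub("rup_g", "Rup_G", group_key))
  refs <- census$references
  ref <- refs$protein_id[refs$group == grp]
  if (length(ref) != 1L) stop("no unique reference for group ", grp)
  wins <- lapply(names(off$offsets), function(m)
    c(off$offsets[[m]], off$offsets[[m]] + off$widths[[m]] - 1L))
  names(wins) <- names(off$offsets)
  wins <- wins[names(wins) %in% c("g1", "g2", "g3", "g4", "g5")]
  motif_map(ref, wins)
}

# Map ungapped reference positions to alignment columns.
reference_columns <- function(ref_aligned) {
  chars <- strsplit(ref_aligned, "")[[1]]
  which(chars != "-")
}

#' Project motif windows through an alignment
#'
#' Maps each reference motif window to its alignment columns, then reads,
#' for every sequence, the ungapped residues in those columns.  A window in
#' which a sequence is more than 50% gap characters is recorded as absent
#' (`NA`), never as an empty string.  Per-sequence ungapped start offsets
#' are recorded so that G1-G2 insertion lengths can be measured.
#'
#' @param alignment named character vector of aligned sequences (equal
#'   lengths), including the reference
#' @param map a [motif_map()]
#' @param max_gap_frac gap fraction above which a window is absent
#' @return data.frame of class `motif_sets`: one row per sequence, columns
#'   `protein_id`, one column per motif window, and `<motif>_start` ungapped
#'   offsets (NA when absent)
#' @export
project_motifs <- function(alignment, map, max_gap_frac = 0.5) {
  stopifnot(inherits(map, "motif_map"))
  if (!(map$reference_id %in% names(alignment))) {
    stop("reference ", map$reference_id, " missing from alignment")
  }
  if (length(unique(nchar(alignment))) > 1L) {
    stop("aligned sequences have unequal lengths")
  }
  ref_cols <- reference_columns(alignment[[map$reference_id]])
  chars <- strsplit(alignment, "")
  ungapped_pos <- lapply(chars, function(x) cumsum(x != "-"))
  out <- data.frame(protein_id = names(alignment), stringsAsFactors = FALSE)
  for (m in names(map$windows)) {
    w <- map$windows[[m]]
    if (w[2L] > length(ref_cols)) {
      stop("map window '", m, "' outside reference length")
    }
    cols <- ref_cols[w[1L]:w[2L]]
    res <- vapply(seq_along(alignment), function(i) {
      cc <- chars[[i]][cols]
      if (mean(cc == "-") > max_gap_frac) return(NA_character_)
      paste(cc[cc != "-"], collapse = "")
    }, "")
    starts <- vapply(seq_along(alignment), function(i) {
      cc <- chars[[i]][cols]
      if (mean(cc == "-") > max_gap_frac) return(NA_integer_)
      ng <- which(cc != "-")
      if (length(ng) == 0L) return(NA_integer_)
      as.integer(ungapped_pos[[i]][cols[ng[1L]]])
    }, 1L)
    out[[m]] <- res
    out[[paste0(m, "_start")]] <- starts
  }
  class(out) <- c("motif_sets", class(out))
  out
}

#' Conservation profile of a motif window
#'
#' Per-column residue frequencies over the present (non-absent) windows,
#' with a consensus string and per-column information content.  Consensus
#' rule: the single residue with frequency >= `single_threshold`; otherwise
#' the smallest residue class jointly reaching `class_threshold` (written
#' `[..]`); otherwise `x`.
#'
#' @param windows character vector of motif window strings (NAs and windows
#'   whose length differs from the modal length are dropped)
#' @param single_threshold frequency for a single-letter consensus
#' @param class_threshold joint frequency for a class consensus
#' @return list of class `conservation_profile`: `freq` (L x 20 matrix),
#'   `consensus` (character scalar), `information` (bits per column),
#'   `n_windows`
#' @export
motif_profile <- function(windows, single_threshold = 0.5,
                          class_threshold = 0.8) {
  windows <- windows[!is.na(windows)]
  if (length(windows) == 0L) stop("zero present windows")
  len <- as.integer(names(sort(table(nchar(windows)), decreasing = TRUE))[1L])
  windows <- windows[nchar(windows) == len]
  m <- do.call(rbind, strsplit(windows, ""))
  freq <- t(apply(m, 2L, function(col) {
    tab <- table(factor(col, levels = AA20))
    as.numeric(tab) / length(col)
  }))
  colnames(freq) <- AA20
  rownames(freq) <- NULL
  consensus <- apply(freq, 1L, function(f) {
    best <- which.max(f)
    if (f[best] >= single_threshold) return(AA20[best])
    ord <- order(-f)
    cum <- cumsum(f[ord])
    k <- which(cum >= class_threshold)[1L]
    if (!is.na(k) && k <= 4L) {
      return(paste0("[", paste(AA20[ord][1:k], collapse = ""), "]"))
    }
    "x"
  })
  info <- apply(freq, 1L, function(f) {
    nz <- f[f > 0]
    log2(20) + sum(nz * log2(nz))
  })
  structure(list(freq = freq, consensus = paste(consensus, collapse = ""),
                 information = info, n_windows = length(windows)),
            class = "conservation_profile")
}

#' Position-frequency-matrix TSV for a conservation profile
#'
#' @param profile a `conservation_profile`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_profile <- function(profile, path) {
  df <- as.data.frame(profile$freq)
  df <- cbind(column = seq_len(nrow(df)), df,
              information = profile$information)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

MECHANISM_LEVELS <- c("INTRINSIC_ARG", "G2THR_GTPGQ", "RAS_LIKE_Q",
                      "RAS_LIKE_NO_Q", "UNCALLED")

#' Rule-based catalytic-mechanism call
#'
#' Applies the mechanism rules in order to each protein's G2/G3 windows:
#' 1. an arginine directly after the conserved G2 threonine together with a
#'    `TxPGQ` G3 - intrinsic arginine finger (MglA Group 1 type);
#' 2. a `GT..Q` G3 with a G2 threonine in place of the arginine - the
#'    shared Groups 2-5 mechanism;
#' 3. a `DxxGQ` G3 - eukaryote-like Ras mechanism with the catalytic
#'    glutamine (Rup Group 2 type);
#' 4. a `DxxG` G3 lacking the glutamine - Ras-like without the catalytic
#'    glutamine, presumably supplied in trans (Rup Group 1 type);
#' otherwise UNCALLED.  G4/G5 signatures (`[NT]KxD`, `NxFD`, `SA[KL]`,
#' `DAR`) are recorded as evidence only, never as call criteria.
#'
#' @param motif_sets a `motif_sets` data.frame from [project_motifs()] (or
#'   any data.frame with `protein_id` and `g1`..`g5` columns)
#' @return data.frame of class `mechanism_calls`: `protein_id`, `call`,
#'   `evidence` (semicolon-joined matched rules; empty only for UNCALLED)
#' @export
call_mechanism <- function(motif_sets) {
  need <- c("protein_id", "g2", "g3")
  if (!all(need %in% names(motif_sets))) {
    stop("motif_sets must have columns: ", paste(need, collapse = ", "))
  }
  n <- nrow(motif_sets)
  call <- character(n)
  evidence <- character(n)
  for (i in seq_len(n)) {
    g2 <- motif_sets$g2[i]
    g3 <- motif_sets$g3[i]
    g4 <- if ("g4" %in% names(motif_sets)) motif_sets$g4[i] else NA
    g5 <- if ("g5" %in% names(motif_sets)) motif_sets$g5[i] else NA
    ev <- character(0)
    has_g2 <- !is.na(g2)
    has_g3 <- !is.na(g3)
    arg_finger <- has_g2 && grepl("TR", g2, fixed = TRUE)
    thr_in_place <- has_g2 && grepl("T", g2, fixed = TRUE) &&
      !grepl("TR", g2, fixed = TRUE)
    if (arg_finger && has_g3 && grepl("^T.PGQ$", g3)) {
      call[i] <- "INTRINSIC_ARG"
      ev <- c(ev, "G2:arginine-adjacent-to-T", "G3:TxPGQ")
    } else if (has_g3 && grepl("^GT", g3) && grepl("Q$", g3) && thr_in_place) {
      call[i] <- "G2THR_GTPGQ"
      ev <- c(ev, "G2:threonine-in-place-of-R", "G3:GTPGQ-like")
    } else if (has_g3 && grepl("^D..GQ", g3)) {
      call[i] <- "RAS_LIKE_Q"
      ev <- c(ev, "G3:DxxGQ")
    } else if (has_g3 && grepl("^D..G", g3) &&
               (nchar(g3) < 5L || substr(g3, 5L, 5L) != "Q")) {
      call[i] <- "RAS_LIKE_NO_Q"
      ev <- c(ev, "G3:DxxG-no-Q")
    } else {
      call[i] <- "UNCALLED"
    }
    # annotations, never call criteria
    if (!is.na(g4) && grepl("^[NT]K.D$", g4)) ev <- c(ev, "G4:[NT]KxD")
    if (!is.na(g4) && grepl("^N.FD$", g4)) ev <- c(ev, "G4:NxFD")
    if (!is.na(g5) && grepl("^DAR", g5)) ev <- c(ev, "G5:DAR")
    if (!is.na(g5) && grepl("^SA[KL]", g5)) ev <- c(ev, "G5:SA[KL]")
    evidence[i] <- paste(ev, collapse = ";")
  }
  out <- data.frame(protein_id = motif_sets$protein_id, call = call,
                    evidence = evidence, stringsAsFactors = FALSE)
  class(out) <- c("mechanism_calls", class(out))
  out
}

#' Detect the G1-G2 insertion
#'
#' The bacterial MglA lineage carries an insertion between the G1 and G2
#' motifs that Rup (and archaeal/eukaryotic) sequences lack.  The insertion
#' length is the observed ungapped G1-to-G2 spacing minus the reference
#' spacing; the flag is raised at `min_length` or more extra residues.
#'
#' @param motif_sets a `motif_sets` data.frame with `g1`, `g1_start`, `g2`,
#'   `g2_start` columns
#' @param reference_spacing ungapped residue count between the end of G1
#'   and the start of G2 in the insertion-free reference layout
#' @param min_length minimum extra residues to flag (default 5)
#' @return data.frame: `protein_id`, `insertion_length` (NA when G1 or G2
#'   absent), `insertion_present`
#' @export
detect_insertion <- function(motif_sets, reference_spacing, min_length = 5L) {
  need <- c("g1", "g1_start", "g2", "g2_start")
  if (!all(need %in% names(motif_sets))) {
    stop("motif_sets must carry g1/g2 windows with start offsets")
  }
  spacing <- motif_sets$g2_start -
    (motif_sets$g1_start + nchar(motif_sets$g1) - 1L) - 1L
  len <- ifelse(is.na(motif_sets$g1) | is.na(motif_sets$g2), NA_integer_,
                as.integer(spacing - reference_spacing))
  data.frame(protein_id = motif_sets$protein_id,
             insertion_length = len,
             insertion_present = !is.na(len) & len >= min_length,
             stringsAsFactors = FALSE)
}
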