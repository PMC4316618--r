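#' Motif templates for synthetic protein families
#'
#' A motif template describes a protein family as a set of conserved sequence
#' motifs (with ambiguity classes) separated by background spacers.  The
#' G-motif notation follows the P-loop GTPase convention: a fixed capital
#' letter is invariant, `x` is any residue drawn from the background
#' frequency table, and `[TS]` is a uniform choice over the listed class.
#'
#' @param group group label (e.g. `"MglA_G1"`)
#' @param family family label: `"MglA"`, `"Rup"`, `"MglB"` or `"none"`
#' @param mechanism true catalytic-mechanism label planted for the group
#' @param motifs named list of motif consensus strings, in N- to C-terminal
#'   order (e.g. `list(g1 = "GxxxxGK[TS]", ...)`)
#' @param lead number of background residues before the first motif
#' @param spacers numeric vector of background spacer lengths between
#'   consecutive motifs (`length(motifs) - 1` values)
#' @param total_length realized protein length in residues
#' @param g1_g2_insertion_length extra residues inserted between the G1 and
#'   G2 motifs; `> 0` only for MglA-family templates (the bacterial MglA
#'   lineage carries a G1-G2 insertion absent from Rup and archaeal/eukaryote
#'   GTPases)
#' @param decoy_class one of `"none"`, `"abc"`, `"truncation"`, `"roco"`
#' @return an object of class `motif_template`
#' @export
motif_template <- function(group, family, mechanism, motifs, lead, spacers,
                           total_length, g1_g2_insertion_length = 0L,
                           decoy_class = "none") {
  stopifnot(length(motifs) >= 1L, length(spacers) == length(motifs) - 1L,
            total_length > 0L, lead >= 0L, all(spacers >= 0L),
            g1_g2_insertion_length >= 0L)
  if (g1_g2_insertion_length > 0L && family != "MglA") {
    stop("only MglA-family templates may carry a G1-G2 insertion")
  }
  parsed <- lapply(motifs, parse_motif_spec)
  widths <- vapply(parsed, length, 1L)
  ins <- if (length(motifs) >= 2L) g1_g2_insertion_length else 0L
  fixed <- lead + sum(widths) + sum(spacers) + ins
  if (fixed > total_length) {
    stop(sprintf("template '%s': motifs + spacers (%d) exceed total_length (%d)",
                 group, fixed, total_length))
  }
  structure(list(group = group, family = family, mechanism = mechanism,
                 motifs = motifs, parsed = parsed, lead = lead,
                 spacers = spacers, total_length = as.integer(total_length),
                 g1_g2_insertion_length = as.integer(g1_g2_insertion_length),
                 decoy_class = decoy_class),
            class = "motif_template")
}

# Parse a motif consensus string into a list of allowed-residue sets:
# NULL = any residue (background), length-1 = invariant, length>1 = class.
parse_motif_spec <- function(spec) {
  out <- list()
  i <- 1L
  n <- nchar(spec)
  while (i <= n) {
    ch <- substr(spec, i, i)
    if (ch == "x") {
      out[[length(out) + 1L]] <- NULL_SLOT
      i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(spec, i, n), fixed = TRUE)
      if (j < 0) stop("unbalanced '[' in motif spec: ", spec)
      cls <- strsplit(substr(spec, i + 1L, i + j - 2L), "")[[1]]
      cls <- setdiff(cls, "/")
      if (!all(cls %in% AA20)) stop("bad class in motif spec: ", spec)
      out[[length(out) + 1L]] <- cls
      i <- i + j
    } else if (ch %in% AA20) {
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("bad character '", ch, "' in motif spec: ", spec)
    }
  }
  out
}

# Sentinel for "any residue" slots (list() cannot hold NULL directly).
NULL_SLOT <- structure("ANY", class = "any_residue")

is_any_slot <- function(x) inherits(x, "any_residue")

#' Realize a protein sequence from a motif template
#'
#' Draws background residues for lead, spacer and tail positions from the
#' fixed background frequency table, realizes each motif position according
#' to its ambiguity class, and records where each motif landed.  Uses the
#' current R random-number stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param template a [motif_template()]
#' @param background optional character vector of residues (length >=
#'   `total_length`) supplying the background positions instead of fresh
#'   draws; used to give related families a shared ancestral background so
#'   they are detectably homologous
#' @param background_divergence expected substitutions/site applied to the
#'   supplied background (Poisson, as in [evolve_family()])
#' @return list with `sequence` (character scalar), `offsets` (named integer
#'   vector of 1-based motif start positions), `windows` (named character
#'   vector of realized motif strings), and `mask` (per-position allowed-set
#'   list used by [evolve_family()])
#' @export
realize_template <- function(template, background = NULL,
                             background_divergence = 0) {
  stopifnot(inherits(template, "motif_template"))
  widths <- vapply(template$parsed, length, 1L)
  nm <- length(template$parsed)
  spacers <- template$spacers
  # the G1-G2 insertion widens the first spacer
  if (nm >= 2L) spacers[1L] <- spacers[1L] + template$g1_g2_insertion_length
  tail_len <- template$total_length - template$lead - sum(widths) - sum(spacers)
  mask <- vector("list", template$total_length)
  offsets <- integer(nm)
  pos <- template$lead + 1L
  for (k in seq_len(nm)) {
    offsets[k] <- pos
    for (j in seq_len(widths[k])) {
      slot <- template$parsed[[k]][[j]]
      if (!is_any_slot(slot)) mask[[pos]] <- slot  # NULL slots stay free
      pos <- pos + 1L
    }
    if (k < nm) pos <- pos + spacers[k]
  }
  names(offsets) <- names(template$motifs)
  res <- character(template$total_length)
  free <- vapply(mask, is.null, TRUE)
  if (is.null(background)) {
    res[free] <- sample_background(sum(free))
  } else {
    if (length(background) < template$total_length) {
      stop("background pool shorter than total_length")
    }
    bg <- background[seq_len(template$total_length)]
    if (background_divergence > 0) {
      bg <- mutate_branch(bg, background_divergence, NULL)
    }
    res[free] <- bg[free]
  }
  for (i in which(!free)) {
    allowed <- mask[[i]]
    res[i] <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }
  windows <- vapply(seq_len(nm), function(k) {
    paste(res[offsets[k]:(offsets[k] + widths[k] - 1L)], collapse = "")
  }, "")
  names(windows) <- names(template$motifs)
  list(sequence = paste(res, collapse = ""), offsets = offsets,
       windows = windows, mask = mask)
}

#' Default family templates for the synthetic census
#'
#' The planted families mirror the observed group-specific motif signatures:
#' MglA Group 1 carries the intrinsic arginine finger adjacent to the G2
#' threonine and a `TVPGQ` G3; Groups 2-5 replace the arginine with a
#' threonine and share a `GTPGQ` G3; Group 2 carries the unusual `NxFD` G4
#' and (with Group 3) the `DAR` G5; Rup sequences are eukaryote-like
#' (`DxxG[Q]` G3, canonical `NKxD` G4) and lack the G1-G2 insertion, with
#' Group 1 missing the catalytic G3 glutamine.  MglB partners are
#' Roadblock/LC7-like with a conserved aspartate-glycine pair.  Decoys:
#' ABC-transporter-like Walker-motif proteins, MglA-like truncations that
#' lack the guanine-binding G4/G5 regions, and long Roco-like proteins with
#' N-terminal leucine-rich repeats.
#'
#' @return named list of [motif_template()] objects
#' @export
default_templates <- function() {
  g_motifs <- function(g2, g3, g4, g5) {
    list(g1 = "GxxxxGK[TS]", g2 = g2, g3 = g3, g4 = g4, g5 = g5)
  }
  mgla_spacers <- c(24, 14, 52, 18)
  rup_spacers <- c(20, 14, 50, 18)
  mglb_motifs <- function(b2) list(b1 = "LxV[IV]SxxG", b2 = b2)
  list(
    mgla_g1 = motif_template("MglA_G1", "MglA", "INTRINSIC_ARG",
      g_motifs("xTR", "TVPGQ", "[NT]KxD", "SA[KL]"),
      lead = 12, spacers = mgla_spacers, total_length = 195,
      g1_g2_insertion_length = 12),
    mgla_g2 = motif_template("MglA_G2", "MglA", "G2THR_GTPGQ",
      g_motifs("xTT", "GTPGQ", "NxFD", "DAR"),
      lead = 12, spacers = mgla_spacers, total_length = 176,
      g1_g2_insertion_length = 9),
    mgla_g3 = motif_template("MglA_G3", "MglA", "G2THR_GTPGQ",
      g_motifs("xTT", "GTPGQ", "NxxD", "DAR"),
      lead = 12, spacers = mgla_spacers, total_length = 185,
      g1_g2_insertion_length = 10),
    mgla_g4 = motif_template("MglA_G4", "MglA", "G2THR_GTPGQ",
      g_motifs("xTT", "GTPGQ", "[NT]KxD", "SA[KL]"),
      lead = 12, spacers = mgla_spacers, total_length = 180,
      g1_g2_insertion_length = 8),
    mgla_g5 = motif_template("MglA_G5", "MglA", "G2THR_GTPGQ",
      g_motifs("xTT", "GTPGQ", "[NT]KxD", "SA[KL]"),
      lead = 12, spacers = mgla_spacers, total_length = 188,
      g1_g2_insertion_length = 11),
    rup_g1 = motif_template("Rup_G1", "Rup", "RAS_LIKE_NO_Q",
      g_motifs("xTx", "DTAG[TSAE]", "NKxD", "SA[KL]"),
      lead = 10, spacers = rup_spacers, total_length = 170),
    rup_g2 = motif_template("Rup_G2", "Rup", "RAS_LIKE_Q",
      g_motifs("xTx", "DTAGQ", "NKxD", "SA[KL]"),
      lead = 10, spacers = rup_spacers, total_length = 165),
    mglb_g1 = motif_template("MglB_G1", "MglB", "none",
      mglb_motifs("DxxG"), lead = 16, spacers = c(60), total_length = 145),
    mglb_g2 = motif_template("MglB_G2", "MglB", "none",
      mglb_motifs("xxDG"), lead = 16, spacers = c(60), total_length = 150),
    mglb_g3 = motif_template("MglB_G3", "MglB", "none",
      mglb_motifs("xxDG"), lead = 16, spacers = c(60), total_length = 140),
    mglb_g4 = motif_template("MglB_G4", "MglB", "none",
      mglb_motifs("xxDG"), lead = 16, spacers = c(60), total_length = 148),
    mglb_g5 = motif_template("MglB_G5", "MglB", "none",
      mglb_motifs("xxDG"), lead = 16, spacers = c(60), total_length = 143),
    mglb_orphan = motif_template("MglB_orphan", "MglB", "none",
      mglb_motifs("xxDG"), lead = 16, spacers = c(60), total_length = 155),
    decoy_abc = motif_template("ABC_decoy", "none", "none",
      list(walker_a = "GxxGxGK[ST]", walker_b = "xxxxD[ED]"),
      lead = 40, spacers = c(120), total_length = 310,
      decoy_class = "abc"),
    decoy_roco = motif_template("Roco_decoy", "none", "RAS_LIKE_Q",
      list(lrr1 = "LxxLxLxxN", lrr2 = "LxxLxLxxN",
           g1 = "GxxxxGK[TS]", g2 = "xTx", g3 = "DTAGQ",
           g4 = "NKxD", g5 = "SA[KL]", cor = "WxxLxxxL"),
      lead = 10, spacers = c(6, 30, 20, 14, 50, 18, 25), total_length = 290,
      decoy_class = "roco"),
    decoy_truncation = motif_template("Truncation_decoy", "none", "none",
      list(g1 = "GxxxxGK[TS]", g2 = "xTT", g3 = "GTPGQ"),
      lead = 12, spacers = c(24, 14), total_length = 120,
      decoy_class = "truncation")
  )
}
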