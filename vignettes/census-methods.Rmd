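---
title: "Methods: the prokaryotic small-GTPase census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the prokaryotic small-GTPase census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rasprok)
```

## The procedure

`rasprok` implements a genome-scale census of small Ras-superfamily
GTPases (the MglA and Rup families) and their MglB (Roadblock/LC7) GAP
partners.  The procedure has five stages, each exposed as ordinary R
functions so that any stage can be replaced by externally computed inputs
(hit tables, alignments, trees).

**Harvesting.**  Starting from one or more seed proteins, candidates are
the union of (i) similarity hits of the seed at the significance cutoff,
(ii) every protein whose resolved domain architecture contains one of the
collection domains chosen from the domain-frequency census of the seed
hits, and (iii) similarity hits of the extracted domain regions of those
collection-domain members (the "expansion" pass, one round by default).
Domain architectures resolve overlaps greedily: the highest-scoring hit is
kept and every hit sharing at least one residue with it is discarded,
repeating until no hits remain.  Exclusions then apply, each with a single
recorded reason: architectures containing an ABC-transporter-like domain
(`ABC_tran`, `ABC_tran_2`, `AAA_21`) are decoys; sequences shorter than
150 aa are truncations that have lost conserved regions.  Sequences longer
than 240 aa are *flagged* not-small but retained, because long Roco-like
relatives are informative tree context even though they are excluded from
the small-GTPase census rows.  The MglB harvest reuses the same machinery
with the Roadblock/LC7 domain and no length exclusion (fusion proteins are
retained); the MglB band [129, 179] aa is reported as an annotation only.

**Genome context.**  A GTPase and an MglB are coupled when they are
encoded on the same replicon within four genes of each other, measured as
ordinal gene-index distance, strand-agnostic, with circular wrap-around
(`d = min(|i-j|, N - |i-j|)`).  We read "within four genes" as index
offset ≤ 4 (up to three intervening genes); the window is a parameter
because the phrase could also be read as intervening-gene count.  Each
GTPase is labeled by its partner count (1:1, 1:2, or 1:k verbatim);
GTPases and MglBs with no partner are orphans.  Couplings never cross
replicons.

**Motifs and mechanisms.**  G1–G5 windows are anchored on a reference
sequence (a `motif_map` of 1-based residue ranges) and projected through a
multiple alignment: a sequence's window is its ungapped residues in the
reference window's columns, recorded as *absent* when more than half the
columns are gaps — never guessed.  Mechanism rules apply in order:
an arginine immediately after the conserved G2 threonine together with a
`TxPGQ` G3 gives the intrinsic-arginine-finger call (MglA Group 1); a
`GT..Q` G3 with a G2 threonine in place of the arginine gives the shared
Groups 2–5 call; a `DxxGQ` G3 the eukaryote-like Ras call; a `DxxG` G3
without glutamine the Ras-like-without-Q call (Rup Group 1); otherwise
UNCALLED.  MglA-specific rules run first because the Ras-like patterns are
supersets.  G4/G5 signatures (`[NT]KxD`, `NxFD`, `SA[KL]`, `DAR`) are
recorded as evidence only.  The G1–G2 insertion diagnostic of bacterial
MglA is the observed ungapped G1-to-G2 spacing minus the insertion-free
reference spacing, flagged at ≥ 5 extra residues (default; the insertion
planted by the generator is 8–12 residues, well clear of alignment
jitter).  Conservation profiles use a 0.5 single-residue and 0.8
class-consensus threshold; these are conventional display choices with no
downstream effect on calls.

**Trees.**  Distances are Poisson-corrected p-distances over mutually
ungapped columns, `d = -ln(1 - p)`, capped at `d(0.95)` with a warning for
saturated pairs.  Trees are canonical neighbor joining; negative branch
lengths are clamped to zero, and zero-length internal edges are collapsed
into polytomies so that arbitrary resolutions of indistinguishable
sequences never contribute bipartitions (this is what makes the consensus
of identical sequences a star rather than an artifact of deterministic
tie-breaking).  Bootstrap resamples columns with replacement; the
consensus keeps exactly the bipartitions present in strictly more than
half the replicates, with the retention fraction as support.  The default
is 100 replicates — a deliberate scale-down of the conventional 1,000,
adequate for the synthetic data sizes used here; the count is a parameter.

**Coevolution congruence.**  Visual GTPase/GAP clade matching is
operationalized as: restrict both trees to mapped leaves; an internal
bipartition {S, S̄} of the GTPase tree *matches* when some bipartition
{T, T̄} of the MglB tree has at least one partner of every S-member inside
T and at least one partner of every non-member inside T̄; for 1:2 systems
the satisfying partner is recorded as the coevolving-clade choice.  The
congruence fraction is matched / total internal bipartitions.  It is a
defined artifact statistic (the source procedure was visual), invariant to
rerooting, equal to 1 for identical histories under a bijection, and near
zero under partner-map shuffles.

**Classification.**  On the midpoint-rooted candidate tree, a leaf is MglA
(or Rup) when it falls in the minimal clade containing all of that
family's reference leaves and none of the other's.  When the tree is
ambiguous for a leaf, a vote decides: coupling to MglB and a present G1–G2
insertion each count toward MglA, a Ras-like mechanism call toward Rup;
ties yield family `none` with evidence `ambiguous`.  Groups are maximal
reference-pure clades; members inherit the label, everything else is
`unclassified`.  Reference-anchored labeling replaces manual tree
inspection; on real data the references are user-supplied characterized
proteins, on synthetic data the planted group exemplars.  The "small" band
is 150–240 aa inclusive at both ends (following the textual "240 aa or
less" over the tabular "<240 aa" variant; the discrepancy is noted here
rather than resolved).

## The synthetic data generator

The generator is the package's test bed: it emulates the *composition*
the census must resolve, not real genomes.  Each protein family is a motif
template — fixed residues, ambiguity classes (`[T/S]`), and free
background positions drawn from a fixed amino-acid frequency table
(approximate average proteome composition, frozen for reproducibility).
Group templates carry the published signatures: `TVPGQ`/G2-arginine for
MglA Group 1, `GTPGQ`/G2-threonine for Groups 2–5, `NxFD` G4 and `DAR` G5
for Group 2 (Group 3 shares `DAR`), eukaryote-like `DxxG[Q]` motifs for
Rup with the glutamine absent in Group 1, and an 8–12 residue G1–G2
insertion in all (and only) MglA templates.  Lengths sit inside the
observed bands: MglA/Rup 165–195 aa, MglB 140–155 aa, truncations 120 aa,
Roco-like decoys 290 aa, ABC-like decoys 310 aa.

Families must be *homologous* for a similarity-driven census to work, so
group roots are not independent: background segments (lead, inter-motif
spacers, insertion, tail) derive from shared ancestral segment pools —
MglA and Rup ancestors each 0.3 expected substitutions/site from a common
pool, group roots 0.25 from their family ancestor, and members evolve
along a rescaled coalescent tree with root-to-tip depth
`substitution_rate` (default 0.1).  Segment-wise pooling keeps homologous
regions in register across layouts with different spacer lengths, which is
what lets MAFFT anchor the motif columns correctly.  Substitution is a
per-site Poisson process that respects the template mask: invariant motif
positions never change, class positions mutate within their class, free
positions over the other 19 residues.  MglB partners of each group's
coupled systems evolve along the *same* pruned tree topology as their
GTPases — the planted families are genuinely coevolved — and second
partners of 1:2 systems are grafted as short-branch sisters.

Placement puts each system on one replicon as a block: the GTPase, with
partners at distances drawn from the configured weight over 1..4, at least
five filler genes between blocks, so planted couplings are unambiguous and
orphan MglBs (placed ≥ 5 indices from any GTPase) are provably orphan
under the window-4 rule.  A fixed per-genome seed substream makes each
genome's layout independent of how many genomes follow it.  A configurable
fraction of planted members (default 0.1) is emitted *without* domain
hits, emulating divergent family members below the domain-model gathering
threshold — these are exactly the proteins the expansion search exists to
recover.  Decoys plant the documented failure modes: ABC-like proteins
carry a spurious (architecture-resolvable) Miro match, truncations are
MglA-like fragments below 150 aa, Roco-like proteins combine N-terminal
LRRs with a Rup-like G domain above 240 aa.

What the generator does **not** emulate: real domain-score distributions
(synthetic hits have stylized scores), insertions/deletions within
families (evolution is substitution-only, so motif offsets are exact in
the manifest), compositional bias and low-complexity tracts, horizontal
transfer, operon strandedness, and any taxonomic signal.  Passing tests
therefore demonstrate the correctness of the census *logic* — harvesting
set algebra, exclusion rules, window arithmetic, projection, tree and
congruence computations — under controlled divergence, not performance on
real proteomes, where alignment quality and domain-model sensitivity
dominate.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `e_value_threshold` | 1e−4 | similarity significance cutoff (dimensionless) |
| `min_length` / `max_length` | 150 / 240 aa | small-GTPase band; below = excluded truncation, above = flagged not-small |
| `window` | 4 genes | coupling window (ordinal index distance) |
| `expansion_rounds` | 1 | region-query re-search passes |
| `substitution_rate` | 0.1 subst/site | root-to-tip divergence of planted families |
| `n_replicates` | 100 | bootstrap replicates |
| `insertion min_length` | 5 aa | G1–G2 insertion flag threshold |

The similarity search is Smith–Waterman under BLOSUM62 (gap open 11,
extend 1) with a Karlin–Altschul e-value `E = K·m·n·exp(−λS)` using fixed
ungapped constants (λ = 0.3176, K = 0.134) and the database residue count
as `n`.  This is a monotone surrogate adequate for the cutoff semantics at
desk scale, not a BLAST replica; the threshold is configurable to
compensate, and externally computed outfmt-6 tables are interchangeable
with the built-in backend.

## Numerical and degenerate-input choices

Score ties in architecture resolution break by lower e-value, then longer
interval, then domain name, for determinism.  Search output orders by
query, e-value, then subject id.  An all-negative local alignment scores 0
with empty coordinates.  Distance computation errors on pairs with zero
comparable columns rather than imputing.  Readers reject malformed input
(duplicate ids, non-consecutive gene indices, inverted coordinates,
negative e-values) with file and line context instead of repairing.
Empty inputs propagate as empty results (empty census, empty report rows)
except where the operation is undefined (profiles of zero windows, NJ
below three taxa, congruence with an empty map), which are errors.

## Problem sizes

The default synthetic census — the package's study conditions — is 30
genomes × 110 genes (3,300 proteins), 180 GTPase systems across the seven
groups (MglA 40/30/30/20/20, Rup 25/15), 15% orphan MglB fraction, 15%
1:2 systems, coupling distances weighted 0.4/0.3/0.2/0.1 over 1..4, and
26 decoys.  The full pipeline on these sizes runs in about a minute;
module tests use a 6-genome census.  These sizes were chosen to exercise
every planted feature class with enough members per group for stable
clades while staying comfortable for routine test runs.

## Known limitations

Group assignment needs at least one reference per group present in the
tree; clades without references stay unclassified by design.  Family
assignment of the long Roco-like decoys can fall on either side of the
midpoint root depending on the realized tree (they are excluded from the
small census either way).  The congruence statistic conditions on the
partner map and does not test branch lengths.  The e-value surrogate is
not calibrated against BLAST bit scores; ingest real BLAST tables when
parity matters.
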