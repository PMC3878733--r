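---
title: "Methods: miRNA locus discovery, expression and degradome analysis in mirloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA locus discovery, expression and degradome analysis in mirloci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirloci)
```

This vignette documents the models and procedures implemented in
`mirloci`, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic benchmark
does and does not demonstrate about real data.

## The discovery model

Plant miRNA genes leave a characteristic footprint in small-RNA
libraries: two tight read clusters — the 5p and 3p mature products of
Dicer-like processing — separated by a short loop region, sitting on
genomic sequence that folds into a stable stem-loop. The pipeline
turns that footprint into an operational definition.

**Exact mapping.** Reads are placed on the genome with zero
mismatches, on both strands, via a k-mer index (`k = 12` by default; a
k below 8 is refused as unspecific, since a 12-mer seed plus full
verification is already minimal for 16-nt reads). Mismatch tolerance
exists only when matching reads against a reference mature set, where
0–2 mismatches accommodate cross-species homologs. Multi-mapping
reads are counted fully at every placement and carry an `n_hits`
annotation so unique placements can be distinguished downstream.

**Greedy count-ordered clustering.** Alignments are visited in
decreasing count order (ties broken by chromosome, start, strand,
sequence — the order must be total for the procedure to be
deterministic, and the tie-break is this package's choice). The first
read seeds a cluster whose coordinates are frozen at that read's
interval; each subsequent read joins the first existing cluster, in
creation order, whose window `[start − 3, end + 5]` on the same
strand fully contains it. "Contains" is full containment of the read
interval, matching the isomiR window semantics used later: the window
is asymmetric because 5′ ends of plant miRNAs are precise while 3′
ends wobble.

**Pairing and folding.** Ordered, non-overlapping cluster pairs on
one strand with an inner gap (upstream end to downstream start)
strictly below 150 nt become pre-miRNA candidates; the genomic span
of the pair is extracted (reverse-complemented on the minus strand; a
configurable flank defaults to 0 since the cluster pair itself is the
evidence for the precursor extent) and folded.

**Acceptance filters.** A candidate becomes a locus when all of the
following hold, and otherwise carries one reason code per failed
filter:

| filter | rule | default |
|---|---|---|
| `MFE` | minimum free energy of the candidate | ≤ −35 kcal/mol |
| `STEM` | count-weighted fraction of arm reads on the stems | ≥ 0.9 |
| `FIVE_PRIME` | count-weighted modal-5′ fraction, per arm | ≥ 0.5 |
| `FAMILY` | dominant 3p read within 2 mismatches of a reference mature | family mode only |

Two interpretation points deserve note. First, "reads on the stem" is
tested against the stem intervals *expanded by 5 nt* (`stem_slack`):
a genuine Dicer product legitimately carries up to +5 nt of templated
3′ variation past the paired region (the same window that assigns
isomiRs), and the 3p mature's own 2-nt 3′ overhang is unpaired by
definition, so a literal paired-bases-only test would reject real
loci. Loop-derived fragments still fail, because they sit fully
inside the terminal loop. Second, the 5′-homogeneity threshold
quantifies "little fluctuation around the 5′ start": it is computed
per arm as the count fraction sharing the modal 5′ position, both
arms must reach it, and the 0.5 default is this package's
quantification of an otherwise qualitative criterion, exposed as a
parameter.

A structure with more than one terminal loop (multiloop) or no pairs
fails `STEM` outright. When accepted candidates overlap — including
on *opposite* strands, which happens because the reverse complement
of a hairpin is itself a hairpin and antisense reads can nominate a
mirror candidate — the candidate carrying the read majority wins,
then the lower MFE.

**Homology expansion.** The mature 3p sequence of each accepted locus
is re-mapped exactly; around every additional placement a ±120 nt
window (configurable; sized generously for plant pre-miRNA lengths)
is folded, the putative precursor is trimmed
to the stem-loop spanning the mature and its pairing partner — the
window's random flanks are context, not precursor, and would
otherwise contribute spurious branches — and the placement is
accepted if that hairpin reaches the MFE threshold with the mature on
a stem. Gene copies sharing one mature sequence get one family name
with numeric suffixes.

## The folding engine

Folding is a pluggable contract: any `function(seq)` returning a
dot-bracket string and an MFE can be substituted, which decouples the
−35 kcal/mol acceptance rule from any one thermodynamic package. The
built-in engine (Rcpp) is a dynamic program over a nearest-neighbour
model:

* stacking free energies for the 36 ordered Watson–Crick/G:U pair
  stacks (values in `inst/extdata/nn_stack.tsv`, kcal/mol at 37 °C);
* hairpin, bulge and internal-loop penalties by loop length,
  tabulated to 30 nt and extrapolated as `E(30) + 1.75·RT·ln(n/30)`
  (`inst/extdata/nn_loops.tsv`);
* affine multiloop cost (3.4 kcal/mol per multiloop + 0.4 per branch,
  unpaired bases free);
* minimum hairpin loop 3, interior loops capped at 30 unpaired nt,
  no pseudoknots, no dangling-end terms, `N` unpairable.

The DP is exact for this model: the test suite checks it against
exhaustive enumeration of all secondary structures on every length-12
{G,C} sequence (274 structure skeletons, 4096 sequences). The engine
never reports a positive MFE because the open chain is always
available at zero. Dot-bracket output is produced by traceback with an
energy tolerance of 10⁻⁶ kcal/mol.

## Expression, isomiRs, degradome

**RPM** is count / total *input* reads × 10⁶. The denominator follows
the stated definition — all sequenced reads, not mapped reads — and
both totals are recorded so either normalisation can be derived.
Fold-changes divide RPM values; a zero denominator with a nonzero
numerator is reported as the flag `ON_OFF` rather than a pseudocount
ratio, because a locus silent in one library is qualitatively
different from a small ratio (no pseudocount is applied by default).
Both-zero is `UNDEFINED`. The arm ratio is 3p/5p counts, `NA` when
the 5p arm has no reads. No significance test is attached to
fold-changes: the design this models has one library per condition,
so replicate-aware inference is out of scope.

**IsomiR decomposition** anchors a read on the precursor inside the
[−3, +5] window and takes the *maximal templated prefix*: among all
admissible anchorings, the longest precursor-matching prefix wins and
the residue is the 3′ tail (≤ 3 nt). This is the conservative
convention — a base is only called non-templated when it cannot be
explained by the template — and every tail base is literally checked
against the template. Two disambiguation rules close the corner
cases: a mismatch on the read's final base is always treated as a
1-nt tail rather than a substitution (the two are indistinguishable,
and the tail reading is standard), and one internal substitution is
tolerated only when the tail is empty — allowing both at once would
let a late tail base coincide with the template and break the
non-templatedness invariant. Tails of all A are adenylated, all U
(= T in DNA space) uridylated, anything else mixed.

**Alternative duplexes** are searched among the observed 5′-start
modes on each arm: any arm pairing whose duplex shows exactly 2-nt 3′
overhangs on both strands (projected through the folded helix across
bulges) is reported alongside the canonical pair.

**Target scoring** is an Allen-style plant complementarity score:
mismatch 1.0, G:U 0.5, gap 2.0, all doubled at miRNA
positions 2–13, at most one bulge on either strand, cutoff 3.0, all
configurable. The production scanner is a vectorised shifted-lookup
formulation of the same model; the per-window reference scorer and an
exhaustive-enumeration oracle pin both down in the tests.
**Cleavage calls** anchor degradome tags by exact 20-nt prefix match
(the MmeI tag length), pile up 5′ ends inside each site, and convert
the modal position via: transcript base `t` in a gapless site
`[s, s+m)` pairs miRNA position `s + m − t`, so a fragment starting
at the base paired with position 10 is the canonical 10/11 cut. A
modal count compatible with a uniform pileup across the site
(one-sided binomial tail, Bonferroni-corrected by site length,
p ≥ 0.05) is flagged low-confidence — the decision rule is this
package's own.

## The synthetic benchmark

`sim_config()` defaults define the benchmark study: 12 planted
hairpin loci and 8 decoys in ~13 kb of genome, two conditions (A =
induced, B = control). The design mirrors the features the pipeline
must handle: one locus expressed ~6-fold higher in A; one on/off
locus (145 expected reads in A, none in B); one passenger-dominant
locus (5p/3p mean counts 20/4); two gene copies of one mature
sequence ~2000 nt apart; three minus-strand loci; per-read 1-nt
adenylation/uridylation at 4 %/6 %; antisense reads at 5 %;
loop-derived 16–19 nt fragments at 2 %; 70 % canonical read ends with
5′ offsets concentrated at 0 (plant Dicer cuts the 5′ end precisely;
3′ ends carry most of the variation) and all offsets inside [−3, +5].
Counts are Poisson around the configured means — the simplest noise
model consistent with library sampling — and all randomness flows
through R's default Mersenne–Twister generator, so outputs are
byte-identical for a fixed seed.

Construction details that matter:

* hairpins are arm + A/C-only loop (18–24 nt, unpairable with itself,
  so the terminal loop stays single-stranded for loop reads) +
  reverse-complement arm with up to two designed G:U wobbles — real
  duplexes are imperfect, and a perfect inverted repeat would make
  arm reads strand-ambiguous to any exact mapper; 2-nt extensions
  outside the paired arms give the mature duplex its canonical 2-nt
  3′ overhangs;
* each hairpin is accepted at design time only if the region the
  pipeline will actually extract folds to ≤ −38 kcal/mol with a
  single ≥ 16-nt terminal loop — a 3 kcal/mol margin below the
  acceptance threshold so that small cluster-coordinate jitter from
  isomiR sampling cannot flip a planted locus across the cutoff;
* decoys are AT-rich (non-folding) regions carrying two read sites
  < 150 nt apart with 5′ ends fluctuating uniformly over 6 offsets;
* a weighted background of ~50,000 unmappable reads per library (200
  distinct sequences) emulates the non-miRNA bulk of real libraries,
  which keeps RPM denominators comparable between conditions — without
  it, fold-changes in RPM space would be distorted by the miRNA
  induction itself;
* degradome tags are 20-nt transcript suffixes, 80 % starting at the
  nucleotide paired with miRNA position 10, the rest uniform; the
  multi-site transcript carries five sites of one miRNA with only
  sites 2 and 5 cleaved.

The generator's manifest (coordinates, arms, matures, designed MFE,
per-class emission tallies) suffices to compute every downstream
expectation without re-reading the FASTA outputs.

**What passing the benchmark shows — and what it does not.** Recovery
of 12/12 planted loci with 0 decoys demonstrates that the clustering
geometry, window semantics, folding threshold and filter cascade
compose correctly, and the 3-binomial-SD recovery of planted NTA,
offset, antisense and cleavage fractions shows the quantification is
unbiased at realistic depths. The generator does not simulate
sequencing errors, adapter artifacts, quality scores, repeat-induced
multi-mapping beyond designed gene copies, or RNA degradation
background, so performance on real libraries — where the 5′-homogeneity
and stem thresholds meet messier signals — is not certified by these
tests. With the study-like expression means, the sparsest arms carry
~4–5 expected reads (deliberately: real studies report loci at
exactly this depth); at some seeds a Poisson zero-draw can leave an
arm empty and its locus undiscoverable, which is a property of the
sampling, not the algorithm. The shipped fixture seed (1) recovers
all twelve.

## Problem sizes and degenerate inputs

The test suite and acceptance script run the full benchmark (~2,500
mapped reads per library over ~13 kb, plus a 20,000-read single-locus
library for fraction recovery and 4,096 exhaustive folding cases);
these sizes were chosen to put every expectation at least three
standard deviations from its decision boundary while keeping a full
run in minutes on one core. Degenerate inputs are defined: empty read
tables run cleanly to an empty result with a warning; an unpairable
sequence folds to MFE 0 with no structure; clusters of a single read
are legal; reference matching refuses an empty reference set;
sequences with more than 5 % ambiguous bases are refused by the
folder; zero library totals are an error rather than an NaN factory.
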