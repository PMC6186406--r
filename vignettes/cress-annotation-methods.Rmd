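---
title: "Annotating and classifying CRESS DNA virus genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and classifying CRESS DNA virus genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cressannot)
```

## The biological problem

Circular Rep-encoding single-stranded DNA (CRESS DNA) viruses are among the
smallest eukaryotic viruses: covalently closed circles, typically under
3.5 kb, encoding one to three major proteins. Two features make them
computationally tractable. First, replication initiates by a rolling-circle
mechanism at a conserved origin (*ori*): a nonanucleotide motif — canonically
`NANTATTAC` — exposed in the loop of a hairpin (stem-loop) structure. Second,
the replication-associated protein (Rep) combines an HUH endonuclease domain
carrying the rolling-circle replication motifs I–III with a superfamily-3
helicase domain carrying Walker-A, Walker-B, Motif C and an arginine finger,
always in that N- to C-terminal order. A genome with a Rep but no
identifiable capsid ORF is a "circular molecule" (replicon), not a bona fide
virus.

Taxonomy in this group is demarcated by pairwise identity (PI): the fraction
of identical columns in a global pairwise alignment. Each established family
has an observed genome-wide PI floor among its members and a species
demarcation threshold (e.g. Circoviridae: 55% floor, 80% species;
Genomoviridae: 53% / 78%; Smacoviridae: 55% / 77%, with genus assignment
additionally requiring 40% Rep amino-acid PI; Bacilladnaviridae species are
demarcated at 75% Rep amino-acid PI instead of genome-wide PI). Genomes below
80% versus everything known are new species or entirely novel; genomes below
70% versus everything known cannot be assigned to an existing group at all.

`cressannot` implements this annotation and classification procedure as a
reusable, fully testable pipeline: ORF discovery on circles, ori detection,
Rep identification by motif quorum, capsid calling by intrinsic-disorder
profile, circular-aware SDT-style PI computation, the demarcation cascade,
two-stage greedy clustering, and the Rep-alignment preparation steps used for
phylogenetics (motif-anchored trimming, neighbour joining, support-threshold
branch collapsing). A synthetic-genome generator with a full ground-truth
channel makes every stage verifiable without downloading anything.

## Coordinate and sequence conventions

All coordinates are 0-based half-open and modular; `end` may exceed the
genome length to represent origin-spanning features, and conversion to
1-based inclusive coordinates happens only at the GFF3 boundary (where
origin-spanning features are emitted as two parts sharing an ID, the GFF3
circular convention). Genomes are uppercase IUPAC DNA; `U` is normalised to
`T` on input. Features overlapping `N` runs are kept, not dropped — assembly
gaps should not silently delete calls.

## ORF discovery and major-ORF selection

`find_orfs()` scans all six frames of the tripled sequence so that ORFs
crossing the origin junction are seen in full context, deduplicates starts
modulo the genome length, and truncates any ORF to at most one full circle
(a frame with no stop anywhere is reported with a `no_stop` flag). The
major-ORF rule is strictly greater than 100 amino acids (`min_aa = 101`),
reading the "\>100 aa" convention literally; both the threshold and the
ATG-only start policy are configurable because neither is a settled
convention in this field. The stop codon is included in the interval and
excluded from the protein, which fixes all length arithmetic.
`select_major_orfs()` is greedy by descending protein length with zero
overlap tolerance by default ("non-overlapping" taken literally); real
ambisense genomes can overlap slightly, so the tolerance is exposed.

Interrupted Rep genes are rescued by a minimal canonical-splice-site scan
(`find_spliced_rep()`): a `GT..AG` intron of 50–300 nt whose removal joins
two same-strand fragments into one stop-free frame, choosing the splice that
maximises the joined protein and breaking ties by the shorter intron. This
is a deliberate, documented substitute for trained gene-structure models,
which are out of scope; it is exact on canonically spliced genes and makes
no claim beyond them.

## Origin detection

`find_nonamer_candidates()` matches the degenerate canonical pattern with at
most one mismatch at the non-N positions (the tolerance is a package
decision — published genomes describe "similar sequences" without stating a
rule) plus an extended list of nonamers observed in annotated CRESS DNA
genomes, matched exactly. `detect_stem_loop()` replaces thermodynamic
folding with a scored inverted-repeat search (G:C pair +3, A:T pair +2,
mismatch −2; stems 5–14 bp, loops 9–14 nt containing the full nonamer,
flanks of 60 nt). Its acceptance surface is planted-hairpin recovery, not
free-energy agreement. `call_ori()` prefers apex-supported candidates, then
canonical-pattern matches with fewest mismatches, then stem score; a
motif-only hit is returned flagged when nothing has apex support, mirroring
the published observation that occasional genomes carry the motif outside a
predicted hairpin.

## Genome-organization genotypes

Genomes are typed I–VIII by (number of major ORFs, sense relation, ori
strand relative to Rep, ori region relative to Rep). The mapping ships as
versioned configuration data (`cress_type_map()`), not hard-coded logic,
because the published typing scheme is cited rather than defined in the
sources this package follows. Three rows are fixed points (II = ambisense,
ori on the Rep strand 5' of Rep; V = unisense with ori on the Rep strand;
VIII = Rep-only replicon); the remaining rows complete the domain so the map
is total, with origins inside an ORF folded onto the 3' rows. The ori region
is decided by gap membership — which intergenic gap contains the motif —
rather than by metric distance, which is not invariant to spacer lengths.
The synthetic generator and the classifier share this single map, so
genotype recovery tests detect map drift rather than re-deriving the map.

## Rep identification and capsid calling

`scan_rep_motifs()` records the leftmost hit of each degenerate motif
pattern and requires at least 4 of the 7 motifs present *in canonical
order* (`is_rep`). The quorum is a package decision: the original
identifications used database homology searches, which are out of scope
here, and a motif quorum is the transparent in-repo criterion.

Capsids are called from intrinsic-disorder profiles of non-Rep ORFs. The
neural-network disorder predictor used in the original workflow is not
reproducible from its description, so `disorder_profile()` substitutes a
transparent compositional scale (the TOP-IDP per-residue propensities,
min-max normalised to [0, 1]) smoothed by a centered 15-residue moving
average with edge truncation. An ORF whose first 100 residues are at least
50% disordered (`theta = 0.5`, exposed — "high proportion" is not defined
anywhere authoritative) is a putative capsid; reports always carry the raw
fraction so users can re-threshold. Genomes with a Rep but no called capsid
are labelled circular molecules. Because the substitute predictor is
compositional, the synthetic generator plants disorder compositionally too
(disorder-promoting pool E,K,S,P,Q,G,R,A versus order-promoting
W,F,I,L,V,Y,C,M); the two are co-designed as a test harness, and passing
these tests validates the pipeline's logic, not any biophysical claim about
real capsids.

## Pairwise identity and the demarcation cascade

`pairwise_identity()` is an affine-gap global (end-to-end) aligner
implemented in compiled code with deterministic tie-breaks
(diagonal \> up \> left): nucleotides score +2/−1 with gap open −4 and
extend −1; amino acids use BLOSUM62 with −10/−1. PI counts identical columns
over *all* alignment columns — gaps count in the denominator, matching the
gap-penalising convention of sequence demarcation tools; an
`ignore_terminal_gaps` flag exists because terminal overhangs after circular
registration are a registration artifact, not evolution. The aligner is
validated exactly against an independent brute-force dynamic program in the
test suite. Because alignment parameters of the original SDT/MUSCLE stack
are not printed anywhere, PIs on real data may differ from published values
by a point or two; all thresholded decisions log the measured value so such
differences are visible.

Sequence demarcation operates on linearised sequences, so circular genomes
are registered first (`circular_genome_identity()`): ori-anchored rotation
when both origins are known (rotate each so the nonamer starts at 0; take
the best of forward and reverse-complement orientation), otherwise a
coarse-to-fine rotation scan at step L/32. The registration used is always
reported.

`demarcate()` is a pure decision function over measured identities, so the
threshold semantics are testable exactly: species thresholds fire at `>=`,
family floors at `>=`, and the novelty rules are strict (`< 0.80` novel,
`< 0.70` unassigned), following the wording conventions of the demarcation
framework. The family floors are treated as assignment floors — the
framework describes them as observed lower limits, which is ambiguous, and
this reading is logged with every call. `greedy_cluster()` reproduces the
two-stage representative clustering used to thin Rep datasets (70% cut-off,
re-clustered at 50% when more than 20 clusters remain), and
`barcode_rank()` applies the strict \>95% species rule used for COI
barcoding of host specimens.

## Phylogenetic preparation

`trim_to_motif_anchors()` trims a Rep alignment to the median column of
RCR motif I and the median column of the arginine finger ("close to" the
motifs is operationalised as the median; min/max variants would also be
defensible and the anchors are reported), then drops rows left with fewer
than 200 residues. `nj_tree()` is standard neighbour joining on 1 − PI with
negative branches clamped to zero and the deficit moved to the sister edge;
it is a desk-scale sanity tree, not a replacement for likelihood inference,
which this package deliberately does not perform. `collapse_low_support()`
contracts internal edges whose support falls below a threshold (the
post-processing applied to published trees at 70–80% SH-like support),
never removes leaves, and emits a canonical Newick (children ordered by
smallest leaf label) so collapsed trees compare stably.

## The synthetic-genome generator

`generate_genome()` realises a specification — length (default uniform
1700–3300 nt, the size range of small CRESS DNA genomes), genotype, nonamer
(default the canonical `TAGTATTAC`), hairpin geometry (8 bp GC-rich stem,
11 nt loop), Rep of 290 aa with all seven motifs planted at fixed positions,
capsid of 230 aa with a compositionally disordered or ordered N-terminus,
and an optional `GT..AG` intron — and returns the genome together with its
complete ground truth.

Unambiguous ground truth is engineered, not hoped for. Reverse translation
uses a fixed codon table chosen so that shifted reading frames of a coding
region cannot acquire start codons from background-residue junctions; an
11-nt guard with a stop in all three frames precedes every gene so no
upstream reading frame can run through it; the Rep background alphabet
excludes residues that could seed spurious motif matches, making the
leftmost-hit motif scan exact; and the intron filler avoids `A` and `G` so
the planted donor/acceptor pair is the only candidate splice. After
assembly the generator re-annotates its own output with the package's
detectors and re-draws the random background if any spurious feature
survives — a long chance ORF, or a rival apex-supported nonamer — so the
emitted truth channel is exact by construction. This is also why recovery
tests asserting 100% are meaningful: they verify the annotators, because
any disagreement between generator and annotator is a real defect, never
generation noise. The corresponding limitation is stated plainly: these
genomes are architectural idealisations (uniform background, fixed codon
usage, perfect stems, compositional disorder) and passing them says nothing
about recombination, codon bias, degenerate motifs or homology-only capsids
in real data.

`mutate_isolate()` applies per-site substitutions (to a uniformly chosen
different base) and geometric(0.5)-length indels, returning a coordinate
map so planted features can be tracked. `make_reference_panel()` builds
labelled families/species/isolates whose *realised* pairwise identities are
rejection-sampled into requested bands — the classifier consumes realised
PI, so bands must hold in realised terms, not in substitution-model
expectation. Default bands sit at least three identity points away from
every demarcation threshold so rank-recovery tests measure the cascade, not
boundary luck.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the study scale chosen
for this package: 200 synthetic genomes across all 8 genotypes for
planted-feature recovery; 501 mutants (167 at each of p = 0.05, 0.2, 0.45,
L = 2000) for PI calibration against the 3-standard-error binomial
envelope; a 2-family, 2-species, 3-isolate panel with 2 novel queries per
family for rank recovery; and 50 random additive trees (4–16 taxa) for NJ
topology recovery. Determinism: every stochastic step is seeded, ties in
every search are broken by fixed rules (documented per function), and
identical inputs produce byte-identical reports. Degenerate inputs error
early with informative messages (empty FASTA, non-IUPAC letters, empty
reference sets, inverted anchor columns, mixed support scales).

## Known limitations

- Capsid calls use only the disorder branch; the original workflow also
  used database homology, so calls on real data can differ where homology
  was decisive.
- The genotype map rows other than II, V and VIII are best-effort
  completions of a cited-but-undefined scheme and should be validated
  before cross-study genotype comparisons.
- PI values depend on alignment parameters that published analyses do not
  print; expect deviations of ±1–2 points on real data.
- The NJ tree is for sanity checks; likelihood trees and their supports
  must come from external tools, whose Newick output this package consumes.
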