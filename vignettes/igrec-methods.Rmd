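---
title: "Methods: how igrec characterises Ig-like receptor families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how igrec characterises Ig-like receptor families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igrec)
```

## The problem

Leukocyte Ig-like receptors (LILR), their rodent counterparts (PIR) and the
related killer Ig-like receptors (KIR) are innate immune receptor families
built from repeated C2-set immunoglobulin domains. Characterising such a
family in a newly sequenced genome involves a chain of classic analyses:
find candidate open reading frames, keep the ones that actually encode Ig
domains, decide which family each candidate belongs to, check whether it
duplicates an already-annotated sequence, classify it as inhibitory,
activating or soluble from its signalling architecture, and ask whether it
is expressed at all. `igrec` implements that chain as a reusable, tested
pipeline, and ships a synthetic-fixture generator so that every stage can
be validated against known truth — something the real genome never offers.

## Candidate discovery

`find_orfs()` scans all six reading frames for ATG-to-stop spans of at
least `min_aa_length` residues (default 100). Nested open reading frames
that share a stop codon are collapsed to the longest. Codons containing
`N` are treated as neither start nor stop and translate to `X`. This is a
deliberately plain ORF finder: splice-aware gene prediction is out of
scope, and the fixtures are single-exon by construction.

Ig domains are detected with position-specific scoring matrices
(`build_pssm()`): natural-log odds against a uniform 20-residue
background with pseudocount smoothing,

$$\mathrm{entry}(i,a) \;=\; \ln\frac{c_{ia} + \lambda/20}{n + \lambda} \;-\; \ln\frac{1}{20},$$

where $c_{ia}$ counts residue $a$ at column $i$ over $n$ aligned examples
and $\lambda$ is the pseudocount. `scan_domains()` scores every window
against every family profile, keeps windows whose best score reaches the
threshold, and resolves overlaps greedily by descending score (ties to the
leftmost window). The default threshold is half the mean profile
self-score: under log-odds scoring, unrelated sequence scores near zero
while a true domain at the fixture's divergence levels loses well under
half its self-score, so the midpoint separates the two regimes with a wide
margin. `X` residues score as the per-column mean, which keeps N-induced
ambiguity neutral. The threshold is a package choice, explicit and
configurable; no claim is made that it reproduces any particular BLAST
cut-off.

## Phylogenetic family assignment

The phylogenetic engine is written from first principles because its
parameters fully specify the computation: amino-acid p-distance with
pairwise deletion, neighbour joining, and bootstrap confidence from
resampled alignment columns.

* **p-distance, pairwise deletion** (`p_distance()`): for each sequence
  pair, columns where either row carries `-` or `X` are skipped; the
  distance is the fraction of remaining columns that differ. Pairs with no
  comparable columns are flagged undefined rather than raising an error;
  the tree builder refuses matrices containing them.
* **Neighbour joining** (`nj_tree()`): the classic agglomeration on
  $Q(i,j) = (n-2)\,d(i,j) - \sum_k d(i,k) - \sum_k d(j,k)$, the standard
  two-term branch-length formula, and the reduction
  $d(u,k) = \tfrac12\!\left(d(i,k)+d(j,k)-d(i,j)\right)$. Ties in $Q$ are
  broken by the lexicographically smallest pair of cluster labels (each
  cluster labelled by its smallest member leaf) and negative branch
  lengths are clamped to zero without redistribution — both standard,
  both chosen for determinism. On additive matrices the implementation
  recovers the generating topology exactly and branch lengths to 1e-9
  (tested over random 5–8 leaf trees, and against brute-force least
  squares over all 15 topologies at five leaves).
* **Bootstrap** (`bootstrap_supports()`): alignment columns are resampled
  with replacement, the distance matrix and NJ tree are rebuilt, and each
  internal edge of the original tree is labelled with the percentage of
  replicates containing the same leaf bipartition. Replicates that produce
  an undefined distance pair are redrawn and counted. 1000 replicates is
  the protocol default. `majority_consensus()` builds the >50% (or
  stricter) consensus from any tree set, labelling retained bipartitions
  with their frequencies.

Multiple alignment is a star alignment (`build_domain_alignment()`): every
domain is globally aligned (match +2, mismatch −1, gap −2) to a family
profile consensus acting as anchor, and stacked in anchor coordinates;
insertions relative to the anchor are dropped and counted. This replaces
progressive multiple alignment with $O(n)$ pairwise alignments that keep
all domains in one coordinate frame. Its adequacy is tested by what
matters downstream — family-recovery accuracy — not by resemblance to any
particular aligner's output. The anchor must be a profile related to the
sequences being stacked (any family consensus works at the package's
divergence defaults); anchoring to an unrelated sequence degrades the
frame and is not supported.

Family calls are distance-based rather than read off the tree: each query
domain gets the mean pairwise-deletion p-distance to every family's
reference set, and is assigned to the nearest family when the margin
(second-best minus best) reaches `ambiguity_margin`, default 0.05.
Receptors take the majority family over their assigned domains; ties and
all-unassigned cases stay `unassigned`, and receptors whose assigned
domains span two or more families are flagged chimeric. A published
"clusters with" judgement is visual; the margin rule is the nearest
testable formalisation, and 0.05 is this package's default, chosen as
roughly half the gap between within-family and between-family mean
distances at the default divergences.

## Redundancy and novelty

Three pieces of evidence decide whether a candidate is new:

* global percent identity from Needleman–Wunsch alignment (match +2,
  mismatch −1, gap −2; traceback ties resolved diagonal > up > left),
  counted as identical pairs over residue-pair columns;
* chromosomal overlap (any positive overlap counts as "same locus");
* identical Ig domains (pairwise-deletion p-distance exactly zero).

`novelty_verdict()` codifies the case-by-case reasoning such analyses use
into one total rule: identity ≥ 95% *and* overlap → `duplicate`; overlap
with all query domains identical but identity below threshold →
`alt_transcript_candidate` (two transcripts plausibly from one gene — the
ambiguity is preserved, not forced); everything else → `novel`, including
high identity at non-overlapping loci, which indicates a paralogous copy
rather than a duplicate annotation.

## Structural classification

`predict_tm()` is a Kyte–Doolittle sliding-window detector (window 19,
threshold 1.6 — the conventional strong-transmembrane setting for that
scale): the maximal run of passing windows, extended to its full residue
span, is the single transmembrane segment. When several runs pass, the
highest-peak run wins and exact ties go to the most C-terminal run — type
I receptors carry their true membrane anchor near the C-terminus, and this
rule avoids mistaking a hydrophobic signal peptide for it. Signal-peptide
trimming is deliberately not performed; that is a logged limitation, not
an oversight.

ITIMs are the 6-residue consensus `[V/L/S/N] x Y x x [L/V]`, scanned only
C-terminal of the transmembrane segment (`scan_itims()`): an inhibitory
motif is functional only in the cytoplasm. Motif matches elsewhere are
reported separately as non-signalling matches and never affect the class.
The decision table in `classify_receptor()` is total:

| TM | tail ITIM | TM arginine | class |
|----|-----------|-------------|-------|
| absent | – | – | soluble |
| present | ≥1 | – | inhibitory |
| present | 0 | yes | activating |
| present | 0 | no | unclassified |

`unclassified` is an addition of this package: membrane-anchored proteins
with no signalling feature do occur as ORF artefacts, and a total function
needs somewhere to put them.

## Expression calling

Reads are mapped ungapped, full length, on both strands, scored
`matches − cost × mismatches` with `N` never matching, and accepted when
the score reaches `ceil(0.8 L)`. With 36-base reads this admits at most 2
mismatches at cost 2 and 3 at cost 1, so the cost-1 pass accepts a strict
superset of the cost-2 pass — the two-pass protocol (map at cost 2,
re-map at cost 1) can only raise coverage. Multi-mapping reads take a
single best placement with deterministic tie-breaking (reference order,
leftmost, `+` strand). Placement search uses exact pigeonhole seeding: a
placement with at most $m$ mismatches must match one of $m{+}1$ disjoint
read segments perfectly, so hashed subject k-mers enumerate every
acceptable placement; the search is verified against an exhaustive scan
in the tests.

Coverage is per-base depth from accepted placements; a transcript is
called expressed when *strictly more than* 99% of its bases are covered.
The percentage is rounded to an integer for reporting but the call uses
full precision — at the 99 boundary the strict rule decides.

## The synthetic fixtures: what they emulate, and what they do not

`build_profiles()` simulates related receptor families as descendants of
one ancestral ~90-residue Ig-domain consensus (defaults: three families,
inter-family divergence 0.4). `synthesize_gene()` assembles receptors
from a signal peptide, 2/4/6 mutated consensus domains, a stalk, a
21-residue strongly hydrophobic transmembrane block (with an arginine for
activating receptors, absent for soluble ones) and a cytoplasmic tail
carrying an implanted ITIM for inhibitory receptors. Class truth is
verified on the final mutated protein with the generator's own
independent checks and resampled until it holds, so the classifier module
is genuinely cross-checked rather than self-fulfilling. Back-translation
uses one fixed codon per amino acid — codon usage matters to nothing
downstream of ORF finding, and a fixed table keeps fixtures
byte-reproducible.

`build_fixture()` places genes and decoy ORFs (valid ORFs with no Ig
material) on both strands of several contigs, separated by AT-only
spacers. The spacer contains stop codons in all six frames within a dozen
bases and no ATG or CAT trinucleotide, so reading frames never bridge
placements; after assembly the contigs are re-scanned and any placement
that spawns a spurious ORF at the fixture's minimum length is
regenerated. The default composition — 26 Ig-receptor genes (16 LILR-like
with a 7 inhibitory / 4 activating / 5 soluble split, six KIR-like, four
six-domain PIR-like) plus 51 decoys, giving a 77 → 26 discovery funnel —
mirrors the repertoire structure this package targets. The default
within-family divergence is 0.15, just inside the generator's requirement
of half the inter-family divergence.

`simulate_reads()` draws 36-base reads from expressed coding sequences on
both strands, with Poisson per-transcript counts around
`depth × length / 36` and independent substitution errors (defaults:
depth 12, error rate 1%). Read starts are drawn uniformly over the padded
interval and clamped into range (edge-clamped sampling), so expected
per-base depth is uniform out to the transcript ends; plain uniform starts
would systematically undercover terminal bases. Even so, base-level
coverage is Poisson: saturation of every base of a ~1 kb transcript is
only near-certain from depth ~30, and the full-coverage guarantees are
tested there. Known simplifications: substitutions only (the
mapping model is ungapped, so indel errors would exercise nothing),
uniform errors with a constant Q30 placeholder quality, no paired ends,
no splice isoforms, no genomic repeats.

Because paralogs within a family share identical 36-base windows with
appreciable probability, the deterministic single-best-placement rule
lets the earlier-ordered reference win those windows, and some expressed
paralogs legitimately fall below the strict >99% cut in the full
26-gene run — much as real coverage tables spread well below 100%. The
clean-coverage guarantees (100% for an expressed transcript, 0% for an
unexpressed one) therefore hold, and are tested, on fixtures where
paralogous shadowing cannot occur. Passing tests on these fixtures shows
the machinery is correct under controlled truth; it does not certify
performance on real genomes, where domain boundaries, splice structure
and repeat content are all harder.

## Numerical and size choices

* Alignment scoring is integer; distance and support computations are
  double precision. NJ tie-breaks and clamping are described above.
* The bootstrap and every other stochastic step derive their streams from
  one master seed (`pipeline_config(seed = ...)`), so whole runs are
  checksum-reproducible.
* Test problem sizes are chosen to make the suite sharp but quick: 100
  additive matrices for NJ exactness, 1000 random pairs for p-distance,
  100 simulated domains for assignment accuracy, 200 bootstrap replicates
  where convergence is asserted, and the full 77-ORF fixture with 1000
  replicates for the end-to-end funnel. The determinism check re-runs the
  pipeline at 25 replicates, since determinism is independent of the
  replicate count.

## Known limitations

* Single-exon gene models only; no splice-aware discovery.
* One transmembrane segment per protein (type I receptor assumption).
* No signal-peptide prediction; the C-terminal tie rule is the mitigation.
* Star alignment discards insertions relative to the anchor; long
  insertions in real receptors would be invisible to the distance
  computation.
* The profile threshold and assignment margin are package defaults with
  documented rationale, not values inherited from any published pipeline.
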