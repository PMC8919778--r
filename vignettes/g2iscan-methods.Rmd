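---
title: "Methods: group II intron detection and context analysis with g2iscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group II intron detection and context analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g2iscan)
```

# The detection model

Group II introns (G2Is) are mobile retroelements with six structured RNA
domains; domain V is the catalytic core and domain IV usually carries an
open reading frame for the intron-encoded protein (IEP), whose reverse
transcriptase (RT) domain is the most conserved protein-level signal.
`g2iscan` treats detection as evidence integration over three hit classes,
each arriving as tabular output of an external search (or of the built-in
Smith–Waterman scanner):

1. **RT hits** (translated homology): kept when e-value ≤ 1e−10 and query
   coverage is *strictly* greater than 40%; overlapping survivors on the
   same strand are collapsed to the hit with the highest bit score, whose
   query lineage assigns the IEP type.
2. **Domain V/VI hits** (covariance model): kept when the bit score is
   strictly greater than 24.
3. **Domain I–IV hits**: kept under the alignment rule (e-value ≤ 1e−10
   and coverage > 60%) or the covariance-model rule (e-value ≤ 1e−2),
   depending on each hit's recorded evidence source.

Assembly then applies a single distance rule. An RT hit and a domain V/VI
hit on the same replicon and strand, with the RT upstream in intron
orientation, are joined into an *IEP-containing* call when the
nearest-boundary gap is at most `max_gap` = 1,300 nt. Domain V/VI hits not
consumed this way become *ORF-less* calls when at least one domain I–IV
hit lies upstream within the same bound. The 1,300-nt default reflects the
empirical distribution of RT-to-domain-V distances in curated reference
introns (99% lie within it); it is configuration, not a constant.

Three aspects of the rule are deliberate design choices where only a
distance was specified:

* **Orientation.** The RT ORF sits in domain IV, 5′ of domain V, so the RT
  (or domain I–IV) hit must be upstream of domain V/VI in intron
  orientation. `require_upstream_order = FALSE` disables this.
* **Distance definition.** Gap = nearest-boundary separation, with
  overlapping intervals clamped to 0. On circular replicons the gap wraps
  the origin.
* **Ambiguity resolution.** When several pairings are feasible, pairing is
  greedy by smallest gap with the RT bit score breaking ties, and each hit
  joins at most one call. This is exact in the well-separated regime the
  planted-truth tests exercise; it is *not* a global bipartite matcher,
  and pathological chains of overlapping candidates can in principle be
  paired sub-optimally (the assembly test suite compares greedy against an
  exhaustive minimum-total-gap oracle on random configurations).

Two documented blind spots are inherited from the evidence model rather
than fixable downstream: the outer intron of a twintron is not assembled
(its domain V lies beyond another whole intron), and tandem domain V/VI
duplications flanking one IEP can yield two calls unless
`collapse_duplicated_dvvi = TRUE`.

# IEP classification

For each IEP-containing call the region from 1,000 nt upstream of the RT
hit to 200 nt downstream of domain VI (intron orientation; clamped on
linear replicons, wrapped on circular ones) is extracted. Reference IEP
peptides are aligned against the three forward reading frames (genetic
code 11, BLOSUM62, affine gaps 11/1); the best local alignment defines the
subject peptide.

* **Interrupted**: one or more stop codons strictly inside the subject
  span (a stop at the final codon is the normal ORF end). This takes
  precedence over every other label, mirroring a workflow in which
  interrupted sequences are set aside before ORF analysis. Because a
  maximal Smith–Waterman alignment can extend a few residues past the true
  peptide into flanking sequence — occasionally across a stop codon — each
  candidate stop is validated by requiring independent homology to the
  winning reference on *both* flanks (raw score ≥ 60 per side, ≥ 10 aa):
  the two-HSP signature with which a translated search presents a genuinely
  interrupted gene. Unsupported stops are treated as alignment-boundary
  artifacts.
* Otherwise the longest stop-to-stop ORF overlapping the RT hit is taken
  (starts ATG/GTG/TTG), and its peptide is scanned against the call's
  15 type-specific conserved motifs (10–50 aa each). A motif counts as
  present when its best ungapped BLOSUM62 match reaches 60% of the motif
  self-score; **short ORF** = at least 5 of 15 motifs missing, else
  **canonical**. The "five missing" threshold is the only testable reading
  of a manually curated criterion ("about 5 or more"); the 0.6 per-motif
  fraction is exposed as `motif_threshold` because the original manual
  match criterion is unrecoverable.

Peptides are clustered greedily at 85% identity: sequences sorted
longest-first (ties lexicographic by id), each joining the first cluster
whose representative it matches at ≥ 0.85, identity being matches over the
shorter sequence on a local alignment — the convention of
greedy-incremental clustering tools. Representatives are therefore the
longest members. Internal stops are stripped (`strip_stops()`) before
clustering so residue strings are contiguous.

# 5′ ends and terminator context

Published 5′-end consensus alignments exist for nine IEP lineages (A, B,
C, D, E, F (g2–g5), ML, CL1, CL2; CL1/CL2 serve their A/B subtypes).
`build_profile()` converts an alignment into a position log-odds matrix,
`log2((count + 0.1) / (n + 0.4) / 0.25)` per column against a uniform
background, dropping all-gap columns. The profile is scanned over the
1,200 nt upstream of the IEP; the best site scoring at least 10 bits is
the 5′ end, and ties in candidate sites resolve to the highest score.
Bacterial G (g1) has no published consensus and is always excluded. The
log-odds scan replaces a profile-HMM search; the 10-bit acceptance rule is
kept identical, which is the decision that matters downstream.

Terminator context: the distance from the intron 5′ end to the 3′ end of
the nearest upstream same-strand rho-independent terminator is reported
when within `max_search` = 5,000 nt (distances are non-negative by
construction; terminators downstream of the 5′ end are never matched).
Terminators are L-shaped when the 10-nt tail immediately after the
stem–loop contains ≥ 4 U residues (T on the DNA sense strand), else
I-shaped; the 10-nt tail window is this package's choice, as the tail
extent is not defined by the shape rule itself.

# Replication geometry

*ter* is placed half the replicon length from *ori* (floor division for
odd lengths). Replichore 1 is the ascending-coordinate arc from *ori* to
*ter*; on it the top (+) strand is the leading strand. Positions exactly
at *ori*/*ter* belong to replichore 1. This convention is stated
explicitly because the insertion-bias score depends on it:
IB = n(lagging)/n(leading), `Inf` when nothing is on the leading strand,
`undefined` when no call is classified; IB ≥ 5 is a strong and 2 ≤ IB < 5
a moderate lagging-strand bias.

GC skew is (G − C)/(G + C) per 10 kb window, N bases excluded, windows
with no G or C flagged and scored 0. The GC skew index splits the replicon
into 4,096 equal windows and combines `sr` — the Fourier power at
frequency 1 over the mean power at all nonzero frequencies, which is large
exactly when skew flips sign once around the replicon — with `dist`, the
amplitude (max − min) of the cumulative window skew anchored at 0:
`gcsi = sqrt((sr / 6000) · (dist / 600))`, clipped to [0, 1]. The window
count and the two normalisation constants follow the generalized-GCSI
convention and are exposed as arguments. Anchoring the cumulative skew at
0 makes GCSI exactly invariant under reverse complement; per-replicon
values are reported, and for multi-replicon assemblies the longest
replicon's value is the natural genome-level summary.

# The synthetic-data generator

`generate_genome()` draws i.i.d. bases at a chosen GC content with a
per-replichore G/C imbalance of ±`skew_amplitude` switching at *ori* and
*ter* — the minimal model that produces the two-replichore skew signature.
`plant()` overwrites genome sequence with intron elements and emits truth
tables, internal hit tables (convertible to the external 12-column and
tblout dialects by `write_hit_tables()`), and terminator records.

The parts library (`g2i_parts_library()`) is generated deterministically
from a fixed seed: per IEP type, 15 motifs of 18–36 aa whose concatenation
(with GS linkers) is the canonical peptide; motifs 11–15 form the RT
domain, so the ORF ends immediately after the RT hit and a planted domain
V/VI at any gap ≥ 3 nt never overwrites coding sequence. Reverse
translation varies synonymous codons with the position so shifted reading
frames contain stop codons at natural density — otherwise a frame-shifted
pseudo-ORF can outrun the real one. Interruptions are written as TAA
codons inside the RT domain; deletions remove motifs head-first (never the
RT motifs). All sequences are synthetic: they exercise the pipeline's
decision rules, not intron biology, so passing tests demonstrate correct
rule implementation — thresholds, orientation, coordinate arithmetic,
classification logic — and nothing about sensitivity on real genomes,
where hit quality depends on the external search tools and reference sets.
Decoys cover the three false-call modes: an RT whose nearest domain V/VI
is beyond the gap bound, a domain V/VI hit below 24 bits, and a domain I
hit on the opposite strand of an unpaired domain V/VI.

Truth tables are evaluated against the supplied `assembly_config`, so
regenerating with `max_gap = 1000` flips the expectation for planted gaps
in (1000, 1300].

# Numerical and interface choices

* Internal coordinates are 0-based half-open with explicit strand; all
  emitted files (GFF3, TSV) are 1-based inclusive, and converting twice is
  the identity.
* The built-in scanner reports bit scores and pseudo-e-values under fixed
  Karlin–Altschul parameters (protein λ = 0.267, K = 0.041; nucleotide
  λ = 0.625, K = 0.41). These are internally consistent for fixtures and
  must never be compared with e-values from external search tools.
* Genetic code 11 throughout; start codons ATG/GTG/TTG; ambiguous codons
  translate to X; translation of stops is `*`, which BLOSUM62 scores, so
  interrupted subjects still align.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state.

# Evaluation study sizes

The packaged evaluation (`scripts/acceptance.R`, mirrored by the
acceptance test suite) uses: ten 1-Mb genomes with 5 IEP-containing + 2
ORF-less introns and 3 decoys each for end-to-end recovery; 60 planted
IEPs (20 per status class) for classification; 50 random peptide families
of 6 members for the clustering oracle; 100 random 20-kb genomes, four
planted amplitudes (0.02–0.2) at 410 kb and 20 shuffled 102-kb genomes
for the skew/GCSI properties; and twelve terminator-context introns (six
bacterial-C-type within 50 nt of a terminator, six CL-type at least
2,000 nt away). These sizes keep the full evaluation within a few minutes
on one CPU while leaving every decision boundary explicitly exercised.

# Known limitations

* Twintron outer introns are not detected; tandem domain V/VI duplications
  can duplicate calls unless collapsed.
* Greedy pairing and greedy clustering are order-deterministic heuristics,
  not global optimisers.
* The GCSI normalisation constants are conventions; comparisons are
  meaningful within a consistent configuration.
* GenBank input is read for sequence and source metadata only; feature
  tables are ignored by design (the pipeline is sequence-driven).
* The 5′-profile scan assumes the IEP anchor is reliable; calls without a
  located IEP, and types without a published consensus, get no 5′ end and
  drop out of terminator-distance statistics.
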