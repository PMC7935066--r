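---
title: "Methods: miRNA curation, slicing-target prediction and conservation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA curation, slicing-target prediction and conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirslice)
library(dplyr)
```

## Scope and model

Cnidarian miRNAs behave in a plant-like way: instead of recognising targets
through a 7-nt seed match, they bind with extensive, near-perfect antisense
complementarity and direct Argonaute-mediated cleavage ("slicing") of the
target between the nucleotides opposite miRNA positions 10 and 11. mirslice
implements the complete desk-scale analysis chain this biology calls for:

1. **Curation** — decide which candidate hairpin precursors are bona fide
   miRNAs from their duplex geometry, read support and fold significance.
2. **Target discovery** — scan transcriptomes for highly complementary
   antisense sites under explicit per-region mismatch budgets, then
   re-validate candidate sites at the duplex level.
3. **Degradome verification** — confirm sites with PARE/degradome reads whose
   5′ ends mark cleavage positions under an exact-offset geometry.
4. **Conservation** — compare verified miRNA–target pairs across species via
   reciprocal-best-hit orthology, classify them as conserved (I), shared
   (II) or rule-failing (III), and summarise repertoire evolution with
   substitution profiles, Dollo gain/loss reconstruction and turnover rates.

Every input the pipeline consumes can also be *generated*, with ground truth
known by construction, by the synthetic-data module. All tests and the
acceptance script run on such fixtures.

## Curation criteria

`curate_mirnas()` applies six criteria, each recorded separately so the audit
table lists every failure reason:

| criterion | default | meaning |
|---|---|---|
| upstream score | ≥ 10 | discovery-tool score, skipped when absent |
| star 3′ overhang | = 2 nt | the Drosha/Dicer processing signature |
| 5′ consistency | ≥ 0.90 | fraction of mature-arm reads sharing the modal 5′ start |
| mature/star pairs | ≥ 16 | base pairs joining mature to star in the fold |
| read depth | ≥ 10 | mature-arm reads (configurable to whole-stack) |
| fold p-value | < 0.05 | randomisation test of folding strength |

Terminal-loop-size and star-consistency requirements are deliberately
disabled by default (cnidarian precursors do not obey them); switches exist.
Two conventions the criteria leave open are fixed as: the minimum read count
is taken over mature-arm reads only (configurable), and modal-start ties are
broken toward the annotated mature start, else the smaller coordinate.
When the mature 5′ terminus itself is unpaired in the fold — real hairpins
fray — the overhang anchor advances up to 2 nt inward to the first paired
mature position.

### Folding and the randomisation p-value

The fold criterion is a randomisation test, not an energy estimate, so the
package scores structures by Nussinov base-pair maximisation (nested
\{A:U, G:C, G:U\} pairs, hairpin loops ≥ 3 nt) rather than a thermodynamic
model; an external folding backend returning an energy can be plugged into
`shuffle_pvalue()` unchanged. The p-value compares the observed pair count
against `n_shuffles` dinucleotide-preserving shuffles
(Altschul–Erickson Eulerian-path shuffling) with the add-one estimator
`(1 + ties-or-better)/(n + 1)`, so p can never be 0 and equals 1 on
homopolymers. The significance threshold defaults to 0.05, the usual
randomisation-test convention, and is configurable. Max-pairs folding is
degenerate: several structures can tie at the optimum, and the traceback
picks one deterministically (5′-most partner first). Candidate tables may
therefore carry an explicit dot-bracket structure — used in preference to
de-novo folding — which also lets fixtures control geometry and fold
significance independently.

## Target discovery rules

`scan_transcript()` slides the miRNA antiparallel along the transcript
(miRNA position 1 opposite the 3′-most window nucleotide) and charges
mismatches to regions:

* position 1 — exempt under `free_5prime` (the `-c` convention);
* positions 2..11 — the seed window, budget 2 (`-s 11 -S 2`);
* downstream of the seed — budget 2 (`-m 2`);
* the final nucleotide — exempt (`-n 1`).

The seed window is anchored at position 1 (positions 2–11 charged); the
alternative 2–12 anchoring is a one-constant change. Scanning is ungapped
and counts G:U wobbles as mismatches — the behaviour of a nucleotide-space
read mapper. Overlapping sites are all reported; degradome evidence
disambiguates downstream.

`validate_site()` then re-examines each candidate window (±3 nt) with an
affine-gap duplex dynamic program (WC +2, G:U +1, mismatch −1, gap open −3,
extend −2; terminal overhangs free). At this stage G:U counts as a pair
(thermodynamic semantics — the deliberate asymmetry with the scan stage
reconciles mapper-based discovery with hybridisation-based acceptance), at
most one bulge is tolerated on either strand, and miRNA positions 9–12 —
the region opposite the catalytic centre — must all be paired. One caveat
uncovered during testing: a duplex score is *not* invariant under jointly
reverse-complementing both strands whenever the optimum uses a wobble
(complementing G:U yields the non-pairing C:A), so the symmetry property the
package asserts is strand-swap symmetry, plus reverse-complement invariance
under WC-only scoring.

## Degradome geometry

Slicing leaves a 3′ fragment whose 5′ end sits at the transcript nucleotide
pairing miRNA position 10. With `end` the site coordinate pairing miRNA
position 1, the supported cleavage coordinate is `end − 9`; a read supports
a site only if its 5′ end equals it exactly (an `offset_nt` knob exists for
sensitivity analysis). Reads mapping to more than one location are discarded
before counting, and one supporting read suffices by default — both
conservative conventions the verification rule leaves open. The
inclusive-count convention is pinned by round-trip consistency:
`make_degradome_reads()` places signal reads where `verify_sites()` must
find them, and a +1-nt shift of every read destroys every verification.

## Conservation layer

Orthology is operationalised as reciprocal best hits under local alignment
(match +2, mismatch −1, gap open 5, extend 2, via Biostrings); ties are
broken lexicographically and flagged, and a tabular-hits adapter accepts
precomputed external aligner output. Categories follow the
verified-reference perspective:

* **I** — the same miRNA family is in the other repertoire and has a
  validated site on the reciprocal homolog (conserved target);
* **II** — a different miRNA has a validated site *and* the reference miRNA
  is absent from the other repertoire (shared target);
* **III** — a candidate site exists on the homolog but fails duplex
  validation;
* **none** — otherwise, including missing homologs.

Because a degraded site would not be rediscovered by scanning, the
comparison also projects every reference site onto its homolog through a
global alignment and validates the projected window; this is what makes
category III decidable. miRNA identity across species is the family label
given in the input, not a re-clustering. Site regions use an any-overlap CDS
rule (a site straddling a CDS boundary is CDS — the coding-region constraint
is the biologically meaningful case), and site-location conservation
projects the reference site midpoint through the transcript alignment with
a 30-nt tolerance.

Substitution counting over ungapped offset alignments offers two
first-class modes, because the convention behind published totals is not
recoverable: `distinct_minus_one` (minimum changes under a star phylogeny)
and `non_modal_count` (sequences differing from the plurality nucleotide).
Both are invariant to input order; only columns covered by every sequence
count. Dollo reconstruction places each family's single gain at the MRCA of
its possessors and reads losses off the edges where presence ends; turnover
divides the repertoire symmetric difference by the divergence window
(e.g. D = 23 over 16.2–35.3 Myr gives 0.652–1.420 families/Myr), with an
explicit per-lineage flag rather than a hidden convention.

## Synthetic data: what it emulates, and what it does not

The generators emulate the *statistical structure* the rules inspect:
hairpins with exact duplex geometry (the star arm is the reverse complement
of the first `m − overhang` mature nucleotides plus a non-pairing tail, so
mature/star pairs = `m − overhang` by construction); read stacks with a
tunable 5′-homogeneity fraction (round-half-up; the remainder shifted ±1–2
nt uniformly — a stand-in, as real read-level noise is not characterised);
planted target sites with exact per-region mismatch counts (injected letters
pair under neither WC nor wobble rules, so truth is exact under both
matching semantics); degradome reads at the slicer coordinate plus uniform
noise; ortholog transcripts under i.i.d. substitution/indel processes in
which indels never enter planted sites (keeping mismatch truth countable);
and mature families with known per-position substitution counts. Planted
sites never overlap. Sequences are i.i.d. uniform over \{A,C,G,U\}: no codon
structure, UTR composition, expression levels, sequencing error or quality
scores. Passing tests therefore demonstrate that the *rules and geometry*
are implemented exactly, not that the pipeline's error rates on real tissue
libraries are known.

Default scenario conditions: 22-nt miRNAs with a 5′ U, 300-nt transcripts,
3 decoy transcripts per species, 3 degradome reads per verified site,
zero background mutation (category differences are then attributable only to
the planted plan); category III plants 3 seed + 3 tail mismatches, past
every budget. Test and acceptance problem sizes (200 scan oracle pairs,
50 degradome seeds, 30–50 scenario seeds, 25-transcript RBH pools) were
chosen as the smallest sets that exercise every rule boundary and keep the
whole suite comfortably reproducible on a laptop.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere user-facing; 0-based
  half-open only in BED export.
* `T` is accepted in any input and mapped to `U`; any other letter is an
  error.
* Ties in `quantify_known()` read assignment: fewest mismatches, then
  fewest end-shifts, then lexicographic mature id; blacklist matching is
  exact both-strand substring matching by default.
* Empty inputs return empty, correctly-typed tibbles (an empty miRNA set
  yields an empty site report, not an error); a read stack with no
  mature-arm reads has consistency 0.
* Pipeline outputs are fully ordered (transcript id, coordinate, miRNA id),
  so identical configs and seeds reproduce byte-identical tables; the run
  manifest records the package version, a content hash of the config, and
  the seed. Configs serialise to YAML.

## Known limitations

* Pair-maximisation folding has no stacking energies; its shuffle p-value
  separates genuine hairpins from shuffles at precursor scale but is a
  weaker discriminator than an MFE-based test, and its optimum is
  degenerate (mitigated by the explicit-structure channel).
* The scan stage is ungapped; bulged sites are only recovered through the
  projection-plus-validation path.
* RBH on nucleotide local alignment is adequate at desk scale; genome-scale
  or highly diverged comparisons should import external tabular hits.
* Dollo parsimony forbids convergent gain; a family gained twice
  independently will be reconstructed as one ancient gain plus losses.
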