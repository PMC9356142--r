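---
title: "Designing recursive editing guide cascades: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing recursive editing guide cascades: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editcascade)
```

## The problem

CRISPR-Cas9 homology-directed repair (HDR) installs precise edits from a
donor template, but most double-strand breaks resolve through error-prone
end joining into short insertions and deletions. Because these indel
outcomes are semideterministic, the abundant ones can be *retargeted*: a
second guide RNA that matches an indel allele — but neither the wildtype
nor the donor-edited (HDR) allele — re-cuts the failed repair products and
gives the donor another chance. Applied recursively over levels A (the
wildtype-targeting entry guide), B, C, ..., this converts indel mass into
HDR mass while depleting undesired alleles. `editcascade` designs such
cascades and evaluates them in silico.

## The allele algebra

Alleles are concrete DNA sequences with a lineage of (guide, outcome)
events and a *mass*: the product of conditional outcome frequencies along
the lineage, conditional on the indel (non-HDR) repair channel. The
wildtype allele has mass 1; a full outcome distribution applied to a parent
splits its mass exactly (tested to 1e-9). All coordinates are 0-based and
half-open; insertions anchor before their start index; the blunt SpCas9 cut
between protospacer positions 17 and 18 is represented by the index of the
first base 3' of the cut.

Microhomology makes deletions ambiguous — several equal-length spans yield
the same product — so deletions are canonicalized to their leftmost
alignment, and alleles are compared by exact sequence. Lineages that
converge to the same sequence are merged by summing mass: a guide targets
sequences, not histories. One consequence, visible in the tandem-repeat
fixtures, is that different editing paths (a 3-bp then 6-bp deletion, or
6-bp then 3-bp) legitimately pool their mass into one frontier allele.

## The bundled outcome model

Published repair-outcome predictors are machine-learned; this package
bundles a deliberately simple, deterministic, hand-computable model that
preserves the two structural features recursive design exploits —
microhomology-mediated deletions and cut-adjacent duplications — and keeps
every number in the test suite derivable by hand. It is exposed through the
same adapter seam as any external predictor (`register_predictor()`), and
every distribution is validated at that seam.

For a cut at index $c$, all canonical deletions of length $d \le d_{max}$
whose span covers or abuts the cut ($s \le c \le s+d$) receive weight

$$w = (1+m)^2\, e^{-d/\lambda}$$

with $m$ the microhomology length of the canonical alignment (capped at
`mh_max`), plus a +1 duplication of the base 5' of the cut with weight
$\beta_1$ and a +2 duplication of the preceding dinucleotide with weight
$\beta_2$. Weights normalize to frequencies; outcomes below
`min_report_freq` pool into a truncated-mass remainder, so reported
frequencies plus the remainder always sum to 1.

Defaults: $\lambda = 10$ bp, $\beta_1 = 3.0$, $\beta_2 = 0.3$,
$d_{max} = 30$ bp, `mh_max` = 15, `min_report_freq` = 0.01. Worked example:
a unique 3-bp microhomology pair with total deletion length 6 scores
$(1+3)^2 e^{-0.6} = 8.78$, beating the +1 duplication (3.0) and every
repeat-free deletion (at most $e^{-0.1} = 0.905$).

### A structural consequence of these defaults

The deletion enumeration admits roughly $\sum_{d \le 30}(d+1)$ distinct
spans, carrying total weight ~90-165 in any design-sized window. The +1
duplication's share is therefore bounded near 3%, regardless of context.
Two things follow, and both are deliberate consequences of keeping the
stated defaults rather than retuning them:

* sites whose dominant outcome is the +1 duplication can rank it first,
  but its mass cannot reach the default `min_targeted_mass` of 0.05, so
  insertion-led cascades terminate at level A and classify non-Recursive
  under defaults. The retargeting mechanics for such sites (a B guide
  spanning the duplicated base, matching the +1 allele and neither
  wildtype nor donor) are exercised in the tests at an explicitly relaxed
  `min_targeted_mass = 0.02`. In real data, +1 duplications are frequently
  the dominant outcome class; this is a calibration property of the
  bundled model, not of the method.
* high outcome concentration requires engineered microhomology. The
  fixture generator therefore plants period-3 tandem repeats (18 bp, six
  copies of a 3-mer unit) with a PAM placed so the cut falls inside the
  repeat: successive 3-bp microhomology deletions then dominate every
  round, top-2 concentration exceeds the 0.5 entry gate, and a three-level
  A1/B1/C1 cascade emerges — the same architecture as deep alt-EJ deletion
  chains at natural loci.

## Guide finding and filtering

Guides are all 20-mers 5' of an NGG PAM, both strands (NAG sites are
ignored). On-target efficacy uses a bundled heuristic in $[0,1]$ — base
0.6, +0.2 for GC content in $[0.40, 0.70]$, −0.2 for a homopolymer of 5,
−0.2 for a protospacer ending TT — pluggable like the predictor.
Off-target counting is exhaustive Hamming-distance search (default: no
sites allowed at ≤2 mismatches, NGG-adjacent, intended site excluded),
acceptable at fixture scale and swappable for genome scale.

Retargeting guides must avoid the wildtype allele (entry guides are
exempt — they must cut wildtype) and the HDR allele, and must cut within
`proximity_bp` (default 10) of the prior edit so that a donor with 40-50 bp
homology arms spans both the new cut and the edit it corrects. Because a
microhomology deletion's junction is ambiguous across the homology tract,
the "prior edit position" is an interval — `[start, start+m]` for
deletions, `[start, start+len]` for insertions — and distance is measured
to that interval. A point edit degenerates to simple distance; without the
interval form, PAM-proximal cuts near long repeats would be spuriously
rejected.

## The recursive search

Per level, the search predicts outcomes for each frontier allele, expands
the top `top_outcomes_per_allele` (default 2) children, enumerates
candidates near the new edits, and scores each candidate with the
*retarget score* $M(g) \times R(g)$: $M$ is the summed mass of frontier
alleles the guide matches, and $R$ is the fraction of the guide's own
predicted outcome mass for which some qualifying next-level guide exists
(a one-step look-ahead; deeper look-ahead is out of scope). The two
ingredients are both frequencies of serial events, hence the product; the
score is a priority metric for comparing reagents at a locus, not a
quantitative predictor of HDR improvement. When a guide matches several
frontier alleles, $R$ is evaluated on the highest-mass matched allele.

Candidates with targeted mass below `min_targeted_mass` are dropped; up to
`guides_per_level_max` (default 2) survive per level, ranked by retarget
score with fully specified tie-breaks (on-target score, leftmost position,
then + strand) so runs are byte-identical. At the final level the
qualifying candidates are re-ranked purely by efficacy and specificity
(on-target descending, off-target hits ascending): there is no next level
for the look-ahead to serve. One entry guide is selected per cascade
(alternative entry guides define alternative cascades); guides already
chosen at an earlier level are excluded from later pools, since sequence
merging can regenerate an earlier level's target allele deeper in the
tree. Labels follow the field convention: letter = level, number = rank of
targeted-outcome abundance within the level.

*Retargeting efficiency* at level $L$ is the fraction of the indel mass
cut at level $L$ that the level-$L{+}1$ guides cover; a site is classified
Recursive when the level-0 efficiency strictly exceeds 20%. The overall
rank score used to order scan databases is the entry guide's retarget
score (equal to its retargetable fraction $R$, since $M = 1$ at level A).

## The mass-flow simulator

The simulator propagates expected allele masses, not sampled cells:
deterministic expectation dynamics are reproducible and sufficient for
ranking cascades. Each round, every allele matched by an active guide
loses `cut_efficiency` (default 0.9) of its mass; `hdr_fraction` (default
0.25) of the removed mass enters the absorbing HDR pool and the rest
redistributes over that allele's predicted outcomes, with
below-threshold outcomes flowing to an inert residual indel pool. The HDR
allele and unmatched alleles are inert. `sequential` activates one level
per round in order (the donor is re-supplied each round, modeled as a
constant `hdr_fraction`); `simultaneous` activates all levels every round
until `rounds_max` or the targetable mass falls under `min_mass`. Masses
sum to 1 every round to 1e-9, HDR is nondecreasing, and adding a
retargeting level can only increase final HDR — the in-model analogue of
the method's central claim. The model deliberately omits RNP degradation,
target-site blocking, cell division and toxicity, so it cannot reproduce
the empirical observation that simultaneous delivery can underperform
sequential delivery; both schedules are reported side by side instead.

## Scan pipelines

Three database modes reuse the same per-site machinery, so every emitted
record is bitwise-identical to a direct `run_recursion` call on that
window. In genome mode every enumerated guide is an entry candidate; its
±50 bp window must pass the concentration gate (top-2 outcome mass ≥ 0.5)
before the full search runs, and records whose entry cuts lie within 5 bp
collapse to the better-scoring one. Codon mode extracts start/stop codon
features from GFF3, drops redundant isoform entries covering the same
codon, uses ±30 bp windows and requires the entry cut proximal to the
codon. Variant mode reads VCF, discards records whose REF/ALT length
difference exceeds 50 bp, builds ±50 bp windows, installs (or, with the
revert flag, corrects) the variant as the HDR edit, and requires the entry
cut proximal to the variant; complex records that are neither pure indels
nor same-length substitutions after anchor trimming are skipped with a
logged id. Windows that would cross a contig edge are skipped.

## What the synthetic fixtures do and do not show

The generator emulates the package's input universe — a multi-contig
FASTA, a GFF3 with isoform-duplicated stop codons, a VCF with qualifying
SNVs, background SNVs and a >50 bp deletion — with planted constructs
whose expected cascade structure is recorded in a truth table and verified
by actually running the recursion before a plant is accepted. The
background is rejection-sampled to be free of duplicate 23-mers (both
strands), flanks must break the repeat period at both repeat edges, and no
other candidate cut may fall within 8 bp of a planted repeat, so the scan
answer is known by construction. Problem sizes (4 × 5 kb contigs, ~10
plants) keep a full genome scan under a minute. What passing these tests
shows is that the search, scoring, classification and pipelines implement
their contracts exactly; what they cannot show is predictive accuracy on
real repair outcomes, which is the job of the external predictors behind
the adapter seam, or wet-lab editing efficiencies.

## Numerical choices and limitations

* Ties everywhere are broken deterministically (frequency, indel length,
  child sequence; score, on-target, position, strand), so identical
  inputs serialize byte-identically.
* Degenerate bases (N) are rejected in design windows; the off-target
  scan treats them as mismatches via exact matching.
* `classify_site` is strict at the threshold: efficiency 0.20 is not
  Recursive, 0.21 is.
* The HDR:indel ratio reports `Inf` when indel mass is exactly zero and 0
  when HDR mass is zero.
* Chromosomal rearrangements, large deletions, bulge-tolerant off-target
  matching, CFD/MIT specificity scores, multi-nuclease chemistries and
  quantitative HDR prediction are out of scope.
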