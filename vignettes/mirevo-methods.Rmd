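---
title: "Models and methods behind mirevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mirevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mirevo` analyses the evolution of a clustered plant miRNA family that
targets NBS-LRR resistance genes.  This vignette explains the models the
package implements, the assumptions behind them, the tunable parameters
and their defaults, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the underlying procedure
was originally manual or unstated.  Nothing here states an empirical
result that the test suite does not itself compute.

## 1. Hairpin discovery

**Scan.** A mature query (20–24 nt, U ≡ T) is matched ungapped against
both strands of the genome; every window with Hamming distance ≤
`max_mismatches` (default 3) is a hit.  Hits of different queries on an
identical span are merged, keeping the fewest-mismatch query — several
family members often share one locus.  Coordinates are 0-based
half-open (BED convention) throughout, and minus-strand candidate
windows are stored query-oriented with an exact back-mapping, so every
hit ↔ window ↔ precursor coordinate round-trip is exact by construction
(and asserted in tests).

**Window and fold.** `extract_candidate()` takes `flank` = 450 nt on
each side of the hit, clipped at contig ends.  The folding backend is
deliberately narrow — sequence in, a table of (dot-bracket, score) out —
and the built-in engine is a Nussinov-style maximum-base-pairing fold:
minimum hairpin loop 3 nt, G·U wobble allowed, objective = number of
pairs (reported energy is −pairs).  "Suboptimal" structures are
alternative co-optimal tracebacks obtained with perturbed deterministic
tie-breaking (default `n_suboptimal` = 10).  This engine has no
thermodynamics; it exists so the whole pipeline runs with zero external
dependencies, and on the synthetic templates (whose loops are drawn from
{A, C} so they cannot self-pair) the designed structure *is* the
maximum-pairing structure.  A thermodynamic folder could be swapped in
behind the same interface.

**Trim.** The original procedure shortened the ~900-bp window by hand;
`fold_and_trim()` makes this deterministic: sub-windows centred on the
mature are folded at increasing half-widths (60, 90, 130, 180, 250,
350, 450 nt), and the first structure passing validation is trimmed to
the minimal span covering mature + miR\* plus `flank_keep` = 5 nt, then
refolded and re-validated.

**Validation.** A hairpin is accepted iff (a) the mature lies entirely
in one arm, (b) ≥ `min_paired` = 15 of its 22 positions pair to the
opposite arm, (c) no asymmetric bulge > `max_bulge` = 4 nt interrupts
the miR/miR\* duplex, and (d) the duplex closes a *single* terminal
loop — the stem may continue inward past the mature's partners, but a
bifurcation between the duplex's inner ends (a multiloop) is a
rejection.  These thresholds are not facts from any one study — the
source procedure accepted "promising" structures by eye — they follow
common plant-miRNA annotation practice and are exposed as arguments.
Rejections carry machine-readable reasons (`window_too_short`,
`no_stem`, `mature_in_loop`, `duplex_too_weak`, `multiloop`).

**miR\*.** The star is read off the accepted structure's pairing map:
partners of the mature block, shifted to leave a 2-nt 3′ overhang on
each duplex end (Dicer convention), clipped at precursor bounds.
Bulges shift the coordinates implicitly because partners, not offsets,
are used; a bulged star arm yields a star longer than 22 nt.

## 2. Region-partitioned substitution rates

Each precursor is tiled into five spans: 5′-stem, miR\*, loop (strictly
between the duplex spans), miR, 3′-stem, in mirrored order when the
mature is on the 5′ arm.  Within a precursor group (aligned orthologous
precursors), per-region fixed differences are counted per member pair:
a column counts iff both rows carry non-gap bases that differ — gap
columns contribute nothing.  Counting indels as single events is
available (`--count-indels` semantics via the per-column rule) but off
by default: the rate formula's length normalisation already absorbs
length differences.  The region mask is projected through the alignment
from a reference member (the longest ungapped sequence, by default);
per-member partitions supply the per-member region lengths.

The pairwise rate is `diffs / max(len_A, len_B) / (2 T)` with `T` the
divergence time in Myr — the age of the two tips' most recent common
ancestor in the chronogram (ultrametricity enforced to a relative 1e-6).
Rates are averaged per group over all pairs with `T` > 0; same-species
duplicate pairs (T = 0) are excluded and counted.  Whether only
cross-species pairs should enter the average is genuinely ambiguous in
the source procedure; the default is all T > 0 pairs, with a
`cross_species_only` switch.

**Saturation.** The default estimator uses raw differences, exactly as
published.  Raw distances saturate: for `2kT` ≳ 0.75 the estimator
materially under-reports the true rate (at `2kT` = 1.0 the expected raw
proportion is 0.553 of sites, i.e. the loop rate of the default scenario
is reported near 0.0055 rather than 0.01).  `correct = TRUE` applies the
exact Jukes–Cantor inversion `d = −¾ ln(1 − 4p/3)` before the time
division and is what the simulation-recovery tests use; it returns `NA`
when p ≥ 0.75.

## 3. Target expectation scoring

Scoring follows the published psRNATarget-style scheme; the analysis
cutoffs (strict ≤ 2.0, relaxed > 2.0–3.0) are the only values fixed by
the source analysis, so all constants are arguments: per position from
the miRNA 5′ end, Watson–Crick match 0, G·U 0.5, mismatch 1.0, gap 2.0,
each doubled at seed positions 2–13.  At most one gap per duplex: the
server behind the scheme permits very few gaps and unbounded gapping
explodes the search space.  A gap on the target side leaves a miRNA
position unpaired; an inserted target base sits between two miRNA
positions and is penalised at the index of the following position (a
convention this package fixes, since none is published).  `scan_cds()`
enumerates every ungapped window and all single-gap variants and
reports the minimum-expectation duplex per non-overlapping locus, ties
broken by smaller offset then fewer gaps.  A central-mismatch flag
(positions 9–11) marks candidate translational repression but never
filters anything.  The search is CDS-only; UTRs and duplex
thermodynamics are out of scope.

## 4. Network statistics

The targeting network has one directed edge per (miRNA, gene) best
site, plus undirected homology edges derived from family/species
labels: paralog = same family and species, ortholog = same family,
different species; never across families.  Genes without a predicted
site remain as isolated nodes so that targeted fractions have the full
denominator.

*Unique vs shared*: a target is unique to a miRNA iff it is the gene's
only incoming miRNA.  *Sharing*: for every unordered homologous pair of
the requested relation, the incoming miRNA id sets are compared
(`frac_share_any` = intersecting, `frac_identical` = equal); pairs where
both sets are empty are excluded and counted.  The published sharing
percentages never state whether the unit is the pair or the gene, so
both are implemented (`unit = "pair"` default, `unit = "gene"` = a gene
shares if any of its homologs does) and neither is asserted as *the*
published definition.  An optional `canonical` mapping normalises
species-prefixed miRNA names before cross-species comparison.

*Family size vs miRNA count*: Spearman's ρ with mid-ranked ties;
p-value by exhaustive permutation (all distinct arrangements of the
rank vector, two-sided) for n ≤ 10 families, t-approximation above.

Exports: a native single-table TSV (node and edge records; byte-stable
round-trip through `import_network()`), GraphML via igraph, and SIF.
Fuzzy cluster visualisation is explicitly out of scope.

## 5. Duplication context

For each *MIR* locus, the `k` = 10 nearest protein-coding genes per
side by interval-midpoint distance (ties to the lower start
coordinate).  A tandem call requires the same chromosome, no coding
gene between the loci, and identical unions of flanking sets — the
classic "identical ten flanking genes, nothing in between" rule.  A
segmental call lays both flank lists in chromosomal order and looks for
a colinear run of ≥ `min_run` = 3 consecutive homologous genes
(homology from a precomputed pair table, e-value < 1e-4, symmetrised);
inversions are deliberately not matched because the procedure orders
matches by chromosome location.  The e-value cutoff was printed as
"10e-04" in the source methods — literally 1e-3, conventionally 1e-4;
the package defaults to 1e-4 and leaves it an argument.  A
chromosome whitelist (a dataset-specific filter in the original
analysis) can be applied by pre-filtering the annotation.

## 6. The synthetic world

The generators emit every input the pipeline consumes, with truth
records that tests resolve against the emitted files.

* `make_hairpin()` builds templates matching the canonical precursor
  topology: a designed stem (≥ 22 bp so the mature fits), G·U wobbles
  that stay paired, single-base bulges confined to the arm opposite the
  mature, and a 22-nt mature centred in its arm.  Loop bases come from
  {A, C} only — a deliberate departure from real loops that makes the
  designed structure the unique maximum-pairing structure, so structure
  recovery is exactly testable.
* `evolve_family()` runs Jukes–Cantor per site at the site's
  region-specific rate along an ultrametric tree (substitution
  probability `¾(1 − e^{−4kt/3})` per branch, new base uniform over the
  three alternatives).  No indels: real precursors vary in length
  (roughly 84–171 bp) under an unknown indel process that we do not
  attempt to emulate — this is the main respect in which a green test
  says nothing about real data, and it is also why per-tip alignments
  are trivially exact.
* `plant_genome()` embeds templates and mature-mutated copies (half
  reverse-complemented) in an i.i.d. uniform background, with
  dinucleotide-shuffled (Altschul–Erickson) templates as decoys —
  composition preserved, stems destroyed, isolating the structure
  filter.  Uniform background underestimates the repeat content of real
  genomes; transposon-derived false candidates are not modelled.
* `make_target_set()` builds two-species gene families ("spA"/"spB",
  mirroring a tomato/potato comparison) and plants reverse-complement
  windows edited to an exact designed penalty: a half-unit uses a
  non-seed G·U (requires a G/U in the miRNA there — reported as
  unreachable otherwise, with the closest achievable value), integer
  units use one seed mismatch (2.0) then non-seed mismatches.  Each
  site goes into both species' copy of the named member, giving
  orthologs shared sites as in the real network.  Backgrounds are
  scrubbed until no non-planted window scores ≤ 3.0.

**Default scenario** (`run_pipeline()`): an 8-tip chronogram of depth
50 Myr containing an 8-Myr terminal split (the tomato–potato scale);
region rates 0.001 (stems), 0.0005 (miR, miR\*), 0.01 (loop)
substitutions/site/Myr — miR/miR\* most constrained, loop fastest, the
canonical plant-miRNA pattern; three hairpin templates (stems 26–34,
wobbles and bulges), three mutated copies at 1–3 mature mismatches,
five decoys in 50 kb; five target families of sizes 4,3,2,2,1 with
planted penalties spanning 0–3.0 and several genes targeted by two
miRNAs, so redundancy statistics are non-degenerate.  These values were
chosen once as a realistic stated world and are not tuned to test
outcomes.

## 7. Numerical and design choices

* Determinism: every generator takes a `seed` and restores the caller's
  RNG state; equal seeds give byte-identical outputs (tested).
* The ordering-recovery property for region rates is evaluated on
  groups of three replicate loci: single 22-nt regions at rates of
  4e-4 vs 1e-3 differ by fractions of an expected substitution per
  pair, so single-locus rank recovery is noise-limited — just as real
  rate comparisons average within precursor groups of several members.
* Exact permutation p-values enumerate all distinct rank arrangements
  (ties collapse duplicates), so tied data are handled without
  approximation for n ≤ 10.
* Degenerate inputs: empty genomes yield empty hit tables; sharing
  summaries with zero included pairs report `NA` fractions and
  `n_pairs` = 0; a constant family-size vector yields `NA` ρ with a
  warning; `T` ≤ 0 in the rate formula and non-ultrametric chronograms
  are errors.
* Known limitations: no small-RNA read-stack evidence, no phasiRNA
  production, no expression modelling, no genome-wide de-novo miRNA
  annotation, no thermodynamic folding, no phylogeny inference (trees
  and family maps are consumed as inputs).
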