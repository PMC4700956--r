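# mirevo

Evolutionary analysis of clustered plant miRNA gene families that
regulate **NBS-LRR disease-resistance (R-) genes** — the situation typified
by the 22-nt miR482/2118 superfamily in the Solanaceae, whose members
target the conserved P-loop motif of *R*-gene transcripts and whose
precursors evolve under sharply region-specific constraint.

`mirevo` implements the full desk analysis as tested, reusable R code:

1. **Hairpin discovery** — scan a genome for mature-miRNA matches
   (Hamming distance ≤ 3 over both strands), cut a ±450 bp candidate
   window, fold it, trim deterministically to a minimal hairpin, validate
   the structure, and locate the miR\* span from the pairing map under
   the Dicer 2-nt 3′-overhang convention.
2. **Region-partitioned substitution rates** — tile each precursor into
   5′-stem / miR\* / loop / miR / 3′-stem, count fixed differences per
   region within an orthologous precursor group, and convert them to
   substitutions · site⁻¹ · Myr⁻¹ with

   `rate = diffs / max(len_A, len_B) / (2 T)`

   where `T` is the divergence time read off an ultrametric chronogram.
3. **Target prediction** — psRNATarget-style expectation scoring
   (match 0, G·U 0.5, mismatch 1, gap 2; penalties doubled at seed
   positions 2–13), with the strict (≤ 2.0) and relaxed (> 2.0–3.0)
   cutoffs.
4. **Targeting-network statistics** — the bipartite miRNA→gene network
   with ortholog/paralog homology edges; unique vs shared targets per
   miRNA, sharing fractions over homologous gene pairs, Spearman
   correlation of *R*-gene family size with miRNA count (exact
   permutation p for n ≤ 10), targeted fractions per species, and
   TSV/GraphML/SIF export.
5. **Duplication context** — the ten nearest flanking protein-coding
   genes per side of each *MIR* locus; tandem calls (same chromosome, no
   intervening coding gene, identical flanking sets) and segmental calls
   (≥ 3 colinear homologous flanking genes below an e-value cutoff).
6. **Synthetic data** — seeded generators for every input with known
   ground truth: designed hairpin templates, region-rate evolution under
   Jukes–Cantor along a chronogram, genomes with planted loci and
   dinucleotide-shuffled decoys, and two-species CDS sets with target
   sites planted at exact designed penalties.

## Worked example

```r
library(mirevo)

h <- make_hairpin(stem_len = 30, loop_len = 6, n_wobbles = 2,
                  mature_arm = "3p", seed = 11)
h
#> <precursor hairpin_s11> 66 nt, mature [40,62) on three' arm, star [6,28)
#> CCGATAATCTACCCGCAGAGGACAGTGGCGCACACCTGCCACTGTCCTCTGCGGGTAGATTATTGG
#> ((((((((((((((((((((((((((((((......))))))))))))))))))))))))))))))

gen  <- plant_genome(list(h), n_decoys = 3, bg_len = 20000, seed = 5)
hits <- scan_genome(c(miR_test = mature_seq(h)), gen$genome)
hits
#>   query_id contig start   end strand mismatches
#> 1 miR_test   ctg1 11584 11606      -          0
#> 2 miR_test   ctg1 11620 11642      +          0

p <- fold_and_trim(extract_candidate(hits[2, ], gen$genome))
validate_hairpin(p)$n_paired
#> [1] 22
```

Both hits sit on the planted locus: the mature matches on the forward
strand and, because the hairpin is nearly self-complementary, its miR\*
arm matches on the reverse strand — exactly what happens with real
precursors.  The folded candidate trims back to the planted 66-nt
hairpin with all 22 mature positions paired.

The assembled pipeline on the default synthetic scenario:

```r
res <- run_pipeline("out", seed = 1)
res$rates
#>   group_id      region    mean_rate           sd n_pairs n_excluded
#> 1     grp1  five_prime 0.0004613095 0.0008204191      28          0
#> 2     grp1    mir_star 0.0006870362 0.0005750216      28          0
#> 3     grp1        loop 0.0074404762 0.0025063302      28          0
#> 4     grp1         mir 0.0007183442 0.0005844093      28          0
#> 5     grp1 three_prime 0.0000000000 0.0000000000      28          0
```

The loop evolves an order of magnitude faster than miR/miR\* (truth:
0.01 vs 0.0005 substitutions/site/Myr; the default raw-difference
estimator under-reports the loop rate at this tree depth because raw
distances saturate — `group_region_rates(..., correct = TRUE)` applies
the Jukes–Cantor inversion and recovers ≈ 0.010).

```r
res$sharing$ortholog
#> <sharing_summary ortholog/pair> n=26 (excluded 8) share_any=0.3076923 identical=0.2307692
res$correlation[c("rho", "p_value")]
#> $rho      0.895
#> $p_value  0.0667   (exact permutation, n = 5 families)
```

`run_pipeline()` writes every declared artifact (genome/CDS/precursor
FASTA, structure file, hits BED, rates TSV, sites TSV, score matrix,
network TSV/GraphML/SIF, summary JSON, synteny calls TSV) under the
output directory.  A command-line front end with `simulate`, `discover`,
`rates`, `targets`, `network` and `synteny` subcommands lives at
`inst/cli/mirevo.R`.

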