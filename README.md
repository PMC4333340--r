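# exclumap

Simulation and fine-mapping of incompletely penetrant, incompletely
dominant loci in experimental rodent crosses.

`exclumap` is for geneticists working the classic route from a spontaneous
Mendelian phenotype to its causal variant: large F2 intercrosses, exclusion
mapping from affected-animal genotypes, recombinant progeny testing,
marker-assisted congenic strains, and a strain-unique variant screen. The
bundled worked example is the rat *Renag1* locus on chromosome 14, where
unilateral renal agenesis (URA) in ACI rats maps to intron 1 of *Kit* and
an endogenous-retrovirus LTR insertion shared with the *Hooded*
coat-colour locus.

## The core logic

For a dominant causal allele with penetrances
`p_NN = 0 < p_CH < p_CC` (non-carrier / heterozygote / homozygous
carrier), every affected animal carries at least one carrier allele, so an
affected animal homozygous non-carrier at a marker **excludes** that
marker from the locus. Candidate intervals are the maximal runs of
non-excluded markers, reported between the nearest excluding markers
(outer-bound convention). The recessive mirror image retains only markers
at which every phenotype-positive animal is homozygous-recessive.

Simulated meioses use the Haldane map function
`r(d) = (1 - exp(-2d/100))/2` on a marker grid, with the causal position
carried as a pseudo-marker; phenotypes are drawn per genotype from a
penetrance/anomaly-class/laterality model (defaults: `p_CC = 0.134`,
`p_CH = 0.067`, URA/URH/HUN mix 0.678/0.188/0.134, URA right-sided with
probability 0.84).

## Worked example

Fifty-four affected F2 recombinants, genotyped at nine chromosome 14
microsatellites:

```r
library(exclumap)
fx <- renag1_exclusion_fixture()
map_dominant_exclusion(fx$genotypes, fx$map)
#> dominant-exclusion mapping report (tolerance 0): 9 markers, 1 interval(s)
#>    marker chrom pos_mb       status n_excluding n_observed
#>  D14Rat78    14  17.42     EXCLUDED          30         54
#>   D14Arb6    14  22.00     EXCLUDED          30         54
#>   D14Uwm7    14  34.25     EXCLUDED          30         54
#>   D14Uwm8    14  34.73 NOT_EXCLUDED           0         54
#>   D14Uwm9    14  35.11 NOT_EXCLUDED           0         54
#>  D14Uwm12    14  36.25     EXCLUDED          24         54
#>  D14Rat65    14  36.41     EXCLUDED          24         54
#>  D14Rat15    14  42.72     EXCLUDED          24         54
#>  D14Rat88    14  65.96     EXCLUDED          24         54
#> Candidate interval chr14: D14Uwm7 (34.25 Mb) .. D14Uwm12 (36.25 Mb) [width 2.00 Mb]
```

Every marker at or outside the D14Uwm7/D14Uwm12 flanks is excluded by at
least one affected animal homozygous for the non-carrier (BN) allele; the
two interior markers never are. The locus lies in the 2.0 Mb interval
between the excluding flanks.

Progeny testing of the six recombinant chromosomes that confer the
phenotype intersects their outer bounds down to the 0.38 Mb gap between
D14Uwm8 (34.73 Mb) and D14Uwm9 (35.11 Mb) — a single protein-coding gene,
*Kit*:

```r
pg <- renag1_progeny_fixture()
intersect_conferring_segments(pg$results)
#> Progeny-test refinement from 6 conferring segment(s)
#>   conservative: Candidate interval chr14: D14Uwm8 (34.73 Mb) .. D14Uwm9 (35.11 Mb) [width 0.38 Mb]
#>   minimal: empty (locus localized to overlapping uncertainty gaps)
```

Incidence and laterality statistics, and the diagnostic PCR logic for the
three-allele insertion polymorphism in *Kit* intron 1:

```r
incidence(351, 4994)           # F2 incidence
#> 351/4994 = 7.0% (95% CI 6.3-7.8%)
side_bias_test(200, 238)       # URA right-side bias, exact binomial
#> [1] 9.583627e-28
fisher_exact_2x2(rbind(c(49, 189), c(35, 263)))  # congenic 1 vs 2
#> [1] 0.005901014

pairs <- kit_primer_pairs()
predict_amplicon(pairs$AB, insertion_allele("SELF_EMPTY"))         # 1006
predict_amplicon(pairs$AB, insertion_allele("IRISH_SOLITARY_LTR")) # 1590
predict_amplicon(pairs$AB, insertion_allele("HOODED_FULL_ERV"))    # NA (too long)
predict_amplicon(pairs$CD, insertion_allele("HOODED_FULL_ERV"))    # 997
```

And the variant screen: across two ACI, two BN, one COP and one F344
sequence, none of the five *Kit* SNPs is unique to ACI (the solitary-LTR
insertion, invisible to reference-mapped SNP tables, is):

```r
scr <- unique_variants(kit_snp_calls(), "ACI", c("BN", "COP", "F344"))
nrow(scr$candidates)  #> 0
scr$discordant$pos    #> 34945200 34903999  (within-strain disagreements)
```

## Simulation

```r
map <- renag1_marker_map()
sim <- simulate_f2(20000, map, causal_pos_mb = 34.96, seed = 1)
mean(sim$phenotypes$anomaly != "NONE")   # ~0.067 = 0.25*0.134 + 0.5*0.067
cs  <- simulate_congenic_program(congenic_sim_map(), "14",
                                 c(34.25, 36.25), seed = 1)
```

`run_pipeline(run_config(seed = 1))` chains
simulate → exclusion-map → progeny-test → stats and emits a TSV/JSON
artifact bundle with an md5 manifest; runs are byte-reproducible given the
seed.

## Command line

An `exclumap` script is installed under `exec/`:

```sh
exclumap simulate-cross --design f2 --n 2000 --seed 1 --out-prefix out/f2
exclumap map-exclusion --genotypes g.tsv --phenotypes p.tsv --map m.tsv
exclumap stats fisher --a 49 --b 189 --c 35 --d 263
exclumap amplicon --pair AB --allele irish
exclumap make-fixtures --out-dir fixtures/
```

## Package layout

- `R/genome_model.R`, `R/io.R` — maps, genotype/phenotype tables, TSV I/O,
  validation
- `R/cross_sim.R`, `R/congenic.R` — F2/backcross meiosis simulation,
  penetrance model, congenic breeding programs
- `R/fine_mapping.R` — dominant exclusion / recessive inclusion mappers,
  containment validation
- `R/progeny_testing.R` — donor-segment inference, conferring-segment
  intersection, recombinant classification
- `R/incidence_stats.R` — exact incidence/Fisher/laterality statistics
- `R/variant_screen.R`, `R/amplicon.R` — strain-unique variant screen
  (VCF via VariantAnnotation), insertion-allele PCR logic
- `R/fixtures.R`, `R/pipeline.R`, `R/cli.R` — worked-example fixtures,
  end-to-end pipeline, CLI

See `vignettes/exclusion-mapping-methods.Rmd` for the model, conventions
and limitations.
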