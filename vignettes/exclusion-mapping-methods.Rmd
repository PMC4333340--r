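---
title: "Methods: cross simulation and exclusion fine-mapping of a dominant locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross simulation and exclusion fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exclumap)
```

# The problem

A spontaneous congenital anomaly — unilateral renal agenesis (URA) and its
milder relatives, unilateral renal hypoplasia (URH) and
hydroureteronephrosis (HUN) — segregates in crosses between a carrier
inbred rat strain (ACI) and non-carrier strains (BN, COP) as a trait driven
by a single autosomal locus on chromosome 14, *Renag1*. The locus is
**incompletely dominant** (heterozygotes express at roughly half the
homozygous-carrier rate) and **incompletely penetrant** (most carriers are
unaffected). Those two properties dictate the whole analytical strategy
implemented here:

1. because one carrier allele suffices, *every affected animal carries at
   least one carrier allele at the locus*; an affected animal homozygous
   for the non-carrier allele at a marker therefore **excludes** that
   marker from the locus (`map_dominant_exclusion()`);
2. because penetrance is incomplete, unaffected animals carry no usable
   information, and large F2 populations are needed to accumulate affected
   recombinants;
3. recombinant chromosomes are individually **progeny tested** — backcrossed
   to the recipient strain and scored for affected offspring — and the
   outer bounds of the phenotype-conferring segments are intersected
   (`intersect_conferring_segments()`);
4. congenic strains carrying only the candidate segment on the recipient
   background confirm sufficiency (`simulate_congenic_program()` models the
   marker-assisted breeding);
5. within the final interval, the causal variant must be **unique to the
   carrier strain** across all sequenced strains (`unique_variants()`), and
   a structural insertion allele is typed by diagnostic PCR product sizes
   (`predict_amplicon()`).

The recessive mirror image, `map_recessive_inclusion()`, handles loci where
the phenotype requires homozygosity for the recessive allele (the hooded
coat-colour allele in the ACI x COP cross): a marker is retained only where
every phenotype-positive animal is homozygous-recessive.

# The simulation model

## Meiosis

Gametes are simulated on the locus grid of each chromosome (its markers,
plus the causal position inserted as a pseudo-marker). Physical positions
(Mb) are converted to genetic positions (cM) linearly at `cm_per_mb`
(default 0.5 cM/Mb, a typical rat autosomal average; the true local
recombination landscape of the mapped region is unknown, so the rate is
configurable everywhere and all mapping logic depends only on marker
*order*). Between adjacent loci at distance $d$ cM, a recombination occurs
with the Haldane (no-interference) probability

$$ r(d) = \tfrac12\left(1 - e^{-2d/100}\right), $$

drawn independently per interval. This matches the closed form used by the
tests, so Monte-Carlo recombinant fractions can be checked against an
analytic oracle.

Crossovers are realized **at marker resolution**: a gamete is the ancestry
state at each locus, and a crossover between discordant adjacent markers is
located somewhere inside that interval. No explicit within-interval
breakpoint coordinate is sampled, because every downstream query —
genotype calls, donor-segment inference, interval containment — is made at
marker positions, and a true breakpoint necessarily lies inside the
inferred uncertainty gap between the outermost carrier call and the nearest
non-carrier call.

## Phenotype

Each animal's phenotype is drawn from `penetrance_model()` conditional on
its causal-locus genotype:

| parameter | default | meaning / origin |
|---|---|---|
| `p_CC` | 0.134 | penetrance in homozygous carriers — the carrier-strain cohort incidence (29/216) |
| `p_CH` | 0.067 | penetrance in heterozygotes — half of `p_CC`, the incomplete-dominance observation |
| `p_NN` | 0 | phenocopy rate; 0 reflects the working assumption that the locus is the sole determinant |
| `class_mix` | 0.678/0.188/0.134 | URA/URH/HUN split among affected animals, the observed anomaly spectrum |
| `q_right` | 0.84 | probability a URA is right-sided (200/238 observed); set 0.5 to emulate the congenic background, where the bias disappears |
| `p_bilateral_hun` | 0 | bilateral HUN probability (2/4994 observed; negligible) |

Expected F2 incidence under the defaults is
$0.25\,p_{CC} + 0.5\,p_{CH} = 0.067$, close to — but deliberately not tuned
to — the observed 7.0% (351/4994): the published heterozygote penetrance is
stated only as "approximately half" the homozygote value, so the model uses
exactly half and the tests assert against the *model expectation*, not the
observed cohort value.

Laterality is a phenotype-model parameter, not a second simulated locus.
The right-side bias evidently maps outside the primary locus (it vanishes
on the congenic background), but no position for the modifier is known, so
simulating one would be invention. URH and HUN sides are uniform (no
significant bias was observed for those classes). Sex is not simulated:
incidence is reported to be similar in males and females.

## What the generator does and does not emulate

Emulated: F2 1:2:1 segregation, Haldane recombination on an arbitrary
marker map, the penetrance/class/laterality model above, backcross progeny
testing from any stored haplotype pair, and multi-generation
marker-assisted congenic breeding (positive selection for donor-interval
heterozygosity each generation; negative selection on background markers
from generation `negative_selection_start`, default N5; 20 progeny screened
per generation — a realistic multi-litter screen; final sib intercross).

Not emulated: crossover interference (Haldane is interference-free),
litter/pedigree structure, maternal effects, X-linkage, multi-locus
epistasis, genotyping error, and selection on phenotype during breeding. A
green simulation-based test therefore establishes correctness of the
mapping logic *under this stated world*, not robustness to, e.g.,
genotyping error — which enters the mappers only through the explicit
`tolerance` parameter.

# Numerical and convention choices

* **Outer-bound convention.** A candidate interval is reported *between the
  nearest excluding markers*: the quoted bounds are themselves excluded
  positions. This matches how flanking-marker intervals are conventionally
  quoted (the worked example's "2.0 Mb interval defined by D14Uwm7 and
  D14Uwm12" spans 34.25–36.25 even though both bound markers are excluded).
  A side with no excluding marker is reported unbounded, never silently
  clipped to the map end.
* **Missing calls are non-informative by fiat**: exclusion requires a
  positive observation of non-carrier homozygosity, and inclusion mapping
  likewise only counts observed violations. A marker with no observed call
  is `NON_INFORMATIVE` and joins candidate runs (it cannot contradict
  them).
* **Phenocopy tolerance** defaults to 0 — every affected animal is treated
  as a carrier. It is exposed because URH/HUN could in principle be
  phenocopies; `containment_probability()` shows how tolerance restores
  interval coverage when `p_NN > 0`.
* **Multiple candidate runs** are all reported, ranked by number of
  supporting animals (ties: wider first). The worked example yields a
  single run.
* **Progeny-test intersection.** The headline (conservative) interval is
  the intersection of *outer* bounds of all conferring segments, optionally
  intersected with a prior interval and clipped at positions excluded by
  genotyped affected progeny. The *minimal* interval (intersection of inner
  segments) is diagnostic only — it is legitimately **empty** when two
  conferring chromosomes break from opposite sides within the same marker
  gap, which is precisely the configuration that pins the locus to that
  gap. A segment "confers" with any affected progeny (`n_affected >= 1`);
  penetrance-based gating is deliberately avoided because expected affected
  counts per tested litter are small (about `p_CH` per progeny).
* **Exact tests.** `fisher_exact_2x2()` uses the minimum-likelihood
  two-sided rule (sum all hypergeometric outcomes no more probable than the
  observed one, relative tolerance 1e-7) — the convention of the R
  implementation historically used for such data, reproducing its p-values
  exactly. The laterality test is the analogous exact binomial against 0.5;
  a Fisher-style variant (observed split vs an equal-sized balanced
  pseudo-group) is available behind `method = "fisher"` because the exact
  construction behind published side-bias p-values is ambiguous. Reported
  p-value floors (2.2e-16) are reproduced as inequalities only.
* **Clopper–Pearson 95% intervals** accompany every incidence; they are
  additive (no intervals were published) but standard for small-count
  anomaly data.
* **Degenerate inputs.** Empty animal sets error; an all-excluded marker
  set returns an empty interval list plus a diagnostic rather than
  erroring (it is a legitimate, informative outcome); a congenic
  generation with no heterozygous candidate is reported as a failed
  program, not an exception.

# Variant screen and insertion-allele logic

A candidate variant must be non-reference in *every* sequence of the
carrier strain and reference in *every* sequence of every contrast strain.
Sequences of one strain that disagree at a position make it `DISCORDANT`;
such positions are reported separately and never silently dropped nor
adjudicated — multiple independent sequences of the same inbred strain do
disagree in practice, and resolving them is a wet-lab question. Absent
rows default to the reference state, the usual convention of variant
tables.

The insertion-allele PCR model captures a three-allele structural
polymorphism: empty site (0 bp), solitary LTR (584 bp), full ERV
(7098 bp, the only allele containing the element-internal primer site).
A site-flanking pair amplifies `empty_site_product + insert_length`, with
`max_amplifiable_bp = 5000` as the practical ceiling of standard PCR (the
full-ERV allele's 8104 bp predicted product yields no band); an internal
pair amplifies a fixed product only when the internal site is present —
that product length is a *parameter*, because the internal primer's offset
within the element is not derivable from published flanking coordinates.
`genotype_from_products()` inverts the model over all six
homozygous/heterozygous combinations; observed band sets must match
predicted band unions exactly.

# Known limitations

* The linear cM/Mb conversion is a stand-in; no genetic map length for the
  chromosome is published. All interval *coordinates* are physical, so
  this affects only recombination rates in simulation.
* The progeny-testing fixture encodes the six conferring chromosomes
  structurally; per-chromosome progeny counts were published only
  graphically and are plausible stand-ins, never asserted.
* The published 379 kb progeny-test interval width is not reproduced as an
  exact number: the printed flank coordinates (34.73, 35.11 Mb) imply
  380 kb and the underlying base-pair marker positions are unpublished.
  The package asserts the bounds, not the rounded width.
* Congenic cohort affected counts are reconstructed from printed
  percentages and cohort sizes; the associated significance tests are
  checked at the alpha = 0.05 level rather than to printed p-value digits.
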