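Package: exclumap
Title: Simulation and Exclusion Fine-Mapping of Incompletely Penetrant
    Dominant Loci in Experimental Rodent Crosses
Version: 0.1.0
Authors@R:
    person("Exclumap", "Developers", email = "exclumap@example.org",
           role = c("aut", "cre"))
Description: Forward simulation of F2 intercrosses, backcrosses and
    marker-assisted congenic breeding programs segregating a biallelic,
    incompletely dominant and incompletely penetrant causal locus;
    exclusion mapping of dominant carrier alleles and inclusion mapping
    of recessive alleles from phenotype-positive genotypes; recombinant
    chromosome classification and progeny-test interval intersection;
    exact categorical statistics (Fisher's exact 2x2 test, exact binomial
    laterality test, Clopper-Pearson incidence intervals); and a
    strain-unique variant screen with insertion-allele PCR amplicon
    prediction. The worked example throughout is the rat Renag1 locus on
    chromosome 14, where a solitary endogenous-retrovirus LTR in Kit
    intron 1 segregates with unilateral renal agenesis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
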