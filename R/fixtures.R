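# Worked-example fixtures for the rat Renag1/Hooded locus on chromosome 14.
# Marker names and Mb positions, population counts, insertion-allele sizes
# and diagnostic product lengths are the published values; genotype
# patterns are reconstructed structurally (which markers were excluded by
# which recombinant class), since per-animal tables were published only
# graphically. Everything is generated in code — no data files.

#' Marker map for the chromosome 14 worked example
#'
#' The nine microsatellite markers with published Mb positions spanning
#' the region: D14Rat78 (17.42), D14Arb6 (22.00), D14Uwm7 (34.25),
#' D14Uwm8 (34.73), D14Uwm9 (35.11), D14Uwm12 (36.25), D14Rat65 (36.41),
#' D14Rat15 (42.72), D14Rat88 (65.96).
#'
#' @param cm_per_mb linear conversion rate for genetic positions.
#' @return a [genetic_map()].
#' @export
renag1_marker_map <- function(cm_per_mb = 0.5) {
  genetic_map(
    marker = c("D14Rat78", "D14Arb6", "D14Uwm7", "D14Uwm8", "D14Uwm9",
               "D14Uwm12", "D14Rat65", "D14Rat15", "D14Rat88"),
    chrom = "14",
    pos_mb = c(17.42, 22.00, 34.25, 34.73, 35.11, 36.25, 36.41, 42.72,
               65.96),
    cm_per_mb = cm_per_mb)
}

#' Exclusion-mapping fixture: affected F2 recombinants
#'
#' Genotypes of 54 affected F2 animals carrying recombinations across the
#' locus, reconstructed structurally: 30 animals homozygous non-carrier
#' (BN) proximally up to D14Uwm7 and heterozygous beyond, 24 heterozygous
#' proximally and homozygous non-carrier from D14Uwm12 distally. Every
#' marker at or outside the D14Uwm7/D14Uwm12 flanks is excluded by at
#' least one animal; the interior markers never are, so dominant exclusion
#' mapping returns the 2.0 Mb interval 34.25-36.25.
#'
#' @return list with `map`, `genotypes`, `phenotypes`.
#' @export
renag1_exclusion_fixture <- function() {
  map <- renag1_marker_map()
  left_type <- c("N", "N", "N", "H", "H", "H", "H", "H", "H")
  right_type <- c("H", "H", "H", "H", "H", "N", "N", "N", "N")
  calls <- rbind(
    matrix(rep(left_type, 30), nrow = 30, byrow = TRUE),
    matrix(rep(right_type, 24), nrow = 24, byrow = TRUE))
  ids <- sprintf("F2-R%02d", seq_len(54))
  dimnames(calls) <- list(ids, map$marker)
  anomaly <- c(rep("URA", 37), rep("URH", 10), rep("HUN", 7))
  side <- c(rep("RIGHT", 31), rep("LEFT", 6),    # URA, right-biased
            rep(c("RIGHT", "LEFT"), 5),          # URH
            rep(c("RIGHT", "LEFT"), length.out = 7))
  list(map = map, genotypes = genotype_matrix(calls),
       phenotypes = phenotype_table(ids, anomaly, side))
}

#' Inclusion-mapping fixture: hooded-phenotype F2 animals
#'
#' Coat-colour mapping in the ACI x COP cross: the hooded allele is the
#' recessive COP (non-carrier) allele, so every hooded-phenotype animal
#' must be homozygous non-carrier at the locus. 40 animals, homozygous
#' COP at every marker strictly inside D14Arb6-D14Rat15 with some animal
#' heterozygous at each marker at or outside the flanks; recessive
#' inclusion mapping returns the 20.72 Mb interval 22.00-42.72.
#'
#' @return list with `map`, `genotypes`.
#' @export
hooded_inclusion_fixture <- function() {
  map <- renag1_marker_map()
  left_type <- c("H", "H", "N", "N", "N", "N", "N", "N", "N")
  right_type <- c("N", "N", "N", "N", "N", "N", "N", "H", "H")
  calls <- rbind(
    matrix(rep(left_type, 22), nrow = 22, byrow = TRUE),
    matrix(rep(right_type, 18), nrow = 18, byrow = TRUE))
  ids <- sprintf("AC-F2-%02d", seq_len(40))
  dimnames(calls) <- list(ids, map$marker)
  list(map = map, genotypes = genotype_matrix(calls))
}

#' Progeny-testing fixture: six conferring recombinant chromosomes
#'
#' Marker calls for the six recombinant chromosomes proven by backcross
#' progeny testing to confer the phenotype. The two informative flanking
#' recombinants break between D14Uwm8 and D14Uwm9 from opposite sides, so
#' the outer-bound intersection is the 34.73-35.11 Mb interval (the
#' published candidate region containing only Kit); their inner donor
#' segments are disjoint, so the minimal interval is empty. Progeny counts
#' are plausible stand-ins (the published counts are graphical only) and
#' are not asserted anywhere.
#'
#' @return list with `map`, `calls` (matrix of marker calls, one row per
#'   recombinant), `results` (list of [progeny_test_result()]).
#' @export
renag1_progeny_fixture <- function() {
  map <- renag1_marker_map()
  calls <- rbind(
    `F2-4747p` = c("N", "N", "N", "N", "H", "N", "N", "N", "N"),
    `F2-3892`  = c("H", "H", "H", "H", "N", "N", "N", "N", "N"),
    `F2-3766`  = c("N", "N", "H", "H", "H", "H", "H", "H", "N"),
    `F2-3840`  = c("N", "H", "H", "H", "H", "H", "H", "N", "N"),
    `F2-4101`  = c("H", "H", "H", "H", "H", "H", "H", "H", "H"),
    `F2-4388`  = c("N", "N", "N", "H", "H", "H", "H", "H", "N"))
  colnames(calls) <- map$marker
  tested <- c(12, 22, 30, 26, 24, 20)
  affected <- c(1, 2, 3, 2, 1, 1)
  results <- lapply(seq_len(nrow(calls)), function(i)
    progeny_test_result(
      infer_donor_segment(calls[i, ], map,
                          animal_id = rownames(calls)[i]),
      tested[i], affected[i]))
  list(map = map, calls = calls, results = results)
}

#' Published population counts for the worked example
#'
#' The observed counts behind the incidence and laterality statistics:
#' the F2 population (4994 evaluated; 351 affected; 238 URA of which 200
#' right-sided; 66 URH; 47 HUN), the parental/congenic cohorts with
#' affected counts reconstructed from the printed percentages
#' (ACI 29/216 = 13.4%, Con1 49/238 = 20.6%, Con2 35/298 = 11.7%), and
#' the embryo screen (6 of 75 with asymmetric nephric-duct marker
#' expression, 4 right / 2 left).
#'
#' @return nested list of counts.
#' @export
renag1_observed_counts <- function() {
  list(
    f2 = list(n = 4994L, affected = 351L,
              ura = 238L, ura_right = 200L, urh = 66L, hun = 47L),
    strains = data.frame(
      strain = c("ACI", "Con1", "Con2"),
      n = c(216L, 238L, 298L),
      affected = c(29L, 49L, 35L),
      stringsAsFactors = FALSE),
    embryos = list(n = 75L, abnormal = 6L, right = 4L, left = 2L))
}

#' Kit SNP fixture: multi-strain, multi-sequence states at five SNPs
#'
#' The five SNPs found between carrier (ACI) and reference (BN) Kit
#' sequences, with the published cross-strain states: at every SNP the
#' non-reference state is shared with COP and/or F344, so none is unique
#' to ACI. Two positions (34,945,200 and 34,903,999) carry the published
#' within-strain disagreements between whole-genome and PCR-derived
#' sequences and surface as DISCORDANT.
#'
#' @return a [strain_variant_calls()] table.
#' @export
kit_snp_calls <- function() {
  seqs <- data.frame(
    strain = c("ACI", "ACI", "BN", "BN", "COP", "F344"),
    sequence_id = c("WGS1", "WGS2", "REF", "WGS2", "WGS", "WGS"),
    stringsAsFactors = FALSE)
  pos <- c(34947632, 34945425, 34945200, 34904134, 34903999)
  state <- rbind(                      # rows = sequences, cols = positions
    ACI_WGS1 = c("alt", "alt", "alt", "alt", "alt"),
    ACI_WGS2 = c("alt", "alt", "ref", "alt", "ref"),  # the discordant WGS
    BN_REF   = c("ref", "ref", "ref", "ref", "ref"),
    BN_WGS2  = c("ref", "ref", "ref", "ref", "ref"),
    COP_WGS  = c("alt", "alt", "alt", "alt", "alt"),
    F344_WGS = c("alt", "alt", "ref", "alt", "ref"))
  strain_variant_calls(
    strain = rep(seqs$strain, each = length(pos)),
    sequence_id = rep(seqs$sequence_id, each = length(pos)),
    chrom = "14", pos = rep(pos, nrow(seqs)),
    state = as.character(t(state)))
}

#' Write the worked-example fixtures to a directory
#'
#' Emits every bundled fixture as plain TSV: the marker map, the exclusion
#' and inclusion genotype/phenotype tables, the progeny-test calls and
#' counts, the strain incidence counts, the Kit SNP table, and the
#' primer-pair x allele amplicon table. All files pass [validate_tables()]
#' where applicable.
#'
#' @param output_dir writable directory (created if absent).
#' @return invisibly, the written paths.
#' @export
make_fixtures <- function(output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  ex <- renag1_exclusion_fixture()
  write_genetic_map(ex$map, p("renag1_map.tsv"))
  write_genotypes(ex$genotypes, p("renag1_exclusion_genotypes.tsv"))
  write_phenotypes(ex$phenotypes, p("renag1_exclusion_phenotypes.tsv"))
  hd <- hooded_inclusion_fixture()
  write_genotypes(hd$genotypes, p("hooded_inclusion_genotypes.tsv"))
  pg <- renag1_progeny_fixture()
  write_genotypes(genotype_matrix(pg$calls), p("renag1_progeny_calls.tsv"))
  counts <- data.frame(
    animal = rownames(pg$calls),
    n_tested = vapply(pg$results, `[[`, 0L, "n_progeny_tested"),
    n_affected = vapply(pg$results, `[[`, 0L, "n_affected"))
  utils::write.table(counts, p("renag1_progeny_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(renag1_observed_counts()$strains,
                     p("strain_incidence_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(kit_snp_calls(), p("kit_variant_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pairs <- kit_primer_pairs()
  alleles <- hooded_alleles()
  amp <- expand.grid(pair = names(pairs), allele = names(alleles),
                     stringsAsFactors = FALSE)
  amp$product_bp <- mapply(function(pr, al)
    predict_amplicon(pairs[[pr]], alleles[[al]]), amp$pair, amp$allele)
  utils::write.table(amp, p("amplicon_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stopifnot(nrow(validate_tables(ex$map, ex$genotypes,
                                 ex$phenotypes)) == 0L)
  invisible(list.files(output_dir, full.names = TRUE))
}
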