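test_that("the Kit SNP fixture yields no carrier-unique candidate", {
  scr <- unique_variants(kit_snp_calls(), "ACI", c("BN", "COP", "F344"))
  expect_identical(nrow(scr$positions), 5L)
  expect_identical(nrow(scr$candidates), 0L)
  # the two published within-strain disagreements surface as DISCORDANT
  expect_setequal(scr$discordant$pos, c(34945200, 34903999))
  expect_true(all(grepl("ACI", scr$discordant$discordant_strains)))
})

test_that("a strain contrasted with itself has no unique variants", {
  calls <- kit_snp_calls()
  scr <- unique_variants(calls, "ACI", "ACI")
  expect_identical(nrow(scr$candidates), 0L)
  expect_error(unique_variants(calls, "SHR", "BN"), "absent from calls")
})

test_that("interval filtering and a true candidate", {
  calls <- rbind(
    strain_variant_calls("ACI", c("s1", "s2"), "14", 100, "alt"),
    strain_variant_calls("BN", "s1", "14", 200, "alt"))
  scr <- unique_variants(calls, "ACI", "BN")
  expect_identical(scr$candidates$pos, 100)   # BN is ref at 100 by absence
  scr2 <- unique_variants(calls, "ACI", "BN", chrom = "14",
                          interval_mb = c(150, 250))
  expect_identical(nrow(scr2$candidates), 0L)
})

test_that("unique_variants matches a brute-force set comparison and is order-independent", {
  set.seed(515)
  oracle <- function(calls, carrier, contrasts) {
    seqs <- unique(calls[, c("strain", "sequence_id")])
    out <- numeric(0)
    for (p in sort(unique(calls$pos))) {
      st <- sapply(seq_len(nrow(seqs)), function(j) {
        r <- calls[calls$pos == p & calls$strain == seqs$strain[j] &
                   calls$sequence_id == seqs$sequence_id[j], ]
        if (nrow(r)) r$state[1] else "ref"
      })
      uniq <- all(st[seqs$strain == carrier] == "alt") &&
        all(st[seqs$strain %in% contrasts] == "ref")
      if (uniq) out <- c(out, p)
    }
    out
  }
  for (i in 1:50) {
    strains <- c("A", "B", "C")
    seqs <- data.frame(strain = rep(strains, each = 2),
                       sequence_id = rep(c("s1", "s2"), 3))
    pos <- sample(1:30, 6)
    rows <- expand.grid(j = seq_len(nrow(seqs)), pos = pos)
    keep <- runif(nrow(rows)) < 0.6
    calls <- strain_variant_calls(
      seqs$strain[rows$j[keep]], seqs$sequence_id[rows$j[keep]],
      "1", rows$pos[keep],
      sample(c("alt", "ref"), sum(keep), replace = TRUE,
             prob = c(0.7, 0.3)))
    scr <- unique_variants(calls, "A", c("B", "C"))
    expect_setequal(scr$candidates$pos, oracle(calls, "A", c("B", "C")))
    # shuffling the input rows changes nothing
    scr2 <- unique_variants(calls[sample(nrow(calls)), ], "A", c("B", "C"))
    expect_identical(scr$positions, scr2$positions)
  }
})

test_that("read_strain_vcf maps samples to strain sequences", {
  skip_if_not_installed("VariantAnnotation")
  d <- withr::local_tempdir()
  vcf <- file.path(d, "kit.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=14>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ACI_1", "ACI_2", "BN_1", sep = "\t"),
    paste("14", "34947632", ".", "G", "A", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/0", sep = "\t"),
    paste("14", "34945200", ".", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "0/0", "0/0", sep = "\t")), vcf)
  smap <- file.path(d, "samples.tsv")
  writeLines(c("sample\tstrain\tsequence_id",
               "ACI_1\tACI\tWGS1", "ACI_2\tACI\tWGS2", "BN_1\tBN\tREF"),
             smap)
  calls <- suppressWarnings(read_strain_vcf(vcf, smap))
  expect_identical(nrow(calls), 6L)
  scr <- unique_variants(calls, "ACI", "BN")
  expect_identical(scr$candidates$pos, 34947632)
  expect_identical(scr$discordant$pos, 34945200)
  expect_error(read_strain_vcf(vcf, file.path(d, "nope.tsv")),
               "not found")
})

test_that("predict_amplicon reproduces the full diagnostic band pattern", {
  pairs <- kit_primer_pairs()
  al <- hooded_alleles()
  expect_identical(predict_amplicon(pairs$AB, al$SELF_EMPTY), 1006L)
  expect_identical(predict_amplicon(pairs$AB, al$IRISH_SOLITARY_LTR),
                   1590L)                       # 1006 + 584
  expect_identical(predict_amplicon(pairs$AB, al$HOODED_FULL_ERV),
                   NA_integer_)                 # 1006 + 7098 > 5000
  expect_identical(predict_amplicon(pairs$CD, al$HOODED_FULL_ERV), 997L)
  expect_identical(predict_amplicon(pairs$CD, al$SELF_EMPTY), NA_integer_)
  expect_identical(predict_amplicon(pairs$CD, al$IRISH_SOLITARY_LTR),
                   NA_integer_)
  # the ceiling is configurable: long-range PCR would recover the band
  lr <- primer_pair("AB", empty_site_product_bp = 1006L,
                    max_amplifiable_bp = 10000L)
  expect_identical(predict_amplicon(lr, al$HOODED_FULL_ERV), 8104L)
  expect_error(primer_pair("XY"), "exactly one")
})

test_that("genotype_from_products inverts predict_amplicon for all 6 genotypes", {
  pairs <- kit_primer_pairs()
  al <- hooded_alleles()
  combos <- expand.grid(a1 = names(al), a2 = names(al),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$a1 <= combos$a2, ]
  for (r in seq_len(nrow(combos))) {
    bands <- lapply(pairs, function(p)
      unique(stats::na.omit(c(predict_amplicon(p, al[[combos$a1[r]]]),
                              predict_amplicon(p, al[[combos$a2[r]]])))))
    inferred <- genotype_from_products(bands)
    expect_false(inferred$conflict)
    hit <- any(inferred$genotypes$allele1 == combos$a1[r] &
               inferred$genotypes$allele2 == combos$a2[r] |
               inferred$genotypes$allele1 == combos$a2[r] &
               inferred$genotypes$allele2 == combos$a1[r])
    expect_true(hit)
  }
  # worked examples
  expect_identical(
    genotype_from_products(list(AB = 1590, CD = NULL))$genotypes$label,
    "IRISH_SOLITARY_LTR")
  expect_identical(
    genotype_from_products(list(AB = 1006, CD = NULL))$genotypes$label,
    "SELF_EMPTY")
  het <- genotype_from_products(list(AB = c(1006, 1590)))
  expect_identical(het$genotypes$label, "SELF_EMPTY/IRISH_SOLITARY_LTR")
  # a 1590 AB band with a 997 CD band is a genuine genotype: the
  # solitary-LTR / full-ERV heterozygote
  het2 <- genotype_from_products(list(AB = 1590, CD = 997))
  expect_identical(het2$genotypes$label,
                   "IRISH_SOLITARY_LTR/HOODED_FULL_ERV")
  # truly inconsistent observation: three AB states implied
  bad <- genotype_from_products(list(AB = c(1006, 1590), CD = 997))
  expect_true(bad$conflict)
  expect_gt(nrow(bad$violations), 0)
  expect_error(genotype_from_products(list(ZZ = 100)), "unknown primer")
})
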