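# Strain-unique variant screen over multi-strain, multi-sequence variant
# tables. A candidate must be carried (non-reference) by every sequence of
# the carrier strain and by no sequence of any contrast strain; positions
# where sequences of one strain disagree are surfaced as DISCORDANT, never
# silently dropped — whole-genome and PCR-derived sequences of the same
# inbred strain do disagree in practice.

#' Build a strain variant call table
#'
#' One row per (sequence, position): which independently derived sequence
#' of which strain carries which state at the position. Multiple sequences
#' per strain are the norm (e.g. two whole-genome sequences plus PCR
#' resequencing).
#'
#' @param strain,sequence_id,chrom,pos,state parallel vectors; `state` is
#'   `"ref"` or `"alt"`.
#' @return a `strain_variant_calls` data frame.
#' @export
strain_variant_calls <- function(strain, sequence_id, chrom, pos, state) {
  df <- data.frame(strain = as.character(strain),
                   sequence_id = as.character(sequence_id),
                   chrom = as.character(chrom),
                   pos = as.numeric(pos),
                   state = as.character(state),
                   stringsAsFactors = FALSE)
  bad <- !(df$state %in% c("ref", "alt"))
  if (any(bad)) stop("state must be 'ref' or 'alt'")
  class(df) <- c("strain_variant_calls", "data.frame")
  df
}

#' Screen an interval for variants unique to the carrier strain
#'
#' A position is a candidate iff every sequence of `carrier_strain` carries
#' the non-reference state and every sequence of every contrast strain does
#' not. Sequences with no row at a position are taken as reference (the
#' usual convention of variant tables, which record departures from the
#' reference only). Positions where the sequences of any relevant strain
#' disagree are flagged DISCORDANT and reported separately; a discordant
#' position is never a candidate.
#'
#' @param calls a [strain_variant_calls()] table.
#' @param carrier_strain strain whose unique variants are sought.
#' @param contrast_strains strains the carrier must differ from.
#' @param chrom,interval_mb optional filter: chromosome and numeric
#'   length-2 position bounds (same units as `pos`).
#' @return a `variant_screen` list: `positions` (per-position summary with
#'   `is_candidate` and `discordant_strains`), `candidates`, `discordant`.
#' @examples
#' calls <- kit_snp_calls()
#' scr <- unique_variants(calls, "ACI", c("BN", "COP", "F344"))
#' nrow(scr$candidates)   # 0: no variant is unique to ACI
#' @export
unique_variants <- function(calls, carrier_strain, contrast_strains,
                            chrom = NULL, interval_mb = NULL) {
  strains <- c(carrier_strain, contrast_strains)
  if (!(carrier_strain %in% calls$strain))
    stop("carrier strain ", carrier_strain, " absent from calls")
  if (!is.null(chrom)) calls <- calls[calls$chrom == chrom, , drop = FALSE]
  if (!is.null(interval_mb))
    calls <- calls[calls$pos >= min(interval_mb) &
                   calls$pos <= max(interval_mb), , drop = FALSE]
  seqs <- unique(calls[calls$strain %in% strains,
                       c("strain", "sequence_id")])
  key <- unique(calls[, c("chrom", "pos")])
  key <- key[order(key$chrom, key$pos), , drop = FALSE]
  res <- lapply(seq_len(nrow(key)), function(i) {
    here <- calls$chrom == key$chrom[i] & calls$pos == key$pos[i]
    st <- vapply(seq_len(nrow(seqs)), function(j) {
      row <- here & calls$strain == seqs$strain[j] &
        calls$sequence_id == seqs$sequence_id[j]
      if (any(row)) calls$state[row][1L] else "ref"
    }, character(1L))
    disc <- vapply(strains, function(s)
      length(unique(st[seqs$strain == s])) > 1L, logical(1L))
    carrier_alt <- all(st[seqs$strain == carrier_strain] == "alt")
    contrast_ref <- all(st[seqs$strain %in% contrast_strains] == "ref")
    data.frame(chrom = key$chrom[i], pos = key$pos[i],
               is_candidate = carrier_alt && contrast_ref && !any(disc),
               discordant_strains = paste(strains[disc], collapse = ","),
               stringsAsFactors = FALSE)
  })
  positions <- do.call(rbind, res)
  if (is.null(positions))
    positions <- data.frame(chrom = character(), pos = numeric(),
                            is_candidate = logical(),
                            discordant_strains = character())
  structure(list(positions = positions,
                 candidates = positions[positions$is_candidate, ,
                                        drop = FALSE],
                 discordant = positions[positions$discordant_strains != "",
                                        , drop = FALSE],
                 carrier_strain = carrier_strain,
                 contrast_strains = contrast_strains),
            class = "variant_screen")
}

#' @export
print.variant_screen <- function(x, ...) {
  cat(sprintf(
    "Variant screen: %s vs %s — %d positions, %d candidate(s), %d discordant\n",
    x$carrier_strain, paste(x$contrast_strains, collapse = "/"),
    nrow(x$positions), nrow(x$candidates), nrow(x$discordant)))
  if (nrow(x$candidates)) print(x$candidates, row.names = FALSE)
  if (nrow(x$discordant)) {
    cat("discordant (within-strain disagreement, not adjudicated):\n")
    print(x$discordant, row.names = FALSE)
  }
  invisible(x)
}

#' Read strain variant calls from a VCF plus a sample-to-strain map
#'
#' Wraps `VariantAnnotation::readVcf`: each VCF sample column becomes one
#' sequence of one strain via the sidecar TSV (columns `sample`, `strain`,
#' `sequence_id`). A sample is `"alt"` at a position when its GT carries
#' any non-reference allele. Positions are 1-based per VCF convention.
#'
#' @param vcf_path VCF (v4.x) file.
#' @param sample_map_path TSV mapping sample -> (strain, sequence_id).
#' @return a [strain_variant_calls()] table.
#' @export
read_strain_vcf <- function(vcf_path, sample_map_path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_strain_vcf requires the VariantAnnotation package")
  smap <- read_tsv_checked(sample_map_path,
                           c("sample", "strain", "sequence_id"))
  vcf <- VariantAnnotation::readVcf(vcf_path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF ", vcf_path, " has no GT field")
  missing <- setdiff(colnames(gt), smap$sample)
  if (length(missing))
    stop("samples absent from ", sample_map_path, ": ",
         paste(missing, collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  out <- lapply(colnames(gt), function(s) {
    state <- ifelse(grepl("[1-9]", gt[, s]), "alt", "ref")
    i <- match(s, smap$sample)
    strain_variant_calls(smap$strain[i], smap$sequence_id[i], chrom, pos,
                         state)
  })
  res <- do.call(rbind, out)
  class(res) <- c("strain_variant_calls", "data.frame")
  rownames(res) <- NULL
  res
}
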