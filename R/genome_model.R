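#' exclumap: cross simulation and exclusion fine-mapping of dominant loci
#'
#' Tools for the classic experimental-cross route to a Mendelian locus:
#' simulate F2 intercrosses, backcrosses and marker-assisted congenic
#' programs segregating an incompletely dominant, incompletely penetrant
#' causal allele; fine-map it from affected-animal genotypes by exclusion
#' (dominant carrier alleles) or inclusion (recessive alleles); refine the
#' interval by recombinant progeny testing; and screen a candidate interval
#' for strain-unique variants, including structural insertion alleles typed
#' by diagnostic PCR product sizes.
#'
#' The bundled worked example is the rat \emph{Renag1} locus on chromosome
#' 14 (unilateral renal agenesis in ACI rats), whose candidate interval
#' collapses onto intron 1 of \emph{Kit} and an endogenous-retrovirus LTR
#' insertion allele shared with the \emph{Hooded} coat-colour locus.
#'
#' @docType package
#' @name exclumap-package
#' @aliases exclumap
#' @keywords internal
"_PACKAGE"

GENO_CODES <- c("C", "H", "N")        # carrier hom / het / non-carrier hom
ANOMALY_CLASSES <- c("URA", "URH", "HUN")
SIDES <- c("LEFT", "RIGHT", "BILATERAL")

#' Convert a physical position to a genetic position
#'
#' Linear conversion from megabases to centimorgans. The printed coordinates
#' for most microsatellite panels are physical only, so a single genome-wide
#' rate (default 0.5 cM/Mb, a typical rat autosomal average) stands in for
#' the unknown local recombination landscape. The rate is configurable
#' everywhere it is used.
#'
#' @param position_mb physical position(s) in Mb, non-negative.
#' @param cm_per_mb conversion rate in cM per Mb, positive scalar.
#' @return genetic position(s) in cM.
#' @examples
#' mb_to_cm(34.25)           # 17.125 cM at the default rate
#' mb_to_cm(2, cm_per_mb = 0.5)
#' @export
mb_to_cm <- function(position_mb, cm_per_mb = 0.5) {
  stopifnot(is.numeric(position_mb), is.numeric(cm_per_mb),
            length(cm_per_mb) == 1L)
  if (any(position_mb < 0)) stop("position_mb must be non-negative")
  if (cm_per_mb <= 0) stop("cm_per_mb must be > 0")
  position_mb * cm_per_mb
}

#' Haldane recombination fraction
#'
#' Maps a genetic distance in cM to a recombination fraction under the
#' Haldane (no crossover interference) map function,
#' r = (1 - exp(-2d/100)) / 2. Monotone increasing, 0 at d = 0, and
#' approaching 1/2 for unlinked loci.
#'
#' @param distance_cm genetic distance(s) in centimorgans, non-negative.
#' @return recombination fraction(s) in [0, 0.5).
#' @examples
#' haldane_recomb_fraction(10)   # ~0.0906
#' @export
haldane_recomb_fraction <- function(distance_cm) {
  stopifnot(is.numeric(distance_cm))
  if (any(distance_cm < 0)) stop("distance_cm must be non-negative")
  0.5 * (1 - exp(-2 * distance_cm / 100))
}

#' Construct a genetic map
#'
#' An ordered marker map: one row per marker with chromosome label,
#' physical position in Mb and genetic position in cM. When `pos_cm` is not
#' supplied it is derived linearly from `pos_mb` via [mb_to_cm()].
#'
#' @param marker character vector of unique marker names.
#' @param chrom chromosome label per marker.
#' @param pos_mb physical position per marker (Mb, non-negative).
#' @param pos_cm optional genetic positions (cM); derived if `NULL`.
#' @param cm_per_mb linear conversion rate used when deriving `pos_cm`.
#' @return a `genetic_map`, a data frame with columns
#'   `marker`, `chrom`, `pos_mb`, `pos_cm`, sorted by chromosome and
#'   position, with the conversion rate kept as attribute `cm_per_mb`.
#' @examples
#' genetic_map(c("D14Uwm7", "D14Uwm12"), "14", c(34.25, 36.25))
#' @export
genetic_map <- function(marker, chrom, pos_mb, pos_cm = NULL,
                        cm_per_mb = 0.5) {
  marker <- as.character(marker)
  chrom <- rep_len(as.character(chrom), length(marker))
  stopifnot(length(pos_mb) == length(marker))
  if (anyDuplicated(marker))
    stop("duplicate marker names: ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (any(pos_mb < 0)) stop("pos_mb must be non-negative")
  if (is.null(pos_cm)) pos_cm <- mb_to_cm(pos_mb, cm_per_mb)
  stopifnot(length(pos_cm) == length(marker))
  map <- data.frame(marker = marker, chrom = chrom,
                    pos_mb = as.numeric(pos_mb),
                    pos_cm = as.numeric(pos_cm),
                    stringsAsFactors = FALSE)
  map <- map[order(map$chrom, map$pos_mb), , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos_mb[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions on chromosome ", ch,
           " must be strictly increasing")
    g <- map$pos_cm[map$chrom == ch]
    if (any(diff(g) < 0))
      stop("pos_cm must be non-decreasing in pos_mb on chromosome ", ch)
  }
  attr(map, "cm_per_mb") <- cm_per_mb
  class(map) <- c("genetic_map", "data.frame")
  map
}

map_chrom <- function(map, chrom) {
  sub <- map[map$chrom == chrom, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no markers on chromosome ", chrom)
  sub
}

#' Construct a genotype matrix
#'
#' Animals x markers grid of strain-role-coded calls: `"C"` homozygous
#' carrier (donor strain), `"H"` heterozygous, `"N"` homozygous non-carrier
#' (recipient strain), `NA` missing. Role-based coding lets one engine serve
#' crosses against different recipient strains.
#'
#' @param calls character matrix (or coercible) of `"C"/"H"/"N"/NA`.
#' @param animal_ids,marker_names optional dimnames; taken from `calls`
#'   when absent.
#' @return a `genotype_matrix` (character matrix with dimnames).
#' @export
genotype_matrix <- function(calls, animal_ids = rownames(calls),
                            marker_names = colnames(calls)) {
  calls <- as.matrix(calls)
  mode(calls) <- "character"
  if (is.null(animal_ids) || is.null(marker_names))
    stop("animal_ids and marker_names are required")
  if (length(animal_ids) != nrow(calls) ||
      length(marker_names) != ncol(calls))
    stop("dimnames do not match the call grid dimensions")
  bad <- !is.na(calls) & !(calls %in% GENO_CODES)
  if (any(bad))
    stop("invalid genotype codes: ",
         paste(unique(calls[bad]), collapse = ", "))
  dimnames(calls) <- list(as.character(animal_ids),
                          as.character(marker_names))
  class(calls) <- c("genotype_matrix", class(calls))
  calls
}

#' Construct a phenotype table
#'
#' One record per animal: anomaly class (`NONE`, `URA`, `URH`, `HUN`) and
#' affected side (`LEFT`, `RIGHT`, `BILATERAL`, or `NA` for unaffected
#' animals). `BILATERAL` is only meaningful for HUN, the one class observed
#' bilaterally.
#'
#' @param animal_id character vector.
#' @param anomaly anomaly class per animal.
#' @param side side per animal (`NA` iff anomaly is `NONE`).
#' @return a `phenotype_table` data frame.
#' @export
phenotype_table <- function(animal_id, anomaly, side) {
  df <- data.frame(animal_id = as.character(animal_id),
                   anomaly = as.character(anomaly),
                   side = as.character(side),
                   stringsAsFactors = FALSE)
  bad <- !(df$anomaly %in% c("NONE", ANOMALY_CLASSES))
  if (any(bad)) stop("invalid anomaly class: ",
                     paste(unique(df$anomaly[bad]), collapse = ", "))
  bad <- !is.na(df$side) & !(df$side %in% SIDES)
  if (any(bad)) stop("invalid side: ",
                     paste(unique(df$side[bad]), collapse = ", "))
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Validate map, genotype and phenotype tables against each other
#'
#' Report-based validation: never throws on content problems, instead
#' returns one row per issue. An empty report means all invariants hold:
#' markers known to the map and in map order, positions strictly increasing,
#' unique animal ids, side present iff an anomaly is, and `BILATERAL`
#' restricted to HUN.
#'
#' @param map a [genetic_map()].
#' @param genotypes a [genotype_matrix()] or `NULL`.
#' @param phenotypes a [phenotype_table()] or `NULL`.
#' @return data frame with columns `component`, `id`, `issue`.
#' @export
validate_tables <- function(map, genotypes = NULL, phenotypes = NULL) {
  issues <- list()
  note <- function(component, id, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      component = component, id = id, issue = issue,
      stringsAsFactors = FALSE)

  for (ch in unique(map$chrom)) {
    p <- map$pos_mb[map$chrom == ch]
    if (any(diff(p) <= 0))
      note("map", ch, "marker positions not strictly increasing")
  }
  if (anyDuplicated(map$marker))
    note("map", map$marker[duplicated(map$marker)][1L],
         "duplicate marker name")

  if (!is.null(genotypes)) {
    unknown <- setdiff(colnames(genotypes), map$marker)
    for (m in unknown) note("genotypes", m, "marker absent from map")
    known <- intersect(colnames(genotypes), map$marker)
    if (!identical(known, map$marker[map$marker %in% known]))
      note("genotypes", "", "marker columns not in map order")
    dup <- rownames(genotypes)[duplicated(rownames(genotypes))]
    for (a in unique(dup)) note("genotypes", a, "duplicate animal id")
  }

  if (!is.null(phenotypes)) {
    dup <- phenotypes$animal_id[duplicated(phenotypes$animal_id)]
    for (a in unique(dup)) note("phenotypes", a, "duplicate animal id")
    bad <- phenotypes$anomaly == "NONE" & !is.na(phenotypes$side)
    for (a in phenotypes$animal_id[bad])
      note("phenotypes", a, "side given for unaffected animal")
    bad <- phenotypes$anomaly != "NONE" & is.na(phenotypes$side)
    for (a in phenotypes$animal_id[bad])
      note("phenotypes", a, "affected animal lacks side")
    bad <- !is.na(phenotypes$side) & phenotypes$side == "BILATERAL" &
      phenotypes$anomaly != "HUN"
    for (a in phenotypes$animal_id[bad])
      note("phenotypes", a, "BILATERAL only permitted for HUN")
  }

  if (length(issues) == 0L)
    return(data.frame(component = character(), id = character(),
                      issue = character(), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
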