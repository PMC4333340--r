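# Marker-assisted congenic breeding simulator. One heterozygous breeder is
# carried forward per backcross generation: positive selection requires
# heterozygosity across every donor-interval marker in every generation;
# negative selection (from `negative_selection_start` onwards) additionally
# picks the candidate with the fewest donor alleles at background markers.
# A final heterozygote x heterozygote intercross fixes the donor interval.

#' Simulate a marker-assisted congenic breeding program
#'
#' Starting from an F1 founder, repeatedly backcrosses to the recipient
#' strain, each generation selecting a breeder heterozygous at all markers
#' inside the donor interval; from generation `negative_selection_start`
#' onwards the breeder with the lowest donor-allele count at background
#' markers (markers on other chromosomes) is preferred. Optionally finishes
#' with a sib intercross to recover animals homozygous for donor alleles
#' across the interval.
#'
#' Without background selection the expected donor fraction of the diploid
#' background halves each generation: (1/2)^(N+1) after N backcrosses.
#'
#' @param map a [genetic_map()] with the donor chromosome and at least one
#'   background chromosome.
#' @param donor_chrom chromosome carrying the donor interval.
#' @param donor_interval_mb numeric length-2, Mb bounds of the interval;
#'   must cover at least two markers.
#' @param n_backcross_generations number of backcross generations.
#' @param negative_selection_start first generation at which background
#'   selection applies (`Inf` disables it).
#' @param n_per_generation progeny screened per generation (default 20, a
#'   realistic multi-litter screen for a speed-congenic rat program).
#' @param intercross run the final heterozygote intercross step.
#' @param n_intercross progeny screened in the intercross step.
#' @param seed optional integer seed.
#' @return a `congenic_sim` list: `generations` (one row per generation:
#'   `generation`, `n_screened`, `n_eligible`, `bg_donor_fraction`),
#'   `success`, `failed_generation` (NA unless no heterozygous candidate
#'   was found), and `n_homozygous_founders` from the intercross.
#' @export
simulate_congenic_program <- function(map, donor_chrom, donor_interval_mb,
                                      n_backcross_generations = 9L,
                                      negative_selection_start = 5L,
                                      n_per_generation = 20L,
                                      intercross = TRUE,
                                      n_intercross = 40L,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(donor_interval_mb) == 2L)
  donor_interval_mb <- sort(donor_interval_mb)
  chroms <- unique(map$chrom)
  if (!(donor_chrom %in% chroms)) stop("donor_chrom not in map")
  bg_chroms <- setdiff(chroms, donor_chrom)
  if (length(bg_chroms) == 0L)
    stop("map must contain at least one background chromosome")
  sub_d <- map_chrom(map, donor_chrom)
  in_iv <- sub_d$pos_mb >= donor_interval_mb[1L] &
    sub_d$pos_mb <= donor_interval_mb[2L]
  if (sum(in_iv) < 2L)
    stop("donor interval must be covered by at least 2 markers")
  n_bg <- sum(map$chrom %in% bg_chroms)

  # per-chromosome locus grids and current breeder haplotypes (F1 founder;
  # the dam-derived haplotype is always all-recipient after any backcross)
  grids <- lapply(chroms, function(ch) map_chrom(map, ch)$pos_cm)
  names(grids) <- chroms
  sire <- lapply(grids, function(p) rep(1L, length(p)))

  gens <- data.frame(generation = 0L, n_screened = NA_integer_,
                     n_eligible = NA_integer_, bg_donor_fraction = 0.5)
  failed_generation <- NA_integer_
  n_gen <- as.integer(n_backcross_generations)
  if (n_gen > 0) for (g in seq_len(n_gen)) {
    gam <- lapply(chroms, function(ch)
      sim_gametes(sire[[ch]], rep(0L, length(grids[[ch]])),
                  grids[[ch]], n_per_generation))
    names(gam) <- chroms
    eligible <- rowSums(gam[[donor_chrom]][, in_iv, drop = FALSE]) ==
      sum(in_iv)
    if (!any(eligible)) {
      failed_generation <- g
      gens <- rbind(gens, data.frame(generation = g,
                                     n_screened = n_per_generation,
                                     n_eligible = 0L,
                                     bg_donor_fraction = NA_real_))
      break
    }
    bg_count <- Reduce(`+`, lapply(bg_chroms, function(ch)
      rowSums(gam[[ch]])))
    cand <- which(eligible)
    sel <- if (g >= negative_selection_start) {
      cand[which.min(bg_count[cand])]
    } else if (length(cand) == 1L) cand else sample(cand, 1L)
    sire <- lapply(chroms, function(ch) gam[[ch]][sel, ])
    names(sire) <- chroms
    gens <- rbind(gens, data.frame(
      generation = g, n_screened = n_per_generation,
      n_eligible = sum(eligible),
      bg_donor_fraction = bg_count[sel] / (2 * n_bg)))
  }

  n_hom <- NA_integer_
  if (intercross && is.na(failed_generation)) {
    # sib intercross: both parents carry the selected recombinant
    # chromosome over the recipient background
    g1 <- sim_gametes(sire[[donor_chrom]],
                      rep(0L, length(grids[[donor_chrom]])),
                      grids[[donor_chrom]], n_intercross)
    g2 <- sim_gametes(sire[[donor_chrom]],
                      rep(0L, length(grids[[donor_chrom]])),
                      grids[[donor_chrom]], n_intercross)
    hom <- rowSums((g1[, in_iv, drop = FALSE] == 1L) &
                   (g2[, in_iv, drop = FALSE] == 1L)) == sum(in_iv)
    n_hom <- sum(hom)
  }

  structure(list(generations = gens,
                 success = is.na(failed_generation),
                 failed_generation = failed_generation,
                 n_homozygous_founders = n_hom,
                 donor_chrom = donor_chrom,
                 donor_interval_mb = donor_interval_mb,
                 donor_markers = sub_d$marker[in_iv],
                 seed = seed),
            class = "congenic_sim")
}

#' @export
print.congenic_sim <- function(x, ...) {
  cat("Congenic breeding simulation:", nrow(x$generations) - 1L,
      "backcross generations\n")
  cat("  donor interval:", x$donor_chrom, ":",
      paste(x$donor_interval_mb, collapse = "-"), "Mb (",
      length(x$donor_markers), "markers )\n")
  if (!x$success)
    cat("  PROGRAM FAILED at generation", x$failed_generation,
        "(no heterozygous candidate)\n")
  print(x$generations, row.names = FALSE)
  if (!is.na(x$n_homozygous_founders))
    cat("  intercross founders homozygous across interval:",
        x$n_homozygous_founders, "\n")
  invisible(x)
}
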