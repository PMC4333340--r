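# Exclusion mapping of a dominant carrier allele (any phenotype-positive
# animal homozygous non-carrier at a marker excludes that marker) and the
# recessive-allele mirror image (a marker is retained only where every
# positive animal is homozygous for the recessive code). Intervals use the
# outer-bound convention: a candidate interval is reported between the
# nearest excluding markers on either side, matching how flanking-marker
# bounds are quoted in practice.

#' Candidate interval
#'
#' A chromosome segment bounded by flanking informative markers. A side
#' with no excluding marker is unbounded (`bounded_* = FALSE`, bound
#' position `NA`); `width_mb` is defined only when both bounds exist.
#'
#' @param chrom chromosome.
#' @param left_marker,right_marker bound marker names (`NA` if unbounded).
#' @param left_mb,right_mb bound positions in Mb (`NA` if unbounded).
#' @param bounded_left,bounded_right logical bound flags.
#' @param n_support number of animals supporting the interval.
#' @return a `candidate_interval` list with `width_mb`.
#' @export
candidate_interval <- function(chrom, left_marker = NA, right_marker = NA,
                               left_mb = NA, right_mb = NA,
                               bounded_left = !is.na(left_mb),
                               bounded_right = !is.na(right_mb),
                               n_support = NA_integer_) {
  if (bounded_left && bounded_right && left_mb > right_mb)
    stop("left bound exceeds right bound")
  structure(list(chrom = chrom,
                 left_marker = left_marker, right_marker = right_marker,
                 left_mb = left_mb, right_mb = right_mb,
                 bounded_left = bounded_left, bounded_right = bounded_right,
                 width_mb = if (bounded_left && bounded_right)
                   right_mb - left_mb else NA_real_,
                 n_support = n_support),
            class = "candidate_interval")
}

#' @export
print.candidate_interval <- function(x, ...) {
  fmt <- function(b, m, p) if (b) sprintf("%s (%.2f Mb)", m, p) else "open"
  cat(sprintf("Candidate interval chr%s: %s .. %s%s\n", x$chrom,
              fmt(x$bounded_left, x$left_marker, x$left_mb),
              fmt(x$bounded_right, x$right_marker, x$right_mb),
              if (!is.na(x$width_mb))
                sprintf(" [width %.2f Mb]", x$width_mb) else ""))
  invisible(x)
}

#' Does a candidate interval contain a position?
#'
#' Unbounded sides contain everything on that side of the chromosome.
#'
#' @param interval a [candidate_interval()].
#' @param chrom,pos_mb query position.
#' @return logical.
#' @export
interval_contains <- function(interval, chrom, pos_mb) {
  if (!identical(as.character(interval$chrom), as.character(chrom)))
    return(FALSE)
  (!interval$bounded_left || pos_mb >= interval$left_mb) &&
    (!interval$bounded_right || pos_mb <= interval$right_mb)
}

# shared marker-status -> interval machinery -------------------------------

# status: per-marker vector in {EXCLUDED, NOT_EXCLUDED, NON_INFORMATIVE},
# parallel to `sub` (one chromosome, map order). Runs of non-excluded
# markers become candidate intervals bounded by the nearest excluding
# marker on each side.
intervals_from_status <- function(sub, status, support_fun) {
  keep <- status != "EXCLUDED"
  if (!any(keep)) return(list())
  runs <- rle(keep)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in which(runs$values)) {
    i <- starts[k]; j <- ends[k]
    bl <- i > 1L
    br <- j < nrow(sub)
    out[[length(out) + 1L]] <- candidate_interval(
      chrom = sub$chrom[1L],
      left_marker = if (bl) sub$marker[i - 1L] else NA,
      right_marker = if (br) sub$marker[j + 1L] else NA,
      left_mb = if (bl) sub$pos_mb[i - 1L] else NA,
      right_mb = if (br) sub$pos_mb[j + 1L] else NA,
      bounded_left = bl, bounded_right = br,
      n_support = support_fun(sub$marker[i:j]))
  }
  # ranked by supporting animals, widest runs breaking ties
  ord <- order(-vapply(out, function(x) as.double(x$n_support), 0),
               vapply(out, function(x) {
                 if (is.na(x$width_mb)) -Inf else -x$width_mb
               }, 0))
  out[ord]
}

exclusion_report <- function(markers, intervals, mode, tolerance,
                             diagnostic = NULL) {
  structure(list(markers = markers, intervals = intervals, mode = mode,
                 tolerance = tolerance, diagnostic = diagnostic),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("%s mapping report (tolerance %d): %d markers, %d interval(s)\n",
              x$mode, x$tolerance, nrow(x$markers), length(x$intervals)))
  print(x$markers, row.names = FALSE)
  if (!is.null(x$diagnostic)) cat("note:", x$diagnostic, "\n")
  for (iv in x$intervals) print(iv)
  invisible(x)
}

check_mapper_input <- function(genotypes, map) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0L)
    stop("no phenotype-positive animals supplied")
  unknown <- setdiff(colnames(genotypes), map$marker)
  if (length(unknown))
    stop("markers absent from map: ", paste(unknown, collapse = ", "))
}

#' Exclusion mapping of a dominant carrier allele
#'
#' Each input animal is phenotype-positive and therefore assumed to carry
#' at least one carrier allele at the causal locus. A marker at which more
#' than `tolerance` animals are homozygous non-carrier (`N`) is excluded
#' from the locus; missing calls never exclude. Maximal runs of
#' non-excluded markers become candidate intervals bounded by the nearest
#' excluding marker on each side (outer-bound convention). `tolerance`
#' defaults to 0; raise it to absorb suspected phenocopies.
#'
#' @param genotypes [genotype_matrix()] of phenotype-positive animals.
#' @param map a [genetic_map()].
#' @param tolerance number of excluding animals tolerated per marker.
#' @return an `exclusion_report`: per-marker status
#'   (`EXCLUDED`/`NOT_EXCLUDED`/`NON_INFORMATIVE`) with excluding-animal
#'   counts, and candidate intervals ranked by supporting animals. When
#'   every marker is excluded the interval list is empty and a diagnostic
#'   is attached.
#' @examples
#' fx <- renag1_exclusion_fixture()
#' rep <- map_dominant_exclusion(fx$genotypes, fx$map)
#' rep$intervals[[1]]$width_mb   # 2.0
#' @export
map_dominant_exclusion <- function(genotypes, map, tolerance = 0L) {
  check_mapper_input(genotypes, map)
  mapper_core(genotypes, map, tolerance, mode = "dominant-exclusion",
              n_violating = function(calls) sum(calls == "N", na.rm = TRUE),
              supports = function(calls) calls %in% c("C", "H"))
}

#' Inclusion mapping of a recessive allele
#'
#' Mirror image of [map_dominant_exclusion()] for a recessive causal
#' allele: every phenotype-positive animal must be homozygous for the
#' recessive code at the locus, so a marker is retained only where at most
#' `tolerance` positive animals are not homozygous-recessive. Used, e.g.,
#' to place the rat hooded coat-colour allele (recessive, non-carrier
#' strain homozygote) from hooded-phenotype F2 animals.
#'
#' @inheritParams map_dominant_exclusion
#' @param recessive_code genotype code of the recessive homozygote
#'   (default `"N"`).
#' @return an `exclusion_report`.
#' @export
map_recessive_inclusion <- function(genotypes, map, recessive_code = "N",
                                    tolerance = 0L) {
  check_mapper_input(genotypes, map)
  stopifnot(recessive_code %in% GENO_CODES)
  mapper_core(genotypes, map, tolerance, mode = "recessive-inclusion",
              n_violating = function(calls)
                sum(!is.na(calls) & calls != recessive_code),
              supports = function(calls)
                !is.na(calls) & calls == recessive_code)
}

mapper_core <- function(genotypes, map, tolerance, mode, n_violating,
                        supports) {
  cols <- map$marker[map$marker %in% colnames(genotypes)]
  geno <- genotypes[, cols, drop = FALSE]
  n_excl <- apply(geno, 2L, n_violating)
  n_obs <- apply(geno, 2L, function(x) sum(!is.na(x)))
  status <- ifelse(n_obs == 0L, "NON_INFORMATIVE",
                   ifelse(n_excl > tolerance, "EXCLUDED", "NOT_EXCLUDED"))
  sub_all <- map[map$marker %in% cols, , drop = FALSE]
  markers <- data.frame(marker = cols,
                        chrom = sub_all$chrom[match(cols, sub_all$marker)],
                        pos_mb = sub_all$pos_mb[match(cols, sub_all$marker)],
                        status = unname(status[cols]),
                        n_excluding = unname(n_excl[cols]),
                        n_observed = unname(n_obs[cols]),
                        stringsAsFactors = FALSE)
  sup_mat <- sapply(cols, function(m) supports(geno[, m]))
  if (!is.matrix(sup_mat))
    sup_mat <- matrix(sup_mat, nrow = nrow(geno),
                      dimnames = list(NULL, cols))
  intervals <- list()
  for (ch in unique(markers$chrom)) {
    sub <- markers[markers$chrom == ch, , drop = FALSE]
    ivs <- intervals_from_status(
      sub, sub$status,
      support_fun = function(run_markers)
        sum(rowSums(sup_mat[, run_markers, drop = FALSE]) > 0L))
    intervals <- c(intervals, ivs)
  }
  diagnostic <- if (length(intervals) == 0L)
    "every marker excluded: no candidate interval remains (phenocopies or wrong chromosome?)"
  exclusion_report(markers, intervals, mode, tolerance, diagnostic)
}

#' Interval containment probability under simulation
#'
#' Validation harness: repeatedly simulates an F2 cross, maps the locus
#' from the affected animals, and reports the fraction of replicates whose
#' candidate interval(s) contain the true causal position. With a
#' phenocopy-free model (`p_NN = 0`) and tolerance 0 every affected animal
#' truly carries a carrier allele, so containment is a logical certainty.
#'
#' @param n_replicates number of simulated crosses.
#' @param map,model,causal_chrom,causal_pos_mb as in [simulate_f2()].
#' @param n_progeny F2 animals per replicate.
#' @param tolerance passed to [map_dominant_exclusion()].
#' @param seed integer seed for the whole experiment.
#' @return fraction of replicates (in [0, 1]) with the causal position
#'   inside a returned interval.
#' @export
containment_probability <- function(n_replicates, map,
                                    model = penetrance_model(),
                                    causal_chrom = map$chrom[1L],
                                    causal_pos_mb, n_progeny = 400L,
                                    tolerance = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_replicates)) {
    sim <- simulate_f2(n_progeny, map, model, causal_chrom, causal_pos_mb)
    aff <- sim$phenotypes$animal_id[sim$phenotypes$anomaly != "NONE"]
    if (length(aff) == 0L) next
    rep_ <- map_dominant_exclusion(sim$genotypes[aff, , drop = FALSE],
                                   map, tolerance)
    contained <- any(vapply(rep_$intervals, interval_contains,
                            logical(1L), chrom = causal_chrom,
                            pos_mb = causal_pos_mb))
    if (contained) hits <- hits + 1L
  }
  hits / n_replicates
}
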