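# Recombinant-chromosome progeny testing: infer the donor segment carried
# by each recombinant animal (inner bounds at the outermost
# carrier-informative markers, outer bounds at the nearest non-carrier
# markers, with the breakpoint somewhere in the uncertainty gap between
# them), then intersect the segments proven to confer the phenotype.

#' Infer the donor segment of one recombinant chromosome
#'
#' The inner segment spans the outermost markers called carrier (`C` or
#' `H`); the outer bounds sit at the nearest flanking markers called
#' non-carrier (`N`), or are open at the chromosome end. The two
#' inner/outer differences are the uncertainty gaps containing the true
#' breakpoints. Missing calls are skipped (non-informative).
#'
#' @param calls named character vector of genotype calls for one animal,
#'   names = markers on a single chromosome.
#' @param map a [genetic_map()].
#' @param animal_id optional id carried into the result.
#' @return a `recombinant_segment` list: inner/outer bound markers and Mb
#'   positions, `bounded_left`/`bounded_right` outer-bound flags, and
#'   `gap_left_mb`/`gap_right_mb` uncertainty-gap widths. If the animal has
#'   no carrier-informative call, `no_segment = TRUE`.
#' @export
infer_donor_segment <- function(calls, map, animal_id = NA_character_) {
  mk <- names(calls)
  if (is.null(mk)) stop("calls must be named by marker")
  unknown <- setdiff(mk, map$marker)
  if (length(unknown))
    stop("markers absent from map: ", paste(unknown, collapse = ", "))
  sub <- map[match(mk, map$marker), , drop = FALSE]
  if (length(unique(sub$chrom)) != 1L)
    stop("calls span multiple chromosomes")
  ord <- order(sub$pos_mb)
  sub <- sub[ord, , drop = FALSE]
  calls <- calls[ord]
  carrier <- which(!is.na(calls) & calls %in% c("C", "H"))
  if (length(carrier) == 0L)
    return(structure(list(animal_id = animal_id, chrom = sub$chrom[1L],
                          no_segment = TRUE),
                     class = "recombinant_segment"))
  i1 <- min(carrier); i2 <- max(carrier)
  non_l <- which(!is.na(calls) & calls == "N" & seq_along(calls) < i1)
  non_r <- which(!is.na(calls) & calls == "N" & seq_along(calls) > i2)
  ol <- if (length(non_l)) max(non_l) else NA_integer_
  or <- if (length(non_r)) min(non_r) else NA_integer_
  structure(list(
    animal_id = animal_id, chrom = sub$chrom[1L], no_segment = FALSE,
    inner_left_marker = sub$marker[i1], inner_left_mb = sub$pos_mb[i1],
    inner_right_marker = sub$marker[i2], inner_right_mb = sub$pos_mb[i2],
    outer_left_marker = if (!is.na(ol)) sub$marker[ol] else NA_character_,
    outer_left_mb = if (!is.na(ol)) sub$pos_mb[ol] else NA_real_,
    outer_right_marker = if (!is.na(or)) sub$marker[or] else NA_character_,
    outer_right_mb = if (!is.na(or)) sub$pos_mb[or] else NA_real_,
    bounded_left = !is.na(ol), bounded_right = !is.na(or),
    gap_left_mb = if (!is.na(ol)) sub$pos_mb[i1] - sub$pos_mb[ol]
                  else NA_real_,
    gap_right_mb = if (!is.na(or)) sub$pos_mb[or] - sub$pos_mb[i2]
                   else NA_real_),
    class = "recombinant_segment")
}

#' Progeny-test result for one recombinant segment
#'
#' @param segment a `recombinant_segment`.
#' @param n_progeny_tested progeny evaluated for the phenotype.
#' @param n_affected affected progeny (`<= n_progeny_tested`); the segment
#'   confers the phenotype when at least one progeny is affected.
#' @return a `progeny_test_result` list with logical `confers`.
#' @export
progeny_test_result <- function(segment, n_progeny_tested, n_affected) {
  stopifnot(inherits(segment, "recombinant_segment"),
            n_affected >= 0, n_progeny_tested >= 0)
  if (n_affected > n_progeny_tested)
    stop("n_affected exceeds n_progeny_tested")
  structure(list(segment = segment,
                 n_progeny_tested = as.integer(n_progeny_tested),
                 n_affected = as.integer(n_affected),
                 confers = n_affected > 0L),
            class = "progeny_test_result")
}

#' Intersect phenotype-conferring recombinant segments
#'
#' Refines the candidate interval from progeny testing. The conservative
#' (headline) interval is the intersection of the outer bounds of every
#' conferring segment, optionally intersected with a prior interval and
#' clipped at markers excluded by genotyped affected progeny (homozygous
#' non-carrier calls). The minimal interval is the intersection of the
#' inner segments; it may be empty — two conferring chromosomes whose
#' donor segments abut from opposite sides localize the locus entirely to
#' the overlap of their uncertainty gaps — and is reported for diagnostics
#' only. Conservative always contains minimal.
#'
#' When excluded positions split the conservative interval, all resulting
#' sub-intervals are returned in `candidates` and the one overlapping the
#' most conferring inner segments (ties: widest, then leftmost) is reported
#' as conservative.
#'
#' @param results list of [progeny_test_result()].
#' @param prior optional [candidate_interval()] intersected in.
#' @param excluded_positions optional numeric Mb positions (named by marker
#'   if available) excluded by affected-progeny genotypes.
#' @return an `interval_refinement` list: `conservative`
#'   ([candidate_interval()]), `minimal` (interval or `NULL` when empty),
#'   `candidates`, `n_conferring`.
#' @export
intersect_conferring_segments <- function(results, prior = NULL,
                                          excluded_positions = NULL) {
  conf <- Filter(function(r) isTRUE(r$confers), results)
  if (length(conf) == 0L) stop("no conferring segment among the results")
  segs <- lapply(conf, `[[`, "segment")
  if (any(vapply(segs, `[[`, logical(1L), "no_segment")))
    stop("a conferring result carries no donor segment")
  chrom <- unique(vapply(segs, `[[`, character(1L), "chrom"))
  if (length(chrom) != 1L) stop("segments span multiple chromosomes")

  ol <- vapply(segs, function(s)
    if (s$bounded_left) s$outer_left_mb else -Inf, 0)
  or <- vapply(segs, function(s)
    if (s$bounded_right) s$outer_right_mb else Inf, 0)
  L <- max(ol); R <- min(or)
  lm <- if (is.finite(L))
    segs[[which.max(ol)]]$outer_left_marker else NA_character_
  rm_ <- if (is.finite(R))
    segs[[which.min(or)]]$outer_right_marker else NA_character_
  if (!is.null(prior)) {
    if (prior$bounded_left && prior$left_mb > L) {
      L <- prior$left_mb; lm <- prior$left_marker
    }
    if (prior$bounded_right && prior$right_mb < R) {
      R <- prior$right_mb; rm_ <- prior$right_marker
    }
  }
  if (L > R) {
    i <- which.max(ol); j <- which.min(or)
    stop(sprintf(
      "empty intersection: segment of %s (outer left %.2f Mb) conflicts with segment of %s (outer right %.2f Mb)",
      segs[[i]]$animal_id, L, segs[[j]]$animal_id, R))
  }

  il <- vapply(segs, `[[`, 0, "inner_left_mb")
  ir <- vapply(segs, `[[`, 0, "inner_right_mb")
  minimal <- if (max(il) <= min(ir)) {
    candidate_interval(chrom,
                       left_marker = segs[[which.max(il)]]$inner_left_marker,
                       right_marker = segs[[which.min(ir)]]$inner_right_marker,
                       left_mb = max(il), right_mb = min(ir),
                       n_support = length(segs))
  } else NULL

  # split the conservative span at excluded positions strictly inside it
  ex <- excluded_positions[!is.na(excluded_positions)]
  ex <- ex[ex > L & ex < R]
  ex <- sort(ex)
  bl <- c(is.finite(L), rep(TRUE, length(ex)))
  lpos <- c(if (is.finite(L)) L else NA_real_, unname(ex))
  lmk <- c(lm, if (is.null(names(ex))) rep(NA_character_, length(ex))
               else names(ex))
  rpos <- c(unname(ex), if (is.finite(R)) R else NA_real_)
  rmk <- c(if (is.null(names(ex))) rep(NA_character_, length(ex))
           else names(ex), rm_)
  br <- c(rep(TRUE, length(ex)), is.finite(R))
  candidates <- lapply(seq_along(lpos), function(k) {
    lo <- if (bl[k]) lpos[k] else -Inf
    hi <- if (br[k]) rpos[k] else Inf
    n_sup <- sum(il <= hi & ir >= lo)
    candidate_interval(chrom,
                       left_marker = lmk[k], right_marker = rmk[k],
                       left_mb = if (bl[k]) lpos[k] else NA,
                       right_mb = if (br[k]) rpos[k] else NA,
                       bounded_left = bl[k], bounded_right = br[k],
                       n_support = n_sup)
  })
  width_of <- function(iv) {
    lo <- if (iv$bounded_left) iv$left_mb else -Inf
    hi <- if (iv$bounded_right) iv$right_mb else Inf
    hi - lo
  }
  ord <- order(-vapply(candidates, function(x) as.double(x$n_support), 0),
               -vapply(candidates, width_of, 0),
               vapply(candidates, function(x)
                 if (x$bounded_left) x$left_mb else -Inf, 0))
  candidates <- candidates[ord]
  structure(list(conservative = candidates[[1L]], minimal = minimal,
                 candidates = candidates, n_conferring = length(segs)),
            class = "interval_refinement")
}

#' @export
print.interval_refinement <- function(x, ...) {
  cat("Progeny-test refinement from", x$n_conferring,
      "conferring segment(s)\n  conservative: ")
  print(x$conservative)
  if (is.null(x$minimal)) {
    cat("  minimal: empty (locus localized to overlapping uncertainty gaps)\n")
  } else {
    cat("  minimal:      ")
    print(x$minimal)
  }
  invisible(x)
}

#' Classify animals with a recombination inside a region
#'
#' Lists animals whose genotype calls change between adjacent informative
#' markers inside or immediately flanking the region — the observable
#' signature of at least one crossover there. (Compensating double
#' crossovers on the two homologues leave the genotype unchanged and are
#' invisible to any genotype-based classifier.)
#'
#' @param genotypes a [genotype_matrix()].
#' @param map a [genetic_map()].
#' @param chrom,left_mb,right_mb the region.
#' @return data frame `animal_id`, `n_discordant_steps` for listed animals.
#' @export
classify_recombinants <- function(genotypes, map, chrom, left_mb,
                                  right_mb) {
  sub <- map_chrom(map, chrom)
  sub <- sub[sub$marker %in% colnames(genotypes), , drop = FALSE]
  inside <- which(sub$pos_mb >= left_mb & sub$pos_mb <= right_mb)
  if (length(inside) == 0L) inside <- integer(0)
  lo <- if (length(inside)) min(inside) else
    max(1L, sum(sub$pos_mb < left_mb))
  hi <- if (length(inside)) max(inside) else lo
  sel <- seq(max(1L, lo - 1L), min(nrow(sub), hi + 1L))
  if (length(sel) < 2L)
    return(data.frame(animal_id = character(),
                      n_discordant_steps = integer()))
  calls <- genotypes[, sub$marker[sel], drop = FALSE]
  n_steps <- apply(calls, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(0L)
    sum(v[-1L] != v[-length(v)])
  })
  hit <- n_steps > 0L
  data.frame(animal_id = rownames(genotypes)[hit],
             n_discordant_steps = unname(n_steps[hit]),
             stringsAsFactors = FALSE)
}
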