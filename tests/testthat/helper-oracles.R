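# Independent oracles and random-instance generators shared across tests.
# Oracles are deliberately written set-/position-wise, a different route
# from the run-length machinery inside the package.

# random mapper instance: <= 10 markers on one chromosome, <= 25 animals
random_mapper_instance <- function(n_markers = sample(2:10, 1),
                                   n_animals = sample(1:25, 1),
                                   p_missing = 0.1) {
  pos <- sort(round(runif(n_markers, 1, 100), 3))
  while (any(diff(pos) == 0))
    pos <- sort(round(runif(n_markers, 1, 100), 3))
  map <- genetic_map(sprintf("M%02d", seq_len(n_markers)), "1", pos)
  calls <- matrix(sample(c("C", "H", "N", NA), n_markers * n_animals,
                         replace = TRUE,
                         prob = c(0.3, 0.4, 0.2, p_missing)),
                  nrow = n_animals,
                  dimnames = list(sprintf("A%02d", seq_len(n_animals)),
                                  map$marker))
  list(map = map, genotypes = genotype_matrix(calls))
}

# position-wise brute force: a marker position is consistent with the
# locus iff at most `tolerance` animals contradict carrier status there;
# candidate regions are the connected components of the consistent set.
oracle_mapper <- function(genotypes, map, mode = c("dominant", "recessive"),
                          recessive_code = "N", tolerance = 0) {
  mode <- match.arg(mode)
  ok <- vapply(map$marker, function(m) {
    v <- genotypes[, m]
    bad <- if (mode == "dominant") sum(v == "N", na.rm = TRUE)
           else sum(!is.na(v) & v != recessive_code)
    bad <= tolerance
  }, logical(1))
  comp <- split(seq_along(ok)[ok], cumsum(!ok)[ok])
  intervals <- lapply(comp, function(idx) {
    i <- min(idx); j <- max(idx)
    list(left_mb = if (i > 1) map$pos_mb[i - 1] else NA,
         right_mb = if (j < nrow(map)) map$pos_mb[j + 1] else NA,
         bounded_left = i > 1, bounded_right = j < nrow(map))
  })
  list(consistent = unname(ok), intervals = unname(intervals))
}

# compare an exclusion_report with the oracle on the same instance
expect_matches_oracle <- function(report, oracle, map) {
  expect_identical(report$markers$status != "EXCLUDED", oracle$consistent)
  ivs <- report$intervals
  expect_equal(length(ivs), length(oracle$intervals))
  key <- function(x) sprintf("%s|%s|%s|%s",
                             x$bounded_left,
                             ifelse(x$bounded_left, x$left_mb, ""),
                             x$bounded_right,
                             ifelse(x$bounded_right, x$right_mb, ""))
  expect_setequal(vapply(ivs, key, ""), vapply(oracle$intervals, key, ""))
}

# exhaustive hypergeometric enumeration for a 2x2 table via explicit
# binomial-coefficient products (no dhyper)
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_all <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, a_all) + lchoose(r2, c1 - a_all) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[match(tab[1, 1], a_all)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# position-wise brute force for progeny-test intersection: consistent
# positions lie inside every conferring outer interval (strictly inside,
# bounds being excluded markers) and at no excluded position
oracle_consistent_positions <- function(results, grid,
                                        excluded_positions = numeric(0)) {
  conf <- Filter(function(r) r$confers, results)
  keep <- rep(TRUE, length(grid))
  for (r in conf) {
    s <- r$segment
    if (s$bounded_left) keep <- keep & grid > s$outer_left_mb
    if (s$bounded_right) keep <- keep & grid < s$outer_right_mb
  }
  for (e in excluded_positions) keep <- keep & grid != e
  grid[keep]
}

# random recombinant-segment set over a shared marker grid; guarantees a
# common consistent position so the intersection is never empty
random_segment_set <- function(n_segments = sample(2:5, 1),
                               n_markers = 8) {
  pos <- sort(sample(seq(2, 98, by = 2), n_markers))
  map <- genetic_map(sprintf("M%d", seq_len(n_markers)), "1", pos)
  anchor <- sample(seq_len(n_markers - 1), 1)  # locus between these
  results <- lapply(seq_len(n_segments), function(k) {
    i <- sample(seq_len(anchor), 1)
    j <- sample(anchor:n_markers, 1)[1]
    calls <- rep(NA_character_, n_markers)
    calls[i:j] <- "H"
    if (i > 1) calls[seq_len(i - 1)] <- "N"
    if (j < n_markers) calls[(j + 1):n_markers] <- "N"
    names(calls) <- map$marker
    progeny_test_result(
      infer_donor_segment(calls, map, animal_id = paste0("S", k)),
      n_progeny_tested = 10, n_affected = sample(0:3, 1))
  })
  # ensure at least one confers
  if (!any(vapply(results, `[[`, logical(1), "confers")))
    results[[1]] <- progeny_test_result(results[[1]]$segment, 10, 1)
  list(map = map, results = results,
       anchor_mb = mean(pos[c(anchor, anchor + 1)]))
}
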