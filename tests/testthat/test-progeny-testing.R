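map14 <- renag1_marker_map()

test_that("donor-segment inference on forced patterns", {
  # all heterozygous: inner = whole span, both outer bounds open
  calls <- setNames(rep("H", 9), map14$marker)
  s <- infer_donor_segment(calls, map14, "x")
  expect_identical(c(s$inner_left_marker, s$inner_right_marker),
                   c("D14Rat78", "D14Rat88"))
  expect_false(s$bounded_left || s$bounded_right)

  # (N, N, H, H, N) on five ordered markers
  m5 <- genetic_map(paste0("m", 1:5), "1", 1:5)
  calls <- setNames(c("N", "N", "H", "H", "N"), m5$marker)
  s <- infer_donor_segment(calls, m5)
  expect_identical(c(s$inner_left_marker, s$inner_right_marker),
                   c("m3", "m4"))
  expect_identical(c(s$outer_left_marker, s$outer_right_marker),
                   c("m2", "m5"))
  expect_equal(c(s$gap_left_mb, s$gap_right_mb), c(1, 1))

  # no carrier-informative call
  calls <- setNames(c("N", NA, "N", "N", "N"), m5$marker)
  expect_true(infer_donor_segment(calls, m5)$no_segment)
})

test_that("inferred inner segments are always inside the true ancestry", {
  set.seed(99)
  sim <- simulate_f2(50, map14, causal_pos_mb = 34.96, seed = 99)
  loci <- sim$truth$loci
  sire <- list(h1 = sim$truth$hap1[1, ], h2 = sim$truth$hap2[1, ])
  bc <- simulate_backcross(sire, loci, n = 500)
  for (i in seq_len(500)) {
    calls <- bc$genotypes[i, ]
    s <- infer_donor_segment(calls, map14, animal_id = i)
    truth <- setNames(bc$gametes[i, loci$marker_idx], map14$marker)
    if (s$no_segment) {
      expect_true(all(truth == 0L))
      next
    }
    # carrier calls always sit on true donor ancestry, and when the true
    # gamete carries a single donor block the inferred inner segment is
    # contained in it (multi-block gametes legitimately bridge non-donor
    # stretches between their outermost carrier markers)
    expect_true(all(truth[!is.na(calls) & calls == "H"] == 1L))
    if (sum(rle(as.vector(truth))$values == 1L) == 1L) {
      sel <- map14$pos_mb >= s$inner_left_mb &
        map14$pos_mb <= s$inner_right_mb
      expect_true(all(truth[sel] == 1L))
    }
    if (s$bounded_left)
      expect_identical(truth[[s$outer_left_marker]], 0L)
    if (s$bounded_right)
      expect_identical(truth[[s$outer_right_marker]], 0L)
  }
})

test_that("the progeny fixture refines to the published 34.73-35.11 bounds", {
  pg <- renag1_progeny_fixture()
  ref <- intersect_conferring_segments(pg$results)
  expect_identical(ref$n_conferring, 6L)
  cons <- ref$conservative
  expect_identical(c(cons$left_marker, cons$right_marker),
                   c("D14Uwm8", "D14Uwm9"))
  expect_equal(c(cons$left_mb, cons$right_mb), c(34.73, 35.11))
  # the two flanking recombinants have disjoint donor segments: the
  # minimal interval is empty and the locus sits in the gap overlap
  expect_null(ref$minimal)
})

test_that("a single conferring segment returns its own bounds", {
  pg <- renag1_progeny_fixture()
  one <- pg$results[3]                         # F2-3766
  ref <- intersect_conferring_segments(one)
  s <- one[[1]]$segment
  expect_equal(c(ref$conservative$left_mb, ref$conservative$right_mb),
               c(s$outer_left_mb, s$outer_right_mb))
  expect_equal(c(ref$minimal$left_mb, ref$minimal$right_mb),
               c(s$inner_left_mb, s$inner_right_mb))
})

test_that("intersection matches the position-wise brute force on random sets", {
  set.seed(808)
  for (i in 1:200) {
    rs <- random_segment_set()
    ref <- intersect_conferring_segments(rs$results)
    grid <- seq(0.5, 100.5, by = 0.25)
    ok <- oracle_consistent_positions(rs$results, grid)
    cons <- ref$conservative
    lo <- if (cons$bounded_left) cons$left_mb else -Inf
    hi <- if (cons$bounded_right) cons$right_mb else Inf
    expect_equal(range(ok), range(grid[grid > lo & grid < hi]))
    # conservative contains minimal
    if (!is.null(ref$minimal)) {
      expect_gte(ref$minimal$left_mb, lo)
      expect_lte(ref$minimal$right_mb, hi)
    }
  }
})

test_that("adding a conferring segment never widens either interval", {
  set.seed(123)
  for (i in 1:50) {
    rs <- random_segment_set(n_segments = 4)
    conf <- Filter(function(r) r$confers, rs$results)
    if (length(conf) < 2) next
    r_few <- intersect_conferring_segments(conf[-length(conf)])
    r_all <- intersect_conferring_segments(conf)
    lo <- function(x) if (x$bounded_left) x$left_mb else -Inf
    hi <- function(x) if (x$bounded_right) x$right_mb else Inf
    expect_gte(lo(r_all$conservative), lo(r_few$conservative))
    expect_lte(hi(r_all$conservative), hi(r_few$conservative))
  }
})

test_that("excluded positions clip the conservative interval", {
  pg <- renag1_progeny_fixture()
  wide <- pg$results[3:5]                      # spanning segments only
  ref0 <- intersect_conferring_segments(wide)
  ref1 <- intersect_conferring_segments(
    wide, excluded_positions = c(D14Uwm12 = 36.25))
  expect_lt(ref1$conservative$right_mb, ref0$conservative$right_mb)
  expect_identical(ref1$conservative$right_marker, "D14Uwm12")
})

test_that("an empty intersection names the conflicting segments", {
  m5 <- genetic_map(paste0("m", 1:5), "1", 1:5)
  seg <- function(calls, id)
    infer_donor_segment(setNames(calls, m5$marker), m5, id)
  r <- list(
    progeny_test_result(seg(c("H", "N", "N", "N", "N"), "left"), 10, 1),
    progeny_test_result(seg(c("N", "N", "N", "N", "H"), "right"), 10, 1))
  expect_error(intersect_conferring_segments(r),
               "empty intersection.*left.*right")
  expect_error(intersect_conferring_segments(list(
    progeny_test_result(seg(c("H", NA, NA, NA, NA), "a"), 10, 0))),
    "no conferring segment")
})

test_that("recombinant classification agrees with the Haldane expectation", {
  # two markers d cM apart: an F2 genotype differs across the interval
  # with probability 2r(1-r) (compensating double crossovers are
  # invisible to genotype data)
  d <- 12
  m2 <- genetic_map(c("a", "b"), "1", c(10, 20), pos_cm = c(0, d))
  sim <- simulate_f2(5000, m2, penetrance_model(0, 0, 0),
                     causal_pos_mb = 15, seed = 31)
  rec <- classify_recombinants(sim$genotypes, m2, "1", 10, 20)
  r <- haldane_recomb_fraction(d)
  p <- 2 * r * (1 - r)
  expect_lt(abs(nrow(rec) / 5000 - p), 3 * sqrt(p * (1 - p) / 5000))
  # trivial cases
  g <- genotype_matrix(rbind(u = c("H", "H"), v = c("N", "H")),
                       marker_names = m2$marker,
                       animal_ids = c("u", "v"))
  out <- classify_recombinants(g, m2, "1", 10, 20)
  expect_identical(out$animal_id, "v")
})

test_that("progeny_test_result validates its counts", {
  pg <- renag1_progeny_fixture()
  s <- pg$results[[1]]$segment
  expect_error(progeny_test_result(s, 5, 6), "exceeds")
  expect_false(progeny_test_result(s, 5, 0)$confers)
})
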