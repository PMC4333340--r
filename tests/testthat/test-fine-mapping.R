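test_that("the exclusion fixture maps to the published 2.0 Mb interval", {
  fx <- renag1_exclusion_fixture()
  rep <- map_dominant_exclusion(fx$genotypes, fx$map)
  expect_identical(length(rep$intervals), 1L)
  iv <- rep$intervals[[1]]
  expect_identical(iv$left_marker, "D14Uwm7")
  expect_identical(iv$right_marker, "D14Uwm12")
  expect_equal(c(iv$left_mb, iv$right_mb), c(34.25, 36.25))
  expect_equal(iv$width_mb, 2.0)
  st <- rep$markers
  expect_identical(st$status[st$marker %in% c("D14Uwm8", "D14Uwm9")],
                   rep("NOT_EXCLUDED", 2))
  expect_true(all(st$status[!st$marker %in% c("D14Uwm8", "D14Uwm9")] ==
                  "EXCLUDED"))
})

test_that("the hooded inclusion fixture maps to the 20.72 Mb interval", {
  fx <- hooded_inclusion_fixture()
  rep <- map_recessive_inclusion(fx$genotypes, fx$map)
  iv <- rep$intervals[[1]]
  expect_identical(c(iv$left_marker, iv$right_marker),
                   c("D14Arb6", "D14Rat15"))
  expect_equal(iv$width_mb, 20.72)
})

test_that("a single fully heterozygous animal is uninformative", {
  map <- renag1_marker_map()
  g <- genotype_matrix(matrix("H", 1, 9,
                              dimnames = list("A1", map$marker)))
  rep <- map_dominant_exclusion(g, map)
  expect_identical(length(rep$intervals), 1L)
  expect_false(rep$intervals[[1]]$bounded_left)
  expect_false(rep$intervals[[1]]$bounded_right)
  expect_true(is.na(rep$intervals[[1]]$width_mb))
})

test_that("degenerate inputs produce the specified errors/diagnostics", {
  map <- renag1_marker_map()
  g0 <- genotype_matrix(matrix(character(0), 0, 9),
                        animal_ids = character(0),
                        marker_names = map$marker)
  expect_error(map_dominant_exclusion(g0, map), "no phenotype-positive")
  gN <- genotype_matrix(matrix("N", 2, 9,
                               dimnames = list(c("a", "b"), map$marker)))
  rep <- map_dominant_exclusion(gN, map)
  expect_identical(length(rep$intervals), 0L)
  expect_match(rep$diagnostic, "every marker excluded")
  gx <- genotype_matrix(matrix("H", 1, 1,
                               dimnames = list("a", "DXunknown")))
  expect_error(map_dominant_exclusion(gx, map), "absent from map")
})

test_that("missing calls never exclude and NON_INFORMATIVE markers join runs", {
  map <- genetic_map(c("m1", "m2", "m3"), "1", c(1, 2, 3))
  calls <- rbind(A1 = c("N", NA, "H"), A2 = c("N", NA, "H"))
  colnames(calls) <- map$marker
  rep <- map_dominant_exclusion(genotype_matrix(calls), map)
  expect_identical(rep$markers$status, c("EXCLUDED", "NON_INFORMATIVE",
                                         "NOT_EXCLUDED"))
  expect_identical(rep$intervals[[1]]$left_marker, "m1")
  expect_false(rep$intervals[[1]]$bounded_right)
})

test_that("both mappers match the brute-force oracle on random instances", {
  set.seed(314)
  for (i in 1:250) {
    inst <- random_mapper_instance()
    tol <- sample(0:1, 1)
    expect_matches_oracle(
      map_dominant_exclusion(inst$genotypes, inst$map, tol),
      oracle_mapper(inst$genotypes, inst$map, "dominant",
                    tolerance = tol),
      inst$map)
    expect_matches_oracle(
      map_recessive_inclusion(inst$genotypes, inst$map, tolerance = tol),
      oracle_mapper(inst$genotypes, inst$map, "recessive",
                    tolerance = tol),
      inst$map)
  }
})

test_that("adding affected animals is monotone (exclusion only grows)", {
  set.seed(55)
  for (i in 1:50) {
    inst <- random_mapper_instance(n_animals = 20)
    g <- inst$genotypes
    r1 <- map_dominant_exclusion(g[1:10, , drop = FALSE], inst$map)
    r2 <- map_dominant_exclusion(g, inst$map)
    was_excluded <- r1$markers$status == "EXCLUDED"
    expect_true(all(r2$markers$status[was_excluded] == "EXCLUDED"))
    w1 <- suppressWarnings(max(c(-Inf, vapply(
      r1$intervals, function(x) x$width_mb, 0)), na.rm = TRUE))
    w2 <- suppressWarnings(max(c(-Inf, vapply(
      r2$intervals, function(x) x$width_mb, 0)), na.rm = TRUE))
    if (is.finite(w1) && is.finite(w2)) expect_lte(w2, w1 + 1e-12)
  }
})

test_that("reversing marker order yields the mirrored interval", {
  fx <- renag1_exclusion_fixture()
  flip <- 200 - rev(fx$map$pos_mb)
  map_r <- genetic_map(rev(fx$map$marker), "14", flip)
  rep <- map_dominant_exclusion(fx$genotypes, map_r)
  iv <- rep$intervals[[1]]
  expect_identical(c(iv$left_marker, iv$right_marker),
                   c("D14Uwm12", "D14Uwm7"))
  expect_equal(iv$width_mb, 2.0)
})

test_that("phenocopy-free containment holds and tolerance rescues phenocopies", {
  map <- renag1_marker_map()
  # phenocopy-free: quick 25-replicate version (the 200-replicate run is
  # an acceptance criterion)
  expect_equal(containment_probability(25, map, causal_pos_mb = 34.96,
                                       n_progeny = 300, seed = 8), 1.0)
  # with phenocopies, tolerance 0 can drop below 1 while a matched
  # tolerance restores containment
  leaky <- penetrance_model(p_CC = 0.4, p_CH = 0.2, p_NN = 0.05)
  p0 <- containment_probability(40, map, leaky, causal_pos_mb = 34.96,
                                n_progeny = 300, tolerance = 0, seed = 21)
  p5 <- containment_probability(40, map, leaky, causal_pos_mb = 34.96,
                                n_progeny = 300, tolerance = 12, seed = 21)
  expect_lt(p0, 1)
  expect_gt(p5, p0)
})
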