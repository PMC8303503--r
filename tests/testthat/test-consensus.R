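# Build a two-dataset family over a shared universe with a prescribed
# plus-set overlap.
family_with_overlap <- function(universe_size, k1, k2, overlap) {
  ids <- sprintf("g%03d", seq_len(universe_size))
  s1 <- ids[seq_len(k1)]
  s2 <- c(ids[seq_len(overlap)],
          if (k2 > overlap) ids[(k1 + 1):(k1 + k2 - overlap)])
  set_family(list(D1 = list(universe = ids, plus = s1, minus = character()),
                  D2 = list(universe = ids, plus = s2, minus = character())))
}

test_that("set intersection across datasets is plain and validated", {
  fam <- set_family(list(
    D1 = list(universe = c("A", "B", "C", "X"), plus = c("A", "B", "C"),
              minus = "X"),
    D2 = list(universe = c("B", "C", "D", "Y"), plus = c("B", "C", "D"),
              minus = "Y")))
  expect_setequal(intersect_sets(fam, c("D1", "D2"), "plus"), c("B", "C"))
  expect_length(intersect_sets(fam, c("D1", "D2"), "minus"), 0)
  expect_error(intersect_sets(fam, c("D1", "D9"), "plus"), "unknown")
  expect_error(set_family(list(D1 = list(universe = "A", plus = "B",
                                         minus = character()))),
               "within the universe")
  expect_error(set_family(list(D1 = list(universe = c("A", "B"), plus = "A",
                                         minus = "A"))), "overlap")
})

test_that("exact two-set tail probability matches closed forms", {
  expect_equal(exact_two_set_p(c(10, 10), c(5, 5), 10, 0), 1.0)
  expect_equal(exact_two_set_p(c(10, 10), c(5, 5), 10, 5), 1 / 252,
               tolerance = 1e-12)
  # direct hypergeometric when universes coincide
  expect_equal(exact_two_set_p(c(20, 20), c(6, 8), 20, 3),
               phyper(2, 6, 14, 8, lower.tail = FALSE), tolerance = 1e-12)
  expect_error(exact_two_set_p(c(10, 10), c(5, 5), 10, 6), "exceed")
})

test_that("permutation intersection p handles boundary cases exactly", {
  fam0 <- set_family(list(
    D1 = list(universe = sprintf("g%d", 1:10), plus = sprintf("g%d", 1:3),
              minus = character()),
    D2 = list(universe = sprintf("g%d", 6:15), plus = sprintf("g%d", 13:15),
              minus = character())))
  rep0 <- permutation_intersection_p(fam0, c("D1", "D2"), "plus",
                                     n_iterations = 50, seed = 1)
  expect_equal(rep0$observed_size, 0)
  expect_equal(rep0$p_value, 1.0)  # every random size is >= 0

  # both sets equal to their universes: every draw reproduces the overlap
  ids <- sprintf("g%d", 1:8)
  fam1 <- set_family(list(D1 = list(universe = ids, plus = ids,
                                    minus = character()),
                          D2 = list(universe = ids, plus = ids,
                                    minus = character())))
  rep1 <- permutation_intersection_p(fam1, c("D1", "D2"), "plus",
                                     n_iterations = 50, seed = 1)
  expect_equal(rep1$p_value, 1.0)
  expect_equal(rep1$observed_size, 8)

  expect_error(permutation_intersection_p(fam1, c("D1", "D2"), "plus",
                                          n_iterations = 0), ">= 1")

  # seeded runs reproduce; the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99)
  r_a <- permutation_intersection_p(fam0, c("D1", "D2"), "plus", 200, seed = 7)
  expect_identical(runif(1), before)
  r_b <- permutation_intersection_p(fam0, c("D1", "D2"), "plus", 200, seed = 7)
  expect_identical(r_a$p_value, r_b$p_value)
})

test_that("permutation p is monotone non-increasing in observed overlap", {
  ps <- vapply(0:5, function(ov) {
    fam <- family_with_overlap(40, 10, 10, ov)
    permutation_intersection_p(fam, c("D1", "D2"), "plus",
                               n_iterations = 2000, seed = 5)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("permutation p agrees with the exact tail on shared universes", {
  fam <- family_with_overlap(10, 5, 5, 5)
  rep <- permutation_intersection_p(fam, c("D1", "D2"), "plus",
                                    n_iterations = 10000, seed = 2)
  p_exact <- 1 / 252
  mc_sd <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(rep$p_value - p_exact), 3 * mc_sd)
  expect_equal(rep$p_value_corrected,
               (rep$p_value * 10000 + 1) / 10001, tolerance = 1e-12)
})

test_that("null families produce no excess of small p-values", {
  set.seed(31)
  ids <- sprintf("g%03d", 1:100)
  ps <- replicate(120, {
    fam <- set_family(list(
      D1 = list(universe = ids, plus = sample(ids, 10), minus = character()),
      D2 = list(universe = ids, plus = sample(ids, 10), minus = character())))
    permutation_intersection_p(fam, c("D1", "D2"), "plus",
                               n_iterations = 400)$p_value
  })
  # fraction below 0.05 should be at the nominal level up to MC noise
  expect_lt(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})

test_that("venn counts cover every dataset subset", {
  fam <- family_with_overlap(30, 8, 8, 4)
  vc <- venn_counts(fam, "plus")
  expect_equal(nrow(vc), 3)  # D1, D2, D1&D2
  expect_equal(vc$size[vc$datasets == "D1&D2"], 4)
  expect_equal(sort(vc$size[vc$n_datasets == 1]), c(8, 8))
})
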