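test_that("expected fraction is the focal condition's share of cells", {
  meta <- data.frame(condition = rep(c("TBI", "Control"), c(6296, 3704)))
  expect_equal(expected_fraction(meta), 0.6296)
  meta2 <- data.frame(condition = rep(c("TBI", "Control"), c(5739, 4261)))
  expect_equal(expected_fraction(meta2), 0.5739)
  expect_equal(expected_fraction(
    data.frame(condition = rep(c("TBI", "Control"), 50))), 0.5)
  expect_error(expected_fraction(data.frame(condition = rep("TBI", 5))),
               "present")
})

test_that("two-sided binomial p equals exhaustive enumeration", {
  tab <- function(k, n) data.frame(cluster = "c", cells_control = n - k,
                                   cells_tbi = k)
  # observed equals expectation
  expect_equal(binomial_enrichment(tab(5, 10), p0 = 0.5)$p_value, 1)
  # n=10, k=9, p0=0.5: 22/1024 by counting outcomes no likelier than k=9
  expect_equal(binomial_enrichment(tab(9, 10), p0 = 0.5)$p_value, 22 / 1024)
  # near-null fraction under the study's p0 is enriched with p close to 1
  r <- binomial_enrichment(tab(126, 200), p0 = 0.6296)
  expect_gt(r$p_value, 0.9)
  expect_identical(r$direction, "enriched")
  # full grid vs the base-R exact test
  for (p0 in c(0.3, 0.5, 0.6296)) {
    for (n in 1:25) {
      for (k in 0:n) {
        expect_equal(binomial_enrichment(tab(k, n), p0 = p0)$p_value,
                     stats::binom.test(k, n, p0)$p.value,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("binomial p is symmetric at p0 = 0.5 and monotone away from n*p0", {
  tab <- function(k, n) data.frame(cluster = "c", cells_control = n - k,
                                   cells_tbi = k)
  for (n in c(7, 12, 20)) {
    p <- vapply(0:n, function(k)
      binomial_enrichment(tab(k, n), p0 = 0.5)$p_value, numeric(1))
    expect_equal(p, rev(p), tolerance = 1e-12)
    above <- p[(floor(n * 0.5) + 1):(n + 1)]
    expect_true(all(diff(above) <= 1e-12))
  }
})

test_that("enrichment table handles empty clusters and direction labels", {
  tab <- data.frame(cluster = c("a", "b", "c"),
                    cells_control = c(30, 0, 50),
                    cells_tbi = c(70, 0, 50))
  r <- binomial_enrichment(tab, p0 = 0.5)
  expect_false(r$testable[2])
  expect_true(is.na(r$p_value[2]))
  expect_identical(r$direction, c("enriched", NA, "none"))
  expect_error(binomial_enrichment(tab, p0 = 1), "inside")
  # composition_table pivots cell metadata correctly
  meta <- data.frame(population = c("a", "a", "b"),
                     condition = c("TBI", "Control", "TBI"))
  ct <- composition_table(meta)
  expect_equal(ct$cells_tbi, c(1, 1))
  expect_equal(ct$cells_control, c(1, 0))
})

test_that("overlap percentages and similarity counts match set arithmetic", {
  a <- list(p1 = letters[1:10], p2 = letters[1:3], empty = character())
  b <- list(q1 = letters[1:10], q2 = letters[11:20],
            q3 = c(letters[1:4], "zz"))
  m <- overlap_matrix(a, b)
  expect_equal(m["p1", "q1"], 100)
  expect_equal(m["p1", "q2"], 0)
  expect_equal(m["p1", "q3"], 40)
  expect_true(all(is.na(m["empty", ])))
  expect_identical(attr(m, "undefined_rows"), "empty")
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 100))

  sets <- list(x = c("a", "b", "c"), y = c("b", "c", "d", "e"),
               z = c("f"))
  sc <- similarity_counts(sets)
  expect_equal(unname(diag(sc)), c(3L, 4L, 1L))
  expect_equal(sc["x", "y"], 2L)
  expect_equal(sc["x", "z"], 0L)
  expect_identical(sc, t(sc))
  expect_error(similarity_counts(sets[1]), "at least two")
  expect_error(similarity_counts(setNames(sets, c("x", "x", "z"))),
               "duplicate")
})

test_that("keyword filtering is a case-insensitive substring match", {
  tab <- data.frame(term_id = c("GO:1", "GO:2", "GO:3"),
                    description = c("positive regulation of neuron differentiation",
                                    "ribosome assembly",
                                    "axonogenesis"),
                    p = c(0.01, 0.02, 0.03))
  f <- keyword_filter(tab)
  expect_true("GO:1" %in% f$term_id)   # matches 'Neuron'
  expect_false("GO:2" %in% f$term_id)
  expect_true("GO:3" %in% f$term_id)   # matches 'Axon'/'Axonogenesis'
  expect_identical(keyword_filter(tab, character()), tab)
  expect_length(default_keywords(), 23)
})
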