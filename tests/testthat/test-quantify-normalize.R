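mk_loci <- function(starts, width = 60L) {
  data.frame(locus_id = sprintf("L%02d", seq_along(starts)), chrom = "chr1",
             start = starts, end = starts + width, strand = "+")
}

mk_reads2 <- function(starts, len = 22L, sample = "s1", strand = "+") {
  n <- length(starts)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             chrom = rep("chr1", n), start = starts, end = starts + len,
             strand = rep(strand, n), seq = rep("A", n),
             sample = rep(sample, n))
}

test_that("read counting follows the 50%-overlap rule and conserves reads", {
  loci <- mk_loci(c(100L, 500L))
  em <- count_matrix(mk_reads2(integer(0)), loci)
  expect_true(all(dim(em$values) == c(2, 0)))

  em <- count_matrix(mk_reads2(rep(110L, 10)), loci)
  expect_equal(em$values["L01", "s1"], 10L)

  # 50% boundary: read [89,111) overlaps locus [100,160) by 11/22 -> counted;
  # read [88,110) overlaps by 10/22 -> unassigned
  em <- count_matrix(mk_reads2(c(89L, 88L)), loci)
  expect_equal(em$values["L01", "s1"], 1L)
  expect_equal(attr(em, "unassigned")[["s1"]], 1L)

  # opposite strand is never counted
  em <- count_matrix(mk_reads2(110L, strand = "-"), loci)
  expect_equal(sum(em$values), 0L)

  withr::with_seed(41, {
    reads <- rbind(
      mk_reads2(sample.int(900, 200, replace = TRUE), sample = "s1"),
      mk_reads2(sample.int(900, 150, replace = TRUE), sample = "s2"))
    loci <- mk_loci(c(50L, 200L, 400L, 700L))
    em <- count_matrix(reads, loci)
    expect_equal(unclass(em$values), bf_count(reads, loci))
    expect_equal(colSums(em$values) + attr(em, "unassigned"),
                 c(s1 = 200L, s2 = 150L))
  })

  expect_error(count_matrix(mk_reads2(1L), rbind(mk_loci(1L), mk_loci(1L))),
               "duplicate")
})

test_that("TMM factors are exact on degenerate designs and match a
           straight-line recomputation", {
  base <- withr::with_seed(2, rnbinom(200, mu = 80, size = 5) + 1L)
  y_id <- matrix(rep(base, 4), ncol = 4,
                 dimnames = list(sprintf("L%03d", 1:200), paste0("s", 1:4)))
  f <- tmm_factors(expression_matrix(y_id, "raw_counts"))
  expect_equal(unname(f$factors), rep(1, 4))

  # pure library-size scaling leaves factors at 1
  y_sc <- y_id; y_sc[, 2] <- y_id[, 1] * 3L
  f <- tmm_factors(expression_matrix(y_sc, "raw_counts"))
  expect_equal(unname(f$factors), rep(1, 4), tolerance = 1e-12)

  # seeded 4-sample NB fixture vs the independent oracle, to 1e-10
  y <- withr::with_seed(11, matrix(rnbinom(400, mu = 150, size = 8),
                                   ncol = 4,
                                   dimnames = list(sprintf("L%03d", 1:100),
                                                   paste0("s", 1:4))))
  em <- expression_matrix(y, "raw_counts")
  got <- tmm_factors(em)
  ref <- match(got$reference_sample, colnames(y))
  raw <- vapply(seq_len(4), function(k) {
    if (k == ref) 1 else tmm_oracle_factor(y[, k], y[, ref])
  }, numeric(1))
  expected <- raw / exp(mean(log(raw)))
  expect_equal(unname(got$factors), expected, tolerance = 1e-10)

  # scaling every count by a constant leaves factors unchanged
  got2 <- tmm_factors(expression_matrix(y * 5L, "raw_counts"))
  expect_equal(got2$factors, got$factors, tolerance = 1e-12)

  expect_error(tmm_factors(expression_matrix(y[, 1, drop = FALSE],
                                             "raw_counts")), "2 samples")
  y0 <- y; y0[, 2] <- 0L
  expect_error(tmm_factors(expression_matrix(y0, "raw_counts")), "s2")
})

test_that("TMM factors agree with edgeR on a well-behaved fixture", {
  y <- withr::with_seed(33, matrix(rnbinom(1200, mu = 200, size = 10),
                                   ncol = 6,
                                   dimnames = list(sprintf("L%03d", 1:200),
                                                   paste0("s", 1:6))))
  ours <- tmm_factors(expression_matrix(y, "raw_counts"))$factors
  theirs <- edgeR::calcNormFactors(y, method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("normalization is linear with column sums 1e6 / factor", {
  y <- matrix(c(1L, 0L, 3L, 2L, 5L, 1L), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  f <- list(reference_sample = "s1", factors = c(s1 = 1, s2 = 1))
  unit <- matrix(c(1L, 999999L, 2L, 999998L), ncol = 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  nm <- tmm_normalize(expression_matrix(unit, "raw_counts"), f)
  expect_equal(nm$values["a", "s1"], 1.0)  # count 1, 1e6 library, factor 1

  em <- expression_matrix(y, "raw_counts")
  f2 <- tmm_factors(em)
  nm2 <- tmm_normalize(em, f2)
  expect_equal(colSums(nm2$values), 1e6 / f2$factors[colnames(y)])
  # doubling a count doubles its normalized value at fixed factors
  y2 <- y; y2[1, 1] <- 2L * y[1, 1]
  nm3 <- tmm_normalize(expression_matrix(y2, "raw_counts"), f)
  nm1 <- tmm_normalize(em, f)
  expect_equal(nm3$values[1, 1] * sum(y2[, 1]) / sum(y[, 1]),
               2 * nm1$values[1, 1])

  expect_error(tmm_normalize(em, list(factors = c(s1 = 1))), "s2")
})

test_that("expression gates sit on their published boundaries", {
  y <- matrix(c(9L, 10L, 0L, 0L), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  em <- expression_matrix(y, "raw_counts")
  expect_identical(expression_gates(em, "sum_reads"), "b")

  v <- matrix(c(0.1, 0.1, 0.1, 0.100001), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "above"), c("s1", "s2")))
  nm <- expression_matrix(v, "tmm_normalized")
  expect_identical(expression_gates(nm, "any_sample"), "above")  # strict >

  # 71 samples: ceiling(7.1) = 8 columns required
  v71 <- matrix(0, nrow = 2, ncol = 71,
                dimnames = list(c("seven", "eight"), sprintf("s%02d", 1:71)))
  v71["seven", 1:7] <- 1; v71["eight", 1:8] <- 1
  nm71 <- expression_matrix(v71, "tmm_normalized")
  expect_identical(expression_gates(nm71, "fraction_of_samples"), "eight")

  # monotonicity: adding reads never un-expresses a locus
  y2 <- y; y2["a", 1] <- y2["a", 1] + 5L
  expect_true("b" %in% expression_gates(expression_matrix(y2, "raw_counts"),
                                        "sum_reads"))
  expect_error(expression_gates(nm, "sum_reads"), "raw counts")
  expect_error(expression_gates(em, "any_sample"), "normalized")
})
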