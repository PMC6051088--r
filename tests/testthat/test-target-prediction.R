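revcomp_rna <- function(s) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")
}

test_that("a perfect complementary site scores the closed-form sum", {
  withr::with_seed(5, {
    mir <- rand_rna(22)
    utr <- paste0(rand_rna(80), revcomp_rna(mir), rand_rna(80))
  })
  sch <- scoring_scheme()
  hits <- duplex_align(mir, utr, sch, min_score = 100)
  expect_gte(length(hits), 1)
  best <- hits[[1]]
  # independent closed form: every position pairs at +5, seed positions x4
  expected <- sum(ifelse(1:22 %in% 2:8, 5 * 4, 5))
  expect_equal(best$score, expected)
  expect_equal(best$utr_start, 80L)
  expect_equal(best$utr_end, 102L)
  expect_true(all(best$pair_type == 2))

  # non-overlap: removing the site leaves nothing near that score
  expect_true(all(vapply(hits[-1], function(h) h$score < expected,
                         logical(1))))
})

test_that("sequences with no pairable bases never align", {
  # A needs U, G needs C or U: an A/G miRNA vs an A/G UTR cannot pair
  mir <- paste(rep(c("A", "G"), 11), collapse = "")
  utr <- paste(rep(c("G", "A"), 60), collapse = "")
  expect_length(duplex_align(mir, utr), 0L)
  expect_error(duplex_align("", utr), "empty")
})

test_that("the DP matches an exhaustive ungapped-offset oracle", {
  sch <- scoring_scheme(gap_open = 1000, gap_extend = 1000)  # forbid gaps
  pair_score <- function(m, u) sch$pair_scores[m, u]
  withr::with_seed(29, {
    for (rep in 1:25) {
      mir <- rand_rna(12)
      utr <- rand_rna(40)
      mr <- rev(strsplit(mir, "")[[1]])
      uu <- strsplit(utr, "")[[1]]
      best <- 0
      for (off in seq_len(40 - 1)) {      # all alignments of mr against utr
        for (i0 in 1:12) for (i1 in i0:12) {
          if (off + i1 - i0 > 40) next
          sc <- 0
          for (k in i0:i1) {
            mult <- if ((12 - k + 1) %in% sch$seed_positions) 4 else 1
            sc <- sc + pair_score(mr[k], uu[off + k - i0]) * mult
          }
          best <- max(best, sc)
        }
      }
      hits <- duplex_align(mir, utr, sch)
      got <- if (length(hits)) hits[[1]]$score else 0
      expect_equal(got, best, info = paste(mir, utr))
    }
  })
})

test_that("duplex energies follow the stack table and loop penalties", {
  tab <- knmir:::.stack_energy_table()
  expect_true(all(tab < 0))  # appending pairs never destabilizes

  # GC-rich perfect duplex clears the -20 kcal/mol threshold by summing the
  # shipped table over known steps: alternating GC/CG pairs
  mir <- paste(rep("GC", 11), collapse = "")
  utr <- paste0("AAAA", revcomp_rna(mir), "AAAA")
  h <- duplex_align(mir, utr)[[1]]
  en <- duplex_energy(h, mir, utr)
  p <- rep(c("GC", "CG"), length.out = 22)
  expected <- 4.09 + sum(tab[cbind(p[1:21], p[2:22])])
  expect_equal(en, expected, tolerance = 1e-9)
  expect_lt(en, -20)

  # a single pair has no stack
  one <- list(pairs = matrix(c(1L, 5L), 1), pair_type = 2L)
  expect_error(duplex_energy(one, "A", "AAAAU"), "fewer than 2")

  # an interior mismatch converts two stacks into one +3 loop
  mir2 <- "GGGGGGGGGG"
  utr2 <- "CCCCCACCCC"   # one central mismatch against the Gs
  h2 <- duplex_align(mir2, utr2, scoring_scheme(seed_multiplier = 1))
  if (length(h2) && any(h2[[1]]$pair_type == 0)) {
    en2 <- duplex_energy(h2[[1]], mir2, utr2)
    full <- duplex_energy(duplex_align(mir2, "CCCCCCCCCC",
                                       scoring_scheme(seed_multiplier = 1))[[1]],
                          mir2, "CCCCCCCCCC")
    expect_gt(en2, full)  # the loop is destabilizing
  }
})

test_that("emitted predictions always satisfy both published thresholds", {
  cfg <- sim_config(seed = 23, n_utrs = 60, planted_sites_per_mirna = 1,
                    n_target_pool = 20)
  mirs <- withr::with_seed(23, setNames(
    vapply(1:6, function(i) rand_rna(22), character(1)), paste0("m", 1:6)))
  pl <- plant_target_sites(mirs, cfg)
  pred <- predict_targets(mirs, pl$utrs)
  expect_true(all(pred$alignment_score >= 140))
  expect_true(all(pred$duplex_energy <= -20))
  planted_pairs <- paste(pl$target_truth$mirna_id, pl$target_truth$gene_id)
  got_pairs <- paste(pred$mirna, pred$gene)
  expect_gte(mean(planted_pairs %in% got_pairs), 0.9)
})

test_that("the scrambled-sequence null discards shared-gene hits and is
           anti-monotone in the number of scrambles", {
  cfg <- sim_config(seed = 31, n_utrs = 40, planted_sites_per_mirna = 1,
                    n_target_pool = 15)
  mirs <- withr::with_seed(31, setNames(
    vapply(1:4, function(i) rand_rna(22), character(1)), paste0("m", 1:4)))
  pl <- plant_target_sites(mirs, cfg)

  # no scramble can reach the thresholds on random UTRs: all pass
  pred <- scramble_null_filter(mirs, pl$utrs, seed = 1)
  expect_true(all(pred$passed_scramble_null))

  # plant the first scramble's own perfect site on a gene the true miRNA
  # also targets: that gene must now be discarded
  chars <- strsplit(mirs[[1]], "")[[1]]
  scr1 <- knmir:::.with_seed(99, paste(sample(chars), collapse = ""))
  g1 <- pred$gene[pred$mirna == "m1"][1]
  utrs2 <- pl$utrs
  utrs2[[g1]] <- paste0(utrs2[[g1]], revcomp_rna(scr1))
  pred2 <- scramble_null_filter(mirs, utrs2, seed = 99)
  expect_false(any(pred2$passed_scramble_null[pred2$mirna == "m1" &
                                                pred2$gene == g1]))

  # more scrambles can only discard more
  p1 <- scramble_null_filter(mirs, utrs2, n_scrambles = 1, seed = 99)
  p5 <- scramble_null_filter(mirs, utrs2, n_scrambles = 5, seed = 99)
  s1 <- p1[p1$passed_scramble_null, c("mirna", "gene")]
  s5 <- p5[p5$passed_scramble_null, c("mirna", "gene")]
  expect_true(all(paste(s5$mirna, s5$gene) %in% paste(s1$mirna, s1$gene)))

  expect_error(scramble_null_filter(mirs, pl$utrs, n_scrambles = 0),
               "n_scrambles")
})

test_that("target aggregation applies the ceiling fraction rule exactly", {
  inc <- data.frame(
    mirna = c("m1", "m2", "m3", "m1", "m2", "m1", rep(paste0("m", 1:30), 1)),
    gene = c("hub", "hub", "hub", "two", "two", "solo",
             rep("universal", 30)),
    passed_scramble_null = TRUE)
  got <- aggregate_targets(inc, n_mirnas = 30)          # threshold 3
  expect_setequal(got, c("hub", "universal"))

  # brute-force threshold scan oracle
  counts <- tapply(inc$mirna, inc$gene, function(x) length(unique(x)))
  expect_setequal(got, names(counts)[counts >= ceiling(0.10 * 30)])

  expect_setequal(aggregate_targets(inc, n_mirnas = 30,
                                    mirna_fraction = 1 / 30),
                  unique(inc$gene))  # every gene hit by >= 1 miRNA
  expect_error(aggregate_targets(inc, mirna_fraction = 0), "fraction")
})
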