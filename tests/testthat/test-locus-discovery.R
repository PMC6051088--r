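mk_reads <- function(starts, len = 22L, chrom = "chr1", strand = "+") {
  data.frame(read_id = sprintf("r%03d", seq_along(starts)),
             chrom = rep(chrom, length(starts)), start = starts,
             end = starts + len, strand = rep(strand, length(starts)),
             seq = rep("ACGT", length(starts)),
             sample = rep("s1", length(starts)))
}

test_that("stack_reads merges runs and matches a brute-force interval merge", {
  loci <- stack_reads(mk_reads(c(100L, 500L)), max_gap = 50)
  expect_length(loci, 2L)
  expect_equal(loci[[1]]$start, 100L)
  expect_equal(loci[[1]]$end, 122L)

  one <- stack_reads(mk_reads(150L))
  expect_length(one, 1L)
  expect_equal(one[[1]]$total_reads, 1L)

  expect_identical(stack_reads(mk_reads(integer(0))), list())
  expect_error(stack_reads(mk_reads(-5L)), "malformed")

  # brute-force oracle: number of maximal overlapping runs at max_gap = 0
  withr::with_seed(31, {
    starts <- sort(sample.int(2000, 100, replace = TRUE))
    reads <- mk_reads(starts, len = 15L)
    got <- stack_reads(reads, max_gap = 0, max_precursor_length = 10000)
    ends <- starts + 15L
    runs <- 1L
    cur_end <- ends[1]
    for (i in 2:100) {
      if (starts[i] > cur_end) runs <- runs + 1L
      cur_end <- max(cur_end, ends[i])
    }
    expect_length(got, runs)
    expect_equal(sum(vapply(got, `[[`, integer(1), "total_reads")), 100L)
  })
})

test_that("over-long loci are split at the deepest coverage valley", {
  # two dense stacks close enough to merge but jointly over-long
  starts <- c(rep(100L, 20), rep(260L, 20))
  loci <- stack_reads(mk_reads(starts), max_gap = 150,
                      max_precursor_length = 120)
  expect_length(loci, 2L)
  expect_true(all(vapply(loci, function(l) l$end - l$start, integer(1))
                  <= 120))
  expect_equal(sum(vapply(loci, `[[`, integer(1), "total_reads")), 40L)
  expect_setequal(vapply(loci, `[[`, integer(1), "start"), c(100L, 260L))
})

test_that("folding DP equals exhaustive enumeration and is well-formed", {
  expect_equal(fold_hairpin("AAAAAA")$pairing_score, 0L)
  expect_equal(fold_hairpin("AAAAAA")$structure, "......")
  expect_equal(fold_hairpin("GGGAAACCC")$pairing_score, 9L)
  expect_error(fold_hairpin("ACGTN"), "non-RNA")
  expect_error(fold_hairpin("ACGU", min_loop = 2), "min_loop")

  withr::with_seed(11, {
    for (i in 1:40) {
      n <- sample(4:12, 1)
      s <- rand_rna(n)
      f <- fold_hairpin(s)
      expect_equal(f$pairing_score, bf_fold_best(s), info = s)
      expect_equal(nchar(f$structure), n)
      db <- strsplit(f$structure, "")[[1]]
      expect_equal(sum(db == "("), sum(db == ")"))
      # minimum hairpin loop of 3 between any pair
      if (nrow(f$pairs)) expect_true(all(f$pairs[, 2] - f$pairs[, 1] > 3))
    }
  })
})

test_that("dinucleotide shuffles preserve composition exactly", {
  dinucs <- function(x) {
    v <- strsplit(x, "")[[1]]
    sort(paste0(v[-length(v)], v[-1]))
  }
  withr::with_seed(8, {
    for (i in 1:10) {
      s <- rand_rna(60)
      sh <- dinucleotide_shuffle(s, 5)
      for (x in sh) expect_identical(dinucs(x), dinucs(s))
    }
  })
})

test_that("randfold p-values obey their formula bounds and separate planted
           hairpins from decoys", {
  expect_equal(randfold_pvalue("AAAAAAAAAA", 99, seed = 1), 1.0)
  expect_error(randfold_pvalue("ACG", 99), "too short")
  expect_error(randfold_pvalue(rand_rna(30), 10), "n_shuffles")

  withr::with_seed(6, {
    p <- vapply(1:20, function(i) randfold_pvalue(rand_rna(50), 19),
                numeric(1))
    expect_true(all(p > 0 & p <= 1))
    expect_true(all(p >= 1 / 20))
  })

  cfg <- sim_config(seed = 5, n_true_hairpins = 12, n_decoy_loci = 12)
  g <- generate_genome(cfg)
  p_hp <- vapply(g$truth$hairpins$precursor_seq, randfold_pvalue,
                 numeric(1), n_shuffles = 99, seed = 5, USE.NAMES = FALSE)
  p_dc <- vapply(seq_len(nrow(g$truth$decoys)), function(i) {
    d <- g$truth$decoys[i, ]
    s <- chartr("T", "U", substring(g$genome[["chr1"]], d$start + 1, d$end))
    randfold_pvalue(s, 99, seed = 5)
  }, numeric(1))
  expect_lt(median(p_hp), median(p_dc))
  expect_true(all(p_hp <= 0.05))  # planted stems are unambiguous
})

test_that("randfold p-values are valid (conservative) on random sequences", {
  # with a discrete pairing score the >=-tie rule makes p super-uniform:
  # P(p <= t) must not exceed t beyond Monte-Carlo noise
  withr::with_seed(12, {
    p <- vapply(1:200, function(i) randfold_pvalue(rand_rna(70), 49),
                numeric(1))
    for (t in c(0.05, 0.1, 0.25, 0.5)) {
      expect_lte(mean(p <= t), t + 3 * sqrt(t * (1 - t) / 200))
    }
  })
})

test_that("the Dicer signature score separates clean stacks from smears", {
  cfg <- sim_config(seed = 2, n_true_hairpins = 1, n_decoy_loci = 0,
                    background_read_rate = 0)
  g <- generate_genome(cfg)
  hp <- g$truth$hairpins[1, ]

  # perfectly homogeneous mature stack: signature exactly 1
  clean <- mk_reads(rep(hp$mature_start, 30))
  loci <- stack_reads(clean)
  rna <- chartr("T", "U",
                substring(g$genome[["chr1"]], loci[[1]]$start + 1,
                          loci[[1]]$end))
  # widen to the full precursor so the stem is foldable
  loci <- list(modifyList(loci[[1]], list(start = hp$start, end = hp$end)))
  rna <- hp$precursor_seq
  sc <- score_candidate(loci[[1]], rna, fold_hairpin(rna))
  expect_false(is.null(sc$candidate))
  expect_equal(sc$candidate$signature_score, 1.0)
  expect_true(grepl(sc$candidate$mature_seq, rna, fixed = TRUE))

  # uniform random smear: below the cutoff in >= 95% of seeded trials
  withr::with_seed(14, {
    fails <- vapply(1:100, function(i) {
      starts <- hp$start + sample.int(50, 30, replace = TRUE)
      sm <- stack_reads(mk_reads(starts, len = 20L))[[1]]
      sm$start <- hp$start; sm$end <- hp$end
      r <- score_candidate(sm, hp$precursor_seq,
                           fold_hairpin(hp$precursor_seq))
      is.null(r$candidate) || r$candidate$signature_score < 0.6
    }, logical(1))
    expect_gte(mean(fails), 0.95)
  })

  empty <- loci[[1]]; empty$reads <- empty$reads[0, ]; empty$total_reads <- 0L
  expect_error(score_candidate(empty, rna, fold_hairpin(rna)), "no supporting")
})

test_that("discovery recovers planted hairpins and rejects decoys", {
  cfg <- sim_config(seed = 19, n_true_hairpins = 20, n_decoy_loci = 20,
                    read_depth_per_locus = 50)
  g <- generate_genome(cfg)
  reads <- simulate_reads(g$genome, g$truth, cfg)
  cand <- discover_candidates(reads[, names(reads) != "origin"], g$genome,
                              seed = 19)
  cand <- cand[cand$total_reads >= 10, ]  # drop background singletons
  hp <- g$truth$hairpins
  hit <- vapply(seq_len(nrow(hp)), function(i) {
    any(cand$start < hp$end[i] & cand$end > hp$start[i])
  }, logical(1))
  dc <- g$truth$decoys
  leak <- vapply(seq_len(nrow(dc)), function(i) {
    any(cand$start < dc$end[i] & cand$end > dc$start[i])
  }, logical(1))
  expect_gte(mean(hit), 0.9)
  expect_gte(mean(!leak), 0.9)
  # emitted mature is always a substring of its precursor
  expect_true(all(mapply(grepl, cand$mature_seq, cand$precursor_seq,
                         MoreArgs = list(fixed = TRUE))))
})
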