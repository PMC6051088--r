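# Independent oracles used across the suite.  Everything here is deliberately
# naive (exhaustive enumeration, straight-line arithmetic, O(n^3) loops) and
# shares no code path with the package internals it checks.

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# exhaustive maximum pairing score over all nested structures (hairpin loops
# >= min_loop), by full recursion without memoization
bf_fold_best <- function(seq, min_loop = 3L) {
  s <- strsplit(seq, "")[[1]]
  w <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, "CG" = 3L, "AU" = 2L, "GU" = 1L, 0L)
  }
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_loop + 1L):j) {
      if (k > j) break
      wk <- w(s[i], s[k])
      if (wk > 0L) {
        best <- max(best, wk + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(s) < 2) return(0L)
  rec(1L, length(s))
}

# straight-line recomputation of the TMM factor of one sample vs a reference
tmm_oracle_factor <- function(yk, yr, trim_m = 0.30, trim_a = 0.05) {
  Nk <- sum(yk); Nr <- sum(yr)
  keep <- yk > 0 & yr > 0
  yk <- yk[keep]; yr <- yr[keep]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  ord_m <- order(M); ord_a <- order(A)
  rank_m <- integer(n); rank_m[ord_m] <- seq_len(n)
  rank_a <- integer(n); rank_a[ord_a] <- seq_len(n)
  sel <- which(rank_m >= lo_m & rank_m <= hi_m &
                 rank_a >= lo_a & rank_a <= hi_a)
  num <- 0; den <- 0
  for (i in sel) {
    wi <- 1 / ((Nk - yk[i]) / (Nk * yk[i]) + (Nr - yr[i]) / (Nr * yr[i]))
    num <- num + wi * M[i]
    den <- den + wi
  }
  2^(num / den)
}

# naive average-linkage (UPGMA) merge heights from a distance matrix
upgma_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  Dm <- D
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(NA, NA); bd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d <- mean(Dm[active[[i]], active[[j]]])
      if (d < bd - 1e-12) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- active[-best]
    active[[length(active) + 1]] <- merged
  }
  heights
}

# brute-force read-to-locus counting: double loop, >= 50% overlap rule,
# ties to the lower-start locus
bf_count <- function(reads, loci, id_col = "locus_id") {
  samples <- sort(unique(reads$sample))
  out <- matrix(0L, nrow(loci), length(samples),
                dimnames = list(loci[[id_col]], samples))
  for (r in seq_len(nrow(reads))) {
    best <- NA; best_start <- Inf
    for (l in seq_len(nrow(loci))) {
      if (reads$chrom[r] != loci$chrom[l] ||
          reads$strand[r] != loci$strand[l]) next
      ov <- min(reads$end[r], loci$end[l]) - max(reads$start[r], loci$start[l])
      if (ov >= 0.5 * (reads$end[r] - reads$start[r]) &&
          loci$start[l] < best_start) {
        best <- l; best_start <- loci$start[l]
      }
    }
    if (!is.na(best)) {
      out[best, reads$sample[r]] <- out[best, reads$sample[r]] + 1L
    }
  }
  out
}

# constructed filter-cascade fixture: n_pass candidates that survive every
# step plus 10 candidates failing at each named step, fates known by design
make_cascade_fixture <- function(n_pass = 50, n_fail = 10, seed = 421) {
  withr::with_seed(seed, {
    known <- vapply(1:10, function(i) rand_rna(22), character(1))
    # exactly 11 GC of 22 so the pass population has zero GC spread and the
    # planted GC outliers (GC = 0) sit unambiguously beyond 2 SD
    mk_seq <- function() {
      repeat {
        s <- paste(sample(c(sample(c("G", "C"), 11, replace = TRUE),
                            sample(c("A", "U"), 11, replace = TRUE))),
                   collapse = "")
        if (knmir::homology_evalue(s, known) < 0.3) next  # safety margin
        return(s)
      }
    }
    row <- function(id, start, reads, p, sig, mat) {
      data.frame(locus_id = id, chrom = "chr1", start = start,
                 end = start + 60L, strand = "+", total_reads = reads,
                 randfold_p = p, signature_score = sig, mature_seq = mat,
                 stringsAsFactors = FALSE)
    }
    rows <- list(); pos <- 0L
    nxt <- function() { pos <<- pos + 500L; pos }
    pass_ids <- sprintf("pass_%02d", seq_len(n_pass))
    pass_seqs <- vapply(seq_len(n_pass), function(i) mk_seq(), character(1))
    for (i in seq_len(n_pass)) {
      rows[[length(rows) + 1]] <-
        row(pass_ids[i], nxt(), 50L, 0.01, 0.9, pass_seqs[i])
    }
    for (i in 1:n_fail) {  # step 1: too few reads (9 < 10; 10 passes)
      rows[[length(rows) + 1]] <-
        row(sprintf("lowreads_%02d", i), nxt(), 9L, 0.01, 0.9, mk_seq())
    }
    rrna_starts <- integer(n_fail)
    for (i in 1:n_fail) {  # step 2: decoy overlap
      s <- nxt(); rrna_starts[i] <- s
      rows[[length(rows) + 1]] <-
        row(sprintf("decoy_%02d", i), s, 50L, 0.01, 0.9, mk_seq())
    }
    for (i in 1:n_fail) {  # step 3: weak structure (0.05 is not < 0.05)
      rows[[length(rows) + 1]] <-
        row(sprintf("weakfold_%02d", i), nxt(), 50L, 0.05, 0.9, mk_seq())
    }
    for (i in 1:n_fail) {  # step 4: duplicate mature, lower signature
      rows[[length(rows) + 1]] <-
        row(sprintf("dup_%02d", i), nxt(), 50L, 0.01, 0.7, pass_seqs[i])
    }
    for (i in 1:n_fail) {  # step 5: identical to a known miRNA
      rows[[length(rows) + 1]] <-
        row(sprintf("known_%02d", i), nxt(), 50L, 0.01, 0.9, known[i])
    }
    for (i in 1:n_fail) {  # step 6: GC far outside the population
      s <- strsplit(paste(rep("A", 22), collapse = ""), "")[[1]]
      s[i] <- "U"  # keep sequences distinct, GC stays 0
      rows[[length(rows) + 1]] <-
        row(sprintf("gcout_%02d", i), nxt(), 50L, 0.01, 0.9,
            paste(s, collapse = ""))
    }
    list(
      candidates = do.call(rbind, rows),
      rrna_bed = data.frame(chrom = "chr1", start = rrna_starts + 10L,
                            end = rrna_starts + 30L, name = "rRNA",
                            score = 0, strand = "+"),
      known = known,
      pass_ids = pass_ids
    )
  })
}
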