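#' Assemble reads into candidate loci
#'
#' Maximal same-strand runs of reads whose inter-read gap is at most
#' `max_gap` become loci; loci longer than `max_precursor_length` are split
#' recursively at the deepest coverage valley (reads at the split go to the
#' side holding the larger share of the read, ties left).
#'
#' @param reads Read-placement data.frame (read_id, chrom, start, end,
#'   strand, seq, sample; 0-based half-open).
#' @param max_gap Maximum gap (bases) between reads merged into one locus.
#' @param max_precursor_length Maximum locus length in bases.
#' @return List of loci; each is a list with chrom, start, end, strand,
#'   total_reads, depth (per-position coverage) and reads (the supporting
#'   rows).
#' @export
stack_reads <- function(reads, max_gap = 30L, max_precursor_length = 120L) {
  if (nrow(reads) == 0) return(list())
  if (any(reads$start < 0 | reads$start >= reads$end)) {
    stop("malformed read coordinates: need 0 <= start < end")
  }
  loci <- list()
  for (key in unique(paste(reads$chrom, reads$strand))) {
    sub <- reads[paste(reads$chrom, reads$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    run_start <- sub$start[1]
    run_end <- sub$end[1]
    run_rows <- 1L
    flush <- function(rows, lo, hi) {
      loci[[length(loci) + 1L]] <<- list(
        chrom = sub$chrom[1], start = lo, end = hi,
        strand = sub$strand[1], reads = sub[rows, , drop = FALSE]
      )
    }
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - run_end <= max_gap) {
        run_end <- max(run_end, sub$end[i])
        run_rows <- c(run_rows, i)
      } else {
        flush(run_rows, run_start, run_end)
        run_start <- sub$start[i]
        run_end <- sub$end[i]
        run_rows <- i
      }
    }
    flush(run_rows, run_start, run_end)
  }
  out <- list()
  for (loc in loci) out <- c(out, .split_locus(loc, max_precursor_length))
  lapply(out, .finish_locus)
}

.locus_depth <- function(loc) {
  depth <- integer(loc$end - loc$start)
  for (i in seq_len(nrow(loc$reads))) {
    a <- max(loc$reads$start[i], loc$start) - loc$start + 1L
    b <- min(loc$reads$end[i], loc$end) - loc$start
    if (b >= a) depth[a:b] <- depth[a:b] + 1L
  }
  depth
}

.split_locus <- function(loc, max_len) {
  if (loc$end - loc$start <= max_len) return(list(loc))
  # a single over-long read cannot be split further; keep it whole
  if (nrow(loc$reads) < 2) return(list(loc))
  depth <- .locus_depth(loc)
  interior <- 2:(length(depth) - 1L)
  valley <- interior[which.min(depth[interior])]
  cut <- loc$start + valley - 1L  # split point (0-based)
  left_share <- pmin(loc$reads$end, cut) - loc$reads$start
  go_left <- left_share >= (loc$reads$end - loc$reads$start) / 2
  mk <- function(rows) {
    r <- loc$reads[rows, , drop = FALSE]
    list(chrom = loc$chrom, start = min(r$start), end = max(r$end),
         strand = loc$strand, reads = r)
  }
  if (all(go_left) || all(!go_left)) return(list(loc))  # no reduction
  c(.split_locus(mk(go_left), max_len), .split_locus(mk(!go_left), max_len))
}

.finish_locus <- function(loc) {
  loc$total_reads <- nrow(loc$reads)
  loc$depth <- .locus_depth(loc)
  tab <- table(paste(loc$reads$seq, loc$reads$start))
  loc$n_distinct_reads <- length(tab)
  loc
}

#' Fold an RNA sequence by weighted base-pair maximization
#'
#' Nussinov-style dynamic programming maximizing the summed pair weights
#' (G-C = 3, A-U = 2, G-U = 1) over nested structures whose hairpin loops
#' hold at least `min_loop` unpaired bases.  Traceback is deterministic:
#' position i pairs with the smallest admissible partner achieving the
#' optimum, else stays unpaired.
#'
#' @param seq RNA sequence (A/C/G/U).
#' @param min_loop Minimum hairpin loop size, >= 3.
#' @return List with `structure` (dot-bracket), `pairing_score` (integer) and
#'   `pairs` (2-column matrix of 1-based paired positions).
#' @export
fold_hairpin <- function(seq, min_loop = 3L) {
  if (min_loop < 3) stop("min_loop must be >= 3")
  code <- .encode_rna(seq)
  res <- .cpp_fold(code, as.integer(min_loop))
  structure_chr <- rep(".", length(code))
  if (nrow(res$pairs) > 0) {
    structure_chr[res$pairs[, 1]] <- "("
    structure_chr[res$pairs[, 2]] <- ")"
  }
  list(structure = paste(structure_chr, collapse = ""),
       pairing_score = res$score,
       pairs = res$pairs)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Eulerian-walk shuffle: every shuffle has exactly the
#' same dinucleotide composition (and therefore mononucleotide composition,
#' first and last base) as the input.
#'
#' @param seq RNA sequence (A/C/G/U), length >= 2.
#' @param n Number of shuffles.
#' @return Character vector of `n` shuffled sequences.
#' @export
dinucleotide_shuffle <- function(seq, n = 1L) {
  code <- .encode_rna(seq)
  m <- .cpp_dinuc_shuffle(code, as.integer(n))
  apply(m, 1, .decode_rna)
}

#' Shuffle-based p-value for folding stability
#'
#' p = (c + 1) / (n_shuffles + 1), where c counts dinucleotide-preserving
#' shuffles whose pairing score is at least the observed score.  The minimum
#' attainable p is 1 / (n_shuffles + 1).
#'
#' @param seq RNA sequence, >= 4 nt.
#' @param n_shuffles Number of shuffles, >= 19.
#' @param min_loop Minimum hairpin loop size passed to the folding scorer.
#' @param seed Optional seed; when given, shuffles are drawn from a local RNG
#'   stream without disturbing the caller's.
#' @return p-value in (0, 1].
#' @export
randfold_pvalue <- function(seq, n_shuffles = 99L, min_loop = 3L,
                            seed = NULL) {
  if (n_shuffles < 19) stop("n_shuffles must be >= 19")
  code <- .encode_rna(seq)
  if (length(code) < 4) stop("sequence too short to shuffle (< 4 nt)")
  obs <- .cpp_fold(code, as.integer(min_loop))$score
  .with_seed(seed, {
    shuf <- .cpp_dinuc_shuffle(code, as.integer(n_shuffles))
    scores <- .cpp_fold_score_many(shuf, as.integer(min_loop))
    (sum(scores >= obs) + 1) / (n_shuffles + 1)
  })
}

#' Score a locus as a Dicer-processed hairpin candidate
#'
#' The mature arm is the maximal read stack (modal 5' end, modal length); the
#' star is the region base-paired to the mature arm extended by the canonical
#' 2-nt 3' overhang.  The signature score is the fraction of locus reads
#' consistent with the mature/star/loop partition (within 2 nt of an arm, or
#' inside the loop) multiplied by the modal-5'-end fraction.  A candidate is
#' emitted only when at least half of the mature positions are base-paired
#' (the mature arm lies on a stem) and the signature score reaches
#' `min_signature`.
#'
#' @param locus A locus from [stack_reads()].
#' @param precursor_seq RNA sequence of the locus interval (genomic strand).
#' @param fold Result of [fold_hairpin()] on `precursor_seq`.
#' @param min_signature Minimum signature score for emission (default 0.6).
#' @return List with `candidate` (one-row data.frame, or NULL) and `reason`
#'   (NA when emitted).
#' @export
score_candidate <- function(locus, precursor_seq, fold, min_signature = 0.6) {
  if (locus$total_reads == 0) stop("locus has no supporting reads")
  reads <- locus$reads

  starts <- table(reads$start)
  modal_start <- as.integer(names(starts)[which.max(starts)])
  homogeneity <- max(starts) / nrow(reads)
  at_modal <- reads[reads$start == modal_start, , drop = FALSE]
  lens <- table(at_modal$end - at_modal$start)
  modal_len <- as.integer(names(lens)[which.max(lens)])
  mature_lo <- modal_start
  mature_hi <- modal_start + modal_len  # 0-based half-open, genomic

  # local 1-based coordinates within the precursor
  loc_lo <- mature_lo - locus$start + 1L
  loc_hi <- mature_hi - locus$start
  loc_lo <- max(loc_lo, 1L)
  loc_hi <- min(loc_hi, nchar(precursor_seq))

  pairs <- fold$pairs
  partner <- rep(NA_integer_, nchar(precursor_seq))
  if (nrow(pairs) > 0) {
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
  }
  mature_pos <- loc_lo:loc_hi
  paired_frac <- mean(!is.na(partner[mature_pos]))
  reject <- function(reason) list(candidate = NULL, reason = reason)
  if (paired_frac < 0.5) return(reject("mature arm not on a stem"))

  partners <- partner[mature_pos]
  partners <- partners[!is.na(partners)]
  star_lo_local <- min(partners)
  star_hi_local <- min(max(partners) + 2L, nchar(precursor_seq))
  star_lo <- locus$start + star_lo_local - 1L  # back to genomic 0-based
  star_hi <- locus$start + star_hi_local

  near <- function(s, e, lo, hi) abs(s - lo) <= 2 & abs(e - hi) <= 2
  loop_lo <- min(mature_hi, star_hi)
  loop_hi <- max(mature_lo, star_lo)
  consistent <- near(reads$start, reads$end, mature_lo, mature_hi) |
    near(reads$start, reads$end, star_lo, star_hi) |
    (reads$start >= loop_lo - 2 & reads$end <= loop_hi + 2)
  signature <- mean(consistent) * homogeneity
  if (signature < min_signature) {
    return(reject(sprintf("signature score %.3f below %.3f",
                          signature, min_signature)))
  }

  mature_seq <- substr(precursor_seq, loc_lo, loc_hi)
  star_seq <- substr(precursor_seq, star_lo_local, star_hi_local)
  cand <- data.frame(
    locus_id = sprintf("%s:%d-%d:%s", locus$chrom, locus$start, locus$end,
                       locus$strand),
    chrom = locus$chrom, start = locus$start, end = locus$end,
    strand = locus$strand, total_reads = locus$total_reads,
    precursor_seq = precursor_seq, structure = fold$structure,
    pairing_score = fold$pairing_score,
    mature_start = mature_lo, mature_end = mature_hi,
    mature_seq = mature_seq, star_seq = star_seq,
    signature_score = signature, gc_fraction = .gc_fraction(mature_seq),
    stringsAsFactors = FALSE
  )
  list(candidate = cand, reason = NA_character_)
}

#' Discover hairpin candidates from a read table
#'
#' Runs [stack_reads()], folds every locus, attaches the shuffle p-value and
#' applies [score_candidate()].
#'
#' @param reads Read-placement data.frame.
#' @param genome Named character vector of chromosome sequences (DNA).
#' @param max_gap,max_precursor_length Passed to [stack_reads()].
#' @param min_loop Minimum hairpin loop size.
#' @param n_shuffles Shuffles for the folding p-value.
#' @param min_signature Signature-score cutoff for emission.
#' @param seed Optional seed for the shuffle p-values.
#' @return data.frame of candidates (one row each) with a `randfold_p`
#'   column; rejected loci are recorded in the `rejections` attribute.
#' @export
discover_candidates <- function(reads, genome, max_gap = 30L,
                                max_precursor_length = 120L, min_loop = 3L,
                                n_shuffles = 99L, min_signature = 0.6,
                                seed = NULL) {
  loci <- stack_reads(reads, max_gap, max_precursor_length)
  out <- list()
  rejections <- data.frame(locus = character(), reason = character())
  .with_seed(seed, {
    for (loc in loci) {
      dna <- substring(genome[[loc$chrom]], loc$start + 1L, loc$end)
      if (loc$strand == "-") dna <- .revcomp_dna(dna)
      rna <- .as_rna(dna)
      fold <- fold_hairpin(rna, min_loop)
      sc <- score_candidate(loc, rna, fold, min_signature)
      lid <- sprintf("%s:%d-%d:%s", loc$chrom, loc$start, loc$end, loc$strand)
      if (is.null(sc$candidate)) {
        rejections[nrow(rejections) + 1L, ] <- list(lid, sc$reason)
        next
      }
      cand <- sc$candidate
      cand$randfold_p <- randfold_pvalue(rna, n_shuffles, min_loop)
      out[[length(out) + 1L]] <- cand
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(locus_id = character())
  rownames(res) <- NULL
  attr(res, "rejections") <- rejections
  res
}
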