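#' Filter thresholds for the candidate cascade
#'
#' Defaults are the published cutoffs: at least 10 reads per locus, folding
#' p < 0.05, homology E-value < 0.1 flags a known miRNA, GC outliers beyond
#' 2 population standard deviations, at least 10 summed reads for the
#' expression gate, and TMM-normalized expression > 0.1.
#'
#' @param min_locus_reads Minimum reads covering a locus.
#' @param structure_p_max Maximum shuffle-folding p-value.
#' @param evalue_max Candidates with a best E-value below this against the
#'   known-miRNA set are treated as previously annotated.
#' @param gc_sd_multiplier Number of SDs defining a GC outlier.
#' @param min_total_reads Minimum summed reads across samples (expression
#'   gate).
#' @param tmm_expression_min Normalized-expression cutoff for the gates.
#' @return List of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_locus_reads = 10L, structure_p_max = 0.05,
                              evalue_max = 0.1, gc_sd_multiplier = 2,
                              min_total_reads = 10L,
                              tmm_expression_min = 0.1) {
  th <- list(min_locus_reads = min_locus_reads,
             structure_p_max = structure_p_max, evalue_max = evalue_max,
             gc_sd_multiplier = gc_sd_multiplier,
             min_total_reads = min_total_reads,
             tmm_expression_min = tmm_expression_min)
  if (any(unlist(th) <= 0)) stop("all thresholds must be strictly positive")
  class(th) <- "filter_thresholds"
  th
}

#' Karlin-Altschul lambda for an ungapped scoring system
#'
#' Solves sum_ij p_i p_j exp(lambda * s_ij) = 1 for the unique positive root,
#' under a background distribution (uniform by default).  The expected pair
#' score must be negative and a positive score attainable.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param p Background base frequencies (length 4, sums to 1).
#' @return lambda in nats.
#' @export
karlin_lambda <- function(match = 1, mismatch = -2, p = rep(0.25, 4)) {
  pm <- sum(p^2)                 # probability of an identical pair
  expected <- pm * match + (1 - pm) * mismatch
  if (expected >= 0) stop("expected pair score must be negative")
  if (match <= 0) stop("a positive match score is required")
  f <- function(l) pm * exp(l * match) + (1 - pm) * exp(l * mismatch) - 1
  upper <- 1
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(1e-8, upper), tol = 1e-12)$root
}

#' Karlin-Altschul K for an ungapped lattice scoring system
#'
#' Standard series approximation for i.i.d. lattice scores: with per-pair
#' score X (match with probability sum p_i^2, else mismatch), span d the gcd
#' of attainable score differences, and random walk S_k,
#' K = lambda * exp(-2 * sigma) / (A * (1 - exp(-lambda * d))), where
#' sigma = sum_k (1/k) (P(S_k >= 0) + E[exp(lambda S_k); S_k < 0]) and
#' A = E[X exp(lambda X)].  The walk distribution is evaluated by exact
#' convolution.
#'
#' @param match,mismatch,p As in [karlin_lambda()].
#' @param lambda Optional precomputed lambda.
#' @param k_max Number of series terms.
#' @return K (dimensionless).
#' @export
karlin_K <- function(match = 1, mismatch = -2, p = rep(0.25, 4),
                     lambda = NULL, k_max = 60L) {
  if (is.null(lambda)) lambda <- karlin_lambda(match, mismatch, p)
  pm <- sum(p^2)
  scores <- c(match, mismatch)
  probs <- c(pm, 1 - pm)
  d <- .gcd_vec(abs(diff(sort(unique(scores)))))
  A <- sum(scores * probs * exp(lambda * scores))

  # exact convolution of the walk distribution on the integer lattice
  lo <- min(scores); hi <- max(scores)
  offset <- 1L - k_max * lo
  dist <- numeric(k_max * (hi - lo) + 1L)
  step <- numeric(length(dist))
  step[scores + offset] <- probs
  cur <- numeric(length(dist)); cur[0 + offset] <- 1
  sigma <- 0
  for (k in seq_len(k_max)) {
    nxt <- numeric(length(cur))
    nz <- which(cur > 0)
    for (s in seq_along(scores)) {
      idx <- nz + scores[s]
      keep <- idx >= 1 & idx <= length(nxt)
      nxt[idx[keep]] <- nxt[idx[keep]] + cur[nz[keep]] * probs[s]
    }
    cur <- nxt
    vals <- seq_along(cur) - offset
    neg <- vals < 0
    sigma <- sigma + (sum(cur[!neg]) + sum(cur[neg] * exp(lambda * vals[neg]))) / k
  }
  lambda * exp(-2 * sigma) / (A * (1 - exp(-lambda * d)))
}

.gcd_vec <- function(x) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  Reduce(g, x)
}

#' Best homology E-value of a query against a sequence database
#'
#' Smith-Waterman local alignment (via [Biostrings::pairwiseAlignment()])
#' of the query against every database entry; the best score S is converted
#' to E = K * m * n * exp(-lambda * S) with m the query length and n the
#' total database length, using ungapped Karlin-Altschul statistics for the
#' match/mismatch scores under uniform base composition.
#'
#' @param query Nucleotide sequence (DNA or RNA alphabet).
#' @param database Character vector of database sequences (may be empty).
#' @param match,mismatch Substitution scores (defaults +1/-2).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L costs
#'   `gap_open + gap_extend * L` (defaults 5 and 2, i.e. open -5 extend -2).
#' @return Best (smallest) E-value; `Inf` for an empty database.
#' @export
homology_evalue <- function(query, database, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2) {
  if (missing(query) || is.null(query) || !nzchar(query)) {
    stop("empty query sequence")
  }
  if (length(database) == 0) return(Inf)
  q <- Biostrings::DNAString(.as_dna(query))
  db <- Biostrings::DNAStringSet(.as_dna(database))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  S <- max(Biostrings::pairwiseAlignment(
    db, q, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend,
    scoreOnly = TRUE))
  lambda <- karlin_lambda(match, mismatch)
  K <- karlin_K(match, mismatch, lambda = lambda)
  m <- nchar(query)
  n <- sum(nchar(database))
  K * m * n * exp(-lambda * S)
}

#' Remove GC-content outliers
#'
#' GC fractions are computed on the mature sequences; candidates farther than
#' `gc_sd_multiplier` population standard deviations from the mean are
#' dropped in a single pass.
#'
#' @param candidates Candidate data.frame (needs a `mature_seq` column).
#' @param gc_sd_multiplier Number of SDs defining an outlier.
#' @return Retained candidates.
#' @export
gc_outlier_filter <- function(candidates, gc_sd_multiplier = 2) {
  if (nrow(candidates) == 0) return(candidates)
  if (nrow(candidates) == 1) {
    warning("single candidate: GC outlier filter is a pass-through")
    return(candidates)
  }
  gc <- vapply(candidates$mature_seq, .gc_fraction, numeric(1),
               USE.NAMES = FALSE)
  mu <- mean(gc)
  sd_pop <- sqrt(mean((gc - mu)^2))
  keep <- abs(gc - mu) <= gc_sd_multiplier * sd_pop
  candidates[keep, , drop = FALSE]
}

#' Apply the manual filter cascade
#'
#' Steps, in order: (1) locus read support >= `min_locus_reads`; (2) no
#' overlap (>= 1 bp, strand-blind) with rRNA/tRNA decoy intervals; (3)
#' shuffle-folding p < `structure_p_max`; (4) duplicate removal, collapsing
#' identical mature sequences to the highest-signature locus; (5) homology
#' screen, dropping candidates whose best E-value against the known-miRNA
#' set is below `evalue_max`; (6) GC-outlier removal.  Every transition is
#' recorded in an auditable report.
#'
#' @param candidates Candidate data.frame from [discover_candidates()].
#' @param rrna_trna_bed data.frame of decoy intervals (chrom, start, end;
#'   0-based half-open); required, may have zero rows.
#' @param known_mirnas Character vector of known mature miRNA sequences
#'   (may be empty).
#' @param thresholds A [filter_thresholds()].
#' @return List with `candidates` (retained rows) and `report` (class
#'   `filter_report`: `per_step` counts and per-candidate `rejections`).
#' @export
apply_filter_cascade <- function(candidates, rrna_trna_bed, known_mirnas,
                                 thresholds = filter_thresholds()) {
  if (missing(rrna_trna_bed) || is.null(rrna_trna_bed)) {
    stop("rRNA/tRNA annotation is required for the decoy-overlap step")
  }
  if (missing(known_mirnas) || is.null(known_mirnas)) {
    stop("a known-miRNA set (possibly empty) is required for the homology ",
         "screen")
  }
  steps <- c("read_support", "rrna_trna_overlap", "structure_pvalue",
             "duplicate_removal", "homology_screen", "gc_outlier")
  per_step <- data.frame(step = steps, candidates_in = NA_integer_,
                         candidates_out = NA_integer_)
  rejections <- data.frame(id = character(), step = character(),
                           reason = character())
  note <- function(ids, step, reason) {
    if (length(ids)) {
      rejections <<- rbind(rejections,
                           data.frame(id = ids, step = step, reason = reason))
    }
  }
  cur <- candidates

  run_step <- function(k, keep, reason) {
    per_step$candidates_in[k] <<- nrow(cur)
    note(cur$locus_id[!keep], steps[k], reason)
    cur <<- cur[keep, , drop = FALSE]
    per_step$candidates_out[k] <<- nrow(cur)
  }

  run_step(1, if (nrow(cur)) cur$total_reads >= thresholds$min_locus_reads
              else logical(0),
           sprintf("fewer than %d locus reads", thresholds$min_locus_reads))

  keep2 <- if (nrow(cur) == 0) logical(0) else {
    if (nrow(rrna_trna_bed) == 0) rep(TRUE, nrow(cur)) else {
      hits <- rep(FALSE, nrow(cur))
      for (ch in unique(cur$chrom)) {
        qi <- which(cur$chrom == ch)
        si <- which(rrna_trna_bed$chrom == ch)
        if (!length(si)) next
        q <- IRanges::IRanges(cur$start[qi] + 1L, cur$end[qi])
        s <- IRanges::IRanges(rrna_trna_bed$start[si] + 1L,
                              rrna_trna_bed$end[si])
        hits[qi] <- IRanges::countOverlaps(q, s, minoverlap = 1L) > 0
      }
      !hits
    }
  }
  run_step(2, keep2, "overlaps an rRNA/tRNA interval")

  run_step(3, if (nrow(cur)) cur$randfold_p < thresholds$structure_p_max
              else logical(0),
           sprintf("folding p >= %g", thresholds$structure_p_max))

  keep4 <- if (nrow(cur) == 0) logical(0) else {
    ord <- order(-cur$signature_score, cur$chrom, cur$start)
    !duplicated(cur$mature_seq[ord])[order(ord)]
  }
  run_step(4, keep4, "duplicate mature sequence")

  keep5 <- if (nrow(cur) == 0) logical(0) else {
    vapply(cur$mature_seq, function(s) {
      homology_evalue(s, known_mirnas) >= thresholds$evalue_max
    }, logical(1), USE.NAMES = FALSE)
  }
  run_step(5, keep5,
           sprintf("homologous to a known miRNA (E < %g)",
                   thresholds$evalue_max))

  keep6 <- if (nrow(cur) < 2) rep(TRUE, nrow(cur)) else {
    retained <- gc_outlier_filter(cur, thresholds$gc_sd_multiplier)
    cur$locus_id %in% retained$locus_id
  }
  run_step(6, keep6,
           sprintf("GC content beyond %g SD of the mean",
                   thresholds$gc_sd_multiplier))

  report <- list(per_step = per_step, rejections = rejections)
  class(report) <- "filter_report"
  list(candidates = cur, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Filter cascade report\n")
  print(x$per_step, row.names = FALSE)
  cat(nrow(x$rejections), "rejection(s) recorded\n")
  invisible(x)
}

#' Assign Knm identifiers to retained candidates
#'
#' IDs have the form `Knm<chromosome number>_<serial>`, where the serial is
#' the candidate's 1-based rank in (chromosome, start)-sorted order over the
#' full genome-wide set.  Duplicate (chrom, start, strand) coordinates are a
#' contract violation.
#'
#' @param candidates Candidate data.frame with chrom/start/strand columns.
#' @return The same data.frame with a `knm_id` column, in sorted order.
#' @export
assign_knm_ids <- function(candidates) {
  if (nrow(candidates) == 0) {
    candidates$knm_id <- character(0)
    return(candidates)
  }
  key <- paste(candidates$chrom, candidates$start, candidates$strand)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, start, strand) after deduplication: ",
         key[duplicated(key)][1])
  }
  chrom_num <- gsub("\\D", "", candidates$chrom)
  chrom_num[chrom_num == ""] <- "0"
  ord <- order(as.integer(chrom_num), candidates$start)
  out <- candidates[ord, , drop = FALSE]
  out$knm_id <- sprintf("Knm%s_%d", gsub("\\D", "", out$chrom),
                        seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
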