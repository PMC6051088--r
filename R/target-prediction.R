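#' Scoring scheme for miRNA-UTR complementarity alignment
#'
#' Classic miRanda-style values: Watson-Crick complement +5, G:U wobble +1,
#' mismatch -3, gap open -9, gap extend -4; pair scores at miRNA seed
#' positions 2-8 are multiplied by 4.
#'
#' @param complementary,wobble,mismatch Pair scores.
#' @param gap_open,gap_extend Positive gap penalties (a gap of length L
#'   costs `gap_open + (L - 1) * gap_extend`).
#' @param seed_positions miRNA positions (1-based from the 5' end) whose
#'   pair scores are up-weighted.
#' @param seed_multiplier Seed up-weighting factor.
#' @return List of class `scoring_scheme` including the 4x4 pair-score
#'   matrix (miRNA base x UTR base).
#' @export
scoring_scheme <- function(complementary = 5, wobble = 1, mismatch = -3,
                           gap_open = 9, gap_extend = 4,
                           seed_positions = 2:8, seed_multiplier = 4) {
  if (!(complementary > wobble && wobble > mismatch)) {
    stop("need complementary > wobble > mismatch")
  }
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be positive (they are subtracted)")
  }
  m <- matrix(mismatch, 4, 4, dimnames = list(.RNA_BASES, .RNA_BASES))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- complementary
  m["G", "U"] <- m["U", "G"] <- wobble
  structure(list(pair_scores = m, gap_open = gap_open,
                 gap_extend = gap_extend, seed_positions = seed_positions,
                 seed_multiplier = seed_multiplier),
            class = "scoring_scheme")
}

#' Align a miRNA against a 3'UTR by antiparallel complementarity
#'
#' Smith-Waterman-style local alignment where the miRNA is read antiparallel
#' to the UTR and positions score by base-pairing ability rather than
#' identity; seed-region pair scores are multiplied by the scheme's
#' `seed_multiplier`.  All non-overlapping local maxima above `min_score`
#' are returned, best first.
#'
#' @param mirna miRNA sequence (RNA alphabet, 5'->3').
#' @param utr UTR sequence (RNA alphabet, 5'->3').
#' @param scheme A [scoring_scheme()].
#' @param min_score Only alignments scoring strictly above this are
#'   returned.
#' @return List of alignments: score, utr_start/utr_end (0-based half-open),
#'   mirna_start/mirna_end (1-based, 5'->3'), pairs (miRNA position, UTR
#'   position, 1-based) and pair_type (2 complement, 1 wobble, 0 mismatch).
#' @export
duplex_align <- function(mirna, utr, scheme = scoring_scheme(),
                         min_score = 0) {
  if (!nzchar(mirna) || !nzchar(utr)) stop("empty sequence")
  hits <- .cpp_duplex_align(
    .encode_rna(mirna), .encode_rna(utr), scheme$pair_scores,
    as.integer(scheme$seed_positions), scheme$seed_multiplier,
    scheme$gap_open, scheme$gap_extend, min_score, 64L)
  lapply(hits, function(h) {
    h$utr_start <- h$utr_start - 1L  # to 0-based half-open
    h
  })
}

# Nearest-neighbor stack free energies (kcal/mol at 37C) for Watson-Crick
# pair steps; wobble-containing steps carry a flat mildly stabilizing value
# so stacking is always favourable.  Pairs are named by (strand1 base,
# strand2 base); the step (p1, p2) has strand1 5'-x1 x2-3'.
.stack_energy_table <- function() {
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  E <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  wc <- list(
    c("AU", "AU", -0.93), c("AU", "UA", -1.10), c("UA", "AU", -1.33),
    c("CG", "UA", -2.08), c("CG", "AU", -2.11), c("GC", "UA", -2.24),
    c("GC", "AU", -2.35), c("CG", "GC", -2.36), c("GC", "GC", -3.26),
    c("GC", "CG", -3.42)
  )
  rev_pair <- function(p) paste0(substr(p, 2, 2), substr(p, 1, 1))
  for (s in wc) {
    E[s[1], s[2]] <- as.numeric(s[3])
    E[rev_pair(s[2]), rev_pair(s[1])] <- as.numeric(s[3])
  }
  E[is.na(E)] <- -0.5  # steps involving a G:U wobble
  E
}

#' Duplex free energy of an alignment
#'
#' Sum of nearest-neighbor stacking energies over consecutive base-pair
#' steps, plus 4.09 kcal/mol duplex initiation; every interior loop or bulge
#' between pairs contributes a flat +3.0 kcal/mol.  More negative is more
#' stable.  At least two base pairs are required.
#'
#' @param alignment One alignment from [duplex_align()].
#' @param mirna,utr The aligned sequences (RNA alphabet).
#' @return Free energy in kcal/mol.
#' @export
duplex_energy <- function(alignment, mirna, utr) {
  pt <- alignment$pair_type
  pm <- alignment$pairs[pt > 0, , drop = FALSE]
  if (nrow(pm) < 2) stop("alignment has fewer than 2 base pairs")
  ord <- order(pm[, 1])
  pm <- pm[ord, , drop = FALSE]
  mir <- strsplit(toupper(mirna), "")[[1]]
  ut <- strsplit(toupper(utr), "")[[1]]
  tab <- .stack_energy_table()
  pair_id <- paste0(mir[pm[, 1]], ut[pm[, 2]])
  energy <- 4.09
  for (i in seq_len(nrow(pm) - 1)) {
    stacked <- pm[i + 1, 1] == pm[i, 1] + 1 && pm[i + 1, 2] == pm[i, 2] - 1
    energy <- energy + if (stacked) tab[pair_id[i], pair_id[i + 1]] else 3.0
  }
  energy
}

#' Predict targets of a set of miRNAs against a UTR set
#'
#' Every miRNA is aligned against every UTR; alignments reaching
#' `score_min` with duplex energy at or below `energy_max` are emitted (the
#' best-scoring site per miRNA-gene pair).
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param utrs Named character vector of UTR sequences.
#' @param scheme A [scoring_scheme()].
#' @param score_min Minimum alignment score (default 140).
#' @param energy_max Maximum (least negative) duplex energy in kcal/mol
#'   (default -20).
#' @return data.frame: mirna, gene, utr_start, utr_end (0-based half-open),
#'   alignment_score, duplex_energy.
#' @export
predict_targets <- function(mirnas, utrs, scheme = scoring_scheme(),
                            score_min = 140, energy_max = -20) {
  rows <- list()
  for (m in names(mirnas)) {
    for (g in names(utrs)) {
      hits <- duplex_align(mirnas[[m]], utrs[[g]], scheme,
                           min_score = score_min - 1e-9)
      best <- NULL
      for (h in hits) {
        if (h$score < score_min) next
        if (sum(h$pair_type > 0) < 2) next
        en <- duplex_energy(h, mirnas[[m]], utrs[[g]])
        if (en > energy_max) next
        if (is.null(best) || h$score > best$alignment_score) {
          best <- data.frame(mirna = m, gene = g, utr_start = h$utr_start,
                             utr_end = h$utr_end, alignment_score = h$score,
                             duplex_energy = en)
        }
      }
      if (!is.null(best)) rows[[length(rows) + 1L]] <- best
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), gene = character(),
               utr_start = integer(), utr_end = integer(),
               alignment_score = numeric(), duplex_energy = numeric())
  stopifnot(all(out$alignment_score >= score_min),
            all(out$duplex_energy <= energy_max))
  rownames(out) <- NULL
  out
}

#' Scrambled-sequence null filter for target predictions
#'
#' Runs the full predictor for each miRNA and for `n_scrambles` uniform
#' random permutations of its nucleotides; a true-miRNA target gene also
#' predicted for any scramble is discarded (`passed_scramble_null = FALSE`).
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param utrs Named character vector of UTR sequences.
#' @param scheme A [scoring_scheme()].
#' @param n_scrambles Number of scrambles (default 5, >= 1).
#' @param seed Seed for the scramble permutations.
#' @param score_min,energy_max Prediction thresholds.
#' @param mode `"gene"` (default: a scramble hit anywhere on the same gene
#'   discards the prediction) or `"overlap"` (only a scramble site
#'   overlapping the true site's UTR coordinates discards it).
#' @return Prediction data.frame with a `passed_scramble_null` column.
#' @export
scramble_null_filter <- function(mirnas, utrs, scheme = scoring_scheme(),
                                 n_scrambles = 5L, seed = NULL,
                                 score_min = 140, energy_max = -20,
                                 mode = c("gene", "overlap")) {
  mode <- match.arg(mode)
  if (n_scrambles < 1) stop("n_scrambles must be >= 1")
  true_pred <- predict_targets(mirnas, utrs, scheme, score_min, energy_max)
  true_pred$passed_scramble_null <- TRUE
  .with_seed(seed, {
    for (m in names(mirnas)) {
      rows_m <- which(true_pred$mirna == m)
      if (!length(rows_m)) next
      chars <- strsplit(mirnas[[m]], "")[[1]]
      for (k in seq_len(n_scrambles)) {
        scr <- paste(sample(chars), collapse = "")
        scr_pred <- predict_targets(setNames(scr, "scramble"), utrs, scheme,
                                    score_min, energy_max)
        if (nrow(scr_pred) == 0) next
        kill <- if (mode == "gene") {
          true_pred$gene[rows_m] %in% scr_pred$gene
        } else {
          vapply(rows_m, function(r) {
            same <- scr_pred[scr_pred$gene == true_pred$gene[r], ,
                             drop = FALSE]
            any(same$utr_start < true_pred$utr_end[r] &
                  same$utr_end > true_pred$utr_start[r])
          }, logical(1))
        }
        true_pred$passed_scramble_null[rows_m][kill] <- FALSE
      }
    }
  })
  true_pred
}

#' Aggregate target genes across miRNAs
#'
#' A gene is retained when it is a surviving (`passed_scramble_null`) target
#' of at least `ceiling(mirna_fraction * n_mirnas)` distinct miRNAs.
#'
#' @param predictions Prediction data.frame with a `passed_scramble_null`
#'   column.
#' @param n_mirnas Number of miRNAs queried (defaults to the number of
#'   distinct miRNAs in `predictions`).
#' @param mirna_fraction Fraction of miRNAs a gene must be targeted by, in
#'   (0, 1].
#' @return Character vector of retained gene ids (sorted).
#' @export
aggregate_targets <- function(predictions, n_mirnas = NULL,
                              mirna_fraction = 0.10) {
  if (mirna_fraction <= 0 || mirna_fraction > 1) {
    stop("mirna_fraction must lie in (0, 1]")
  }
  ok <- predictions[predictions$passed_scramble_null, , drop = FALSE]
  if (is.null(n_mirnas)) n_mirnas <- length(unique(predictions$mirna))
  if (n_mirnas < 1) stop("need at least one miRNA prediction list")
  need <- ceiling(mirna_fraction * n_mirnas)
  counts <- tapply(ok$mirna, ok$gene, function(x) length(unique(x)))
  sort(names(counts)[counts >= need])
}
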