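#' Construct an expression matrix container
#'
#' @param values Numeric loci x samples matrix with dimnames.
#' @param kind `"raw_counts"` or `"tmm_normalized"`.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, kind = c("raw_counts",
                                               "tmm_normalized")) {
  kind <- match.arg(kind)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("values must carry row (locus) and column (sample) names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate locus ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (kind == "raw_counts" && any(values != round(values))) {
    stop("raw counts must be integers")
  }
  structure(list(values = values, kind = kind), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d loci x %d samples\n", x$kind,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Count reads per locus and sample
#'
#' A read is assigned to a locus when at least 50% of the read's length
#' overlaps the locus on the same strand (ties between adjacent loci go to
#' the lower-start locus).  Reads overlapping no locus stay unassigned; per-
#' sample unassigned totals are kept in the `unassigned` attribute so that
#' assigned + unassigned = total.
#'
#' @param reads Read-placement data.frame with a `sample` column.
#' @param loci data.frame of non-overlapping loci with id column (`knm_id`
#'   if present, else `locus_id`), chrom, start, end, strand.
#' @return [expression_matrix()] of raw counts.
#' @export
count_matrix <- function(reads, loci) {
  id_col <- if ("knm_id" %in% names(loci)) "knm_id" else "locus_id"
  ids <- loci[[id_col]]
  if (anyDuplicated(ids)) stop("duplicate locus ids")
  samples <- sort(unique(reads$sample))
  counts <- matrix(0L, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, samples))
  unassigned <- setNames(integer(length(samples)), samples)
  if (nrow(reads) > 0 && length(ids) > 0) {
    assigned_to <- rep(NA_integer_, nrow(reads))
    for (key in unique(paste(loci$chrom, loci$strand))) {
      li <- which(paste(loci$chrom, loci$strand) == key)
      ri <- which(paste(reads$chrom, reads$strand) == key)
      if (!length(ri)) next
      q <- IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri])
      s <- IRanges::IRanges(loci$start[li] + 1L, loci$end[li])
      hits <- IRanges::findOverlaps(q, s)
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- IRanges::width(IRanges::pintersect(q[qh], s[sh]))
      frac_ok <- ov >= 0.5 * IRanges::width(q[qh])
      qh <- qh[frac_ok]; sh <- sh[frac_ok]
      if (length(qh)) {
        ord <- order(qh, loci$start[li][sh])  # tie -> lower-start locus
        first <- !duplicated(qh[ord])
        assigned_to[ri[qh[ord][first]]] <- li[sh[ord][first]]
      }
    }
    for (k in seq_along(samples)) {
      in_sample <- reads$sample == samples[k]
      tab <- table(assigned_to[in_sample])
      counts[as.integer(names(tab)), k] <- as.integer(tab)
      unassigned[k] <- sum(in_sample & is.na(assigned_to))
    }
  } else if (nrow(reads) > 0) {
    unassigned[] <- as.integer(table(factor(reads$sample, levels = samples)))
  }
  out <- expression_matrix(counts, "raw_counts")
  attr(out, "unassigned") <- unassigned
  out
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' The reference is the sample whose 75th-percentile count fraction is
#' closest to the mean of those fractions.  For each sample against the
#' reference, over loci nonzero in both, M = log2((y_k/N_k)/(y_r/N_r)) and
#' A = 0.5 * log2((y_k/N_k)(y_r/N_r)); the upper and lower `trim_m` of M and
#' `trim_a` of A are discarded, and the factor is 2 to the weighted mean of
#' the surviving M values with inverse-variance (binomial delta-method)
#' weights.  Factors are rescaled to geometric mean 1.
#'
#' @param counts [expression_matrix()] of raw counts, >= 2 samples.
#' @param trim_m Two-sided trim fraction on M (default 0.30).
#' @param trim_a Two-sided trim fraction on A (default 0.05).
#' @return List with `reference_sample` and named `factors`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(counts, "expression_matrix"),
            counts$kind == "raw_counts")
  y <- counts$values
  if (ncol(y) < 2) stop("TMM needs at least 2 samples")
  N <- colSums(y)
  if (any(N == 0)) {
    stop("sample(s) with no counts: ",
         paste(colnames(y)[N == 0], collapse = ", "))
  }
  f75 <- apply(y, 2, function(col) quantile(col, 0.75, names = FALSE)) / N
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- setNames(rep(1, ncol(y)), colnames(y))
  for (k in seq_len(ncol(y))) {
    if (k == ref) next
    factors[k] <- .tmm_pair_factor(y[, k], y[, ref], N[k], N[ref],
                                   trim_m, trim_a, colnames(y)[k])
  }
  factors <- factors / exp(mean(log(factors)))
  list(reference_sample = colnames(y)[ref], factors = factors)
}

.tmm_pair_factor <- function(yk, yr, Nk, Nr, trim_m, trim_a, sample_name) {
  ok <- yk > 0 & yr > 0
  if (!any(ok)) {
    stop("sample ", sample_name, " shares no nonzero locus with the ",
         "reference")
  }
  yk <- yk[ok]; yr <- yr[ok]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  w <- 1 / ((Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr))
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep)) return(1)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' TMM-scaled counts per million
#'
#' value = count / (library size x factor) x 1e6, so each normalized column
#' sums to 1e6 / factor.
#'
#' @param counts [expression_matrix()] of raw counts.
#' @param factors Result of [tmm_factors()] on the same samples.
#' @return [expression_matrix()] of kind `tmm_normalized`.
#' @export
tmm_normalize <- function(counts, factors) {
  stopifnot(inherits(counts, "expression_matrix"),
            counts$kind == "raw_counts")
  y <- counts$values
  missing <- setdiff(colnames(y), names(factors$factors))
  if (length(missing)) {
    stop("no normalization factor for sample(s): ",
         paste(missing, collapse = ", "))
  }
  f <- factors$factors[colnames(y)]
  N <- colSums(y)
  norm <- sweep(y, 2, N * f, "/") * 1e6
  expression_matrix(norm, "tmm_normalized")
}

#' Expression gates
#'
#' Three published gating rules: `sum_reads` keeps loci whose summed raw
#' counts across samples reach `min_total_reads`; `any_sample` keeps loci
#' with normalized expression strictly above `expression_min` in at least one
#' sample; `fraction_of_samples` requires that in at least
#' `ceiling(sample_fraction * n_samples)` samples.
#'
#' @param x [expression_matrix()]; raw counts for `sum_reads`, normalized
#'   otherwise.
#' @param mode One of `"sum_reads"`, `"any_sample"`,
#'   `"fraction_of_samples"`.
#' @param min_total_reads Summed-read cutoff (sum_reads mode).
#' @param expression_min Normalized-expression cutoff (strict >).
#' @param sample_fraction Fraction of samples for `fraction_of_samples`.
#' @return Character vector of retained locus ids.
#' @export
expression_gates <- function(x, mode = c("sum_reads", "any_sample",
                                         "fraction_of_samples"),
                             min_total_reads = 10L, expression_min = 0.1,
                             sample_fraction = 0.10) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values
  if (mode == "sum_reads") {
    if (x$kind != "raw_counts") stop("sum_reads gate needs raw counts")
    keep <- rowSums(v) >= min_total_reads
  } else {
    if (x$kind != "tmm_normalized") {
      stop(mode, " gate needs a TMM-normalized matrix")
    }
    n_above <- rowSums(v > expression_min)
    keep <- if (mode == "any_sample") n_above >= 1L
            else n_above >= ceiling(sample_fraction * ncol(v))
  }
  rownames(v)[keep]
}
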