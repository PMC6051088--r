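#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (sort ascending, q_(i) = p_(i) * m / i, cumulative
#' minimum from the largest rank, cap at 1), returned in input order.
#' Delegates to [stats::p.adjust()]; NAs are excluded from m and propagated.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Paired tumour/normal differential expression
#'
#' Per locus, a paired Student t-test on the per-pair differences of
#' normalized expression (two-sided, n_pairs - 1 df).  The fold change is
#' the mean over pairs of (tumour + eps) / (normal + eps), with eps = 0.01
#' pseudo-expression guarding near-total-loss loci.  Loci with zero variance
#' of differences get p = NaN (with a warning) and are excluded from the BH
#' denominator.
#'
#' @param normalized [expression_matrix()] of kind `tmm_normalized`.
#' @param annotations Sample table with columns sample, pair, condition
#'   (values `tumour` / `normal`); every pair needs exactly one of each.
#' @param method `"paired"` (default) or `"welch"` (unpaired unequal
#'   variance).
#' @param eps Pseudo-expression for fold changes.
#' @param log2_values Test log2(value + eps) instead of the normalized
#'   values.
#' @return data.frame with locus id, mean_fc, log2fc, t_stat, p, bh_p,
#'   direction.
#' @export
paired_de <- function(normalized, annotations, method = c("paired", "welch"),
                      eps = 0.01, log2_values = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(normalized, "expression_matrix"),
            normalized$kind == "tmm_normalized")
  v <- normalized$values
  ann <- annotations[annotations$sample %in% colnames(v), , drop = FALSE]
  pairs <- unique(ann$pair)
  t_col <- n_col <- character(length(pairs))
  for (i in seq_along(pairs)) {
    rows <- ann[ann$pair == pairs[i], , drop = FALSE]
    tc <- rows$sample[rows$condition == "tumour"]
    nc <- rows$sample[rows$condition == "normal"]
    if (length(tc) != 1 || length(nc) != 1) {
      stop("pair ", pairs[i], " must have exactly one tumour and one ",
           "normal sample")
    }
    t_col[i] <- tc; n_col[i] <- nc
  }
  n <- length(pairs)
  if (n < 3) stop("need at least 3 complete pairs")
  Tm <- v[, t_col, drop = FALSE]
  Nm <- v[, n_col, drop = FALSE]
  X <- if (log2_values) log2(Tm + eps) else Tm
  Y <- if (log2_values) log2(Nm + eps) else Nm

  if (method == "paired") {
    D <- X - Y
    mbar <- rowMeans(D)
    s <- apply(D, 1, sd)
    df <- n - 1
    t_stat <- mbar / (s / sqrt(n))
  } else {
    vx <- apply(X, 1, var); vy <- apply(Y, 1, var)
    se2 <- vx / n + vy / n
    t_stat <- (rowMeans(X) - rowMeans(Y)) / sqrt(se2)
    df <- se2^2 / ((vx / n)^2 / (n - 1) + (vy / n)^2 / (n - 1))
    s <- sqrt(se2)
  }
  # identical tumour/normal columns are a true null (t = 0, p = 1); zero
  # variance around a nonzero difference leaves t undefined
  zero_var <- !is.na(s) & s == 0
  identical_null <- zero_var & rowMeans(X - Y) == 0
  t_stat[identical_null] <- 0
  p <- 2 * pt(-abs(t_stat), df)
  p[identical_null] <- 1
  zero_var <- zero_var & !identical_null
  p[zero_var] <- NaN
  if (any(zero_var)) {
    warning(sum(zero_var), " locus/loci with zero variance of differences; ",
            "p reported as NaN and excluded from BH correction")
  }
  mean_fc <- rowMeans((Tm + eps) / (Nm + eps))
  data.frame(
    locus_id = rownames(v),
    mean_fc = mean_fc,
    log2fc = log2(mean_fc),
    t_stat = t_stat,
    p = p,
    bh_p = bh_adjust(ifelse(is.nan(p), NA, p)),
    direction = ifelse(mean_fc > 1, "up", "down"),
    row.names = NULL
  )
}

#' Hierarchical clustering on 1 - Pearson correlation
#'
#' Average-linkage (UPGMA) agglomeration with distance 1 - r, applied to the
#' locus axis and (optionally) the sample axis.  Zero-variance rows are
#' excluded with a warning.
#'
#' @param mat Numeric matrix (loci x samples).
#' @param cluster_samples Also cluster the sample axis.
#' @return List with `row_hclust`, `col_hclust` (or NULL), `row_order`,
#'   `col_order` and the ids actually clustered.
#' @export
hier_cluster <- function(mat, cluster_samples = TRUE) {
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need at least 2 rows and columns")
  rv <- apply(mat, 1, var)
  if (any(rv == 0)) {
    warning(sum(rv == 0), " zero-variance row(s) excluded from clustering")
    mat <- mat[rv > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("fewer than 2 rows with variance remain")
  row_d <- as.dist(1 - cor(t(mat)))
  row_h <- hclust(row_d, method = "average")
  col_h <- NULL
  if (cluster_samples) {
    cv <- apply(mat, 2, var)
    if (any(cv == 0)) {
      warning(sum(cv == 0), " zero-variance column(s) excluded")
      mat <- mat[, cv > 0, drop = FALSE]
    }
    col_h <- hclust(as.dist(1 - cor(mat)), method = "average")
  }
  list(row_hclust = row_h, col_hclust = col_h,
       row_order = rownames(mat)[row_h$order],
       col_order = if (!is.null(col_h)) colnames(mat)[col_h$order])
}
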