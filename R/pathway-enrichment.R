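#' Hypergeometric pathway over-representation
#'
#' For each pathway, the upper-tail hypergeometric probability of observing
#' at least the seen overlap when drawing `|query|` genes from the universe
#' with the pathway's genes marked; BH correction across all tested
#' pathways.  Pathways are intersected with the universe before testing.
#'
#' @param query Character vector of query genes (e.g. aggregated miRNA
#'   targets).
#' @param pathways Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Gene universe; defaults to the union of all pathway
#'   genes.  Query genes outside the universe are dropped with a warning.
#' @param bh_max Significance threshold reported in the `significant`
#'   column (default 0.05).
#' @return data.frame sorted by bh_p then pathway name: pathway, n_pathway,
#'   n_overlap, overlap_genes (comma-separated), p, bh_p, significant.
#' @export
enrich_pathways <- function(query, pathways, universe = NULL,
                            bh_max = 0.05) {
  if (length(query) == 0) stop("empty query gene set")
  if (length(pathways) == 0) stop("no pathways to test")
  if (is.null(universe)) universe <- unique(unlist(pathways))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty gene universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query genes inside the universe")
  }
  N <- length(universe)
  nq <- length(query)
  rows <- lapply(names(pathways), function(nm) {
    pw <- intersect(unique(pathways[[nm]]), universe)
    ov <- intersect(query, pw)
    p <- phyper(length(ov) - 1, length(pw), N - length(pw), nq,
                lower.tail = FALSE)
    data.frame(pathway = nm, n_pathway = length(pw), n_overlap = length(ov),
               overlap_genes = paste(sort(ov), collapse = ","), p = p)
  })
  out <- do.call(rbind, rows)
  out$bh_p <- bh_adjust(out$p)
  out$significant <- out$bh_p <= bh_max
  out <- out[order(out$bh_p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
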