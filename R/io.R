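#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a plain named
#' character vector.  Duplicate record identifiers are an error.
#'
#' @param path Path to a FASTA file (plain text, wrapped or single-line).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED file (0-based half-open intervals)
#'
#' Accepts 3- to 6-column BED.  Coordinates are validated: integer, start >= 0
#' and start < end (empty intervals are rejected); offending lines are named.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(),
                      strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    stop("BED line(s) with fewer than 3 fields: line ",
         paste(which(n_col < 3), collapse = ", "))
  }
  grab <- function(k, default) {
    vapply(fields, function(f) if (length(f) >= k) f[k] else default,
           character(1))
  }
  start <- suppressWarnings(as.integer(grab(2, NA)))
  end <- suppressWarnings(as.integer(grab(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("non-integer BED coordinates: line ", paste(bad, collapse = ", "))
  }
  bad <- which(start < 0L | start >= end)
  if (length(bad)) {
    stop("invalid BED interval (need 0 <= start < end): line ",
         paste(bad, collapse = ", "))
  }
  data.frame(
    chrom = grab(1, NA), start = start, end = end,
    name = grab(4, "."),
    score = suppressWarnings(as.numeric(grab(5, "0"))),
    strand = grab(6, "+")
  )
}

#' Write a 6-column BED file
#'
#' @param bed data.frame with chrom, start, end and optionally name, score,
#'   strand columns; coordinates 0-based half-open.
#' @param path Output path.
#' @export
write_bed <- function(bed, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  if (any(bed$start < 0 | bed$start >= bed$end)) {
    stop("invalid interval(s): need 0 <= start < end")
  }
  out <- data.frame(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    name = if ("name" %in% names(bed)) bed$name else ".",
    score = if ("score" %in% names(bed)) bed$score else 0,
    strand = if ("strand" %in% names(bed)) bed$strand else "+"
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a numeric TSV matrix (header = sample ids, first column = row ids)
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  widths <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(widths)) > 1) {
    stop("ragged TSV matrix rows: line ",
         paste(which(widths != widths[1]), collapse = ", "))
  }
  df <- read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' Write a numeric TSV matrix
#'
#' @param mat Matrix with dimnames.
#' @param path Output path.
#' @param id_header Header for the row-id column.
#' @export
write_tsv_matrix <- function(mat, path, id_header = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  colnames(df)[1] <- id_header
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (name, description, genes per line).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Write gene sets to a GMT file
#'
#' @param pathways Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, nm, pathways[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a read-placement table (TSV or minimal SAM)
#'
#' TSV columns: read_id, chrom, start, end, strand, seq, sample (0-based
#' half-open coordinates).  SAM input (mapped records only) is converted to the
#' same table; sample is taken from the RG tag when present.
#'
#' @param path Path to a `.tsv` or `.sam` file.
#' @return data.frame of read placements.
#' @export
read_reads <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    f <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(f, function(x) length(x) >= 10, logical(1))
    f <- f[ok]
    flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
    mapped <- bitwAnd(flag, 4L) == 0L
    f <- f[mapped]
    flag <- flag[mapped]
    pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
    seq <- vapply(f, function(x) x[10], character(1))
    rg <- vapply(f, function(x) {
      tag <- grep("^RG:Z:", x, value = TRUE)
      if (length(tag)) sub("^RG:Z:", "", tag[1]) else "sample1"
    }, character(1))
    return(data.frame(
      read_id = vapply(f, `[`, character(1), 1),
      chrom = vapply(f, `[`, character(1), 3),
      start = pos - 1L, end = pos - 1L + nchar(seq),
      strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
      seq = seq, sample = rg
    ))
  }
  df <- read.delim(path)
  need <- c("read_id", "chrom", "start", "end", "strand", "seq", "sample")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("read table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a read-placement table as TSV
#'
#' @param reads data.frame from [simulate_reads()] or [read_reads()].
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
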