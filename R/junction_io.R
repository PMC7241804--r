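# Tabular and sequence IO: junction-count matrices, expression matrices,
# sample metadata, and FASTA.  All tabular formats are TSV with a header
# row; writers emit LF endings and hyphenated junction identifiers.

#' Parse a junction identifier
#'
#' Junction identifiers are printed as `chrom:start-end` with 1-based
#' inclusive coordinates.  Published tables often use an en-dash between the
#' coordinates; both the en-dash and the plain hyphen are accepted (and a
#' `-` may also separate chromosome from start).
#'
#' @param text identifier string, e.g. `"chr20:44443109-44444493"`.
#' @param gene gene symbol the junction belongs to.
#' @param strand one of `"+"`, `"-"`, `"unknown"`.
#' @return an object of class `"junction_id"`: a list with fields `chrom`,
#'   `start`, `end`, `gene`, `strand`.
#' @examples
#' parse_junction_id("chr20:44443109–44444493", "UBE2C")
#' @export
parse_junction_id <- function(text, gene, strand = "unknown") {
  stopifnot(is.character(text), length(text) == 1L,
            is.character(gene), length(gene) == 1L)
  strand <- match.arg(strand, c("+", "-", "unknown"))
  norm <- gsub("–", "-", text)
  m <- regmatches(norm, regexec("^(.+?)[:-]([0-9]+)[:-]([0-9]+)$", norm))[[1]]
  if (length(m) != 4L)
    stop_fmt("malformed junction identifier '%s': expected chrom:start-end", text)
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (!nzchar(m[2]))
    stop_fmt("malformed junction identifier '%s': empty chromosome", text)
  if (start >= end)
    stop_fmt("invalid junction '%s': start (%s) must be < end (%s)",
             text, m[3], m[4])
  structure(list(chrom = m[2], start = start, end = end,
                 gene = gene, strand = strand),
            class = "junction_id")
}

#' @export
#' @method format junction_id
format.junction_id <- function(x, ...) {
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
}

#' @export
print.junction_id <- function(x, ...) {
  cat(sprintf("<junction> %s (%s, strand %s)\n", format(x), x$gene, x$strand))
  invisible(x)
}

#' Construct a junction count matrix
#'
#' The central count container: a junctions-by-samples matrix of
#' non-negative integer read counts, a gene symbol per junction, and a
#' condition label per sample.
#'
#' @param counts integer matrix, junctions x samples, with junction
#'   identifier rownames (`chrom:start-end`) and sample-name colnames.
#' @param gene character vector of gene symbols, one per row of `counts`.
#' @param condition named character vector mapping every sample to its
#'   condition label.
#' @return an object of class `"junction_counts"` with fields `counts`,
#'   `gene`, `condition`, and a parsed `junctions` data frame
#'   (junction_id, chrom, start, end, gene).
#' @export
junction_counts <- function(counts, gene, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must have junction rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate junction identifiers: %s",
             paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                   collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_fmt("duplicate sample names")
  if (length(gene) != nrow(counts))
    stop_fmt("gene vector length (%d) != number of junctions (%d)",
             length(gene), nrow(counts))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_fmt("counts must be non-negative integers; first violation at junction '%s', sample '%s'",
             rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  storage.mode(counts) <- "integer"
  if (is.null(names(condition)) ||
      !setequal(names(condition), colnames(counts)))
    stop_fmt("condition must be a named vector covering exactly the samples")
  condition <- condition[colnames(counts)]
  parsed <- lapply(seq_len(nrow(counts)), function(i)
    parse_junction_id(rownames(counts)[i], gene[i]))
  junctions <- data.frame(
    junction_id = rownames(counts),
    chrom = vapply(parsed, `[[`, "", "chrom"),
    start = vapply(parsed, `[[`, 0, "start"),
    end = vapply(parsed, `[[`, 0, "end"),
    gene = gene,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, gene = gene, condition = condition,
                 junctions = junctions),
            class = "junction_counts")
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("<junction_counts> %d junctions x %d samples, %d genes\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$gene))))
  tab <- table(x$condition)
  cat("  conditions:", paste(sprintf("%s (n=%d)", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.junction_counts <- function(x) dim(x$counts)

#' Read a junction count matrix from TSV
#'
#' Expects a header row; columns `junction_id`, `gene`, then one column per
#' sample with integer counts.  Sample conditions come from a two-column
#' metadata TSV (`sample`, `condition`).
#'
#' @param path path to the counts TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @return a [junction_counts] object, row and column order as in the file.
#' @export
read_junction_counts <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3L || !identical(names(tab)[1:2], c("junction_id", "gene")))
    stop_fmt("%s: expected columns junction_id, gene, <samples...>", path)
  samples <- names(tab)[-(1:2)]
  counts <- matrix(NA_integer_, nrow(tab), length(samples),
                   dimnames = list(tab$junction_id, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(tab[[j + 2L]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad) > 0L)
      stop_fmt("%s: non-integer or negative count '%s' at row %d (junction '%s'), column '%s'",
               path, tab[[j + 2L]][bad[1]], bad[1], tab$junction_id[bad[1]],
               samples[j])
    counts[, j] <- as.integer(v)
  }
  meta <- read_metadata(metadata_path)
  unknown <- setdiff(names(meta), samples)
  if (length(unknown) > 0L)
    stop_fmt("%s: metadata names unknown sample(s): %s", metadata_path,
             paste(unknown, collapse = ", "))
  missing <- setdiff(samples, names(meta))
  if (length(missing) > 0L)
    stop_fmt("%s: no condition for sample(s): %s", metadata_path,
             paste(missing, collapse = ", "))
  junction_counts(counts, tab$gene, meta)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample`, `condition`.
#' @return named character vector mapping sample to condition.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE,
                            colClasses = "character")
  if (!all(c("sample", "condition") %in% names(meta)))
    stop_fmt("%s: expected columns sample, condition", path)
  if (anyDuplicated(meta$sample))
    stop_fmt("%s: duplicate sample names in metadata", path)
  stats::setNames(meta$condition, meta$sample)
}

#' Write a junction count matrix to TSV
#'
#' Inverse of [read_junction_counts()]; hyphenated identifiers, LF endings.
#'
#' @param x a [junction_counts] object.
#' @param path output TSV path.
#' @param metadata_path optional path for the sample metadata TSV.
#' @return `path`, invisibly.
#' @export
write_junction_counts <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "junction_counts"))
  out <- data.frame(junction_id = rownames(x$counts), gene = x$gene,
                    x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  if (!is.null(metadata_path)) {
    meta <- data.frame(sample = names(x$condition),
                       condition = unname(x$condition))
    utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  invisible(path)
}

#' Read a gene expression matrix from TSV
#'
#' Expects a header row; columns `gene` then one column per sample with
#' non-negative real values (RSEM-style normalized expression).
#'
#' @param path path to the expression TSV.
#' @return numeric matrix, genes x samples, gene symbols as rownames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L || names(tab)[1] != "gene")
    stop_fmt("%s: expected columns gene, <samples...>", path)
  if (anyDuplicated(tab$gene))
    stop_fmt("%s: duplicate gene symbols", path)
  samples <- names(tab)[-1]
  vals <- matrix(NA_real_, nrow(tab), length(samples),
                 dimnames = list(tab$gene, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0L)
      stop_fmt("%s: negative or non-numeric value '%s' at row %d (gene '%s'), column '%s'",
               path, tab[[j + 1L]][bad[1]], bad[1], tab$gene[bad[1]], samples[j])
    vals[, j] <- v
  }
  vals
}

#' Write a gene expression matrix to TSV
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  out <- data.frame(gene = rownames(values), values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read sequences from FASTA
#'
#' Sequences are uppercased; an optional `offset=<int>` token in the
#' description line records the 1-based genomic coordinate of the first
#' base (default 1).
#'
#' @param path FASTA file.
#' @return list of `"sequence_record"` objects (fields `name`, `sequence`,
#'   `offset`), named by record name.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_fmt("%s: no FASTA records", path)
  headers <- names(set)
  name <- sub("\\s.*$", "", headers)
  if (anyDuplicated(name))
    stop_fmt("%s: duplicate record name(s): %s", path,
             paste(unique(name[duplicated(name)]), collapse = ", "))
  offs <- rep(1, length(set))
  hit <- regmatches(headers, regexpr("offset=[0-9]+", headers))
  has <- grepl("offset=[0-9]+", headers)
  offs[has] <- as.numeric(sub("offset=", "", hit))
  recs <- lapply(seq_along(set), function(i) {
    s <- toupper(as.character(set[[i]]))
    if (!nzchar(s)) stop_fmt("%s: empty sequence for record '%s'", path, name[i])
    if (grepl("[^ACGTN]", s))
      stop_fmt("%s: record '%s' contains non-ACGTN characters", path, name[i])
    sequence_record(name[i], s, offs[i])
  })
  stats::setNames(recs, name)
}

#' Construct a sequence record
#'
#' @param name record name (keyed to a gene or region).
#' @param sequence DNA string over A/C/G/T/N.
#' @param offset 1-based genomic coordinate of the first base.
#' @return an object of class `"sequence_record"`.
#' @export
sequence_record <- function(name, sequence, offset = 1) {
  stopifnot(nzchar(name), nzchar(sequence))
  structure(list(name = name, sequence = toupper(sequence),
                 offset = as.numeric(offset)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence> %s: %d bp, offset %d\n", x$name,
              nchar(x$sequence), as.integer(x$offset)))
  invisible(x)
}

#' Write sequence records to FASTA
#'
#' @param records list of `"sequence_record"` objects.
#' @param path output FASTA path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (r in records) {
    writeLines(sprintf(">%s offset=%d", r$name, as.integer(r$offset)), con,
               sep = "\n")
    n <- nchar(r$sequence)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$sequence, starts, pmin(starts + width - 1L, n)),
               con, sep = "\n")
  }
  invisible(path)
}
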