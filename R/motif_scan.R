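# Scan for the polyadenylation-signal hexamer (AAUAAA, searched as DNA
# AATAAA) near splice junctions called as alternative splicing events.
# "Near" means within `window` bp of either junction endpoint; when the
# junction's strand is unknown both strands are scanned (the minus strand
# as the reverse complement TTTATT on the forward text).

PAS_MOTIF <- "AATAAA"

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# All 1-based start positions of literal pattern `pat` in `text`,
# including overlapping occurrences (zero-width lookahead).
motif_positions <- function(text, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), text, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Find polyadenylation-signal motifs near a junction
#'
#' Scans the union of the two windows `[start - window, start + window]`
#' and `[end - window, end + window]` (clipped to sequence coverage) for
#' `AATAAA` on the plus strand and its reverse complement `TTTATT` on the
#' minus strand.  With an annotated junction strand only that strand is
#' scanned.  Hits are deduplicated by (position, strand) and sorted by
#' position.
#'
#' @param seq a `"sequence_record"` covering the junction region.
#' @param junction a `"junction_id"`.
#' @param window flank width in bp (default 500).
#' @return data frame: `junction`, `position` (genomic coordinate of the
#'   leftmost matched base), `strand`, `offset` (signed distance from the
#'   nearest junction endpoint, negative = upstream), `matched_text`.
#' @export
find_pas_motifs <- function(seq, junction, window = 500) {
  stopifnot(inherits(seq, "sequence_record"), inherits(junction, "junction_id"),
            window > 0)
  seq_from <- seq$offset
  seq_to <- seq$offset + nchar(seq$sequence) - 1
  if (junction$start < seq_from || junction$end > seq_to)
    stop_fmt("junction %s outside sequence coverage [%d, %d]",
             format(junction), as.integer(seq_from), as.integer(seq_to))
  windows <- rbind(c(junction$start - window, junction$start + window),
                   c(junction$end - window, junction$end + window))
  windows[, 1] <- pmax(windows[, 1], seq_from)
  windows[, 2] <- pmin(windows[, 2], seq_to)
  strands <- if (junction$strand == "unknown") c("+", "-") else junction$strand
  hits <- list()
  for (w in seq_len(nrow(windows))) {
    lo <- windows[w, 1]; hi <- windows[w, 2]
    if (hi - lo + 1 < 6) next
    sub <- substr(seq$sequence, lo - seq_from + 1, hi - seq_from + 1)
    for (strand in strands) {
      pat <- if (strand == "+") PAS_MOTIF else revcomp(PAS_MOTIF)
      pos <- motif_positions(sub, pat) + lo - 1
      if (length(pos) > 0)
        hits[[length(hits) + 1L]] <- data.frame(position = pos,
                                                strand = strand)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(junction = character(0), position = numeric(0),
                      strand = character(0), offset = numeric(0),
                      matched_text = character(0), stringsAsFactors = FALSE))
  h <- do.call(rbind, hits)
  h <- h[!duplicated(paste(h$position, h$strand)), , drop = FALSE]
  d_start <- h$position - junction$start
  d_end <- h$position - junction$end
  offset <- ifelse(abs(d_start) <= abs(d_end), d_start, d_end)
  out <- data.frame(junction = format(junction), position = h$position,
                    strand = h$strand, offset = offset,
                    matched_text = PAS_MOTIF, stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan a set of called ASEs for the polyadenylation signal
#'
#' Takes the significance-ordered ASE table, keeps the top `top_k` called
#' events, and scans each one's gene sequence.  ASEs without an available
#' sequence are recorded as untested rather than failing the scan.
#'
#' @param ases a [select_ases()] data frame (sorted by significance).
#' @param seqs named list of `"sequence_record"` objects keyed by gene.
#' @param window flank width in bp (default 500).
#' @param top_k number of top ASEs to scan (default 20; larger than the
#'   list is fine).
#' @return data frame: `junction`, `gene`, `p_enrichment`, `tested`,
#'   `has_motif`, `n_hits`, `nearest_offset` (smallest |offset|, NA when
#'   no hit).
#' @export
scan_ase_set <- function(ases, seqs, window = 500, top_k = 20) {
  stopifnot(is.data.frame(ases), top_k >= 1)
  sel <- ases[ases$is_ase, , drop = FALSE]
  sel <- utils::head(sel, top_k)
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    g <- sel$gene[i]
    base <- data.frame(junction = sel$junction[i], gene = g,
                       p_enrichment = sel$p_enrichment[i],
                       stringsAsFactors = FALSE)
    if (is.na(g) || is.null(seqs[[g]]))
      return(cbind(base, tested = FALSE, has_motif = NA, n_hits = NA_integer_,
                   nearest_offset = NA_real_))
    jx <- parse_junction_id(sel$junction[i], g)
    hits <- find_pas_motifs(seqs[[g]], jx, window)
    cbind(base, tested = TRUE, has_motif = nrow(hits) > 0,
          n_hits = nrow(hits),
          nearest_offset = if (nrow(hits) > 0) min(abs(hits$offset))
                           else NA_real_)
  })
  if (length(rows) == 0L)
    return(data.frame(junction = character(0), gene = character(0),
                      p_enrichment = numeric(0), tested = logical(0),
                      has_motif = logical(0), n_hits = integer(0),
                      nearest_offset = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
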