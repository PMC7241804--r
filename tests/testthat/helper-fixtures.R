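# Shared fixture builders: everything is generated in code at test time.

# A balanced two-condition splice structure with Poisson counts.
make_structure <- function(n_junctions, n_r = 3, lambda = 50, gene = "G",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(rpois(n_junctions * 2 * n_r, lambda), nrow = n_junctions)
  rownames(counts) <- sprintf("chr1:%d-%d", 1000 * seq_len(n_junctions),
                              1000 * seq_len(n_junctions) + 500)
  colnames(counts) <- c(paste0("A", seq_len(n_r)), paste0("B", seq_len(n_r)))
  condition <- setNames(rep(c("A", "B"), each = n_r), colnames(counts))
  splice_structure(gene, counts, condition)
}

# A small junction_counts object: `genes` junctions-per-gene spec, two
# conditions with n_r samples each.
make_junction_counts <- function(genes = c(G1 = 3, G2 = 2), n_r = 3,
                                 lambda = 50, conditions = c("A", "B"),
                                 seed = 1) {
  set.seed(seed)
  n <- sum(genes)
  samples <- c(paste0(conditions[1], seq_len(n_r)),
               paste0(conditions[2], seq_len(n_r)))
  counts <- matrix(rpois(n * 2 * n_r, lambda), nrow = n)
  rownames(counts) <- sprintf("chr1:%d-%d", 1000 * seq_len(n),
                              1000 * seq_len(n) + 500)
  colnames(counts) <- samples
  gene <- rep(names(genes), genes)
  condition <- setNames(rep(conditions, each = n_r), samples)
  junction_counts(counts, gene, condition)
}

# alr coordinates of one structure's counts for a given reference, computed
# directly from the definition (independent of the package pipeline).
alr_by_hand <- function(counts, pseudocount = 0.5, ref = nrow(counts)) {
  t(apply(counts + pseudocount, 2, function(s) {
    x <- s / sum(s)
    log(x[-ref] / x[ref])
  }))
}

# One-sided Fisher p by exhaustive hypergeometric summation.
fisher_greater_by_hand <- function(ot, nt, on, nn) {
  m <- ot + on
  ks <- max(0, m - nn):min(nt, m)
  w <- choose(nt, ks) * choose(nn, m - ks)
  sum(w[ks >= ot]) / sum(w)
}

# Brute-force motif positions: position-by-position 6-mer comparison.
scan_by_hand <- function(sequence, pattern) {
  n <- nchar(sequence)
  hits <- integer(0)
  for (i in seq_len(max(0, n - 5))) {
    if (substr(sequence, i, i + 5) == pattern) hits <- c(hits, i)
  }
  hits
}

# Wilcoxon-type AUC: probability a differential gene ranks above a null.
rank_auc <- function(p, is_diff) {
  ok <- !is.na(p)
  p <- p[ok]; is_diff <- is_diff[ok]
  r <- rank(p)
  n1 <- sum(is_diff); n0 <- sum(!is_diff)
  (sum(r[!is_diff]) - n0 * (n0 + 1) / 2) / (n1 * n0)
}
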