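# Per-gene differential splice-structure testing.
#
# A gene's splice structure is its vector of junction-spanning read counts
# c = (c1, ..., cn) per sample.  To remove gene-expression level from the
# comparison the counts are normalized to a composition x = c / sum(c),
# which is mapped to unconstrained coordinates with the additive log-ratio
# (alr) transform y_i = ln(x_i / x_n), i = 1..n-1.  The two conditions are
# then compared with a two-sample Hotelling T2 statistic; a scaled version
# follows an F distribution with (n - 1, 2*n_r - n + 1) degrees of
# freedom, so the test is only defined for genes with fewer than
# 2*n_r + 1 junctions.  Genes over the bound are made testable by
# amalgamating small junctions into one bin.

#' Configuration for the differential splice-structure test
#'
#' @param min_mean_count "in use" threshold: a junction is kept when its
#'   per-condition mean count reaches this value (default 3).
#' @param in_use_mode `"any"` keeps junctions over threshold in at least
#'   one condition (condition-specific junctions are signal); `"both"`
#'   requires both conditions.
#' @param max_bins amalgamation target: genes with more in-use junctions
#'   are reduced to this many bins, one of which is the amalgamated bin
#'   (default 6, the largest testable dimension at 3 replicates).  `Inf`
#'   disables amalgamation.
#' @param pseudocount added to every count before composition
#'   normalization so the log-ratio transform is defined at zero
#'   (default 0.5).
#' @param alpha nominal significance level used in summaries.
#' @param pinv_tolerance reciprocal-condition-number threshold below which
#'   the pooled covariance is treated as singular and inverted with a
#'   pseudo-inverse.
#' @return an object of class `"diffsplice_config"`.
#' @export
diffsplice_config <- function(min_mean_count = 3, in_use_mode = c("any", "both"),
                              max_bins = 6, pseudocount = 0.5, alpha = 0.05,
                              pinv_tolerance = 1e-10) {
  in_use_mode <- match.arg(in_use_mode)
  stopifnot(min_mean_count >= 0, max_bins >= 2, pseudocount > 0,
            alpha > 0, alpha < 1, pinv_tolerance > 0)
  structure(list(min_mean_count = min_mean_count, in_use_mode = in_use_mode,
                 max_bins = max_bins, pseudocount = pseudocount,
                 alpha = alpha, pinv_tolerance = pinv_tolerance),
            class = "diffsplice_config")
}

#' Construct one gene's splice structure
#'
#' @param gene gene symbol.
#' @param counts junctions x samples matrix of non-negative integers with
#'   junction-identifier rownames.
#' @param condition named vector over the samples with exactly two labels
#'   and equal replicate counts.
#' @return an object of class `"splice_structure"` with fields `gene`,
#'   `counts`, `condition`, `n_r`, `amalgamated`.
#' @export
splice_structure <- function(gene, counts, condition) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("j%d", seq_len(nrow(counts)))
  stopifnot(all(counts >= 0), !is.null(colnames(counts)))
  condition <- condition[colnames(counts)]
  tab <- table(condition)
  if (length(tab) != 2L)
    stop_fmt("gene %s: exactly two conditions required (got %d)", gene,
             length(tab))
  if (tab[1] != tab[2])
    stop_fmt("gene %s: equal replicate counts per condition required (%d vs %d)",
             gene, tab[1], tab[2])
  structure(list(gene = gene, counts = counts, condition = condition,
                 n_r = as.integer(tab[1]), amalgamated = FALSE),
            class = "splice_structure")
}

#' Largest testable junction count
#'
#' The null F distribution of the test has denominator degrees of freedom
#' `2*n_r - n + 1`, positive only while `n <= 2*n_r`.  With 3 replicates
#' per condition only genes with fewer than 7 junctions get a p-value.
#'
#' @param n_r replicates per condition (>= 2).
#' @return the largest junction count `n` with `2*n_r - n + 1 > 0`.
#' @export
max_testable_junctions <- function(n_r) {
  if (!is_count(n_r) || n_r < 2)
    stop_fmt("n_r must be an integer >= 2 (got %s)", format(n_r))
  as.integer(2 * n_r)
}

#' Filter junctions to those "in use"
#'
#' Keeps junctions whose mean count reaches `cfg$min_mean_count` in at
#' least one condition (or both, with `in_use_mode = "both"`), preserving
#' junction order.
#'
#' @param structure a [splice_structure].
#' @param cfg a [diffsplice_config].
#' @return the filtered [splice_structure] (possibly with zero rows).
#' @export
filter_in_use <- function(structure, cfg = diffsplice_config()) {
  stopifnot(inherits(structure, "splice_structure"))
  conds <- unique(structure$condition)
  means <- sapply(conds, function(cc)
    rowMeans(structure$counts[, structure$condition == cc, drop = FALSE]))
  if (!is.matrix(means)) means <- matrix(means, nrow = 1L)
  ok <- means >= cfg$min_mean_count
  keep <- if (cfg$in_use_mode == "any") rowSums(ok) >= 1L
          else rowSums(ok) == length(conds)
  structure$counts <- structure$counts[keep, , drop = FALSE]
  structure
}

#' Amalgamate small junctions into one bin
#'
#' When a gene has more in-use junctions than `cfg$max_bins`, the
#' `max_bins - 1` junctions with the largest overall mean counts are kept
#' (in their original order, ties broken by position) and all remaining
#' junctions are summed, per sample, into a single `AMALGAM` bin, so the
#' gene contributes exactly `max_bins` bins and per-sample count totals
#' are conserved exactly.
#'
#' @param structure a filtered [splice_structure].
#' @param cfg a [diffsplice_config].
#' @return a [splice_structure] with at most `max_bins` rows; field
#'   `amalgamated` records whether binning happened.
#' @export
amalgamate <- function(structure, cfg = diffsplice_config()) {
  stopifnot(inherits(structure, "splice_structure"))
  n <- nrow(structure$counts)
  if (!is.finite(cfg$max_bins) || n <= cfg$max_bins) {
    structure$amalgamated <- FALSE
    return(structure)
  }
  mu <- rowMeans(structure$counts)
  rank <- order(-mu, seq_along(mu))
  keep <- sort(rank[seq_len(cfg$max_bins - 1L)])
  rest <- setdiff(seq_len(n), keep)
  amalgam <- colSums(structure$counts[rest, , drop = FALSE])
  structure$counts <- rbind(structure$counts[keep, , drop = FALSE],
                            AMALGAM = amalgam)
  structure$amalgamated <- TRUE
  structure
}

#' Normalize a count vector to a composition
#'
#' `x_i = (c_i + pseudocount) / sum_j (c_j + pseudocount)`: the pattern of
#' junction usage with gene-expression level divided out.  The pseudocount
#' keeps every component strictly positive so the log-ratio transform is
#' defined.
#'
#' @param c vector of non-negative counts, length >= 2.
#' @param pseudocount positive offset (default 0.5).
#' @return numeric vector summing to 1 with strictly positive components.
#' @export
normalize_pattern <- function(c, pseudocount = 0.5) {
  stopifnot(pseudocount > 0, all(c >= 0))
  if (length(c) < 2L)
    stop_fmt("a composition needs at least 2 parts (got %d)", length(c))
  s <- c + pseudocount
  s / sum(s)
}

#' Additive log-ratio transform
#'
#' Maps an n-part composition to n-1 unconstrained coordinates,
#' `y_i = ln(x_i / x_ref)` for every i except the reference (default: the
#' last part), in original order.  The choice of reference does not affect
#' the downstream T2 statistic.
#'
#' @param x strictly positive composition vector.
#' @param reference_index index of the denominator part.
#' @return numeric vector of length `length(x) - 1` with attribute
#'   `reference_index`.
#' @export
alr_transform <- function(x, reference_index = length(x)) {
  if (any(x <= 0))
    stop_fmt("alr transform requires strictly positive components")
  stopifnot(reference_index >= 1, reference_index <= length(x))
  y <- log(x[-reference_index] / x[reference_index])
  attr(y, "reference_index") <- as.integer(reference_index)
  y
}

#' Two-sample Hotelling T2 on alr coordinates
#'
#' With `n_r` replicate alr vectors of dimension `p = n - 1` per
#' condition, computes `T2 = (n_r/2) * d' S^-1 d` where `d` is the
#' difference of condition mean vectors and `S` the pooled covariance
#' (divisor `2*n_r - 2`), and the scaled statistic
#' `F = T2 * (2*n_r - n + 1) / ((2*n_r - 2) * (n - 1))`, referred to the
#' F distribution with `(n - 1, 2*n_r - n + 1)` degrees of freedom.  A
#' numerically singular pooled covariance is inverted with the
#' Moore-Penrose pseudo-inverse and flagged.
#'
#' @param Y_A,Y_B matrices of alr coordinates, replicates in rows
#'   (`n_r` x p each).
#' @param cfg a [diffsplice_config] (supplies `pinv_tolerance`).
#' @return list with `T2`, `F_stat`, `df1`, `df2`, `p_value`, `status`
#'   (one of `"tested"`, `"singular_covariance_pinv"`, `"untestable_df"`,
#'   `"untestable_single_junction"`).
#' @export
hotelling_t2 <- function(Y_A, Y_B, cfg = diffsplice_config()) {
  Y_A <- as.matrix(Y_A); Y_B <- as.matrix(Y_B)
  stopifnot(nrow(Y_A) == nrow(Y_B), ncol(Y_A) == ncol(Y_B))
  n_r <- nrow(Y_A)
  p <- ncol(Y_A)
  if (p < 1L)
    return(list(T2 = NA_real_, F_stat = NA_real_, df1 = NA_integer_,
                df2 = NA_integer_, p_value = NA_real_,
                status = "untestable_single_junction"))
  n <- p + 1L
  df1 <- p
  df2 <- as.integer(2L * n_r - n + 1L)
  if (df2 <= 0L)
    return(list(T2 = NA_real_, F_stat = NA_real_, df1 = df1, df2 = df2,
                p_value = NA_real_, status = "untestable_df"))
  d <- colMeans(Y_A) - colMeans(Y_B)
  S <- ((n_r - 1) * stats::cov(Y_A) + (n_r - 1) * stats::cov(Y_B)) /
    (2 * n_r - 2)
  status <- "tested"
  if (p == 1L) {
    s2 <- as.numeric(S)
    if (s2 <= 0) {
      status <- "singular_covariance_pinv"
      quad <- if (abs(d) < .Machine$double.eps) 0 else Inf
    } else quad <- d^2 / s2
  } else {
    rc <- tryCatch(rcond(S), error = function(e) 0)
    if (!is.finite(rc) || rc < cfg$pinv_tolerance) {
      status <- "singular_covariance_pinv"
      Sinv <- MASS::ginv(S)
    } else {
      Sinv <- solve(S)
    }
    quad <- as.numeric(t(d) %*% Sinv %*% d)
  }
  T2 <- (n_r * n_r / (2 * n_r)) * quad
  F_stat <- T2 * df2 / ((2 * n_r - 2) * df1)
  p_value <- stats::pf(F_stat, df1, df2, lower.tail = FALSE)
  list(T2 = T2, F_stat = F_stat, df1 = df1, df2 = df2, p_value = p_value,
       status = status)
}

#' Test one gene for differential splice structure
#'
#' The full per-gene pipeline: "in use" filtering, amalgamation,
#' per-sample composition normalization, alr transform (last-bin
#' reference), and the Hotelling T2 / F test.  Untestable genes are
#' flagged by status, never raised as errors.
#'
#' @param structure a [splice_structure].
#' @param cfg a [diffsplice_config].
#' @return one-row data frame: `gene`, `n_junctions_total`,
#'   `n_junctions_used` (bins entering the test), `amalgamated`, `T2`,
#'   `F_stat`, `df1`, `df2`, `p_value`, `status`.
#' @export
test_gene <- function(structure, cfg = diffsplice_config()) {
  stopifnot(inherits(structure, "splice_structure"))
  n_total <- nrow(structure$counts)
  st <- filter_in_use(structure, cfg)
  st <- amalgamate(st, cfg)
  n_used <- nrow(st$counts)
  res <- if (n_used < 2L) {
    list(T2 = NA_real_, F_stat = NA_real_,
         df1 = NA_integer_, df2 = NA_integer_, p_value = NA_real_,
         status = if (n_used == 1L || n_total == 1L)
           "untestable_single_junction" else "untestable_df")
  } else {
    Y <- apply(st$counts, 2, function(cc)
      alr_transform(normalize_pattern(cc, cfg$pseudocount)))
    if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
    Y <- t(Y)  # samples x (n_used - 1)
    A <- Y[st$condition == sort(unique(st$condition))[1], , drop = FALSE]
    B <- Y[st$condition == sort(unique(st$condition))[2], , drop = FALSE]
    hotelling_t2(A, B, cfg)
  }
  data.frame(gene = structure$gene, n_junctions_total = n_total,
             n_junctions_used = n_used, amalgamated = st$amalgamated,
             T2 = res$T2, F_stat = res$F_stat,
             df1 = as.integer(res$df1), df2 = as.integer(res$df2),
             p_value = res$p_value, status = res$status,
             stringsAsFactors = FALSE)
}
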