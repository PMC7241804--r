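# Outlier-based calling of alternative splicing events (ASEs) in a
# tumor-versus-normal cohort.
#
# Junction counts are normalized to reads-per-million, divided by the
# gene's RSEM-style expression value, and log-transformed.  A junction is
# an ASE when tumor samples exceed the Tukey upper fence of the normal
# samples significantly more often than normal samples do (one-sided
# Fisher exact test).  The fence/Fisher construction is a reconstruction
# of the outlier statistic referenced by the source analyses, with the
# fence multiplier and significance level exposed as parameters.

#' Normalize junction counts by library size and gene expression
#'
#' `value = ln((count / library_size * 1e6 + pseudocount) /
#' (expression + pseudocount))`, where `library_size` is the per-sample
#' total junction count and `expression` the junction's gene's value in
#' `expr` for that sample.  The pseudocount keeps every entry finite.
#'
#' @param counts a [junction_counts] object.
#' @param expr genes x samples expression matrix covering every junction's
#'   gene and every sample.
#' @param pseudocount positive offset (default 1).
#' @return matrix of class `"normalized_junctions"`, same shape as the
#'   counts, with attributes `gene` (per row), `pseudocount`, and
#'   `library_size`.
#' @export
normalize_junctions <- function(counts, expr, pseudocount = 1) {
  stopifnot(inherits(counts, "junction_counts"), pseudocount > 0)
  missing <- setdiff(unique(counts$gene), rownames(expr))
  if (length(missing) > 0L)
    stop_fmt("expression matrix lacks gene(s): %s",
             paste(missing, collapse = ", "))
  samples <- colnames(counts$counts)
  if (!all(samples %in% colnames(expr)))
    stop_fmt("expression matrix lacks sample(s): %s",
             paste(setdiff(samples, colnames(expr)), collapse = ", "))
  lib <- colSums(counts$counts)
  # an all-zero sample has RPM 0 for every junction; avoid 0/0
  rpm <- sweep(counts$counts, 2, pmax(lib, 1), "/") * 1e6
  denom <- expr[counts$gene, samples, drop = FALSE] + pseudocount
  out <- log((rpm + pseudocount) / denom)
  structure(out, class = c("normalized_junctions", class(out)),
            gene = counts$gene, pseudocount = pseudocount,
            library_size = lib)
}

#' Call per-junction outlier samples against the normal cohort
#'
#' For each junction, the fence is `Q3 + k_fence * IQR` computed over the
#' NORMAL samples only; any sample (tumor or normal) strictly above the
#' fence is an outlier for that junction.  Upper-tail only: the target
#' signature is aberrantly high junction usage in tumors.
#'
#' @param norm a `"normalized_junctions"` matrix.
#' @param normal_samples,tumor_samples sample name vectors (>= 3 normals).
#' @param k_fence fence multiplier (default 1.5, the Tukey convention).
#' @return object of class `"outlier_calls"`: list with `outlier` (logical
#'   junctions x samples matrix over both groups), `fence` (per-junction
#'   threshold), `normal_samples`, `tumor_samples`, `k_fence`.
#' @export
call_outliers <- function(norm, normal_samples, tumor_samples,
                          k_fence = 1.5) {
  stopifnot(length(tumor_samples) >= 1)
  if (length(normal_samples) < 3L)
    stop_fmt("need >= 3 normal samples for stable quartiles (got %d)",
             length(normal_samples))
  miss <- setdiff(c(normal_samples, tumor_samples), colnames(norm))
  if (length(miss) > 0L)
    stop_fmt("samples not in matrix: %s", paste(miss, collapse = ", "))
  nm <- norm[, normal_samples, drop = FALSE]
  q <- t(apply(nm, 1, stats::quantile, probs = c(0.25, 0.75), names = FALSE))
  fence <- q[, 2] + k_fence * (q[, 2] - q[, 1])
  all_s <- c(normal_samples, tumor_samples)
  outlier <- sweep(norm[, all_s, drop = FALSE], 1, fence, ">")
  structure(list(outlier = outlier, fence = fence,
                 normal_samples = normal_samples,
                 tumor_samples = tumor_samples, k_fence = k_fence,
                 gene = attr(norm, "gene")),
            class = "outlier_calls")
}

#' Select ASEs: junctions with significantly more tumor outliers
#'
#' Per junction, a one-sided Fisher exact test on the 2x2 table of
#' outlier status by cohort; a junction is an ASE when the enrichment p is
#' below `alpha` AND the tumor outlier fraction exceeds the normal one.
#'
#' @param calls an [call_outliers()] result.
#' @param alpha significance level (default 0.05).
#' @return data frame with one row per junction: `junction`, `gene`,
#'   `n_outlier_tumor`, `n_outlier_normal`, `n_tumor`, `n_normal`,
#'   `fence`, `p_enrichment`, `is_ase`, sorted by `p_enrichment`.
#' @export
select_ases <- function(calls, alpha = 0.05) {
  stopifnot(inherits(calls, "outlier_calls"), alpha >= 0, alpha <= 1)
  ot <- rowSums(calls$outlier[, calls$tumor_samples, drop = FALSE])
  on <- rowSums(calls$outlier[, calls$normal_samples, drop = FALSE])
  nt <- length(calls$tumor_samples); nn <- length(calls$normal_samples)
  p <- vapply(seq_along(ot), function(i) {
    stats::fisher.test(matrix(c(ot[i], nt - ot[i], on[i], nn - on[i]), 2),
                       alternative = "greater")$p.value
  }, 0)
  out <- data.frame(junction = rownames(calls$outlier),
                    gene = calls$gene %||% NA_character_,
                    n_outlier_tumor = as.integer(ot),
                    n_outlier_normal = as.integer(on),
                    n_tumor = nt, n_normal = nn,
                    fence = calls$fence,
                    p_enrichment = p,
                    is_ase = p < alpha & (ot / nt) > (on / nn),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_enrichment, out$junction), ]
  rownames(out) <- NULL
  out
}

#' Count ASEs per sample
#'
#' A sample's ASE count is the number of called ASE junctions for which
#' that sample is an outlier.
#'
#' @param ases a [select_ases()] data frame.
#' @param calls the [call_outliers()] result the ASEs came from.
#' @return data frame: `sample`, `condition` (normal/tumor), `n_ases`.
#' @export
count_ases_per_sample <- function(ases, calls) {
  stopifnot(inherits(calls, "outlier_calls"))
  keep <- ases$junction[ases$is_ase]
  sub <- calls$outlier[rownames(calls$outlier) %in% keep, , drop = FALSE]
  n <- colSums(sub)
  data.frame(sample = colnames(calls$outlier),
             condition = ifelse(colnames(calls$outlier) %in%
                                  calls$tumor_samples, "tumor", "normal"),
             n_ases = as.integer(n),
             stringsAsFactors = FALSE)
}

#' Flag samples with high ASE burden
#'
#' A sample is "high" when its ASE count strictly exceeds
#' `median + k_sd * SD` over all samples.  The default multiplier is 0.5;
#' 0 and 1.0 are the conventional sensitivity settings.
#'
#' @param n_ases numeric vector of per-sample ASE counts (named).
#' @param k_sd standard-deviation multiplier (default 0.5).
#' @return named logical vector.
#' @export
assign_high_ase_group <- function(n_ases, k_sd = 0.5) {
  stopifnot(length(n_ases) >= 2)
  cut <- stats::median(n_ases) + k_sd * stats::sd(n_ases)
  res <- n_ases > cut
  res[is.na(res)] <- FALSE
  res
}

#' Compare ASE burden between expression-defined groups
#'
#' Splits samples into a high-expression group (z-score above
#' `z_threshold`, default 2) and the rest, and compares their ASE counts
#' with a two-sided two-sample Student's t-test.
#'
#' @param n_ases named numeric vector of per-sample ASE counts.
#' @param z named numeric vector of expression z-scores for one gene,
#'   covering the same samples.
#' @param z_threshold z-score cutoff defining the high group (default 2).
#' @return list: `n_high`, `n_rest`, `mean_high`, `mean_rest`,
#'   `mean_difference`, `t`, `p_value`.
#' @export
compare_expression_groups <- function(n_ases, z, z_threshold = 2) {
  common <- intersect(names(n_ases), names(z))
  if (length(common) < 4L)
    stop_fmt("need >= 4 samples shared between ASE counts and z-scores")
  n_ases <- n_ases[common]; z <- z[common]
  high <- z > z_threshold
  if (sum(high) < 2L || sum(!high) < 2L)
    stop_fmt("each expression group needs >= 2 samples (high: %d, rest: %d)",
             sum(high), sum(!high))
  tt <- stats::t.test(n_ases[high], n_ases[!high], var.equal = TRUE)
  list(n_high = sum(high), n_rest = sum(!high),
       mean_high = mean(n_ases[high]), mean_rest = mean(n_ases[!high]),
       mean_difference = mean(n_ases[high]) - mean(n_ases[!high]),
       t = unname(tt$statistic), p_value = tt$p.value)
}
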