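# Synthetic junction-count experiments with known ground truth.
#
# The generative model mirrors the structure the splice-pattern test
# assumes: a gene expresses a small set of transcripts, each transcript
# spans a subset of the gene's junctions, and the transcript mixture
# induces a covariance structure on junction counts.  Replicate-to-
# replicate variation in transcript proportions is Dirichlet, per-sample
# total junction depth is negative binomial, and observed counts are
# multinomial given depth and per-junction read shares.

#' Specify one simulated gene
#'
#' Builds a per-gene specification: junction-incidence vectors for each
#' transcript, transcript proportions in condition A (`base_props`), and a
#' tilted copy of those proportions in condition B whose total-variation
#' distance from `base_props` is `effect` (probability mass `effect` moved
#' from transcript 1 to transcript 2).
#'
#' By default a gene has two transcripts: junction 1 is shared
#' (constitutive), odd-indexed junctions belong to transcript 1 and
#' even-indexed to transcript 2 — the minimal alternative-splicing pattern
#' in which shifting the transcript mix shifts junction usage.
#'
#' @param gene gene symbol.
#' @param n_junctions number of junctions (>= 1).
#' @param transcripts optional list of 0/1 incidence vectors, one per
#'   transcript, each of length `n_junctions`.
#' @param base_props transcript proportions in condition A (sum to 1);
#'   default `c(0.75, 0.25)` for the two-transcript design.
#' @param effect total-variation distance between condition A and B
#'   proportions, in `[0, min(base_props[1], 1 - base_props[2]))`.
#' @return an object of class `"sim_gene_spec"`.
#' @export
sim_gene_spec <- function(gene, n_junctions, transcripts = NULL,
                          base_props = NULL, effect = 0) {
  stopifnot(is_count(n_junctions), n_junctions >= 1, effect >= 0, effect <= 1)
  if (is.null(transcripts)) {
    n <- n_junctions
    t1 <- as.integer(seq_len(n) %% 2L == 1L); t1[1] <- 1L
    t2 <- as.integer(seq_len(n) %% 2L == 0L); t2[1] <- 1L
    transcripts <- if (n == 1L) list(t1) else list(t1, t2)
  }
  k <- length(transcripts)
  for (tr in transcripts) {
    if (length(tr) != n_junctions || !all(tr %in% c(0, 1)))
      stop_fmt("each transcript must be a 0/1 vector of length %d", n_junctions)
    if (sum(tr) < 1) stop_fmt("each transcript must use at least one junction")
  }
  inc <- do.call(rbind, transcripts)
  if (any(colSums(inc) == 0))
    stop_fmt("every junction must be used by at least one transcript")
  if (is.null(base_props))
    base_props <- if (k == 2L) c(0.75, 0.25) else rep(1 / k, k)
  stopifnot(length(base_props) == k, all(base_props >= 0))
  if (abs(sum(base_props) - 1) > 1e-12)
    stop_fmt("base_props must sum to 1")
  alt_props <- base_props
  if (effect > 0) {
    if (k < 2L) stop_fmt("a differential gene needs >= 2 transcripts")
    if (base_props[1] - effect < 0 || base_props[2] + effect > 1)
      stop_fmt("effect %.3f incompatible with base_props", effect)
    alt_props[1] <- alt_props[1] - effect
    alt_props[2] <- alt_props[2] + effect
  }
  structure(list(gene = gene, n_junctions = as.integer(n_junctions),
                 transcripts = transcripts, base_props = base_props,
                 alt_props = alt_props, effect = effect,
                 is_differential = effect > 0),
            class = "sim_gene_spec")
}

#' Simulation configuration
#'
#' Defaults are the study conditions the generator emulates: a two-group
#' design with 3 replicates per condition, genes with 3-6 junctions, mean
#' per-gene sequencing depth 300 junction-spanning reads (negative binomial,
#' size 10), Dirichlet concentration 100 for replicate-level transcript-
#' proportion noise, and a usage shift of total-variation 0.5 in the 20% of
#' genes that are truly differential.
#'
#' @param n_genes number of genes.
#' @param frac_differential fraction of genes with a true usage shift.
#' @param n_r replicates per condition (>= 2).
#' @param depth_mean mean total junction-read depth per gene per sample.
#' @param depth_dispersion negative-binomial size parameter for depth;
#'   `Inf` means fixed (deterministic) depth.
#' @param overdispersion Dirichlet concentration for transcript-proportion
#'   noise across replicates; `Inf` means proportions are fixed at the
#'   condition means.
#' @param effect usage-shift magnitude (total-variation distance) for
#'   differential genes.
#' @param n_junctions_range inclusive range of junctions per gene.
#' @param seed root seed; every draw is reproducible from the config alone.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 200, frac_differential = 0.2, n_r = 3,
                       depth_mean = 300, depth_dispersion = 10,
                       overdispersion = 100, effect = 0.5,
                       n_junctions_range = c(3, 6), seed = 1) {
  stopifnot(is_count(n_genes), n_genes >= 1,
            frac_differential >= 0, frac_differential <= 1,
            is_count(n_r), n_r >= 2,
            depth_mean > 0, depth_dispersion > 0, overdispersion > 0,
            effect >= 0, effect <= 1,
            length(n_junctions_range) == 2,
            n_junctions_range[1] >= 1,
            n_junctions_range[1] <= n_junctions_range[2],
            is_count(seed))
  structure(list(n_genes = as.integer(n_genes),
                 frac_differential = frac_differential, n_r = as.integer(n_r),
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 overdispersion = overdispersion, effect = effect,
                 n_junctions_range = as.integer(n_junctions_range),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Transcript proportions -> expected per-junction read shares.
junction_shares <- function(spec, theta) {
  inc <- do.call(rbind, spec$transcripts)
  w <- as.numeric(crossprod(inc, theta))
  w / sum(w)
}

# One Dirichlet draw via independent gammas; concentration Inf collapses to
# the mean vector.
rdirichlet1 <- function(alpha) {
  if (any(!is.finite(alpha))) stop_fmt("non-finite Dirichlet parameter")
  g <- vapply(alpha, function(a) if (a > 0) stats::rgamma(1, shape = a) else 0,
              0)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Simulate one gene's junction count vector
#'
#' Draws transcript proportions from a Dirichlet centred on the condition's
#' proportions, converts them to expected per-junction read shares through
#' the incidence vectors, draws a total depth (negative binomial), and
#' draws counts multinomially.  The RNG stream is split deterministically
#' from `cfg$seed` and the (gene, condition, replicate) keys, so the same
#' arguments always return the same vector.
#'
#' @param spec a [sim_gene_spec].
#' @param cfg a [sim_config].
#' @param condition `"A"` or `"B"`.
#' @param replicate_index replicate number within the condition (1-based).
#' @return integer vector of length `spec$n_junctions`.
#' @export
simulate_gene <- function(spec, cfg, condition, replicate_index) {
  stopifnot(inherits(spec, "sim_gene_spec"), inherits(cfg, "sim_config"))
  condition <- match.arg(condition, c("A", "B"))
  props <- if (condition == "A") spec$base_props else spec$alt_props
  seed <- derive_seed(cfg$seed, spec$gene, condition, replicate_index)
  with_seed(seed, {
    theta <- if (is.infinite(cfg$overdispersion)) props
             else rdirichlet1(cfg$overdispersion * props)
    shares <- junction_shares(spec, theta)
    depth <- if (is.infinite(cfg$depth_dispersion)) round(cfg$depth_mean)
             else stats::rnbinom(1, mu = cfg$depth_mean,
                                 size = cfg$depth_dispersion)
    as.integer(stats::rmultinom(1, depth, shares))
  })
}

#' Simulate a full two-condition junction-count experiment
#'
#' Generates `cfg$n_genes` genes, each with a junction count in
#' `cfg$n_junctions_range` and a `cfg$frac_differential` chance of carrying
#' a usage shift of magnitude `cfg$effect`, then simulates `2 * n_r`
#' samples (conditions A and B).  Junction coordinates place each gene on
#' its own locus so identifiers are unique.
#'
#' @param cfg a [sim_config].
#' @return list with elements `counts` (a [junction_counts] object with
#'   condition labels A/B) and `truth` (data frame: gene, is_differential,
#'   effect, n_junctions).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  specs <- with_seed(derive_seed(cfg$seed, "specs"), {
    lapply(seq_len(cfg$n_genes), function(g) {
      nj_choices <- seq(cfg$n_junctions_range[1], cfg$n_junctions_range[2])
      nj <- nj_choices[sample.int(length(nj_choices), 1)]
      diff <- stats::runif(1) < cfg$frac_differential
      sim_gene_spec(sprintf("G%04d", g), nj,
                    effect = if (diff) cfg$effect else 0)
    })
  })
  samples <- c(paste0("A", seq_len(cfg$n_r)), paste0("B", seq_len(cfg$n_r)))
  condition <- stats::setNames(rep(c("A", "B"), each = cfg$n_r), samples)
  rows <- list(); genes <- character(0); ids <- character(0)
  for (g in seq_along(specs)) {
    spec <- specs[[g]]
    mat <- vapply(samples, function(s) {
      simulate_gene(spec, cfg, unname(condition[s]),
                    as.integer(sub("^[AB]", "", s)))
    }, integer(spec$n_junctions))
    if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1L)
    rows[[g]] <- mat
    genes <- c(genes, rep(spec$gene, spec$n_junctions))
    j <- seq_len(spec$n_junctions)
    start <- g * 100000 + j * 1000
    ids <- c(ids, sprintf("chr%d:%d-%d", (g %% 22L) + 1L, start, start + 500L))
  }
  counts <- do.call(rbind, rows)
  dimnames(counts) <- list(ids, samples)
  truth <- data.frame(
    gene = vapply(specs, `[[`, "", "gene"),
    is_differential = vapply(specs, `[[`, FALSE, "is_differential"),
    effect = vapply(specs, `[[`, 0, "effect"),
    n_junctions = vapply(specs, `[[`, 0L, "n_junctions"),
    stringsAsFactors = FALSE
  )
  list(counts = junction_counts(counts, genes, condition), truth = truth)
}

# Remove every occurrence of the polyadenylation hexamer (both strands)
# from a background sequence by mutating the middle base of each hit.
scrub_motif <- function(seq, motifs = c("AATAAA", "TTTATT")) {
  repeat {
    hit <- FALSE
    for (m in motifs) {
      p <- regexpr(m, seq, fixed = TRUE)
      if (p > 0) {
        hit <- TRUE
        substr(seq, p + 2L, p + 2L) <- if (m == "AATAAA") "C" else "G"
      }
    }
    if (!hit) return(seq)
  }
}

#' Simulate gene-region sequences with optional planted AAUAAA motifs
#'
#' For each junction, emits a random background sequence covering
#' `[start - window, end + window]`.  When `plant_motif` is `TRUE` for a
#' junction, a single `AATAAA` (the DNA form of the AAUAAA polyadenylation
#' signal) is planted at a recorded position within `window` bp of the
#' junction start; otherwise every occurrence of the hexamer (either
#' strand) is scrubbed from the background, so a scan finds exactly the
#' planted signals.
#'
#' @param junctions list of `"junction_id"` objects (one gene each; record
#'   names are the gene symbols and must be unique).
#' @param plant_motif logical vector, one per junction.
#' @param window flank width in bp (> 0).
#' @param seed integer seed.
#' @return named list of `"sequence_record"` objects; each carries a
#'   `planted_at` attribute (genomic coordinate of the planted motif, or
#'   `NA`).
#' @export
simulate_sequences <- function(junctions, plant_motif, window = 500,
                               seed = 1) {
  stopifnot(window > 0, length(plant_motif) == length(junctions))
  genes <- vapply(junctions, `[[`, "", "gene")
  if (anyDuplicated(genes))
    stop_fmt("one junction per gene required (duplicate gene symbols)")
  recs <- lapply(seq_along(junctions), function(i) {
    jx <- junctions[[i]]
    with_seed(derive_seed(seed, "seq", jx$gene), {
      from <- max(1, jx$start - window)
      to <- jx$end + window
      len <- to - from + 1
      seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      seq <- scrub_motif(seq)
      planted_at <- NA_real_
      if (plant_motif[i]) {
        # plant within the upstream window of the junction start
        lo <- max(1, jx$start - window - from + 1)
        hi <- max(lo, jx$start - from + 1 - 6)
        pos <- if (hi > lo) sample(seq(lo, hi), 1) else lo
        substr(seq, pos, pos + 5L) <- "AATAAA"
        seq <- local({
          # planting can create flanking hits; re-scrub around, keep plant
          s <- seq
          pre <- if (pos > 1) scrub_motif(substr(s, 1, pos - 1)) else ""
          post <- if (pos + 6 <= nchar(s)) scrub_motif(substr(s, pos + 6, nchar(s))) else ""
          paste0(pre, "AATAAA", post)
        })
        planted_at <- from + pos - 1
      }
      structure(sequence_record(jx$gene, seq, from), planted_at = planted_at)
    })
  })
  stats::setNames(recs, genes)
}

#' Simulate a tumor/normal cohort with planted alternative splicing events
#'
#' Synthetic stand-in for a tumor-versus-normal junction cohort: background
#' junction counts are negative binomial with a matching RSEM-style
#' expression matrix, and for `n_ase` genes one junction is over-expressed
#' (`fold`-fold) in a random `outlier_frac` of tumor samples — the
#' signature the outlier-based ASE caller is designed to detect.
#'
#' @param n_normal,n_tumor cohort sizes.
#' @param n_genes number of genes (3 junctions each).
#' @param n_ase number of genes carrying a planted tumor-specific junction.
#' @param outlier_frac fraction of tumor samples that are outliers for a
#'   planted junction.
#' @param fold over-expression factor in outlier samples.
#' @param base_mu,base_size negative-binomial background count parameters.
#' @param seed integer seed.
#' @return list with `counts` (a [junction_counts], conditions
#'   normal/tumor), `expression` (genes x samples matrix), and
#'   `truth` (character vector of planted junction identifiers).
#' @export
simulate_ase_dataset <- function(n_normal = 20, n_tumor = 20, n_genes = 30,
                                 n_ase = 10, outlier_frac = 0.4, fold = 8,
                                 base_mu = 30, base_size = 10, seed = 1) {
  stopifnot(n_ase <= n_genes, n_normal >= 3, n_tumor >= 1)
  with_seed(derive_seed(seed, "ase"), {
    samples <- c(paste0("N", seq_len(n_normal)), paste0("T", seq_len(n_tumor)))
    condition <- stats::setNames(
      rep(c("normal", "tumor"), c(n_normal, n_tumor)), samples)
    n_j <- 3L
    genes <- rep(sprintf("G%03d", seq_len(n_genes)), each = n_j)
    start <- rep(seq_len(n_genes) * 50000, each = n_j) +
      rep(seq_len(n_j) * 1000, n_genes)
    ids <- sprintf("chr%d:%d-%d", (rep(seq_len(n_genes), each = n_j) %% 22L) + 1L,
                   start, start + 400L)
    counts <- matrix(stats::rnbinom(length(ids) * length(samples),
                                    mu = base_mu, size = base_size),
                     nrow = length(ids),
                     dimnames = list(ids, samples))
    planted <- character(0)
    tumor <- which(condition == "tumor")
    for (g in seq_len(n_ase)) {
      row <- (g - 1L) * n_j + 1L  # first junction of gene g
      k <- max(1L, round(outlier_frac * length(tumor)))
      hit <- sample(tumor, k)
      counts[row, hit] <- counts[row, hit] * fold + fold
      planted <- c(planted, ids[row])
    }
    expr <- matrix(stats::rlnorm(n_genes * length(samples),
                                 meanlog = log(10), sdlog = 0.3),
                   nrow = n_genes,
                   dimnames = list(sprintf("G%03d", seq_len(n_genes)), samples))
    list(counts = junction_counts(counts, genes, condition),
         expression = expr, truth = planted)
  })
}
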