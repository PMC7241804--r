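# Unit and property tests for the per-gene compositional Hotelling T2 test.

test_that("the testability bound solves the degrees-of-freedom inequality", {
  # largest n with 2*n_r - n + 1 > 0
  expect_equal(max_testable_junctions(3), 6L)
  expect_equal(max_testable_junctions(4), 8L)
  expect_equal(max_testable_junctions(2), 4L)
  expect_error(max_testable_junctions(1), "n_r")
  for (n_r in 2:6) {
    n_max <- max_testable_junctions(n_r)
    expect_true(2 * n_r - n_max + 1 > 0)
    expect_false(2 * n_r - (n_max + 1) + 1 > 0)
  }
})

test_that("'in use' filtering keeps junctions over threshold in >= 1 condition", {
  # junction means per condition: (5,0) kept, (2,2) dropped, (4,4) kept
  counts <- rbind(c(5, 5, 5, 0, 0, 0),
                  c(2, 2, 2, 2, 2, 2),
                  c(4, 4, 4, 4, 4, 4))
  rownames(counts) <- c("chr1:1-2", "chr1:3-4", "chr1:5-6")
  colnames(counts) <- c(paste0("A", 1:3), paste0("B", 1:3))
  cond <- setNames(rep(c("A", "B"), each = 3), colnames(counts))
  st <- splice_structure("G", counts, cond)

  # brute-force the at-least-one-condition rule over enumerated mean pairs
  means <- cbind(rowMeans(counts[, 1:3]), rowMeans(counts[, 4:6]))
  expected_keep <- apply(means >= 3, 1, any)
  kept <- filter_in_use(st, diffsplice_config(min_mean_count = 3))
  expect_identical(rownames(kept$counts), rownames(counts)[expected_keep])

  # "both" mode drops condition-specific junctions
  kept_both <- filter_in_use(st, diffsplice_config(min_mean_count = 3,
                                                   in_use_mode = "both"))
  expect_identical(rownames(kept_both$counts), "chr1:5-6")

  # a zero threshold is the identity
  expect_identical(filter_in_use(st, diffsplice_config(min_mean_count = 0))$counts,
                   st$counts)
})

test_that("amalgamation yields exactly max_bins bins and conserves totals", {
  st <- make_structure(9, n_r = 3, seed = 11)
  out <- amalgamate(st, diffsplice_config())
  expect_true(out$amalgamated)
  expect_equal(nrow(out$counts), 6L)  # 5 kept + 1 amalgamated bin
  expect_equal(colSums(out$counts), colSums(st$counts))
  expect_true("AMALGAM" %in% rownames(out$counts))
  # the 5 kept junctions are the largest by overall mean, original order
  mu <- rowMeans(st$counts)
  keep <- sort(order(-mu)[1:5])
  expect_identical(rownames(out$counts)[1:5], rownames(st$counts)[keep])

  # at or under the boundary the structure is untouched
  st6 <- make_structure(6, n_r = 3, seed = 12)
  out6 <- amalgamate(st6, diffsplice_config())
  expect_false(out6$amalgamated)
  expect_identical(out6$counts, st6$counts)

  # conservation holds for a range of sizes
  for (n in c(7, 8, 12, 20)) {
    sti <- make_structure(n, n_r = 3, seed = n)
    outi <- amalgamate(sti, diffsplice_config())
    expect_equal(colSums(outi$counts), colSums(sti$counts))
    expect_equal(nrow(outi$counts), 6L)
  }
})

test_that("pattern normalization returns strictly positive compositions", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:10, 1)
    cc <- rpois(n, 40)
    x <- normalize_pattern(cc)
    expect_equal(sum(x), 1, tolerance = 1e-12)
    expect_true(all(x > 0))
    expect_equal(x, (cc + 0.5) / sum(cc + 0.5))
  }
  expect_equal(normalize_pattern(c(10, 10)), c(0.5, 0.5))
  # zero counts collapse to the uniform composition
  expect_equal(normalize_pattern(c(0, 0, 0)), rep(1 / 3, 3))
  expect_error(normalize_pattern(5), "at least 2")
})

test_that("the alr transform matches its definition and handles references", {
  expect_equal(unclass(alr_transform(c(0.5, 0.5)))[1], 0,
               ignore_attr = TRUE)
  expect_equal(as.numeric(alr_transform(rep(0.25, 4))), rep(0, 3))
  # direct evaluation of the log-ratio formula
  y <- alr_transform(c(0.2, 0.3, 0.5), reference_index = 3)
  expect_equal(as.numeric(y), c(log(0.4), log(0.6)), tolerance = 1e-12)
  expect_equal(as.numeric(y), c(-0.9162907, -0.5108256), tolerance = 1e-6)
  # non-last reference keeps original order of the remaining parts
  y1 <- alr_transform(c(0.2, 0.3, 0.5), reference_index = 1)
  expect_equal(as.numeric(y1), c(log(1.5), log(2.5)), tolerance = 1e-12)
  expect_error(alr_transform(c(0.5, 0, 0.5)), "positive")
})

test_that("identical groups give T2 = 0 and p = 1", {
  set.seed(101)
  Y <- matrix(rnorm(6), 3)  # 2 dimensions: pooled covariance stays regular
  res <- hotelling_t2(Y, Y)
  expect_equal(res$T2, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$status, "tested")
  # even a rank-deficient case keeps the zero-difference answer
  Y3 <- matrix(rnorm(9), 3)
  res3 <- hotelling_t2(Y3, Y3)
  expect_equal(res3$T2, 0, tolerance = 1e-8)
  expect_equal(res3$p_value, 1, tolerance = 1e-8)
})

test_that("for two-junction genes the test reduces to the pooled t statistic", {
  # 1-D oracle: F equals the squared two-sample t times the df scaling
  set.seed(41)
  n_r <- 3
  for (i in 1:200) {
    st <- make_structure(2, n_r = n_r, lambda = sample(c(20, 80, 300), 1))
    res <- test_gene(st, diffsplice_config(min_mean_count = 0))
    y <- alr_by_hand(st$counts)
    tt <- t.test(y[1:n_r], y[n_r + 1:n_r], var.equal = TRUE)
    F_oracle <- unname(tt$statistic)^2 * (2 * n_r - 1) / (2 * n_r - 2)
    expect_equal(res$F_stat, F_oracle, tolerance = 1e-10)
    expect_equal(res$df1, 1L)
    expect_equal(res$df2, 2L * n_r - 1L)
  }
})

test_that("T2 is invariant to the alr reference choice", {
  set.seed(51)
  cfg <- diffsplice_config(min_mean_count = 0)
  for (i in 1:100) {
    n <- sample(3:5, 1)  # non-singular regime at n_r = 3
    st <- make_structure(n, n_r = 3, lambda = 60)
    t2 <- vapply(seq_len(n), function(ref) {
      Y <- alr_by_hand(st$counts, ref = ref)
      hotelling_t2(Y[1:3, , drop = FALSE], Y[4:6, , drop = FALSE], cfg)$T2
    }, 0)
    expect_equal(max(abs(t2 - t2[1])) / max(abs(t2[1]), 1e-12), 0,
                 tolerance = 1e-8)
  }
})

test_that("test_gene fills statuses, degrees of freedom, and amalgamation", {
  # single-junction gene: no composition to test
  st1 <- make_structure(1, n_r = 3, seed = 61)
  r1 <- test_gene(st1, diffsplice_config(min_mean_count = 0))
  expect_equal(r1$status, "untestable_single_junction")
  expect_true(is.na(r1$p_value))

  # 8 in-use junctions at n_r = 3: amalgamated to 6 bins, df (5, 1)
  st8 <- make_structure(8, n_r = 3, lambda = 100, seed = 62)
  r8 <- test_gene(st8)
  expect_true(r8$amalgamated)
  expect_equal(r8$n_junctions_used, 6L)
  expect_equal(r8$df1, 5L)
  expect_equal(r8$df2, 1L)

  # over the bound with amalgamation disabled: untestable
  r8u <- test_gene(st8, diffsplice_config(max_bins = Inf))
  expect_equal(r8u$status, "untestable_df")
  expect_true(is.na(r8u$p_value))

  # everything filtered out: untestable, not an error
  st0 <- make_structure(3, n_r = 3, lambda = 1, seed = 63)
  r0 <- test_gene(st0, diffsplice_config(min_mean_count = 100))
  expect_true(is.na(r0$p_value))
})

test_that("a planted usage shift is detected in most replicates", {
  # power oracle: effect 0.5, depth 500, n_r = 3
  cfg <- sim_config(n_genes = 1, frac_differential = 1, depth_mean = 500,
                    effect = 0.5, n_junctions_range = c(4, 4), seed = 1)
  hits <- 0L
  for (s in 1:60) {
    cfg$seed <- s
    sim <- simulate_dataset(cfg)
    fit <- diff_splice(sim$counts)
    if (isTRUE(fit$results$p_value < 0.05)) hits <- hits + 1L
  }
  expect_gt(hits / 60, 0.5)
})

test_that("dataset-level results are ordered, adjusted, and sample-order invariant", {
  sim <- simulate_dataset(sim_config(n_genes = 40, seed = 71))
  fit <- diff_splice(sim$counts)
  res <- fit$results
  expect_setequal(res$gene, sim$truth$gene)
  p <- res$p_value[!is.na(res$p_value)]
  expect_true(!is.unsorted(p))
  # BH q-values match p.adjust over defined p
  expect_equal(res$q_value[!is.na(res$p_value)], p.adjust(p, "BH"))
  expect_true(all(res$q_value >= res$p_value - 1e-12, na.rm = TRUE))

  # permuting sample order changes nothing
  perm <- sample(colnames(sim$counts$counts))
  shuffled <- junction_counts(sim$counts$counts[, perm], sim$counts$gene,
                              sim$counts$condition[perm])
  fit2 <- diff_splice(shuffled)
  expect_equal(fit2$results, fit$results)

  # a single testable gene has q = p
  one <- make_junction_counts(genes = c(G1 = 3), n_r = 3, seed = 72)
  f1 <- diff_splice(one, config = diffsplice_config(min_mean_count = 0))
  expect_equal(f1$results$q_value, f1$results$p_value)

  # unequal group sizes are a design error
  bad_cond <- setNames(c("A", "A", "A", "A", "B", "B"),
                       colnames(sim$counts$counts))
  expect_error(junction_counts(sim$counts$counts, sim$counts$gene,
                               bad_cond) |> diff_splice(),
               "equal replicate")
})

test_that("fit object methods print, summarise, and export", {
  sim <- simulate_dataset(sim_config(n_genes = 15, seed = 81))
  fit <- diff_splice(sim$counts)
  expect_s3_class(fit, "diffsplice")
  expect_output(print(fit), "Hotelling")
  s <- summary(fit)
  expect_output(print(s), "genes")
  expect_identical(as.data.frame(fit), fit$results)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diffsplice_results(fit, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(fit$results))
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
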