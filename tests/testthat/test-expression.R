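test_that("size_factors implement median-of-ratios", {
  m <- cbind(a = c(10, 20, 30), b = c(10, 20, 30))
  expect_equal(size_factors(m), c(a = 1, b = 1))
  m2 <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "positive")
})

test_that("size_factors agree with the DESeq2 implementation", {
  withr::with_seed(10, {
    mu <- rlnorm(3000, 4, 1)
    depth <- c(0.5, 1, 1.5, 2)
    m <- sapply(depth, function(d) rnbinom(3000, mu = mu * d, size = 10))
    colnames(m) <- paste0("s", 1:4)
  })
  sf <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(sf / sf[1]), unname(ref / ref[1]), tolerance = 1e-10)
  # normalized library sums nearly equal despite 4x depth differences
  sums <- colSums(normalize_counts(m, sf))
  expect_lt(diff(range(sums)) / mean(sums), 0.05)
})

test_that("group_log2fc is a pseudocounted log-ratio of group means", {
  # two invariant features pin the median-of-ratios factors at 1, so the
  # remaining feature's fold change passes through unchanged
  m <- cbind(f1 = c(20, 5, 7), f2 = c(20, 5, 7),
             m1 = c(10, 5, 7), m2 = c(10, 5, 7))
  rownames(m) <- c("a", "b", "c")
  samples <- tibble::tibble(sample_id = colnames(m),
                            sex = c("F", "F", "M", "M"))
  fc <- group_log2fc(m, samples, pseudocount = 0)
  expect_equal(fc$log2fc, c(1, 0, 0))
  # antisymmetry under group swap
  fc_rev <- group_log2fc(m, samples, "M", "F", pseudocount = 0)
  expect_equal(fc$log2fc, -fc_rev$log2fc)
  expect_error(group_log2fc(m, samples, "F", "X"), "at least one sample")
})

test_that("embryo_expressed_filter uses a strict mean-count threshold", {
  m <- rbind(a = rep(101, 4), b = rep(100, 4), c = rep(0, 4))
  keep <- embryo_expressed_filter(m)
  expect_equal(unname(keep), c(TRUE, FALSE, FALSE))
  expect_true(all(embryo_expressed_filter(m, 0)[c("a", "b")]))
})

test_that("region_shift_test flags shifted regions and stays null-calibrated", {
  withr::with_seed(11, {
    fc <- c(rnorm(102, -0.6, 0.2), rnorm(300, 0, 0.2))
    rg <- rep(c("ZDIFF", "PAR"), c(102, 300))
    res <- region_shift_test(fc, rg, alternative = "less")
    expect_lt(res$p_value[res$region == "ZDIFF"], 1e-6)
    expect_gt(res$p_value[res$region == "PAR"], 0.01)
    # symmetric log2FCs around zero: p approximately uniform
    ps <- replicate(300, region_shift_test(rnorm(60), rep("A", 60),
                                           alternative = "less")$p_value)
    expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
    # between-regions mode uses the rank-sum test
    rb <- region_shift_test(fc, rg, mode = "between_regions",
                            alternative = "less")
    expect_lt(rb$p_value, 1e-6)
  })
  expect_error(region_shift_test(numeric(0), character(0)), regexp = ".")
})

test_that("dc_onset detects the early deficit and not the late stage", {
  s <- sim_full()
  regions <- s$genes[, c("gene_id", "region")]
  early <- simulate_embryo_counts(s, "early", seed = 800)
  res_e <- dc_onset(early$counts, early$samples, regions)
  expect_true(res_e$significant[res_e$region == "ZDIFF"])
  expect_false(any(res_e$significant[res_e$region != "ZDIFF"]))
  expect_lt(res_e$median_log2fc[res_e$region == "ZDIFF"], -0.3)
  late <- simulate_embryo_counts(s, "late", seed = 801)
  res_l <- dc_onset(late$counts, late$samples, regions)
  expect_false(any(res_l$significant))
})

test_that("bin_de_scan filters, tests and ranks bins", {
  withr::with_seed(12, {
    n_bins <- 400
    mu <- rlnorm(n_bins, 3, 1)
    m <- sapply(1:12, function(i) rnbinom(n_bins, mu = mu, size = 10))
    rownames(m) <- sprintf("b%03d", seq_len(n_bins))
    colnames(m) <- c(paste0("F", 1:6), paste0("M", 1:6))
    # inject an 8x female excess into one well-covered bin
    hot <- which.max(mu)
    m[hot, 1:6] <- rnbinom(6, mu = mu[hot] * 8, size = 10)
  })
  samples <- tibble::tibble(sample_id = colnames(m),
                            sex = rep(c("F", "M"), each = 6))
  scan <- bin_de_scan(m, samples, min_mean = 5)
  hot_row <- scan[scan$bin_id == rownames(m)[hot], ]
  # with 6v6 samples the exact rank-sum p has a floor, so a few null bins
  # may tie the injected bin at the minimum adjusted p
  expect_equal(hot_row$p_adj, min(scan$p_adj))
  expect_gt(hot_row$log2fc, 1)
  expect_true(all(scan$p_adj >= scan$p_value))
  # infinite threshold -> nothing tested
  expect_equal(nrow(bin_de_scan(m, samples, min_mean = Inf)), 0)
  expect_error(bin_de_scan(m[, c(1, 7)],
                           samples[c(1, 7), ]), "2 samples")
})

test_that("bin_de_scan is calibrated under the null", {
  rates <- vapply(1:5, function(i) {
    withr::with_seed(100 + i, {
      mu <- rlnorm(300, 3.5, 0.8)
      m <- sapply(1:12, function(j) rnbinom(300, mu = mu, size = 10))
      rownames(m) <- sprintf("b%03d", 1:300)
      colnames(m) <- c(paste0("F", 1:6), paste0("M", 1:6))
    })
    samples <- tibble::tibble(sample_id = colnames(m),
                              sex = rep(c("F", "M"), each = 6))
    scan <- bin_de_scan(m, samples, min_mean = 5)
    c(mean(scan$p_value < 0.05), sum(scan$p_adj < 0.05))
  }, numeric(2))
  expect_true(all(rates[1, ] <= 0.07))   # raw rejection rate
  expect_true(all(rates[2, ] <= 1))      # BH discoveries under the null
})

test_that("cv_compare contrasts young and old variability per region", {
  s <- sim_full()
  regions <- s$genes[, c("gene_id", "region")]
  ag <- simulate_aging_signals(s, "F", 3, 3, seed = 810)
  res <- cv_compare(ag$signal, ag$samples, regions)
  zd <- res$tests[res$tests$region == "ZDIFF", ]
  expect_lt(zd$p_adj, 2e-16)
  expect_gt(zd$median_cv_old, zd$median_cv_young)
  agm <- simulate_aging_signals(s, "M", 3, 3, seed = 811)
  resm <- cv_compare(agm$signal, agm$samples, regions)
  expect_true(all(resm$tests$p_adj > 0.05))
  # degenerate constant signals: ties everywhere, p = 1 branch
  const <- matrix(5, nrow = 4, ncol = 6,
                  dimnames = list(paste0("g", 1:4),
                                  c(paste0("y", 1:3), paste0("o", 1:3))))
  cs <- tibble::tibble(sample_id = colnames(const),
                       age_group = rep(c("young", "old"), each = 3))
  cres <- cv_compare(const, cs, tibble::tibble(gene_id = paste0("g", 1:4),
                                               region = "AUTOSOME"))
  expect_equal(cres$tests$p_value, 1)
  expect_true(all(cres$cv$cv_young == 0))
})

test_that("cv_compare keeps its type-I error near nominal under the null", {
  s <- sim_genome(sim_config(seed = 64, scale = 0.1, n_autosomes = 2,
                             aging_sdlog = 0))
  regions <- s$genes[, c("gene_id", "region")]
  rej <- vapply(1:40, function(i) {
    ag <- simulate_aging_signals(s, "F", 3, 3, seed = 900 + i)
    res <- cv_compare(ag$signal, ag$samples, regions)
    any(res$tests$p_value < 0.05 &
          res$tests$region == "ZDIFF")
  }, logical(1))
  expect_lte(mean(rej), 0.125)  # 0.05 nominal; binomial slack over 40 runs
})

test_that("age_decline_correlation ranks declining chromosome classes", {
  ages <- seq(5, 50, length.out = 8)
  withr::with_seed(13, {
    # X genes decline faster than autosomal genes
    mk <- function(slope, n) t(sapply(seq_len(n), function(i)
      pmax(0, 100 + slope * ages + rnorm(8, 0, 5))))
    m <- rbind(mk(-1.5, 60), mk(-0.2, 120))
    rownames(m) <- sprintf("g%03d", 1:180)
    cls <- tibble::tibble(gene_id = rownames(m),
                          class = rep(c("X", "AUTOSOME"), c(60, 120)))
    # one gene observed at zero in 5 of 8 time points must be dropped
    m["g001", ] <- c(0, 0, 0, 0, 0, 3, 4, 5)
  })
  res <- age_decline_correlation(m, ages, cls)
  expect_false("g001" %in% res$per_gene$gene_id)
  expect_lt(res$comparisons$p_adj, 0.001)
  med <- tapply(res$per_gene$r, res$per_gene$class, median)
  expect_lt(med[["X"]], med[["AUTOSOME"]])
  # a strictly decreasing gene has r = -1
  lin <- matrix(rep(seq(80, 10, length.out = 8), 2), nrow = 2,
                byrow = TRUE, dimnames = list(c("lin1", "lin2"), NULL))
  lin[2, ] <- lin[2, ] + 1
  r1 <- age_decline_correlation(lin, ages,
                                tibble::tibble(gene_id = c("lin1", "lin2"),
                                               class = c("X", "AUTOSOME")))
  expect_equal(unname(r1$per_gene$r), c(-1, -1))
  expect_error(age_decline_correlation(m[, 1:2], ages[1:2], cls), "3 time")
})
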