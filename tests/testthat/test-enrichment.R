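test_that("bin_log2fc computes pseudocounted ratios on shared bins", {
  bins <- tibble::tibble(chrom = "Z", start = c(0, 10, 20),
                         end = c(10, 20, 30))
  f <- dplyr::mutate(bins, value = c(3, 5, 0))
  m <- dplyr::mutate(bins, value = c(1, 5, 0))
  fc <- bin_log2fc(f, m, pseudocount = 1)
  expect_equal(fc$log2fc, c(1, 0, 0))  # log2(4/2), equal, pseudocount guard
  m2 <- dplyr::mutate(bins[-1, ], value = 1)
  expect_error(bin_log2fc(f, m2), "same bin set")
  expect_error(bin_log2fc(f, m, pseudocount = 0), "> 0")
})

test_that("stratum_median_log2fc groups bins by midpoint", {
  lay <- toy_layout()
  st <- artemia_strata()
  bins <- tibble::tibble(
    chrom = "Z",
    start = c(49e6, 50e6, 51e6, 1e6, 2e6),
    end = c(49e6, 50e6, 51e6, 1e6, 2e6) + 1e4
  )
  fc <- dplyr::mutate(bins, log2fc = c(1, 1.5, 2, 0.1, 0.3))
  med <- stratum_median_log2fc(fc, st, lay)
  expect_equal(med$median_log2fc[med$group == "S0"], 1.5)
  expect_equal(med$median_log2fc[med$group == "PAR"], 0.2)
  expect_true(is.na(med$median_log2fc[med$group == "AUTOSOME"]))
  # all-equal track: every non-empty group shares the same median
  fc2 <- dplyr::mutate(bins, log2fc = 0.7)
  med2 <- stratum_median_log2fc(fc2, st, lay)
  expect_true(all(med2$median_log2fc[med2$n_bins > 0] == 0.7))
})

test_that("recovered stratum medians match the configured enrichment", {
  s <- sim_full()
  expt <- simulate_cuttag_experiment(s, n_rep = 3, width_bp = 1e4,
                                     seed = 700)
  med <- stratum_median_log2fc(sexed_log2fc(expt), s$strata, s$layout)
  truth <- c(S0 = 1.280, S1 = 1.169, S2 = 0.435, ZDIFF_OUTSIDE = 0.8,
             PAR = 0, AUTOSOME = 0)
  got <- setNames(med$median_log2fc, med$group)[names(truth)]
  expect_true(all(abs(got - truth) < 0.1))
})

test_that("window_summary returns per-window quartiles", {
  s <- sim_small()
  lay <- s$layout
  bins <- make_bins(lay, 1e4)
  zbins <- bins[bins$chrom == lay$z_name, ]
  const <- dplyr::mutate(zbins, value = 5)
  ws <- window_summary(const, lay, 14)
  expect_equal(nrow(ws), 14)
  expect_true(all(ws$median == 5 & ws$min == 5 & ws$max == 5))
  expect_error(window_summary(const, lay, 0), ">= 1")
  # female simulation: windows inside Z(diff) exceed PAR-only windows
  f <- cpm_track(simulate_cuttag_counts(sim_full(), "F", 1e4, seed = 710))
  wsf <- window_summary(f, sim_full()$layout, 14)
  par_end <- sim_full()$layout$par_boundary_bp
  par_win <- wsf$end <= par_end
  zd_win <- wsf$start >= par_end
  expect_gt(min(wsf$median[zd_win]), max(wsf$median[par_win]))
})

test_that("gene_signal averages over the strand-aware extended span", {
  lay <- zw_layout(tibble::tibble(name = "c1", length_bp = 10000), "c1", 5000)
  bins <- make_bins(lay, 100)
  const <- dplyr::mutate(bins, value = 2.5)
  genes <- tibble::tibble(gene_id = c("a", "b"), chrom = "c1",
                          start = c(3001, 3001), end = c(5000, 5000),
                          strand = c("+", "-"))
  gs <- gene_signal(const, genes, lay)
  expect_equal(gs$signal, c(2.5, 2.5))
  # mirrored coverage gives equal signals for opposite strands
  v <- sin(seq_len(nrow(bins))) + 2
  fwd <- dplyr::mutate(bins, value = v)
  rev <- dplyr::mutate(bins, value = rev(v))
  gplus <- tibble::tibble(gene_id = "g", chrom = "c1", start = 2001,
                          end = 4000, strand = "+")
  gminus <- tibble::tibble(gene_id = "g", chrom = "c1", start = 6001,
                           end = 8000, strand = "-")
  expect_equal(gene_signal(fwd, gplus, lay)$signal,
               gene_signal(rev, gminus, lay)$signal, tolerance = 1e-9)
  # upstream clipped at the chromosome start
  edge <- tibble::tibble(gene_id = "e", chrom = "c1", start = 101,
                         end = 600, strand = "+")
  expect_equal(gene_signal(const, edge, lay)$signal, 2.5)
  expect_error(gene_signal(const, dplyr::mutate(edge, chrom = "nope"), lay),
               "unknown")
})

test_that("metaprofile is flat under constant coverage", {
  lay <- zw_layout(tibble::tibble(name = "c1", length_bp = 1e5), "c1", 5e4)
  bins <- make_bins(lay, 50)
  const <- dplyr::mutate(bins, value = 3)
  withr::with_seed(9, {
    genes <- tibble::tibble(
      gene_id = sprintf("g%d", 1:30), chrom = "c1",
      start = seq(2000, 90000, length.out = 30),
      end = seq(2000, 90000, length.out = 30) +
        sample(c(300, 1200, 5000, 9000), 30, replace = TRUE),
      strand = sample(c("+", "-"), 30, TRUE), group = "all")
  })
  genes$start <- round(genes$start); genes$end <- round(pmin(genes$end, 99000))
  prof <- metaprofile(const, genes, lay)
  expect_equal(nrow(prof), (1000 + 5000 + 1000) / 50)
  expect_true(all(abs(prof$median_signal - 3) < 1e-9))
  # genes shorter than the resolution are skipped with a warning
  short <- dplyr::bind_rows(genes,
    tibble::tibble(gene_id = "tiny", chrom = "c1", start = 500, end = 520,
                   strand = "+", group = "all"))
  expect_warning(metaprofile(const, short, lay), "shorter")
})

test_that("metaprofile separates promoter peaks from broad enrichment", {
  cfg <- sim_config(seed = 61, scale = 0.02, n_autosomes = 2,
                    n_genes = c(autosome = 150, par = 30, zdiff = 60),
                    tpm_meanlog = log(60), bin_base_mean = 500)
  s <- sim_genome(cfg)
  genes <- s$genes[s$genes$expressed, ]
  genes$group <- genes$region
  mk_prof <- function(sex) {
    trk <- cpm_track(simulate_cuttag_counts(s, sex, 200, seed = 720))
    metaprofile(trk, genes, s$layout, resolution_bp = 200)
  }
  pm <- mk_prof("M")
  auto_m <- pm[pm$group == "AUTOSOME", ]
  tss_zone <- abs(auto_m$position) <= 600
  body_zone <- auto_m$position > 1500 & auto_m$position < 4500
  # male autosomal signal: peaked at the TSS, near-baseline in the body
  expect_gt(mean(auto_m$median_signal[tss_zone]),
            2 * mean(auto_m$median_signal[body_zone]))
  pf <- mk_prof("F")
  # female Z(diff) genes: elevated body signal relative to autosomal genes
  zd_f <- pf[pf$group == "ZDIFF", ]
  auto_f <- pf[pf$group == "AUTOSOME", ]
  expect_gt(mean(zd_f$median_signal[zd_f$position > 1500 &
                                      zd_f$position < 4500]),
            2 * mean(auto_f$median_signal[auto_f$position > 1500 &
                                            auto_f$position < 4500]))
})

test_that("classify_expressed and tpm_from_counts follow their rules", {
  expect_equal(classify_expressed(c(12, 9.9, 0), c(0, 9.9, 15)),
               c(TRUE, FALSE, TRUE))
  expect_true(all(classify_expressed(c(1, 2), c(3, 4), cutoff = 0)))
  expect_error(classify_expressed(-1, 5), "non-negative")
  tpm <- tpm_from_counts(c(100, 200, 50), c(1000, 4000, 500))
  expect_equal(sum(tpm), 1e6)
  expect_gt(tpm[1], tpm[2])  # shorter gene, same rate ordering
})

test_that("every CPM track sums to one million", {
  s <- sim_small()
  for (sex in c("F", "M")) {
    trk <- cpm_track(simulate_cuttag_counts(s, sex, 5e3, seed = 730))
    expect_equal(sum(trk$value), 1e6)
  }
})

test_that("log2FC tracks are null-calibrated without sex-specific folds", {
  cfg <- sim_config(seed = 62,
                    stratum_log2_enrichment = c(S0 = 0, S1 = 0, S2 = 0,
                                                ZDIFF_OUTSIDE = 0))
  s <- sim_genome(cfg)
  expt <- simulate_cuttag_experiment(s, n_rep = 3, width_bp = 1e4,
                                     seed = 740)
  med <- stratum_median_log2fc(sexed_log2fc(expt), s$strata, s$layout)
  big <- med$n_bins >= 200
  expect_true(all(abs(med$median_log2fc[big]) < 0.05))
  expect_true(all(abs(med$median_log2fc) < 0.15, na.rm = TRUE))
})

test_that("recovered S0 medians increase with the configured enrichment", {
  meds <- vapply(c(0, 0.5, 1, 1.5), function(delta) {
    cfg <- sim_config(seed = 63,
                      stratum_log2_enrichment = c(S0 = delta, S1 = 0.6,
                                                  S2 = 0.2,
                                                  ZDIFF_OUTSIDE = 0.4))
    s <- sim_genome(cfg)
    expt <- simulate_cuttag_experiment(s, n_rep = 3, width_bp = 1e4,
                                       seed = 750)
    med <- stratum_median_log2fc(sexed_log2fc(expt), s$strata, s$layout)
    med$median_log2fc[med$group == "S0"]
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})
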