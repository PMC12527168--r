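# Expression-level statistics: median-of-ratios normalization with naive
# group log2 fold changes (a deliberately transparent stand-in for a full
# shrinkage-based differential expression fit — downstream statistics here
# operate on log2FC distributions, not on per-gene Wald tests), embryonic
# dosage-compensation onset testing, a bin-wise differential expression scan
# for unannotated transcripts, and aging variability statistics.

counts_to_matrix <- function(counts, feature_col = "gene_id") {
  counts <- as_tibble(counts)
  fc <- intersect(c(feature_col, "gene_id", "feature_id", "bin_id"),
                  names(counts))[1]
  if (is.na(fc)) abort("counts need a feature id column (e.g. `gene_id`)")
  m <- as.matrix(counts[, setdiff(names(counts), fc)])
  rownames(m) <- counts[[fc]]
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Median-of-ratios size factors
#'
#' Per sample, the median over features (restricted to features with
#' positive counts in every sample) of the ratio of the count to the
#' feature's geometric mean across samples, rescaled to geometric mean 1.
#'
#' @param counts Count tibble (feature id column + one column per sample) or
#'   numeric matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    abort("no feature has positive counts in every sample")
  }
  lg <- log(m[pos, , drop = FALSE])
  ratios <- lg - rowMeans(lg)
  sf <- exp(apply(ratios, 2, median))
  sf / exp(mean(log(sf)))
}

#' Normalize counts by size factors
#'
#' @inheritParams size_factors
#' @param sf Optional precomputed [size_factors()].
#' @return Numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  sf <- sf %||% size_factors(m)
  sweep(m, 2, sf, "/")
}

#' Group log2 fold change on normalized counts
#'
#' `log2((mean_A + pc) / (mean_B + pc))` per feature, where the means are
#' taken over size-factor-normalized counts in each sample group.
#'
#' @inheritParams size_factors
#' @param samples Sample sheet with `sample_id` and the grouping column.
#' @param group_a,group_b Group labels compared (A over B; e.g. `"F"`, `"M"`).
#' @param group_col Column of `samples` holding the labels (default `"sex"`).
#' @param pseudocount Pseudocount on the normalized-mean scale (default 1).
#' @return Tibble `feature_id`, `base_mean`, `mean_a`, `mean_b`, `log2fc`.
#' @export
group_log2fc <- function(counts, samples, group_a = "F", group_b = "M",
                         group_col = "sex", pseudocount = 1) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  samples <- as_tibble(samples)
  ids_a <- samples$sample_id[samples[[group_col]] == group_a]
  ids_b <- samples$sample_id[samples[[group_col]] == group_b]
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    abort("both groups must contain at least one sample")
  }
  norm <- normalize_counts(m)
  ma <- rowMeans(norm[, ids_a, drop = FALSE])
  mb <- rowMeans(norm[, ids_b, drop = FALSE])
  tibble(feature_id = rownames(m), base_mean = unname(rowMeans(norm)),
         mean_a = unname(ma), mean_b = unname(mb),
         log2fc = unname(log2((ma + pseudocount) / (mb + pseudocount))))
}

#' Expressed-feature filter on raw mean counts
#'
#' @inheritParams size_factors
#' @param min_mean_count Keep features whose mean raw count across the
#'   samples of the comparison exceeds this (strict `>`; default 100).
#' @return Logical vector along features.
#' @export
embryo_expressed_filter <- function(counts, min_mean_count = 100) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  rowMeans(m) > min_mean_count
}

#' Test per-region shifts of a log2 fold-change distribution
#'
#' Default mode tests, per region, the gene log2FC values against zero with
#' a one-sided signed-rank test (continuity corrected). Because a
#' signed-rank test between two independent gene groups is ill-defined, the
#' alternative `between_regions` mode compares two regions' log2FC vectors
#' with a rank-sum test instead.
#'
#' @param log2fc Numeric vector of per-gene log2 fold changes.
#' @param regions Character vector of region labels along `log2fc`.
#' @param mode `"one_sample_vs_zero"` (default) or `"between_regions"`.
#' @param alternative Test direction (default `"less"`: values shifted below
#'   zero).
#' @param adjust_m Bonferroni family size; defaults to the number of tests
#'   performed.
#' @return Tibble with one row per region (or region pair): `region`, `n`,
#'   `median_log2fc`, `statistic`, `p_value`, `p_adj`.
#' @export
region_shift_test <- function(log2fc, regions,
                              mode = c("one_sample_vs_zero",
                                       "between_regions"),
                              alternative = "less", adjust_m = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(log2fc) == length(regions))
  levels <- unique(regions)
  if (mode == "one_sample_vs_zero") {
    out <- purrr::map(levels, function(rg) {
      v <- log2fc[regions == rg]
      if (length(v) == 0) abort(sprintf("region %s is empty", rg))
      ht <- signed_rank_test(v, alternative = alternative)
      tibble(region = rg, n = length(v), median_log2fc = median(v),
             statistic = ht$statistic, p_value = ht$p_value)
    })
  } else {
    pairs <- utils::combn(levels, 2, simplify = FALSE)
    out <- purrr::map(pairs, function(pr) {
      a <- log2fc[regions == pr[1]]; b <- log2fc[regions == pr[2]]
      ht <- rank_sum_test(a, b, alternative = alternative)
      tibble(region = paste(pr, collapse = " vs "),
             n = length(a) + length(b),
             median_log2fc = median(a) - median(b),
             statistic = ht$statistic, p_value = ht$p_value)
    })
  }
  out <- bind_rows(out)
  m <- adjust_m %||% nrow(out)
  mutate(out, p_adj = adjust_pvalues(.data$p_value, "bonferroni", m = m))
}

#' Dosage-compensation onset test for one embryo stage
#'
#' End-to-end wrapper: filters expressed genes (mean raw count >
#' `min_mean_count`), computes female/male log2 fold changes on
#' median-of-ratios-normalized counts, and tests each region's log2FC
#' distribution against zero with a one-sided signed-rank test
#' (Bonferroni-adjusted over the regions tested).
#'
#' @param counts,samples As produced by [simulate_embryo_counts()] (or read
#'   from TSV).
#' @param gene_regions Tibble `gene_id`, `region`.
#' @param min_mean_count Expressed-gene filter (default 100).
#' @param alternative Direction for the signed-rank test (default `"less"`:
#'   female expression below male).
#' @param alpha Significance level applied to the adjusted p-value for the
#'   `significant` flag (default 0.05).
#' @return Tibble: `region`, `n`, `median_log2fc`, `statistic`, `p_value`,
#'   `p_adj`, `significant`.
#' @export
dc_onset <- function(counts, samples, gene_regions, min_mean_count = 100,
                     alternative = "less", alpha = 0.05) {
  m <- counts_to_matrix(counts)
  keep <- embryo_expressed_filter(m, min_mean_count)
  m <- m[keep, , drop = FALSE]
  fc <- group_log2fc(m, samples, "F", "M")
  fc <- left_join(fc, as_tibble(gene_regions),
                  by = c(feature_id = "gene_id"))
  res <- region_shift_test(fc$log2fc, fc$region, "one_sample_vs_zero",
                           alternative)
  mutate(res, significant = .data$p_adj < alpha)
}

#' Bin-wise differential expression scan
#'
#' Scans fixed-width genomic bins (typically 50 bp of RNA coverage) for
#' sex-biased signal outside the gene annotation. Bins whose mean
#' normalized count falls below `min_mean` are excluded before testing (an
#' independent-filtering analogue), remaining bins are tested with a
#' two-sided rank-sum test on normalized counts, and Benjamini-Hochberg
#' adjustment is applied over the tested bins.
#'
#' @param counts Bin count tibble (`bin_id` + sample columns) or matrix.
#' @param samples Sample sheet with `sample_id` and `sex`.
#' @param bins Optional tibble `bin_id`, `chrom`, `start`, `end` for the
#'   Manhattan output.
#' @param min_mean Independent-filtering threshold on the mean normalized
#'   count (default 5).
#' @return Tibble sorted by decreasing `neg_log10_padj`: `bin_id` (+ bin
#'   coordinates when given), `base_mean`, `log2fc`, `statistic`, `p_value`,
#'   `p_adj`, `neg_log10_padj`.
#' @export
bin_de_scan <- function(counts, samples, bins = NULL, min_mean = 5) {
  m <- if (is.matrix(counts)) counts else counts_to_matrix(counts)
  samples <- as_tibble(samples)
  f_ids <- samples$sample_id[samples$sex == "F"]
  m_ids <- samples$sample_id[samples$sex == "M"]
  if (length(f_ids) < 2 || length(m_ids) < 2) {
    abort("need at least 2 samples per sex")
  }
  norm <- normalize_counts(m)
  keep <- rowMeans(norm) >= min_mean
  if (!any(keep)) {
    return(tibble(bin_id = character(), base_mean = numeric(),
                  log2fc = numeric(), statistic = numeric(),
                  p_value = numeric(), p_adj = numeric(),
                  neg_log10_padj = numeric()))
  }
  nk <- norm[keep, , drop = FALSE]
  tests <- apply(nk, 1, function(v) {
    ht <- rank_sum_test(v[f_ids], v[m_ids], "two_sided")
    c(ht$statistic, ht$p_value)
  })
  out <- tibble(
    bin_id = rownames(nk),
    base_mean = rowMeans(nk),
    log2fc = log2((rowMeans(nk[, f_ids, drop = FALSE]) + 1) /
                    (rowMeans(nk[, m_ids, drop = FALSE]) + 1)),
    statistic = tests[1, ],
    p_value = tests[2, ],
    p_adj = adjust_pvalues(tests[2, ], "bh")
  )
  out <- mutate(out, neg_log10_padj = -log10(.data$p_adj))
  if (!is.null(bins)) out <- left_join(out, as_tibble(bins), by = "bin_id")
  arrange(out, dplyr::desc(.data$neg_log10_padj))
}

#' Compare per-gene signal variability between age groups
#'
#' Computes, per gene, the coefficient of variation (sd/mean, n-1
#' denominator) of the signal across individuals within each age group, and
#' compares the young and old CV distributions per region with a two-sided
#' rank-sum test, Bonferroni-adjusted for `m_comparisons` (default 6: two
#' sexes times three regions, the full comparison family even when a single
#' sex is analyzed in one call).
#'
#' @param signal Signal tibble (`gene_id` + one column per individual) or
#'   matrix.
#' @param samples Sample sheet with `sample_id` and `age_group`
#'   (`young`/`old`).
#' @param gene_regions Tibble `gene_id`, `region`.
#' @param m_comparisons Bonferroni family size (default 6).
#' @return List with `tests` (tibble `region`, `n_genes`, `median_cv_young`,
#'   `median_cv_old`, `statistic`, `p_value`, `p_adj`) and `cv` (per-gene
#'   tibble).
#' @export
cv_compare <- function(signal, samples, gene_regions, m_comparisons = 6) {
  m <- if (is.matrix(signal)) signal else counts_to_matrix(signal)
  samples <- as_tibble(samples)
  young <- samples$sample_id[samples$age_group == "young"]
  old <- samples$sample_id[samples$age_group == "old"]
  if (length(young) < 2 || length(old) < 2) {
    abort("need at least 2 individuals per age group")
  }
  row_cv <- function(mm) {
    mu <- rowMeans(mm)
    s <- apply(mm, 1, sd)
    if_else(mu != 0, s / mu, NA_real_)
  }
  cv <- tibble(gene_id = rownames(m),
               cv_young = row_cv(m[, young, drop = FALSE]),
               cv_old = row_cv(m[, old, drop = FALSE]))
  cv <- left_join(cv, as_tibble(gene_regions), by = "gene_id")
  tests <- purrr::map(unique(cv$region), function(rg) {
    d <- cv[cv$region == rg & complete.cases(cv[, c("cv_young", "cv_old")]), ]
    ht <- rank_sum_test(d$cv_young, d$cv_old, "two_sided")
    tibble(region = rg, n_genes = nrow(d),
           median_cv_young = median(d$cv_young),
           median_cv_old = median(d$cv_old),
           statistic = ht$statistic, p_value = ht$p_value)
  })
  tests <- bind_rows(tests)
  tests <- mutate(tests, p_adj = adjust_pvalues(.data$p_value, "bonferroni",
                                                m = m_comparisons))
  list(tests = tests, cv = cv)
}

#' Age-decline correlation of mean expression
#'
#' For a gene-by-time-point table of mean expression, drops genes with zero
#' mean in more than half of the time points, computes each remaining
#' gene's Pearson correlation of mean expression with age (negative values
#' indicate declining output), and compares the correlation distributions
#' between chromosome classes (e.g. X-linked versus autosomal genes) with a
#' two-sided rank-sum test without continuity correction, Bonferroni
#' adjusted.
#'
#' @param mean_expr Tibble (`gene_id` + one column per time point) or
#'   matrix of per-time-point mean expression.
#' @param ages Numeric vector of ages, one per time-point column.
#' @param gene_class Tibble `gene_id`, `class` (two or more classes).
#' @param adjust_m Bonferroni family size (default: number of pairwise class
#'   comparisons).
#' @return List with `per_gene` (tibble `gene_id`, `class`, `r`) and
#'   `comparisons` (tibble `classes`, `statistic`, `p_value`, `p_adj`).
#' @export
age_decline_correlation <- function(mean_expr, ages, gene_class,
                                    adjust_m = NULL) {
  m <- if (is.matrix(mean_expr)) mean_expr else counts_to_matrix(mean_expr)
  if (ncol(m) != length(ages)) {
    abort("`ages` must have one entry per time-point column")
  }
  if (ncol(m) < 3) abort("need at least 3 time points")
  keep <- rowSums(m == 0) <= ncol(m) / 2
  m <- m[keep, , drop = FALSE]
  r <- apply(m, 1, function(v) {
    suppressWarnings(pearson_r(v, ages))
  })
  per_gene <- left_join(tibble(gene_id = rownames(m), r = r),
                        as_tibble(gene_class), by = "gene_id")
  per_gene <- per_gene[!is.na(per_gene$r) & !is.na(per_gene$class), ]
  classes <- unique(per_gene$class)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  comparisons <- purrr::map(pairs, function(pr) {
    a <- per_gene$r[per_gene$class == pr[1]]
    b <- per_gene$r[per_gene$class == pr[2]]
    ht <- rank_sum_test(a, b, "two_sided", continuity = FALSE)
    tibble(classes = paste(pr, collapse = " vs "),
           statistic = ht$statistic, p_value = ht$p_value)
  })
  comparisons <- bind_rows(comparisons)
  m_adj <- adjust_m %||% nrow(comparisons)
  comparisons <- mutate(
    comparisons,
    p_adj = adjust_pvalues(.data$p_value, "bonferroni", m = m_adj))
  list(per_gene = per_gene[, c("gene_id", "class", "r")],
       comparisons = comparisons)
}
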