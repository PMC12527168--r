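# Sex inference from expressed-SNP allelic balance. ZW females are
# functionally hemizygous on the differentiated Z stratum, so their expressed
# Z(diff) SNPs are monoallelic (allelic balance 0) while PAR SNPs, where Z
# and W still recombine, stay biallelic; ZZ males look alike in both regions.

#' Filter expressed-SNP records
#'
#' Keeps records that fall inside an exon (optional), pass the mapping
#' quality filters on both alleles (`MQM > mq_min` and `MQMR > mq_min`,
#' strict; missing quality fails), and pass the read-depth filter. The
#' default depth rule is total depth `AO + RO > depth_min`; the published
#' per-allele rule (`AO > 10` and `RO > 10`) would discard every monoallelic
#' site and with it the method's signal, so it is available as
#' `depth_mode = "both"` for auditing, along with `"either"`.
#'
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `AO`, `RO`,
#'   `MQM`, `MQMR`.
#' @param exons Tibble of exon intervals (`chrom`, `start`, `end`, 1-based
#'   inclusive); required when `require_exonic = TRUE`.
#' @param mq_min Mapping-quality threshold (default 20, strict `>`).
#' @param depth_min Depth threshold (default 10, strict `>`).
#' @param depth_mode `"total"` (default), `"both"` or `"either"`.
#' @param require_exonic Keep only exon-overlapping records (default `TRUE`).
#' @return The surviving rows of `variants`, order preserved.
#' @export
filter_variants <- function(variants, exons = NULL, mq_min = 20,
                            depth_min = 10,
                            depth_mode = c("total", "both", "either"),
                            require_exonic = TRUE) {
  depth_mode <- match.arg(depth_mode)
  variants <- as_tibble(variants)
  need <- c("chrom", "pos", "AO", "RO")
  if (!all(need %in% names(variants))) {
    abort("`variants` needs columns chrom, pos, AO, RO (and MQM, MQMR)")
  }
  bad <- which(variants$AO < 0 | variants$RO < 0)
  if (length(bad)) {
    abort(sprintf("negative allele counts in record(s) %s (e.g. %s:%d)",
                  paste(head(bad, 3), collapse = ", "),
                  variants$chrom[bad[1]], variants$pos[bad[1]]))
  }
  mqm <- variants$MQM %||% rep(NA_real_, nrow(variants))
  mqmr <- variants$MQMR %||% rep(NA_real_, nrow(variants))
  keep <- !is.na(mqm) & !is.na(mqmr) & mqm > mq_min & mqmr > mq_min
  keep <- keep & switch(depth_mode,
    total = (variants$AO + variants$RO) > depth_min,
    both = variants$AO > depth_min & variants$RO > depth_min,
    either = variants$AO > depth_min | variants$RO > depth_min
  )
  if (require_exonic) {
    if (is.null(exons)) abort("`exons` required when require_exonic = TRUE")
    keep <- keep & positions_in_intervals(variants$chrom, variants$pos, exons)
  }
  variants[keep, ]
}

# membership of 1-based positions in 1-based inclusive intervals
positions_in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  for (chr in unique(chrom)) {
    iv <- intervals[intervals$chrom == chr, ]
    i <- which(chrom == chr)
    if (nrow(iv) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(pos[i], pos[i]),
      IRanges::IRanges(iv$start, iv$end)
    )
    out[i[unique(S4Vectors::queryHits(hit))]] <- TRUE
  }
  out
}

#' Allelic balance of a variant record
#'
#' Minor-observation fraction `min(AO, RO) / (AO + RO)`, recomputed from the
#' allele-observation counts so that `AB == 0` means exactly "monoallelic
#' observation" regardless of the genotype call. `NA` when `AO + RO == 0`.
#'
#' @param AO,RO Non-negative integer vectors of alternate / reference
#'   observation counts.
#' @return Numeric vector in `[0, 0.5]` (or `NA`).
#' @export
allelic_balance <- function(AO, RO) {
  total <- AO + RO
  if_else(total > 0, pmin(AO, RO) / total, NA_real_)
}

#' Summarize allelism in PAR versus differentiated Z
#'
#' Assigns each (already filtered) record to PAR or Z(diff) via
#' [classify_position()] (autosomal records are dropped), computes allelic
#' balance, removes `NA` records, and counts monoallelic (`AB == 0`) versus
#' biallelic (`AB > 0`) SNPs per region.
#'
#' @param variants Filtered variant tibble (see [filter_variants()]).
#' @param layout A [zw_layout()].
#' @return Tibble of class `zw_absummary` with one row per region (`PAR`,
#'   `ZDIFF`): `n_snps`, `n_mono`, `n_bi`, `frac_mono`, and a list column
#'   `ab` holding the allelic-balance values.
#' @export
summarize_allelism <- function(variants, layout) {
  variants <- as_tibble(variants)
  region <- classify_position(variants$chrom, variants$pos, layout)
  ab <- allelic_balance(variants$AO, variants$RO)
  keep <- region != "AUTOSOME" & !is.na(ab)
  d <- tibble(region = region[keep], ab = ab[keep])
  out <- purrr::map(c("PAR", "ZDIFF"), function(rg) {
    v <- d$ab[d$region == rg]
    tibble(region = rg, n_snps = length(v), n_mono = sum(v == 0),
           n_bi = sum(v > 0),
           frac_mono = if (length(v)) mean(v == 0) else NA_real_,
           ab = list(v))
  })
  out <- bind_rows(out)
  class(out) <- c("zw_absummary", class(out))
  out
}

#' Call the sex of an individual from its allelism summary
#'
#' A female (ZW) call requires the monoallelic fraction on the
#' differentiated Z to exceed the PAR fraction by at least `delta_min` AND a
#' one-sided rank-sum test of `AB(ZDIFF) < AB(PAR)` significant at `alpha`;
#' otherwise the call is male (ZZ). If either region has fewer than
#' `min_snps` usable records the call is `UNCERTAIN`.
#'
#' @param absummary A [summarize_allelism()] result.
#' @param delta_min Minimum monoallelic-fraction excess (default 0.3).
#' @param alpha Significance level for the rank-sum test (default 0.05).
#' @param min_snps Minimum usable SNPs per region (default 20).
#' @return One-row tibble: `label` (`F`/`M`/`UNCERTAIN`), `delta_mono`,
#'   `p_value`, `n_par`, `n_zdiff`.
#' @export
call_sex <- function(absummary, delta_min = 0.3, alpha = 0.05,
                     min_snps = 20) {
  stopifnot(inherits(absummary, "zw_absummary"))
  par <- absummary[absummary$region == "PAR", ]
  zd <- absummary[absummary$region == "ZDIFF", ]
  n_par <- par$n_snps; n_zd <- zd$n_snps
  if (n_par < min_snps || n_zd < min_snps) {
    return(tibble(label = "UNCERTAIN", delta_mono = NA_real_,
                  p_value = NA_real_, n_par = n_par, n_zdiff = n_zd))
  }
  delta <- zd$frac_mono - par$frac_mono
  p <- rank_sum_test(zd$ab[[1]], par$ab[[1]], alternative = "less")$p_value
  label <- if (delta >= delta_min && p < alpha) "F" else "M"
  tibble(label = label, delta_mono = delta, p_value = p,
         n_par = n_par, n_zdiff = n_zd)
}

#' Infer sex from raw variant records in one call
#'
#' Convenience wrapper: [filter_variants()], [summarize_allelism()],
#' [call_sex()].
#'
#' @inheritParams filter_variants
#' @inheritParams call_sex
#' @param layout A [zw_layout()].
#' @return One-row tibble as for [call_sex()].
#' @export
infer_sex <- function(variants, exons, layout, mq_min = 20, depth_min = 10,
                      depth_mode = "total", delta_min = 0.3, alpha = 0.05,
                      min_snps = 20) {
  filtered <- filter_variants(variants, exons, mq_min, depth_min, depth_mode)
  call_sex(summarize_allelism(filtered, layout), delta_min, alpha, min_snps)
}
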