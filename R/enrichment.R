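# Coverage analytics for CUT&Tag-like binned tracks: CPM normalization,
# female/male log2 fold-change tracks, per-stratum medians, Z-chromosome
# window summaries, gene-level signal extraction and scaled metaprofiles.

check_same_bins <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(a$chrom, b$chrom) ||
      !identical(as.numeric(a$start), as.numeric(b$start)) ||
      !identical(as.numeric(a$end), as.numeric(b$end))) {
    abort("tracks are not on the same bin set")
  }
}

track_value_col <- function(track) {
  for (cand in c("value", "cpm", "count")) {
    if (cand %in% names(track)) return(cand)
  }
  abort("track needs a `value`, `cpm` or `count` column")
}

#' CPM-normalize a coverage track
#'
#' @param track Tibble `chrom`, `start`, `end` plus a `count` (or `value`)
#'   column.
#' @return The track with a `value` column of counts per million (sums to
#'   1e6).
#' @export
cpm_track <- function(track) {
  col <- track_value_col(track)
  out <- track[, c("chrom", "start", "end")]
  out$value <- cpm_normalize(track[[col]])
  out
}

#' Average several tracks bin-wise
#'
#' @param tracks List of tracks on the same bin set, each with a `value`
#'   column.
#' @return One track whose `value` is the bin-wise mean.
#' @export
average_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  ref <- tracks[[1]]
  vals <- purrr::map(tracks, function(t) {
    check_same_bins(ref, t)
    t[[track_value_col(t)]]
  })
  out <- ref[, c("chrom", "start", "end")]
  out$value <- Reduce(`+`, vals) / length(vals)
  out
}

#' Per-bin log2 fold change between female and male coverage
#'
#' `log2((F + pc) / (M + pc))` on CPM-normalized tracks sharing one bin set.
#' The pseudocount guards the logarithm at empty bins.
#'
#' @param female,male CPM tracks (tibbles `chrom`, `start`, `end`, `value`).
#' @param pseudocount Positive pseudocount in CPM units (default 1).
#' @return Tibble `chrom`, `start`, `end`, `log2fc`.
#' @export
bin_log2fc <- function(female, male, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be > 0")
  check_same_bins(female, male)
  f <- female[[track_value_col(female)]]
  m <- male[[track_value_col(male)]]
  tibble(chrom = female$chrom, start = female$start, end = female$end,
         log2fc = log2((f + pseudocount) / (m + pseudocount)))
}

#' Median log2 fold change per stratum and region
#'
#' Each bin is assigned by its midpoint to `S0`/`S1`/`S2`, `ZDIFF_OUTSIDE`
#' (differentiated-Z bins outside the stratum intervals), `PAR` or
#' `AUTOSOME`, and the median per group is reported.
#'
#' @param log2fc A [bin_log2fc()] result.
#' @param strata A [zw_strata()] map.
#' @param layout A [zw_layout()].
#' @return Tibble `group`, `n_bins`, `median_log2fc` (groups with no bins
#'   get `NA`).
#' @export
stratum_median_log2fc <- function(log2fc, strata, layout) {
  annotated <- annotate_bins(log2fc, layout, strata)
  groups <- c("S0", "S1", "S2", "ZDIFF_OUTSIDE", "PAR", "AUTOSOME")
  out <- purrr::map(groups, function(g) {
    v <- annotated$log2fc[annotated$group == g]
    tibble(group = g, n_bins = length(v),
           median_log2fc = if (length(v)) median(v) else NA_real_)
  })
  bind_rows(out)
}

#' Quartile summary of Z-chromosome coverage in equal windows
#'
#' Splits the Z into `n_windows` equally sized windows and summarizes the
#' distribution of bin values (assigned by bin midpoint) per window — the
#' tabular backbone of a windowed box plot along the chromosome.
#'
#' @param track A coverage track (typically CPM on 10-kb bins).
#' @param layout A [zw_layout()].
#' @param n_windows Number of windows (default 14).
#' @return Tibble `window`, `start`, `end`, `n_bins`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
window_summary <- function(track, layout, n_windows = 14) {
  if (n_windows < 1) abort("`n_windows` must be >= 1")
  col <- track_value_col(track)
  z <- track[track$chrom == layout$z_name, ]
  if (nrow(z) == 0) abort("track has no bins on the Z chromosome")
  win <- make_equal_windows(chrom_length(layout, layout$z_name), n_windows)
  mid0 <- (z$start + z$end - 1) / 2  # 0-based midpoint
  idx <- findInterval(mid0, win$start)
  stats <- group_by(tibble(window = idx, v = z[[col]]), .data$window) |>
    summarise(n_bins = n(),
              min = min(.data$v), q1 = quantile(.data$v, 0.25, names = FALSE),
              median = median(.data$v),
              q3 = quantile(.data$v, 0.75, names = FALSE),
              max = max(.data$v), .groups = "drop")
  out <- left_join(win, stats, by = "window")
  out$n_bins[is.na(out$n_bins)] <- 0L
  out
}

# per-interval weighted mean of track values (0-based half-open spans)
interval_mean_signal <- function(track, chrom, span_start0, span_end0) {
  col <- track_value_col(track)
  out <- rep(NA_real_, length(chrom))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    tb <- track[track$chrom == chr, ]
    if (nrow(tb) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(span_start0[i] + 1, span_end0[i]),
      IRanges::IRanges(tb$start + 1, tb$end)
    )
    q <- S4Vectors::queryHits(hit); s <- S4Vectors::subjectHits(hit)
    ow <- pmin(span_end0[i][q], tb$end[s]) -
      pmax(span_start0[i][q], tb$start[s])
    num <- rowsum(ow * tb[[col]][s], q)
    den <- rowsum(ow, q)
    out[i[as.integer(rownames(num))]] <- num / den
  }
  out
}

#' Mean coverage signal per gene
#'
#' Mean CPM over the gene body plus `upstream_bp` of 5' flank
#' (strand-aware: upstream of the TSS), clipped at chromosome edges.
#'
#' @param track Coverage track at base- or fine-bin resolution, CPM values.
#' @param genes Tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param layout A [zw_layout()].
#' @param upstream_bp 5' extension in bp (default 1000).
#' @return `genes` with an extra `signal` column.
#' @export
gene_signal <- function(track, genes, layout, upstream_bp = 1000) {
  genes <- as_tibble(genes)
  if (!all(genes$chrom %in% layout$chromosomes$name)) {
    bad <- setdiff(unique(genes$chrom), layout$chromosomes$name)
    abort(sprintf("gene(s) on unknown chromosome: %s",
                  paste(bad, collapse = ", ")))
  }
  len <- chrom_length(layout, genes$chrom)
  s0 <- if_else(genes$strand == "+",
                pmax(0, genes$start - 1 - upstream_bp), genes$start - 1)
  e0 <- if_else(genes$strand == "+",
                as.numeric(genes$end), pmin(len, genes$end + upstream_bp))
  mutate(genes, signal = interval_mean_signal(track, genes$chrom, s0, e0))
}

#' Scaled metaprofile across gene groups
#'
#' Gene bodies are linearly rescaled onto a `body_bp / resolution_bp` grid
#' between TSS and TES while `flank_bp` of unscaled flank is kept on both
#' sides; minus-strand genes are reversed so the 5' flank always comes
#' first. The per-group profile value at each grid point is the median over
#' genes. Genes shorter than `resolution_bp` are skipped with a warning.
#'
#' @param track Fine-resolution CPM track.
#' @param genes Tibble `gene_id`, `chrom`, `start`, `end`, `strand`, plus a
#'   `group` column naming the gene group.
#' @param layout A [zw_layout()].
#' @param body_bp Scaled gene-body length (default 5000).
#' @param flank_bp Unscaled flank on each side (default 1000).
#' @param resolution_bp Grid resolution (default 50).
#' @return Tibble of class `zw_metaprofile`: `group`, `position` (bp
#'   relative to the scaled TSS, from `-flank_bp` to `body_bp + flank_bp`),
#'   `median_signal`, `n_genes`.
#' @export
metaprofile <- function(track, genes, layout, body_bp = 5000,
                        flank_bp = 1000, resolution_bp = 50) {
  genes <- as_tibble(genes)
  if (!"group" %in% names(genes)) abort("`genes` needs a `group` column")
  short <- (genes$end - genes$start + 1) < resolution_bp
  if (any(short)) {
    warn(sprintf("skipping %d gene(s) shorter than the grid resolution",
                 sum(short)))
    genes <- genes[!short, ]
  }
  n_flank <- flank_bp / resolution_bp
  n_body <- body_bp / resolution_bp
  stopifnot(n_flank == round(n_flank), n_body == round(n_body))
  len <- chrom_length(layout, genes$chrom)
  cells <- purrr::pmap(
    list(genes$chrom, genes$start, genes$end, genes$strand, len,
         genes$group, seq_len(nrow(genes))),
    function(chrom, start, end, strand, clen, group, gi) {
      gl <- end - start + 1
      # 0-based half-open cell bounds in genomic coordinates, 5' -> 3'
      up <- seq(0, n_flank) * resolution_bp
      body <- seq(0, n_body) / n_body * gl
      down <- seq(0, n_flank) * resolution_bp
      if (strand == "+") {
        b <- c((start - 1 - flank_bp) + up,
               (start - 1) + body[-1],
               end + down[-1])
      } else {
        b <- rev(c((end + flank_bp) - up,
                   end - body[-1],
                   (start - 1) - down[-1]))
      }
      starts <- pmax(0, pmin(clen, b[-length(b)]))
      ends <- pmax(0, pmin(clen, b[-1]))
      pos_index <- seq_len(n_flank + n_body + n_flank)
      if (strand == "-") pos_index <- rev(pos_index)
      tibble(gene = gi, group = group, cell = pos_index,
             chrom = chrom, s0 = starts, e0 = ends)
    }
  )
  cells <- bind_rows(cells)
  cells <- cells[cells$e0 > cells$s0, ]
  cells$signal <- interval_mean_signal(track, cells$chrom, cells$s0,
                                       cells$e0)
  prof <- group_by(cells, .data$group, .data$cell) |>
    summarise(median_signal = median(.data$signal, na.rm = TRUE),
              n_genes = n(), .groups = "drop")
  prof <- mutate(prof,
                 position = (.data$cell - n_flank - 1) * resolution_bp +
                   resolution_bp / 2,
                 .after = "group")
  prof <- select(prof, -"cell")
  class(prof) <- c("zw_metaprofile", class(prof))
  prof
}

#' Classify genes as expressed from sex-specific TPM
#'
#' A gene is expressed when its TPM reaches the cutoff in either sex.
#'
#' @param tpm_female,tpm_male Non-negative TPM vectors aligned to genes.
#' @param cutoff TPM cutoff (default 10).
#' @return Logical vector.
#' @export
classify_expressed <- function(tpm_female, tpm_male, cutoff = 10) {
  if (any(tpm_female < 0, na.rm = TRUE) || any(tpm_male < 0, na.rm = TRUE)) {
    abort("TPM values must be non-negative")
  }
  tpm_female >= cutoff | tpm_male >= cutoff
}

#' Transcripts per million from counts and gene lengths
#'
#' `rate_i = count_i / length_kb_i; TPM_i = rate_i * 1e6 / sum(rate)`.
#'
#' @param counts Non-negative counts.
#' @param length_bp Gene lengths in bp.
#' @return TPM vector summing to 1e6.
#' @export
tpm_from_counts <- function(counts, length_bp) {
  if (any(length_bp <= 0)) abort("gene lengths must be positive")
  rate <- counts / (length_bp / 1000)
  total <- sum(rate)
  if (total <= 0) abort("cannot compute TPM from all-zero counts")
  rate * 1e6 / total
}
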