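# File interchange. Established readers are used for the standard formats
# (vcfR for VCF, rtracklayer for BED/bedGraph); the minimal-dialect VCF
# writer emits the small record subset the sex-inference stage consumes.
# VCF/GFF coordinates are 1-based inclusive; BED/bedGraph are 0-based
# half-open — conversion happens here, nowhere else.

#' Read a minimal-dialect VCF of expressed SNPs
#'
#' Expects INFO keys `AO`, `RO`, `MQM`, `MQMR` (as written by a
#' FreeBayes-style caller). Multi-allelic records (comma in ALT) are skipped
#' with a warning.
#'
#' @param path VCF file path (plain text or gzipped).
#' @return Tibble `chrom`, `pos`, `ref`, `alt`, `AO`, `RO`, `MQM`, `MQMR`.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  info <- function(key) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = key)))
  }
  out <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT,
                AO = as.integer(info("AO")), RO = as.integer(info("RO")),
                MQM = info("MQM"), MQMR = info("MQMR"))
  out[!multi, ]
}

#' Write variant records as a minimal VCF v4.2
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`, `AO`, `RO`,
#'   `MQM`, `MQMR`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate allele observation count\">",
    "##INFO=<ID=RO,Number=1,Type=Integer,Description=\"Reference allele observation count\">",
    "##INFO=<ID=MQM,Number=1,Type=Float,Description=\"Mean mapping quality of alternate observations\">",
    "##INFO=<ID=MQMR,Number=1,Type=Float,Description=\"Mean mapping quality of reference observations\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- sprintf("AO=%d;RO=%d;MQM=%.2f;MQMR=%.2f",
                  variants$AO, variants$RO, variants$MQM, variants$MQMR)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read intervals from a BED file (exons, strata)
#'
#' @param path BED path (0-based half-open on disk).
#' @return Tibble `chrom`, `start`, `end` (1-based inclusive) plus `name`
#'   when present.
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr))
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble `chrom`, `start`, `end` (1-based inclusive),
#'   optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start, intervals$end)
  )
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write the stratum map as BED
#'
#' @param strata A [zw_strata()] map.
#' @param layout A [zw_layout()] (for the Z chromosome name).
#' @param path Output path.
#' @export
write_strata_bed <- function(strata, layout, path) {
  write_intervals_bed(
    tibble(chrom = layout$z_name, start = strata$start_bp,
           end = strata$end_bp, name = strata$label),
    path
  )
}

#' Read a coverage track from bedGraph
#'
#' @param path bedGraph path.
#' @return Tibble `chrom`, `start`, `end` (0-based half-open), `value`.
#' @export
read_track_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         value = gr$score)
}

#' Write a coverage track as bedGraph
#'
#' @param track Tibble `chrom`, `start`, `end` (0-based half-open) and a
#'   value column (`value`, `cpm` or `count`).
#' @param path Output path.
#' @export
write_track_bedgraph <- function(track, path) {
  col <- track_value_col(track)
  gr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1, track$end),
    score = track[[col]]
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read / write a genome layout as YAML
#'
#' The YAML carries `chromosomes` (name -> length), `z_name` and
#' `par_boundary_bp`.
#'
#' @param path YAML path.
#' @return [read_layout_yaml()] returns a [zw_layout()].
#' @export
read_layout_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  zw_layout(
    tibble(name = names(y$chromosomes),
           length_bp = as.numeric(unlist(y$chromosomes))),
    z_name = y$z_name, par_boundary_bp = y$par_boundary_bp
  )
}

#' @rdname read_layout_yaml
#' @param layout A [zw_layout()].
#' @export
write_layout_yaml <- function(layout, path) {
  yaml::write_yaml(
    list(chromosomes = as.list(setNames(layout$chromosomes$length_bp,
                                        layout$chromosomes$name)),
         z_name = layout$z_name,
         par_boundary_bp = layout$par_boundary_bp),
    path
  )
  invisible(path)
}

#' Read / write tab-separated tables (count matrices, survival tables)
#'
#' Thin readr wrappers fixing the delimiter and column-type guessing.
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_table_tsv
#' @param x Data frame to write.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
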