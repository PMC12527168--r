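# Coordinate conventions used throughout the package:
#  * user-facing positions (VCF-style) are 1-based inclusive;
#  * bins and windows (BED-style) are 0-based half-open.

#' Describe the chromosomes of a ZW genome
#'
#' A genome layout records the chromosome names and lengths, which chromosome
#' is the Z, and the 1-based position of the pseudoautosomal boundary: Z
#' positions at or below the boundary belong to the PAR (where Z and W still
#' recombine), positions above it to the differentiated stratum Z(diff).
#'
#' @param chromosomes Data frame with columns `name` and `length_bp`.
#' @param z_name Name of the Z chromosome; must occur exactly once in
#'   `chromosomes`.
#' @param par_boundary_bp 1-based position of the PAR/Z(diff) boundary on the
#'   Z. Positions `<= par_boundary_bp` are PAR. Default 46,043,529.
#'
#' @return An object of class `zw_layout`.
#' @export
#' @examples
#' zw_layout(
#'   tibble::tibble(name = c("chr1", "chrZ"), length_bp = c(2e7, 6e7)),
#'   z_name = "chrZ", par_boundary_bp = 4.6e7
#' )
zw_layout <- function(chromosomes, z_name, par_boundary_bp = 46043529) {
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("name", "length_bp") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns `name` and `length_bp`")
  }
  chromosomes$length_bp <- as.numeric(chromosomes$length_bp)
  if (anyDuplicated(chromosomes$name)) {
    abort("duplicated chromosome names in layout")
  }
  if (any(chromosomes$length_bp <= 0)) abort("chromosome lengths must be > 0")
  if (sum(chromosomes$name == z_name) != 1L) {
    abort(sprintf("Z chromosome '%s' must appear exactly once", z_name))
  }
  z_len <- chromosomes$length_bp[chromosomes$name == z_name]
  par_boundary_bp <- as.numeric(par_boundary_bp)
  if (par_boundary_bp <= 0 || par_boundary_bp >= z_len) {
    abort("`par_boundary_bp` must lie strictly inside the Z chromosome")
  }
  structure(
    list(chromosomes = chromosomes[, c("name", "length_bp")],
         z_name = z_name,
         par_boundary_bp = par_boundary_bp),
    class = "zw_layout"
  )
}

#' @export
print.zw_layout <- function(x, ...) {
  cat(sprintf(
    "<zw_layout> %d chromosomes, Z = %s (%.0f bp), PAR boundary at %.0f\n",
    nrow(x$chromosomes), x$z_name,
    x$chromosomes$length_bp[x$chromosomes$name == x$z_name],
    x$par_boundary_bp
  ))
  invisible(x)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chromosomes$name)
  layout$chromosomes$length_bp[i]
}

#' Evolutionary strata of the differentiated Z
#'
#' A stratum map is a set of non-overlapping, sorted 1-based inclusive
#' intervals on the Z chromosome, each labelled S0 (oldest, most
#' differentiated), S1 or S2. Z positions outside all intervals are labelled
#' `"OUTSIDE"` by [stratum_label()].
#'
#' @param intervals Data frame with columns `start_bp`, `end_bp`, `label`
#'   (each label one of `"S0"`, `"S1"`, `"S2"`).
#' @param layout Optional [zw_layout()]; if supplied, intervals are checked to
#'   lie within the Z chromosome.
#'
#' @return A tibble of class `zw_strata`, sorted by `start_bp`.
#' @export
zw_strata <- function(intervals, layout = NULL) {
  intervals <- as_tibble(intervals)
  req <- c("start_bp", "end_bp", "label")
  if (!all(req %in% names(intervals))) {
    abort("`intervals` needs columns start_bp, end_bp, label")
  }
  intervals <- arrange(intervals[, req], .data$start_bp)
  if (!all(intervals$label %in% c("S0", "S1", "S2"))) {
    abort("stratum labels must be S0, S1 or S2")
  }
  if (any(intervals$start_bp > intervals$end_bp) || any(intervals$start_bp < 1)) {
    abort("stratum intervals must satisfy 1 <= start_bp <= end_bp")
  }
  if (nrow(intervals) > 1 &&
      any(intervals$start_bp[-1] <= intervals$end_bp[-nrow(intervals)])) {
    abort("stratum intervals must not overlap")
  }
  if (!is.null(layout) &&
      any(intervals$end_bp > chrom_length(layout, layout$z_name))) {
    abort("stratum intervals extend beyond the Z chromosome")
  }
  class(intervals) <- c("zw_strata", class(intervals))
  intervals
}

#' Default stratum map of the brine shrimp Z chromosome
#'
#' The published stratum coordinates of the *Artemia franciscana* Z (chr6):
#' S1 46,085,001-48,385,001; S0 in three blocks 48,665,001-53,365,001,
#' 53,585,001-54,575,001 and 54,715,001-61,855,001; S2 63,345,001-64,075,001.
#'
#' @param scale Positive factor applied to all coordinates (used by the
#'   synthetic-data generator to shrink the genome; default 1).
#' @return A [zw_strata()] tibble.
#' @export
artemia_strata <- function(scale = 1) {
  stopifnot(scale > 0)
  iv <- tibble(
    start_bp = c(46085001, 48665001, 53585001, 54715001, 63345001),
    end_bp   = c(48385001, 53365001, 54575001, 61855001, 64075001),
    label    = c("S1", "S0", "S0", "S0", "S2")
  )
  if (scale != 1) {
    iv$start_bp <- pmax(1, round(iv$start_bp * scale))
    iv$end_bp <- pmax(iv$start_bp, round(iv$end_bp * scale))
  }
  zw_strata(iv)
}

#' Classify genomic positions as autosomal, PAR or differentiated Z
#'
#' Positions on non-Z chromosomes are `AUTOSOME`; Z positions at or below the
#' PAR boundary are `PAR`, above it `ZDIFF`. (The boundary base itself is
#' assigned to the PAR.)
#'
#' @param chrom Character vector of chromosome names.
#' @param pos_bp Integer vector of 1-based positions (recycled against
#'   `chrom`).
#' @param layout A [zw_layout()].
#'
#' @return Character vector with values `"AUTOSOME"`, `"PAR"`, `"ZDIFF"`.
#' @export
#' @examples
#' lay <- zw_layout(tibble::tibble(name = c("chr1", "Z"),
#'                                 length_bp = c(1e7, 6.58e7)), "Z")
#' classify_position(c("Z", "Z", "chr1"), c(46043528, 46043530, 5000), lay)
classify_position <- function(chrom, pos_bp, layout) {
  stopifnot(inherits(layout, "zw_layout"))
  n <- max(length(chrom), length(pos_bp))
  chrom <- rep_len(chrom, n)
  pos_bp <- rep_len(as.numeric(pos_bp), n)
  len <- chrom_length(layout, chrom)
  if (anyNA(len)) {
    bad <- unique(chrom[is.na(len)])
    abort(sprintf("unknown chromosome(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(pos_bp < 1 | pos_bp > len)) {
    abort("position(s) outside chromosome bounds")
  }
  out <- rep("AUTOSOME", n)
  on_z <- chrom == layout$z_name
  out[on_z] <- if_else(pos_bp[on_z] <= layout$par_boundary_bp, "PAR", "ZDIFF")
  out
}

#' Label Z positions by evolutionary stratum
#'
#' @param pos_bp Integer vector of 1-based positions on the Z.
#' @param strata A [zw_strata()] map.
#' @return Character vector with values `"S0"`, `"S1"`, `"S2"` or `"OUTSIDE"`.
#' @export
stratum_label <- function(pos_bp, strata) {
  stopifnot(inherits(strata, "zw_strata"))
  pos_bp <- as.numeric(pos_bp)
  if (any(pos_bp < 1)) abort("positions must be >= 1")
  idx <- findInterval(pos_bp, strata$start_bp)
  inside <- idx >= 1 & pos_bp <= c(strata$end_bp, -Inf)[pmax(idx, 1)]
  out <- rep("OUTSIDE", length(pos_bp))
  out[inside] <- strata$label[idx[inside]]
  out
}

#' Tile every chromosome with fixed-width bins
#'
#' Bins are 0-based half-open intervals `[start, end)` that cover each
#' chromosome without gaps or overlap; the final bin of a chromosome is
#' truncated when the length is not a multiple of `width_bp`.
#'
#' @param layout A [zw_layout()].
#' @param width_bp Positive bin width in bp.
#' @return Tibble with columns `chrom`, `start`, `end`.
#' @export
make_bins <- function(layout, width_bp) {
  stopifnot(inherits(layout, "zw_layout"))
  width_bp <- as.numeric(width_bp)
  if (length(width_bp) != 1 || is.na(width_bp) || width_bp < 1) {
    abort("`width_bp` must be a positive integer")
  }
  out <- purrr::map2(
    layout$chromosomes$name, layout$chromosomes$length_bp,
    function(nm, len) {
      starts <- seq(0, len - 1, by = width_bp)
      tibble(chrom = nm, start = starts, end = pmin(starts + width_bp, len))
    }
  )
  bind_rows(out)
}

#' Split one chromosome into equally sized windows
#'
#' The first `n_windows - 1` windows have width `floor(length / n_windows)`;
#' the last window absorbs the remainder, so the windows exactly cover
#' `[0, chrom_length_bp)`.
#'
#' @param chrom_length_bp Chromosome length in bp.
#' @param n_windows Number of windows (default 14, the window count used for
#'   Z-chromosome box plot summaries).
#' @return Tibble with columns `window`, `start`, `end` (0-based half-open).
#' @export
make_equal_windows <- function(chrom_length_bp, n_windows = 14) {
  chrom_length_bp <- as.numeric(chrom_length_bp)
  n_windows <- as.integer(n_windows)
  if (n_windows < 1) abort("`n_windows` must be >= 1")
  if (n_windows > chrom_length_bp) {
    abort("`n_windows` exceeds the chromosome length")
  }
  w <- floor(chrom_length_bp / n_windows)
  starts <- (seq_len(n_windows) - 1) * w
  ends <- c(starts[-1], chrom_length_bp)
  tibble(window = seq_len(n_windows), start = starts, end = ends)
}

# 1-based midpoint of 0-based half-open bins
bin_midpoint <- function(start, end) floor((start + end - 1) / 2) + 1

#' Annotate bins with region class and stratum
#'
#' Assigns each bin, by its midpoint, a region class (`AUTOSOME`, `PAR`,
#' `ZDIFF`) and for differentiated-Z bins a stratum group (`S0`, `S1`, `S2`,
#' or `ZDIFF_OUTSIDE` for Z(diff) bins outside every stratum interval).
#'
#' @param bins Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param layout A [zw_layout()].
#' @param strata A [zw_strata()] map.
#' @return `bins` with extra columns `region` and `group`.
#' @export
annotate_bins <- function(bins, layout, strata) {
  mid <- bin_midpoint(bins$start, bins$end)
  region <- classify_position(bins$chrom, mid, layout)
  group <- region
  zd <- region == "ZDIFF"
  if (any(zd)) {
    lab <- stratum_label(mid[zd], strata)
    group[zd] <- if_else(lab == "OUTSIDE", "ZDIFF_OUTSIDE", lab)
  }
  mutate(bins, region = region, group = group)
}
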