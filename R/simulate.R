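# Seeded generator for a synthetic ZW/ZZ study. The generator emits every
# input the analysis stages consume (expressed-SNP variant records, binned
# CUT&Tag-like counts, embryo RNA count matrices, aged-individual signal
# matrices, lifetime tables), with the statistical structure the analyses
# assume: ZW females hemizygous on the differentiated Z stratum, female
# specific stratum-graded chromatin enrichment, a stage-dependent embryonic
# dose deficit, aged-female multiplicative noise, and sex-specific Weibull
# lifetimes.

#' Configuration of the synthetic ZW study
#'
#' Bundles every tunable of the generator. The defaults describe the study
#' conditions emulated throughout the package: a 21-chromosome genome of
#' ~1.7 Gb whose Z (chr6, 65.8 Mb) carries a PAR boundary at 46,043,529 and
#' the [artemia_strata()] stratum map; 5956 expressed autosomal genes, 330 in
#' the PAR and 102 on Z(diff); per-stratum female log2 enrichment 1.280 (S0),
#' 1.169 (S1), 0.435 (S2) and 0.8 for Z(diff) outside the strata; an early
#' embryo female Z(diff) dose deficit of 0.65 that resolves by the late
#' stage; aged-female multiplicative noise with sdlog 0.6; Weibull(k = 3)
#' lifetimes with mean 45 d (females) and 60 d (males).
#'
#' The autosomal complement is sized so that Z(diff) is a small fraction
#' (~1.2%) of the genome, as in the real karyotype; this matters because CPM
#' normalization constrains library composition, and a generator whose
#' enriched compartment occupied a large genome fraction would depress
#' CPM-scale fold changes everywhere else (see the methods vignette).
#'
#' @param seed Integer seed; fixing it makes every generator output
#'   reproducible.
#' @param scale Positive factor applied to chromosome lengths, stratum
#'   coordinates and gene counts, for scaled-down runs.
#' @param n_autosomes,autosome_length_bp,z_length_bp,par_boundary_bp Genome
#'   geometry (pre-`scale`).
#' @param n_genes Named integer vector: expressed genes per region
#'   (`autosome`, `par`, `zdiff`).
#' @param snp_rate_per_exon_kb Heterozygous population SNPs per exon kb.
#' @param ref_divergence_rate Homozygous-alternate (reference-divergence)
#'   SNPs per exon kb.
#' @param seq_error Sequencing error rate; hemizygous sites leak
#'   `Binomial(depth, seq_error)` reads of the absent allele.
#' @param read_depth_mean,nb_dispersion Negative-binomial depth model:
#'   mean and dispersion phi (variance `mu + phi * mu^2`).
#' @param stratum_log2_enrichment Named vector of female log2 enrichment per
#'   stratum (`S0`, `S1`, `S2`) and for Z(diff) bins outside the strata
#'   (`ZDIFF_OUTSIDE`).
#' @param promoter_peak_fold Coverage multiplier on `TSS +- 500` bp of
#'   expressed genes (both sexes).
#' @param bin_base_mean Expected reads per 10-kb coverage bin per library
#'   before fold multipliers (scaled proportionally for other bin widths).
#' @param low_mq_fraction Fraction of SNP records given a failing mapping
#'   quality (< 20), as filter decoys.
#' @param embryo_dose_deficit Named vector `c(early = , late = )`:
#'   multiplicative deficit of female Z(diff) expression per embryo stage.
#' @param embryo_depth_factor Expected counts per TPM unit in embryo
#'   libraries (so a TPM-20 gene averages 100 reads at the default 5).
#' @param aging_sdlog Sdlog of the mean-preserving log-normal factor applied
#'   per gene and individual to old-female Z(diff) signals.
#' @param aging_base_sdlog Sdlog of the global measurement noise applied to
#'   every signal.
#' @param survival_shape,survival_mean_days Weibull shape and sex-specific
#'   mean lifetimes in days (named `F`, `M`).
#' @param tpm_meanlog,tpm_sdlog Log-normal law of true gene expression (TPM).
#'
#' @return A list of class `zw_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       scale = 1,
                       n_autosomes = 20L,
                       autosome_length_bp = 8.2e7,
                       z_length_bp = 65800000,
                       par_boundary_bp = 46043529,
                       n_genes = c(autosome = 5956L, par = 330L, zdiff = 102L),
                       snp_rate_per_exon_kb = 2,
                       ref_divergence_rate = 0.5,
                       seq_error = 0.005,
                       read_depth_mean = 40,
                       nb_dispersion = 0.1,
                       stratum_log2_enrichment = c(S0 = 1.280, S1 = 1.169,
                                                   S2 = 0.435,
                                                   ZDIFF_OUTSIDE = 0.8),
                       promoter_peak_fold = 4,
                       bin_base_mean = 50,
                       low_mq_fraction = 0.05,
                       embryo_dose_deficit = c(early = 0.65, late = 1),
                       embryo_depth_factor = 5,
                       aging_sdlog = 0.6,
                       aging_base_sdlog = 0.1,
                       survival_shape = 3,
                       survival_mean_days = c(F = 45, M = 60),
                       tpm_meanlog = log(30),
                       tpm_sdlog = 1) {
  stopifnot(scale > 0, n_autosomes >= 1, autosome_length_bp > 0,
            z_length_bp > 0, par_boundary_bp > 0,
            snp_rate_per_exon_kb > 0, ref_divergence_rate >= 0,
            seq_error >= 0, seq_error < 1,
            read_depth_mean > 0, nb_dispersion > 0,
            promoter_peak_fold > 0, bin_base_mean > 0,
            low_mq_fraction >= 0, low_mq_fraction < 1,
            all(embryo_dose_deficit > 0), all(embryo_dose_deficit <= 1),
            aging_sdlog >= 0, aging_base_sdlog >= 0,
            survival_shape > 0, all(survival_mean_days > 0))
  if (!all(c("autosome", "par", "zdiff") %in% names(n_genes))) {
    abort("`n_genes` needs entries autosome, par, zdiff")
  }
  if (!all(c("S0", "S1", "S2", "ZDIFF_OUTSIDE") %in%
           names(stratum_log2_enrichment))) {
    abort("`stratum_log2_enrichment` needs S0, S1, S2 and ZDIFF_OUTSIDE")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "zw_sim_config")
}

# seed derivation for sub-draws; kept well below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147480000)
}

scaled_layout <- function(config) {
  s <- config$scale
  auto_len <- max(1, round(config$autosome_length_bp * s))
  z_len <- max(2, round(config$z_length_bp * s))
  boundary <- min(z_len - 1, max(1, round(config$par_boundary_bp * s)))
  nm <- paste0("chr", seq_len(config$n_autosomes + 1))
  z_name <- if (config$n_autosomes + 1 >= 6) "chr6" else nm[length(nm)]
  lengths <- rep(auto_len, config$n_autosomes + 1)
  lengths[match(z_name, nm)] <- z_len
  zw_layout(tibble(name = nm, length_bp = lengths), z_name, boundary)
}

scaled_gene_counts <- function(config) {
  n <- round(unlist(config$n_genes[c("autosome", "par", "zdiff")]) *
               config$scale)
  setNames(pmax(1L, as.integer(n)), c("autosome", "par", "zdiff"))
}

# place n non-overlapping genes of the given lengths uniformly in
# [lo, hi] (1-based inclusive); returns start positions
place_genes <- function(n, lengths, lo, hi) {
  free <- (hi - lo + 1) - sum(lengths)
  if (free < n) {
    abort(sprintf(
      "region [%d, %d] too small for %d genes (needs %d more bp)",
      lo, hi, n, n - free))
  }
  gaps <- floor(sort(runif(n)) * free)
  lo + gaps + c(0, cumsum(lengths[-n]))
}

make_exons <- function(gene_id, start, end, n_exons) {
  len <- end - start + 1
  k <- min(n_exons, max(1, len %/% 120))
  if (k == 1) {
    return(tibble(gene_id = gene_id, start = start, end = end))
  }
  # alternate exon/intron segments with random proportions, min 30 bp each
  nseg <- 2 * k - 1
  prop <- stats::rexp(nseg) + 0.15
  w <- floor(prop / sum(prop) * (len - nseg * 30)) + 30
  w[nseg] <- len - sum(w[-nseg])
  bounds <- start + c(0, cumsum(w))
  idx <- seq(1, nseg, by = 2)
  tibble(gene_id = gene_id, start = bounds[idx], end = bounds[idx + 1] - 1)
}

#' Build the synthetic genome: layout, strata and gene annotation
#'
#' Places the configured number of expressed genes uniformly and without
#' overlap in each region (autosomes, PAR, differentiated Z), each with 1-5
#' exons, a strand, and a true expression level drawn from a log-normal TPM
#' law. Region labels derive from [classify_position()] applied to the TSS.
#'
#' @param config A [sim_config()].
#' @return A list of class `zw_sim` with elements `config`, `layout`,
#'   `strata`, `genes` (tibble: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `tss`, `region`, `true_tpm`, `expressed`) and `exons` (tibble:
#'   `gene_id`, `chrom`, `start`, `end`, 1-based inclusive).
#' @export
sim_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "zw_sim_config"))
  layout <- scaled_layout(config)
  strata <- artemia_strata(config$scale)
  counts <- scaled_gene_counts(config)
  withr::with_seed(derive_seed(config$seed, 1), {
    autos <- setdiff(layout$chromosomes$name, layout$z_name)
    # split autosomal genes across autosomes (equal lengths -> near-equal)
    n_auto_chr <- as.vector(table(factor(
      sample(autos, counts[["autosome"]], replace = TRUE), levels = autos)))
    regions <- tibble(
      chrom = c(autos, layout$z_name, layout$z_name),
      region = c(rep("AUTOSOME", length(autos)), "PAR", "ZDIFF"),
      lo = c(rep(1, length(autos)), 1, layout$par_boundary_bp + 1),
      hi = c(rep(chrom_length(layout, autos[1]), length(autos)),
             layout$par_boundary_bp, chrom_length(layout, layout$z_name)),
      n = c(n_auto_chr, counts[["par"]], counts[["zdiff"]])
    )
    genes <- purrr::pmap(regions, function(chrom, region, lo, hi, n) {
      if (n == 0) return(NULL)
      span <- hi - lo + 1
      max_len <- max(300, min(20000, floor(span / (2 * n))))
      len <- pmin(max_len, pmax(300, round(rlnorm(n, log(2000), 0.6))))
      start <- place_genes(n, len, lo, hi)
      tibble(chrom = chrom, region = region, start = start,
             end = start + len - 1)
    })
    genes <- bind_rows(genes)
    ng <- nrow(genes)
    genes <- mutate(genes,
      gene_id = sprintf("g%05d", row_number()),
      strand = sample(c("+", "-"), ng, replace = TRUE),
      tss = if_else(.data$strand == "+", .data$start, .data$end),
      true_tpm = rlnorm(ng, config$tpm_meanlog, config$tpm_sdlog),
      expressed = .data$true_tpm >= 10,
      n_exons = sample(1:5, ng, replace = TRUE)
    )
    stopifnot(identical(genes$region,
                        classify_position(genes$chrom, genes$tss, layout)))
    exons <- purrr::pmap(
      genes[, c("gene_id", "start", "end", "n_exons")],
      function(gene_id, start, end, n_exons)
        make_exons(gene_id, start, end, n_exons)
    )
    exons <- left_join(bind_rows(exons),
                       genes[, c("gene_id", "chrom")], by = "gene_id")
    exons <- exons[, c("gene_id", "chrom", "start", "end")]
  })
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tss",
                     "region", "true_tpm", "expressed", "n_exons")]
  structure(list(config = config, layout = layout, strata = strata,
                 genes = genes, exons = exons),
            class = "zw_sim")
}

#' @export
print.zw_sim <- function(x, ...) {
  cat(sprintf("<zw_sim> %d genes on %d chromosomes (scale %.3g, seed %d)\n",
              nrow(x$genes), nrow(x$layout$chromosomes), x$config$scale,
              x$config$seed))
  invisible(x)
}

rnb <- function(n, mu, phi) rnbinom(n, mu = mu, size = 1 / phi)

#' Simulate expressed-SNP allele observations for one individual
#'
#' Heterozygous population SNPs are placed in exons at
#' `snp_rate_per_exon_kb`; additional homozygous-alternate sites model
#' divergence from the reference assembly. Per-site depth is negative
#' binomial. Females are hemizygous on the differentiated Z stratum: at
#' their Z(diff) heterozygous sites the silent allele receives only
#' `Binomial(depth, seq_error)` leakage reads, so the allelic balance is
#' (near) zero, while all other heterozygous sites are `Binomial(depth, 1/2)`
#' in both sexes. A fraction of records carries failing mapping quality as
#' filter decoys.
#'
#' @param sim A [sim_genome()] result.
#' @param sex `"F"` (ZW) or `"M"` (ZZ) — ground truth, stored only in the
#'   `truth` attribute of the result, never in the variant fields.
#' @param seed Integer seed (default: derived from the config seed).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `AO`, `RO`,
#'   `MQM`, `MQMR`, sorted by position, plus a `truth` attribute (tibble with
#'   `type` and `hemizygous`).
#' @export
simulate_expressed_snps <- function(sim, sex = c("F", "M"), seed = NULL) {
  stopifnot(inherits(sim, "zw_sim"))
  sex <- match.arg(sex)
  cfg <- sim$config
  seed <- seed %||% derive_seed(cfg$seed, 2)
  ex <- left_join(sim$exons, sim$genes[, c("gene_id", "region")],
                  by = "gene_id")
  kb <- (ex$end - ex$start + 1) / 1000
  withr::with_seed(seed, {
    n_het <- rpois(nrow(ex), cfg$snp_rate_per_exon_kb * kb)
    n_div <- rpois(nrow(ex), cfg$ref_divergence_rate * kb)
    idx <- rep.int(seq_len(nrow(ex)), n_het + n_div)
    type <- unlist(purrr::map2(n_het, n_div,
                               function(h, d) rep(c("het", "div"), c(h, d))))
    ns <- length(idx)
    pos <- ex$start[idx] +
      floor(runif(ns) * (ex$end[idx] - ex$start[idx] + 1))
    region <- ex$region[idx]
    depth <- rnb(ns, cfg$read_depth_mean, cfg$nb_dispersion)
    hemi <- sex == "F" & region == "ZDIFF" & type == "het"
    leak <- rbinom(ns, depth, cfg$seq_error)
    ao <- integer(ns); ro <- integer(ns)
    # balanced heterozygous observation
    bal <- type == "het" & !hemi
    ao[bal] <- rbinom(sum(bal), depth[bal], 0.5)
    ro[bal] <- depth[bal] - ao[bal]
    # hemizygous het site: the retained allele is ref or alt with equal odds
    if (any(hemi)) {
      ref_kept <- runif(sum(hemi)) < 0.5
      ao[hemi] <- if_else(ref_kept, leak[hemi], depth[hemi] - leak[hemi])
      ro[hemi] <- depth[hemi] - ao[hemi]
    }
    div <- type == "div"
    ao[div] <- depth[div] - leak[div]
    ro[div] <- leak[div]
    mqm <- runif(ns, 30, 60)
    mqmr <- runif(ns, 30, 60)
    decoy <- runif(ns) < cfg$low_mq_fraction
    mqm[decoy] <- runif(sum(decoy), 5, 19.5)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, ns, replace = TRUE)
    alt <- alleles[(match(ref, alleles) + sample(1:3, ns, TRUE) - 1) %% 4 + 1]
  })
  out <- tibble(chrom = ex$chrom[idx], pos = pos, ref = ref, alt = alt,
                AO = ao, RO = ro, MQM = mqm, MQMR = mqmr)
  truth <- tibble(type = type, hemizygous = hemi)
  o <- order(out$chrom, out$pos)
  out <- out[o, ]
  attr(out, "truth") <- truth[o, ]
  out
}

# expected coverage fold per bin for one sex, given the annotated bins
bin_fold <- function(sim, bins_annot, sex) {
  cfg <- sim$config
  fold <- rep(1, nrow(bins_annot))
  if (sex == "F") {
    zd <- bins_annot$region == "ZDIFF"
    fold[zd] <- 2^cfg$stratum_log2_enrichment[bins_annot$group[zd]]
  }
  # promoter peaks of expressed genes, both sexes
  genes <- sim$genes[sim$genes$expressed, ]
  for (chr in unique(genes$chrom)) {
    g <- genes[genes$chrom == chr, ]
    b <- which(bins_annot$chrom == chr)
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(pmax(1, g$tss - 500), g$tss + 500),
      IRanges::IRanges(bins_annot$start[b] + 1, bins_annot$end[b])
    )
    touched <- b[unique(S4Vectors::subjectHits(hit))]
    fold[touched] <- fold[touched] * cfg$promoter_peak_fold
  }
  fold
}

#' Simulate binned CUT&Tag-like coverage for one individual
#'
#' Per-bin raw counts are negative binomial around a smooth baseline. Bins
#' overlapping `TSS +- 500` of expressed genes carry a promoter peak in both
#' sexes; for females, differentiated-Z bins are additionally multiplied by
#' `2^Delta` with the per-stratum enrichment from the configuration. Library
#' sizes vary uniformly 0.5-2x between individuals (CPM normalization cancels
#' this).
#'
#' @inheritParams simulate_expressed_snps
#' @param width_bp Bin width (default 10 kb; 5 kb and finer widths work the
#'   same way, with the baseline scaled proportionally).
#' @return Coverage tibble `chrom`, `start`, `end`, `count` (raw counts, one
#'   value per bin of [make_bins()]).
#' @export
simulate_cuttag_counts <- function(sim, sex = c("F", "M"), width_bp = 10000,
                                   seed = NULL) {
  stopifnot(inherits(sim, "zw_sim"))
  sex <- match.arg(sex)
  cfg <- sim$config
  seed <- seed %||% derive_seed(cfg$seed, 3)
  bins <- annotate_bins(make_bins(sim$layout, width_bp), sim$layout,
                        sim$strata)
  chr_idx <- match(bins$chrom, sim$layout$chromosomes$name)
  chr_len <- sim$layout$chromosomes$length_bp[chr_idx]
  mid <- bin_midpoint(bins$start, bins$end)
  # deterministic smooth baseline (three waves per chromosome)
  smooth <- 1 + 0.25 * sin(2 * pi * 3 * mid / chr_len + chr_idx)
  base <- cfg$bin_base_mean * (bins$end - bins$start) / 1e4 * smooth
  fold <- bin_fold(sim, bins, sex)
  withr::with_seed(seed, {
    libsize <- runif(1, 0.5, 2)
    count <- rnb(nrow(bins), base * fold * libsize, cfg$nb_dispersion)
  })
  tibble(chrom = bins$chrom, start = bins$start, end = bins$end,
         count = count)
}

#' Simulate a replicated CUT&Tag experiment
#'
#' @inheritParams simulate_cuttag_counts
#' @param n_rep Replicates per sex.
#' @return Tibble with columns `sample_id`, `sex`, `replicate`, `chrom`,
#'   `start`, `end`, `count` (long format, one row per bin and sample).
#' @export
simulate_cuttag_experiment <- function(sim, n_rep = 3, width_bp = 10000,
                                       seed = NULL) {
  cfg <- sim$config
  seed <- seed %||% derive_seed(cfg$seed, 4)
  design <- tidyr::expand_grid(sex = c("F", "M"), replicate = seq_len(n_rep))
  out <- purrr::pmap(
    mutate(design, i = row_number()),
    function(sex, replicate, i) {
      trk <- simulate_cuttag_counts(sim, sex, width_bp,
                                    seed = derive_seed(seed, i))
      mutate(trk,
             sample_id = sprintf("%s%d", sex, replicate),
             sex = sex, replicate = replicate, .before = 1)
    }
  )
  bind_rows(out)
}

#' Simulate single-embryo RNA-seq counts
#'
#' Gene counts are negative binomial with mean proportional to the gene's
#' true TPM. In females, differentiated-Z genes are multiplied by the
#' stage-specific dose deficit (default 0.65 at the early stage, 1 at the
#' late stage, by which dosage compensation is complete). Library sizes vary
#' 0.5-2x.
#'
#' @inheritParams simulate_expressed_snps
#' @param stage `"early"` (blastula, 1-2 dpf analogue) or `"late"`
#'   (post-gastrula, 4 dpf analogue).
#' @param n_per_sex Embryos per sex (default 3).
#' @return List with `counts` (tibble: `gene_id` + one integer column per
#'   sample) and `samples` (tibble: `sample_id`, `sex`, `stage`,
#'   `replicate`).
#' @export
simulate_embryo_counts <- function(sim, stage = c("early", "late"),
                                   n_per_sex = 3, seed = NULL) {
  stopifnot(inherits(sim, "zw_sim"))
  stage <- match.arg(stage)
  cfg <- sim$config
  seed <- seed %||% derive_seed(cfg$seed, 5)
  genes <- sim$genes
  samples <- tidyr::expand_grid(sex = c("F", "M"),
                                replicate = seq_len(n_per_sex))
  samples <- mutate(samples,
                    sample_id = sprintf("%s_%s%d", stage, .data$sex,
                                        .data$replicate),
                    stage = stage)
  deficit <- cfg$embryo_dose_deficit[[stage]]
  base <- genes$true_tpm * cfg$embryo_depth_factor
  withr::with_seed(seed, {
    mat <- purrr::map2(samples$sex, seq_len(nrow(samples)), function(sx, j) {
      mu <- base * runif(1, 0.5, 2)
      if (sx == "F") mu <- mu * if_else(genes$region == "ZDIFF", deficit, 1)
      rnb(length(mu), mu, cfg$nb_dispersion)
    })
  })
  counts <- as_tibble(setNames(mat, samples$sample_id))
  counts <- mutate(counts, gene_id = genes$gene_id, .before = 1)
  list(counts = counts,
       samples = samples[, c("sample_id", "sex", "stage", "replicate")])
}

#' Simulate per-gene chromatin signal for young and old individuals
#'
#' Each gene has a base signal (its true TPM); every measurement carries a
#' small global log-normal noise (`aging_base_sdlog`). Old females
#' additionally receive an independent, per-gene and per-individual,
#' mean-preserving log-normal factor (`aging_sdlog`) on differentiated-Z
#' genes only, raising the coefficient of variation there without moving the
#' mean. Males and young females never receive the aging factor.
#'
#' @inheritParams simulate_expressed_snps
#' @param n_young,n_old Individuals per age group (>= 2 for CV analyses).
#' @return List with `signal` (tibble: `gene_id` + one numeric column per
#'   individual) and `samples` (tibble: `sample_id`, `sex`, `age_group`).
#' @export
simulate_aging_signals <- function(sim, sex = c("F", "M"), n_young = 3,
                                   n_old = 3, seed = NULL) {
  stopifnot(inherits(sim, "zw_sim"))
  sex <- match.arg(sex)
  cfg <- sim$config
  seed <- seed %||% derive_seed(cfg$seed, 6)
  genes <- sim$genes
  ng <- nrow(genes)
  samples <- tibble(
    sample_id = c(sprintf("%s_young%d", sex, seq_len(n_young)),
                  sprintf("%s_old%d", sex, seq_len(n_old))),
    sex = sex,
    age_group = rep(c("young", "old"), c(n_young, n_old))
  )
  s0 <- cfg$aging_base_sdlog
  s1 <- cfg$aging_sdlog
  withr::with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(samples)), function(j) {
      x <- genes$true_tpm * rlnorm(ng, -s0^2 / 2, s0)
      if (sex == "F" && samples$age_group[j] == "old" && s1 > 0) {
        zd <- genes$region == "ZDIFF"
        x[zd] <- x[zd] * rlnorm(sum(zd), -s1^2 / 2, s1)
      }
      x
    })
  })
  signal <- as_tibble(setNames(cols, samples$sample_id))
  signal <- mutate(signal, gene_id = genes$gene_id, .before = 1)
  list(signal = signal, samples = samples)
}

#' Simulate individual lifetimes for one sex
#'
#' Lifetimes are Weibull with the configured shape and a scale chosen so the
#' mean equals the configured sex-specific mean (`scale = mean /
#' gamma(1 + 1/shape)`). Optional right-censoring at `censor_day`.
#'
#' @param config A [sim_config()] (or a [sim_genome()] result, whose config
#'   is used).
#' @param sex `"F"` or `"M"`.
#' @param n Number of individuals.
#' @param censor_day Optional administrative censoring time in days.
#' @param seed Integer seed.
#' @return Tibble `id`, `sex`, `time_days`, `event` (1 = death observed,
#'   0 = censored).
#' @export
simulate_lifespans <- function(config, sex = c("F", "M"), n,
                               censor_day = NULL, seed = NULL) {
  if (inherits(config, "zw_sim")) config <- config$config
  stopifnot(inherits(config, "zw_sim_config"), n >= 1)
  sex <- match.arg(sex)
  seed <- seed %||% derive_seed(config$seed, 7)
  k <- config$survival_shape
  lambda <- config$survival_mean_days[[sex]] / gamma(1 + 1 / k)
  withr::with_seed(seed, t <- rweibull(n, shape = k, scale = lambda))
  event <- rep(1L, n)
  if (!is.null(censor_day)) {
    event <- as.integer(t <= censor_day)
    t <- pmin(t, censor_day)
  }
  tibble(id = sprintf("%s%05d", sex, seq_len(n)), sex = sex,
         time_days = t, event = event)
}

#' Simulate a replicated two-sex lifespan study
#'
#' @inheritParams simulate_lifespans
#' @param n_per_group Individuals per sex per replicate culture (default 50).
#' @param n_strata Replicate cultures (default 3).
#' @return Tibble `id`, `sex`, `time_days`, `event`, `stratum`.
#' @export
simulate_lifespan_study <- function(config, n_per_group = 50, n_strata = 3,
                                    censor_day = NULL, seed = NULL) {
  if (inherits(config, "zw_sim")) config <- config$config
  seed <- seed %||% derive_seed(config$seed, 8)
  out <- purrr::map(seq_len(n_strata), function(s) {
    bind_rows(
      simulate_lifespans(config, "F", n_per_group, censor_day,
                         seed = derive_seed(seed, 2 * s)),
      simulate_lifespans(config, "M", n_per_group, censor_day,
                         seed = derive_seed(seed, 2 * s + 1))
    ) |>
      mutate(stratum = sprintf("R%d", s),
             id = paste0(.data$id, "_R", s))
  })
  bind_rows(out)
}
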