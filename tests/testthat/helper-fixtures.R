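# Shared fixtures. The full-scale synthetic genome is expensive (~6 s), so it
# is built lazily once per test run and reused across files.

.fixture_env <- new.env(parent = emptyenv())

sim_full <- function() {
  if (is.null(.fixture_env$sim_full)) {
    .fixture_env$sim_full <- sim_genome(sim_config(seed = 1))
  }
  .fixture_env$sim_full
}

# small two-autosome genome for unit tests that do not need the full layout
sim_small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, scale = 0.1, n_autosomes = 2,
             n_genes = c(autosome = 400, par = 60, zdiff = 40), ...)
}

sim_small <- function() {
  if (is.null(.fixture_env$sim_small)) {
    .fixture_env$sim_small <- sim_genome(sim_small_config())
  }
  .fixture_env$sim_small
}

toy_layout <- function() {
  zw_layout(
    tibble::tibble(name = c("chr1", "Z"), length_bp = c(1e7, 65800000)),
    z_name = "Z"
  )
}

# average per-sex CPM tracks and the one-read pseudocount of an experiment
sexed_log2fc <- function(expt) {
  pc <- 1e6 / mean(tapply(expt$count, expt$sample_id, sum))
  cpm <- lapply(split(expt, expt$sample_id), cpm_track)
  sexes <- tapply(expt$sex, expt$sample_id, unique)
  f <- average_tracks(cpm[names(sexes)[sexes == "F"]])
  m <- average_tracks(cpm[names(sexes)[sexes == "M"]])
  bin_log2fc(f, m, pseudocount = pc)
}
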