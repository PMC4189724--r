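# Shared synthetic dataset, built once per test run (lazily).
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$data)) {
    cfg <- synth_config(depths = c(SD8 = 3e4, C5 = 3e4, LD3 = 3e4))
    genome <- generate_toy_genome(cfg, seed = 11)
    sim <- simulate_libraries(genome, seed = 11)
    fqdir <- file.path(tempdir(), "srnapipe-fixture")
    fq <- write_simulation(sim, fqdir)
    cleaned <- clean_fastq_libraries(fq, adapter3 = cfg$adapter3,
                                     adapter5 = cfg$adapter5)
    hits <- map_tags(cleaned$tags, genome$scaffolds)
    ann <- classify(hits, cleaned$tags, genome$features,
                    genome$known_mature)
    .fixture_cache$data <- list(cfg = cfg, genome = genome, sim = sim,
                                fq = fq, cleaned = cleaned, hits = hits,
                                ann = ann)
  }
  .fixture_cache$data
}

# a designed mini-locus: single-scaffold genome holding one perfect hairpin
# (flank + mature + loop + star + flank), returning everything needed to run
# the hairpin module on it
mini_hairpin_world <- function(mature, counts,
                               libs = c("SD8", "C5", "LD3"),
                               flank_len = 30L, seed = 42L) {
  withr::with_seed(seed, {
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    star <- revcomp(mature)
    precursor <- paste0(pad(8), mature, "GAACAGGAAC", star, pad(8))
    scaffold <- paste0(pad(flank_len), precursor, pad(flank_len))
    genome <- setNames(scaffold, "chr_toy")
    tags <- data.frame(sequence = mature, stringsAsFactors = FALSE)
    for (i in seq_along(libs)) tags[[libs[i]]] <- counts[i]
    hits <- map_tags(tags, genome)
    windows <- extract_candidates(hits, genome, flank = 60L)
    list(genome = genome, tags = tags, hits = hits, windows = windows,
         mature = mature, precursor = precursor)
  })
}
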