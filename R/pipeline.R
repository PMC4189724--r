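#' Assemble and validate a pipeline configuration
#'
#' One configuration object carries every tunable of the pipeline, so each
#' number in the output reports is recomputable from the inputs plus this
#' config. All gaps the underlying study leaves open (quality threshold,
#' polyA rule, adapter-match length, MFE acceptance threshold, significance
#' thresholds) surface here as named keys with defaults.
#'
#' @param synth a [synth_config()] for the synthetic stage, or NULL when
#'   `fastq`, `genome_fa`, `gff`, `mature_fa`, `transcripts_fa` point at
#'   existing inputs.
#' @param fastq named vector of FASTQ paths (names = libraries); ignored when
#'   `synth` is given.
#' @param genome_fa,gff,mature_fa,transcripts_fa input paths (ignored with
#'   `synth`).
#' @param control control library label (default `"SD8"`).
#' @param seed integer seed recorded in the run manifest.
#' @param quality_threshold,polyA_min_run,polyA_min_frac,adapter_min_match
#'   cleaning thresholds, see [clean_reads()].
#' @param flank,merge_dist,min_count,min_paired,max_bulge,mfe_max novel-miRNA
#'   thresholds, see [hairpin_candidates()].
#' @param p_threshold,fc_threshold,low_threshold expression thresholds, see
#'   [diff_expression()].
#' @param target_cutoff target-score cutoff, see [target_scheme()].
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), fastq = NULL,
                            genome_fa = NULL, gff = NULL, mature_fa = NULL,
                            transcripts_fa = NULL, control = "SD8",
                            seed = 1L, quality_threshold = 20,
                            polyA_min_run = 6L, polyA_min_frac = 0.7,
                            adapter_min_match = 6L, flank = 150L,
                            merge_dist = 50L, min_count = 5L,
                            min_paired = 16L, max_bulge = 4L, mfe_max = -18,
                            p_threshold = 0.01, fc_threshold = 1,
                            low_threshold = 1, target_cutoff = 4) {
  cfg <- as.list(environment())
  if (is.null(synth)) {
    for (f in c("fastq", "genome_fa", "gff", "mature_fa")) {
      if (is.null(cfg[[f]])) stop("without a synth config, '", f,
                                  "' must be provided")
    }
    libs <- names(cfg$fastq)
  } else {
    stopifnot(inherits(synth, "synth_config"))
    libs <- names(synth$depths)
  }
  if (!control %in% libs) {
    stop("control library '", control, "' is not among the libraries: ",
         paste(libs, collapse = ", "))
  }
  stopifnot(p_threshold >= 0, p_threshold <= 1, fc_threshold >= 0,
            flank >= 0, min_count >= 0, mfe_max <= 0, target_cutoff >= 0)
  cfg$libraries <- libs
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full small-RNA pipeline
#'
#' Executes synth (optional) -> clean -> annotate -> novel -> diffexpr ->
#' targets and writes all reports to `outdir`: per-library cleaning reports,
#' the composition report, known miRNA counts, novel miRNA candidate and
#' accepted tables (locus strings `scaffold:start:end`), the differential
#' expression table, the target hit table, and `run_manifest.json` recording
#' package version, seed and all thresholds. Rerunning with the same
#' configuration and seed reproduces byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return (invisibly) a list with the in-memory results of each stage and
#'   `paths` of the written reports.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  # --- synth (optional)
  if (!is.null(config$synth)) {
    genome <- pipeline_stage("synth",
      generate_toy_genome(config$synth, seed = config$seed))
    sim <- pipeline_stage("synth", simulate_libraries(genome,
                                                      seed = config$seed))
    gpaths <- write_genome_files(genome, file.path(outdir, "inputs"))
    fq <- write_simulation(sim, file.path(outdir, "inputs"))
    adapter3 <- config$synth$adapter3
    adapter5 <- config$synth$adapter5
    features <- genome$features
    mature_ref <- genome$known_mature
    transcripts <- genome$transcripts
    genome_seq <- genome$scaffolds
  } else {
    sim <- NULL
    fq <- config$fastq
    genome_seq <- read_fasta(config$genome_fa)
    features <- read_features_gff3(config$gff)
    mature_ref <- read_fasta(config$mature_fa)
    transcripts <- if (!is.null(config$transcripts_fa))
      read_fasta(config$transcripts_fa) else character(0)
    adapter3 <- config$adapter3
    adapter5 <- config$adapter5
    if (is.null(adapter3) || is.null(adapter5)) {
      stop("adapter sequences are required when not simulating")
    }
  }

  # --- clean
  cleaned <- pipeline_stage("clean", clean_fastq_libraries(
    fq, adapter3 = adapter3, adapter5 = adapter5,
    quality_threshold = config$quality_threshold,
    polyA_min_run = config$polyA_min_run,
    polyA_min_frac = config$polyA_min_frac,
    adapter_min_match = config$adapter_min_match))
  for (lib in names(cleaned$reports)) {
    paths <- c(paths, write_tsv(cleaned$reports[[lib]],
                                file.path(outdir,
                                          paste0("cleaning_", lib, ".tsv"))))
  }
  tags <- cleaned$tags
  libs <- setdiff(names(tags), "sequence")
  totals <- vapply(libs, function(l) sum(tags[[l]]), numeric(1))

  # --- annotate
  hits <- pipeline_stage("annotate", map_tags(tags, genome_seq))
  ann <- pipeline_stage("annotate", classify(hits, tags, features,
                                             mature_ref))
  paths <- c(paths, write_tsv(ann$report,
                              file.path(outdir, "composition.tsv")))
  known <- pipeline_stage("annotate", identify_known_mirnas(tags, mature_ref))
  paths <- c(paths, write_tsv(known, file.path(outdir, "known_mirnas.tsv")))

  # --- novel
  unann <- ann$records$tag[ann$records$category == "unannotated"]
  uhits <- hits[hits$tag %in% unann, , drop = FALSE]
  windows <- pipeline_stage("novel", extract_candidates(
    uhits, genome_seq, flank = config$flank, merge_dist = config$merge_dist))
  cands <- pipeline_stage("novel", hairpin_candidates(
    windows, genome_seq, tags, min_count = config$min_count,
    min_paired = config$min_paired, max_bulge = config$max_bulge,
    mfe_max = config$mfe_max))
  accepted <- pipeline_stage("novel", screen_candidates(cands))
  if (nrow(cands)) {
    paths <- c(paths, write_tsv(cands,
                                file.path(outdir, "novel_candidates.tsv")))
  }
  paths <- c(paths, write_tsv(accepted,
                              file.path(outdir, "novel_accepted.tsv")))

  # --- diffexpr (known miRNAs)
  de <- NULL
  if (nrow(known)) {
    de <- pipeline_stage("diffexpr", diff_expression(
      known[, c("mirna", libs)], totals, control = config$control,
      p_threshold = config$p_threshold, fc_threshold = config$fc_threshold,
      low_threshold = config$low_threshold))
    paths <- c(paths, write_tsv(de, file.path(outdir, "diffexpr.tsv")))
  }

  # --- targets (accepted novel matures vs transcripts)
  hits_tab <- NULL
  if (nrow(accepted) && length(transcripts)) {
    mir <- setNames(accepted$mature,
                    paste0("novel-", seq_len(nrow(accepted))))
    keep <- nchar(mir) >= 20 & nchar(mir) <= 24
    if (any(keep)) {
      hits_tab <- pipeline_stage("targets", scan_transcriptome(
        mir[keep], transcripts,
        scheme = target_scheme(cutoff = config$target_cutoff)))
      paths <- c(paths, write_tsv(hits_tab,
                                  file.path(outdir, "targets.tsv")))
    }
  }

  manifest <- list(
    package = "srnapipe",
    version = as.character(utils::packageVersion("srnapipe")),
    seed = config$seed,
    control = config$control,
    libraries = libs,
    thresholds = config[c("quality_threshold", "polyA_min_run",
                          "polyA_min_frac", "adapter_min_match", "flank",
                          "merge_dist", "min_count", "min_paired",
                          "max_bulge", "mfe_max", "p_threshold",
                          "fc_threshold", "low_threshold", "target_cutoff")])
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, file.path(outdir, "run_manifest.json"))

  invisible(list(simulation = sim, cleaned = cleaned, hits = hits,
                 annotation = ann, known = known, windows = windows,
                 candidates = cands, accepted = accepted,
                 diffexpr = de, targets = hits_tab, paths = paths))
}
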