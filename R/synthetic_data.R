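#' Generator settings for the synthetic three-library dataset
#'
#' The defaults state the world the pipeline is tested in: three libraries
#' (endodormancy SD8, ecodormancy C5, active growth LD3) of 18-30 nt inserts
#' sequenced as fixed-length reads, with artifact proportions and sRNA class
#' composition mirroring the published per-library accounting of a poplar
#' cambium dormancy experiment (sub-percent adapter artifacts, ~1.3% short
#' inserts, ~22% known miRNA reads, ~23% rRNA, ~42% unannotated), planted
#' known-miRNA fold changes of 0 / +-1 / +-2 (log2) against the SD8 control,
#' and depths at the lower end of the 1e5-1e6 per-library range so the
#' default dataset runs on one CPU in minutes.
#'
#' @param n_scaffolds,scaffold_length toy genome dimensions.
#' @param n_known_mirna,n_novel_mirna planted miRNA loci.
#' @param n_rrna,n_trna,n_snrna,n_snorna,n_repeat,n_exon,n_intron planted
#'   feature counts per class.
#' @param n_transcripts toy target transcripts (each receives a perfect site
#'   for one novel miRNA while supplies last).
#' @param n_noise unmappable noise tags.
#' @param known_mirna_lengths,known_mirna_weights mature lengths (recycled)
#'   and relative abundances of the known miRNAs.
#' @param fc_c5,fc_ld3 planted log2 fold changes of the known miRNAs in C5 /
#'   LD3 relative to SD8 (recycled).
#' @param read_length raw read length (nt).
#' @param adapter3,adapter5 adapter sequences recorded in the manifest.
#' @param depths named vector of per-library raw read depths.
#' @param artifact_fractions named fractions of raw reads per removal
#'   category (`low_quality`, `adapter3_null`, `insert_null`,
#'   `adapter5_contaminants`, `smaller_than_18nt`, `polyA`).
#' @param class_fractions named fractions of clean reads per tag class
#'   (`known_mirna`, `novel_mirna`, `rRNA`, `tRNA`, `snRNA`, `snoRNA`,
#'   `repeat`, `exon`, `intron`, `noise`); must sum to 1.
#' @return validated config list of class `synth_config`.
#' @export
synth_config <- function(n_scaffolds = 3L, scaffold_length = 60000L,
                         n_known_mirna = 10L, n_novel_mirna = 6L,
                         n_rrna = 4L, n_trna = 4L, n_snrna = 2L,
                         n_snorna = 2L, n_repeat = 3L, n_exon = 5L,
                         n_intron = 5L, n_transcripts = 6L, n_noise = 20L,
                         known_mirna_lengths = 21L,
                         known_mirna_weights = NULL,
                         fc_c5 = c(0, 1, -1, 2, -2),
                         fc_ld3 = c(2, -2, 0, 1, -1),
                         read_length = 49L,
                         adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                         adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                         depths = c(SD8 = 1e5, C5 = 1e5, LD3 = 1e5),
                         artifact_fractions = c(
                           low_quality = 0.005, adapter3_null = 0.0005,
                           insert_null = 0.0002,
                           adapter5_contaminants = 0.0015,
                           smaller_than_18nt = 0.013, polyA = 0.0001),
                         class_fractions = c(
                           known_mirna = 0.22, novel_mirna = 0.02,
                           rRNA = 0.23, tRNA = 0.045, snRNA = 0.001,
                           snoRNA = 0.001, `repeat` = 0.029, exon = 0.025,
                           intron = 0.008, noise = 0.421)) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$artifact_fractions >= 0), all(cfg$class_fractions >= 0))
  if (sum(cfg$artifact_fractions) > 1) {
    stop("artifact fractions sum to more than 1")
  }
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9) {
    stop("class fractions must sum to 1")
  }
  if (is.null(names(depths)) || any(!nzchar(names(depths)))) {
    stop("depths must be a named vector of libraries")
  }
  if (is.null(cfg$known_mirna_weights) && n_known_mirna > 0) {
    cfg$known_mirna_weights <- rep(1, n_known_mirna)
  }
  class(cfg) <- "synth_config"
  cfg
}

RNG_ALPH <- c("A", "C", "G", "T")

random_seq <- function(n) {
  paste(sample(RNG_ALPH, n, replace = TRUE), collapse = "")
}

# a tag is clean-safe when the read cleaner will pass it through unchanged
clean_safe <- function(x, cfg) {
  a3 <- substr(cfg$adapter3, 1L, 6L)
  a5 <- substr(cfg$adapter5, 1L, 6L)
  !grepl(a3, x, fixed = TRUE) & !startsWith(x, a5) &
    !(grepl("AAAAAA", x, fixed = TRUE) &
        nchar(gsub("[^A]", "", x)) / nchar(x) >= 0.7)
}

draw_clean_safe <- function(n, cfg, forbid = character(0), gen) {
  out <- character(n)
  for (i in seq_len(n)) {
    for (attempt in 1:500) {
      cand <- gen()
      if (clean_safe(cand, cfg) && !(cand %in% forbid) && !(cand %in% out)) {
        out[i] <- cand
        break
      }
    }
    if (!nzchar(out[i])) stop("could not draw a clean-safe sequence")
  }
  out
}

#' Generate a toy genome with planted features
#'
#' Builds random scaffolds and plants non-overlapping features: known miRNA
#' loci (whose mature sequences form the bundled reference), novel miRNA
#' precursor hairpins (5' arm = mature, loop, 3' arm = reverse complement of
#' the mature, so the planted window folds into a stem-loop under the
#' package's own folding engine), and rRNA/tRNA/snRNA/snoRNA/repeat/exon/
#' intron intervals. Also generates toy target transcripts carrying perfect
#' complementary sites for novel miRNAs. Deterministic for a fixed
#' (config, seed).
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return object of class `toy_genome`: `scaffolds` (named character),
#'   `features` (data.frame feature_id/class/scaffold/start/end/strand),
#'   `known_mature` (named character), `novel` (data.frame of precursor and
#'   mature/star coordinates), `transcripts`, `target_sites`, `config`,
#'   `seed`.
#' @export
generate_toy_genome <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(seed, {
    scaffolds <- setNames(
      vapply(seq_len(config$n_scaffolds), function(i) {
        random_seq(config$scaffold_length)
      }, character(1)),
      sprintf("scaffold_%d", seq_len(config$n_scaffolds)))

    occupied <- lapply(scaffolds, function(s) cbind(start = integer(0),
                                                    end = integer(0)))
    place <- function(len) {
      if (config$n_scaffolds == 0L || len > config$scaffold_length) {
        stop("feature demand exceeds scaffold capacity")
      }
      for (attempt in 1:200) {
        sc <- sample(names(scaffolds), 1L)
        start <- sample.int(config$scaffold_length - len + 1L, 1L)
        end <- start + len - 1L
        occ <- occupied[[sc]]
        if (!nrow(occ) ||
            all(end + 10L < occ[, "start"] | start - 10L > occ[, "end"])) {
          occupied[[sc]] <<- rbind(occ, c(start, end))
          return(list(scaffold = sc, start = start, end = end))
        }
      }
      stop("feature demand exceeds scaffold capacity")
    }
    write_seq <- function(sc, start, sequence) {
      substr(scaffolds[[sc]], start, start + nchar(sequence) - 1L) <<- sequence
      invisible(NULL)
    }

    features <- list()
    add_feature <- function(id, class, sc, start, end, strand) {
      features[[length(features) + 1L]] <<- data.frame(
        feature_id = id, class = class, scaffold = sc, start = start,
        end = end, strand = strand, stringsAsFactors = FALSE)
    }

    # known miRNAs: clean-safe matures written into the genome
    known_mature <- character(0)
    if (config$n_known_mirna > 0L) {
      lens <- rep_len(config$known_mirna_lengths, config$n_known_mirna)
      seqs <- character(config$n_known_mirna)
      for (i in seq_len(config$n_known_mirna)) {
        seqs[i] <- draw_clean_safe(1L, config, forbid = seqs, gen = function() {
          body <- random_seq(lens[i] - 1L)
          first <- if (runif(1) < 0.6) "T" else sample(RNG_ALPH, 1L)
          paste0(first, body)
        })
      }
      known_mature <- setNames(seqs,
                               sprintf("syn-miR%03d", seq_along(seqs)))
      for (i in seq_along(seqs)) {
        loc <- place(nchar(seqs[i]))
        write_seq(loc$scaffold, loc$start, seqs[i])
        add_feature(names(known_mature)[i], "known_mirna", loc$scaffold,
                    loc$start, loc$end, "+")
      }
    }

    # novel miRNA precursors: arm + loop + reverse-complement arm
    novel <- NULL
    if (config$n_novel_mirna > 0L) {
      rows <- vector("list", config$n_novel_mirna)
      taken <- unname(known_mature)
      for (i in seq_len(config$n_novel_mirna)) {
        mlen <- sample(20:23, 1L)
        mature <- draw_clean_safe(1L, config, forbid = taken, gen = function() {
          body <- random_seq(mlen - 1L)
          first <- if (runif(1) < 0.85) "T" else sample(RNG_ALPH, 1L)
          paste0(first, body)
        })
        star <- revcomp(mature)
        if (!clean_safe(star, config) || star %in% taken) {
          # rare; redraw the mature so both arms survive cleaning
          mature <- draw_clean_safe(1L, config, forbid = c(taken, star),
                                    gen = function() {
                                      paste0("T", random_seq(mlen - 1L))
                                    })
          star <- revcomp(mature)
        }
        taken <- c(taken, mature, star)
        flank5 <- random_seq(8L)
        loop <- random_seq(10L)
        flank3 <- random_seq(8L)
        precursor <- paste0(flank5, mature, loop, star, flank3)
        loc <- place(nchar(precursor))
        write_seq(loc$scaffold, loc$start, precursor)
        id <- sprintf("syn-novel%03d", i)
        add_feature(id, "novel_mirna_precursor", loc$scaffold, loc$start,
                    loc$end, "+")
        rows[[i]] <- data.frame(
          mirna = id, mature = mature, star = star,
          scaffold = loc$scaffold, start = loc$start, end = loc$end,
          strand = "+",
          mature_start = loc$start + 8L,
          mature_end = loc$start + 8L + nchar(mature) - 1L,
          stringsAsFactors = FALSE)
      }
      novel <- do.call(rbind, rows)
    }

    # interval features on existing random sequence
    lens <- c(rRNA = 120L, tRNA = 75L, snRNA = 100L, snoRNA = 90L,
              `repeat` = 200L, exon = 300L, intron = 400L)
    nper <- c(rRNA = config$n_rrna, tRNA = config$n_trna,
              snRNA = config$n_snrna, snoRNA = config$n_snorna,
              `repeat` = config$n_repeat, exon = config$n_exon,
              intron = config$n_intron)
    for (cl in names(nper)) {
      for (i in seq_len(nper[[cl]])) {
        loc <- place(lens[[cl]])
        strand <- sample(c("+", "-"), 1L)
        add_feature(sprintf("syn-%s%03d", cl, i), cl, loc$scaffold,
                    loc$start, loc$end, strand)
      }
    }

    features <- if (length(features)) do.call(rbind, features) else
      data.frame(feature_id = character(0), class = character(0),
                 scaffold = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 stringsAsFactors = FALSE)
    rownames(features) <- NULL

    # toy transcripts with planted perfect sites for novel miRNAs
    transcripts <- character(0)
    target_sites <- data.frame(transcript = character(0),
                               mirna = character(0), start = integer(0),
                               end = integer(0), stringsAsFactors = FALSE)
    if (config$n_transcripts > 0L) {
      transcripts <- setNames(
        vapply(seq_len(config$n_transcripts), function(i) random_seq(600L),
               character(1)),
        sprintf("syn-tx%03d", seq_len(config$n_transcripts)))
      if (!is.null(novel)) {
        k <- min(nrow(novel), config$n_transcripts)
        for (i in seq_len(k)) {
          site <- revcomp(novel$mature[i])
          pos <- sample.int(600L - nchar(site) + 1L, 1L)
          tx <- names(transcripts)[i]
          substr(transcripts[[tx]], pos, pos + nchar(site) - 1L) <- site
          target_sites <- rbind(target_sites, data.frame(
            transcript = tx, mirna = novel$mirna[i], start = pos,
            end = pos + nchar(site) - 1L, stringsAsFactors = FALSE))
        }
      }
    }

    out <- list(scaffolds = scaffolds, features = features,
                known_mature = known_mature, novel = novel,
                transcripts = transcripts, target_sites = target_sites,
                config = config, seed = seed)
    class(out) <- "toy_genome"
    out
  })
}

feature_sequence <- function(genome, row) {
  s <- substr(genome$scaffolds[[row$scaffold]], row$start, row$end)
  if (row$strand == "-") revcomp(s) else s
}

# draw `n` clean-safe fragments (18-30 nt) from a feature's sense sequence;
# antisense = TRUE reverse-complements them (an antisense-strand read)
feature_fragments <- function(genome, row, n, cfg, antisense = FALSE,
                              forbid = character(0)) {
  fseq <- feature_sequence(genome, row)
  draw_clean_safe(n, cfg, forbid = forbid, gen = function() {
    w <- sample(18:30, 1L)
    start <- sample.int(nchar(fseq) - w + 1L, 1L)
    frag <- substr(fseq, start, start + w - 1L)
    if (antisense) revcomp(frag) else frag
  })
}

#' Simulate the three raw FASTQ libraries with a ground-truth manifest
#'
#' Builds the tag pool from the planted genome features (known and novel
#' matures, star arms, ncRNA / repeat / degradation fragments, unmappable
#' noise), applies the planted per-library fold changes to known miRNAs, and
#' samples each library: artifact reads are planted at exactly
#' `round(fraction * depth)` per removal category, and the remaining clean
#' reads are drawn multinomially over tag weights. Reads are
#' `insert + 3' adapter + random fill` at fixed read length, Phred+33
#' qualities on a two-level model (high for everything except planted
#' low-quality reads). Deterministic for fixed (genome, seed); the number of
#' reads per library equals the requested depth exactly.
#'
#' @param genome a [generate_toy_genome()] result.
#' @param seed integer seed.
#' @param depths optional override of `genome$config$depths`.
#' @return object of class `srna_simulation`: `libraries` (per library:
#'   `sequences`, `qualities`, `ids`), and `manifest` with `tags` (per-tag
#'   class, weights, expected and realized clean counts per library),
#'   `artifacts` (planted category counts per library), `fold_changes`,
#'   `adapters`, `depths`, `seed`.
#' @export
simulate_libraries <- function(genome, seed = 1L, depths = NULL) {
  stopifnot(inherits(genome, "toy_genome"))
  cfg <- genome$config
  if (is.null(depths)) depths <- cfg$depths
  if (sum(depths) <= 0) stop("zero total depth")
  libs <- names(depths)

  local_seed(seed + 1000L, {
    # ---- tag pool with base weights ----
    tag_rows <- list()
    add_tags <- function(seqs, class, feature_id, w) {
      tag_rows[[length(tag_rows) + 1L]] <<- data.frame(
        sequence = seqs, class = class, feature_id = feature_id,
        base_weight = w, stringsAsFactors = FALSE)
    }
    frac <- cfg$class_fractions
    pool_seqs <- function() unlist(lapply(tag_rows, `[[`, "sequence"))

    if (length(genome$known_mature) && frac[["known_mirna"]] > 0) {
      w <- cfg$known_mirna_weights / sum(cfg$known_mirna_weights)
      add_tags(unname(genome$known_mature), "known_mirna",
               names(genome$known_mature), frac[["known_mirna"]] * w)
    }
    if (!is.null(genome$novel) && frac[["novel_mirna"]] > 0) {
      n <- nrow(genome$novel)
      add_tags(genome$novel$mature, "novel_mirna", genome$novel$mirna,
               frac[["novel_mirna"]] * 0.9 / n)
      add_tags(genome$novel$star, "novel_star",
               paste0(genome$novel$mirna, "*"),
               frac[["novel_mirna"]] * 0.1 / n)
    }
    for (cl in c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")) {
      rows <- genome$features[genome$features$class == cl, , drop = FALSE]
      if (!nrow(rows) || frac[[cl]] == 0) next
      nfrag <- 3L
      for (i in seq_len(nrow(rows))) {
        frags <- feature_fragments(genome, rows[i, ], nfrag, cfg,
                                   forbid = pool_seqs())
        add_tags(frags, cl, rows$feature_id[i],
                 rep(frac[[cl]] / (nrow(rows) * nfrag), nfrag))
      }
    }
    for (cl in c("exon", "intron")) {
      rows <- genome$features[genome$features$class == cl, , drop = FALSE]
      if (!nrow(rows) || frac[[cl]] == 0) next
      for (i in seq_len(nrow(rows))) {
        sense <- feature_fragments(genome, rows[i, ], 2L, cfg,
                                   forbid = pool_seqs())
        anti <- feature_fragments(genome, rows[i, ], 1L, cfg,
                                  antisense = TRUE,
                                  forbid = c(pool_seqs(), sense))
        w <- frac[[cl]] / (nrow(rows) * 3L)
        add_tags(sense, paste0(cl, "_sense"), rows$feature_id[i], rep(w, 2L))
        add_tags(anti, paste0(cl, "_antisense"), rows$feature_id[i], w)
      }
    }
    if (cfg$n_noise > 0L && frac[["noise"]] > 0) {
      gset <- Biostrings::DNAStringSet(genome$scaffolds)
      noise <- draw_clean_safe(cfg$n_noise, cfg, forbid = pool_seqs(),
                               gen = function() random_seq(sample(18:30, 1L)))
      # reject any noise tag that happens to map to the toy genome
      for (i in seq_along(noise)) {
        while (sum(Biostrings::vcountPattern(noise[i], gset)) +
               sum(Biostrings::vcountPattern(revcomp(noise[i]), gset)) > 0) {
          noise[i] <- draw_clean_safe(1L, cfg, forbid = c(pool_seqs(), noise),
                                      gen = function() {
                                        random_seq(sample(18:30, 1L))
                                      })
        }
      }
      add_tags(noise, "noise", NA_character_,
               rep(frac[["noise"]] / cfg$n_noise, cfg$n_noise))
    }
    tags <- if (length(tag_rows)) do.call(rbind, tag_rows) else
      data.frame(sequence = character(0), class = character(0),
                 feature_id = character(0), base_weight = numeric(0),
                 stringsAsFactors = FALSE)
    rownames(tags) <- NULL

    # ---- per-library weights: planted fold changes on known miRNAs ----
    fc <- NULL
    if (length(genome$known_mature)) {
      fc <- data.frame(
        mirna = names(genome$known_mature),
        SD8 = 0,
        C5 = rep_len(cfg$fc_c5, length(genome$known_mature)),
        LD3 = rep_len(cfg$fc_ld3, length(genome$known_mature)),
        stringsAsFactors = FALSE)
    }
    # planted fold changes multiply known-miRNA weights; the noise class
    # absorbs the slack so every planted tag keeps its nominal expected
    # fraction in every library (fold changes are exact in expectation)
    weights <- vapply(libs, function(lib) {
      w <- tags$base_weight
      if (!is.null(fc) && lib %in% names(fc)) {
        idx <- match(tags$feature_id, fc$mirna)
        mult <- ifelse(is.na(idx), 1, 2^fc[[lib]][idx])
        w <- w * ifelse(tags$class == "known_mirna", mult, 1)
      }
      noise <- tags$class == "noise"
      slack <- 1 - sum(w[!noise])
      if (any(noise) && slack > 0) {
        w[noise] <- w[noise] * slack / sum(w[noise])
      }
      w / sum(w)
    }, numeric(nrow(tags)))
    if (nrow(tags) == 1L) {
      weights <- matrix(weights, nrow = 1L, dimnames = list(NULL, libs))
    }

    # ---- sample each library ----
    art_names <- names(cfg$artifact_fractions)
    a3 <- cfg$adapter3
    a5 <- cfg$adapter5
    rl <- cfg$read_length
    finish_read <- function(inserts) {
      core <- paste0(inserts, a3)
      pad_len <- pmax(0L, rl - nchar(core))
      total <- sum(pad_len)
      pads <- character(length(inserts))
      if (total > 0) {
        big <- paste(sample(RNG_ALPH, total, replace = TRUE), collapse = "")
        ends <- cumsum(pad_len)
        pads <- substring(big, ends - pad_len + 1L, ends)
        pads[pad_len == 0L] <- ""
      }
      substring(paste0(core, pads), 1L, rl)
    }
    draw_artifact <- function(cat) {
      if (cat == "adapter3_null") {
        repeat {
          r <- random_seq(rl)
          if (!grepl(substr(a3, 1, 6), r, fixed = TRUE)) return(r)
        }
      } else if (cat == "insert_null") {
        finish_read("")
      } else if (cat == "adapter5_contaminants") {
        repeat {
          ins <- paste0(substr(a5, 1, 8), random_seq(12L))
          if (!grepl(substr(a3, 1, 6), ins, fixed = TRUE)) return(finish_read(ins))
        }
      } else if (cat == "smaller_than_18nt") {
        repeat {
          ins <- random_seq(sample(10:17, 1L))
          if (clean_safe(ins, cfg)) return(finish_read(ins))
        }
      } else if (cat == "polyA") {
        finish_read(strrep("A", 22L))
      } else stop("unknown artifact: ", cat)
    }

    libraries <- list()
    realized <- matrix(0L, nrow(tags), length(libs),
                       dimnames = list(NULL, libs))
    expected <- realized
    artifacts <- matrix(0L, length(art_names) , length(libs),
                        dimnames = list(art_names, libs))
    for (lib in libs) {
      depth <- as.integer(depths[[lib]])
      if (depth <= 0) stop("zero total depth for library ", lib)
      n_art <- setNames(as.integer(round(cfg$artifact_fractions * depth)),
                        art_names)
      clean_total <- depth - sum(n_art)
      if (clean_total < 0) stop("artifact fractions exceed depth")
      artifacts[, lib] <- n_art

      counts <- if (nrow(tags)) {
        as.integer(rmultinom(1L, clean_total, weights[, lib]))
      } else integer(0)
      if (!nrow(tags) && clean_total > 0) {
        stop("no tags to sample clean reads from")
      }
      realized[, lib] <- counts
      expected[, lib] <- clean_total * weights[, lib]

      clean_reads <- rep(tags$sequence, counts)
      seqs <- finish_read(clean_reads)
      quals <- rep(strrep("I", rl), length(seqs))

      # low-quality reads: ordinary tag reads with a bad quality string
      if (n_art[["low_quality"]] > 0L) {
        lq_tags <- tags$sequence[sample.int(nrow(tags),
                                            n_art[["low_quality"]],
                                            replace = TRUE,
                                            prob = weights[, lib])]
        seqs <- c(seqs, finish_read(lq_tags))
        quals <- c(quals, rep(strrep("#", rl), n_art[["low_quality"]]))
      }
      for (cat in setdiff(art_names, "low_quality")) {
        if (n_art[[cat]] > 0L) {
          seqs <- c(seqs, vapply(seq_len(n_art[[cat]]),
                                 function(i) draw_artifact(cat),
                                 character(1)))
          quals <- c(quals, rep(strrep("I", rl), n_art[[cat]]))
        }
      }
      stopifnot(length(seqs) == depth)
      ord <- sample.int(depth)
      libraries[[lib]] <- list(
        sequences = seqs[ord], qualities = quals[ord],
        ids = sprintf("%s_%07d", lib, seq_len(depth)))
    }

    tag_table <- cbind(
      tags[, c("sequence", "class", "feature_id")],
      setNames(as.data.frame(expected), paste0("expected_", libs)),
      setNames(as.data.frame(realized), paste0("count_", libs)))

    out <- list(
      libraries = libraries,
      manifest = list(tags = tag_table, artifacts = artifacts,
                      fold_changes = fc, adapters = c(adapter3 = a3,
                                                      adapter5 = a5),
                      artifact_fractions = cfg$artifact_fractions,
                      class_fractions = cfg$class_fractions,
                      depths = depths, seed = seed))
    class(out) <- "srna_simulation"
    out
  })
}

#' Write a simulation to FASTQ files
#'
#' @param sim a [simulate_libraries()] result.
#' @param outdir output directory (created if needed).
#' @return named vector of FASTQ paths.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "srna_simulation"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  vapply(names(sim$libraries), function(lib) {
    x <- sim$libraries[[lib]]
    write_fastq(x$sequences, x$qualities, x$ids,
                file.path(outdir, paste0(lib, ".fastq")))
  }, character(1))
}

#' Write the toy genome, annotation and references to disk
#'
#' Emits the genome FASTA, a GFF3 of planted features (1-based inclusive
#' coordinates), the mature known-miRNA reference FASTA, per-class ncRNA
#' reference FASTAs, and the toy transcript FASTA.
#'
#' @param genome a [generate_toy_genome()] result.
#' @param outdir output directory.
#' @return named vector of written paths.
#' @export
write_genome_files <- function(genome, outdir) {
  stopifnot(inherits(genome, "toy_genome"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"),
             gff = file.path(outdir, "features.gff3"),
             mature = file.path(outdir, "mature_mirnas.fa"),
             transcripts = file.path(outdir, "transcripts.fa"))
  write_fasta(genome$scaffolds, paths[["genome"]])
  f <- genome$features
  gff <- c("##gff-version 3",
           if (nrow(f)) sprintf("%s\tsrnapipe\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                                f$scaffold, f$class, f$start, f$end,
                                f$strand, f$feature_id))
  writeLines(gff, paths[["gff"]])
  write_fasta(genome$known_mature, paths[["mature"]])
  write_fasta(genome$transcripts, paths[["transcripts"]])
  paths
}

#' Read a features GFF3 written by [write_genome_files()]
#' @param path GFF3 file.
#' @return data.frame feature_id/class/scaffold/start/end/strand.
#' @export
read_features_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) {
    return(data.frame(feature_id = character(0), class = character(0),
                      scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  parts <- strsplit(ln, "\t", fixed = TRUE)
  data.frame(
    feature_id = sub("^ID=", "", vapply(parts, `[[`, "", 9L)),
    class = vapply(parts, `[[`, "", 3L),
    scaffold = vapply(parts, `[[`, "", 1L),
    start = as.integer(vapply(parts, `[[`, "", 4L)),
    end = as.integer(vapply(parts, `[[`, "", 5L)),
    strand = vapply(parts, `[[`, "", 7L),
    stringsAsFactors = FALSE)
}
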