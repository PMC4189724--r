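#' Extract candidate precursor windows around unannotated tag clusters
#'
#' Merges genome hits of unannotated tags on the same scaffold and strand
#' into clusters (tags closer than `merge_dist` join one cluster) and extends
#' each cluster by `flank` nucleotides on both sides, clipping at scaffold
#' edges. Each window is a candidate precursor in which the tag may sit on
#' either arm.
#'
#' @param hits a [map_tags()] result restricted to unannotated tags.
#' @param genome genome as accepted by [map_tags()].
#' @param flank flanking nucleotides on each side (default 150).
#' @param merge_dist maximum gap between tags in one cluster (default 50).
#' @return data.frame: `scaffold`, `start`, `end`, `strand` (window), plus
#'   `tags` (comma-separated member tags).
#' @export
extract_candidates <- function(hits, genome, flank = 150L, merge_dist = 50L) {
  genome <- as_genome_set(genome)
  if (!nrow(hits)) {
    return(data.frame(scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      tags = character(0), stringsAsFactors = FALSE))
  }
  slen <- setNames(Biostrings::width(genome), names(genome))
  out <- list()
  for (key in unique(paste(hits$scaffold, hits$strand))) {
    sub <- hits[paste(hits$scaffold, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cl_start <- sub$start[1]; cl_end <- sub$end[1]
    members <- sub$tag[1]
    flush <- function(s, e, m) {
      sc <- sub$scaffold[1]
      out[[length(out) + 1L]] <<- data.frame(
        scaffold = sc,
        start = max(1L, s - flank),
        end = min(slen[[sc]], e + flank),
        strand = sub$strand[1],
        tags = paste(unique(m), collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (nrow(sub) > 1L) {
      for (i in 2:nrow(sub)) {
        if (sub$start[i] - cl_end - 1L <= merge_dist) {
          cl_end <- max(cl_end, sub$end[i])
          members <- c(members, sub$tag[i])
        } else {
          flush(cl_start, cl_end, members)
          cl_start <- sub$start[i]; cl_end <- sub$end[i]
          members <- sub$tag[i]
        }
      }
    }
    flush(cl_start, cl_end, members)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$scaffold, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# duplex screening of a mature region within a folded precursor:
# pairedness, loop avoidance, and bulge asymmetry of the mature:star duplex
mature_duplex_stats <- function(structure, mature_start, mature_end) {
  partner <- pairing_table(structure)
  pos <- mature_start:mature_end
  part <- partner[pos]
  paired <- sum(!is.na(part))
  self_pairing <- any(!is.na(part) & part >= mature_start & part <= mature_end)
  max_bulge <- 0L
  pp <- pos[!is.na(part)]
  if (length(pp) >= 2L) {
    q <- partner[pp]
    for (i in seq_len(length(pp) - 1L)) {
      gap_m <- pp[i + 1L] - pp[i] - 1L
      gap_s <- q[i] - q[i + 1L] - 1L
      if (gap_s < 0L) { self_pairing <- TRUE; next }  # partner not monotone
      max_bulge <- max(max_bulge, abs(gap_m - gap_s))
    }
  }
  list(paired = paired, spans_loop = self_pairing, max_bulge = max_bulge)
}

#' Fold and screen precursor windows into hairpin candidates
#'
#' For each window: folds the precursor with [fold_hairpin()], picks the
#' mature arm as the most abundant member tag (ties broken by the 5'-most
#' position in the window), locates the star arm as the region pairing the
#' mature, and records the screening verdicts used by [screen_candidates()]:
#' `length_ok` (mature 20-23 nt), `count_ok` (more than `min_count` reads in
#' at least one library), `duplex_ok` (at least `min_paired` mature bases
#' paired, a maximum asymmetric bulge of `max_bulge` nt in the duplex, and a
#' mature that does not span the loop), `energy_ok` (MFE at or below
#' `mfe_max` kcal/mol).
#'
#' @param windows an [extract_candidates()] result.
#' @param genome genome as accepted by [map_tags()].
#' @param tags data.frame: `sequence` plus per-library count columns.
#' @param min_count read-count threshold: accepted when count > this value in
#'   at least one library (default 5).
#' @param min_paired minimum paired mature bases (default 16).
#' @param max_bulge maximum asymmetric bulge in the duplex (default 4).
#' @param mfe_max MFE acceptance threshold, kcal/mol (default -18).
#' @param params,backend folding model, see [fold_hairpin()].
#' @return data.frame of class `hairpin_candidates`: one row per window with
#'   precursor locus and sequence, dot-bracket `structure`, `mfe`, mature
#'   sequence/arm/coordinates, star sequence and `star_observed`, per-library
#'   mature counts, and the four screening flags.
#' @export
hairpin_candidates <- function(windows, genome, tags,
                               min_count = 5L, min_paired = 16L,
                               max_bulge = 4L, mfe_max = -18,
                               params = fold_energy_params(),
                               backend = NULL) {
  genome <- as_genome_set(genome)
  libs <- setdiff(names(tags), "sequence")
  counts <- as.matrix(tags[, libs, drop = FALSE])
  rownames(counts) <- tags$sequence
  rows <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows[i, ]
    prec <- as.character(Biostrings::subseq(genome[[w$scaffold]],
                                            w$start, w$end))
    if (w$strand == "-") prec <- revcomp(prec)
    fold <- fold_hairpin(prec, params = params, backend = backend)
    members <- strsplit(w$tags, ",", fixed = TRUE)[[1]]
    members <- members[members %in% rownames(counts)]
    if (!length(members)) next
    tot <- rowSums(counts[members, , drop = FALSE])
    # most abundant tag is the mature; ties break 5'-most in the precursor
    mpos <- vapply(members, function(m) {
      p <- regexpr(m, prec, fixed = TRUE)
      as.integer(p)
    }, integer(1))
    members <- members[mpos > 0L]; tot <- tot[mpos > 0L]
    mpos <- mpos[mpos > 0L]
    if (!length(members)) next
    ord <- order(-tot, mpos)
    mature <- members[ord[1L]]
    mstart <- mpos[ord[1L]]
    mend <- mstart + nchar(mature) - 1L
    dup <- mature_duplex_stats(fold$structure, mstart, mend)
    # star arm: the window pairing the mature (outermost partners)
    partner <- pairing_table(fold$structure)
    part <- partner[mstart:mend]
    star_seq <- NA_character_
    if (any(!is.na(part))) {
      srange <- range(part, na.rm = TRUE)
      star_seq <- substr(prec, srange[1], srange[2])
    }
    mcounts <- counts[mature, , drop = TRUE]
    rows[[i]] <- data.frame(
      scaffold = w$scaffold, start = w$start, end = w$end,
      strand = w$strand,
      locus = sprintf("%s:%d:%d", w$scaffold, w$start, w$end),
      precursor = prec, structure = fold$structure, mfe = fold$mfe,
      mature = mature, mature_start = mstart, mature_end = mend,
      mature_arm = if (!is.na(star_seq) &&
                       mstart < min(partner[mstart:mend], na.rm = TRUE))
        "5p" else "3p",
      star = star_seq,
      star_observed = !is.na(star_seq) && star_seq %in% rownames(counts),
      t(mcounts),
      length_ok = nchar(mature) >= 20L && nchar(mature) <= 23L,
      count_ok = any(mcounts > min_count),
      duplex_ok = dup$paired >= min_paired && !dup$spans_loop &&
        dup$max_bulge <= max_bulge,
      energy_ok = fold$mfe <= mfe_max,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame()
  }
  class(res) <- c("hairpin_candidates", class(res))
  res
}

#' Accept novel miRNAs from screened hairpin candidates
#'
#' A candidate is accepted when all four verdicts hold: mature length 20-23
#' nt, read count above the threshold in at least one library, duplex
#' criteria satisfied, and MFE at or below the acceptance threshold.
#' Candidates are deduplicated across loci and libraries by mature sequence,
#' keeping the lowest-MFE locus (ties: first by locus order). The result is
#' independent of candidate input order.
#'
#' @param candidates a [hairpin_candidates()] result.
#' @return the accepted subset, one row per unique mature sequence.
#' @export
screen_candidates <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  ok <- candidates$length_ok & candidates$count_ok &
    candidates$duplex_ok & candidates$energy_ok
  acc <- candidates[ok, , drop = FALSE]
  if (!nrow(acc)) return(acc)
  acc <- acc[order(acc$mature, acc$mfe, acc$locus), , drop = FALSE]
  acc <- acc[!duplicated(acc$mature), , drop = FALSE]
  acc <- acc[order(acc$locus), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

#' Summary statistics of accepted novel miRNAs
#'
#' @param accepted a [screen_candidates()] result (nonempty).
#' @param libs count columns to report per-library candidate counts for
#'   (default: columns starting with `count_` or matching library names).
#' @return list with `n` (total accepted), `per_library` (candidates with a
#'   positive count per library), `mfe_mean`, `mfe_sd` (sample sd), and
#'   `u5_fraction` (fraction of matures beginning with uridine).
#' @export
novel_mirna_stats <- function(accepted, libs = NULL) {
  if (!nrow(accepted)) stop("empty accepted candidate set")
  if (is.null(libs)) {
    libs <- setdiff(names(accepted),
                    c("scaffold", "start", "end", "strand", "locus",
                      "precursor", "structure", "mfe", "mature",
                      "mature_start", "mature_end", "mature_arm", "star",
                      "star_observed", "length_ok", "count_ok", "duplex_ok",
                      "energy_ok"))
  }
  per_lib <- vapply(libs, function(l) sum(accepted[[l]] > 0), numeric(1))
  list(n = nrow(accepted),
       per_library = per_lib,
       mfe_mean = mean(accepted$mfe),
       mfe_sd = if (nrow(accepted) > 1L) sd(accepted$mfe) else 0,
       u5_fraction = mean(startsWith(chartr("U", "T", accepted$mature), "T")))
}

#' Build dinucleotide-shuffled decoy candidates
#'
#' Shuffles each candidate's precursor while preserving dinucleotide
#' composition, refolds it, and re-evaluates the structural verdicts at the
#' same mature coordinates with the original counts carried over. This is
#' the standard permutation control: true hairpins should survive screening
#' while shuffled decoys mostly fail the duplex and energy criteria.
#'
#' @param candidates a [hairpin_candidates()] result.
#' @param min_paired,max_bulge,mfe_max screening constants as in
#'   [hairpin_candidates()].
#' @param params,backend folding model.
#' @return candidates table for the decoys (same columns).
#' @export
shuffle_decoys <- function(candidates, min_paired = 16L, max_bulge = 4L,
                           mfe_max = -18, params = fold_energy_params(),
                           backend = NULL) {
  out <- candidates
  for (i in seq_len(nrow(candidates))) {
    prec <- dinucleotide_shuffle(candidates$precursor[i])
    fold <- fold_hairpin(prec, params = params, backend = backend)
    ms <- candidates$mature_start[i]
    me <- candidates$mature_end[i]
    dup <- mature_duplex_stats(fold$structure, ms, me)
    out$precursor[i] <- prec
    out$structure[i] <- fold$structure
    out$mfe[i] <- fold$mfe
    out$mature[i] <- substr(prec, ms, me)
    out$duplex_ok[i] <- dup$paired >= min_paired && !dup$spans_loop &&
      dup$max_bulge <= max_bulge
    out$energy_ok[i] <- fold$mfe <= mfe_max
  }
  out
}
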