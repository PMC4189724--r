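ANNOTATION_CATEGORIES <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA",
                           "repeat", "exon_sense", "exon_antisense",
                           "intron_sense", "intron_antisense", "unannotated")

# feature-class precedence for hierarchical classification (highest first);
# miRNA assignment is sequence-level and outranks all of these
CLASS_PRIORITY <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat", "exon",
                    "intron")

as_genome_set <- function(genome) {
  if (inherits(genome, "toy_genome")) genome <- genome$scaffolds
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stop("empty genome")
  }
  genome
}

#' Map clean tags to a genome by exact matching
#'
#' Reports every perfect (0-mismatch) occurrence of each tag on both strands,
#' with 1-based inclusive coordinates. Minus-strand hits are loci whose
#' reverse complement equals the tag.
#'
#' @param tags character vector of tag sequences, or a data.frame with a
#'   `sequence` column.
#' @param genome named character vector, `DNAStringSet`, FASTA path, or a
#'   [generate_toy_genome()] object.
#' @return data.frame with columns `tag`, `scaffold`, `start`, `end`,
#'   `strand`, `mismatches` (always 0). Tags with no hit are recorded in the
#'   `unmapped` attribute.
#' @export
map_tags <- function(tags, genome) {
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- unique(norm_dna(tags, allow_n = FALSE))
  genome <- as_genome_set(genome)
  out <- vector("list", 2L * length(tags))
  k <- 0L
  for (tag in tags) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else revcomp(tag)
      m <- Biostrings::vmatchPattern(pat, genome)
      st <- S4Vectors::elementNROWS(m)
      if (any(st > 0L)) {
        hits <- do.call(rbind, lapply(which(st > 0L), function(si) {
          r <- m[[si]]
          data.frame(tag = tag, scaffold = names(genome)[si],
                     start = BiocGenerics::start(r), end = BiocGenerics::end(r),
                     strand = strand, mismatches = 0L,
                     stringsAsFactors = FALSE)
        }))
        k <- k + 1L
        out[[k]] <- hits
      }
    }
  }
  hits <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(tag = character(0), scaffold = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  attr(hits, "unmapped") <- setdiff(tags, hits$tag)
  hits
}

#' Composition report with recomputed percentages
#'
#' Validates that per-category unique-tag and total-read counts sum to the
#' library totals, and recomputes two-decimal percentages of those totals.
#'
#' @param counts data.frame with a `category` column whose first row `all`
#'   holds library totals, followed by one row per annotation category, and
#'   paired `<lib>_unique` / `<lib>_total` count columns.
#' @return the input with a `<col>_pct` column added per count column;
#'   class `composition_report`.
#' @export
composition_report <- function(counts) {
  stopifnot(is.data.frame(counts), counts$category[1] == "all")
  num_cols <- setdiff(names(counts), "category")
  for (cc in num_cols) {
    total <- counts[[cc]][1]
    body <- counts[[cc]][-1]
    if (sum(body) != total) {
      stop("category counts for ", cc, " sum to ", sum(body),
           ", expected ", total)
    }
    counts[[paste0(cc, "_pct")]] <- round_half_up(100 * counts[[cc]] / total, 2L)
  }
  class(counts) <- c("composition_report", class(counts))
  counts
}

#' Hierarchically classify mapped tags into annotation categories
#'
#' Each tag receives exactly one category. A tag equal to a mature reference
#' miRNA (after U/T normalization) is `miRNA` regardless of its genomic hits;
#' otherwise the highest-priority feature class overlapped by any of its hits
#' wins, in the order rRNA > tRNA > snRNA > snoRNA > repeat > exon > intron.
#' Exon and intron assignments are split into `_sense` / `_antisense` by
#' comparing hit and feature strands. Ties at equal priority break on the
#' lexicographically smallest feature id. Tags with no qualifying overlap
#' (including unmapped tags) are `unannotated`.
#'
#' @param hits a [map_tags()] result.
#' @param tags data.frame: `sequence` plus one count column per library.
#' @param features data.frame of genomic features: `feature_id`, `class`
#'   (rRNA/tRNA/snRNA/snoRNA/repeat/exon/intron; other classes are ignored),
#'   `scaffold`, `start`, `end`, `strand`. May be NULL (no features).
#' @param mature_ref named character vector of mature miRNA sequences
#'   (optional).
#' @return list with `records` (data.frame `tag`, `category`, `reference_id`)
#'   and `report` (a [composition_report()] over the count columns of `tags`).
#' @export
classify <- function(hits, tags, features = NULL, mature_ref = NULL) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  libs <- setdiff(names(tags), "sequence")
  tag_seq <- tags$sequence
  category <- rep("unannotated", length(tag_seq))
  ref_id <- rep(NA_character_, length(tag_seq))

  if (!is.null(mature_ref)) {
    mm <- match_known(tag_seq, mature_ref)
    category[!is.na(mm)] <- "miRNA"
    ref_id[!is.na(mm)] <- mm[!is.na(mm)]
  }

  if (!is.null(features) && nrow(features) && nrow(hits)) {
    features <- features[features$class %in% CLASS_PRIORITY, , drop = FALSE]
  }
  if (!is.null(features) && nrow(features) && nrow(hits)) {
    fgr <- GenomicRanges::GRanges(
      features$scaffold,
      IRanges::IRanges(features$start, features$end))
    hgr <- GenomicRanges::GRanges(
      hits$scaffold, IRanges::IRanges(hits$start, hits$end))
    ov <- GenomicRanges::findOverlaps(hgr, fgr)
    if (length(ov)) {
      qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
      cand <- data.frame(
        tag = hits$tag[qi],
        class = features$class[si],
        feature_id = features$feature_id[si],
        sense = hits$strand[qi] == features$strand[si],
        stringsAsFactors = FALSE)
      cand$rank <- match(cand$class, CLASS_PRIORITY)
      cand <- cand[order(cand$tag, cand$rank, cand$feature_id), , drop = FALSE]
      best <- cand[!duplicated(cand$tag), , drop = FALSE]
      idx <- match(best$tag, tag_seq)
      sel <- !is.na(idx) & category[idx] == "unannotated"
      idx <- idx[sel]; best <- best[sel, , drop = FALSE]
      cat_name <- ifelse(best$class %in% c("exon", "intron"),
                         paste0(best$class,
                                ifelse(best$sense, "_sense", "_antisense")),
                         best$class)
      category[idx] <- cat_name
      ref_id[idx] <- best$feature_id
    }
  }

  records <- data.frame(tag = tag_seq, category = category,
                        reference_id = ref_id, stringsAsFactors = FALSE)

  cnt <- as.matrix(tags[, libs, drop = FALSE])
  counts <- data.frame(category = c("all", ANNOTATION_CATEGORIES))
  for (lib in libs) {
    uniq <- vapply(ANNOTATION_CATEGORIES, function(cc) {
      sum(cnt[, lib] > 0 & category == cc)
    }, numeric(1))
    tot <- vapply(ANNOTATION_CATEGORIES, function(cc) {
      sum(cnt[category == cc, lib])
    }, numeric(1))
    counts[[paste0(lib, "_unique")]] <- c(sum(cnt[, lib] > 0), uniq)
    counts[[paste0(lib, "_total")]] <- c(sum(cnt[, lib]), tot)
  }
  list(records = records, report = composition_report(counts))
}

# exact sequence-level matching of tags to mature reference miRNAs;
# returns the matched reference id (lexicographically first on duplicates)
match_known <- function(tag_seq, mature_ref) {
  if (is.null(names(mature_ref)) || any(!nzchar(names(mature_ref)))) {
    stop("mature reference sequences must be named")
  }
  if (anyDuplicated(names(mature_ref))) {
    stop("duplicate reference ids: ",
         paste(unique(names(mature_ref)[duplicated(names(mature_ref))]),
               collapse = ", "))
  }
  ref <- setNames(norm_dna(unname(mature_ref), allow_n = FALSE),
                  names(mature_ref))
  ref <- ref[order(names(ref))]
  names(ref)[match(norm_dna(tag_seq, allow_n = FALSE), ref)]
}

#' Quantify known miRNAs by exact match to a mature reference
#'
#' A tag is assigned to a known miRNA if and only if it equals the mature
#' reference sequence exactly (after U/T normalization); one mismatch is
#' enough to leave it unassigned. Per-miRNA counts are sums over assigned
#' tags in each library.
#'
#' @param tags data.frame: `sequence` plus one count column per library.
#' @param mature_ref named character vector of mature miRNA sequences.
#' @return data.frame `mirna`, `sequence`, then per-library counts; one row
#'   per reference miRNA detected in at least one library.
#' @export
identify_known_mirnas <- function(tags, mature_ref) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  libs <- setdiff(names(tags), "sequence")
  mm <- match_known(tags$sequence, mature_ref)
  hit <- !is.na(mm)
  if (!any(hit)) {
    out <- data.frame(mirna = character(0), sequence = character(0))
    for (lib in libs) out[[lib]] <- integer(0)
    return(out)
  }
  agg <- stats::aggregate(tags[hit, libs, drop = FALSE],
                          by = list(mirna = mm[hit]), FUN = sum)
  seqs <- setNames(norm_dna(unname(mature_ref)), names(mature_ref))
  out <- data.frame(mirna = agg$mirna, sequence = unname(seqs[agg$mirna]),
                    agg[, libs, drop = FALSE], stringsAsFactors = FALSE,
                    check.names = FALSE)
  out <- out[order(out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  out
}
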