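CLEANING_CATEGORIES <- c("adapter3_null", "insert_null",
                         "adapter5_contaminants", "smaller_than_18nt",
                         "polyA", "clean_reads")

#' Build and validate a read-cleaning report
#'
#' A cleaning report accounts for every raw read exactly once: low-quality
#' reads are removed first (`high_quality = total_reads - low_quality`), and
#' every high-quality read falls into exactly one of five removal categories
#' or `clean_reads`. Percentages are recomputed from counts relative to the
#' high-quality total and rounded half-up to two decimals, the convention of
#' published per-library accounting tables.
#'
#' @param counts named numeric vector with `total_reads`, `high_quality`, and
#'   the five removal categories (`adapter3_null`, `insert_null`,
#'   `adapter5_contaminants`, `smaller_than_18nt`, `polyA`). `clean_reads`
#'   may be supplied (then checked) or omitted (then derived by subtraction).
#' @param library name of the library (optional).
#' @return a `cleaning_report` data.frame with columns `category`, `count`,
#'   `percent` (two decimals; NA for `total_reads`).
#' @export
cleaning_report <- function(counts, library = NA_character_) {
  counts <- unlist(counts)
  need <- c("total_reads", "high_quality", "adapter3_null", "insert_null",
            "adapter5_contaminants", "smaller_than_18nt", "polyA")
  missing <- setdiff(need, names(counts))
  if (length(missing)) stop("missing counts: ", paste(missing, collapse = ", "))
  removed <- sum(counts[c("adapter3_null", "insert_null",
                          "adapter5_contaminants", "smaller_than_18nt",
                          "polyA")])
  clean <- counts[["high_quality"]] - removed
  if ("clean_reads" %in% names(counts) &&
      counts[["clean_reads"]] != clean) {
    stop("cleaning report does not balance: high_quality (",
         counts[["high_quality"]], ") != removals (", removed,
         ") + clean_reads (", counts[["clean_reads"]], ")")
  }
  if (clean < 0) stop("removal categories exceed the high-quality total")
  if (counts[["high_quality"]] > counts[["total_reads"]]) {
    stop("high_quality exceeds total_reads")
  }
  cats <- c("total_reads", "high_quality", "adapter3_null", "insert_null",
            "adapter5_contaminants", "smaller_than_18nt", "polyA",
            "clean_reads")
  cnt <- c(counts[need], clean_reads = unname(clean))[cats]
  pct <- round_half_up(100 * cnt / cnt[["high_quality"]], 2L)
  pct[["total_reads"]] <- NA_real_
  out <- data.frame(category = cats, count = unname(cnt),
                    percent = unname(pct), stringsAsFactors = FALSE)
  attr(out, "library") <- library
  class(out) <- c("cleaning_report", class(out))
  out
}

#' Clean raw small-RNA reads into 18-30 nt tags
#'
#' Assigns every read to exactly one category, evaluated in a fixed order:
#' low quality first, then (on high-quality reads) 3' adapter absence, empty
#' insert, 5' adapter contamination, polyA insert, and finally insert length.
#' Reads surviving all filters become clean tags. A read must be
#' adapter-trimmed before its insert length can be judged, which fixes the
#' precedence.
#'
#' "Low quality" is defined here (the convention is a documented choice) as
#' mean Phred score < `quality_threshold` or more than `max_n_frac` N bases.
#' The 3' adapter is located by the first exact occurrence of its first
#' `adapter_min_match` bases; reads without such a hit are `adapter3_null`,
#' as are reads whose trimmed insert exceeds `max_len` (an adapter signal
#' outside the expected window). A polyA insert has a run of at least
#' `polyA_min_run` A's and at least `polyA_min_frac` A overall.
#'
#' @param reads character vector of raw reads, or a FASTQ path.
#' @param qualities Phred+33 quality strings (ignored when `reads` is a path).
#' @param adapter3,adapter5 adapter sequences (required).
#' @param min_len,max_len clean insert length bounds (default 18-30 nt).
#' @param quality_threshold mean-Phred cutoff (default 20).
#' @param max_n_frac maximum tolerated N fraction (default 0.1).
#' @param polyA_min_run,polyA_min_frac polyA rule (defaults 6 and 0.7).
#' @param adapter_min_match adapter prefix length for matching (default 6).
#' @return list with `tags` (data.frame `sequence`, `count`, sorted by
#'   decreasing count) and `report` (a [cleaning_report()]).
#' @export
clean_reads <- function(reads, qualities = NULL, adapter3, adapter5,
                        min_len = 18L, max_len = 30L,
                        quality_threshold = 20, max_n_frac = 0.1,
                        polyA_min_run = 6L, polyA_min_frac = 0.7,
                        adapter_min_match = 6L) {
  if (missing(adapter3) || missing(adapter5) ||
      is.null(adapter3) || is.null(adapter5)) {
    stop("both 3' and 5' adapter sequences must be provided")
  }
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)$", reads)) {
    fq <- read_fastq(reads)
    reads <- fq$sequences
    qualities <- fq$qualities
  }
  n <- length(reads)
  if (n == 0L) {
    zero <- setNames(rep(0, 7), c("total_reads", "high_quality",
                                  CLEANING_CATEGORIES[-6]))
    return(list(tags = data.frame(sequence = character(0), count = integer(0)),
                report = cleaning_report(zero)))
  }
  reads <- toupper(reads)
  adapter3 <- norm_dna(adapter3, allow_n = FALSE)
  adapter5 <- norm_dna(adapter5, allow_n = FALSE)

  # 1. quality gate
  if (is.null(qualities)) {
    low_quality <- rep(FALSE, n)
  } else {
    stopifnot(length(qualities) == n)
    offs <- vapply(qualities, function(q) {
      mean(as.integer(charToRaw(q))) - 33
    }, numeric(1), USE.NAMES = FALSE)
    nfrac <- (nchar(reads) - nchar(gsub("N", "", reads, fixed = TRUE))) /
      pmax(nchar(reads), 1L)
    low_quality <- offs < quality_threshold | nfrac > max_n_frac
  }
  hq <- reads[!low_quality]
  category <- rep(NA_character_, length(hq))

  # 2. locate the 3' adapter by its prefix
  a3 <- substr(adapter3, 1L, adapter_min_match)
  pos <- regexpr(a3, hq, fixed = TRUE)
  insert <- ifelse(pos > 0L, substr(hq, 1L, pos - 1L), hq)
  len <- nchar(insert)
  # no adapter hit on an untrimmed-length read, or an adapter signal beyond
  # the longest plausible insert: adapter detection failed. Reads already
  # inside the clean length window with no adapter are treated as pre-trimmed,
  # which makes cleaning idempotent on its own output.
  category[len > max_len] <- "adapter3_null"

  # 3. empty insert: the read is pure adapter
  todo <- is.na(category)
  category[todo & pos == 1L] <- "insert_null"

  # 4. 5' adapter contamination: insert begins with the 5' adapter
  a5 <- substr(adapter5, 1L, adapter_min_match)
  todo <- is.na(category)
  category[todo & startsWith(insert, a5)] <- "adapter5_contaminants"

  # 5. polyA inserts
  todo <- is.na(category)
  run <- strrep("A", polyA_min_run)
  afrac <- (nchar(gsub("[^A]", "", insert))) / pmax(len, 1L)
  category[todo & grepl(run, insert, fixed = TRUE) &
             afrac >= polyA_min_frac] <- "polyA"

  # 6. length
  todo <- is.na(category)
  category[todo & len < min_len] <- "smaller_than_18nt"
  category[is.na(category)] <- "clean_reads"

  clean <- insert[category == "clean_reads"]
  tab <- table(clean)
  tags <- data.frame(sequence = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL

  counts <- c(total_reads = n, high_quality = length(hq),
              vapply(CLEANING_CATEGORIES[-6], function(cc) {
                sum(category == cc)
              }, numeric(1)),
              clean_reads = sum(category == "clean_reads"))
  list(tags = tags, report = cleaning_report(counts))
}

#' Clean several FASTQ libraries into a joint tag table
#'
#' @param files named character vector of FASTQ paths (names = library labels).
#' @param ... passed to [clean_reads()].
#' @return list with `tags` (data.frame `sequence` + one count column per
#'   library, tags present in at least one library) and `reports` (named list
#'   of cleaning reports).
#' @export
clean_fastq_libraries <- function(files, ...) {
  stopifnot(!is.null(names(files)), all(nzchar(names(files))))
  per <- lapply(names(files), function(lib) {
    res <- clean_reads(files[[lib]], ...)
    attr(res$report, "library") <- lib
    res
  })
  names(per) <- names(files)
  all_tags <- sort(unique(unlist(lapply(per, function(x) x$tags$sequence))))
  mat <- vapply(per, function(x) {
    v <- setNames(x$tags$count, x$tags$sequence)
    unname(ifelse(is.na(v[all_tags]), 0L, v[all_tags]))
  }, integer(length(all_tags)))
  if (length(all_tags) == 1L) mat <- matrix(mat, nrow = 1L,
                                            dimnames = list(NULL, names(per)))
  tags <- data.frame(sequence = all_tags, mat, stringsAsFactors = FALSE,
                     check.names = FALSE)
  rownames(tags) <- NULL
  list(tags = tags, reports = lapply(per, `[[`, "report"))
}

#' Length distribution of clean tags
#'
#' @param tags data.frame with a `sequence` column and (for `unit = "total"`)
#'   one or more count columns.
#' @param unit `"unique"` (each tag once) or `"total"` (count-weighted).
#' @param counts optional count vector overriding the count columns.
#' @param lengths lengths over which fractions are reported (default 18:30).
#' @return named numeric vector of fractions summing to 1.
#' @export
size_distribution <- function(tags, unit = c("unique", "total"),
                              counts = NULL, lengths = 18:30) {
  unit <- match.arg(unit)
  if (is.character(tags)) tags <- data.frame(sequence = tags)
  if (nrow(tags) == 0L) stop("empty tag set")
  len <- nchar(tags$sequence)
  w <- if (unit == "unique") {
    rep(1, nrow(tags))
  } else if (!is.null(counts)) {
    counts
  } else {
    cc <- setdiff(names(tags), "sequence")
    if (!length(cc)) stop("unit = 'total' requires count columns")
    rowSums(as.matrix(tags[, cc, drop = FALSE]))
  }
  tot <- tapply(w, factor(len, levels = lengths), sum, default = 0)
  frac <- as.numeric(tot) / sum(w)
  setNames(frac, lengths)
}
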