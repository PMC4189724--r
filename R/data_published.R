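#' Reported read-cleaning statistics for the three cambium libraries
#'
#' Read-accounting counts reported for a published poplar cambium small-RNA
#' sequencing experiment covering endodormancy (8 weeks short day, SD8),
#' ecodormancy (5 weeks chilling, C5) and active growth (3 weeks long day,
#' LD3). Raw data for that experiment were never deposited, so these printed
#' counts are the recomputable record: they are used to validate the cleaning
#' report arithmetic (category counts must sum to the high-quality total, and
#' percentages recomputed from counts must round to the printed two decimals).
#'
#' @return data.frame with columns `category`, `SD8`, `C5`, `LD3` (counts).
#'   Categories follow the standard removal ledger: `total_reads`,
#'   `high_quality`, `adapter3_null`, `insert_null`, `adapter5_contaminants`,
#'   `smaller_than_18nt`, `polyA`, `clean_reads`.
#' @export
cambium_library_stats <- function() {
  data.frame(
    category = c("total_reads", "high_quality", "adapter3_null",
                 "insert_null", "adapter5_contaminants", "smaller_than_18nt",
                 "polyA", "clean_reads"),
    SD8 = c(16688990, 16599916, 8986, 2574, 28453, 220169, 297, 16339437),
    C5  = c(21379082, 21259764, 10757, 2553, 18969, 339653, 352, 20887480),
    LD3 = c(15942869, 15865743, 8894, 2107, 18278, 186610, 616, 15649238),
    stringsAsFactors = FALSE
  )
}

#' Reported percentages for the read-cleaning categories
#'
#' The two-decimal percentages (of the high-quality total) printed alongside
#' [cambium_library_stats()]; used to test that percentage recomputation
#' round-trips the published values.
#'
#' @return data.frame with columns `category`, `SD8`, `C5`, `LD3` (percent).
#' @export
cambium_library_percent <- function() {
  data.frame(
    category = c("high_quality", "adapter3_null", "insert_null",
                 "adapter5_contaminants", "smaller_than_18nt", "polyA",
                 "clean_reads"),
    SD8 = c(100, 0.05, 0.02, 0.17, 1.33, 0.00, 98.43),
    C5  = c(100, 0.05, 0.01, 0.09, 1.60, 0.00, 98.25),
    LD3 = c(100, 0.06, 0.01, 0.12, 1.18, 0.00, 98.64),
    stringsAsFactors = FALSE
  )
}

#' Reported sRNA annotation composition for the three cambium libraries
#'
#' Unique-tag and total-read counts per annotation category, as reported for
#' the same experiment as [cambium_library_stats()] for sRNAs matching the
#' poplar genome perfectly. Category totals sum to the library totals; the
#' miRNA rows reproduce the quoted 22.68% / 24.92% / 13.45% of total clean
#' reads in SD8 / C5 / LD3.
#'
#' @return data.frame with columns `category`, then `<lib>_unique` and
#'   `<lib>_total` for each of SD8, C5, LD3. The first row (`all`) holds the
#'   library totals against which percentages are computed.
#' @export
cambium_annotation_counts <- function() {
  data.frame(
    category = c("all", "exon_antisense", "exon_sense", "intron_antisense",
                 "intron_sense", "miRNA", "rRNA", "repeat", "snRNA",
                 "snoRNA", "tRNA", "unannotated"),
    SD8_unique = c(3487733, 34899, 77352, 8997, 15080, 1479, 135819, 194614,
                   4644, 3171, 46851, 2964827),
    SD8_total = c(16339437, 105910, 313316, 26209, 107476, 3705237, 3749479,
                  474134, 17338, 13771, 721491, 7105076),
    C5_unique = c(3470605, 37745, 112715, 9071, 17907, 1496, 143627, 192856,
                  5485, 3665, 47666, 2898372),
    C5_total = c(20887480, 121410, 379211, 27332, 124816, 5205158, 5370005,
                 505272, 23259, 17953, 1388134, 7724930),
    LD3_unique = c(5854401, 42031, 86849, 14350, 21054, 1698, 77931, 339626,
                   3739, 2610, 59169, 5205344),
    LD3_total = c(15649238, 105942, 282268, 45547, 112381, 2105039, 1229193,
                  828424, 11249, 9582, 468764, 10450849),
    stringsAsFactors = FALSE
  )
}
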