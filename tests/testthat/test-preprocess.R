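ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
HIQ <- function(n) strrep("I", n)

test_that("published SD8 removal counts balance to the printed clean count", {
  stats <- cambium_library_stats()
  counts <- setNames(stats$SD8, stats$category)
  rep <- cleaning_report(counts["clean_reads" != names(counts)])
  expect_identical(rep$count[rep$category == "clean_reads"], 16339437)
  # supplying the printed clean count passes the conservation check
  expect_silent(cleaning_report(counts))
  # a perturbed count is rejected
  bad <- counts; bad[["insert_null"]] <- bad[["insert_null"]] + 1
  expect_error(cleaning_report(bad), "does not balance")
})

test_that("percentages recomputed from printed counts match all three libraries", {
  stats <- cambium_library_stats()
  pcts <- cambium_library_percent()
  for (lib in c("SD8", "C5", "LD3")) {
    rep <- cleaning_report(setNames(stats[[lib]], stats$category), lib)
    got <- rep$percent[match(pcts$category, rep$category)]
    expect_equal(got, pcts[[lib]], info = lib)
  }
})

test_that("each read lands in exactly one category, in the documented order", {
  reads <- c(
    paste0(strrep("G", 20), ADAPTER3, strrep("C", 8)),      # clean 20-mer
    paste0(ADAPTER3, strrep("C", 28)),                      # pure adapter
    strrep("G", 49),                                        # no adapter
    paste0(substr(ADAPTER5, 1, 8), "ACGTACGTACGT", ADAPTER3, "CCCC"), # 5' cont.
    paste0(strrep("A", 22), ADAPTER3, "GGGGGG"),            # polyA
    paste0("ACGTACGTACGT", ADAPTER3, strrep("G", 16)),      # 12-mer: short
    paste0(strrep("G", 20), ADAPTER3, strrep("C", 8))       # low quality
  )
  quals <- c(HIQ(49), HIQ(49), HIQ(49), HIQ(49), HIQ(49), HIQ(49),
             strrep("#", 49))
  res <- clean_reads(reads, quals, adapter3 = ADAPTER3, adapter5 = ADAPTER5)
  rep <- setNames(res$report$count, res$report$category)
  expect_identical(rep[["total_reads"]], 7)
  expect_identical(rep[["high_quality"]], 6)
  expect_identical(rep[["insert_null"]], 1)
  expect_identical(rep[["adapter3_null"]], 1)
  expect_identical(rep[["adapter5_contaminants"]], 1)
  expect_identical(rep[["polyA"]], 1)
  expect_identical(rep[["smaller_than_18nt"]], 1)
  expect_identical(rep[["clean_reads"]], 1)
  expect_identical(res$tags$sequence, strrep("G", 20))
  # conservation: categories partition the high-quality reads
  cats <- c("adapter3_null", "insert_null", "adapter5_contaminants",
            "smaller_than_18nt", "polyA", "clean_reads")
  expect_identical(sum(rep[cats]), rep[["high_quality"]])
})

test_that("empty input gives a zero report; missing adapters error", {
  res <- clean_reads(character(0), character(0), adapter3 = ADAPTER3,
                     adapter5 = ADAPTER5)
  expect_true(all(res$report$count == 0))
  expect_error(clean_reads("ACGT", adapter3 = ADAPTER3), "adapter")
})

test_that("cleaning is idempotent on its own clean tags", {
  fx <- default_fixture()
  tags <- fx$cleaned$tags$sequence
  res <- clean_reads(tags, NULL, adapter3 = fx$cfg$adapter3,
                     adapter5 = fx$cfg$adapter5)
  expect_identical(sort(res$tags$sequence), sort(tags))
  rep <- setNames(res$report$count, res$report$category)
  expect_equal(rep[["clean_reads"]], length(tags))
})

test_that("cleaning recovers the planted artifact counts exactly", {
  fx <- default_fixture()
  for (lib in names(fx$cleaned$reports)) {
    rep <- fx$cleaned$reports[[lib]]
    cnt <- setNames(rep$count, rep$category)
    planted <- fx$sim$manifest$artifacts[, lib]
    expect_equal(cnt[["total_reads"]],
                 unname(fx$sim$manifest$depths[[lib]]))
    expect_equal(cnt[["high_quality"]],
                 unname(fx$sim$manifest$depths[[lib]] -
                          planted[["low_quality"]]))
    for (cat in setdiff(names(planted), "low_quality")) {
      expect_equal(cnt[[cat]], unname(planted[[cat]]), info = cat)
    }
  }
})

test_that("cleaning recovers planted per-tag counts exactly", {
  fx <- default_fixture()
  man <- fx$sim$manifest$tags
  tags <- fx$cleaned$tags
  for (lib in c("SD8", "C5", "LD3")) {
    got <- setNames(tags[[lib]], tags$sequence)[man$sequence]
    got[is.na(got)] <- 0L  # tags planted but never drawn in any library
    expect_identical(unname(got), man[[paste0("count_", lib)]], info = lib)
  }
})

test_that("size distribution handles degenerate and weighted cases", {
  one <- size_distribution(data.frame(sequence = strrep("A", 21)))
  expect_identical(unname(one[["21"]]), 1)
  expect_equal(sum(one), 1, tolerance = 1e-12)

  two <- data.frame(sequence = c(strrep("A", 21), strrep("C", 24)),
                    lib = c(30L, 10L))
  tot <- size_distribution(two, unit = "total")
  expect_equal(unname(tot[c("21", "24")]), c(0.75, 0.25))
  uni <- size_distribution(two, unit = "unique")
  expect_equal(unname(uni[c("21", "24")]), c(0.5, 0.5))
  expect_error(size_distribution(two[0, ]), "empty")
})

test_that("a planted 60/40 length split is recovered within 3 standard errors", {
  cfg <- synth_config(
    n_known_mirna = 2L, n_novel_mirna = 0L, n_rrna = 0L, n_trna = 0L,
    n_snrna = 0L, n_snorna = 0L, n_repeat = 0L, n_exon = 0L, n_intron = 0L,
    n_transcripts = 0L, n_noise = 0L,
    known_mirna_lengths = c(21L, 24L), known_mirna_weights = c(0.6, 0.4),
    fc_c5 = 0, fc_ld3 = 0,
    depths = c(SD8 = 1e5),
    artifact_fractions = c(low_quality = 0, adapter3_null = 0,
                           insert_null = 0, adapter5_contaminants = 0,
                           smaller_than_18nt = 0, polyA = 0),
    class_fractions = c(known_mirna = 1, novel_mirna = 0, rRNA = 0,
                        tRNA = 0, snRNA = 0, snoRNA = 0, `repeat` = 0,
                        exon = 0, intron = 0, noise = 0))
  g <- generate_toy_genome(cfg, seed = 31)
  sim <- simulate_libraries(g, seed = 31)
  cl <- clean_reads(sim$libraries$SD8$sequences, sim$libraries$SD8$qualities,
                    adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  sd <- size_distribution(cl$tags, unit = "total", counts = cl$tags$count)
  se <- sqrt(0.6 * 0.4 / 1e5)
  expect_lt(abs(sd[["21"]] - 0.6), 3 * se)
  expect_lt(abs(sd[["24"]] - 0.4), 3 * se)
})
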