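test_that("generation is deterministic and seed-sensitive", {
  cfg <- synth_config(scaffold_length = 5000L, n_known_mirna = 3L,
                      n_novel_mirna = 1L, n_rrna = 1L, n_trna = 1L,
                      n_snrna = 0L, n_snorna = 0L, n_repeat = 1L,
                      n_exon = 1L, n_intron = 1L, n_transcripts = 1L,
                      n_noise = 3L, depths = c(SD8 = 2000, C5 = 2000,
                                               LD3 = 2000))
  g1 <- generate_toy_genome(cfg, seed = 4)
  g2 <- generate_toy_genome(cfg, seed = 4)
  expect_identical(g1$scaffolds, g2$scaffolds)
  expect_identical(g1$features, g2$features)
  g3 <- generate_toy_genome(cfg, seed = 5)
  expect_false(identical(g1$scaffolds, g3$scaffolds))

  s1 <- simulate_libraries(g1, seed = 4)
  s2 <- simulate_libraries(g2, seed = 4)
  expect_identical(s1$libraries, s2$libraries)
  td <- tempfile(); td2 <- tempfile()
  f1 <- write_simulation(s1, td); f2 <- write_simulation(s2, td2)
  for (lib in names(f1)) {
    expect_identical(readBin(f1[[lib]], "raw", file.size(f1[[lib]])),
                     readBin(f2[[lib]], "raw", file.size(f2[[lib]])))
  }
})

test_that("a zero-feature config yields an empty feature table", {
  cfg <- synth_config(n_known_mirna = 0L, n_novel_mirna = 0L, n_rrna = 0L,
                      n_trna = 0L, n_snrna = 0L, n_snorna = 0L,
                      n_repeat = 0L, n_exon = 0L, n_intron = 0L,
                      n_transcripts = 0L, n_noise = 1L,
                      class_fractions = c(known_mirna = 0, novel_mirna = 0,
                                          rRNA = 0, tRNA = 0, snRNA = 0,
                                          snoRNA = 0, `repeat` = 0,
                                          exon = 0, intron = 0, noise = 1))
  g <- generate_toy_genome(cfg, seed = 2)
  expect_identical(nrow(g$features), 0L)
})

test_that("feature demand beyond scaffold capacity errors explicitly", {
  cfg <- synth_config(n_scaffolds = 1L, scaffold_length = 300L,
                      n_known_mirna = 0L, n_novel_mirna = 0L, n_rrna = 0L,
                      n_trna = 0L, n_snrna = 0L, n_snorna = 0L,
                      n_repeat = 0L, n_exon = 20L, n_intron = 0L,
                      n_transcripts = 0L)
  expect_error(generate_toy_genome(cfg, seed = 1), "capacity")
})

test_that("feature coordinates respect scaffold bounds and 1-based closure", {
  fx <- default_fixture()
  f <- fx$genome$features
  expect_true(all(f$start >= 1))
  expect_true(all(f$start <= f$end))
  slen <- nchar(fx$genome$scaffolds)[match(f$scaffold,
                                           names(fx$genome$scaffolds))]
  expect_true(all(f$end <= slen))
})

test_that("planted precursors fold into hairpins pairing the mature arm", {
  fx <- default_fixture()
  nov <- fx$genome$novel
  for (i in seq_len(nrow(nov))) {
    prec <- substr(fx$genome$scaffolds[[nov$scaffold[i]]],
                   nov$start[i], nov$end[i])
    expect_identical(substr(prec, 9, 8 + nchar(nov$mature[i])),
                     nov$mature[i])
    f <- fold_hairpin(prec)
    partner <- pairing_table(f$structure)
    mpos <- (nov$mature_start[i]:nov$mature_end[i]) - nov$start[i] + 1L
    expect_gte(sum(!is.na(partner[mpos])), 16)
  }
})

test_that("a degenerate one-miRNA mixture yields identical clean reads", {
  cfg <- synth_config(
    n_known_mirna = 1L, n_novel_mirna = 0L, n_rrna = 0L, n_trna = 0L,
    n_snrna = 0L, n_snorna = 0L, n_repeat = 0L, n_exon = 0L, n_intron = 0L,
    n_transcripts = 0L, n_noise = 0L, known_mirna_lengths = 21L,
    fc_c5 = 0, fc_ld3 = 0, depths = c(SD8 = 1000),
    artifact_fractions = c(low_quality = 0, adapter3_null = 0,
                           insert_null = 0, adapter5_contaminants = 0,
                           smaller_than_18nt = 0, polyA = 0),
    class_fractions = c(known_mirna = 1, novel_mirna = 0, rRNA = 0,
                        tRNA = 0, snRNA = 0, snoRNA = 0, `repeat` = 0,
                        exon = 0, intron = 0, noise = 0))
  g <- generate_toy_genome(cfg, seed = 6)
  sim <- simulate_libraries(g, seed = 6)
  expect_identical(length(sim$libraries$SD8$sequences), 1000L)
  cl <- clean_reads(sim$libraries$SD8$sequences, sim$libraries$SD8$qualities,
                    adapter3 = cfg$adapter3, adapter5 = cfg$adapter5)
  expect_identical(nrow(cl$tags), 1L)
  expect_identical(cl$tags$count, 1000L)
  expect_identical(nchar(cl$tags$sequence), 21L)
  expect_identical(cl$tags$sequence, unname(g$known_mature))
})

test_that("simulated read totals equal the requested depth exactly", {
  fx <- default_fixture()
  for (lib in names(fx$sim$libraries)) {
    expect_identical(length(fx$sim$libraries[[lib]]$sequences),
                     as.integer(fx$sim$manifest$depths[[lib]]))
  }
  expect_error(simulate_libraries(fx$genome, seed = 1,
                                  depths = c(SD8 = 0)), "zero total depth")
})

test_that("a planted 4x fold change is recovered within 3 binomial SEs", {
  cfg <- synth_config(n_known_mirna = 4L, fc_c5 = c(2, 0, 0, 0),
                      fc_ld3 = 0, depths = c(SD8 = 5e4, C5 = 5e4))
  g <- generate_toy_genome(cfg, seed = 17)
  sim <- simulate_libraries(g, seed = 17)
  man <- sim$manifest$tags
  row <- man[which(man$feature_id == "syn-miR001"), ]
  expect_identical(nrow(row), 1L)
  ratio <- row$count_C5 / row$count_SD8
  se_log <- sqrt(1 / row$expected_SD8 + 1 / row$expected_C5)
  expect_lt(abs(log(ratio) - log(4)), 3 * se_log)
  # manifest expectations encode the planted change exactly
  expect_equal(row$expected_C5 / row$expected_SD8, 4, tolerance = 1e-9)
})

test_that("ground-truth manifest is internally consistent", {
  fx <- default_fixture()
  man <- fx$sim$manifest
  expect_lte(sum(man$artifact_fractions), 1)
  expect_equal(sum(man$class_fractions), 1, tolerance = 1e-12)
  # every planted miRNA appears in the feature table
  expect_true(all(man$fold_changes$mirna %in%
                    fx$genome$features$feature_id))
  # realized clean totals: depth minus planted artifacts
  for (lib in c("SD8", "C5", "LD3")) {
    expect_equal(sum(man$tags[[paste0("count_", lib)]]),
                 man$depths[[lib]] - sum(man$artifacts[, lib]))
  }
})

test_that("genome files round-trip through FASTA and GFF3", {
  fx <- default_fixture()
  td <- tempfile()
  paths <- write_genome_files(fx$genome, td)
  expect_identical(read_fasta(paths[["genome"]]), fx$genome$scaffolds)
  feats <- read_features_gff3(paths[["gff"]])
  expect_identical(feats, fx$genome$features)
  expect_identical(read_fasta(paths[["mature"]]), fx$genome$known_mature)
})
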