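toy_genome_chr <- function() {
  withr::with_seed(9, {
    setNames(paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
             "chrA")
  })
}

test_that("exact matching reports plus- and minus-strand hits", {
  g <- toy_genome_chr()
  tag <- substr(g, 101, 121)
  hits <- map_tags(tag, g)
  expect_true(any(hits$start == 101 & hits$end == 121 & hits$strand == "+"))
  expect_true(all(hits$mismatches == 0))

  rc <- revcomp(substr(g, 201, 222))
  hits <- map_tags(rc, g)
  expect_true(any(hits$start == 201 & hits$end == 222 & hits$strand == "-"))

  nohit <- map_tags(strrep("ACGT", 6), g)  # 24-mer almost surely absent
  expect_identical(attr(nohit, "unmapped"), strrep("ACGT", 6))
  expect_error(map_tags("ACGTACGTACGTACGTAC", character(0)), "empty genome")
})

test_that("planted tags map back to their planted loci", {
  fx <- default_fixture()
  feats <- fx$genome$features
  for (i in which(feats$class == "known_mirna")[1:3]) {
    tag <- fx$genome$known_mature[[feats$feature_id[i]]]
    hits <- map_tags(tag, fx$genome$scaffolds)
    expect_true(any(hits$scaffold == feats$scaffold[i] &
                      hits$start == feats$start[i] &
                      hits$end == feats$end[i] & hits$strand == "+"))
  }
})

test_that("classification is hierarchical with sense/antisense splitting", {
  g <- toy_genome_chr()
  features <- data.frame(
    feature_id = c("rrna1", "exon1", "exon2"),
    class = c("rRNA", "exon", "exon"),
    scaffold = "chrA",
    start = c(50L, 200L, 300L),
    end = c(120L, 280L, 380L),
    strand = c("+", "+", "-"),
    stringsAsFactors = FALSE)
  tags <- data.frame(
    sequence = c(substr(g, 60, 80),          # inside rRNA
                 substr(g, 210, 230),        # exon, plus-strand feature
                 revcomp(substr(g, 310, 330)), # maps minus over minus feature
                 strrep("ACGT", 6)),         # unmappable
    L1 = c(5L, 3L, 2L, 7L), stringsAsFactors = FALSE)
  hits <- map_tags(tags, g)
  res <- classify(hits, tags, features)
  cat_of <- setNames(res$records$category, res$records$tag)
  expect_identical(unname(cat_of[tags$sequence[1]]), "rRNA")
  expect_identical(unname(cat_of[tags$sequence[2]]), "exon_sense")
  expect_identical(unname(cat_of[tags$sequence[3]]), "exon_sense")
  expect_identical(unname(cat_of[tags$sequence[4]]), "unannotated")
  # brute-force strand check for the exon tags
  expect_identical(sum(res$report$L1_total[-1]), res$report$L1_total[1])
})

test_that("a tag overlapping a feature on the opposite strand is antisense", {
  g <- toy_genome_chr()
  features <- data.frame(feature_id = "exon1", class = "exon",
                         scaffold = "chrA", start = 200L, end = 280L,
                         strand = "-", stringsAsFactors = FALSE)
  tags <- data.frame(sequence = substr(g, 210, 230), L1 = 1L,
                     stringsAsFactors = FALSE)
  res <- classify(map_tags(tags, g), tags, features)
  expect_identical(res$records$category, "exon_antisense")
})

test_that("planted synthetic classes are recovered by classification", {
  fx <- default_fixture()
  man <- fx$sim$manifest$tags
  rec <- fx$ann$records
  cat_of <- setNames(rec$category, rec$tag)
  expect_map <- c(known_mirna = "miRNA", rRNA = "rRNA", tRNA = "tRNA",
                  snRNA = "snRNA", snoRNA = "snoRNA", `repeat` = "repeat",
                  exon_sense = "exon_sense", exon_antisense = "exon_antisense",
                  intron_sense = "intron_sense",
                  intron_antisense = "intron_antisense",
                  noise = "unannotated", novel_mirna = "unannotated",
                  novel_star = "unannotated")
  seen <- man$sequence %in% names(cat_of)
  got <- cat_of[man$sequence[seen]]
  expect_identical(unname(got), unname(expect_map[man$class[seen]]))
})

test_that("known miRNA identification is exact-match only", {
  ref <- c(mirA = "UGGAGCUCCCUUCAUUCCAAU", mirB = "UUGACAGAAGAUAGAGAGCAC")
  tagA <- chartr("U", "T", ref[["mirA"]])
  tag_mismatch <- paste0("A", substr(tagA, 2, 21))  # one mismatch
  tags <- data.frame(sequence = c(tagA, tag_mismatch),
                     SD8 = c(10L, 99L), C5 = c(3L, 1L),
                     stringsAsFactors = FALSE)
  res <- identify_known_mirnas(tags, ref)
  expect_identical(res$mirna, "mirA")
  expect_identical(res$SD8, 10L)
  expect_identical(res$C5, 3L)
  expect_error(identify_known_mirnas(tags, c(a = "ACGU", a = "ACGG")),
               "duplicate")
})

test_that("all planted known miRNAs are detected with manifest counts", {
  fx <- default_fixture()
  known <- identify_known_mirnas(fx$cleaned$tags, fx$genome$known_mature)
  expect_identical(sort(known$mirna), sort(names(fx$genome$known_mature)))
  man <- fx$sim$manifest$tags
  man <- man[man$class == "known_mirna", ]
  for (lib in c("SD8", "C5", "LD3")) {
    got <- setNames(known[[lib]], known$mirna)
    expect_identical(unname(got[man$feature_id]),
                     man[[paste0("count_", lib)]], info = lib)
  }
})

test_that("published composition counts validate and round-trip percentages", {
  rep <- composition_report(cambium_annotation_counts())
  mir <- rep[rep$category == "miRNA", ]
  expect_equal(mir$SD8_total_pct, 22.68)
  expect_equal(mir$C5_total_pct, 24.92)
  expect_equal(mir$LD3_total_pct, 13.45)
  # every printed unique/total percentage round-trips at two decimals
  published_pct <- list(
    SD8_unique_pct = c(100, 1.00, 2.22, 0.26, 0.43, 0.04, 3.89, 5.58, 0.13,
                       0.09, 1.34, 85.01),
    SD8_total_pct = c(100, 0.65, 1.92, 0.16, 0.66, 22.68, 22.95, 2.90, 0.11,
                      0.08, 4.42, 43.48),
    C5_unique_pct = c(100, 1.09, 3.25, 0.26, 0.52, 0.04, 4.14, 5.56, 0.16,
                      0.11, 1.37, 83.51),
    C5_total_pct = c(100, 0.58, 1.82, 0.13, 0.60, 24.92, 25.71, 2.42, 0.11,
                     0.09, 6.65, 36.98),
    LD3_unique_pct = c(100, 0.72, 1.48, 0.25, 0.36, 0.03, 1.33, 5.80, 0.06,
                       0.04, 1.01, 88.91),
    LD3_total_pct = c(100, 0.68, 1.80, 0.29, 0.72, 13.45, 7.85, 5.29, 0.07,
                      0.06, 3.00, 66.78))
  for (col in names(published_pct)) {
    expect_equal(rep[[col]], published_pct[[col]], info = col)
  }
  # a non-additive table is rejected
  bad <- cambium_annotation_counts()
  bad$SD8_total[2] <- bad$SD8_total[2] + 1
  expect_error(composition_report(bad), "sum to")
})
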