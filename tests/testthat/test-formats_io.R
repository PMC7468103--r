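write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("expression loading coerces NA to zero and validates hard errors", {
  dir <- withr::local_tempdir()
  maps <- write_tsv(data.frame(transcript_id = c("T1", "T2"),
                               gene_id = c("G1", "G1"),
                               protein_id = c("P1", "P2")),
                    file.path(dir, "maps.tsv"))
  expr <- file.path(dir, "e.tsv")
  writeLines(c("transcript_id\tS1\tS2", "T1\t5\tNA", "T2\t1\t2"), expr)
  mat <- read_expression_matrix(expr, maps)
  expect_equal(mat$tpm["T1", "S2"], 0)
  expect_equal(mat$tpm["T1", "S1"], 5)

  writeLines("transcript_id\tS1", expr)
  expect_error(read_expression_matrix(expr, maps), "no transcripts")

  writeLines(c("transcript_id\tS1", "T1\t5", "T1\t2"), expr)
  expect_error(read_expression_matrix(expr, maps), "T1")

  writeLines(c("transcript_id\tS1", "T1\t-3"), expr)
  expect_error(read_expression_matrix(expr, maps), "negative")

  writeLines(c("transcript_id\tS1", "T1\tabc"), expr)
  expect_error(read_expression_matrix(expr, maps), "non-numeric")

  writeLines(c("transcript_id\tS1", "T1\t5", "TX\t2"), expr)
  expect_error(read_expression_matrix(expr, maps), "TX")
  expect_message(m <- read_expression_matrix(expr, maps, strict = FALSE),
                 "dropping")
  expect_equal(rownames(m$tpm), "T1")
})

test_that("expression matrices round-trip through write/read exactly", {
  dir <- withr::local_tempdir()
  set.seed(11)
  tpm <- matrix(rlnorm(12, 3, 2), nrow = 4,
                dimnames = list(paste0("T", 1:4), paste0("S", 1:3)))
  t2g <- setNames(rep(c("G1", "G2"), each = 2), paste0("T", 1:4))
  mat <- expression_matrix(tpm, t2g)
  maps <- write_tsv(data.frame(transcript_id = names(t2g), gene_id = t2g),
                    file.path(dir, "maps.tsv"))
  write_expression_matrix(mat, file.path(dir, "e.tsv"))
  back <- read_expression_matrix(file.path(dir, "e.tsv"), maps)
  expect_identical(back$tpm, mat$tpm)
})

test_that("edge reading normalizes dialects, collapses duplicates, filters", {
  dir <- withr::local_tempdir()
  path <- write_tsv(data.frame(protein_a = c("A", "B", "A", "C", "D"),
                               protein_b = c("B", "A", "C", "C", "E"),
                               combined_score = c(950, 910, 900, 980, 899)),
                    file.path(dir, "edges.tsv"))
  expect_message(e <- read_interaction_edges(path, 0.9), "1 self-loop")
  # (A,B) collapsed to max 0.95; (A,C) exactly at threshold kept; 899 dropped
  expect_equal(nrow(e), 2L)
  expect_equal(e$combined_score[e$protein_a == "A" & e$protein_b == "B"],
               0.95)
  expect_equal(e$combined_score[e$protein_a == "A" & e$protein_b == "C"],
               0.9)

  bad <- write_tsv(data.frame(protein_a = "A", protein_b = "B",
                              combined_score = "x"),
                   file.path(dir, "bad.tsv"))
  expect_error(read_interaction_edges(bad), "malformed")
})

test_that("edge canonicalization is order-independent and idempotent", {
  dir <- withr::local_tempdir()
  set.seed(5)
  df <- data.frame(protein_a = sample(LETTERS[1:6], 30, TRUE),
                   protein_b = sample(LETTERS[1:6], 30, TRUE),
                   combined_score = sample(850:999, 30, TRUE))
  p1 <- write_tsv(df, file.path(dir, "e1.tsv"))
  p2 <- write_tsv(df[sample(nrow(df)), ], file.path(dir, "e2.tsv"))
  e1 <- suppressMessages(read_interaction_edges(p1, 0.9))
  e2 <- suppressMessages(read_interaction_edges(p2, 0.9))
  expect_identical(e1, e2)
  expect_true(all(e1$protein_a < e1$protein_b))
})

test_that("variant-region overlap matches a brute-force interval check", {
  dir <- withr::local_tempdir()
  set.seed(21)
  reg <- data.frame(chrom = "chr1",
                    start = seq(0, 900, by = 100),
                    end = seq(0, 900, by = 100) + sample(40:100, 10, TRUE),
                    gene_id = paste0("G", 1:10),
                    region_class = sample(c("cds", "utr5", "utr3",
                                            "splice_site", "promoter_core",
                                            "promoter_domain"), 10, TRUE))
  var <- data.frame(sample_id = sample(c("s1", "s2"), 40, TRUE),
                    chrom = "chr1", pos = sample(1:1000, 40),
                    ref = sample(c("A", "C"), 40, TRUE),
                    alt = sample(c("G", "T"), 40, TRUE))
  vp <- write_tsv(var, file.path(dir, "v.tsv"))
  rp <- write_tsv(reg, file.path(dir, "r.tsv"))
  got <- read_mutation_table(vp, rp)
  # oracle: merge adjacent SNVs by hand, then all-pairs interval test
  mv <- merge_adjacent_snvs(cbind(var, variant_class = "snv"))
  expected <- 0L
  for (i in seq_len(nrow(mv))) for (j in seq_len(nrow(reg))) {
    v_lo <- mv$pos[i]; v_hi <- mv$pos[i] + nchar(mv$ref[i]) - 1L
    r_lo <- reg$start[j] + 1L; r_hi <- reg$end[j]
    if (v_lo <= r_hi && v_hi >= r_lo) expected <- expected + 1L
  }
  expect_equal(nrow(got), expected)
})

test_that("adjacent same-sample SNVs merge into one MNV record", {
  dir <- withr::local_tempdir()
  reg <- write_tsv(data.frame(chrom = "chr1", start = 99L, end = 110L,
                              gene_id = "G1", region_class = "cds"),
                   file.path(dir, "r.tsv"))
  vp <- write_tsv(data.frame(sample_id = c("s1", "s1", "s2"),
                             chrom = "chr1", pos = c(100L, 101L, 100L),
                             ref = c("A", "C", "G"), alt = c("G", "T", "A")),
                  file.path(dir, "v.tsv"))
  rec <- read_mutation_table(vp, reg)
  s1 <- rec[rec$sample_id == "s1", ]
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$variant_class, "mnv")
  expect_equal(rec$variant_class[rec$sample_id == "s2"], "snv")
})

test_that("a variant spanning two functional regions yields two records", {
  dir <- withr::local_tempdir()
  reg <- write_tsv(data.frame(chrom = c("chr1", "chr1"),
                              start = c(90L, 100L), end = c(100L, 120L),
                              gene_id = "G1",
                              region_class = c("promoter_core", "utr5")),
                   file.path(dir, "r.tsv"))
  vp <- write_tsv(data.frame(sample_id = "s1", chrom = "chr1", pos = 100L,
                             ref = "AG", alt = "A"),
                  file.path(dir, "v.tsv"))
  rec <- read_mutation_table(vp, reg)
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$region_class, c("promoter_core", "utr5"))

  bad <- write_tsv(data.frame(chrom = "chr1", start = 0L, end = 10L,
                              gene_id = "G1", region_class = "exon"),
                   file.path(dir, "bad.tsv"))
  expect_error(read_mutation_table(vp, bad), "unknown region_class")
})

test_that("GMT files round-trip", {
  dir <- withr::local_tempdir()
  sets <- list(alpha = c("P1", "P2"), beta = c("P3"))
  write_gmt(sets, file.path(dir, "s.gmt"))
  expect_identical(read_gmt(file.path(dir, "s.gmt")), sets)
})

test_that("cohort pairs enforce disjoint non-empty sample sets", {
  expect_error(cohort_pair("c", character(), "n", "s1"), "non-empty")
  expect_error(cohort_pair("c", "s1", "n", c("s1", "s2")), "disjoint")
  cp <- cohort_pair("c", c("t1", "t2"), "n", "n1")
  expect_s3_class(cp, "CohortPair")
})
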