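test_that("9-mer windows count P - 8 and tile by codon", {
  seq9 <- paste(rep("GCT", 9), collapse = "")   # protein length 9
  w9 <- enumerate_9mers(seq9, "T1")
  expect_equal(nrow(w9), 1)
  expect_equal(c(w9$start, w9$end), c(0L, 27L))

  seq11 <- paste(rep("GCT", 11), collapse = "")
  w11 <- enumerate_9mers(seq11, "T1")
  expect_equal(nrow(w11), 3)
  expect_equal(w11$start, c(0L, 3L, 6L))

  # each window's peptide matches the translated codons it covers
  spec <- fixture_spec(n_transcripts = 1, cds_length = 60, seed = 8)
  tx <- generate_transcriptome(spec)$transcripts
  w <- enumerate_9mers(tx[[1]], names(tx)[1])
  for (i in seq_len(nrow(w))) {
    sub <- substr(tx[[1]], w$start[i] + 1, w$end[i])
    expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                    no.init.codon = TRUE)),
                 w$peptide[i])
  }
})

test_that("windows spanning a stop codon are excluded and reported", {
  # 12 codons with a stop at codon 6
  seq <- paste(c(rep("GCT", 5), "TAA", rep("GCT", 6)), collapse = "")
  w <- enumerate_9mers(seq, "T1")
  expect_equal(attr(w, "excluded_stop"), 4)  # windows over codons incl. #6
  spans_stop <- w$start <= 15 & w$end > 15
  expect_false(any(spans_stop))
})

test_that("genotypes normalize, cap at six alleles and flag homozygosity", {
  g <- hla_genotype(c("HLA-A*02:01", "A*02:01", "B07:02", "B08:01",
                      "C07:01", "C07:02"))
  expect_setequal(g$alleles, c("A0201", "B0702", "B0801", "C0701", "C0702"))
  expect_true(g$homozygous[["A"]])
  expect_false(g$homozygous[["B"]])
  expect_error(hla_genotype(character()), "empty")
  expect_error(hla_genotype("bogus"), "malformed")
})

test_that("immunopeptidome building filters by genotype and strict rank", {
  binders <- data.frame(
    transcript_id = "T1",
    start = c(0L, 3L, 30L, 60L),
    end = c(27L, 30L, 57L, 87L),
    allele = c("A0201", "B0702", "A0201", "A0201"),
    percent_rank = c(0.3, 0.1, 0.5, 0.49),
    peptide = NA_character_, stringsAsFactors = FALSE)
  reg <- build_immunopeptidome(binders, hla_genotype("A0201"), 0.5)
  # rank exactly 0.5 excluded (strict <); B0702 not in genotype
  expect_equal(as.data.frame(reg)$start, c(0L, 60L))
  expect_equal(as.data.frame(reg)$end, c(27L, 87L))

  # overlapping windows from two alleles merge into one interval
  reg2 <- build_immunopeptidome(binders, hla_genotype(c("A0201", "B0702")), 0.5)
  expect_equal(as.data.frame(reg2)$start[1], 0L)
  expect_equal(as.data.frame(reg2)$end[1], 30L)

  expect_error(build_immunopeptidome(binders, character(), 0.5), "empty")
  expect_warning(reg0 <- build_immunopeptidome(binders, hla_genotype("C0102"), 0.5),
                 "no binders")
  expect_equal(nrow(reg0), 0)
})

test_that("rank threshold is monotone and alleles only add regions", {
  fx <- small_fixture()
  b <- fx$binders
  g2 <- hla_genotype(c("A0201", "B2705"))
  for (thr in c(0.1, 0.5, 2)) {
    narrow <- build_immunopeptidome(b, hla_genotype("A0201"), thr)
    wide <- build_immunopeptidome(b, g2, thr)
    expect_gte(region_width(wide), region_width(narrow))
  }
  r1 <- suppressWarnings(build_immunopeptidome(b, hla_genotype("A0201"), 0.1))
  r2 <- build_immunopeptidome(b, hla_genotype("A0201"), 0.5)
  expect_lte(region_width(r1), region_width(r2))
})

test_that("a multi-allele build equals the union of single-allele builds", {
  fx <- small_fixture()
  b <- fx$binders
  alleles <- c("A0201", "B2705", "C0802")
  multi <- build_immunopeptidome(b, hla_genotype(alleles), 5)
  singles <- do.call(rbind, lapply(alleles, function(a)
    as.data.frame(suppressWarnings(
      build_immunopeptidome(b, hla_genotype(a), 5)))))
  union <- target_regions(singles)
  expect_equal(as.data.frame(multi)[, c("transcript_id", "start", "end")],
               as.data.frame(union)[, c("transcript_id", "start", "end")])
})

test_that("positive-assay filtering is exact substring match, length >= 9", {
  binders <- data.frame(transcript_id = "T1", start = 0L, end = 27L,
                        allele = "A0201", percent_rank = 0.1,
                        peptide = c("SIINFEKLM", "AAAAAAAAA"),
                        stringsAsFactors = FALSE)
  kept <- filter_by_positive_assays(binders, c("XSIINFEKLMX"))
  expect_equal(kept$peptide, "SIINFEKLM")
  expect_warning(res <- filter_by_positive_assays(binders, c("SHORTPEP", "XSIINFEKLMX")),
                 "shorter than 9")
  expect_equal(res$peptide, "SIINFEKLM")
  expect_warning(none <- filter_by_positive_assays(binders, character()),
                 "assay")
  expect_equal(nrow(none), 0)
})

test_that("expression filtering drops transcripts at or below the threshold", {
  reg <- target_regions(data.frame(transcript_id = c("T1", "T2", "T3"),
                                   start = 0L, end = 27L))
  expr <- c(T1 = 0.5, T2 = 1.0, T3 = 5)
  kept <- filter_by_expression(reg, expr, threshold = 1)
  expect_equal(kept$transcript_id, "T3")  # 1.0 dropped: strictly more than 1
  # per-patient zero-expression filtering at threshold 0
  expr0 <- c(T1 = 0, T2 = 1.0, T3 = 5)
  kept0 <- filter_by_expression(reg, expr0, threshold = 0)
  expect_setequal(kept0$transcript_id, c("T2", "T3"))
  # missing transcripts follow the policy flag
  expr_part <- c(T3 = 5)
  expect_warning(keep_missing <- filter_by_expression(reg, expr_part, 1, "keep"),
                 "missing")
  expect_setequal(keep_missing$transcript_id, c("T1", "T2", "T3"))
  drop_missing <- filter_by_expression(reg, expr_part, 1, "drop")
  expect_equal(drop_missing$transcript_id, "T3")
})

test_that("fixture binder tables rebuild their own ground-truth region set", {
  fx <- small_fixture()
  rebuilt <- build_immunopeptidome(fx$binders, hla_genotype("A0201"), 0.5)
  expect_equal(as.data.frame(rebuilt)[, c("transcript_id", "start", "end")],
               as.data.frame(fx$truth)[, c("transcript_id", "start", "end")])
})
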