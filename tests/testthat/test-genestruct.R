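## tiny GFF3 fixtures written at test time
write_gff <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), f)
  f
}

cds_line <- function(seqid, start, end, strand, gene, i)
  paste(seqid, "test", "CDS", start, end, ".", strand, ".",
        paste0("ID=", gene, ".cds", i, ";Parent=", gene), sep = "\t")

test_that("gene models derive intron offsets and phases from CDS features", {
  ## single 300-nt CDS: no introns
  g1 <- write_gff(cds_line("chr1", 101, 400, "+", "g1", 1))
  m1 <- parseGeneModel(g1, "g1")
  expect_identical(nrow(m1$introns), 0L)
  expect_identical(m1$coding_length, 300L)
  expect_true(m1$complete)

  ## 100 + 200 nt: intron at offset 100, phase 1
  g2 <- write_gff(c(cds_line("chr1", 1, 100, "+", "g2", 1),
                    cds_line("chr1", 201, 400, "+", "g2", 2)))
  m2 <- parseGeneModel(g2, "g2")
  expect_identical(m2$introns$offset, 100L)
  expect_identical(m2$introns$phase, 1L)

  ## 99 + 201 nt: phase 0
  g3 <- write_gff(c(cds_line("chr1", 1, 99, "+", "g3", 1),
                    cds_line("chr1", 200, 400, "+", "g3", 2)))
  m3 <- parseGeneModel(g3, "g3")
  expect_identical(m3$introns$offset, 99L)
  expect_identical(m3$introns$phase, 0L)
})

test_that("reverse-strand models are read in translation order", {
  ## on the minus strand the rightmost CDS comes first in translation
  g <- write_gff(c(cds_line("chr1", 1, 200, "-", "gm", 1),
                   cds_line("chr1", 301, 400, "-", "gm", 2)))
  m <- parseGeneModel(g, "gm")
  expect_identical(m$exon_lengths, c(100L, 200L))
  expect_identical(m$introns$offset, 100L)
})

test_that("inconsistent gene models are rejected or flagged", {
  g <- write_gff(c(cds_line("chr1", 1, 100, "+", "gx", 1),
                   cds_line("chr1", 50, 200, "+", "gx", 2)))
  expect_error(parseGeneModel(g, "gx"), "overlapping")
  g2 <- write_gff(c(cds_line("chr1", 1, 100, "+", "gy", 1),
                    cds_line("chr1", 201, 300, "-", "gy", 2)))
  expect_error(parseGeneModel(g2, "gy"), "mixed or missing strand")
  g3 <- write_gff(cds_line("chr1", 1, 100, "+", "gz", 1))
  expect_warning(m <- parseGeneModel(g3, "gz"), "not divisible by 3")
  expect_false(m$complete)
  expect_error(parseGeneModel(g3, "nope"), "no CDS")
})

test_that("introns project onto alignment columns through gaps", {
  ## model: 6-nt exon + rest; intron at offset 3 (phase 0) -> residue 2
  g <- write_gff(c(cds_line("chr1", 1, 3, "+", "gg", 1),
                   cds_line("chr1", 101, 112, "+", "gg", 2)))
  m <- parseGeneModel(g, "gg")
  msa <- Biostrings::AAStringSet(c(gg = "MKLIA", other = "MKLIA"))
  pl <- mapIntronsToAlignment(m, msa, "gg")
  expect_identical(pl$column, 2L)
  expect_identical(pl$phase, 0L)

  ## four leading gap columns shift the anchor to column 6
  msa2 <- Biostrings::AAStringSet(c(gg = "----MKLIA", other = "MKLIAMKLI"))
  pl2 <- mapIntronsToAlignment(m, msa2, "gg")
  expect_identical(pl2$column, 6L)

  ## no introns -> empty placement list
  g0 <- write_gff(cds_line("chr1", 1, 15, "+", "g0", 1))
  expect_identical(nrow(mapIntronsToAlignment(parseGeneModel(g0, "g0"),
                                              msa, "gg")), 0L)

  ## too-short rows are a coordinate error naming both lengths
  short <- Biostrings::AAStringSet(c(gg = "MK--"))
  expect_error(mapIntronsToAlignment(m, short, "gg"), "2 residues")
})

test_that("gap insertion shifts downstream placements by one column", {
  g <- write_gff(c(cds_line("chr1", 1, 30, "+", "gi", 1),
                   cds_line("chr1", 101, 130, "+", "gi", 2)))
  m <- parseGeneModel(g, "gi")  # intron at offset 30 -> residue 11
  row <- paste(rep("A", 20), collapse = "")
  msa <- Biostrings::AAStringSet(c(gi = row))
  base <- mapIntronsToAlignment(m, msa, "gi")
  for (at in c(1, 5, 10)) {  # gap inserted before the anchor column
    gapped <- paste0(substr(row, 1, at), "-", substr(row, at + 1, 20))
    shifted <- mapIntronsToAlignment(m,
      Biostrings::AAStringSet(c(gi = gapped)), "gi")
    expect_identical(shifted$column, base$column + 1L)
  }
  ## gap after the anchor leaves it unchanged
  gapped <- paste0(substr(row, 1, 15), "-", substr(row, 16, 20))
  expect_identical(
    mapIntronsToAlignment(m, Biostrings::AAStringSet(c(gi = gapped)),
                          "gi")$column, base$column)
})

test_that("congruence is a symmetric Jaccard index over (column, phase)", {
  a <- data.frame(column = c(10L, 50L), phase = c(0L, 2L))
  b <- data.frame(column = 10L, phase = 0L)
  expect_identical(congruenceScore(a, a), 1)
  expect_identical(congruenceScore(a, b), 0.5)
  expect_identical(congruenceScore(b, a), 0.5)
  disjoint <- data.frame(column = c(20L, 30L), phase = c(1L, 1L))
  expect_identical(congruenceScore(a, disjoint), 0)
  ## same column, different phase is not the same intron
  aphase <- data.frame(column = 10L, phase = 1L)
  expect_identical(congruenceScore(b, aphase), 0)
  empty <- data.frame(column = integer(0), phase = integer(0))
  expect_identical(congruenceScore(empty, empty), 1)
  expect_identical(congruenceScore(a, empty), 0)
})

test_that("discriminating introns must be universal in one group, absent in the other", {
  shared <- data.frame(column = c(5L, 20L), phase = c(0L, 1L))
  tail <- data.frame(column = 80L, phase = 2L)
  withTail <- rbind(shared, tail)
  groupA <- list(withTail, withTail, withTail)
  groupB <- list(shared, shared)
  d <- discriminatingIntrons(groupA, groupB)
  expect_identical(nrow(d), 1L)
  expect_identical(d$column, 80L)
  expect_identical(d$group, "A")

  ## identical groups -> nothing discriminates
  expect_identical(nrow(discriminatingIntrons(groupB, groupB)), 0L)

  ## an intron in 2 of 3 members is not universal
  groupA2 <- list(withTail, withTail, shared)
  expect_identical(nrow(discriminatingIntrons(groupA2, groupB)), 0L)
})

test_that("hyphen/pipe patterns align across sequences", {
  none <- data.frame(column = integer(0), phase = integer(0))
  expect_identical(renderPattern(none, "AAAAA"), "-----")
  one <- data.frame(column = 3L, phase = 0L)
  expect_identical(renderPattern(one, "AAAAA"), "--|---")
  ## gaps render as spaces and keep columns aligned
  expect_identical(renderPattern(none, "AA--A"), "--  -")
  ## a shared intron lands at the same output offset in both rows
  rowX <- "MKLIAMKLIA"; rowY <- "MKLIAMKLIA"
  p <- data.frame(column = 6L, phase = 1L)
  expect_identical(regexpr("|", renderPattern(p, rowX), fixed = TRUE),
                   regexpr("|", renderPattern(p, rowY), fixed = TRUE))
  ## stripped of pipes and spaces, length equals the residue count
  pat <- renderPattern(data.frame(column = 2L, phase = 0L), "AA--A")
  expect_identical(pat, "-|-  -")
  expect_identical(nchar(gsub("[| ]", "", pat)), 3L)
  expect_error(renderPattern(data.frame(column = 99L, phase = 0L), "AAAAA"),
               "outside")
  expect_error(renderPattern(data.frame(column = 3L, phase = 0L), "AA-AA"),
               "gap column")
})

test_that("completeness classes follow the 5% missing-fraction rule", {
  expect_identical(classifyCompleteness(1300, 1560)$class, "fragment")
  expect_identical(classifyCompleteness(1560, 1560)$class, "complete")
  expect_identical(classifyCompleteness(1483, 1560)$class, "partial")
  expect_identical(classifyCompleteness(1481, 1560)$class, "fragment")
  ## exactly 5% missing is still partial
  expect_identical(classifyCompleteness(1482, 1560)$class, "partial")
  ## longer than expected clamps to complete
  expect_identical(classifyCompleteness(1600, 1560)$class, "complete")
  expect_error(classifyCompleteness(100, 0), "positive")
  expect_error(classifyCompleteness(-1, 100), "non-negative")
})

test_that("completeness is monotone in observed length", {
  ranks <- c(complete = 0L, partial = 1L, fragment = 2L)
  lExp <- 1000
  cls <- classifyCompleteness(seq(0, 1100, by = 7), lExp)$class
  expect_true(all(diff(ranks[cls]) <= 0L))
  expect_identical(expectedLength(c(1500, 1620)), 1560)
})
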