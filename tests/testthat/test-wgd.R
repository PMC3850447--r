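sp3 <- readNewick("((A,B)X,C)R;")

make_rec <- function(newick, fam = "f") reconcileFamily(readNewick(newick),
                                                        sp3, fam)

test_that("copy patterns classify per the named classes", {
  ## one duplication, two co-orthologs
  r12 <- make_rec("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);")
  expect_identical(classifyFamilyPattern(r12, "X"), "ONE_TO_TWO")

  ## balanced 4-copy nest: three duplication nodes on one branch
  r124 <- make_rec(paste0("((((A|g1,B|g1),(A|g2,B|g2)),",
                          "((A|g3,B|g3),(A|g4,B|g4))),C|g1);"))
  expect_identical(classifyFamilyPattern(r124, "X"), "ONE_TO_TWO_TO_FOUR")

  ## triplet: two duplication nodes, three copies, no balanced nest
  rtri <- make_rec("((((A|g1,B|g1),(A|g2,B|g2)),(A|g3,B|g3)),C|g1);")
  expect_identical(classifyFamilyPattern(rtri, "X"), "TRIPLET")

  ## caterpillar of four copies is not a one-to-two-to-four
  rcat <- make_rec(paste0("(((((A|g1,B|g1),(A|g2,B|g2)),(A|g3,B|g3)),",
                          "(A|g4,B|g4)),C|g1);"))
  expect_identical(classifyFamilyPattern(rcat, "X"), "OTHER")

  expect_error(classifyFamilyPattern(r12, "A"), "no duplication on branch")
})

test_that("profiles count every duplication group exactly once", {
  recs <- list(
    make_rec("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);", "f1"),
    make_rec("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);", "f2"),
    make_rec("((A|g1,C|g1),B|g1);", "f3"))  # root-branch duplication
  prof <- aggregateProfiles(recs)
  expect_identical(nrow(prof$groups), 3L)
  x <- prof$summary[prof$summary$branch_label == "X", ]
  expect_identical(x$n_families, 2L)
  expect_identical(x$n_one_to_two, 2L)
  r <- prof$summary[prof$summary$branch_label == "R", ]
  expect_identical(r$n_families, 1L)
  ## conservation of evidence: every record lands in exactly one group
  dups <- do.call(rbind, lapply(recs, extractDuplications))
  expect_identical(nrow(unique(dups[, c("branch_id", "family_id")])),
                   nrow(prof$groups))
})

test_that("empty input aggregates to an empty profile and zero calls", {
  recs <- list(make_rec("((A|g1,B|g1),C|g1);"))
  prof <- aggregateProfiles(recs)
  expect_identical(nrow(prof$groups), 0L)
  expect_identical(nrow(callEvents(prof)), 0L)
})

test_that("calling rules follow co-duplication counts and pattern majorities", {
  mk_profile <- function(patterns) {
    ## synthesize a BranchProfiles object for one branch
    groups <- data.frame(branch_id = 5L, branch_label = "X",
                         family_id = paste0("f", seq_along(patterns)),
                         pattern = patterns)
    counts <- table(factor(patterns, levels = c("ONE_TO_TWO",
      "ONE_TO_TWO_TO_FOUR", "TRIPLET", "OTHER")))
    summary <- data.frame(branch_id = 5L, branch_label = "X",
      n_families = length(patterns),
      n_one_to_two = as.integer(counts[1]),
      n_one_to_two_to_four = as.integer(counts[2]),
      n_triplet = as.integer(counts[3]),
      n_other = as.integer(counts[4]))
    structure(list(groups = groups, summary = summary, speciesTree = sp3),
              class = "BranchProfiles")
  }
  verdict <- function(patterns, kMin = 3L)
    callEvents(mk_profile(patterns), callConfig(kMin = kMin))$verdict

  expect_identical(verdict("ONE_TO_TWO"), "SINGLE_GENE_DUP")
  expect_identical(verdict(rep("ONE_TO_TWO", 2)), "SINGLE_GENE_DUP")
  expect_identical(verdict(rep("ONE_TO_TWO", 5)), "WGD")
  expect_identical(verdict(c(rep("TRIPLET", 3), "ONE_TO_TWO")), "WGT")
  expect_identical(verdict(c(rep("ONE_TO_TWO_TO_FOUR", 3), "ONE_TO_TWO")),
                   "TWO_WGD")
  expect_identical(verdict(c("TRIPLET", "ONE_TO_TWO_TO_FOUR", "OTHER")),
                   "AMBIGUOUS")
  ## ONE_TO_TWO dominance beats sporadic multi-copy patterns
  expect_identical(verdict(c(rep("ONE_TO_TWO", 4), "TRIPLET")), "WGD")
})

test_that("adding a duplicated family never demotes a genome-scale verdict", {
  recs <- list(
    make_rec("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);", "f1"),
    make_rec("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);", "f2"),
    make_rec("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);", "f3"))
  base <- callEvents(aggregateProfiles(recs))
  expect_true(base$verdict[base$branch_label == "X"] %in%
                c("WGD", "WGT", "TWO_WGD"))
  for (extra in c("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);",
                  "((((A|g1,B|g1),(A|g2,B|g2)),(A|g3,B|g3)),C|g1);")) {
    more <- c(recs, list(make_rec(extra, "f9")))
    calls <- callEvents(aggregateProfiles(more))
    expect_false(calls$verdict[calls$branch_label == "X"] ==
                   "SINGLE_GENE_DUP")
  }
})

test_that("tandem pairs are flagged by scaffold and gene gap", {
  positions <- data.frame(
    gene_id = c("m11E", "m11E2", "far", "other_scaf"),
    scaffold = c("chr1", "chr1", "chr1", "chr2"),
    index = c(10L, 11L, 17L, 10L))
  pairs <- data.frame(gene1 = c("m11E", "m11E", "m11E", "m11E"),
                      gene2 = c("m11E2", "far", "other_scaf", "missing"))
  expect_message(flags <- flagTandem(pairs, positions, maxGap = 1L),
                 "flagged unknown")
  expect_identical(flags$tandem, c(TRUE, FALSE, FALSE, NA))
})

test_that("the inventory matrix counts genes per species and subtype", {
  recs <- list(
    make_rec("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);", "myo8A"),
    make_rec("((A|g1,B|g1),C|g1);", "myo11B"))
  inv <- buildInventory(recs)
  expect_identical(rownames(inv), c("A", "B", "C"))
  expect_identical(inv["A", "myo8A"], 2L)
  expect_identical(inv["C", "myo8A"], 1L)
  expect_identical(inv["B", "myo11B"], 1L)
  ## a lost subtype shows a zero cell
  recs2 <- list(make_rec("(A|g1,B|g1);", "myoX"), recs[[2]])
  inv2 <- buildInventory(recs2)
  expect_identical(inv2["C", "myoX"], 0L)
  ## unassigned genes are a completeness error
  expect_error(buildInventory(recs, subtypes = c("A|g1" = "myo8A")),
               "without subtype")
})
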