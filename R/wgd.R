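## Branch-wise aggregation of duplications across families and the
## genome-scale calling rules. The logic follows the multi-gene argument:
## several independent families co-duplicated on the same species-tree branch
## support a whole genome duplication, whereas one or two duplicated families
## are more plausibly single-gene (or small-region) duplications. Nested
## balanced one-to-two-to-four patterns indicate two successive WGDs on one
## branch; unnested triplets indicate a triplication (WGT).

.PATTERNS <- c("ONE_TO_TWO", "ONE_TO_TWO_TO_FOUR", "TRIPLET", "OTHER")

#' Classify a family's duplication pattern on one branch
#'
#' Duplication nodes of the family mapped to the given branch are grouped
#' into clusters (maximal parent-child runs of same-branch duplications) and
#' the cluster shape is classified:
#' * `ONE_TO_TWO` — one duplication node, two co-orthologous copies;
#' * `TRIPLET` — two duplication nodes, three copies (no nesting constraint:
#'   both `(a,(b,c))` and `((a,b),c)` qualify);
#' * `ONE_TO_TWO_TO_FOUR` — three duplication nodes in a balanced
#'   `((a,b),(c,d))` arrangement, four copies;
#' * `OTHER` — anything else (including multiple independent clusters on the
#'   same branch).
#'
#' @param rec A [ReconciledFamily-class].
#' @param branchId Species-tree branch: integer node id (child end) or label.
#' @return One of `"ONE_TO_TWO"`, `"ONE_TO_TWO_TO_FOUR"`, `"TRIPLET"`,
#'   `"OTHER"`.
#' @export
classifyFamilyPattern <- function(rec, branchId) {
  stopifnot(is(rec, "ReconciledFamily"))
  sidx <- .tindex(rec@speciesTree)
  bid <- .resolveNodes(rec@speciesTree, branchId, sidx)
  dups <- duplicationNodes(rec)
  onBranch <- dups[rec@dupBranch[as.character(dups)] == bid]
  if (!length(onBranch))
    stop("family ", rec@familyId, " has no duplication on branch ",
         sidx$labels[bid])
  gidx <- .tindex(rec@geneTree)
  inSet <- logical(gidx$n)
  inSet[onBranch] <- TRUE
  ## cluster roots: set members whose parent is not in the set
  par <- gidx$parent[onBranch]
  roots <- onBranch[par == 0L | !inSet[pmax(par, 1L)]]
  if (length(roots) > 1L) return("OTHER")
  r <- roots[[1L]]
  size <- sum(inSet)
  if (size == 1L) return("ONE_TO_TWO")
  if (size == 2L) return("TRIPLET")
  if (size == 3L) {
    kids <- gidx$children[[r]]
    if (length(kids) == 2L && all(inSet[kids])) return("ONE_TO_TWO_TO_FOUR")
  }
  "OTHER"
}

#' Aggregate duplication records into per-branch profiles
#'
#' Every (family, branch) pair with at least one duplication contributes one
#' classified pattern; the summary counts patterns per branch.
#'
#' @param recs List of [ReconciledFamily-class] objects (same species tree).
#' @param records Optional precomputed [extractDuplications()] table
#'   (row-bound over `recs`); recomputed when `NULL`.
#' @return An object of class `BranchProfiles`: a list with `groups` (one
#'   row per family x branch: `branch_id`, `branch_label`, `family_id`,
#'   `pattern`) and `summary` (per branch: `n_families` plus one count
#'   column per pattern class).
#' @export
aggregateProfiles <- function(recs, records = NULL) {
  stopifnot(length(recs) > 0L)
  byId <- setNames(recs, vapply(recs, familyId, ""))
  if (is.null(records))
    records <- do.call(rbind, lapply(recs, extractDuplications))
  if (nrow(records) && !all(records$family_id %in% names(byId)))
    stop("duplication record references unknown family: ",
         paste(setdiff(records$family_id, names(byId)), collapse = ", "))
  sidx <- .tindex(recs[[1L]]@speciesTree)
  if (!nrow(records)) {
    groups <- data.frame(branch_id = integer(0), branch_label = character(0),
                         family_id = character(0), pattern = character(0))
  } else {
    groups <- unique(records[, c("branch_id", "family_id")])
    groups$branch_label <- sidx$labels[groups$branch_id]
    groups$pattern <- mapply(function(f, b)
      classifyFamilyPattern(byId[[f]], b),
      groups$family_id, groups$branch_id)
    groups <- groups[order(groups$branch_id, groups$family_id),
                     c("branch_id", "branch_label", "family_id", "pattern")]
    rownames(groups) <- NULL
  }
  summ <- lapply(split(groups, groups$branch_id), function(g) {
    counts <- table(factor(g$pattern, levels = .PATTERNS))
    data.frame(branch_id = g$branch_id[1L], branch_label = g$branch_label[1L],
               n_families = length(unique(g$family_id)),
               n_one_to_two = as.integer(counts["ONE_TO_TWO"]),
               n_one_to_two_to_four = as.integer(counts["ONE_TO_TWO_TO_FOUR"]),
               n_triplet = as.integer(counts["TRIPLET"]),
               n_other = as.integer(counts["OTHER"]),
               stringsAsFactors = FALSE)
  })
  summ <- if (length(summ)) do.call(rbind, summ) else
    data.frame(branch_id = integer(0), branch_label = character(0),
               n_families = integer(0), n_one_to_two = integer(0),
               n_one_to_two_to_four = integer(0), n_triplet = integer(0),
               n_other = integer(0))
  rownames(summ) <- NULL
  structure(list(groups = groups, summary = summ,
                 speciesTree = recs[[1L]]@speciesTree),
            class = "BranchProfiles")
}

#' @export
print.BranchProfiles <- function(x, ...) {
  cat("BranchProfiles over", nrow(x$summary), "branch(es),",
      nrow(x$groups), "family-branch duplication group(s)\n")
  if (nrow(x$summary)) print(x$summary)
  invisible(x)
}

#' Calling configuration
#'
#' @param kMin Minimum number of independently co-duplicated families on a
#'   branch for a genome-scale call (default 3): the smallest count excluded
#'   by the converse rule that one or two duplicated families indicate
#'   single-gene duplications.
#' @param tandemMaxGap Maximum number of intervening genes for two paralogs
#'   to be flagged as a tandem pair (default 1).
#' @return A list of class `callConfig`.
#' @export
callConfig <- function(kMin = 3L, tandemMaxGap = 1L) {
  kMin <- as.integer(kMin); tandemMaxGap <- as.integer(tandemMaxGap)
  if (kMin < 2L) stop("kMin must be >= 2")
  if (tandemMaxGap < 0L) stop("tandemMaxGap must be >= 0")
  structure(list(kMin = kMin, tandemMaxGap = tandemMaxGap),
            class = "callConfig")
}

#' Call genome-scale duplication events per branch
#'
#' For every branch carrying duplications:
#' * fewer than `kMin` duplicated families -> `SINGLE_GENE_DUP`;
#' * otherwise, if no multi-copy pattern is present or `ONE_TO_TWO`
#'   outnumbers the multi-copy patterns combined -> `WGD`;
#' * otherwise `TWO_WGD` when one-to-two-to-four patterns outnumber
#'   triplets, `WGT` when triplets outnumber them, and `AMBIGUOUS` on ties.
#'
#' @param profiles A `BranchProfiles` object from [aggregateProfiles()].
#' @param config A [callConfig()].
#' @return A data.frame with one row per branch: `branch_id`,
#'   `branch_label`, `verdict`, `n_families`, the four pattern counts,
#'   `k_min` used, and `supporting_families` (comma-separated).
#' @export
callEvents <- function(profiles, config = callConfig()) {
  stopifnot(inherits(profiles, "BranchProfiles"),
            inherits(config, "callConfig"))
  s <- profiles$summary
  if (!nrow(s)) {
    return(data.frame(branch_id = integer(0), branch_label = character(0),
                      verdict = character(0), n_families = integer(0),
                      n_one_to_two = integer(0),
                      n_one_to_two_to_four = integer(0),
                      n_triplet = integer(0), n_other = integer(0),
                      k_min = integer(0), supporting_families = character(0)))
  }
  verdict <- character(nrow(s))
  for (i in seq_len(nrow(s))) {
    n12 <- s$n_one_to_two[i]; n124 <- s$n_one_to_two_to_four[i]
    n3 <- s$n_triplet[i]
    verdict[i] <-
      if (s$n_families[i] < config$kMin) "SINGLE_GENE_DUP"
      else if (n124 + n3 == 0L) "WGD"
      else if (n12 > n124 + n3) "WGD"
      else if (n124 > n3) "TWO_WGD"
      else if (n3 > n124) "WGT"
      else "AMBIGUOUS"
  }
  fams <- vapply(split(profiles$groups$family_id, profiles$groups$branch_id),
                 function(f) paste(sort(unique(f)), collapse = ","), "")
  out <- s
  out$verdict <- verdict
  out$k_min <- config$kMin
  out$supporting_families <- fams[as.character(s$branch_id)]
  out[, c("branch_id", "branch_label", "verdict", "n_families",
          "n_one_to_two", "n_one_to_two_to_four", "n_triplet", "n_other",
          "k_min", "supporting_families")]
}

#' Flag tandem paralog pairs
#'
#' A pair is tandem when both genes lie on the same scaffold with at most
#' `maxGap` intervening genes. Tandem pairs corroborate a single-gene-
#' duplication interpretation; they never override the co-duplication count
#' logic of [callEvents()].
#'
#' @param pairs Two-column data.frame (or matrix) of gene ids.
#' @param positions data.frame with columns `gene_id`, `scaffold`, `index`
#'   (ordinal gene index along the scaffold).
#' @param maxGap Maximum intervening genes (default 1).
#' @return The `pairs` data.frame with a logical `tandem` column; `NA` when
#'   either gene is absent from the position table (logged via `message`).
#' @export
flagTandem <- function(pairs, positions, maxGap = 1L) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("gene1", "gene2")
  i1 <- match(pairs$gene1, positions$gene_id)
  i2 <- match(pairs$gene2, positions$gene_id)
  unknown <- unique(c(pairs$gene1[is.na(i1)], pairs$gene2[is.na(i2)]))
  if (length(unknown))
    message("genes absent from position table (flagged unknown): ",
            paste(unknown, collapse = ", "))
  tandem <- ifelse(
    is.na(i1) | is.na(i2), NA,
    positions$scaffold[i1] == positions$scaffold[i2] &
      abs(positions$index[i1] - positions$index[i2]) - 1L <= maxGap)
  pairs$tandem <- tandem
  pairs
}

#' Build the species x subtype inventory matrix
#'
#' Rows are species in species-tree tip order, columns are subtypes, cells
#' are gene counts — the per-genome presence/absence/copy-number table used
#' to scan branches for coordinated duplications.
#'
#' @param recs List of [ReconciledFamily-class] objects.
#' @param subtypes Named character vector mapping every gene leaf label
#'   (species|gene) to a subtype; defaults to each family's id.
#' @return Integer matrix (species x subtype).
#' @export
buildInventory <- function(recs, subtypes = NULL) {
  sp <- recs[[1L]]@speciesTree
  rows <- do.call(rbind, lapply(recs, function(r) {
    labs <- r@geneTree$tip.label
    data.frame(label = labs,
               species = parseLeafLabel(labs, r@sep)$species,
               sub = if (is.null(subtypes)) r@familyId
                     else unname(subtypes[labs]),
               stringsAsFactors = FALSE)
  }))
  if (anyNA(rows$sub)) {
    missing <- rows$label[is.na(rows$sub)]
    stop("genes without subtype assignment: ",
         paste(head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) ", ...")
  }
  cols <- sort(unique(rows$sub))
  mat <- matrix(0L, nrow = ape::Ntip(sp), ncol = length(cols),
                dimnames = list(sp$tip.label, cols))
  tab <- table(rows$species, rows$sub)
  mat[rownames(tab), colnames(tab)] <- as.integer(tab)
  mat
}
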