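## Gene-family evolution simulator. One lineage enters the species-tree
## root; along every branch each gene copy is subject to exponential-waiting-
## time single-gene duplication (rate lambdaDup per copy per unit branch
## length) and loss (lambdaLoss), and to placed whole-genome events: at a WGD
## each surviving copy doubles independently with probability r (retention);
## at a WGT each copy gains two extra copies, each retained independently
## with probability r. Lineages speciate at species-tree nodes; unary nodes
## are suppressed, so emitted gene trees contain only surviving structure.
## Each (seed, family index) pair gets its own RNG stream, so families are
## individually reproducible.

#' SimulationConfig: study conditions for the gene-family simulator
#'
#' @slot speciesTree Rooted species tree (`phylo`) with branch lengths
#'   (missing lengths default to 1) and labelled internal nodes.
#' @slot events data.frame: `branch` (integer node id at the child end),
#'   `branch_label`, `type` (`"WGD"` or `"WGT"`), `position` in (0,1) along
#'   the branch, `retention` in [0,1].
#' @slot lambdaDup,lambdaLoss Per-copy rates per unit branch length.
#' @slot nFamilies Number of families to simulate.
#' @slot seed Integer master seed.
#' @export
setClass("SimulationConfig",
  representation(
    speciesTree = "phylo",
    events = "data.frame",
    lambdaDup = "numeric",
    lambdaLoss = "numeric",
    nFamilies = "integer",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  ev <- object@events
  if (nrow(ev)) {
    n <- ape::Ntip(object@speciesTree) + object@speciesTree$Nnode
    if (any(ev$branch < 1L | ev$branch > n) ||
        any(ev$branch == ape::Ntip(object@speciesTree) + 1L))
      msgs <- c(msgs, "event branch ids must be valid non-root nodes")
    if (any(ev$position <= 0 | ev$position >= 1))
      msgs <- c(msgs, "event positions must lie strictly inside (0,1)")
    if (any(ev$retention < 0 | ev$retention > 1))
      msgs <- c(msgs, "retention must lie in [0,1]")
    if (any(!ev$type %in% c("WGD", "WGT")))
      msgs <- c(msgs, "event type must be WGD or WGT")
  }
  if (object@lambdaDup < 0 || object@lambdaLoss < 0)
    msgs <- c(msgs, "rates must be >= 0")
  if (object@nFamilies < 0L) msgs <- c(msgs, "nFamilies must be >= 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", ape::Ntip(object@speciesTree), "species,",
      object@nFamilies, "families, seed", object@seed, "\n")
  cat("  lambdaDup =", object@lambdaDup, " lambdaLoss =", object@lambdaLoss,
      "\n")
  if (nrow(object@events)) {
    cat("  events:\n")
    print(object@events[, c("branch_label", "type", "position", "retention")])
  } else cat("  events: none\n")
})

#' Build a simulation configuration
#'
#' @param speciesTree `phylo`, Newick string or file. Branch lengths default
#'   to 1 when absent; internal nodes are auto-labelled `N<id>` when blank.
#' @param events data.frame with columns `branch` (node label or id of the
#'   child end of the branch), `type` (`"WGD"`/`"WGT"`), optional `position`
#'   (default 0.5) and `retention` (default 1).
#' @param lambdaDup,lambdaLoss Per-copy rates per unit branch length.
#' @param nFamilies Number of families.
#' @param seed Master seed (all randomness derives from it).
#' @return A [SimulationConfig-class].
#' @examples
#' sp <- readNewick("(((S1:1,S2:1)A:1,S3:1)B:1,S4:1)R;")
#' cfg <- simulationConfig(sp,
#'   events = data.frame(branch = "A", type = "WGD", retention = 0.9),
#'   lambdaLoss = 0.1, nFamilies = 5, seed = 1)
#' @export
simulationConfig <- function(speciesTree, events = NULL, lambdaDup = 0,
                             lambdaLoss = 0, nFamilies = 1L, seed = 1L) {
  if (is.character(speciesTree)) speciesTree <- readNewick(speciesTree)
  speciesTree <- .ensureNodeLabels(speciesTree)
  if (is.null(speciesTree$edge.length))
    speciesTree$edge.length <- rep(1, nrow(speciesTree$edge))
  sidx <- .tindex(speciesTree)
  if (is.null(events) || !nrow(as.data.frame(events))) {
    ev <- data.frame(branch = integer(0), branch_label = character(0),
                     type = character(0), position = numeric(0),
                     retention = numeric(0))
  } else {
    events <- as.data.frame(events, stringsAsFactors = FALSE)
    if (is.null(events$position)) events$position <- 0.5
    if (is.null(events$retention)) events$retention <- 1
    bid <- .resolveNodes(speciesTree, events$branch, sidx)
    ev <- data.frame(branch = bid, branch_label = sidx$labels[bid],
                     type = as.character(events$type),
                     position = as.numeric(events$position),
                     retention = as.numeric(events$retention),
                     stringsAsFactors = FALSE)
  }
  new("SimulationConfig", speciesTree = speciesTree, events = ev,
      lambdaDup = as.numeric(lambdaDup), lambdaLoss = as.numeric(lambdaLoss),
      nFamilies = as.integer(nFamilies), seed = as.integer(seed))
}

## family-local RNG seed (kept below 2^31)
.familySeed <- function(seed, familyIndex) {
  as.integer((abs(as.numeric(seed)) * 7919 + as.numeric(familyIndex) * 104729)
             %% 2147483647)
}

#' Simulate one gene family along the species tree
#'
#' @param config A [SimulationConfig-class].
#' @param familyIndex Positive integer; together with the config seed it
#'   fully determines the family.
#' @return A list: `tree` (`phylo` gene tree with species|gene leaf labels,
#'   or `NULL` when the family went extinct), `extinct` (logical), `truth`
#'   (data.frame of realized events: `family`, `branch_label`, `type`,
#'   `position`, `copies_before`, `copies_after`).
#' @export
simulateFamily <- function(config, familyIndex) {
  stopifnot(is(config, "SimulationConfig"), familyIndex >= 1L)
  sp <- config@speciesTree
  sidx <- .tindex(sp)
  blen <- numeric(sidx$n)
  blen[sp$edge[, 2L]] <- sp$edge.length
  ## per-branch ordered event tables with absolute positions
  evByBranch <- vector("list", sidx$n)
  ev <- config@events
  if (nrow(ev)) {
    for (b in unique(ev$branch)) {
      e <- ev[ev$branch == b, , drop = FALSE]
      e <- e[order(e$position), , drop = FALSE]
      e$at <- e$position * blen[b]
      evByBranch[[b]] <- e
    }
  }
  env <- new.env(parent = emptyenv())
  env$k <- 0L
  env$evBefore <- list(); env$evAfter <- list()
  env$sgd <- list()
  famTag <- paste0("fam", familyIndex)
  lambdaDup <- config@lambdaDup; lambdaLoss <- config@lambdaLoss
  rate <- lambdaDup + lambdaLoss

  join2 <- function(a, b) {
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(a, b)
  }
  emitLeaf <- function(v) {
    env$k <- env$k + 1L
    makeLeafLabel(sidx$labels[v], paste0(famTag, "_g", env$k))
  }
  bump <- function(slot, key, by) {
    cur <- env[[slot]][[key]]
    env[[slot]][[key]] <- (if (is.null(cur)) 0L else cur) + by
  }

  simBranch <- function(v, tpos, evIdx) {
    L <- blen[v]
    evs <- evByBranch[[v]]
    repeat {
      nextEv <- if (!is.null(evs) && evIdx <= nrow(evs)) evs$at[evIdx] else Inf
      segEnd <- min(nextEv, L)
      w <- if (rate > 0) rexp(1L, rate) else Inf
      if (tpos + w < segEnd) {
        tpos <- tpos + w
        if (runif(1L) < lambdaDup / rate) {
          env$sgd[[length(env$sgd) + 1L]] <-
            data.frame(branch_label = sidx$labels[v], type = "SGD",
                       position = if (L > 0) tpos / L else 0,
                       copies_before = 1L, copies_after = 2L,
                       stringsAsFactors = FALSE)
          a <- simBranch(v, tpos, evIdx)
          b <- simBranch(v, tpos, evIdx)
          return(join2(a, b))
        }
        return(NULL)  # loss
      }
      if (is.finite(nextEv) && segEnd == nextEv) {
        key <- paste0(v, "#", evIdx)
        bump("evBefore", key, 1L)
        if (evs$type[evIdx] == "WGD") {
          retained <- runif(1L) < evs$retention[evIdx]
          bump("evAfter", key, if (retained) 2L else 1L)
          if (retained) {
            a <- simBranch(v, nextEv, evIdx + 1L)
            b <- simBranch(v, nextEv, evIdx + 1L)
            return(join2(a, b))
          }
        } else {  # WGT
          extra <- rbinom(1L, 2L, evs$retention[evIdx])
          bump("evAfter", key, 1L + extra)
          if (extra == 1L) {
            a <- simBranch(v, nextEv, evIdx + 1L)
            b <- simBranch(v, nextEv, evIdx + 1L)
            return(join2(a, b))
          }
          if (extra == 2L) {
            a <- simBranch(v, nextEv, evIdx + 1L)
            b <- simBranch(v, nextEv, evIdx + 1L)
            c3 <- simBranch(v, nextEv, evIdx + 1L)
            return(join2(join2(a, b), c3))
          }
        }
        tpos <- nextEv
        evIdx <- evIdx + 1L
        next
      }
      ## branch end reached
      if (v <= sidx$ntip) return(emitLeaf(v))
      subs <- lapply(sidx$children[[v]], function(c) simBranch(c, 0, 1L))
      subs <- subs[!vapply(subs, is.null, TRUE)]
      if (!length(subs)) return(NULL)
      if (length(subs) == 1L) return(subs[[1L]])
      return(subs)
    }
  }

  set.seed(.familySeed(config@seed, familyIndex))
  ## the root is a speciation: one copy enters each root-child branch
  subs <- lapply(sidx$children[[sidx$root]], function(c) simBranch(c, 0, 1L))
  subs <- subs[!vapply(subs, is.null, TRUE)]
  tree <- if (!length(subs)) NULL
          else if (length(subs) == 1L) subs[[1L]]
          else subs

  truthEv <- do.call(rbind, lapply(names(env$evBefore), function(key) {
    parts <- strsplit(key, "#", fixed = TRUE)[[1L]]
    b <- as.integer(parts[1L]); i <- as.integer(parts[2L])
    e <- evByBranch[[b]]
    data.frame(branch_label = sidx$labels[b], type = e$type[i],
               position = e$position[i],
               copies_before = env$evBefore[[key]],
               copies_after = if (is.null(env$evAfter[[key]])) 0L
                              else env$evAfter[[key]],
               stringsAsFactors = FALSE)
  }))
  truth <- rbind(truthEv, if (length(env$sgd)) do.call(rbind, env$sgd))
  if (is.null(truth))
    truth <- data.frame(branch_label = character(0), type = character(0),
                        position = numeric(0), copies_before = integer(0),
                        copies_after = integer(0))
  truth <- data.frame(family = rep(famTag, nrow(truth)), truth,
                      stringsAsFactors = FALSE)

  phy <- NULL
  if (!is.null(tree)) {
    inner <- .nestedToNewick(tree)
    ## a single surviving lineage still needs a parenthesized newick
    nwk <- if (is.character(tree)) paste0("(", inner, ");")
           else paste0(inner, ";")
    phy <- ape::read.tree(text = nwk)
  }
  list(tree = phy, extinct = is.null(tree), truth = truth)
}

## nested list-of-2 (or character leaf) -> newick
.nestedToNewick <- function(x) {
  if (is.character(x)) return(x)
  paste0("(", paste(vapply(x, .nestedToNewick, ""), collapse = ","), ")")
}

#' Closed-form copy counts in the deterministic regime
#'
#' With no duplication/loss noise and full retention, the copy count of a
#' species is the product over the whole-genome events on its root-to-leaf
#' path of 2 (WGD) or 3 (WGT).
#'
#' @param config A [SimulationConfig-class] with `lambdaDup = lambdaLoss =
#'   0` and all retentions 1 (anything else is a usage error).
#' @param speciesId Species tip label.
#' @return Integer expected copy count.
#' @export
expectedCopyCounts <- function(config, speciesId) {
  stopifnot(is(config, "SimulationConfig"))
  if (config@lambdaDup != 0 || config@lambdaLoss != 0 ||
      (nrow(config@events) && any(config@events$retention != 1)))
    stop("expectedCopyCounts applies to the deterministic regime only ",
         "(lambdaDup = lambdaLoss = 0, retention 1)")
  sidx <- .tindex(config@speciesTree)
  tip <- .resolveNodes(config@speciesTree, speciesId, sidx)
  if (tip > sidx$ntip) stop("not a species tip: ", speciesId)
  path <- integer(0)
  v <- tip
  while (v != 0L) { path <- c(path, v); v <- sidx$parent[v] }
  ev <- config@events[config@events$branch %in% path, , drop = FALSE]
  if (!nrow(ev)) return(1L)
  as.integer(prod(ifelse(ev$type == "WGD", 2L, 3L)))
}

#' Simulate a whole dataset to disk
#'
#' Writes one Newick file per family (empty file for extinct families), a
#' truth table TSV of realized events, a per-family summary TSV, and the
#' configuration as YAML. Re-running with an identical config produces
#' byte-identical output.
#'
#' @param config A [SimulationConfig-class].
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with `forest` (tree file paths), `truth`,
#'   `families` and `config` paths.
#' @export
simulateDataset <- function(config, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fams <- lapply(seq_len(config@nFamilies), function(i)
    simulateFamily(config, i))
  paths <- character(config@nFamilies)
  for (i in seq_len(config@nFamilies)) {
    paths[i] <- file.path(outDir, sprintf("fam%04d.nwk", i))
    if (fams[[i]]$extinct) writeLines(character(0), paths[i])
    else writeNewick(fams[[i]]$tree, paths[i])
  }
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
  truthPath <- file.path(outDir, "truth.tsv")
  write.table(truth, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  famTab <- data.frame(
    family = paste0("fam", seq_len(config@nFamilies)),
    file = basename(paths),
    n_leaves = vapply(fams, function(f)
      if (f$extinct) 0L else ape::Ntip(f$tree), 0L),
    extinct = vapply(fams, `[[`, TRUE, "extinct"))
  famPath <- file.path(outDir, "families.tsv")
  write.table(famTab, famPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(list(
    species_tree = writeNewick(config@speciesTree),
    events = if (nrow(config@events)) lapply(seq_len(nrow(config@events)),
      function(i) as.list(config@events[i, c("branch_label", "type",
                                             "position", "retention")]))
      else list(),
    lambda_dup = config@lambdaDup, lambda_loss = config@lambdaLoss,
    n_families = config@nFamilies, seed = config@seed), cfgPath)
  invisible(list(forest = paths, truth = truthPath, families = famPath,
                 config = cfgPath))
}

#' Synthetic gene-structure fixture
#'
#' Builds a small two-subtype fixture for the gene-structure stage: a
#' gapless protein alignment and matching GFF3 text in which all members
#' share a set of intron positions and every member of group A additionally
#' carries one extra tail intron — the discriminating-intron situation seen
#' between the two class VIII subtypes. All coordinates are synthetic.
#'
#' @param nA,nB Members per group.
#' @param nResidues Protein length (alignment columns; the MSA is gapless).
#' @param sharedOffsets Coding-nucleotide offsets of the introns shared by
#'   both groups.
#' @param extraOffset Offset of the group-A-only tail intron.
#' @return A list: `msa` (`AAStringSet`), `gff` (path to a written GFF3
#'   file), `genesA`, `genesB` (gene ids).
#' @export
makeStructureFixture <- function(nA = 3L, nB = 3L, nResidues = 100L,
                                 sharedOffsets = c(30L, 151L),
                                 extraOffset = 270L) {
  codingLen <- 3L * nResidues
  stopifnot(all(c(sharedOffsets, extraOffset) < codingLen))
  genesA <- paste0("geneA", seq_len(nA))
  genesB <- paste0("geneB", seq_len(nB))
  gffLines <- c("##gff-version 3")
  addGene <- function(g, offsets) {
    bounds <- c(0L, sort(offsets), codingLen)
    pos <- 1L
    lines <- character(0)
    for (i in seq_len(length(bounds) - 1L)) {
      len <- bounds[i + 1L] - bounds[i]
      lines <- c(lines, paste(paste0("scaf_", g), "synthetic", "CDS",
                              pos, pos + len - 1L, ".", "+", ".",
                              paste0("ID=", g, ".cds", i, ";Parent=", g),
                              sep = "\t"))
      pos <- pos + len + 100L  # 100-nt introns
    }
    lines
  }
  for (g in genesA) gffLines <- c(gffLines, addGene(g, c(sharedOffsets,
                                                         extraOffset)))
  for (g in genesB) gffLines <- c(gffLines, addGene(g, sharedOffsets))
  gffPath <- tempfile(fileext = ".gff3")
  writeLines(gffLines, gffPath)
  seqs <- Biostrings::AAStringSet(setNames(
    rep(paste(rep("M", nResidues), collapse = ""), nA + nB),
    c(genesA, genesB)))
  list(msa = seqs, gff = gffPath, genesA = genesA, genesB = genesB)
}
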