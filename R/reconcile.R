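## LCA reconciliation of rooted binary gene trees against a rooted species
## tree. Every internal gene-tree node is mapped to the last common ancestor
## (in the species tree) of its descendant species; a node whose mapping
## equals a child's mapping is a duplication. This mapping minimises the
## duplication count over all ancestor-consistent mappings.

#' ReconciledFamily: a gene tree annotated with species mapping and events
#'
#' Produced by [reconcileFamily()]. Node ids follow ape numbering of the
#' respective tree. `mapping` gives, for every gene-tree node, the id of the
#' species-tree node it maps to; `events` labels each gene-tree node as
#' `"leaf"`, `"speciation"` or `"duplication"`; `dupBranch` gives, for each
#' duplication node, the species-tree branch (identified by the node id at
#' its child end) on which the duplication occurred.
#'
#' @slot familyId Character scalar.
#' @slot geneTree Rooted binary gene tree (`phylo`).
#' @slot speciesTree Rooted species tree (`phylo`), internal nodes labelled.
#' @slot mapping Integer vector over gene-tree node ids.
#' @slot events Character vector over gene-tree node ids.
#' @slot dupBranch Named integer vector: gene-tree duplication node id ->
#'   species-tree branch id.
#' @slot sep Leaf-label separator used.
#' @export
setClass("ReconciledFamily",
  representation(
    familyId = "character",
    geneTree = "phylo",
    speciesTree = "phylo",
    mapping = "integer",
    events = "character",
    dupBranch = "integer",
    sep = "character"
  )
)

setValidity("ReconciledFamily", function(object) {
  gt <- object@geneTree
  n <- ape::Ntip(gt) + gt$Nnode
  msgs <- character(0)
  if (length(object@familyId) != 1L) msgs <- c(msgs, "familyId must be scalar")
  if (length(object@mapping) != n) msgs <- c(msgs, "mapping length != #nodes")
  if (length(object@events) != n) msgs <- c(msgs, "events length != #nodes")
  dup <- which(object@events == "duplication")
  if (!setequal(as.integer(names(object@dupBranch)), dup))
    msgs <- c(msgs, "dupBranch keys must be exactly the duplication nodes")
  if (length(object@dupBranch) &&
      !all(object@dupBranch == object@mapping[as.integer(names(object@dupBranch))]))
    msgs <- c(msgs, "dupBranch must equal the mapping of each duplication node")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ReconciledFamily Family identifier.
#' @param object A `ReconciledFamily`.
#' @export
setGeneric("familyId", function(object) standardGeneric("familyId"))
#' @rdname ReconciledFamily-class
#' @export
setMethod("familyId", "ReconciledFamily", function(object) object@familyId)

#' @describeIn ReconciledFamily The reconciled gene tree.
#' @export
setGeneric("geneTree", function(object) standardGeneric("geneTree"))
#' @rdname ReconciledFamily-class
#' @export
setMethod("geneTree", "ReconciledFamily", function(object) object@geneTree)

#' @describeIn ReconciledFamily Per-node species mapping (integer node ids).
#' @export
setGeneric("speciesMapping", function(object) standardGeneric("speciesMapping"))
#' @rdname ReconciledFamily-class
#' @export
setMethod("speciesMapping", "ReconciledFamily", function(object) object@mapping)

#' @describeIn ReconciledFamily Per-node event labels.
#' @export
setGeneric("nodeEvents", function(object) standardGeneric("nodeEvents"))
#' @rdname ReconciledFamily-class
#' @export
setMethod("nodeEvents", "ReconciledFamily", function(object) object@events)

#' @describeIn ReconciledFamily Gene-tree node ids labelled as duplications.
#' @export
setGeneric("duplicationNodes", function(object) standardGeneric("duplicationNodes"))
#' @rdname ReconciledFamily-class
#' @export
setMethod("duplicationNodes", "ReconciledFamily",
          function(object) as.integer(names(object@dupBranch)))

#' @describeIn ReconciledFamily Number of duplication nodes.
#' @export
setGeneric("nDuplications", function(object) standardGeneric("nDuplications"))
#' @rdname ReconciledFamily-class
#' @export
setMethod("nDuplications", "ReconciledFamily",
          function(object) length(object@dupBranch))

setMethod("show", "ReconciledFamily", function(object) {
  cat("ReconciledFamily '", object@familyId, "'\n", sep = "")
  cat("  gene tree: ", ape::Ntip(object@geneTree), " leaves\n", sep = "")
  nd <- length(object@dupBranch)
  cat("  duplications: ", nd, "\n", sep = "")
  if (nd) {
    sidx <- .tindex(object@speciesTree)
    cat("  on branches: ",
        paste(sidx$labels[object@dupBranch], collapse = ", "), "\n", sep = "")
  }
})

#' Reconcile a gene tree against the species tree
#'
#' Maps every gene-tree node to the species-tree LCA of its descendant
#' species and labels internal nodes as speciation or duplication. A node is
#' a duplication exactly when its mapping equals the mapping of at least one
#' of its children; the duplication is assigned to the species-tree branch
#' above the mapped node, i.e. the event is placed "at the origin of" the
#' mapped clade. The number of duplications so obtained is minimal over all
#' ancestor-consistent mappings.
#'
#' @param geneTree Rooted binary gene tree (`phylo`) with species|gene
#'   leaf labels.
#' @param speciesTree Rooted species tree (`phylo`) whose tips are species
#'   codes. Polytomies are allowed here.
#' @param familyId Identifier carried through to downstream tables.
#' @param sep Leaf-label separator.
#' @param resolvePolytomies Gene trees with polytomies are rejected by
#'   default; set `TRUE` to resolve them arbitrarily (left-to-right, via
#'   [ape::multi2di()]) with a message.
#' @return A [ReconciledFamily-class] object.
#' @examples
#' sp <- readNewick("((A,B)X,C)R;")
#' gt <- readNewick("(((A|g1,B|g1),(A|g2,B|g2)),C|g1);")
#' rec <- reconcileFamily(gt, sp, "fam1")
#' nDuplications(rec)
#' @export
reconcileFamily <- function(geneTree, speciesTree, familyId = "family",
                            sep = "|", resolvePolytomies = FALSE) {
  speciesTree <- .ensureNodeLabels(speciesTree)
  sidx <- .tindex(speciesTree)
  gidx <- .tindex(geneTree)
  ## binarity
  kdeg <- lengths(gidx$children)
  poly <- which(kdeg > 2L)
  if (length(poly)) {
    if (!resolvePolytomies)
      stop("gene tree has non-binary node(s): ",
           paste(poly, collapse = ", "),
           " (set resolvePolytomies = TRUE to resolve left-to-right)")
    message("resolving ", length(poly),
            " polytomy(ies) left-to-right in family ", familyId)
    geneTree <- ape::multi2di(geneTree, random = FALSE)
    gidx <- .tindex(geneTree)
  }
  sp <- parseLeafLabel(geneTree$tip.label, sep)$species
  tipMap <- match(sp, speciesTree$tip.label)
  if (anyNA(tipMap))
    stop("species not in species tree: ",
         paste(unique(sp[is.na(tipMap)]), collapse = ", "))

  n <- gidx$n
  mapping <- integer(n)
  events <- character(n)
  mapping[seq_len(gidx$ntip)] <- tipMap
  events[seq_len(gidx$ntip)] <- "leaf"
  for (v in .postorder(gidx)) {
    kids <- gidx$children[[v]]
    if (!length(kids)) next
    m <- mapping[kids[1L]]
    for (k in kids[-1L]) m <- .lca2(sidx, m, mapping[k])
    mapping[v] <- m
    ## a unary pass-through node (1-tip trees) is no event
    events[v] <- if (length(kids) >= 2L && any(mapping[kids] == m))
      "duplication" else "speciation"
  }
  dup <- which(events == "duplication")
  dupBranch <- setNames(mapping[dup], dup)
  new("ReconciledFamily", familyId = familyId, geneTree = geneTree,
      speciesTree = speciesTree, mapping = mapping, events = events,
      dupBranch = dupBranch, sep = sep)
}

#' Extract one record per duplication event
#'
#' @param rec A [ReconciledFamily-class].
#' @return A data.frame with one row per duplication node: `family_id`,
#'   `node_id`, `branch_id` (species-tree node id at the child end of the
#'   branch), `branch_label`, `n_copies` (leaves under the node) and a
#'   list-column `species_counts` of named per-species descendant copy
#'   counts.
#' @export
extractDuplications <- function(rec) {
  stopifnot(is(rec, "ReconciledFamily"))
  gidx <- .tindex(rec@geneTree)
  sidx <- .tindex(rec@speciesTree)
  dup <- duplicationNodes(rec)
  if (!length(dup)) {
    return(data.frame(family_id = character(0), node_id = integer(0),
                      branch_id = integer(0), branch_label = character(0),
                      n_copies = integer(0),
                      species_counts = I(list())))
  }
  sp <- parseLeafLabel(rec@geneTree$tip.label, rec@sep)$species
  counts <- lapply(dup, function(v) {
    leaves <- .leavesUnder(gidx, v)
    table(sp[leaves])
  })
  data.frame(
    family_id = rec@familyId,
    node_id = dup,
    branch_id = unname(rec@dupBranch),
    branch_label = sidx$labels[rec@dupBranch],
    n_copies = vapply(counts, sum, 0L),
    species_counts = I(lapply(counts, function(x) setNames(as.integer(x), names(x)))),
    stringsAsFactors = FALSE
  )
}

## ---- serialization --------------------------------------------------------

#' Write reconciliations to JSON
#'
#' Serializes a list of reconciled families: family id, gene-tree Newick,
#' per-node mapping and event tables, and the duplication records. The JSON
#' is sufficient to re-run downstream calling exactly.
#'
#' @param recs List of [ReconciledFamily-class] objects.
#' @param path Output file.
#' @export
writeReconciliation <- function(recs, path) {
  sidx <- .tindex(recs[[1L]]@speciesTree)
  payload <- list(
    species_tree = writeNewick(recs[[1L]]@speciesTree),
    families = lapply(recs, function(r) {
      list(family_id = r@familyId,
           gene_tree = writeNewick(r@geneTree),
           mapping = setNames(as.list(sidx$labels[r@mapping]),
                              seq_along(r@mapping)),
           events = setNames(as.list(r@events), seq_along(r@events)))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read reconciliations back from JSON
#'
#' The gene trees stored in the JSON are re-reconciled against the stored
#' species tree, reproducing the original objects deterministically.
#'
#' @param path JSON file written by [writeReconciliation()].
#' @param sep Leaf-label separator.
#' @return List of [ReconciledFamily-class] objects.
#' @export
readReconciliation <- function(path, sep = "|") {
  payload <- jsonlite::read_json(path)
  sp <- readNewick(payload$species_tree)
  lapply(payload$families, function(f)
    reconcileFamily(readNewick(f$gene_tree), sp, f$family_id, sep = sep))
}
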