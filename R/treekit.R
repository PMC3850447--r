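## Rooted-tree toolkit shared by all stages: Newick I/O, node indexing,
## LCA queries, outgroup rooting, and the species|gene leaf-label convention.
## Trees are ape "phylo" objects; node ids follow ape numbering
## (1..Ntip tips, Ntip+1 .. Ntip+Nnode internal, root = Ntip+1).

#' Read a rooted tree from Newick text or a Newick file
#'
#' A thin, validating wrapper around [ape::read.tree()]. The input is treated
#' as a file path when a file of that name exists, otherwise as Newick text.
#' Beyond parsing, the tree is checked for duplicate leaf labels and the
#' obvious malformations (unbalanced parentheses, missing terminal `;`) are
#' reported with the character offset at which they occur.
#'
#' @param x Newick string (terminated by `;`) or path to a Newick file.
#' @return An object of class `phylo`, rooted, preserving child order,
#'   labels and branch lengths.
#' @examples
#' tr <- readNewick("((A:1,B:1)X:1,C:2)R;")
#' writeNewick(tr)
#' @seealso [writeNewick()], [treeLCA()], [rootWithOutgroup()]
#' @export
readNewick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  txt <- if (file.exists(x) && !grepl("[();]", x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  .checkNewickSyntax(txt)
  phy <- tryCatch(ape::read.tree(text = txt),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("newick parse error in: ", substr(txt, 1, 60))
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  phy
}

## cheap syntax scan so errors carry a character offset
.checkNewickSyntax <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unmatched ')' at character ", i)
    }
  }
  if (depth > 0L)
    stop("newick parse error: ", depth,
         " unclosed '(' at end of input (length ", length(chars), ")")
  if (!grepl(";\\s*$", txt))
    stop("newick parse error: missing terminal ';' at character ",
         length(chars))
  invisible(TRUE)
}

#' Write a tree as Newick
#'
#' @param phy A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
writeNewick <- function(phy, file = NULL) {
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

## ---- internal node index -------------------------------------------------

## Flat index of a phylo object: parent vector, ordered children, depths,
## labels per node id. Root has parent 0.
.tindex <- function(phy) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  parent <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]; c <- phy$edge[i, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- ntip + 1L
  depth <- integer(n)
  ## BFS from root (edges in cladewise order guarantee parents first only
  ## after reorder; do explicit queue to be safe)
  queue <- root
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (c in children[[v]]) {
      depth[c] <- depth[v] + 1L
      queue <- c(queue, c)
    }
  }
  labels <- character(n)
  labels[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label))
    labels[root:n] <- phy$node.label
  list(ntip = ntip, n = n, root = root, parent = parent,
       children = children, depth = depth, labels = labels)
}

## postorder node sequence (children before parents)
.postorder <- function(idx) {
  ord <- integer(0)
  stack <- idx$root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ord <- c(v, ord)  # prepend: reversed preorder = children before parents
    stack <- c(stack, idx$children[[v]])
  }
  ord
}

## resolve node labels/ids to integer ids
.resolveNodes <- function(phy, nodes, idx = .tindex(phy)) {
  if (is.numeric(nodes)) {
    ids <- as.integer(nodes)
    bad <- ids[ids < 1L | ids > idx$n]
    if (length(bad)) stop("unknown node id(s): ", paste(bad, collapse = ", "))
    return(ids)
  }
  ids <- match(nodes, idx$labels)
  if (anyNA(ids))
    stop("unknown node label(s): ", paste(nodes[is.na(ids)], collapse = ", "))
  as.integer(ids)
}

## give unlabelled internal nodes stable names N<id> so branches are nameable
.ensureNodeLabels <- function(phy) {
  ntip <- ape::Ntip(phy)
  ids <- ntip + seq_len(phy$Nnode)
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
  blank <- is.na(phy$node.label) | phy$node.label == ""
  phy$node.label[blank] <- paste0("N", ids[blank])
  phy
}

#' Last common ancestor of a set of nodes
#'
#' Returns the unique deepest node that is ancestral to (or equal to) every
#' node in `nodes`. Works for any mixture of tips and internal nodes,
#' addressed by integer id or by label.
#'
#' @param phy A `phylo` object.
#' @param nodes Vector of node ids (integers) or labels (character).
#' @return Integer node id of the LCA.
#' @examples
#' tr <- readNewick("((A,B)X,C)R;")
#' treeLCA(tr, c("A", "B"))  # the node labelled X
#' @export
treeLCA <- function(phy, nodes) {
  idx <- .tindex(phy)
  ids <- .resolveNodes(phy, nodes, idx)
  if (!length(ids)) stop("empty node set")
  cur <- ids[1L]
  for (v in ids[-1L]) cur <- .lca2(idx, cur, v)
  cur
}

.lca2 <- function(idx, a, b) {
  while (idx$depth[a] > idx$depth[b]) a <- idx$parent[a]
  while (idx$depth[b] > idx$depth[a]) b <- idx$parent[b]
  while (a != b) { a <- idx$parent[a]; b <- idx$parent[b] }
  a
}

#' Root a tree on the edge separating an outgroup from the ingroup
#'
#' @param phy A `phylo` object (rooted or effectively unrooted).
#' @param outgroup Character vector of leaf labels forming the outgroup.
#' @param prune When `TRUE` the outgroup subtree is removed after rooting.
#' @return A rooted `phylo`. When the tree is already rooted on the
#'   outgroup edge it is returned unchanged (idempotence).
#' @examples
#' tr <- readNewick("(A,B,OUT);")
#' writeNewick(rootWithOutgroup(tr, "OUT"))
#' @export
rootWithOutgroup <- function(phy, outgroup, prune = FALSE) {
  missing <- setdiff(outgroup, phy$tip.label)
  if (length(missing))
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(outgroup) == length(phy$tip.label))
    stop("outgroup cannot contain every leaf")
  ## already rooted on the outgroup edge? (one root child spans exactly it)
  idx <- .tindex(phy)
  rootKids <- idx$children[[idx$root]]
  if (length(rootKids) == 2L) {
    for (k in rootKids) {
      below <- .leavesUnder(idx, k)
      if (setequal(idx$labels[below], outgroup)) {
        return(if (prune) ape::drop.tip(phy, outgroup) else phy)
      }
    }
  }
  ok <- ape::is.monophyletic(phy, outgroup)
  rooted <- tryCatch(
    ape::root(phy, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) NULL)
  if (!ok || is.null(rooted))
    stop("outgroup is not bipartition-compatible with the tree: ",
         paste(outgroup, collapse = ", "))
  if (prune) rooted <- ape::drop.tip(rooted, outgroup)
  rooted
}

.leavesUnder <- function(idx, v) {
  if (v <= idx$ntip) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (u <= idx$ntip) out <- c(out, u)
    else stack <- c(stack, idx$children[[u]])
  }
  out
}

## ---- leaf-label convention ----------------------------------------------

#' Split species|gene leaf labels
#'
#' Gene-tree leaves carry both a species code and a family-local gene name,
#' joined by a separator (default `|`). The separator must occur exactly
#' once in each label.
#'
#' @param label Character vector of leaf labels.
#' @param sep Single separator character.
#' @return A data.frame with columns `species` and `gene`.
#' @examples
#' parseLeafLabel("At|Myo11E")
#' @export
parseLeafLabel <- function(label, sep = "|") {
  stopifnot(nchar(sep) == 1L)
  nsep <- lengths(regmatches(label, gregexpr(sep, label, fixed = TRUE)))
  bad <- label[nsep != 1L]
  if (length(bad))
    stop("leaf label must contain '", sep, "' exactly once: ",
         paste(bad, collapse = ", "))
  parts <- strsplit(label, sep, fixed = TRUE)
  species <- vapply(parts, `[`, "", 1L)
  gene <- vapply(parts, `[`, "", 2L)
  if (any(species == ""))
    stop("empty species code in label(s): ",
         paste(label[species == ""], collapse = ", "))
  data.frame(species = species, gene = gene, stringsAsFactors = FALSE)
}

#' Compose species|gene leaf labels
#' @param species,gene Character vectors (recycled).
#' @param sep Separator character.
#' @return Character vector of labels.
#' @export
makeLeafLabel <- function(species, gene, sep = "|") {
  if (any(grepl(sep, c(species, gene), fixed = TRUE)))
    stop("separator '", sep, "' must not occur inside species or gene ids")
  paste0(species, sep, gene)
}

#' Species code of every leaf of a gene tree
#' @param phy Gene tree (`phylo`) with species|gene leaf labels.
#' @param sep Separator character.
#' @return Character vector, one species code per tip, named by tip label.
#' @export
leafSpecies <- function(phy, sep = "|") {
  sp <- parseLeafLabel(phy$tip.label, sep)$species
  names(sp) <- phy$tip.label
  sp
}
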