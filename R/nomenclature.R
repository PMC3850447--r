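## Deterministic ortholog/paralog naming from a reconciled family.
## Numbers mark duplications affecting whole branches (multi-species
## ortholog groups); lowercase letters mark additional duplications within
## single species. Rendered grammar: <class><SUBTYPE>[<number>][<letter>],
## e.g. "11B2a". Numbering and lettering follow a canonical tree order
## (children sorted by lexicographically smallest leaf label) so that input
## rotation or file order never changes a name.

#' Parse a rendered myosin-style name
#'
#' @param text Character vector of names such as `"11B2a"` or `"8A"`.
#' @return data.frame with columns `class_id` (integer), `subtype_letter`,
#'   `ortholog_number` (integer or NA), `paralog_letter` (character or NA).
#' @examples
#' parseMyosinName("11B2a")
#' @export
parseMyosinName <- function(text) {
  m <- regmatches(text, regexec("^(8|11)([A-Z])([1-9][0-9]*)?([a-z])?$", text))
  bad <- text[vapply(m, length, 0L) == 0L]
  if (length(bad))
    stop("name does not match <class><SUBTYPE>[number][letter] grammar: ",
         paste(bad, collapse = ", "))
  data.frame(
    class_id = as.integer(vapply(m, `[`, "", 2L)),
    subtype_letter = vapply(m, `[`, "", 3L),
    ortholog_number = suppressWarnings(as.integer(vapply(m, `[`, "", 4L))),
    paralog_letter = ifelse(vapply(m, `[`, "", 5L) == "", NA_character_,
                            vapply(m, `[`, "", 5L)),
    stringsAsFactors = FALSE
  )
}

#' Render a parsed name back to text
#'
#' `renderMyosinName(parseMyosinName(x))` is the identity.
#'
#' @param name data.frame as returned by [parseMyosinName()] (or a list with
#'   the same fields).
#' @return Character vector.
#' @export
renderMyosinName <- function(name) {
  name <- as.data.frame(name, stringsAsFactors = FALSE)
  if (any(!name$class_id %in% c(8L, 11L)))
    stop("class_id must be 8 or 11")
  if (any(!grepl("^[A-Z]$", name$subtype_letter)))
    stop("subtype_letter must be a single uppercase letter")
  paste0(name$class_id, name$subtype_letter,
         ifelse(is.na(name$ortholog_number), "", name$ortholog_number),
         ifelse(is.na(name$paralog_letter), "", name$paralog_letter))
}

#' Letter series for the two ancestral class VIII branches
#'
#' Homologs of the A branch are lettered A, C, E, G, ... and homologs of the
#' B branch B, D, F, H, ..., so membership in one of the two major subtypes
#' stays visible in the name.
#'
#' @param group `"A"` or `"B"`.
#' @param ordinal Positive integer: the k-th named homolog on that branch.
#' @return A single uppercase letter.
#' @examples
#' assignClass8Series("A", 2)  # "C"
#' assignClass8Series("B", 2)  # "D"
#' @export
assignClass8Series <- function(group, ordinal) {
  group <- match.arg(group, c("A", "B"))
  ordinal <- as.integer(ordinal)
  if (is.na(ordinal) || ordinal < 1L) stop("ordinal must be a positive integer")
  pos <- if (group == "A") 2L * ordinal - 1L else 2L * ordinal
  if (pos > 26L) stop("ordinal ", ordinal, " exceeds the alphabet for group ",
                      group)
  LETTERS[pos]
}

## canonical child order: children sorted by their subtree's smallest leaf
## label; returns for each node the ordered children and the smallest label
.canonicalOrder <- function(gidx) {
  minLabel <- character(gidx$n)
  childOrder <- vector("list", gidx$n)
  for (v in .postorder(gidx)) {
    kids <- gidx$children[[v]]
    if (!length(kids)) {
      minLabel[v] <- gidx$labels[v]
    } else {
      ord <- kids[order(minLabel[kids], method = "radix")]
      childOrder[[v]] <- ord
      minLabel[v] <- minLabel[ord[1L]]
    }
  }
  list(childOrder = childOrder, minLabel = minLabel)
}

#' Assign ortholog/paralog names across a reconciled family
#'
#' Duplications mapped to internal (multi-species) species-tree branches cut
#' the gene tree into numbered ortholog groups; duplications mapped to
#' terminal branches yield lowercase paralog letters within a species.
#' Groups are numbered, and letters assigned, in canonical tree order:
#' subtrees are sorted by their lexicographically smallest leaf label, then
#' taken left to right. When the family has a single ortholog group no
#' number is emitted; when a species has a single copy within a group no
#' letter is emitted.
#'
#' @param rec A [ReconciledFamily-class].
#' @param classId 8 or 11.
#' @param subtypeLetter Single uppercase letter naming the subtype.
#' @param calls Optional [callEvents()] table covering the family's branches
#'   (recorded in the result's attributes; naming itself is purely
#'   topological).
#' @param anchors Optional named integer vector `gene leaf label -> ortholog
#'   number` pinning published numbers; remaining groups keep canonical
#'   order on the remaining numbers.
#' @param sep Leaf-label separator.
#' @return data.frame with columns `species`, `gene`, `label` (the leaf
#'   label), `group` (ortholog group ordinal or NA), `name`.
#' @examples
#' sp <- readNewick("((Br,Al)X,Cp)R;")
#' gt <- readNewick(paste0("(((Al|a1,Br|g1),(Al|a2,(Br|g2a,Br|g2b))),",
#'                         "((Al|a3,Br|g3),(Al|a4,(Br|g4a,Br|g4b))));"))
#' rec <- reconcileFamily(gt, sp, "myo11B")
#' assignNames(rec, 11, "B")
#' @export
assignNames <- function(rec, classId, subtypeLetter, calls = NULL,
                        anchors = NULL, sep = "|") {
  stopifnot(is(rec, "ReconciledFamily"))
  gidx <- .tindex(rec@geneTree)
  sidx <- .tindex(rec@speciesTree)
  canon <- .canonicalOrder(gidx)
  dup <- duplicationNodes(rec)
  internalDup <- dup[rec@dupBranch[as.character(dup)] > sidx$ntip]

  ## walk the canonical tree; group signature grows at internal-branch dups
  leafOrder <- integer(0)
  leafSig <- character(gidx$n)
  walk <- function(v, sig) {
    kids <- canon$childOrder[[v]]
    if (is.null(kids)) {
      leafSig[v] <<- sig
      leafOrder <<- c(leafOrder, v)
      return(invisible(NULL))
    }
    isCut <- v %in% internalDup
    for (j in seq_along(kids))
      walk(kids[j], if (isCut) paste0(sig, ".", j) else sig)
  }
  walk(gidx$root, "r")

  sigs <- leafSig[leafOrder]
  groupOf <- match(sigs, unique(sigs))  # first-appearance order = canonical
  nGroups <- length(unique(sigs))

  ## anchor remapping of group numbers
  numbers <- seq_len(nGroups)
  if (!is.null(anchors) && nGroups > 1L) {
    lab <- gidx$labels[leafOrder]
    anchorGroup <- groupOf[match(names(anchors), lab)]
    if (anyNA(anchorGroup))
      stop("anchor gene(s) not in tree: ",
           paste(names(anchors)[is.na(anchorGroup)], collapse = ", "))
    want <- as.integer(anchors)
    agg <- tapply(want, anchorGroup, unique, simplify = FALSE)
    if (any(lengths(agg) != 1L) || anyDuplicated(unlist(agg)))
      stop("conflicting anchor numbers")
    numbers[as.integer(names(agg))] <- unlist(agg)
    free <- setdiff(seq_len(nGroups), unlist(agg))
    numbers[setdiff(seq_len(nGroups), as.integer(names(agg)))] <- free
    if (anyDuplicated(numbers)) stop("anchor numbers collide")
  }

  labels <- gidx$labels[leafOrder]
  idf <- parseLeafLabel(labels, sep)
  out <- data.frame(species = idf$species, gene = idf$gene, label = labels,
                    group = if (nGroups > 1L) numbers[groupOf] else NA_integer_,
                    stringsAsFactors = FALSE)
  ## lowercase letters within (group, species) in canonical order
  key <- paste(groupOf, out$species)
  cnt <- table(key)
  rank <- stats::ave(seq_along(key), key, FUN = seq_along)
  letter <- ifelse(cnt[key] > 1L, letters[rank], NA_character_)
  if (any(cnt > 26L)) stop("more than 26 paralogs of one species in a group")
  out$name <- paste0(classId, subtypeLetter,
                     ifelse(is.na(out$group), "", out$group),
                     ifelse(is.na(letter), "", letter))
  if (anyDuplicated(paste(out$species, out$name)))
    stop("internal error: non-unique names within a species")
  attr(out, "calls") <- calls
  rownames(out) <- NULL
  out
}
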