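## Exon-intron structure evidence. Coding exon coordinates are reduced to
## intron descriptors (coding offset n = number of coding nucleotides before
## the intron; phase p = n mod 3), projected onto protein-alignment columns,
## and compared across sequences. Identical intron positions and phases
## corroborate common ancestry of subtype members; introns fixed in one
## subtype and absent from another discriminate the subtypes.

#' Parse a gene model (CDS features) from GFF3
#'
#' Reads the CDS features of one gene from a GFF3 file (via
#' [rtracklayer::import()]), converts them to coding-local coordinates in
#' translation order (reverse-strand models are reversed), and derives the
#' intron offsets and phases. The intron anchor convention used throughout:
#' an intron with offset n precedes coding nucleotide n+1, i.e. it sits
#' within (phase 1/2) or immediately before (phase 0) the residue
#' `floor(n/3) + 1`.
#'
#' @param gff Path to a GFF3 file with CDS features (1-based inclusive).
#' @param geneId Gene/mRNA identifier matched against the CDS `Parent` or
#'   `ID` attributes.
#' @return A list of class `GeneModel`: `gene_id`, `exon_lengths`,
#'   `coding_length`, `introns` (data.frame `offset`, `phase`), `complete`
#'   (coding length divisible by 3).
#' @export
parseGeneModel <- function(gff, geneId) {
  gr <- rtracklayer::import(gff)
  md <- as.data.frame(gr)
  isCDS <- !is.na(md$type) & md$type == "CDS"
  parents <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) paste(p, collapse = ","), "")
  else rep("", nrow(md))
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep("", nrow(md))
  inParent <- vapply(strsplit(parents, ",", fixed = TRUE),
                     function(p) geneId %in% p, TRUE)
  sel <- isCDS & (inParent | ids == geneId)
  if (!any(sel)) stop("no CDS features found for gene: ", geneId)
  cds <- md[sel, , drop = FALSE]
  strand <- unique(as.character(cds$strand))
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop("CDS features of ", geneId, " have mixed or missing strand")
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(cds) > 1L && any(cds$start[-1L] <= cds$end[-nrow(cds)]))
    stop("overlapping CDS features for gene: ", geneId)
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  lens <- cds$end - cds$start + 1L
  total <- sum(lens)
  complete <- total %% 3L == 0L
  if (!complete)
    warning("coding length of ", geneId, " (", total,
            " nt) is not divisible by 3; model flagged partial")
  offsets <- cumsum(lens)
  offsets <- offsets[-length(offsets)]
  structure(list(gene_id = geneId, exon_lengths = as.integer(lens),
                 coding_length = as.integer(total),
                 introns = data.frame(offset = as.integer(offsets),
                                      phase = as.integer(offsets %% 3L)),
                 complete = complete),
            class = "GeneModel")
}

#' @export
print.GeneModel <- function(x, ...) {
  cat("GeneModel '", x$gene_id, "': ", length(x$exon_lengths), " exon(s), ",
      x$coding_length, " nt coding, ", nrow(x$introns), " intron(s)",
      if (!x$complete) " [partial]", "\n", sep = "")
  invisible(x)
}

## accept AAStringSet or a path to aligned FASTA
.asMSA <- function(msa) {
  if (is.character(msa) && length(msa) == 1L)
    msa <- Biostrings::readAAStringSet(msa)
  msa
}

#' Project a gene model's introns onto protein-alignment columns
#'
#' Each intron is mapped to the alignment column of the residue containing
#' coding nucleotide n+1 (residue `floor(n/3) + 1` of the ungapped row),
#' carrying its phase.
#'
#' @param model A [parseGeneModel()] result.
#' @param msa An `AAStringSet` (aligned, `-` gaps) or path to aligned FASTA.
#' @param rowId Sequence name within the alignment.
#' @return data.frame with columns `column` (1-based alignment column) and
#'   `phase` (0, 1 or 2).
#' @export
mapIntronsToAlignment <- function(model, msa, rowId) {
  msa <- .asMSA(msa)
  if (!rowId %in% names(msa)) stop("row not in alignment: ", rowId)
  chars <- strsplit(as.character(msa[[rowId]]), "")[[1L]]
  nonGap <- which(chars != "-")
  need <- ceiling(model$coding_length / 3)
  if (length(nonGap) < need)
    stop("alignment row ", rowId, " has ", length(nonGap),
         " residues but the gene model implies >= ", need)
  if (!nrow(model$introns))
    return(data.frame(column = integer(0), phase = integer(0)))
  residue <- model$introns$offset %/% 3L + 1L
  data.frame(column = nonGap[residue], phase = model$introns$phase)
}

.placementKeys <- function(p) {
  if (!nrow(p)) character(0) else paste(p$column, p$phase, sep = ":")
}

#' Intron-position congruence between two sequences
#'
#' Jaccard index of the two sets of (column, phase) pairs projected on the
#' same alignment; two empty sets score 1 by convention. An intron shared in
#' position but differing in phase counts as different.
#'
#' @param a,b Placement data.frames from [mapIntronsToAlignment()].
#' @return Fraction in `[0, 1]`.
#' @export
congruenceScore <- function(a, b) {
  ka <- .placementKeys(a); kb <- .placementKeys(b)
  if (!length(ka) && !length(kb)) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Introns discriminating two groups of sequences
#'
#' Returns the (column, phase) pairs present in every member of one group
#' and absent from every member of the other.
#'
#' @param groupA,groupB Non-empty lists of placement data.frames projected
#'   on the same alignment.
#' @return data.frame with columns `column`, `phase`, `group` (`"A"` or
#'   `"B"`, the group that carries the intron).
#' @export
discriminatingIntrons <- function(groupA, groupB) {
  stopifnot(length(groupA) > 0L, length(groupB) > 0L)
  keysA <- lapply(groupA, .placementKeys)
  keysB <- lapply(groupB, .placementKeys)
  fixedA <- Reduce(intersect, keysA)
  fixedB <- Reduce(intersect, keysB)
  anyA <- Reduce(union, keysA)
  anyB <- Reduce(union, keysB)
  discA <- setdiff(fixedA, anyB)
  discB <- setdiff(fixedB, anyA)
  keys <- c(discA, discB)
  if (!length(keys))
    return(data.frame(column = integer(0), phase = integer(0),
                      group = character(0)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(
    column = as.integer(vapply(parts, `[`, "", 1L)),
    phase = as.integer(vapply(parts, `[`, "", 2L)),
    group = rep(c("A", "B"), c(length(discA), length(discB))),
    stringsAsFactors = FALSE)
  out[order(out$column, out$phase), , drop = FALSE]
}

#' Render a hyphen/pipe gene-structure pattern
#'
#' One `-` per non-gap alignment column, one space per gap column, with `|`
#' inserted immediately before the anchor column of each intron, so that
#' sequences sharing an intron show `|` at the same output offset.
#'
#' @param placements Placement data.frame for this row.
#' @param row Aligned sequence (character string, `-` gaps) or an
#'   `AAStringSet` element.
#' @return Pattern string of length `columns + introns`.
#' @export
renderPattern <- function(placements, row) {
  row <- as.character(row)
  chars <- strsplit(row, "")[[1L]]
  ncol <- length(chars)
  if (nrow(placements)) {
    if (any(placements$column < 1L | placements$column > ncol))
      stop("intron anchor column outside alignment span (1..", ncol, ")")
    if (any(chars[placements$column] == "-"))
      stop("intron anchored on a gap column of this row")
  }
  bars <- tabulate(placements$column, nbins = ncol)
  body <- ifelse(chars == "-", " ", "-")
  paste0(vapply(seq_len(ncol), function(j)
    paste0(strrep("|", bars[j]), body[j]), ""), collapse = "")
}

#' Classify sequence completeness
#'
#' A sequence missing nothing relative to the expected full length is
#' complete; missing up to `tau` (default 5%) makes it a partial (usable in
#' tree computations); missing more makes it a fragment (inventory evidence
#' only). Observed lengths exceeding the expectation clamp to complete.
#'
#' @param lObs Observed length(s), residues.
#' @param lExp Expected full length(s), residues (e.g. the mean of complete
#'   sequences of the same subtype).
#' @param tau Missing-fraction threshold (default 0.05). Values landing
#'   exactly on the threshold classify as partial (a 1e-9 tolerance absorbs
#'   floating-point rounding).
#' @return data.frame with columns `l_obs`, `l_exp`, `missing_frac`,
#'   `class` (`"complete"`, `"partial"`, `"fragment"`).
#' @examples
#' classifyCompleteness(1300, 1560)  # fragment
#' @export
classifyCompleteness <- function(lObs, lExp, tau = 0.05) {
  if (any(lExp <= 0)) stop("expected length must be positive")
  if (any(lObs < 0)) stop("observed length must be non-negative")
  n <- max(length(lObs), length(lExp))
  lObs <- rep_len(lObs, n); lExp <- rep_len(lExp, n)
  m <- pmax(0, (lExp - lObs) / lExp)
  eps <- 1e-9
  cls <- ifelse(m <= eps, "complete",
                ifelse(m <= tau + eps, "partial", "fragment"))
  data.frame(l_obs = lObs, l_exp = lExp, missing_frac = m, class = cls,
             stringsAsFactors = FALSE)
}

#' Expected full length from designated complete sequences
#'
#' @param lengths Numeric vector of lengths of complete sequences of one
#'   subtype.
#' @return Their arithmetic mean.
#' @export
expectedLength <- function(lengths) {
  if (!length(lengths)) stop("no complete sequences supplied")
  mean(lengths)
}
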