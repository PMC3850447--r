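## Independent oracles and fixture builders. Everything here works directly
## on ape edge matrices and deliberately shares no code with the package
## internals it checks.

## minimal flat index of a phylo object
oindex <- function(phy) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    parent[c] <- p
    kids[[p]] <- c(kids[[p]], c)
  }
  list(ntip = ntip, n = n, parent = parent, kids = kids, root = ntip + 1L)
}

## ancestors of v including v itself, root last
oancestors <- function(oi, v) {
  out <- v
  while (oi$parent[v] != 0L) {
    v <- oi$parent[v]
    out <- c(out, v)
  }
  out
}

## brute-force LCA: deepest node in the intersection of ancestor sets
oracle_lca <- function(phy, ids) {
  oi <- oindex(phy)
  common <- Reduce(intersect, lapply(ids, function(v) oancestors(oi, v)))
  depth <- vapply(common, function(v) length(oancestors(oi, v)), 0L)
  common[which.max(depth)]  # deepest common node = longest path to root
}

## brute-force minimum duplication count over all ancestor-consistent
## mappings (leaves fixed to their species tips), by dynamic programming:
## cost(node, s) = min over child assignments s1, s2 (each with s
## ancestor-or-equal) of cost(c1,s1) + cost(c2,s2) + dup(s, s1, s2),
## where the node is a speciation only when its children map into distinct
## child subtrees of s, and a duplication otherwise.
oracle_min_dups <- function(geneTree, speciesTree, sep = "|") {
  gi <- oindex(geneTree)
  si <- oindex(speciesTree)
  ancSets <- lapply(seq_len(si$n), function(v) oancestors(si, v))
  sp <- vapply(strsplit(geneTree$tip.label, sep, fixed = TRUE), `[`, "", 1L)
  tipmap <- match(sp, speciesTree$tip.label)
  ## which child subtree of s contains v (NA when v == s)
  childOf <- function(s, v) {
    if (s == v) return(NA_integer_)
    kids <- si$kids[[s]]
    for (c in kids) if (c %in% ancSets[[v]]) return(c)
    stop("internal: v not below s")
  }
  isDup <- function(s, s1, s2) {
    if (s == s1 || s == s2) return(TRUE)
    childOf(s, s1) == childOf(s, s2)
  }
  cost <- function(v) {
    kids <- gi$kids[[v]]
    if (is.null(kids)) {
      out <- rep(Inf, si$n)
      out[tipmap[v]] <- 0
      return(out)
    }
    stopifnot(length(kids) == 2L)
    t1 <- cost(kids[1L]); t2 <- cost(kids[2L])
    out <- rep(Inf, si$n)
    for (s in seq_len(si$n)) {
      best <- Inf
      for (s1 in seq_len(si$n)) {
        if (!is.finite(t1[s1]) || !(s %in% ancSets[[s1]])) next
        for (s2 in seq_len(si$n)) {
          if (!is.finite(t2[s2]) || !(s %in% ancSets[[s2]])) next
          val <- t1[s1] + t2[s2] + as.numeric(isDup(s, s1, s2))
          if (val < best) best <- val
        }
      }
      out[s] <- best
    }
    out
  }
  if (gi$ntip == 1L) return(0L)
  as.integer(min(cost(gi$root)))
}

## enumerate all distinct rooted binary trees on n leaves colored from
## `colors` (unordered children; canonical pairing avoids mirror duplicates)
enumerate_colored_trees <- function(nmax, colors = c("A", "B", "C")) {
  memo <- list()
  gen <- function(n) {
    key <- as.character(n)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (n == 1L) as.list(colors) else {
      res <- list()
      for (k in seq_len(n %/% 2L)) {
        L <- gen(k); R <- gen(n - k)
        for (i in seq_along(L)) {
          js <- if (2L * k == n) seq(i, length(R)) else seq_along(R)
          for (j in js) res[[length(res) + 1L]] <- list(L[[i]], R[[j]])
        }
      }
      res
    }
    memo[[key]] <<- out
    out
  }
  unlist(lapply(2:nmax, gen), recursive = FALSE)
}

## nested color structure -> newick with unique gene ids per species
colored_to_newick <- function(tree, sep = "|") {
  counter <- new.env(parent = emptyenv())
  walk <- function(x) {
    if (is.character(x)) {
      k <- if (is.null(counter[[x]])) 1L else counter[[x]] + 1L
      counter[[x]] <- k
      return(paste0(x, sep, "g", k))
    }
    paste0("(", walk(x[[1]]), ",", walk(x[[2]]), ")")
  }
  paste0(walk(tree), ";")
}

## canonical unlabelled shape string of a rooted tree (for topology checks)
tree_shape <- function(phy) {
  oi <- oindex(phy)
  walk <- function(v) {
    kids <- oi$kids[[v]]
    if (is.null(kids)) return("L")
    paste0("(", paste(sort(vapply(kids, walk, "")), collapse = ""), ")")
  }
  walk(oi$root)
}

## relabel a species tree's tips into species|gene leaves (congruent family)
congruent_gene_tree <- function(speciesTree, sep = "|") {
  gt <- speciesTree
  gt$tip.label <- paste0(gt$tip.label, sep, "g1")
  gt$node.label <- NULL
  gt
}

## the 8-species study tree used by the simulation scenarios
study_tree8 <- function() {
  readNewick(paste0("(((S1:1,S2:1)N2:1,(S3:1,S4:1)N3:1)N1:1,",
                    "((S5:1,S6:1)N5:1,(S7:1,S8:1)N6:1)N4:1)R;"))
}

genome_verdicts <- c("WGD", "WGT", "TWO_WGD", "AMBIGUOUS")

## simulate one replicate and call events; returns the calls table
simulate_and_call <- function(cfg, kMin = 3L) {
  fams <- lapply(seq_len(cfg@nFamilies), function(i) simulateFamily(cfg, i))
  recs <- list()
  for (i in seq_along(fams)) {
    if (fams[[i]]$extinct) next
    recs[[length(recs) + 1L]] <- reconcileFamily(
      fams[[i]]$tree, cfg@speciesTree, familyId = paste0("fam", i))
  }
  if (!length(recs)) return(NULL)
  callEvents(aggregateProfiles(recs), callConfig(kMin = kMin))
}
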