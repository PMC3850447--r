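## Orchestration: read a run configuration, chain the stages
## (reconcile -> call -> name -> inventory -> structure), write the report
## bundle, and score calls against simulator truth.

#' Read a run configuration from YAML (or normalize a list)
#'
#' Recognized fields: `species_tree` (path or Newick), `gene_trees` (vector
#' of paths, a directory, or a glob), `k_min`, `out_dir`, `seed`, optional
#' `naming` (list/data.frame: `family_id`, `class_id`, `subtype_letter`),
#' optional `msa` + `gff` + `structure_genes` for the gene-structure stage,
#' optional `positions` (TSV: gene_id, scaffold, index) for tandem flags.
#'
#' @param config Path to a YAML file or a list.
#' @return Normalized list of class `runConfig`.
#' @export
readRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$species_tree)) stop("config lacks 'species_tree'")
  if (is.null(config$gene_trees)) stop("config lacks 'gene_trees'")
  if (is.null(config$k_min)) config$k_min <- 3L
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) config$out_dir <- "wgdtrace_out"
  structure(config, class = c("runConfig", "list"))
}

.expandGeneTrees <- function(spec) {
  if (length(spec) == 1L && dir.exists(spec))
    return(sort(list.files(spec, pattern = "\\.(nwk|newick|tre|tree)$",
                           full.names = TRUE)))
  if (length(spec) == 1L && grepl("[*?]", spec))
    return(sort(Sys.glob(spec)))
  spec
}

#' Run the full inference chain
#'
#' Reconciles every gene tree against the species tree, aggregates
#' duplications per branch, calls genome-scale events, assigns names (when a
#' naming table is configured), builds the inventory matrix, optionally
#' scores gene-structure congruence, and writes the report bundle
#' (reconciliation JSON, calls TSV/JSON, names TSV, inventory TSV, run
#' manifest JSON) under `out_dir`. Identical configurations produce
#' byte-identical bundles.
#'
#' @param config A list or YAML path accepted by [readRunConfig()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   written paths.
#' @export
runInference <- function(config) {
  config <- readRunConfig(config)
  ## ---- stage: inputs
  spSpec <- config$species_tree
  if (!grepl("[();]", spSpec) && !file.exists(spSpec))
    stop("startup error: species tree file not found: ", spSpec)
  speciesTree <- readNewick(spSpec)
  treePaths <- .expandGeneTrees(config$gene_trees)
  if (!length(treePaths)) stop("startup error: no gene trees matched: ",
                               paste(config$gene_trees, collapse = ", "))
  missing <- treePaths[!file.exists(treePaths)]
  if (length(missing))
    stop("startup error: gene tree file(s) not found: ",
         paste(missing, collapse = ", "))
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  ## ---- stage: reconcile
  recs <- list()
  for (p in treePaths) {
    txt <- paste(readLines(p, warn = FALSE), collapse = "")
    if (!nzchar(trimws(txt))) next  # extinct family placeholder
    fam <- sub("\\.[^.]*$", "", basename(p))
    rec <- tryCatch(
      reconcileFamily(readNewick(txt), speciesTree, familyId = fam),
      error = function(e) stop("stage 'reconcile' failed on ", p, ": ",
                               conditionMessage(e)))
    recs[[fam]] <- rec
  }
  if (!length(recs)) stop("stage 'reconcile': no non-empty gene trees")
  reconPath <- file.path(outDir, "reconciliation.json")
  writeReconciliation(recs, reconPath)

  ## ---- stage: call
  profiles <- aggregateProfiles(recs)
  cfg <- callConfig(kMin = config$k_min)
  calls <- callEvents(profiles, cfg)
  callsPath <- file.path(outDir, "calls.tsv")
  write.table(calls, callsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = list(k_min = cfg$kMin), calls = calls,
         groups = profiles$groups),
    file.path(outDir, "calls.json"), auto_unbox = TRUE, pretty = TRUE)

  ## ---- stage: tandem flags (optional)
  if (!is.null(config$positions)) {
    positions <- read.table(config$positions, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ## candidate pairs: same-species leaf pairs within each family
    pairs <- do.call(rbind, lapply(recs, function(r) {
      sp <- leafSpecies(r@geneTree)
      out <- NULL
      for (s in unique(sp)) {
        g <- names(sp)[sp == s]
        if (length(g) > 1L)
          out <- rbind(out, t(utils::combn(g, 2L)))
      }
      out
    }))
    if (!is.null(pairs)) {
      flags <- flagTandem(as.data.frame(pairs), positions,
                          maxGap = cfg$tandemMaxGap)
      write.table(flags, file.path(outDir, "tandem_flags.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  ## ---- stage: name (optional)
  names_tab <- NULL
  if (!is.null(config$naming)) {
    naming <- as.data.frame(config$naming, stringsAsFactors = FALSE)
    names_tab <- do.call(rbind, lapply(seq_len(nrow(naming)), function(i) {
      fam <- naming$family_id[i]
      if (is.null(recs[[fam]]))
        stop("stage 'name': naming table references unknown family: ", fam)
      nm <- assignNames(recs[[fam]], naming$class_id[i],
                        naming$subtype_letter[i], calls = calls)
      cbind(family_id = fam, nm)
    }))
    write.table(names_tab, file.path(outDir, "names.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## ---- stage: inventory
  inv <- buildInventory(recs)
  invPath <- file.path(outDir, "inventory.tsv")
  write.table(data.frame(species = rownames(inv), inv, check.names = FALSE),
              invPath, sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- stage: structure (optional)
  structure_tab <- NULL
  if (!is.null(config$msa) && !is.null(config$gff) &&
      !is.null(config$structure_genes)) {
    genes <- unlist(config$structure_genes)
    placements <- lapply(genes, function(g)
      mapIntronsToAlignment(parseGeneModel(config$gff, g), config$msa, g))
    names(placements) <- genes
    n <- length(genes)
    mat <- matrix(1, n, n, dimnames = list(genes, genes))
    for (i in seq_len(n)) for (j in seq_len(n))
      mat[i, j] <- congruenceScore(placements[[i]], placements[[j]])
    structure_tab <- mat
    write.table(data.frame(gene = rownames(mat), mat, check.names = FALSE),
                file.path(outDir, "structure_congruence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    msa <- .asMSA(config$msa)
    pats <- vapply(genes, function(g)
      renderPattern(placements[[g]], as.character(msa[[g]])), "")
    writeLines(paste0(format(genes, width = max(nchar(genes))), "  ", pats),
               file.path(outDir, "structure_patterns.txt"))
  }

  ## ---- manifest (no timestamps: bundles must be byte-identical)
  cfgJson <- file.path(outDir, "run_config.json")
  jsonlite::write_json(unclass(config), cfgJson, auto_unbox = TRUE,
                       pretty = TRUE)
  ## hash the config without the bundle location, so identical analyses
  ## hash identically wherever they are written
  canon <- unclass(config)
  canon$out_dir <- NULL
  canonFile <- tempfile(fileext = ".json")
  jsonlite::write_json(canon, canonFile, auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package = "wgdtrace",
    version = as.character(utils::packageVersion("wgdtrace")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(canonFile)),
    n_families = length(recs),
    n_gene_tree_files = length(treePaths),
    outputs = list(reconciliation = basename(reconPath),
                   calls = basename(callsPath),
                   inventory = basename(invPath)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(reconciliations = recs, profiles = profiles, calls = calls,
                 inventory = inv, names = names_tab,
                 structure = structure_tab, out_dir = outDir))
}

#' Score calls against simulator truth
#'
#' Branch-level confusion between genome-scale calls (verdicts `WGD`,
#' `WGT`, `TWO_WGD`, or `AMBIGUOUS`) and the branches carrying simulated
#' whole-genome events, plus verdict-type accuracy among correctly placed
#' calls. The expected verdict per truth branch is `WGD` for one simulated
#' WGD, `TWO_WGD` for two, `WGT` for a triplication.
#'
#' @param calls A [callEvents()] table.
#' @param truth Truth table from [simulateDataset()]/[simulateFamily()] (or
#'   the path to a truth TSV): realized events with `branch_label` and
#'   `type`; background `SGD` rows are ignored.
#' @return A list: `confusion` (per-branch data.frame with `truth_type`,
#'   `called`, `verdict`, `placement`), `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `type_accuracy`.
#' @export
scoreRecovery <- function(calls, truth) {
  if (is.character(truth))
    truth <- read.table(truth, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  wge <- unique(truth[truth$type %in% c("WGD", "WGT"),
                      c("branch_label", "type", "position")])
  expected <- vapply(split(wge, wge$branch_label), function(e) {
    if (any(e$type == "WGT") && all(e$type == "WGT") && nrow(e) == 1L) "WGT"
    else if (all(e$type == "WGD") && nrow(e) == 1L) "WGD"
    else if (all(e$type == "WGD") && nrow(e) >= 2L) "TWO_WGD"
    else "MIXED"
  }, "")
  genome <- c("WGD", "WGT", "TWO_WGD", "AMBIGUOUS")
  called <- calls[calls$verdict %in% genome, , drop = FALSE]
  branches <- union(names(expected), called$branch_label)
  confusion <- data.frame(
    branch_label = branches,
    truth_type = unname(expected[branches]),
    verdict = called$verdict[match(branches, called$branch_label)],
    stringsAsFactors = FALSE)
  confusion$truth_type[is.na(confusion$truth_type)] <- "NONE"
  confusion$called <- !is.na(confusion$verdict)
  confusion$placement <- ifelse(
    confusion$truth_type != "NONE" & confusion$called, "TP",
    ifelse(confusion$truth_type == "NONE", "FP", "FN"))
  tp <- sum(confusion$placement == "TP")
  fp <- sum(confusion$placement == "FP")
  fn <- sum(confusion$placement == "FN")
  correctType <- confusion$placement == "TP" &
    confusion$verdict == confusion$truth_type
  list(confusion = confusion[order(confusion$branch_label), ],
       tp = tp, fp = fp, fn = fn,
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       type_accuracy = if (tp > 0) sum(correctType) / tp else NA_real_)
}
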