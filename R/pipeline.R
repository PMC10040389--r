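#' @include synthetic.R interactions.R connective.R ur_programs.R io.R
NULL

.allowedConfigKeys <- c("seed", "output_dir", "synthetic", "groups",
                        "activity", "thresholds", "cuts")
.allowedSynthKeys <- c("n_programs", "pathways_per_program",
                       "genes_per_pathway", "within_share", "between_share",
                       "n_ligands", "targets_per_ligand", "secreted_fraction",
                       "program_bias", "fp_rate", "fn_rate")
.allowedThresholdKeys <- c("alpha", "fdr", "pcc_min", "top_k",
                           "expressed_threshold")
.allowedCutKeys <- c("k_top", "k_sub")

#' Default synthetic pipeline configuration
#'
#' A two-arm scenario over two organs and two cell types per organ: one
#' pro-inflammatory UR drives its home program in the inflamed arm only,
#' while a second UR drives the other program in both arms, producing the
#' on/off contrast the connective pathway analysis is designed to expose.
#'
#' @param seed integer seed.
#' @param output_dir where \code{\link{runPipeline}} writes artifacts.
#' @return a nested config list accepted by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1L, output_dir = tempfile("mcdm_")) {
  groups <- do.call(rbind, lapply(c("joint", "muscle"), function(og)
    data.frame(group = paste(og, c("Tcell", "fibroblast"), sep = ":"),
               organ = og, cell_type = c("Tcell", "fibroblast"),
               arm = if (og == "joint") "inflamed" else "noninflamed")))
  activity <- rbind(
    data.frame(group = groups$group[groups$arm == "inflamed"], ur = "UR01",
               direction = 1),
    data.frame(group = groups$group, ur = "UR02", direction = 1))
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    synthetic = list(n_programs = 2, pathways_per_program = 10,
                     genes_per_pathway = 50, within_share = 0.5,
                     between_share = 0.05, n_ligands = 8,
                     targets_per_ligand = 120, secreted_fraction = 0.5,
                     program_bias = 0.8, fp_rate = 0.01, fn_rate = 0.1),
    groups = groups,
    activity = activity,
    thresholds = list(alpha = 0.05, fdr = 0.05, pcc_min = 0, top_k = 200,
                      expressed_threshold = 1e-5),
    cuts = list(k_top = 2, k_sub = NULL)
  )
}

.validateConfig <- function(config) {
  bad <- setdiff(names(config), .allowedConfigKeys)
  if (length(bad))
    stop("configuration error: unknown key(s): ", paste(bad, collapse = ", "))
  for (k in c("seed", "output_dir", "synthetic", "groups", "activity"))
    if (is.null(config[[k]])) stop("configuration error: missing key '", k, "'")
  bad <- setdiff(names(config$synthetic), .allowedSynthKeys)
  if (length(bad))
    stop("configuration error: unknown synthetic key(s): ",
         paste(bad, collapse = ", "))
  th <- config$thresholds
  bad <- setdiff(names(th), .allowedThresholdKeys)
  if (length(bad))
    stop("configuration error: unknown threshold key(s): ",
         paste(bad, collapse = ", "))
  if (!is.null(th$alpha) && (th$alpha < 0 || th$alpha > 1))
    stop("configuration error: alpha outside [0, 1]")
  if (!is.null(th$fdr) && (th$fdr < 0 || th$fdr > 1))
    stop("configuration error: fdr outside [0, 1]")
  if (!is.null(th$top_k) && th$top_k < 1)
    stop("configuration error: top_k must be >= 1")
  bad <- setdiff(names(config$cuts), .allowedCutKeys)
  if (length(bad))
    stop("configuration error: unknown cut key(s): ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order — synthetic inputs, DEG intake,
#' MCDM and MO-MCDM construction, UR ranking, pathway enrichment, connective
#' pathway analysis with activation labels and opposing fractions, and
#' UR-to-program mapping — writing every artifact plus a manifest (seed,
#' parameters, parameter hash, stage counts) to \code{output_dir}. Rerunning
#' with the same config reproduces the same manifest hash.
#'
#' @param config nested list as from \code{\link{defaultPipelineConfig}}, or
#'   the path of a YAML file holding one.
#' @return invisibly, a result bundle: truth, prior, degTables, mcdms, momcdm,
#'   urRanking, tree, labels per arm, opposingFractions, urPrograms, manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.list(config$groups)) config$groups <- as.data.frame(config$groups)
  if (is.list(config$activity)) config$activity <- as.data.frame(config$activity)
  .validateConfig(config)
  sy <- config$synthetic
  th <- config$thresholds
  seed <- as.integer(config$seed)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # stage 1: planted pathway collection and prior
  pw <- generatePathwayDB(sy$n_programs, sy$pathways_per_program,
                          sy$genes_per_pathway, sy$within_share,
                          sy$between_share, seed = seed)
  pr <- generatePrior(pw$db, pw$truth, n_ligands = sy$n_ligands,
                      targets_per_ligand = sy$targets_per_ligand,
                      secreted_fraction = sy$secreted_fraction,
                      program_bias = sy$program_bias, seed = seed)
  truth <- pr$truth
  urActivity(truth) <- config$activity
  writeGMT(pw$db, file.path(out, "pathways.gmt"))
  writePrior(pr$prior, file.path(out, "prior_edges.tsv"),
             file.path(out, "prior_annotation.tsv"))

  # stage 2: DEG intake
  groups <- config$groups
  degTables <- generateDegTables(truth, pr$prior, groups$group,
                                 fp_rate = sy$fp_rate, fn_rate = sy$fn_rate,
                                 seed = seed + 1L)
  for (g in names(degTables))
    writeDEGTable(degTables[[g]],
                  file.path(out, paste0("deg_", gsub("[^A-Za-z0-9]", "_", g),
                                        ".tsv")))
  message("DEG intake: ", length(degTables), " tables, ",
          sum(vapply(degTables, function(t) sum(t$fdr < th$fdr), numeric(1))),
          " DEGs")

  # stage 3: MCDMs per organ and the MO-MCDM
  expressed <- stats::setNames(lapply(groups$group, function(g)
    c(geneUniverse(pr$prior), ligands(pr$prior))), groups$group)
  mcdms <- lapply(split(seq_len(nrow(groups)), groups$organ), function(idx) {
    og <- groups$organ[idx[1]]
    tabs <- stats::setNames(degTables[groups$group[idx]],
                            groups$cell_type[idx])
    expr <- stats::setNames(expressed[groups$group[idx]],
                            groups$cell_type[idx])
    buildMCDM(tabs, expr, pr$prior, organ = og, pcc_min = th$pcc_min,
              top_k = th$top_k, fdrCut = th$fdr)
  })
  momcdm <- buildMOMCDM(groups, degTables, expressed, pr$prior,
                        pcc_min = th$pcc_min, top_k = th$top_k,
                        fdrCut = th$fdr)
  for (og in names(mcdms))
    exportMCDM(mcdms[[og]], tsvPath = file.path(out, paste0("mcdm_", og,
                                                            ".tsv")))
  exportMCDM(momcdm, tsvPath = file.path(out, "mo_mcdm.tsv"),
             jsonPath = file.path(out, "mo_mcdm.json"))
  pooled_edges <- do.call(rbind, c(lapply(mcdms, mcdmEdges),
                                   list(mcdmEdges(momcdm))))
  urRanking <- rankURs(MCDMGraph(
    do.call(rbind, lapply(mcdms, function(m) as.data.frame(mcdmNodes(m)))),
    pooled_edges))
  utils::write.table(urRanking, file.path(out, "ur_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # stage 4: pathway enrichment per arm
  arms <- split(groups$group, groups$arm)
  enr <- lapply(arms, function(gs)
    enrichAll(degTables[gs], pw$db, alpha = th$alpha, fdrCut = th$fdr))

  # stage 5: connective pathway analysis on the pooled DEG sets
  sets <- suppressWarnings(pathwayDegSets(degTables, pw$db, fdrCut = th$fdr))
  if (length(sets) < 2L) stop("missing upstream artifact: connective ",
                              "pathway analysis needs >= 2 nonempty pathways")
  tree <- clusterPathways(jaccardMatrix(sets))
  tree <- cutPrograms(tree, k_top = config$cuts$k_top,
                      k_sub = config$cuts$k_sub)
  exportTree(tree, newickPath = file.path(out, "program_tree.nwk"),
             assignPath = file.path(out, "program_assignments.tsv"))
  labels <- lapply(enr, function(e)
    labelPathways(e[e$pathway %in% names(sets), ], alpha = th$alpha))
  prog_ids <- sort(unique(programs(tree)))
  opposing <- vapply(prog_ids, function(p) {
    members <- names(programs(tree))[programs(tree) == p]
    opposingFraction(labels[[1]], labels[[2]], members)
  }, numeric(1))

  # stage 6: UR-to-program mapping
  urTargetTable <- do.call(rbind, lapply(seq_len(nrow(pooled_edges)),
    function(i) data.frame(
      ur = pooled_edges$ligand[i],
      dataset = paste(pooled_edges$receiver_organ[i],
                      pooled_edges$receiver_cell[i], sep = ":"),
      gene = pooled_edges$targets[[i]])))
  programGenes <- lapply(split(names(programs(tree)), programs(tree)),
                         function(pws) unique(unlist(sets[pws])))
  background <- unique(unlist(sets))
  urPrograms <- if (!is.null(urTargetTable) && nrow(urTargetTable))
    urProgramEnrichment(unique(urTargetTable), programGenes, background)
  else NULL
  if (!is.null(urPrograms))
    utils::write.table(urPrograms, file.path(out, "ur_programs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  params_json <- file.path(out, "params.json")
  cfg <- config
  cfg$groups <- as.data.frame(cfg$groups)
  cfg$activity <- as.data.frame(cfg$activity)
  cfg$output_dir <- NULL  # the hash covers parameters, not the destination
  jsonlite::write_json(cfg, params_json, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    seed = seed,
    param_hash = unname(tools::md5sum(params_json)),
    counts = list(
      pathways = length(geneSets(pw$db)),
      clustered_pathways = length(sets),
      ligands = length(ligands(pr$prior)),
      deg_tables = length(degTables),
      mcdm_edges = sum(vapply(mcdms, function(m) nrow(mcdmEdges(m)),
                              numeric(1))),
      mo_mcdm_edges = nrow(mcdmEdges(momcdm)),
      programs = length(prog_ids)),
    files = list.files(out))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, db = pw$db, prior = pr$prior,
                 degTables = degTables, mcdms = mcdms, momcdm = momcdm,
                 urRanking = urRanking, tree = tree, labels = labels,
                 opposingFractions = opposing, urPrograms = urPrograms,
                 manifest = manifest))
}
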