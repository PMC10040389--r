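#' @include methods.R
NULL

#' Read a GMT pathway collection
#'
#' Standard GMT: one pathway per line, tab-separated: name, description, then
#' gene tokens. The signed dialect \code{SYMBOL:+1} / \code{SYMBOL:-1} is
#' accepted and populates the per-gene direction signs.
#'
#' @param path GMT file path.
#' @param source collection tag stored in the result (default: file name).
#' @return a \linkS4class{PathwayDB}.
#' @export
readGMT <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(PathwayDB(stats::setNames(list(), character()), source = source))
  }
  sets <- list()
  signs <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    toks <- f[-c(1, 2)]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0L)
      stop("malformed GMT line ", i, ": empty gene list")
    signed <- grepl(":[+-]?1$", toks)
    if (any(signed) && !all(signed))
      stop("malformed GMT line ", i, ": mixed signed and unsigned tokens")
    if (all(signed)) {
      genes <- sub(":[+-]?1$", "", toks)
      sg <- ifelse(grepl(":-1$", toks), -1, 1)
      names(sg) <- genes
      sets[[f[1]]] <- genes
      signs[[f[1]]] <- sg
    } else {
      sets[[f[1]]] <- toks
      signs[[f[1]]] <- numeric()
    }
  }
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway ids in ", path)
  PathwayDB(sets, signs, source = source)
}

#' Write a PathwayDB to GMT
#'
#' Signed pathways are written in the \code{SYMBOL:+1|-1} dialect; the
#' description column carries the source tag.
#'
#' @param db a \linkS4class{PathwayDB}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGMT <- function(db, path) {
  sets <- geneSets(db)
  signs <- geneSigns(db)
  lines <- vapply(names(sets), function(id) {
    g <- sets[[id]]
    s <- signs[[id]]
    toks <- if (length(s)) {
      sg <- s[g]
      sg[is.na(sg)] <- 1
      paste0(g, ":", ifelse(sg < 0, "-1", "+1"))
    } else g
    paste(c(id, ifelse(is.na(db@source), "na", db@source), toks),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix (MTX triplet or dense delimited)
#'
#' MTX mode: \code{path} is the MatrixMarket file, with row (gene) and column
#' (cell) id files one per line; an optional cell-metadata TSV (rownames in
#' the first column) becomes colData. Dense mode: a delimited file with gene
#' rownames and cell column names.
#'
#' @param path MTX or dense delimited file.
#' @param genesPath,cellsPath id files (MTX mode).
#' @param metaPath optional cell metadata TSV.
#' @param dense TRUE for dense mode (default: inferred from extension).
#' @param sep field separator for dense mode (default tab).
#' @param assayName assay to store values under (default "lognorm").
#' @return a \code{SingleCellExperiment}.
#' @export
readExpressionMatrix <- function(path, genesPath = NULL, cellsPath = NULL,
                                 metaPath = NULL,
                                 dense = !grepl("\\.mtx$", path),
                                 sep = "\t", assayName = "lognorm") {
  if (dense) {
    m <- as.matrix(utils::read.table(path, header = TRUE, sep = sep,
                                     row.names = 1, check.names = FALSE))
  } else {
    stopifnot(!is.null(genesPath), !is.null(cellsPath))
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesPath)
    cells <- readLines(cellsPath)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
           " but ids give ", length(genes), " x ", length(cells))
    dimnames(m) <- list(genes, cells)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
  cd <- if (!is.null(metaPath)) {
    meta <- utils::read.table(metaPath, header = TRUE, sep = "\t",
                              row.names = 1, check.names = FALSE)
    if (!identical(sort(rownames(meta)), sort(colnames(m))))
      stop("dimension mismatch: metadata rows do not match matrix cells")
    S4Vectors::DataFrame(meta[colnames(m), , drop = FALSE])
  } else S4Vectors::DataFrame(row.names = colnames(m))
  a <- stats::setNames(list(m), assayName)
  SingleCellExperiment::SingleCellExperiment(assays = a, colData = cd)
}

#' Write an assay as MTX triplet plus id files
#'
#' @param sce a \code{SingleCellExperiment}.
#' @param dir output directory (created if needed).
#' @param assayName assay to write (default first).
#' @param prefix file prefix (default "matrix").
#' @return invisibly, the written paths.
#' @export
writeExpressionMatrix <- function(sce, dir, assayName = NULL,
                                  prefix = "matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- if (is.null(assayName)) SummarizedExperiment::assay(sce, 1)
  else SummarizedExperiment::assay(sce, assayName)
  paths <- file.path(dir, paste0(prefix, c(".mtx", "_genes.txt",
                                           "_cells.txt", "_meta.tsv")))
  Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                              "generalMatrix"), paths[1])
  writeLines(rownames(m), paths[2])
  writeLines(colnames(m), paths[3])
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  utils::write.table(cbind(cell = rownames(cd), cd), paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a DEG table from TSV
#'
#' Required columns: gene, logFC, pvalue, fdr; a dataset column is added from
#' the argument when absent.
#'
#' @param path TSV file.
#' @param dataset dataset id to fill in when the column is missing.
#' @return data.frame.
#' @export
readDEGTable <- function(path, dataset = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "logFC", "pvalue", "fdr")
  if (!all(need %in% colnames(tab)))
    stop("DEG table ", path, " lacks required column(s): ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  if (!"dataset" %in% colnames(tab)) tab$dataset <- dataset
  if (anyDuplicated(tab$gene)) stop("duplicate gene ids in ", path)
  tab
}

#' Write a DEG table to TSV
#' @param tab data.frame (gene, logFC, pvalue, fdr, dataset).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeDEGTable <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-target prior from edge-list and annotation TSVs
#'
#' @param edgesPath TSV with columns ligand, gene, weight (weights > 0).
#' @param annotationPath TSV with columns ligand, location, molecule_class.
#' @param genes optional full gene universe (default: genes in the edge list).
#' @return a \linkS4class{LigandTargetPrior}.
#' @export
readPrior <- function(edgesPath, annotationPath, genes = NULL) {
  ed <- utils::read.table(edgesPath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("ligand", "gene", "weight") %in% colnames(ed)))
    stop("prior edge list needs columns ligand, gene, weight")
  an <- utils::read.table(annotationPath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("ligand", "location", "molecule_class") %in% colnames(an)))
    stop("annotation needs columns ligand, location, molecule_class")
  lig <- sort(unique(ed$ligand))
  if (!all(lig %in% an$ligand))
    stop("annotation missing for ligand(s): ",
         paste(setdiff(lig, an$ligand), collapse = ", "))
  if (is.null(genes)) genes <- sort(unique(ed$gene))
  pot <- matrix(0, length(lig), length(genes), dimnames = list(lig, genes))
  pot[cbind(match(ed$ligand, lig), match(ed$gene, genes))] <- ed$weight
  loc <- stats::setNames(an$location, an$ligand)
  cls <- stats::setNames(an$molecule_class, an$ligand)
  LigandTargetPrior(pot, loc, cls)
}

#' Write a prior as edge-list and annotation TSVs
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @param edgesPath,annotationPath output files.
#' @return invisibly, the paths.
#' @export
writePrior <- function(prior, edgesPath, annotationPath) {
  pot <- as.matrix(potentials(prior))
  idx <- which(pot > 0, arr.ind = TRUE)
  ed <- data.frame(ligand = rownames(pot)[idx[, 1]],
                   gene = colnames(pot)[idx[, 2]],
                   weight = pot[idx])
  ed <- ed[order(ed$ligand, ed$gene), ]
  utils::write.table(ed, edgesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- ligandInfo(prior)
  utils::write.table(
    data.frame(ligand = rownames(ann), location = ann$location,
               molecule_class = ann$molecule_class),
    annotationPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edgesPath, annotationPath))
}

#' Export an MCDM graph as TSV edge list and JSON
#'
#' The TSV carries one row per edge with semicolon-joined targets; the JSON
#' carries nodes and edges with target arrays.
#'
#' @param graph an \linkS4class{MCDMGraph}.
#' @param tsvPath,jsonPath optional output files.
#' @return invisibly, the edge data.frame in export form.
#' @export
exportMCDM <- function(graph, tsvPath = NULL, jsonPath = NULL) {
  ed <- mcdmEdges(graph)
  flat <- data.frame(
    sender_organ = ed$sender_organ, sender_celltype = ed$sender_cell,
    ligand = ed$ligand, receiver_organ = ed$receiver_organ,
    receiver_celltype = ed$receiver_cell,
    n_targets = vapply(ed$targets, length, integer(1)),
    pcc = ed$pcc,
    targets = vapply(ed$targets, paste, character(1), collapse = ";"))
  if (!is.null(tsvPath))
    utils::write.table(flat, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(jsonPath)) {
    obj <- list(multi_organ = graph@multiOrgan,
                nodes = as.data.frame(mcdmNodes(graph)),
                edges = lapply(seq_len(nrow(ed)), function(i) list(
                  sender_organ = ed$sender_organ[i],
                  sender_celltype = ed$sender_cell[i],
                  ligand = ed$ligand[i],
                  receiver_organ = ed$receiver_organ[i],
                  receiver_celltype = ed$receiver_cell[i],
                  pcc = ed$pcc[i],
                  targets = ed$targets[[i]])))
    jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(flat)
}
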