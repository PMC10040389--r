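#' @include enrichment.R
NULL

#' Quality-control filter for single cells and genes
#'
#' Retains cells with at least \code{min_reads} reads, transcripts in
#' [\code{min_transcripts}, \code{max_transcripts}], at least \code{min_genes}
#' detected genes and mitochondrial fraction below \code{max_mito}; then
#' retains genes detected in at least \code{min_gene_prevalence} of the
#' retained cells. Cells are filtered before genes; applying the filter twice
#' removes nothing further.
#'
#' @param sce \code{SingleCellExperiment} with colData columns reads,
#'   transcripts, genes_detected, mito_fraction.
#' @param min_reads minimum reads per cell (default 10000).
#' @param min_transcripts minimum transcripts per cell (default 400).
#' @param min_genes minimum detected genes per cell (default 200).
#' @param max_mito maximum mitochondrial fraction, exclusive (default 0.20).
#' @param max_transcripts maximum transcripts per cell, inclusive
#'   (default 6000; cells above are treated as likely duplicates).
#' @param min_gene_prevalence minimum fraction of retained cells a gene must
#'   be detected in, inclusive (default 0.10).
#' @return the filtered \code{SingleCellExperiment}.
#' @export
#' @importFrom SummarizedExperiment assay assayNames colData rowData
qcFilter <- function(sce, min_reads = 10000, min_transcripts = 400,
                     min_genes = 200, max_mito = 0.20, max_transcripts = 6000,
                     min_gene_prevalence = 0.10) {
  cd <- SummarizedExperiment::colData(sce)
  need <- c("reads", "transcripts", "genes_detected", "mito_fraction")
  if (!all(need %in% colnames(cd)))
    stop("colData must contain: ", paste(need, collapse = ", "))
  pass_reads <- cd$reads >= min_reads
  pass_tx <- cd$transcripts >= min_transcripts &
    cd$transcripts <= max_transcripts
  pass_genes <- cd$genes_detected >= min_genes
  pass_mito <- cd$mito_fraction < max_mito
  keep <- pass_reads & pass_tx & pass_genes & pass_mito
  if (!any(keep)) {
    stop("all cells removed by QC (failed reads: ", sum(!pass_reads),
         ", transcripts: ", sum(!pass_tx), ", genes: ", sum(!pass_genes),
         ", mito: ", sum(!pass_mito), ")")
  }
  sce <- sce[, keep]
  a <- if ("counts" %in% SummarizedExperiment::assayNames(sce))
    SummarizedExperiment::assay(sce, "counts")
  else SummarizedExperiment::assay(sce, 1)
  prevalence <- rowMeans(a > 0)
  sce[prevalence >= min_gene_prevalence, ]
}

#' Embed cells in a low-dimensional latent space
#'
#' Pluggable embedding; the default projects log-normalized expression onto
#' the top principal components. Any function \code{(mat, dim, seed)}
#' returning a cells x dim matrix can be plugged in instead.
#'
#' @param mat genes x cells matrix of normalized values.
#' @param dim latent dimension (default 32; must not exceed
#'   \code{min(genes, cells)}).
#' @param method "pca" or a function(mat, dim, seed).
#' @param seed integer seed (relevant for stochastic plug-in methods).
#' @return cells x dim coordinate matrix (rownames = cell ids).
#' @export
embedCells <- function(mat, dim = 32, method = "pca", seed = 1L) {
  if (dim > min(dim(mat)))
    stop("configuration error: dim exceeds min(genes, cells)")
  if (is.function(method)) return(method(mat, dim, seed))
  set.seed(as.integer(seed))
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE, rank. = dim)
  coords <- pc$x[, seq_len(dim), drop = FALSE]
  rownames(coords) <- colnames(mat)
  coords
}

.spearmanMatrix <- function(refMat, cellMat) {
  suppressWarnings(stats::cor(refMat, cellMat, method = "spearman"))
}

#' Match each reference profile to its most similar cell
#'
#' For each reference cell-type profile, finds the single cell with the
#' highest Spearman correlation over the shared genes (average ranks for
#' ties); correlation-tied cells are broken by lowest cell index.
#'
#' @param mat genes x cells matrix of normalized expression.
#' @param reference genes x types matrix of reference profiles.
#' @return data.frame (reference, cell, rho).
#' @export
matchReference <- function(mat, reference) {
  shared <- intersect(rownames(mat), rownames(reference))
  if (length(shared) == 0L) stop("no shared genes between matrix and reference")
  rho <- .spearmanMatrix(reference[shared, , drop = FALSE],
                         mat[shared, , drop = FALSE])
  if (anyNA(rho))
    warning("zero-variance vector(s): ", sum(is.na(rho)),
            " reference-cell pair(s) skipped")
  if (all(is.na(rho))) stop("all reference-cell pairs have undefined correlation")
  best <- apply(rho, 1, function(r) {
    if (all(is.na(r))) NA_integer_ else which.max(r)  # lowest index on ties
  })
  data.frame(reference = rownames(rho),
             cell = colnames(mat)[best],
             rho = rho[cbind(seq_len(nrow(rho)), best)],
             row.names = NULL)
}

#' Best reference match per cell
#'
#' For each cell, the reference profile with the highest Spearman correlation
#' over shared genes (ties to the lowest reference index). Used for cluster
#' purity and labeling.
#'
#' @param mat genes x cells matrix.
#' @param reference genes x types matrix.
#' @return named character vector: cell id -> reference label.
#' @export
cellMatches <- function(mat, reference) {
  shared <- intersect(rownames(mat), rownames(reference))
  if (length(shared) == 0L) stop("no shared genes between matrix and reference")
  rho <- .spearmanMatrix(reference[shared, , drop = FALSE],
                         mat[shared, , drop = FALSE])
  lab <- rownames(rho)[apply(rho, 2, which.max)]
  stats::setNames(lab, colnames(mat))
}

#' Least-squares isotonic (non-decreasing) fit
#'
#' Pool-adjacent-violators solution minimizing squared error among all fits
#' non-decreasing in \code{x} (computed with \code{stats::isoreg}). The fit
#' is a function of \code{x}: tied predictor values receive a common fitted
#' value.
#'
#' @param x predictor values.
#' @param y response values.
#' @return fitted values in the original order of \code{x}.
#' @export
isotonicFit <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("input error: need at least 2 points")
  fit <- stats::isoreg(x, y)
  ord <- if (is.null(fit$ord)) seq_along(y) else fit$ord
  out <- numeric(length(y))
  out[ord] <- fit$yf
  out
}

#' Project reference profiles into single-cell expression scale
#'
#' For each reference profile, takes its matched cell (from
#' \code{\link{matchReference}}), fits an isotonic regression with the
#' reference values as input and the natural log of the matched cell's
#' back-transformed expression (pseudocount 1) as output, and returns the
#' rounded exponents of the fitted values as a pseudo-reference expression
#' profile on the single-cell scale.
#'
#' @param reference genes x types matrix.
#' @param mat genes x cells matrix of log10(x+1)-normalized expression.
#' @param matches data.frame from \code{\link{matchReference}}.
#' @return genes x types matrix of rounded projected counts.
#' @export
projectReference <- function(reference, mat, matches) {
  shared <- intersect(rownames(mat), rownames(reference))
  if (length(shared) < 2L) stop("input error: fewer than 2 shared genes")
  out <- matrix(0, length(shared), nrow(matches),
                dimnames = list(shared, matches$reference))
  for (i in seq_len(nrow(matches))) {
    cell <- matches$cell[i]
    x <- reference[shared, matches$reference[i]]
    y <- log(10^mat[shared, cell] - 1 + 1)  # natural log, pseudocount 1
    out[, i] <- round(exp(isotonicFit(x, y)))
  }
  out
}

.knnGraph <- function(coords, k) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(coords))
  el <- matrix(0L, n * k, 2)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    el[((i - 1L) * k + 1L):(i * k), ] <- cbind(i, nb)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Cluster cells with reference points and label by purity escalation
#'
#' Cells and projected reference points are clustered together on their
#' shared latent coordinates with the Leiden algorithm on a k-nearest-neighbor
#' graph. Each cell's reference match (highest Spearman correlation, computed
#' once on expression) defines cluster purity: the fraction of a cluster's
#' cells sharing the modal reference type (reference points do not count
#' toward the denominator). The resolution parameter starts at
#' \code{start_resolution} and increases by \code{resolution_step} until every
#' cluster's purity reaches \code{purity_threshold}; all cells in a cluster
#' get the modal ("dominant") reference label.
#'
#' @param cellLatents cells x dim coordinates.
#' @param refLatents reference-points x dim coordinates (same space).
#' @param cellRefMatch named character: cell -> best reference label (from
#'   \code{\link{cellMatches}}).
#' @param k_neighbors local neighborhood size (default 30).
#' @param start_resolution starting Leiden resolution (default 0.5).
#' @param resolution_step escalation step (default 0.1).
#' @param purity_threshold required per-cluster purity (default 0.70).
#' @param max_resolution escalation cap (default 5.0); unattainable purity at
#'   the cap is an error reporting the worst cluster.
#' @param seed Leiden seed (default 1).
#' @return data.frame (cell, label, cluster, purity, resolution).
#' @export
clusterAndLabel <- function(cellLatents, refLatents, cellRefMatch,
                            k_neighbors = 30, start_resolution = 0.5,
                            resolution_step = 0.1, purity_threshold = 0.70,
                            max_resolution = 5.0, seed = 1L) {
  stopifnot(ncol(cellLatents) == ncol(refLatents))
  cells <- rownames(cellLatents)
  stopifnot(all(cells %in% names(cellRefMatch)))
  coords <- rbind(cellLatents, refLatents)
  g <- .knnGraph(coords, k_neighbors)
  is_cell <- seq_len(nrow(coords)) <= nrow(cellLatents)
  res <- start_resolution
  repeat {
    set.seed(as.integer(seed))
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = res, n_iterations = 5)
    memb <- igraph::membership(cl)
    cell_memb <- memb[is_cell]
    worst <- 1
    purity <- numeric(length(cells))
    label <- character(length(cells))
    ok <- TRUE
    for (cid in unique(cell_memb)) {
      in_cl <- cell_memb == cid
      matches <- cellRefMatch[cells[in_cl]]
      tab <- sort(table(matches), decreasing = TRUE)
      pur <- as.numeric(tab[1]) / sum(in_cl)
      label[in_cl] <- names(tab)[1]
      purity[in_cl] <- pur
      if (pur < purity_threshold) {
        ok <- FALSE
        worst <- min(worst, pur)
      }
    }
    if (ok) {
      return(data.frame(cell = cells, label = label,
                        cluster = as.integer(cell_memb), purity = purity,
                        resolution = res, row.names = NULL))
    }
    res <- res + resolution_step
    if (res > max_resolution + 1e-9)
      stop("purity ", sprintf("%.2f", worst), " below threshold ",
           purity_threshold, " at max resolution ", max_resolution)
  }
}

#' Reference-based cell typing, end to end
#'
#' Convenience wrapper: matches references to cells, projects them into
#' single-cell scale via isotonic regression, embeds cells and projected
#' references jointly, and runs purity-escalated Leiden labeling.
#'
#' @param mat genes x cells matrix of log10(x+1)-normalized expression.
#' @param reference genes x types matrix of reference profiles.
#' @param dim latent dimension (default 32, capped at the data size).
#' @param ... passed to \code{\link{clusterAndLabel}}.
#' @param seed integer seed.
#' @return data.frame as \code{\link{clusterAndLabel}}.
#' @export
typeCells <- function(mat, reference, dim = 32, seed = 1L, ...) {
  matches <- matchReference(mat, reference)
  proj <- projectReference(reference, mat, matches)
  proj_norm <- log10(proj + 1)
  shared <- rownames(proj_norm)
  joint <- cbind(mat[shared, , drop = FALSE], proj_norm)
  dim <- min(dim, nrow(joint) - 1L, ncol(joint) - 1L)
  emb <- embedCells(joint, dim = dim, seed = seed)
  cellRefMatch <- cellMatches(mat, reference)
  clusterAndLabel(emb[seq_len(ncol(mat)), , drop = FALSE],
                  emb[-seq_len(ncol(mat)), , drop = FALSE],
                  cellRefMatch, seed = seed, ...)
}

#' Marker genes per cell-type label
#'
#' Rank-sum differential expression of each label against all other cells
#' (two-sided, BH-adjusted), reporting the label-vs-rest log fold change.
#' Labels with fewer than 3 cells are skipped with a warning.
#'
#' @param mat genes x cells matrix of normalized values.
#' @param labels character per cell.
#' @param fdrCut significance flag threshold (default 0.05).
#' @return data.frame (label, gene, logFC, pvalue, fdr, significant).
#' @export
findMarkers <- function(mat, labels, fdrCut = 0.05) {
  stopifnot(length(labels) == ncol(mat))
  out <- list()
  for (lb in sort(unique(labels))) {
    sel <- labels == lb
    if (sum(sel) < 3L || sum(!sel) < 3L) {
      warning("label '", lb, "' skipped: fewer than 3 cells on one side")
      next
    }
    de <- simpleDE(mat, which(sel), which(!sel))
    de$label <- lb
    de$significant <- de$fdr < fdrCut
    out[[lb]] <- de[order(de$fdr, -de$logFC), ]
  }
  if (length(out) == 0L) stop("no label with enough cells")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("label", "gene", "logFC", "pvalue", "fdr", "significant")]
}
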