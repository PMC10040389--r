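#' @include enrichment.R
NULL

#' Expressed genes of a cell population
#'
#' Back-transforms the log10-normalized layer (10^x - 1) and keeps genes whose
#' mean across the population is at least \code{threshold}. Warns when the
#' result falls outside the 5,000-10,000 band recommended for interaction
#' inference.
#'
#' @param mat genes x cells matrix of log10(x+1)-normalized values for one
#'   population.
#' @param threshold mean back-transformed expression cutoff (default 1e-5).
#' @param band expected size band for the warning (default c(5000, 10000));
#'   NULL disables the check.
#' @return character vector of expressed genes.
#' @export
expressedGenes <- function(mat, threshold = 1e-5, band = c(5000, 10000)) {
  if (is.null(dim(mat)) || ncol(mat) == 0L)
    stop("empty cell population")
  m <- rowMeans(10^mat - 1)
  out <- rownames(mat)[m >= threshold]
  if (!is.null(band) && (length(out) < band[1] || length(out) > band[2]))
    warning(length(out), " expressed genes, outside the expected ",
            band[1], "-", band[2], " band")
  out
}

#' Ligand activity against a receiver's DEGs
#'
#' For each ligand, the Pearson correlation between its regulatory-potential
#' vector and the 0/1 DEG-membership indicator over the candidate universe
#' (receiver expressed genes intersected with the prior's gene space).
#' Ligands with undefined correlation (zero variance) are skipped with a
#' warning; downstream edge construction keeps only activity > 0.
#'
#' @param degGenes character vector of the receiver's DEGs.
#' @param receiverExpressed character vector of the receiver's expressed genes.
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @return data.frame (ligand, pcc), NA pcc for skipped ligands.
#' @export
ligandActivity <- function(degGenes, receiverExpressed, prior) {
  universe <- intersect(receiverExpressed, geneUniverse(prior))
  if (length(universe) == 0L)
    stop("empty candidate universe: no receiver-expressed gene in the prior")
  ind <- as.numeric(universe %in% degGenes)
  pot <- potentials(prior)[, universe, drop = FALSE]
  lig <- ligands(prior)
  pcc <- rep(NA_real_, length(lig))
  if (stats::var(ind) > 0) {
    for (i in seq_along(lig)) {
      v <- as.numeric(pot[i, ])
      if (stats::var(v) > 0) pcc[i] <- stats::cor(v, ind)
    }
  }
  if (anyNA(pcc))
    warning(sum(is.na(pcc)), " ligand(s) skipped: undefined correlation ",
            "(zero-variance vector)")
  data.frame(ligand = lig, pcc = pcc, row.names = NULL)
}

#' Downstream targets of a ligand among a receiver's DEGs
#'
#' Intersects the receiver's DEGs with the ligand's top_k highest-potential
#' genes; weight ties at the k-boundary are all included.
#'
#' @param ligand ligand id.
#' @param degGenes character vector of DEGs.
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @param top_k number of top-weighted prior links considered (default 200).
#' @return character vector of target genes.
#' @export
inferTargets <- function(ligand, degGenes, prior, top_k = 200) {
  w <- ligandWeights(prior, ligand)
  if (length(w) > top_k) {
    ws <- sort(w, decreasing = TRUE)
    cut <- ws[top_k]
    w <- w[w >= cut]  # boundary ties all kept
  }
  sort(intersect(degGenes, names(w)))
}

#' Build a multicellular disease model for one organ
#'
#' For every ordered (sender, receiver) cell-type pair — self-pairs included —
#' each ligand expressed in the sender whose activity against the receiver's
#' DEGs exceeds \code{pcc_min} becomes a directed edge carrying its inferred
#' downstream targets.
#'
#' @param degTables named list (by cell type) of DEG data.frames.
#' @param expressed named list (by cell type) of expressed-gene sets (ligand
#'   ids count as genes here: a ligand is "expressed in the sender" when its
#'   id is in the sender's set).
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @param organ organ label for the nodes.
#' @param cellCounts optional named integer vector of cells per type.
#' @param pcc_min minimum activity (default 0, i.e. activity > 0).
#' @param top_k target-link cap per ligand (default 200).
#' @param fdrCut DEG definition threshold (default 0.05).
#' @return an \linkS4class{MCDMGraph}.
#' @export
buildMCDM <- function(degTables, expressed, prior, organ = "organ",
                      cellCounts = NULL, pcc_min = 0, top_k = 200,
                      fdrCut = 0.05) {
  cts <- names(degTables)
  stopifnot(all(cts %in% names(expressed)))
  if (length(cts) == 1L)
    warning("organ '", organ, "' has a single cell type: self-loops only")
  if (is.null(cellCounts))
    cellCounts <- stats::setNames(rep(NA_integer_, length(cts)), cts)
  nodes <- data.frame(organ = organ, cell_type = cts,
                      n_cells = as.integer(cellCounts[cts]))
  edges <- .inferEdges(
    groups = data.frame(group = cts, organ = organ, cell_type = cts),
    degTables = degTables, expressed = expressed, prior = prior,
    pcc_min = pcc_min, top_k = top_k, fdrCut = fdrCut,
    crossOrganOnly = FALSE, secretedOnly = FALSE)
  MCDMGraph(nodes, edges, multiOrgan = FALSE)
}

# shared pairwise inference over (organ, cell type) groups
.inferEdges <- function(groups, degTables, expressed, prior, pcc_min, top_k,
                        fdrCut, crossOrganOnly, secretedOnly) {
  lig_ok <- ligands(prior)
  if (secretedOnly) {
    ann <- ligandInfo(prior)
    lig_ok <- rownames(ann)[ann$location == "extracellular space"]
  }
  rows <- list()
  k <- 0L
  for (r in seq_len(nrow(groups))) {
    rg <- groups$group[r]
    tab <- degTables[[rg]]
    degs <- unique(tab$gene[tab$fdr < fdrCut])
    if (length(degs) == 0L) next
    act <- tryCatch(
      ligandActivity(degs, expressed[[rg]], prior),
      error = function(e) NULL)
    if (is.null(act)) next
    ok <- act$ligand[!is.na(act$pcc) & act$pcc > pcc_min]
    ok <- intersect(ok, lig_ok)
    if (length(ok) == 0L) next
    pccs <- stats::setNames(act$pcc, act$ligand)
    for (s in seq_len(nrow(groups))) {
      if (crossOrganOnly && groups$organ[s] == groups$organ[r]) next
      sg <- groups$group[s]
      for (lg in ok) {
        if (!lg %in% expressed[[sg]]) next
        tg <- inferTargets(lg, degs, prior, top_k = top_k)
        if (length(tg) == 0L) next
        k <- k + 1L
        rows[[k]] <- data.frame(
          sender_organ = groups$organ[s], sender_cell = groups$cell_type[s],
          ligand = lg, receiver_organ = groups$organ[r],
          receiver_cell = groups$cell_type[r], pcc = unname(pccs[lg]))
        rows[[k]]$targets <- I(list(tg))
      }
    }
  }
  if (k == 0L) {
    ed <- S4Vectors::DataFrame(
      sender_organ = character(), sender_cell = character(),
      ligand = character(), receiver_organ = character(),
      receiver_cell = character(), pcc = numeric())
    ed$targets <- list()
    return(ed)
  }
  S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Build the multi-organ MCDM
#'
#' Pairwise UR inference across all (organ, cell type) groups, restricted to
#' edges whose sender and receiver sit in different organs and whose ligand is
#' located in extracellular space (blood-transportable). Within-organ edges
#' (including autocrine self-pairs) are excluded.
#'
#' @param groups data.frame with columns group, organ, cell_type (group ids
#'   index into \code{degTables} and \code{expressed}).
#' @param degTables named list of DEG data.frames, one per group.
#' @param expressed named list of expressed-gene sets, one per group.
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @param cellCounts optional named integer vector per group.
#' @param pcc_min,top_k,fdrCut as in \code{\link{buildMCDM}}.
#' @return an \linkS4class{MCDMGraph} with \code{multiOrgan = TRUE}.
#' @export
buildMOMCDM <- function(groups, degTables, expressed, prior,
                        cellCounts = NULL, pcc_min = 0, top_k = 200,
                        fdrCut = 0.05) {
  stopifnot(all(c("group", "organ", "cell_type") %in% colnames(groups)))
  if (is.null(cellCounts))
    cellCounts <- stats::setNames(rep(NA_integer_, nrow(groups)),
                                  groups$group)
  nodes <- data.frame(organ = groups$organ, cell_type = groups$cell_type,
                      n_cells = as.integer(cellCounts[groups$group]))
  edges <- .inferEdges(groups, degTables, expressed, prior,
                       pcc_min = pcc_min, top_k = top_k, fdrCut = fdrCut,
                       crossOrganOnly = TRUE, secretedOnly = TRUE)
  MCDMGraph(nodes, edges, multiOrgan = TRUE)
}

#' Rank upstream regulators by downstream reach
#'
#' Primary key: total downstream target genes, counted per (receiver organ,
#' receiver cell type) — distinct genes within each receiver, summed over
#' receivers. Secondary key: number of distinct (organ, cell type) receivers.
#' Final tie-break: lexicographic UR id.
#'
#' @param graph an \linkS4class{MCDMGraph}.
#' @return data.frame (ur, n_targets, n_receivers, rank) ordered by rank.
#' @export
rankURs <- function(graph) {
  ed <- mcdmEdges(graph)
  if (nrow(ed) == 0L)
    return(data.frame(ur = character(), n_targets = integer(),
                      n_receivers = integer(), rank = integer()))
  recv <- paste(ed$receiver_organ, ed$receiver_cell, sep = "\r")
  urs <- sort(unique(ed$ligand))
  n_targets <- integer(length(urs))
  n_receivers <- integer(length(urs))
  for (i in seq_along(urs)) {
    sel <- ed$ligand == urs[i]
    by_recv <- split(ed$targets[sel], recv[sel])
    n_targets[i] <- sum(vapply(by_recv,
                               function(x) length(unique(unlist(x))),
                               integer(1)))
    n_receivers[i] <- length(by_recv)
  }
  ord <- order(-n_targets, -n_receivers, urs)
  data.frame(ur = urs[ord], n_targets = n_targets[ord],
             n_receivers = n_receivers[ord],
             rank = seq_along(urs), row.names = NULL)
}

#' Test UR-target expression against disease severity groups
#'
#' Standardizes each cell's normalized expression to mean 0 / sd 1 over all
#' genes within the cell, scores each cell by the mean standardized expression
#' of the target genes, and compares every pair of severity groups with a
#' two-sided Wilcoxon rank-sum test, Holm-adjusted within the family of
#' pairwise tests.
#'
#' @param mat genes x cells matrix of normalized values.
#' @param targets character vector of UR target genes (must intersect the
#'   measured genes).
#' @param groups factor/character per cell (e.g. healthy / mild / severe);
#'   needs >= 2 groups with >= 3 cells each.
#' @param exact passed to \code{wilcox.test}.
#' @return data.frame (group1, group2, p, p_adj).
#' @export
urTargetSeverity <- function(mat, targets, groups, exact = NULL) {
  targets <- intersect(targets, rownames(mat))
  if (length(targets) == 0L)
    stop("no target gene is measured in the matrix")
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))
  tab <- table(groups)
  use <- names(tab)[tab >= 3]
  if (length(use) < 2L) stop("need >= 2 groups with >= 3 cells")
  z <- scale(mat)  # per-cell (column) standardization
  score <- colMeans(z[targets, , drop = FALSE])
  pairs <- utils::combn(sort(use), 2)
  p <- apply(pairs, 2, function(gp)
    suppressWarnings(stats::wilcox.test(score[groups == gp[1]],
                                        score[groups == gp[2]],
                                        exact = exact)$p.value))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], p = p,
             p_adj = stats::p.adjust(p, "holm"), row.names = NULL)
}

#' Prioritize organs by bootstrapped DEG counts
#'
#' Organs are ranked by the median (or mean) DEG count across bootstrap
#' sampling rounds (the study design resamples 40 cells per group for ten
#' rounds); organs failing the quality criterion are excluded before ranking
#' and the top \code{n_keep} organs are returned.
#'
#' @param degCounts named list: organ -> numeric vector of per-round DEG
#'   counts (>= 1 round each).
#' @param n_keep number of organs to keep (default 5).
#' @param stat "median" (default) or "mean".
#' @param eligible optional named logical; organs marked FALSE (e.g. <= 25
#'   cells with 10,000 reads) are dropped before ranking.
#' @return data.frame (organ, stat, rank) of the selected organs.
#' @export
prioritizeOrgans <- function(degCounts, n_keep = 5,
                             stat = c("median", "mean"), eligible = NULL) {
  stat <- match.arg(stat)
  stopifnot(is.list(degCounts), !is.null(names(degCounts)),
            all(lengths(degCounts) >= 1))
  if (!is.null(eligible))
    degCounts <- degCounts[names(degCounts)[eligible[names(degCounts)]]]
  if (length(degCounts) == 0L) stop("no eligible organ")
  f <- if (stat == "median") stats::median else mean
  s <- vapply(degCounts, f, numeric(1))
  ord <- order(-s, names(s))
  if (length(s) < n_keep)
    warning("only ", length(s), " eligible organs (< n_keep = ", n_keep, ")")
  keep <- utils::head(ord, n_keep)
  data.frame(organ = names(s)[keep], stat = unname(s[keep]),
             rank = seq_along(keep), row.names = NULL)
}
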