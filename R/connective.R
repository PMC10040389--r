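#' @include enrichment.R
NULL

#' DEG-restricted pathway gene sets for one group
#'
#' Restricts every pathway's gene set to the genes differentially expressed in
#' at least one of the group's datasets; pathways whose restricted set is
#' empty are dropped with a warning.
#'
#' @param degTables named list of DEG data.frames for the group's datasets.
#' @param pathwayDB a \linkS4class{PathwayDB}.
#' @param pathways optional subset of pathway ids to restrict (default all).
#' @param fdrCut DEG threshold (default 0.05).
#' @return named list: pathway id -> restricted gene set.
#' @export
pathwayDegSets <- function(degTables, pathwayDB, pathways = NULL,
                           fdrCut = 0.05) {
  if (length(degTables) == 0L) stop("empty group: no datasets")
  deg_union <- unique(unlist(lapply(degTables, function(t)
    t$gene[t$fdr < fdrCut]), use.names = FALSE))
  gs <- geneSets(pathwayDB)
  if (!is.null(pathways)) gs <- gs[intersect(pathways, names(gs))]
  out <- lapply(gs, function(s) intersect(s, deg_union))
  empty <- lengths(out) == 0L
  if (any(empty))
    warning(sum(empty), " pathway(s) dropped: no DEG among member genes")
  out[!empty]
}

#' Pairwise Jaccard similarity of gene sets
#'
#' J(A, B) = |A intersect B| / |A union B|; symmetric with unit diagonal.
#'
#' @param sets named list of character gene sets (nonempty).
#' @return symmetric similarity matrix.
#' @export
jaccardMatrix <- function(sets) {
  if (any(lengths(sets) == 0L))
    stop("Jaccard undefined for empty sets; drop them first")
  n <- length(sets)
  genes <- unique(unlist(sets, use.names = FALSE))
  m <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  inter <- crossprod(m)
  sizes <- lengths(sets)
  uni <- outer(sizes, sizes, "+") - inter
  J <- inter / uni
  dimnames(J) <- list(names(sets), names(sets))
  J
}

#' Cluster pathways by shared genes into a program tree
#'
#' Agglomerative clustering with Ward linkage (the squared-distance
#' "ward.D2" convention) on 1 - Jaccard distances. Merge ties are resolved
#' deterministically by \code{stats::hclust}'s index order.
#'
#' @param similarity symmetric Jaccard similarity matrix
#'   (from \code{\link{jaccardMatrix}}).
#' @return a \linkS4class{ProgramTree} (assignments empty until
#'   \code{\link{cutPrograms}}).
#' @export
clusterPathways <- function(similarity) {
  if (nrow(similarity) < 2L) stop("need at least 2 pathways to cluster")
  d <- 1 - similarity
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  new("ProgramTree", hclust = hc, dist = d)
}

#' Cut a program tree into programs and subprograms
#'
#' Top-level cut into \code{k_top} programs, labeled \code{P1, P2, ...} in
#' decreasing size order; optionally each program's pathways are re-clustered
#' (same distances, same linkage) and cut into subprograms labeled
#' \code{SPi.j}, also by decreasing size.
#'
#' @param tree a \linkS4class{ProgramTree}.
#' @param k_top number of programs (default 2).
#' @param k_sub single count or named-per-program counts of subprograms;
#'   NULL (default) skips the subprogram cut; counts are capped at program
#'   size.
#' @return the tree with \code{programs} (and \code{subprograms}) filled.
#' @export
cutPrograms <- function(tree, k_top = 2, k_sub = NULL) {
  hc <- tree@hclust
  n <- nrow(tree@dist)
  if (k_top > n) stop("k_top exceeds the number of pathways")
  raw <- stats::cutree(hc, k = k_top)
  sizes <- sort(table(raw), decreasing = TRUE)
  relab <- stats::setNames(sprintf("P%d", seq_along(sizes)), names(sizes))
  programs <- stats::setNames(unname(relab[as.character(raw)]), names(raw))
  tree@programs <- programs
  if (!is.null(k_sub)) {
    subs <- character(0)
    prog_ids <- sort(unique(programs))
    for (pi in seq_along(prog_ids)) {
      p <- prog_ids[pi]
      members <- names(programs)[programs == p]
      ks <- if (length(k_sub) > 1L) k_sub[[p]] else k_sub
      ks <- min(ks, length(members))
      if (length(members) == 1L || ks <= 1L) {
        sp <- stats::setNames(rep(1L, length(members)), members)
      } else {
        dsub <- tree@dist[members, members, drop = FALSE]
        hcs <- stats::hclust(stats::as.dist(dsub), method = "ward.D2")
        sp <- stats::cutree(hcs, k = ks)
      }
      ssz <- sort(table(sp), decreasing = TRUE)
      srel <- stats::setNames(seq_along(ssz), names(ssz))
      subs[members] <- sprintf("SP%d.%d", pi, srel[as.character(sp[members])])
    }
    tree@subprograms <- subs
  }
  validObject(tree)
  tree
}

#' Activation label of one pathway within one group
#'
#' Among the group's datasets in which the pathway is significantly enriched
#' (p < alpha): count activated (z > 0), inhibited (z < 0) and
#' direction-undefined (z = NA) calls. The label is the majority direction;
#' equal nonzero counts or only undefined-z significances give
#' "no_direction"; no significant dataset gives "not_significant".
#'
#' @param enrichments data.frame rows for one pathway across one group's
#'   datasets (columns p, z as from \code{\link{enrichAll}}).
#' @param alpha significance threshold on raw p (default 0.05).
#' @return list: label, n_activated, n_inhibited, n_nodir,
#'   n_total_significant.
#' @export
labelPathway <- function(enrichments, alpha = 0.05) {
  sig <- enrichments[enrichments$p < alpha, , drop = FALSE]
  n_act <- sum(!is.na(sig$z) & sig$z > 0)
  n_inh <- sum(!is.na(sig$z) & sig$z < 0)
  n_nodir <- sum(is.na(sig$z) | sig$z == 0)
  n_sig <- nrow(sig)
  label <- if (n_sig == 0L) "not_significant"
  else if (n_act > n_inh) "activated"
  else if (n_inh > n_act) "inhibited"
  else "no_direction"
  list(label = label, n_activated = n_act, n_inhibited = n_inh,
       n_nodir = n_nodir, n_total_significant = n_sig)
}

#' Activation labels for all pathways of a group
#'
#' @param enrichments data.frame from \code{\link{enrichAll}} over the group's
#'   datasets.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame (pathway, label, n_activated, n_inhibited, n_nodir,
#'   n_total_significant).
#' @export
labelPathways <- function(enrichments, alpha = 0.05) {
  pws <- sort(unique(enrichments$pathway))
  rows <- lapply(pws, function(pw) {
    lab <- labelPathway(enrichments[enrichments$pathway == pw, , drop = FALSE],
                        alpha = alpha)
    data.frame(pathway = pw, label = lab$label,
               n_activated = lab$n_activated, n_inhibited = lab$n_inhibited,
               n_nodir = lab$n_nodir,
               n_total_significant = lab$n_total_significant)
  })
  do.call(rbind, rows)
}

#' Fraction of pathways with opposing behavior between two groups
#'
#' A member pathway counts as opposing when it is activated in one group and
#' inhibited in the other, or significantly enriched (label differs from
#' "not_significant") in exactly one of the two groups. Symmetric in A and B.
#'
#' @param labelsA,labelsB data.frames from \code{\link{labelPathways}} for the
#'   two groups.
#' @param members character vector of pathway ids to evaluate (nonempty).
#' @return fraction in [0, 1].
#' @export
opposingFraction <- function(labelsA, labelsB, members) {
  if (length(members) == 0L) stop("empty member set")
  la <- stats::setNames(labelsA$label, labelsA$pathway)[members]
  lb <- stats::setNames(labelsB$label, labelsB$pathway)[members]
  la[is.na(la)] <- "not_significant"
  lb[is.na(lb)] <- "not_significant"
  flip <- (la == "activated" & lb == "inhibited") |
    (la == "inhibited" & lb == "activated")
  onoff <- xor(la != "not_significant", lb != "not_significant")
  mean(flip | onoff)
}

#' GWAS gene-set enrichment within a program
#'
#' Per dataset: right-tailed Fisher enrichment of the GWAS gene set within
#' the program's genes present among that dataset's DEGs, using all DEGs of
#' the dataset as background; BH adjustment across datasets.
#'
#' @param programGenes character vector (a program's restricted genes).
#' @param gwasSet character vector of GWAS-associated genes.
#' @param degTables named list of DEG data.frames.
#' @param fdrCut DEG threshold (default 0.05).
#' @return data.frame (dataset, p, odds_ratio, n_overlap, fdr).
#' @export
gwasEnrichment <- function(programGenes, gwasSet, degTables, fdrCut = 0.05) {
  rows <- list()
  for (ds in names(degTables)) {
    tab <- degTables[[ds]]
    bg <- unique(tab$gene[tab$fdr < fdrCut])
    if (length(bg) == 0L) {
      warning("dataset '", ds, "' skipped: empty DEG background")
      next
    }
    fe <- fisherEnrich(intersect(programGenes, bg), gwasSet, bg)
    rows[[ds]] <- data.frame(dataset = ds, p = fe$p,
                             odds_ratio = fe$odds_ratio,
                             n_overlap = fe$n_overlap)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no dataset with a nonempty DEG background")
  res$fdr <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

#' Cross-partition cluster overlap tests
#'
#' Tests every (A-cluster, B-cluster) pair for overlap with a right-tailed
#' Fisher test on a shared universe of pathways or genes, BH-adjusted over
#' all pairs. Used e.g. to compare programs derived from two pathway
#' collections (gene mode) or from two disease sets (pathway mode).
#'
#' @param partitionA,partitionB named lists: cluster id -> member ids.
#' @param background character vector, the shared universe; every member of
#'   either partition must belong to it.
#' @param mode "pathway" or "gene" (label only; the test is identical).
#' @return data.frame (cluster_a, cluster_b, p, odds_ratio, n_overlap, fdr).
#' @export
programOverlap <- function(partitionA, partitionB, background,
                           mode = c("pathway", "gene")) {
  mode <- match.arg(mode)
  allm <- unique(c(unlist(partitionA), unlist(partitionB)))
  if (!all(allm %in% background))
    stop("mismatched universes: partition members outside the background")
  rows <- list()
  k <- 0L
  for (a in names(partitionA)) {
    for (b in names(partitionB)) {
      fe <- fisherEnrich(partitionA[[a]], partitionB[[b]], background)
      k <- k + 1L
      rows[[k]] <- data.frame(cluster_a = a, cluster_b = b, p = fe$p,
                              odds_ratio = fe$odds_ratio,
                              n_overlap = fe$n_overlap)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

#' Export a program tree as Newick plus assignment table
#'
#' @param tree a \linkS4class{ProgramTree}.
#' @param newickPath optional file to write the Newick string to.
#' @param assignPath optional TSV file for (pathway, program, subprogram).
#' @return invisibly, a list with \code{newick} (string) and
#'   \code{assignments} (data.frame).
#' @export
exportTree <- function(tree, newickPath = NULL, assignPath = NULL) {
  phy <- ape::as.phylo(tree@hclust)
  nwk <- ape::write.tree(phy)
  pws <- tree@hclust$labels
  asg <- data.frame(
    pathway = pws,
    program = if (length(tree@programs)) unname(tree@programs[pws])
      else NA_character_,
    subprogram = if (length(tree@subprograms)) unname(tree@subprograms[pws])
      else NA_character_)
  if (!is.null(newickPath)) writeLines(nwk, newickPath)
  if (!is.null(assignPath))
    utils::write.table(asg, assignPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(newick = nwk, assignments = asg))
}

#' Read a Newick tree exported by \code{\link{exportTree}}
#'
#' @param path file containing one Newick string.
#' @return an \code{ape::phylo} tree.
#' @export
readTreeNewick <- function(path) ape::read.tree(path)
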