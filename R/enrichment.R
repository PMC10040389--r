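#' @include methods.R
NULL

#' Right-tailed Fisher (hypergeometric) gene-set enrichment
#'
#' Tests over-representation of a target gene set within a query set against
#' a background universe, on the 2x2 table (overlap, query-only, target-only,
#' neither). The p-value is the exact right tail P(X >= overlap) of the
#' hypergeometric distribution. The sample odds ratio gets a 0.5 Haldane
#' correction only when a table cell is zero; the p-value is never corrected.
#'
#' @param query character vector, the query gene set (clipped to background).
#' @param target character vector, the target set (clipped to background).
#' @param background character vector, the gene universe.
#' @return list with \code{p}, \code{odds_ratio}, \code{n_overlap}.
#' @export
fisherEnrich <- function(query, target, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("empty background universe")
  query <- unique(intersect(query, background))
  target <- unique(intersect(target, background))
  if (length(query) == 0L) {
    warning("empty query set; p = 1 by convention")
    return(list(p = 1, odds_ratio = NA_real_, n_overlap = 0L))
  }
  N <- length(background)
  K <- length(target)
  n <- length(query)
  a <- length(intersect(query, target))
  # P(X >= a) with X ~ Hypergeometric(N, K, n)
  p <- stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
  b <- n - a
  cc <- K - a
  d <- N - K - b
  if (any(c(a, b, cc, d) == 0L)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    or <- (a * d) / (b * cc)
  }
  list(p = min(p, 1), odds_ratio = or, n_overlap = a)
}

#' Directional activation z-score of a signed gene set
#'
#' Open consistency score standing in for knowledge-base activation calls:
#' over the pathway genes that are differentially expressed and carry a
#' direction annotation, count those whose observed fold-change sign matches
#' the annotation (consistent) versus contradicts it (inconsistent);
#' z = (N_consistent - N_inconsistent) / sqrt(N_consistent + N_inconsistent).
#' Positive z reads "activated", negative "inhibited".
#'
#' @param signs named numeric vector of +/-1 expected directions (names =
#'   genes).
#' @param degTable data.frame with columns gene, logFC, fdr.
#' @param fdrCut DEG significance cut on the fdr column.
#' @return z, or \code{NA} when no signed DEG overlaps (undefined).
#' @export
activationZ <- function(signs, degTable, fdrCut = 0.05) {
  if (length(signs) == 0L) return(NA_real_)
  deg <- degTable[degTable$fdr < fdrCut & degTable$logFC != 0, , drop = FALSE]
  idx <- match(names(signs), deg$gene)
  hit <- !is.na(idx)
  if (!any(hit)) return(NA_real_)
  obs <- sign(deg$logFC[idx[hit]])
  cons <- sum(obs == signs[hit])
  incons <- sum(obs == -signs[hit])
  if (cons + incons == 0L) return(NA_real_)
  (cons - incons) / sqrt(cons + incons)
}

#' Pathway enrichment across datasets
#'
#' Runs \code{\link{fisherEnrich}} for every (dataset, pathway) pair, with a
#' dataset-specific background (all genes measured in that dataset) and the
#' dataset's DEGs (fdr < fdrCut) as query, plus the directional activation
#' z-score when the pathway carries sign annotations. Significance is flagged
#' at raw p < alpha (no multiplicity adjustment at this stage).
#'
#' @param degTables named list of DEG data.frames (gene, logFC, pvalue, fdr).
#' @param pathwayDB a \linkS4class{PathwayDB}.
#' @param alpha raw-p significance threshold (default 0.05).
#' @param fdrCut DEG definition threshold on fdr (default 0.05).
#' @return data.frame: pathway, dataset, p, odds_ratio, z, n_overlap,
#'   significant.
#' @export
enrichAll <- function(degTables, pathwayDB, alpha = 0.05, fdrCut = 0.05) {
  stopifnot(is.list(degTables), !is.null(names(degTables)))
  gs <- geneSets(pathwayDB)
  sg <- geneSigns(pathwayDB)
  out <- vector("list", length(degTables) * length(gs))
  k <- 0L
  for (ds in names(degTables)) {
    tab <- degTables[[ds]]
    bg <- unique(tab$gene)
    degs <- unique(tab$gene[tab$fdr < fdrCut])
    if (length(degs) == 0L)
      warning("dataset '", ds, "' has no DEGs; all pathway p-values are 1")
    for (pw in names(gs)) {
      fe <- if (length(degs)) {
        fisherEnrich(degs, gs[[pw]], bg)
      } else {
        list(p = 1, odds_ratio = NA_real_, n_overlap = 0L)
      }
      z <- activationZ(sg[[pw]], tab, fdrCut = fdrCut)
      k <- k + 1L
      out[[k]] <- data.frame(pathway = pw, dataset = ds, p = fe$p,
                             odds_ratio = fe$odds_ratio, z = z,
                             n_overlap = fe$n_overlap,
                             significant = fe$p < alpha)
    }
  }
  do.call(rbind, out)
}

#' Combine p-values with Fisher's method
#'
#' X2 = -2 * sum(log p) referred to a chi-squared distribution with 2k degrees
#' of freedom; returns the upper-tail probability.
#'
#' @param p numeric vector of p-values in (0, 1]. Zeros are clamped to the
#'   smallest positive double with a warning.
#' @return combined p-value.
#' @export
combineFisher <- function(p) {
  if (length(p) == 0L) stop("no p-values to combine")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (any(is.na(p))) stop("NA p-values cannot be combined")
  if (any(p == 0)) {
    warning("p = 0 clamped to the smallest positive representable value")
    p[p == 0] <- .Machine$double.xmin
  }
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

#' Multiple-testing adjustment (BH step-up or Holm step-down)
#'
#' @param p numeric vector of raw p-values.
#' @param method "BH" or "Holm".
#' @return adjusted p-values, same order as input.
#' @export
adjustP <- function(p, method = c("BH", "Holm")) {
  method <- match.arg(method)
  if (length(p) == 0L) return(numeric())
  stats::p.adjust(p, method = if (method == "BH") "BH" else "holm")
}

#' Cap a DEG table at the n lowest-FDR rows
#'
#' When a table exceeds n rows, the n rows with the lowest FDR are kept.
#' FDR ties at the boundary are broken by larger |logFC|, then by gene id,
#' so the result is deterministic.
#'
#' @param degTable data.frame with columns gene, logFC, fdr.
#' @param n maximum number of rows (default 5000).
#' @return the capped table (row order: ascending fdr under the tie rule).
#' @export
capDEGs <- function(degTable, n = 5000) {
  if (nrow(degTable) <= n) return(degTable)
  ord <- order(degTable$fdr, -abs(degTable$logFC), degTable$gene)
  degTable[ord[seq_len(n)], , drop = FALSE]
}

#' Rank-sum differential expression between two cell groups
#'
#' Simple per-gene two-sided Wilcoxon rank-sum test on normalized values
#' (log10(x+1) scale), BH-adjusted, with the log2 fold change computed on the
#' back-transformed scale with a pseudocount of 1.
#'
#' @param mat genes x cells matrix of normalized values.
#' @param cellsA,cellsB column ids (or indices) of the two groups (>= 3 each).
#' @param exact passed to \code{wilcox.test}; default NULL (R's own rule).
#' @return data.frame gene, logFC, pvalue, fdr.
#' @export
simpleDE <- function(mat, cellsA, cellsB, exact = NULL) {
  a <- mat[, cellsA, drop = FALSE]
  b <- mat[, cellsB, drop = FALSE]
  if (ncol(a) < 3L || ncol(b) < 3L)
    stop("each group needs at least 3 cells")
  n <- nrow(mat)
  pv <- numeric(n)
  for (i in seq_len(n)) {
    pv[i] <- suppressWarnings(
      stats::wilcox.test(a[i, ], b[i, ], exact = exact)$p.value)
  }
  pv[is.na(pv)] <- 1
  back <- function(x) 10^x - 1
  lfc <- log2((rowMeans(back(a)) + 1) / (rowMeans(back(b)) + 1))
  data.frame(gene = rownames(mat), logFC = lfc, pvalue = pv,
             fdr = stats::p.adjust(pv, "BH"), row.names = NULL)
}
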