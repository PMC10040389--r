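#' @include enrichment.R
NULL

#' UR-to-program enrichment with Fisher's-method meta-combination
#'
#' For every (UR, program, dataset) triple: right-tailed Fisher enrichment of
#' the UR's downstream targets (in that dataset) among the program's genes,
#' against the background of all genes appearing in the clustered pathways.
#' Per (UR, program), the per-dataset p-values are combined with Fisher's
#' method, BH-adjusted across all UR x program pairs, and ranked by combined
#' FDR (ties by UR id, then program id).
#'
#' @param urTargetTable data.frame with columns ur, dataset, gene: the UR's
#'   downstream target genes per dataset (e.g. from MCDM edges). URs with no
#'   targets are skipped with a warning.
#' @param programGenes named list: program/subprogram id -> gene set
#'   (DEG-restricted, from \code{\link{pathwayDegSets}} unions).
#' @param background character vector: all genes in the connective pathway
#'   analysis.
#' @return data.frame (ur, program, n_datasets, combined_p, fdr, rank), plus
#'   attribute \code{"per_dataset"} with the raw per-dataset p-values.
#' @export
urProgramEnrichment <- function(urTargetTable, programGenes, background) {
  stopifnot(all(c("ur", "dataset", "gene") %in% colnames(urTargetTable)))
  urs <- sort(unique(urTargetTable$ur))
  per_ds <- list()
  rows <- list()
  k <- 0L
  for (u in urs) {
    sub <- urTargetTable[urTargetTable$ur == u, , drop = FALSE]
    if (nrow(sub) == 0L || all(is.na(sub$gene))) {
      warning("UR '", u, "' skipped: empty target set")
      next
    }
    for (pg in names(programGenes)) {
      ps <- vapply(split(sub$gene, sub$dataset), function(tg) {
        tg <- intersect(tg, background)
        if (length(tg) == 0L) return(1)
        fisherEnrich(tg, programGenes[[pg]], background)$p
      }, numeric(1))
      k <- k + 1L
      per_ds[[k]] <- data.frame(ur = u, program = pg,
                                dataset = names(ps), p = unname(ps))
      rows[[k]] <- data.frame(ur = u, program = pg,
                              n_datasets = length(ps),
                              combined_p = combineFisher(ps))
    }
  }
  if (k == 0L) stop("no UR with a nonempty target set")
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$combined_p, "BH")
  ord <- order(res$fdr, res$combined_p, res$ur, res$program)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  attr(res, "per_dataset") <- do.call(rbind, per_ds)
  res
}

#' Filter URs by molecule class
#'
#' Keeps URs whose molecule class belongs to the allowed set (default the
#' five classes used for UR prioritization: G-protein coupled receptor,
#' cytokine, growth factor, ligand-dependent nuclear receptor, transmembrane
#' receptor). URs without a class annotation are dropped with a warning.
#'
#' @param urs character vector of UR ids.
#' @param prior a \linkS4class{LigandTargetPrior} carrying the annotations.
#' @param allowed character vector of allowed classes.
#' @return the filtered UR vector.
#' @export
filterURClasses <- function(urs, prior,
                            allowed = c("G-protein coupled receptor",
                                        "cytokine", "growth factor",
                                        "ligand-dependent nuclear receptor",
                                        "transmembrane receptor")) {
  ann <- ligandInfo(prior)
  cls <- stats::setNames(ann$molecule_class, rownames(ann))[urs]
  if (anyNA(cls))
    warning(sum(is.na(cls)), " UR(s) dropped: missing class annotation")
  urs[!is.na(cls) & cls %in% allowed]
}

#' Treatment-affected programs and subprograms
#'
#' Right-tailed Fisher enrichment of the treatment-response pathways among
#' each program/subprogram's member pathways, against all clustered pathways
#' as background; BH-adjusted. Programs at FDR < fdrCut are flagged
#' "affected".
#'
#' @param responsePathways character vector of pathways significantly
#'   enriched in the responder-vs-untreated comparison (empty set gives all
#'   non-affected, with a warning).
#' @param programMembers named list: program/subprogram id -> member pathway
#'   ids.
#' @param background character vector of all clustered pathways.
#' @param fdrCut FDR threshold (default 0.05).
#' @return data.frame (program, p, odds_ratio, n_overlap, fdr, affected).
#' @export
affectedSubprograms <- function(responsePathways, programMembers, background,
                                fdrCut = 0.05) {
  if (length(responsePathways) == 0L) {
    warning("empty response-pathway set: nothing can be affected")
    return(data.frame(program = names(programMembers), p = 1,
                      odds_ratio = NA_real_, n_overlap = 0L, fdr = 1,
                      affected = FALSE))
  }
  rows <- lapply(names(programMembers), function(pg) {
    fe <- fisherEnrich(responsePathways, programMembers[[pg]], background)
    data.frame(program = pg, p = fe$p, odds_ratio = fe$odds_ratio,
               n_overlap = fe$n_overlap)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, "BH")
  res$affected <- res$fdr < fdrCut
  res
}

#' Enrichment of an alternative UR's targets among the anchor's, per program
#'
#' For each program/subprogram: right-tailed Fisher test of the alternative
#' UR's targets against the anchor UR's targets, both clipped to the program's
#' genes, with the program's genes as background. Programs containing no
#' anchor target are skipped.
#'
#' @param altTargets character vector (alternative UR downstream genes).
#' @param anchorTargets character vector (anchor UR downstream genes).
#' @param programGenes named list: program id -> gene set.
#' @return data.frame (program, p, odds_ratio, n_overlap).
#' @export
takeoverEnrichment <- function(altTargets, anchorTargets, programGenes) {
  rows <- list()
  for (pg in names(programGenes)) {
    bg <- programGenes[[pg]]
    anchor_in <- intersect(anchorTargets, bg)
    if (length(anchor_in) == 0L) next
    alt_in <- intersect(altTargets, bg)
    fe <- if (length(alt_in) == 0L)
      list(p = 1, odds_ratio = NA_real_, n_overlap = 0L)
    else fisherEnrich(alt_in, anchor_in, bg)
    rows[[pg]] <- data.frame(program = pg, p = fe$p,
                             odds_ratio = fe$odds_ratio,
                             n_overlap = fe$n_overlap)
  }
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(program = character(), p = numeric(),
                      odds_ratio = numeric(), n_overlap = integer())
  rownames(res) <- NULL
  res
}

#' Apply the three takeover criteria to per-UR statistics
#'
#' c1: the activation z-score has the same nonzero sign in responders and
#' non-responders. c2: the UR's fold change moves further in that direction in
#' non-responders vs control than in responders vs control (strict by
#' default; \code{weak = TRUE} also accepts a crossing from negative to >= 0
#' for activators, mirrored for inhibitors). c3: a significant (FDR < fdrCut)
#' fold change of the UR in treated non-responders vs treated responders, in
#' the z-score's direction. A UR is prioritized when its targets are enriched
#' among the anchor's in at least one program (FDR < fdrCut) and c1-c3 all
#' hold. URs missing any statistic are excluded with a reason code.
#'
#' @param stats_df data.frame with columns ur, z_resp, z_nonresp,
#'   fc_resp_vs_ctrl, fc_nonresp_vs_ctrl, fc_nonresp_vs_resp_after,
#'   fdr_nonresp_vs_resp_after, enrich_fdr_min (min takeover-enrichment FDR
#'   over programs).
#' @param fdrCut FDR threshold (default 0.05).
#' @param weak use the weak reading of c2 (default FALSE = strict).
#' @return the input with columns c1, c2, c3, enrichment_ok, prioritized,
#'   excluded, reason.
#' @export
takeoverCriteria <- function(stats_df, fdrCut = 0.05, weak = FALSE) {
  need <- c("ur", "z_resp", "z_nonresp", "fc_resp_vs_ctrl",
            "fc_nonresp_vs_ctrl", "fc_nonresp_vs_resp_after",
            "fdr_nonresp_vs_resp_after", "enrich_fdr_min")
  stopifnot(all(need %in% colnames(stats_df)))
  df <- stats_df
  miss <- !stats::complete.cases(df[, setdiff(need, "ur")])
  df$excluded <- miss
  df$reason <- ifelse(miss, "missing statistic", "")
  s1 <- sign(df$z_resp)
  s2 <- sign(df$z_nonresp)
  df$c1 <- !miss & s1 == s2 & s1 != 0
  dirn <- s1
  up <- df$fc_nonresp_vs_ctrl > df$fc_resp_vs_ctrl
  dn <- df$fc_nonresp_vs_ctrl < df$fc_resp_vs_ctrl
  if (weak) {
    up <- up | (df$fc_resp_vs_ctrl < 0 & df$fc_nonresp_vs_ctrl >= 0)
    dn <- dn | (df$fc_resp_vs_ctrl > 0 & df$fc_nonresp_vs_ctrl <= 0)
  }
  df$c2 <- !miss & ((dirn > 0 & up) | (dirn < 0 & dn))
  sig3 <- df$fdr_nonresp_vs_resp_after < fdrCut
  df$c3 <- !miss & sig3 &
    ((dirn > 0 & df$fc_nonresp_vs_resp_after > 0) |
     (dirn < 0 & df$fc_nonresp_vs_resp_after < 0))
  df$enrichment_ok <- !miss & df$enrich_fdr_min < fdrCut
  df$prioritized <- df$enrichment_ok & df$c1 & df$c2 & df$c3
  df
}

#' Assess every candidate UR for takeover of an anchor UR
#'
#' Computes, from a treatment cohort's DEG tables, the statistics the three
#' takeover criteria need for every candidate UR — activation z-scores from
#' the UR's signed targets in the responder and non-responder pre-treatment
#' contrasts, the UR gene's own fold changes, the post-treatment
#' non-responder-vs-responder fold change and FDR, and the minimal
#' takeover-enrichment FDR across programs — then applies
#' \code{\link{takeoverCriteria}}.
#'
#' @param tables named list of the five cohort DEG tables (as produced by
#'   \code{\link{generateTreatmentCohort}}).
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @param anchor anchor UR id (excluded from the candidates).
#' @param programGenes named list: program/subprogram id -> gene set.
#' @param geneSignMap named +/-1 vector of annotated gene directions (used to
#'   sign each UR's targets for the activation z-score).
#' @param candidates candidate UR ids (default: all prior ligands but the
#'   anchor).
#' @param fdrCut FDR threshold (default 0.05).
#' @param weak weak reading of criterion 2 (default FALSE).
#' @return data.frame from \code{\link{takeoverCriteria}}.
#' @export
takeoverAssess <- function(tables, prior, anchor, programGenes, geneSignMap,
                           candidates = NULL, fdrCut = 0.05, weak = FALSE) {
  need <- c("resp_vs_ctrl", "nonresp_vs_ctrl",
            "treated_nonresp_vs_treated_resp")
  stopifnot(all(need %in% names(tables)))
  if (is.null(candidates)) candidates <- setdiff(ligands(prior), anchor)
  anchor_tg <- names(ligandWeights(prior, anchor))
  fc_of <- function(tab, gene) {
    i <- match(gene, tab$gene)
    if (is.na(i)) NA_real_ else tab$logFC[i]
  }
  fdr_of <- function(tab, gene) {
    i <- match(gene, tab$gene)
    if (is.na(i)) NA_real_ else tab$fdr[i]
  }
  # one BH family across all (candidate, program) enrichment tests
  enr <- list()
  for (u in candidates) {
    te <- takeoverEnrichment(names(ligandWeights(prior, u)), anchor_tg,
                             programGenes)
    if (nrow(te)) {
      te$ur <- u
      enr[[u]] <- te
    }
  }
  enr <- do.call(rbind, enr)
  if (!is.null(enr) && nrow(enr)) {
    enr$fdr <- stats::p.adjust(enr$p, "BH")
    fdr_min <- vapply(split(enr$fdr, enr$ur), min, numeric(1))
  } else fdr_min <- stats::setNames(numeric(), character())
  rows <- lapply(candidates, function(u) {
    tg <- names(ligandWeights(prior, u))
    sgn <- geneSignMap[intersect(tg, names(geneSignMap))]
    data.frame(
      ur = u,
      z_resp = activationZ(sgn, tables$resp_vs_ctrl, fdrCut = fdrCut),
      z_nonresp = activationZ(sgn, tables$nonresp_vs_ctrl, fdrCut = fdrCut),
      fc_resp_vs_ctrl = fc_of(tables$resp_vs_ctrl, u),
      fc_nonresp_vs_ctrl = fc_of(tables$nonresp_vs_ctrl, u),
      fc_nonresp_vs_resp_after =
        fc_of(tables$treated_nonresp_vs_treated_resp, u),
      fdr_nonresp_vs_resp_after =
        fdr_of(tables$treated_nonresp_vs_treated_resp, u),
      enrich_fdr_min = if (u %in% names(fdr_min)) fdr_min[[u]] else NA_real_)
  })
  takeoverCriteria(do.call(rbind, rows), fdrCut = fdrCut, weak = weak)
}
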