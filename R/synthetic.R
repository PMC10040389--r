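#' @include methods.R
NULL

.molClasses <- c("cytokine", "growth factor", "G-protein coupled receptor",
                 "ligand-dependent nuclear receptor", "transmembrane receptor",
                 "other")

.geneIds <- function(n, prefix = "g") sprintf("%s%05d", prefix, seq_len(n))

#' Generate a pathway collection with planted programs
#'
#' Builds a synthetic pathway database in which pathways fall into
#' \code{n_programs} gene-sharing "programs": every pathway of a program
#' carries the same within-program core (a fraction \code{within_share} of its
#' genes), every pathway in the collection carries the same global shared set
#' (fraction \code{between_share}), and the remainder is private to the
#' pathway. Shared fractions are therefore exact by construction. Every gene
#' in the universe receives a +/-1 activation-direction sign, recorded both in
#' the database (signed-GMT style) and in the returned truth object.
#'
#' @param n_programs number of programs (>= 2).
#' @param pathways_per_program pathways per program (>= 2).
#' @param genes_per_pathway genes per pathway (>= 5).
#' @param within_share fraction of a pathway's genes shared within its program.
#' @param between_share fraction shared across all programs; must be smaller
#'   than \code{within_share} and satisfy within + between <= 1.
#' @param seed integer seed; same seed reproduces the output bit-identically.
#' @return list with \code{db} (a \linkS4class{PathwayDB}) and \code{truth}
#'   (a \linkS4class{SyntheticTruth} with programOf, geneSigns, seed filled).
#' @export
generatePathwayDB <- function(n_programs = 2, pathways_per_program = 10,
                              genes_per_pathway = 50, within_share = 0.5,
                              between_share = 0.05, seed = 1L) {
  if (!(within_share > between_share))
    stop("configuration error: within_share must exceed between_share")
  if (n_programs < 2) stop("configuration error: n_programs must be >= 2")
  if (pathways_per_program < 2)
    stop("configuration error: pathways_per_program must be >= 2")
  if (genes_per_pathway < 5)
    stop("configuration error: genes_per_pathway must be >= 5")
  if (within_share < 0 || within_share > 1 || between_share < 0)
    stop("configuration error: shares must be fractions in [0, 1]")
  w <- round(within_share * genes_per_pathway)
  b <- round(between_share * genes_per_pathway)
  if (w + b > genes_per_pathway)
    stop("configuration error: within_share + between_share exceeds 1")
  set.seed(as.integer(seed))
  priv <- genes_per_pathway - w - b
  n_pw <- n_programs * pathways_per_program
  n_genes <- b + n_programs * w + n_pw * priv
  genes <- .geneIds(n_genes)
  nxt <- 1L
  take <- function(k) {
    out <- genes[seq.int(nxt, length.out = k)]
    nxt <<- nxt + k
    out
  }
  global_shared <- take(b)
  sets <- list()
  programOf <- character()
  for (p in seq_len(n_programs)) {
    core <- take(w)
    for (j in seq_len(pathways_per_program)) {
      id <- sprintf("PW_%02d_%02d", p, j)
      sets[[id]] <- sample(c(global_shared, core, take(priv)))
      programOf[id] <- sprintf("PR%d", p)
    }
  }
  sgn <- sample(c(-1, 1), n_genes, replace = TRUE)
  names(sgn) <- genes
  signs <- lapply(sets, function(s) sgn[s])
  db <- PathwayDB(sets, signs, source = "synthetic")
  truth <- new("SyntheticTruth", programOf = programOf, geneSigns = sgn,
               seed = as.integer(seed))
  list(db = db, truth = truth)
}

#' Generate a ligand-to-target prior over a pathway collection
#'
#' Each ligand (UR) is assigned a home program round-robin and draws
#' \code{program_bias} of its targets from that program's genes — shared
#' (core) genes first, then the program's private genes — and the rest from
#' the remaining universe, with positive uniform weights. Core-first drawing
#' reflects why programs exist at all: the same UR-driven genes recur across
#' the program's pathways. \code{floor(secreted_fraction * n_ligands)}
#' ligands (in randomized order) are flagged as located in extracellular
#' space.
#'
#' @param pathwayDB a \linkS4class{PathwayDB} (must be nonempty).
#' @param truth the paired \linkS4class{SyntheticTruth} carrying the
#'   pathway -> program map.
#' @param n_ligands number of ligands.
#' @param targets_per_ligand targets per ligand (<= gene-universe size).
#' @param secreted_fraction fraction of ligands flagged extracellular.
#' @param program_bias fraction of each ligand's targets drawn from its home
#'   program (default 0.8).
#' @param seed integer seed.
#' @return list with \code{prior} (a \linkS4class{LigandTargetPrior}),
#'   \code{truth} (urTargets filled), and \code{homeProgram} (named character).
#' @export
generatePrior <- function(pathwayDB, truth, n_ligands = 10,
                          targets_per_ligand = 30, secreted_fraction = 0.5,
                          program_bias = 0.8, seed = 1L) {
  if (length(geneSets(pathwayDB)) == 0L)
    stop("input error: empty pathway database")
  genes <- geneUniverse(pathwayDB)
  if (targets_per_ligand > length(genes))
    stop("input error: targets_per_ligand exceeds the gene universe")
  set.seed(as.integer(seed))
  programOf <- truth@programOf
  progs <- sort(unique(programOf))
  lig <- sprintf("UR%02d", seq_len(n_ligands))
  pot <- matrix(0, n_ligands, length(genes), dimnames = list(lig, genes))
  home <- progs[(seq_len(n_ligands) - 1L) %% length(progs) + 1L]
  names(home) <- lig
  progSets <- lapply(progs, function(p)
    geneSets(pathwayDB)[names(programOf)[programOf == p]])
  names(progSets) <- progs
  progGenes <- lapply(progSets, function(ss) unique(unlist(ss)))
  # core = genes recurring in at least half of the program's pathways
  progCore <- lapply(progSets, function(ss) {
    cnt <- table(unlist(ss))
    names(cnt)[cnt >= length(ss) / 2]
  })
  targets <- list()
  for (i in seq_len(n_ligands)) {
    hg <- progGenes[[home[i]]]
    core <- progCore[[home[i]]]
    n_home <- min(round(program_bias * targets_per_ligand), length(hg))
    n_core <- min(n_home, length(core))
    hg_pick <- c(sample(core, n_core),
                 if (n_home > n_core)
                   sample(setdiff(hg, core), n_home - n_core))
    rest <- setdiff(genes, hg)
    n_rest <- min(targets_per_ligand - n_home, length(rest))
    tg <- c(hg_pick, if (n_rest > 0) sample(rest, n_rest))
    pot[i, tg] <- stats::runif(length(tg), 0.5, 1)
    targets[[lig[i]]] <- sort(tg)
  }
  n_sec <- floor(secreted_fraction * n_ligands)
  sec_ids <- if (n_sec > 0) sample(lig, n_sec) else character()
  location <- ifelse(lig %in% sec_ids, "extracellular space", "other")
  names(location) <- lig
  mclass <- sample(.molClasses, n_ligands, replace = TRUE)
  names(mclass) <- lig
  prior <- LigandTargetPrior(pot, location, mclass)
  truth@urTargets <- targets
  list(prior = prior, truth = truth, homeProgram = home)
}

# synthesize p and fdr consistent with DEG status: DEG p ~ Beta(0.01, 1)
# truncated to (0, 0.05) (inverse-CDF draw), null p ~ Unif(0.05, 1);
# fdr >= p, below/above the 0.05 cut by construction
.synthPvalues <- function(is_deg) {
  n <- length(is_deg)
  p <- numeric(n)
  fdr <- numeric(n)
  nd <- sum(is_deg)
  if (nd > 0) {
    pd <- 0.05 * stats::runif(nd)^100
    p[is_deg] <- pd
    fdr[is_deg] <- pmin(stats::runif(nd, pd, 0.05), 0.049999)
  }
  if (nd < n) {
    pn <- stats::runif(n - nd, 0.05, 1)
    p[!is_deg] <- pn
    fdr[!is_deg] <- stats::runif(n - nd, pn, 1)
  }
  list(p = p, fdr = fdr)
}

#' Generate DEG tables driven by planted UR activity
#'
#' For each group (e.g. an (organ, cell type) pair or a dataset), the targets
#' of the group's active URs become differentially expressed: the observed
#' fold-change sign is the UR direction multiplied by the gene's annotated
#' activation-direction sign, so an active-up UR moves each target in its
#' annotated direction. Planted DEGs are dropped independently at
#' \code{fn_rate}; non-target genes become false-positive DEGs at
#' \code{fp_rate} with random sign. Tables contain every measured gene; DEGs
#' are the rows with fdr < 0.05 (guaranteed for retained planted targets).
#'
#' @param truth \linkS4class{SyntheticTruth} with \code{urActivity} set
#'   (data.frame group, ur, direction in -1/0/+1).
#' @param prior \linkS4class{LigandTargetPrior}; every active UR must exist.
#' @param groups character vector of group ids to generate tables for.
#' @param fp_rate false-positive DEG rate among non-target genes.
#' @param fn_rate drop rate for planted target DEGs.
#' @param seed integer seed.
#' @return named list (one per group) of data.frames with columns gene,
#'   logFC, pvalue, fdr, dataset.
#' @export
generateDegTables <- function(truth, prior, groups, fp_rate = 0.01,
                              fn_rate = 0.1, seed = 1L) {
  ua <- urActivity(truth)
  active <- ua[ua$direction != 0, , drop = FALSE]
  bad <- setdiff(active$ur, ligands(prior))
  if (length(bad))
    stop("input error: unknown UR id(s): ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  genes <- geneUniverse(prior)
  sgn <- truth@geneSigns
  missing_sign <- setdiff(genes, names(sgn))
  if (length(missing_sign)) {
    add <- rep(1, length(missing_sign))
    names(add) <- missing_sign
    sgn <- c(sgn, add)
  }
  tgt <- urTargets(truth)
  if (length(tgt) == 0L)
    tgt <- lapply(ligands(prior), function(l) names(ligandWeights(prior, l)))
  out <- list()
  for (g in groups) {
    acts <- active[active$group == g, , drop = FALSE]
    net <- numeric(length(genes))
    names(net) <- genes
    for (i in seq_len(nrow(acts))) {
      tg <- intersect(tgt[[acts$ur[i]]], genes)
      net[tg] <- net[tg] + acts$direction[i]
    }
    planted <- names(net)[net != 0 | (net == 0 & names(net) %in%
      unlist(tgt[acts$ur], use.names = FALSE))]
    planted_dir <- sign(net[planted])
    planted_dir[planted_dir == 0] <- sample(c(-1, 1), sum(planted_dir == 0),
                                            replace = TRUE)
    keep <- stats::runif(length(planted)) >= fn_rate
    planted <- planted[keep]
    planted_dir <- planted_dir[keep]
    is_deg <- genes %in% planted
    fp <- !is_deg & stats::runif(length(genes)) < fp_rate
    lfc <- stats::rnorm(length(genes), 0, 0.05)
    if (any(is_deg)) {
      dsign <- planted_dir[match(genes[is_deg], planted)] * sgn[genes[is_deg]]
      lfc[is_deg] <- dsign * abs(stats::rnorm(sum(is_deg), 1.5, 0.4))
    }
    if (any(fp))
      lfc[fp] <- sample(c(-1, 1), sum(fp), replace = TRUE) *
        abs(stats::rnorm(sum(fp), 1.5, 0.4))
    pv <- .synthPvalues(is_deg | fp)
    out[[g]] <- data.frame(gene = genes, logFC = lfc, pvalue = pv$p,
                           fdr = pv$fdr, dataset = g, row.names = NULL)
  }
  out
}

#' Generate negative-binomial single-cell counts with known labels
#'
#' Counts follow NB(mu, dispersion) with variance mu + dispersion * mu^2.
#' Per-type mean vectors are the baseline means perturbed per gene by a
#' log-normal factor whose log-sd is \code{separation}, so pairwise distance
#' between type profiles grows with \code{separation}. The matching reference
#' profile is the noiseless mean matrix. The normalized layer is
#' log10(scaled count + 1) with per-cell scaling to the median library size.
#'
#' @param cell_types character vector of type labels.
#' @param n_cells_per_type single count or per-type vector (0 allowed: the
#'   type is absent from the matrix but present in the reference).
#' @param n_genes number of genes.
#' @param dispersion NB dispersion alpha (> 0).
#' @param separation log-sd of the per-type mean perturbation (> 0).
#' @param seed integer seed.
#' @return list with \code{sce} (a \code{SingleCellExperiment} with assays
#'   \code{counts} and \code{lognorm} and QC colData), \code{reference}
#'   (genes x types mean matrix) and \code{truth} (cellLabels filled).
#' @export
#' @importFrom SingleCellExperiment SingleCellExperiment
generateExpression <- function(cell_types, n_cells_per_type = 100,
                               n_genes = 500, dispersion = 0.2,
                               separation = 2, seed = 1L) {
  if (separation <= 0) stop("configuration error: separation must be > 0")
  if (dispersion <= 0) stop("configuration error: dispersion must be > 0")
  if (length(n_cells_per_type) == 1L)
    n_cells_per_type <- rep(n_cells_per_type, length(cell_types))
  stopifnot(length(n_cells_per_type) == length(cell_types))
  set.seed(as.integer(seed))
  genes <- .geneIds(n_genes)
  base_mu <- exp(stats::rnorm(n_genes, mean = 1, sd = 1))
  ref <- sapply(cell_types, function(tp)
    base_mu * exp(stats::rnorm(n_genes, 0, separation)))
  rownames(ref) <- genes
  n_tot <- sum(n_cells_per_type)
  labels <- rep(cell_types, n_cells_per_type)
  cells <- sprintf("cell%05d", seq_len(n_tot))
  counts <- matrix(0L, n_genes, n_tot, dimnames = list(genes, cells))
  for (j in seq_len(n_tot)) {
    counts[, j] <- stats::rnbinom(n_genes, mu = ref[, labels[j]],
                                  size = 1 / dispersion)
  }
  lib <- colSums(counts)
  scale_to <- stats::median(lib[lib > 0])
  lognorm <- log10(sweep(counts, 2, pmax(lib, 1), "/") * scale_to + 1)
  names(labels) <- cells
  transcripts <- colSums(counts)
  cd <- S4Vectors::DataFrame(
    organ = "organ1",
    subject = sprintf("subj%02d", (seq_len(n_tot) - 1L) %% 4L + 1L),
    disease_state = "sick",
    severity = 0L,
    reads = as.integer(round(transcripts * stats::runif(n_tot, 3, 6))),
    transcripts = as.integer(transcripts),
    genes_detected = as.integer(colSums(counts > 0)),
    mito_fraction = stats::runif(n_tot, 0, 0.1),
    row.names = cells
  )
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts, lognorm = lognorm), colData = cd)
  truth <- new("SyntheticTruth", cellLabels = labels,
               seed = as.integer(seed))
  list(sce = sce, reference = ref, truth = truth)
}

#' Rewire a ligand's targets to overlap an anchor UR
#'
#' Replaces part of \code{takeover}'s target set with genes drawn from
#' \code{anchor}'s targets so that the two share at least \code{overlap} of
#' the anchor's targets; used to plant a takeover UR before
#' \code{\link{generateTreatmentCohort}}.
#'
#' @param prior a \linkS4class{LigandTargetPrior}.
#' @param anchor,takeover ligand ids.
#' @param overlap required shared fraction of the anchor's targets (0-1).
#' @param seed integer seed.
#' @return the modified prior.
#' @export
plantTakeoverTargets <- function(prior, anchor, takeover, overlap = 0.8,
                                 seed = 1L) {
  stopifnot(anchor %in% ligands(prior), takeover %in% ligands(prior))
  set.seed(as.integer(seed))
  pot <- as.matrix(potentials(prior))
  a_tg <- colnames(pot)[pot[anchor, ] > 0]
  need <- ceiling(overlap * length(a_tg))
  shared <- if (need >= length(a_tg)) a_tg else sample(a_tg, need)
  t_w <- pot[takeover, ]
  n_keep <- max(length(t_w[t_w > 0]) - length(shared), 0L)
  own <- setdiff(names(t_w)[t_w > 0], a_tg)
  keep <- utils::head(own, n_keep)
  pot[takeover, ] <- 0
  new_tg <- unique(c(shared, keep))
  pot[takeover, new_tg] <- stats::runif(length(new_tg), 0.5, 1)
  ann <- ligandInfo(prior)
  LigandTargetPrior(pot,
                    stats::setNames(ann$location, rownames(ann)),
                    stats::setNames(ann$molecule_class, rownames(ann)))
}

#' Generate a treatment cohort with a planted takeover UR
#'
#' Emulates an anti-cytokine treatment study: an anchor UR (the treated
#' target, e.g. a TNF-like cytokine) drives disease in responders and
#' non-responders before treatment; after treatment the responders resolve
#' while in non-responders a backup ("takeover") UR keeps the anchor's
#' downstream genes active. By construction the planted takeover UR satisfies
#' all three takeover criteria (consistent activation z in responders and
#' non-responders; fold change further from baseline in non-responders vs
#' control; significant fold change in treated non-responders vs treated
#' responders) and every other UR violates at least one.
#'
#' @param truth \linkS4class{SyntheticTruth} (gene signs used for DEG signs).
#' @param prior \linkS4class{LigandTargetPrior}; UR ids appear as measured
#'   genes in the tables.
#' @param anchor_ur anchor UR id.
#' @param takeover_ur takeover UR id, or \code{NA} to plant none.
#' @param overlap required shared fraction of anchor targets (checked against
#'   the prior; infeasible overlap is an input error).
#' @param seed integer seed.
#' @return list with \code{tables} (named list of 5 DEG data.frames:
#'   resp_vs_ctrl, nonresp_vs_ctrl, treated_resp_vs_ctrl,
#'   treated_nonresp_vs_ctrl, treated_nonresp_vs_treated_resp) and
#'   \code{truth} (takeoverUR recorded).
#' @export
generateTreatmentCohort <- function(truth, prior, anchor_ur, takeover_ur = NA,
                                    overlap = 0.8, seed = 1L) {
  stopifnot(anchor_ur %in% ligands(prior))
  a_tg <- names(ligandWeights(prior, anchor_ur))
  if (!is.na(takeover_ur)) {
    stopifnot(takeover_ur %in% ligands(prior))
    t_tg <- names(ligandWeights(prior, takeover_ur))
    got <- length(intersect(a_tg, t_tg)) / length(a_tg)
    if (got < overlap - 1e-12)
      stop("input error: takeover UR shares only ",
           sprintf("%.2f", got), " of the anchor's targets (need >= ",
           overlap, "); see plantTakeoverTargets()")
  }
  set.seed(as.integer(seed))
  genes <- geneUniverse(prior)
  urs <- ligands(prior)
  sgn <- truth@geneSigns
  missing_sign <- setdiff(genes, names(sgn))
  if (length(missing_sign)) {
    add <- rep(1, length(missing_sign))
    names(add) <- missing_sign
    sgn <- c(sgn, add)
  }
  universe <- c(genes, urs)

  mk_table <- function(deg_genes, deg_lfc, ur_lfc, ur_sig, ds) {
    lfc <- stats::rnorm(length(universe), 0, 0.05)
    names(lfc) <- universe
    is_deg <- universe %in% deg_genes
    lfc[deg_genes] <- deg_lfc
    lfc[names(ur_lfc)] <- ur_lfc
    is_deg <- is_deg | (universe %in% names(ur_sig)[ur_sig])
    pv <- .synthPvalues(is_deg)
    data.frame(gene = universe, logFC = unname(lfc), pvalue = pv$p,
               fdr = pv$fdr, dataset = ds, row.names = NULL)
  }
  sick_lfc <- sgn[a_tg] * abs(stats::rnorm(length(a_tg), 1.5, 0.3))

  ur_sig_false <- stats::setNames(rep(FALSE, length(urs)), urs)

  # before treatment: anchor drives disease in both arms; every candidate
  # UR gene has a measured fold change, but only the takeover UR's moves
  # further from baseline in non-responders
  fc_resp <- stats::setNames(stats::runif(length(urs), 0.2, 0.5), urs)
  fc_resp[anchor_ur] <- 1.0
  fc_nonresp <- fc_resp - stats::runif(length(urs), 0.1, 0.3)
  fc_nonresp[anchor_ur] <- 1.2
  if (!is.na(takeover_ur)) fc_nonresp[takeover_ur] <- fc_resp[takeover_ur] +
    stats::runif(1, 0.5, 1)
  ur_sig_before <- ur_sig_false
  ur_sig_before[anchor_ur] <- TRUE

  tabs <- list(
    resp_vs_ctrl = mk_table(a_tg, sick_lfc, fc_resp, ur_sig_before,
                            "resp_vs_ctrl"),
    nonresp_vs_ctrl = mk_table(a_tg, sick_lfc, fc_nonresp, ur_sig_before,
                               "nonresp_vs_ctrl"),
    treated_resp_vs_ctrl = mk_table(character(), numeric(),
                                    stats::setNames(numeric(), character()),
                                    ur_sig_false, "treated_resp_vs_ctrl")
  )
  # after treatment: non-responders keep the anchor's program running
  # (through the takeover UR when planted)
  keep_deg <- if (!is.na(takeover_ur))
    intersect(a_tg, names(ligandWeights(prior, takeover_ur))) else a_tg
  tabs$treated_nonresp_vs_ctrl <- mk_table(
    keep_deg, sgn[keep_deg] * abs(stats::rnorm(length(keep_deg), 1.2, 0.3)),
    stats::setNames(numeric(), character()), ur_sig_false,
    "treated_nonresp_vs_ctrl")
  # treated non-responders vs treated responders: only the takeover UR gene
  # is significantly shifted
  fc_after <- stats::setNames(stats::rnorm(length(urs), 0, 0.05), urs)
  ur_sig_after <- ur_sig_false
  if (!is.na(takeover_ur)) {
    fc_after[takeover_ur] <- abs(stats::rnorm(1, 1.5, 0.2))
    ur_sig_after[takeover_ur] <- TRUE
  }
  deg_after <- if (!is.na(takeover_ur)) keep_deg else character()
  tabs$treated_nonresp_vs_treated_resp <- mk_table(
    deg_after,
    if (length(deg_after)) sgn[deg_after] *
      abs(stats::rnorm(length(deg_after), 1.2, 0.3)) else numeric(),
    fc_after, ur_sig_after, "treated_nonresp_vs_treated_resp")

  truth@takeoverUR <- if (is.na(takeover_ur)) NA_character_ else takeover_ur
  list(tables = tabs, truth = truth)
}
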