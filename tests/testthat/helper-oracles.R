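# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: explicit summation, brute-force search, direct
# set arithmetic.

# right-tail hypergeometric p by explicit term summation
oracleHyperTail <- function(a, K, n, N) {
  hi <- min(K, n)
  lo <- max(0L, n - (N - K))
  js <- seq.int(max(a, lo), hi)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# pool-adjacent-violators, written as the textbook loop
oraclePAV <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  vals <- as.numeric(y)
  wts <- as.numeric(w)
  lens <- rep(1L, n)
  m <- n
  i <- 1L
  while (i < m) {
    if (vals[i] > vals[i + 1L] + 1e-12) {
      vals[i] <- (vals[i] * wts[i] + vals[i + 1L] * wts[i + 1L]) /
        (wts[i] + wts[i + 1L])
      wts[i] <- wts[i] + wts[i + 1L]
      lens[i] <- lens[i] + lens[i + 1L]
      vals <- vals[-(i + 1L)]
      wts <- wts[-(i + 1L)]
      lens <- lens[-(i + 1L)]
      m <- m - 1L
      if (i > 1L) i <- i - 1L
    } else {
      i <- i + 1L
    }
  }
  rep(vals, lens)
}

# exhaustive least-squares monotone fit over a discretized value grid
oracleMonotoneGrid <- function(y, grid) {
  n <- length(y)
  best <- NULL
  best_err <- Inf
  # enumerate all non-decreasing sequences over grid via stars and bars
  idx <- utils::combn(seq_len(length(grid) + n - 1L), n)
  for (j in seq_len(ncol(idx))) {
    pick <- idx[, j] - seq_len(n) + 1L
    f <- grid[pick]
    err <- sum((y - f)^2)
    if (err < best_err - 1e-15) {
      best_err <- err
      best <- f
    }
  }
  list(fit = best, err = best_err)
}

oracleJaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# mean within/between-program Jaccard by direct set arithmetic over all pairs
oracleProgramJaccards <- function(sets, programOf) {
  ids <- names(sets)
  within <- c()
  between <- c()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      jc <- oracleJaccard(sets[[ids[i]]], sets[[ids[j]]])
      if (programOf[ids[i]] == programOf[ids[j]]) within <- c(within, jc)
      else between <- c(between, jc)
    }
  }
  list(within = mean(within), between = mean(between))
}

# tiny deg table constructor
mkDeg <- function(genes, lfc = 1, fdr = 0.01, dataset = "ds1",
                  pvalue = fdr / 2) {
  data.frame(gene = genes, logFC = rep_len(lfc, length(genes)),
             pvalue = rep_len(pvalue, length(genes)),
             fdr = rep_len(fdr, length(genes)), dataset = dataset)
}

# a deg table over a universe: DEGs significant, rest null
mkDegUniverse <- function(universe, degs, lfc = NULL, dataset = "ds1") {
  if (is.null(lfc)) lfc <- rep(1, length(degs))
  tab <- data.frame(gene = universe, logFC = 0, pvalue = 0.5, fdr = 0.5,
                    dataset = dataset)
  i <- match(degs, universe)
  tab$logFC[i] <- lfc
  tab$pvalue[i] <- 0.001
  tab$fdr[i] <- 0.01
  tab
}

# small prior constructor
mkPrior <- function(weights, secreted = NULL, classes = NULL) {
  lig <- rownames(weights)
  if (is.null(secreted)) secreted <- rep(TRUE, length(lig))
  loc <- ifelse(secreted, "extracellular space", "other")
  names(loc) <- lig
  if (is.null(classes)) classes <- rep("cytokine", length(lig))
  names(classes) <- lig
  LigandTargetPrior(weights, loc, classes)
}

# planted three-organ scenario used by interaction and acceptance tests:
# URs active in every (organ, cell type) group, expressed sets = everything
plantedScenario <- function(seed, n_ligands = 8, targets_per_ligand = 120,
                            planted = c("UR01", "UR02"), direction = 1,
                            organs = c("joint", "lung", "muscle"),
                            cell_types = c("Tcell", "fibroblast"),
                            fp_rate = 0.02, fn_rate = 0.2,
                            secreted_fraction = 1) {
  pw <- generatePathwayDB(seed = seed)
  pr <- generatePrior(pw$db, pw$truth, n_ligands = n_ligands,
                      targets_per_ligand = targets_per_ligand,
                      secreted_fraction = secreted_fraction, seed = seed)
  groups <- expand.grid(organ = organs, cell_type = cell_types,
                        stringsAsFactors = FALSE)
  groups$group <- paste(groups$organ, groups$cell_type, sep = ":")
  truth <- pr$truth
  urActivity(truth) <- do.call(rbind, lapply(planted, function(u)
    data.frame(group = groups$group, ur = u, direction = direction)))
  degTables <- generateDegTables(truth, pr$prior, groups$group,
                                 fp_rate = fp_rate, fn_rate = fn_rate,
                                 seed = seed + 1L)
  expressed <- stats::setNames(
    lapply(groups$group, function(g) c(geneUniverse(pr$prior),
                                       ligands(pr$prior))),
    groups$group)
  list(db = pw$db, prior = pr$prior, truth = truth, groups = groups,
       degTables = degTables, expressed = expressed,
       homeProgram = pr$homeProgram)
}
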