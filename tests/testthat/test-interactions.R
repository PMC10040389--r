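test_that("expressedGenes back-transforms and applies the mean cutoff", {
  m <- rbind(zero = c(0, 0, 0),
             at_cut = rep(log10(1 + 2e-5), 3),
             high = rep(log10(1 + 1), 3))
  colnames(m) <- paste0("c", 1:3)
  out <- expressedGenes(m, band = NULL)
  expect_setequal(out, c("at_cut", "high"))
  expect_length(expressedGenes(m, threshold = Inf, band = NULL), 0)
  expect_warning(expressedGenes(m, band = c(5000, 10000)), "band")
  expect_error(expressedGenes(m[, 0]), "empty")
})

test_that("ligandActivity equals the direct Pearson formula", {
  genes <- paste0("g", 1:500)
  set.seed(15)
  pot <- rbind(UR01 = runif(500), UR02 = runif(500))
  colnames(pot) <- genes
  prior <- mkPrior(pot)
  degs <- sample(genes, 100)

  act <- ligandActivity(degs, genes, prior)
  ind <- as.numeric(genes %in% degs)
  expect_equal(act$pcc[act$ligand == "UR01"], cor(pot["UR01", ], ind),
               tolerance = 1e-12)
  expect_lt(abs(act$pcc[act$ligand == "UR01"]), 0.2)

  # potential proportional to the DEG indicator: PCC = 1
  pot2 <- rbind(UR01 = 2 * ind + 1e-9)
  colnames(pot2) <- genes
  act2 <- ligandActivity(degs, genes, mkPrior(pot2))
  expect_equal(act2$pcc, 1, tolerance = 1e-9)

  # empty DEG set: constant indicator, every ligand skipped
  expect_warning(act0 <- ligandActivity(character(), genes, prior),
                 "skipped")
  expect_true(all(is.na(act0$pcc)))

  expect_error(ligandActivity(degs, "not_a_gene", prior), "universe")
})

test_that("inferTargets intersects DEGs with top-weighted links (ties kept)", {
  genes <- paste0("g", 1:10)
  pot <- matrix(c(10, 9, 8, 8, 8, 3, 2, 1, 0, 0), 1,
                dimnames = list("UR01", genes))
  prior <- mkPrior(pot)
  # top_k = 3 hits the tie at weight 8: g3, g4, g5 all kept
  expect_setequal(inferTargets("UR01", genes, prior, top_k = 3),
                  c("g1", "g2", "g3", "g4", "g5"))
  # sort oracle
  degs <- c("g2", "g4", "g7")
  w <- sort(stats::setNames(as.numeric(pot), genes), decreasing = TRUE)
  oracle <- intersect(degs, names(w)[w >= w[3]])
  expect_setequal(inferTargets("UR01", degs, prior, top_k = 3), oracle)
  # top_k >= genome: all positive-prior DEGs
  expect_setequal(inferTargets("UR01", genes, prior, top_k = 100),
                  paste0("g", 1:8))
  expect_length(inferTargets("UR01", c("g9", "g10"), prior), 0)
  expect_error(inferTargets("URXX", genes, prior), "unknown ligand")
})

test_that("buildMCDM creates one edge per active sender-ligand-receiver", {
  genes <- paste0("g", 1:20)
  pot <- matrix(0, 1, 20, dimnames = list("UR01", genes))
  pot["UR01", 1:5] <- 1
  prior <- mkPrior(pot)
  degs <- mkDegUniverse(genes, paste0("g", 1:5))
  tabs <- list(A = degs, B = mkDegUniverse(genes, character()))
  expr <- list(A = c(genes, "UR01"), B = genes)  # ligand expressed in A only
  mc <- buildMCDM(tabs, expr, prior, organ = "joint")
  ed <- mcdmEdges(mc)
  # receiver must be A (the only cell type with DEGs), sender must express UR01
  expect_equal(nrow(ed), 1)
  expect_equal(ed$sender_cell, "A")
  expect_equal(ed$receiver_cell, "A")
  expect_setequal(ed$targets[[1]], paste0("g", 1:5))
  expect_gt(ed$pcc, 0)

  # no DEGs anywhere: empty edge set
  mc0 <- buildMCDM(list(A = mkDegUniverse(genes, character())),
                   list(A = genes), prior, organ = "x") |>
    suppressWarnings()
  expect_equal(nrow(mcdmEdges(mc0)), 0)
})

test_that("planted secreted URs dominate a permutation null in the MCDM", {
  sc <- plantedScenario(seed = 16, planted = c("UR01", "UR02"),
                        organs = "joint", fp_rate = 0.01, fn_rate = 0.1)
  idx <- sc$groups$organ == "joint"
  tabs <- stats::setNames(sc$degTables[sc$groups$group[idx]],
                          sc$groups$cell_type[idx])
  expr <- stats::setNames(sc$expressed[sc$groups$group[idx]],
                          sc$groups$cell_type[idx])
  mc <- buildMCDM(tabs, expr, sc$prior, organ = "joint")
  ed <- mcdmEdges(mc)
  expect_true(all(c("UR01", "UR02") %in% ed$ligand))
  # every receiver with planted-target DEGs gets the planted ligands
  for (ct in names(tabs)) {
    recv <- ed$ligand[ed$receiver_cell == ct]
    expect_true(all(c("UR01", "UR02") %in% recv))
  }

  # permutation null: shuffling DEG labels kills non-planted activity
  genes <- geneUniverse(sc$prior)
  tab <- tabs[[1]]
  degs <- tab$gene[tab$fdr < 0.05]
  obs <- ligandActivity(degs, genes, sc$prior)
  set.seed(16)
  null_max <- replicate(200, {
    fake <- sample(genes, length(degs))
    a <- ligandActivity(fake, genes, sc$prior)
    stats::quantile(a$pcc, 0.95, na.rm = TRUE)
  })
  cut95 <- stats::quantile(null_max, 0.95)
  planted_pcc <- obs$pcc[obs$ligand %in% c("UR01", "UR02")]
  expect_true(all(planted_pcc > cut95))
})

test_that("MO-MCDM equals the secreted, cross-organ filter of the pooled graph", {
  sc <- plantedScenario(seed = 17, planted = c("UR01", "UR02"),
                        secreted_fraction = 0.5)
  mo <- buildMOMCDM(sc$groups, sc$degTables, sc$expressed, sc$prior)
  ed <- mcdmEdges(mo)
  ann <- ligandInfo(sc$prior)
  secreted <- rownames(ann)[ann$location == "extracellular space"]
  expect_true(all(ed$sender_organ != ed$receiver_organ))
  expect_true(all(ed$ligand %in% secreted))

  # oracle: pooled unrestricted pairwise inference, then filter
  pooled <- buildMCDM(stats::setNames(sc$degTables, sc$groups$group),
                      stats::setNames(sc$expressed, sc$groups$group),
                      sc$prior, organ = "all")
  ped <- mcdmEdges(pooled)
  organ_of <- stats::setNames(sc$groups$organ, sc$groups$group)
  keep <- organ_of[ped$sender_cell] != organ_of[ped$receiver_cell] &
    ped$ligand %in% secreted
  oracle_keys <- sort(paste(ped$sender_cell, ped$ligand,
                            ped$receiver_cell)[keep])
  mo_keys <- sort(paste(paste(ed$sender_organ, ed$sender_cell, sep = ":"),
                        ed$ligand,
                        paste(ed$receiver_organ, ed$receiver_cell,
                              sep = ":")))
  expect_identical(mo_keys, oracle_keys)

  # all ligands non-secreted: empty MO-MCDM
  ann0 <- stats::setNames(rep("other", length(ligands(sc$prior))),
                          ligands(sc$prior))
  cls <- stats::setNames(ann$molecule_class, rownames(ann))
  prior0 <- LigandTargetPrior(as.matrix(potentials(sc$prior)), ann0, cls)
  mo0 <- buildMOMCDM(sc$groups, sc$degTables, sc$expressed, prior0)
  expect_equal(nrow(mcdmEdges(mo0)), 0)
})

test_that("rankURs orders by targets, then receivers, then id", {
  mk_edge <- function(ligand, recv, targets) {
    data.frame(sender_organ = "o1", sender_cell = "s", ligand = ligand,
               receiver_organ = "o1", receiver_cell = recv, pcc = 0.5,
               targets = I(list(targets)))
  }
  edges <- rbind(
    mk_edge("UR_a", "r1", paste0("g", 1:5)),
    mk_edge("UR_a", "r2", paste0("g", 1:4)),
    mk_edge("UR_a", "r3", paste0("g", 3:5)),
    mk_edge("UR_b", "r1", paste0("g", 1:6)),
    mk_edge("UR_b", "r2", paste0("g", 1:6)),
    mk_edge("UR_c", "r1", paste0("g", 1:5)))
  g <- MCDMGraph(data.frame(organ = "o1", cell_type = c("r1", "r2", "r3"),
                            n_cells = 1L), edges)
  rk <- rankURs(g)
  # UR_a: 5+4+3 = 12 targets / 3 receivers; UR_b: 12 / 2; UR_c: 5 / 1
  expect_identical(rk$ur, c("UR_a", "UR_b", "UR_c"))
  expect_identical(rk$n_targets, c(12L, 12L, 5L))
  expect_identical(rk$n_receivers, c(3L, 2L, 1L))

  # permuting edge order leaves the ranking unchanged
  g2 <- MCDMGraph(mcdmNodes(g), edges[sample(nrow(edges)), ])
  expect_identical(rankURs(g2), rk)

  # single UR ranks first; empty graph gives an empty table
  g1 <- MCDMGraph(mcdmNodes(g), edges[1, ])
  expect_equal(rankURs(g1)$rank, 1L)
  g0 <- MCDMGraph(mcdmNodes(g), edges[0, ])
  expect_equal(nrow(rankURs(g0)), 0)

  # recount oracle on a random synthetic graph
  sc <- plantedScenario(seed = 18)
  mo <- buildMOMCDM(sc$groups, sc$degTables, sc$expressed, sc$prior)
  rk2 <- rankURs(mo)
  ed <- mcdmEdges(mo)
  for (i in seq_len(nrow(rk2))) {
    u <- rk2$ur[i]
    sel <- ed$ligand == u
    recv <- paste(ed$receiver_organ, ed$receiver_cell)[sel]
    n_t <- sum(vapply(split(ed$targets[sel], recv),
                      function(x) length(unique(unlist(x))), integer(1)))
    expect_equal(rk2$n_targets[i], n_t)
    expect_equal(rk2$n_receivers[i], length(unique(recv)))
  }
})

test_that("edge invariants hold over a full synthetic run", {
  sc <- plantedScenario(seed = 19)
  mo <- buildMOMCDM(sc$groups, sc$degTables, sc$expressed, sc$prior)
  ed <- mcdmEdges(mo)
  expect_true(all(ed$pcc > 0))
  for (i in seq_len(nrow(ed))) {
    recv_group <- paste(ed$receiver_organ[i], ed$receiver_cell[i], sep = ":")
    tab <- sc$degTables[[recv_group]]
    degs <- tab$gene[tab$fdr < 0.05]
    w <- ligandWeights(sc$prior, ed$ligand[i])
    expect_true(all(ed$targets[[i]] %in% intersect(degs, names(w))))
  }
})

test_that("urTargetSeverity reproduces exact rank-sum and Holm behavior", {
  set.seed(20)
  m <- matrix(rnorm(50 * 16), 50, 16,
              dimnames = list(paste0("g", 1:50), paste0("c", 1:16)))
  tg <- paste0("g", 1:10)
  # two groups of 4 with completely separated scores: p = 2 / C(8,4)
  m2 <- m[, 1:8]
  m2[tg, 1:4] <- m2[tg, 1:4] + 10
  res <- urTargetSeverity(m2, tg, rep(c("severe", "healthy"), each = 4),
                          exact = TRUE)
  expect_equal(res$p, 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(res$p_adj, res$p)  # single test family

  # identical groups: p = 1 after adjustment
  m3 <- cbind(m[, 1:4], m[, 1:4])
  colnames(m3) <- paste0("c", 1:8)
  res3 <- urTargetSeverity(m3, tg, rep(c("a", "b"), each = 4), exact = FALSE)
  expect_equal(res3$p_adj, 1)

  # three groups: 3 pairwise tests with Holm's (3, 2, 1) scaling
  res4 <- urTargetSeverity(m[, 1:12], tg, rep(c("h", "m", "s"), each = 4))
  expect_equal(nrow(res4), 3)
  ord <- order(res4$p)
  expect_equal(res4$p_adj[ord][1], min(3 * res4$p[ord][1], 1))
  expect_true(all(diff(res4$p_adj[ord]) >= -1e-12))

  expect_error(urTargetSeverity(m, "not_measured", rep(c("a", "b"), 8)),
               "measured")
  expect_error(urTargetSeverity(m[, 1:4], tg, c("a", "a", "a", "b")),
               "2 groups")
})

test_that("prioritizeOrgans ranks by median bootstrap DEG count", {
  counts <- list(joint = c(100, 120, 110), lung = c(80, 70, 90),
                 muscle = c(60, 65, 55), skin = c(40, 45, 50),
                 spleen = c(30, 20, 25), kidney = c(0, 0, 0))
  res <- prioritizeOrgans(counts, n_keep = 5)
  expect_identical(res$organ,
                   c("joint", "lung", "muscle", "skin", "spleen"))
  expect_false("kidney" %in% res$organ)

  expect_warning(r1 <- prioritizeOrgans(counts["joint"], n_keep = 5),
                 "eligible")
  expect_identical(r1$organ, "joint")

  elig <- c(joint = TRUE, lung = FALSE, muscle = TRUE, skin = TRUE,
            spleen = TRUE, kidney = TRUE)
  r2 <- prioritizeOrgans(counts, n_keep = 5, eligible = elig)
  expect_false("lung" %in% r2$organ)

  # graded planted activity: the inactive organ misses the top 5 in >= 95%
  set.seed(23)
  hit <- replicate(100, {
    grades <- c(5, 4, 3, 2, 1, 0)
    cnt <- lapply(grades, function(g)
      rpois(10, lambda = 30 * g) + rpois(10, 5))
    names(cnt) <- paste0("org", 1:6)
    !"org6" %in% prioritizeOrgans(cnt, n_keep = 5)$organ
  })
  expect_gte(mean(hit), 0.95)
})
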