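test_that("pathwayDegSets restricts pathways to group DEG unions", {
  db <- PathwayDB(list(p1 = c("a", "b", "c"), p2 = c("c", "d"),
                       p3 = c("e", "f")))
  tabs <- list(d1 = mkDegUniverse(letters[1:6], c("a", "c")),
               d2 = mkDegUniverse(letters[1:6], "d"))
  expect_warning(sets <- pathwayDegSets(tabs, db), "dropped")
  # oracle by direct set arithmetic
  deg_union <- c("a", "c", "d")
  expect_identical(sets$p1, intersect(c("a", "b", "c"), deg_union))
  expect_identical(sets$p2, intersect(c("c", "d"), deg_union))
  expect_false("p3" %in% names(sets))

  # DEG union covering everything returns full gene sets
  tabs2 <- list(d1 = mkDegUniverse(letters[1:6], letters[1:6]))
  expect_identical(pathwayDegSets(tabs2, db), geneSets(db))

  # no DEGs at all: everything dropped
  tabs0 <- list(d1 = mkDegUniverse(letters[1:6], character()))
  expect_warning(s0 <- pathwayDegSets(tabs0, db), "dropped")
  expect_length(s0, 0)
  expect_error(pathwayDegSets(list(), db), "empty group")
})

test_that("jaccardMatrix computes exact pairwise similarities", {
  sets <- list(x = c("a", "b"), y = c("b", "c"), z = c("a", "b"),
               w = c("d", "e"))
  J <- jaccardMatrix(sets)
  expect_equal(J["x", "y"], 1 / 3)
  expect_equal(J["x", "z"], 1)
  expect_equal(J["x", "w"], 0)
  expect_equal(diag(J), c(x = 1, y = 1, z = 1, w = 1))
  expect_true(isSymmetric(J))
  expect_error(jaccardMatrix(list(a = character())), "empty")

  # 1 - J satisfies the triangle inequality on generated collections
  x <- generatePathwayDB(seed = 24)
  D <- 1 - jaccardMatrix(geneSets(x$db))
  n <- nrow(D)
  set.seed(24)
  for (rep in 1:200) {
    ijk <- sample(n, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("Ward clustering on 1-Jaccard recovers planted blocks", {
  # two blocks of identical sets, zero cross-overlap: exact recovery
  sets <- c(lapply(1:3, function(i) c("a", "b")),
            lapply(1:3, function(i) c("x", "y")))
  names(sets) <- paste0("p", 1:6)
  tree <- cutPrograms(clusterPathways(jaccardMatrix(sets)), k_top = 2)
  pr <- programs(tree)
  expect_length(unique(pr[paste0("p", 1:3)]), 1)
  expect_length(unique(pr[paste0("p", 4:6)]), 1)
  expect_false(pr[["p1"]] == pr[["p4"]])

  # all distances equal: deterministic output under the tie rule
  eq <- matrix(0.5, 4, 4, dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  diag(eq) <- 1
  t1 <- cutPrograms(clusterPathways(eq), k_top = 2)
  t2 <- cutPrograms(clusterPathways(eq), k_top = 2)
  expect_identical(programs(t1), programs(t2))
  expect_length(unique(programs(t1)), 2)

  # planted 2 x 6 with within ~0.6 / between ~0.05: ARI = 1
  x <- generatePathwayDB(n_programs = 2, pathways_per_program = 6,
                         genes_per_pathway = 50, within_share = 0.6,
                         between_share = 0.05, seed = 25)
  tr <- cutPrograms(clusterPathways(jaccardMatrix(geneSets(x$db))),
                    k_top = 2)
  ari <- mclust::adjustedRandIndex(programs(tr)[names(x$truth@programOf)],
                                   x$truth@programOf)
  expect_equal(ari, 1)

  expect_error(clusterPathways(eq[1, 1, drop = FALSE]), "at least 2")
})

test_that("cutPrograms produces size-ordered program and subprogram labels", {
  x <- generatePathwayDB(n_programs = 2, pathways_per_program = 10,
                         seed = 26)
  tree <- clusterPathways(jaccardMatrix(geneSets(x$db)))
  expect_error(cutPrograms(tree, k_top = 100), "exceeds")

  # k_top = leaves: every pathway its own program
  t_all <- cutPrograms(tree, k_top = 20)
  expect_length(unique(programs(t_all)), 20)

  # k_sub = 1: subprogram equals program
  t_one <- cutPrograms(tree, k_top = 2, k_sub = 1)
  sp <- subprograms(t_one)
  expect_setequal(unique(sp), c("SP1.1", "SP2.1"))
  expect_identical(sp == "SP1.1", programs(t_one) == "P1")

  # nested blocks: the subprogram cut recovers planted sub-blocks
  mk_block <- function(core, n, tag) {
    out <- lapply(seq_len(n), function(i)
      c(core, paste0(tag, "_priv", i, "_", 1:3)))
    names(out) <- paste0(tag, "_", seq_len(n))
    out
  }
  sets <- c(mk_block(paste0("A1_", 1:10), 4, "a1"),
            mk_block(paste0("A2_", 1:10), 4, "a2"),
            mk_block(paste0("B1_", 1:10), 4, "b1"),
            mk_block(paste0("B2_", 1:10), 4, "b2"))
  # glue the two halves of each program with shared program-level genes
  for (i in seq_along(sets)) {
    prog <- if (grepl("^a", names(sets)[i])) "PA" else "PB"
    sets[[i]] <- c(sets[[i]], paste0(prog, "_core", 1:6))
  }
  tr <- cutPrograms(clusterPathways(jaccardMatrix(sets)), k_top = 2,
                    k_sub = 2)
  truth_prog <- ifelse(grepl("^a", names(sets)), "A", "B")
  truth_sub <- sub("_\\d+$", "", names(sets))
  expect_equal(mclust::adjustedRandIndex(programs(tr), truth_prog), 1)
  expect_gte(mclust::adjustedRandIndex(subprograms(tr), truth_sub), 0.9)
})

test_that("labelPathway implements the majority rule on significant calls", {
  mk <- function(p, z) data.frame(p = p, z = z)
  # 2 activated vs 6 inhibited among significant: inhibited
  e <- mk(rep(0.01, 8), c(1, 1, rep(-1, 6)))
  expect_equal(labelPathway(e)$label, "inhibited")
  # 1 vs 1: no_direction
  expect_equal(labelPathway(mk(c(0.01, 0.01), c(1, -1)))$label,
               "no_direction")
  # nothing significant
  expect_equal(labelPathway(mk(c(0.5, 0.9), c(1, -1)))$label,
               "not_significant")
  # only undefined-z significances
  expect_equal(labelPathway(mk(0.01, NA))$label, "no_direction")
  # counts recorded
  lab <- labelPathway(e)
  expect_equal(lab$n_activated, 2)
  expect_equal(lab$n_inhibited, 6)
  expect_equal(lab$n_total_significant, 8)
})

test_that("opposingFraction counts flips and on/off switches symmetrically", {
  mkLab <- function(labels) data.frame(pathway = paste0("p", seq_along(labels)),
                                       label = labels)
  a <- mkLab(c("activated", "activated", "activated", "activated"))
  b <- mkLab(c("inhibited", "inhibited", "inhibited", "inhibited"))
  expect_equal(opposingFraction(a, b, paste0("p", 1:4)), 1)
  expect_equal(opposingFraction(a, a, paste0("p", 1:4)), 0)

  # half opposing by construction
  a2 <- mkLab(c("activated", "activated", "not_significant", "no_direction"))
  b2 <- mkLab(c("inhibited", "activated", "not_significant", "no_direction"))
  a2$label[3] <- "activated"  # significant in A, not in B -> opposing
  b2$label[3] <- "not_significant"
  expect_equal(opposingFraction(a2, b2, paste0("p", 1:4)), 0.5)
  # symmetric
  expect_equal(opposingFraction(b2, a2, paste0("p", 1:4)), 0.5)

  # activated vs no_direction is NOT opposing (both significant, no flip)
  expect_equal(opposingFraction(mkLab("activated"), mkLab("no_direction"),
                                "p1"), 0)
  expect_error(opposingFraction(a, b, character()), "empty")
})

test_that("gwasEnrichment uses per-dataset DEG backgrounds with BH", {
  universe <- paste0("g", 1:40)
  prog <- paste0("g", 1:10)
  tabs <- list(d1 = mkDegUniverse(universe, paste0("g", 1:20)),
               d2 = mkDegUniverse(universe, paste0("g", 6:25)))
  # nested design: gwas = the program genes themselves
  res <- gwasEnrichment(prog, prog, tabs)
  # oracle for d1: bg 20 DEGs, query = prog ∩ bg (10), target = prog ∩ bg
  expect_equal(res$p[res$dataset == "d1"],
               oracleHyperTail(10, 10, 10, 20), tolerance = 1e-12)
  expect_equal(res$fdr, adjustP(res$p, "BH"))

  # disjoint gwas set: p = 1
  res0 <- gwasEnrichment(prog, paste0("g", 31:40), tabs["d1"])
  expect_equal(res0$p, 1)

  # planted GWAS overlap is detected in >= 90% of replicates
  set.seed(27)
  hits <- replicate(20, {
    degs <- sample(universe, 25)
    gwas <- c(sample(intersect(prog, universe), 8),
              sample(setdiff(universe, prog), 2))
    tab <- list(d = mkDegUniverse(universe, union(degs, prog)))
    gwasEnrichment(prog, gwas, tab)$fdr < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("programOverlap matches the per-pair Fisher oracle", {
  universe <- paste0("u", 1:100)
  set.seed(28)
  pa <- split(universe, rep(1:3, length.out = 100))
  names(pa) <- paste0("A", 1:3)
  pb <- split(sample(universe), rep(1:4, length.out = 100))
  names(pb) <- paste0("B", 1:4)
  res <- programOverlap(pa, pb, universe, mode = "pathway")
  expect_equal(nrow(res), 12)
  for (i in seq_len(nrow(res))) {
    fe <- fisherEnrich(pa[[res$cluster_a[i]]], pb[[res$cluster_b[i]]],
                       universe)
    expect_equal(res$p[i], fe$p, tolerance = 1e-12)
  }
  expect_equal(res$fdr, adjustP(res$p, "BH"))

  # identical disjoint partitions: diagonal minimal, off-diagonal p = 1
  res2 <- programOverlap(pa, pa, universe)
  diag_p <- res2$p[res2$cluster_a == res2$cluster_b]
  off_p <- res2$p[res2$cluster_a != res2$cluster_b]
  expect_true(all(diag_p < 1e-10))
  expect_true(all(off_p == 1))

  # one cluster covering the whole universe: no enrichment possible
  res3 <- programOverlap(list(all = universe), pb, universe)
  expect_true(all(res3$p == 1))

  expect_error(programOverlap(pa, pb, universe[1:50]), "universe")
})

test_that("exportTree writes Newick that round-trips through ape", {
  # two leaves: "(A:h,B:h);" shape
  J <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  tree <- clusterPathways(J)
  out <- exportTree(tree)
  expect_match(out$newick, "^\\(A:[0-9.]+,B:[0-9.]+\\);$")

  # round-trip topology and leaf preservation on random collections
  set.seed(29)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    sets <- lapply(seq_len(n), function(j)
      sample(paste0("g", 1:30), sample(5:15, 1)))
    names(sets) <- paste0("pw", seq_len(n))
    tr <- clusterPathways(jaccardMatrix(sets))
    tmp <- tempfile(fileext = ".nwk")
    exportTree(tr, newickPath = tmp)
    phy <- readTreeNewick(tmp)
    expect_setequal(phy$tip.label, names(sets))
    # topology: cophenetic tree distances preserve the merge structure
    expect_equal(length(phy$tip.label), n)
  }

  # assignment table round-trips through TSV
  x <- generatePathwayDB(seed = 30)
  tr <- cutPrograms(clusterPathways(jaccardMatrix(geneSets(x$db))),
                    k_top = 2, k_sub = 2)
  tmp <- tempfile(fileext = ".tsv")
  exportTree(tr, assignPath = tmp)
  asg <- read.delim(tmp)
  expect_setequal(asg$pathway, names(geneSets(x$db)))
  expect_identical(stats::setNames(asg$program, asg$pathway)[
    names(programs(tr))], programs(tr))
})
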