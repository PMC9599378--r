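# small planted-marker fixture: 2 clusters x 30 cells, each with 3 markers
planted_sce <- function(seed = 11, fold = 6) {
  set.seed(seed)
  genes <- c(paste0("mA", 1:3), paste0("mB", 1:3), paste0("bg", 1:4))
  cells <- paste0("c", 1:60)
  m <- matrix(abs(rnorm(10 * 60, sd = 0.3)), 10, 60,
              dimnames = list(genes, cells))
  m[1:3, 1:30] <- m[1:3, 1:30] + fold
  m[4:6, 31:60] <- m[4:6, 31:60] + fold
  make_log_sce(m)
}
planted_db <- MarkerDB(list(Atype = paste0("mA", 1:3),
                            Btype = paste0("mB", 1:3)))

test_that("oversample pads with replacement and keeps all originals", {
  cl <- paste0("c", 1:10)
  expect_identical(oversample(cl, 10, seed = 1), cl)

  out <- oversample(paste0("x", 1:3), 9, seed = 2)
  expect_length(out, 9)
  expect_true(all(table(out) >= 1))
  expect_setequal(unique(out), paste0("x", 1:3))

  expect_identical(oversample(paste0("x", 1:3), 9, seed = 2),
                   oversample(paste0("x", 1:3), 9, seed = 2))
  expect_error(oversample(character(), 5))
})

test_that("prefilterGenes keeps strictly up-regulated genes only", {
  m <- matrix(c(2, 1, 2, 1,     # up in cluster {c1,c2}
                0.1, 1, 0.1, 1, # down
                1, 1, 1, 1),    # flat: strict > removes it
              nrow = 3, byrow = TRUE,
              dimnames = list(c("up", "down", "flat"), paste0("c", 1:4)))
  m2 <- m[, c(1, 3, 2, 4)]  # cluster cells not contiguous
  sce <- make_log_sce(m2)
  expect_identical(prefilterGenes(sce, c("c1", "c3")), "up")
})

test_that("prefilter agrees with direct mean recomputation on planted data", {
  sce <- planted_sce()
  m <- SummarizedExperiment::assay(sce, "logcounts")
  cluster <- paste0("c", 1:30)
  kept <- prefilterGenes(sce, cluster)
  for (g in rownames(m)) {
    inM <- mean(m[g, cluster])
    outM <- mean(m[g, setdiff(colnames(m), cluster)])
    expect_identical(g %in% kept, inM > outM)
  }
  expect_true(all(paste0("mA", 1:3) %in% kept))
})

test_that("a perfectly separating gene dominates the importance vector", {
  set.seed(21)
  genes <- c("sep", paste0("noise", 1:9))
  cells <- paste0("c", 1:80)
  m <- matrix(abs(rnorm(10 * 80, sd = 1)), 10, 80,
              dimnames = list(genes, cells))
  m["sep", 1:40] <- 5
  m["sep", 41:80] <- 0
  sce <- make_log_sce(m)
  w <- featureImportance(sce, cells[1:40], cells[41:80], genes, seed = 3)
  expect_true(all(w >= 0))
  expect_identical(names(which.max(w)), "sep")
  expect_gt(w["sep"], sum(w) * 0.9)

  # determinism
  w2 <- featureImportance(sce, cells[1:40], cells[41:80], genes, seed = 3)
  expect_identical(w, w2)
})

test_that("constant genes receive zero importance", {
  m <- matrix(1, 3, 20, dimnames = list(paste0("g", 1:3), paste0("c", 1:20)))
  sce <- make_log_sce(m)
  w <- featureImportance(sce, paste0("c", 1:10), paste0("c", 11:20),
                         rownames(m), seed = 1)
  expect_identical(unname(w), rep(0, 3))
})

test_that("reported importances carry the booster's full gain mass", {
  # the raw total-gain vector, renormalized, must match the tool's own
  # normalized gain importance (self-consistency of the accessor)
  set.seed(22)
  genes <- paste0("g", 1:6)
  cells <- paste0("c", 1:60)
  m <- matrix(abs(rnorm(6 * 60)), 6, 60, dimnames = list(genes, cells))
  m[1, 1:30] <- m[1, 1:30] + 2
  m[2, 1:30] <- m[2, 1:30] + 1
  sce <- make_log_sce(m)
  tgt <- cells[1:30]; adv <- cells[31:60]
  w <- featureImportance(sce, tgt, adv, genes, seed = 4)

  X <- t(m[, c(tgt, adv)])
  y <- rep(1:0, each = 30)
  bst <- xgboost::xgb.train(
    params = list(max_depth = 1, objective = "binary:hinge", eta = 0.3,
                  nthread = 1, seed = 4),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1), nrounds = 100,
    verbose = 0)
  imp <- xgboost::xgb.importance(model = bst)
  ref <- stats::setNames(imp$Gain, imp$Feature)
  got <- w[w > 0] / sum(w)
  expect_equal(sort(got), sort(ref[names(got)]), tolerance = 1e-6)
})

test_that("scoreCellTypes sums marker importances and breaks ties", {
  db <- MarkerDB(list(A = "g1", B = c("g2", "g3")))
  tab <- scoreCellTypes(c(g1 = 0.6, g2 = 0.4), db, clusterId = "P1")
  expect_equal(tab$score[tab$cell_type == "A"], 0.6)
  expect_equal(tab$score[tab$cell_type == "B"], 0.4)
  expect_identical(attr(tab, "winner"), "A")
  expect_equal(attr(tab, "margin"), 0.2)

  # all-zero importances: unassigned
  tab0 <- scoreCellTypes(c(g1 = 0, g2 = 0), db)
  expect_identical(attr(tab0, "winner"), "unassigned")
  expect_false(any(tab0$winner))

  # shared gene counts for both types; tie goes to lexicographic smallest
  db2 <- MarkerDB(list(B = "shared", A = "shared"))
  tabs <- suppressMessages(scoreCellTypes(c(shared = 1), db2))
  expect_equal(tabs$score, c(1, 1))
  expect_identical(attr(tabs, "winner"), "A")
})

test_that("Score_t is additive under splitting a marker set", {
  set.seed(23)
  w <- stats::setNames(runif(6), paste0("g", 1:6))
  whole <- MarkerDB(list(T1 = paste0("g", 1:4), T2 = paste0("g", 5:6)))
  split_db <- MarkerDB(list(T1a = paste0("g", 1:2), T1b = paste0("g", 3:4),
                            T2 = paste0("g", 5:6)))
  s_whole <- scoreCellTypes(w, whole)
  s_split <- scoreCellTypes(w, split_db)
  expect_equal(s_whole$score[s_whole$cell_type == "T1"],
               sum(s_split$score[s_split$cell_type %in% c("T1a", "T1b")]))
})

test_that("representative clusters get their true planted types", {
  sce <- planted_sce()
  reps <- new("RepresentativeClusters",
              clusters = list(P1 = paste0("c", 1:30),
                              P2 = paste0("c", 31:60)),
              leftover = character(), threshold = 10L)
  ann <- annotateRepresentativeClusters(sce, reps, planted_db, seed = 6)
  expect_identical(unname(ann$clusterLabels), c("Atype", "Btype"))
  expect_identical(unname(ann$labels[paste0("c", 1:30)]), rep("Atype", 30))
  expect_identical(unname(ann$labels[paste0("c", 31:60)]), rep("Btype", 30))
  expect_identical(nrow(ann$scoreTable), 4L)  # 2 clusters x 2 types
})

test_that("a cluster with no up-regulated gene is unassigned", {
  set.seed(24)
  m <- matrix(abs(rnorm(6 * 40, sd = 0.2)), 6, 40,
              dimnames = list(c(paste0("mA", 1:3), paste0("bg", 1:3)),
                              paste0("c", 1:40)))
  m[1:3, 21:40] <- m[1:3, 21:40] + 5   # markers high OUTSIDE cluster P1
  m[, 1:20] <- 0.01                    # P1 flat and low everywhere
  sce <- make_log_sce(m)
  reps <- new("RepresentativeClusters",
              clusters = list(P1 = paste0("c", 1:20)),
              leftover = paste0("c", 21:40), threshold = 10L)
  db <- MarkerDB(list(Atype = paste0("mA", 1:3), Btype = "bg1"))
  expect_warning(
    ann <- annotateRepresentativeClusters(sce, reps, db, seed = 1),
    "unassigned")
  expect_identical(unname(ann$clusterLabels), "unassigned")
})

test_that("raising a type's marker fold change never flips its cluster away", {
  for (fold in c(3, 6, 12)) {
    sce <- planted_sce(seed = 11, fold = fold)
    reps <- new("RepresentativeClusters",
                clusters = list(P1 = paste0("c", 1:30)),
                leftover = paste0("c", 31:60), threshold = 10L)
    ann <- annotateRepresentativeClusters(sce, reps, planted_db, seed = 6)
    expect_identical(unname(ann$clusterLabels), "Atype")
  }
})
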