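test_that("the five-sequence toy tally matches hand enumeration", {
  truth <- makeDb(
    stats::setNames(replicate(5, randomSeq(40)),
                    c("t1", "t2", "t3", "t4", "t5")),
    list(fullLineage(genus = "g1"), fullLineage(genus = "g2"),
         fullLineage(genus = "g3"), fullLineage(genus = "x1"),
         fullLineage(genus = "x2")))
  pred <- makePredictions(c("t1", "t2", "t3", "t4", "t5"),
                          c("g1", "g9", NA, "g1", NA))
  trainingNames <- c("g1", "g2", "g3", "g7")
  t <- tallyRank(truth, pred, trainingNames, "genus")
  expect_equal(t[c("N", "K", "L", "TP", "MC", "OC", "UC")],
               list(N = 5L, K = 3L, L = 2L, TP = 1L, MC = 1L, OC = 1L,
                    UC = 1L))
  # conservation: TP + MC + UC = K
  expect_equal(t$TP + t$MC + t$UC, t$K)
  # rates with the rule of 10 disabled
  m <- metricsFromTally(t, minDenominator = 1)
  expect_equal(unname(m["TPR"]), 100 / 3, tolerance = 1e-12)
  expect_equal(unname(m["UCR"]), 100 / 3, tolerance = 1e-12)
  expect_equal(unname(m["MCR"]), 100 / 3, tolerance = 1e-12)
  expect_equal(unname(m["OCR"]), 50)
  expect_equal(unname(m["Acc"]), 25)     # TP / (K + OC) = 1/4
  expect_equal(unname(m["AccRDP"]), 20)  # TP / N = 1/5
  # under the rule of 10 all denominators (3, 3, 4, 5) are unreported
  m10 <- metricsFromTally(t)
  expect_true(all(is.na(m10[c("TPR", "UCR", "MCR", "OCR", "Acc",
                              "AccRDP")])))
})

test_that("all-correct predictions give TP = K = N and zero error rates", {
  ids <- sprintf("t%02d", 1:12)
  genera <- sprintf("g%d", rep(1:4, 3))
  truth <- makeDb(stats::setNames(replicate(12, randomSeq(40)), ids),
                  lapply(genera, function(g) fullLineage(genus = g)))
  pred <- makePredictions(ids, genera)
  t <- tallyRank(truth, pred, unique(genera), "genus")
  expect_equal(t$TP, 12L)
  expect_equal(t$K, t$N)
  m <- metricsFromTally(t)
  expect_equal(unname(m[c("TPR", "UCR", "MCR")]), c(100, 0, 0))
  expect_true(is.na(m["OCR"]))   # L = 0: undefined regardless of the rule
})

test_that("truth records unannotated at the rank are excluded from N", {
  lin <- fullLineage()
  lin["species"] <- NA
  lin2 <- fullLineage(genus = "g2", species = "s2")
  truth <- makeDb(c(t1 = randomSeq(40), t2 = randomSeq(40)),
                  list(lin, lin2))
  pred <- makePredictions(c("t1", "t2"), c("g1", "g2"))
  t <- tallyRank(truth, pred, c("s1", "s2"), "species")
  expect_equal(t$N, 1L)
  expect_error(tallyRank(truth, makePredictions("t1", "g1"),
                         c("s1"), "species"), "missing prediction")
})

test_that("fully predicted queries give UC = 0, OC = L and Acc = AccRDP", {
  ids <- sprintf("t%02d", 1:15)
  genera <- c(sprintf("g%d", rep(1:3, 4)), "n1", "n2", "n3")
  truth <- makeDb(stats::setNames(replicate(15, randomSeq(40)), ids),
                  lapply(genera, function(g) fullLineage(genus = g)))
  predNames <- ifelse(genera %in% c("g1", "n1"), "g1", "g2")
  pred <- makePredictions(ids, predNames)
  t <- tallyRank(truth, pred, paste0("g", 1:3), "genus")
  expect_equal(t$UC, 0L)
  expect_equal(t$OC, t$L)
  m <- metricsFromTally(t, minDenominator = 1)
  expect_equal(unname(m["Acc"]), unname(m["AccRDP"]))
  # AccRDP never exceeds K/N
  expect_lte(m[["AccRDP"]], 100 * t$K / t$N)
})

test_that("averaging skips unreported rows and counts contributors", {
  rows <- data.frame(d = c(100, 99), Acc = c(100, 50),
                     OCR = c(NA, 100), TPR = c(100, 100),
                     UCR = c(0, 0), MCR = c(0, 0), AccRDP = c(100, 50))
  a <- averageOverIdentities(rows)
  expect_equal(a$mean[a$metric == "Acc"], 75)
  expect_equal(a$mean[a$metric == "OCR"], 100)
  expect_equal(a$nIdentities[a$metric == "OCR"], 1L)
  expect_equal(a$nIdentities[a$metric == "Acc"], 2L)
  # identical rows average to themselves
  same <- data.frame(d = c(99, 97, 95), TPR = 80, UCR = 5, MCR = 15,
                     OCR = 100, Acc = 40, AccRDP = 40)
  aSame <- averageOverIdentities(same)
  expect_equal(aSame$mean[aSame$metric == "TPR"], 80)
  # all-NA metric stays NA with zero contributors
  allNA <- data.frame(d = 1, TPR = NA_real_, UCR = NA_real_,
                      MCR = NA_real_, OCR = NA_real_, Acc = NA_real_,
                      AccRDP = NA_real_)
  aNA <- averageOverIdentities(allNA)
  expect_true(all(is.na(aNA$mean)))
  expect_true(all(aNA$nIdentities == 0))
})

test_that("evaluateSplit at d = 100 gives perfect scores for top-hit", {
  db <- sharedDb()
  sp <- buildCviSplit(db, 100)
  rows <- evaluateSplit(db, sp, "top", idMat = sharedIdMat())
  g <- rows[rows$rank == "genus", ]
  expect_equal(g$TPR, 100)
  expect_equal(g$UCR, 0)
  expect_equal(g$TP, g$K)
  # conservation at every rank
  expect_equal(rows$TP + rows$MC + rows$UC, rows$K)
})

test_that("raising the bootstrap cutoff never increases OC or decreases UC", {
  db <- sharedDb()
  im <- sharedIdMat()
  sp <- buildCviSplit(db, 95, seed = 2, idMat = im)
  expect_gt(length(sp@S), 0)
  test <- db[sp@S]
  training <- db[trainingIds(sp)]
  pred <- sintaxClassify(test, training, cutoff = 0, seed = 2)
  namesByRank <- taxcvi:::.trainingNamesByRank(training)
  prev <- NULL
  for (cut in c(0, 0.5, 0.8)) {
    pred@cutoff <- cut
    t <- tallyRank(test, pred, namesByRank$genus, "genus")
    if (!is.null(prev)) {
      expect_lte(t$OC, prev$OC)
      expect_gte(t$UC, prev$UC)
    }
    prev <- t
  }
})

test_that("leave-one-out scores singletons as novel and writes sane rates", {
  db <- sharedDb()[1:24]
  rows <- l1oBenchmark(db, "top", minDenominator = 1)
  g <- rows[rows$rank == "genus", ]
  # top-hit never under-classifies when a hit exists
  expect_equal(g$UC, 0L)
  expect_equal(g$N, 24L)
  expect_equal(g$TP + g$MC + g$UC, g$K)
  sTab <- table(as.data.frame(taxTable(db))$species)
  expect_equal(rows[rows$rank == "species", "L"],
               sum(sTab[as.data.frame(taxTable(db))$species] == 1))
})

test_that("metric reports write and re-read as tab-separated text", {
  db <- sharedDb()
  rep <- suppressWarnings(
    cviBenchmark(db, "top", specs = data.frame(d = c(100, 95),
                                               delta = c(0, 0.5)),
                 seed = 2, idMat = sharedIdMat()))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeMetricsReport(rep, path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  expect_true(all(c("rank", "d", "TPR", "AccRDP") %in% colnames(tab)))
  expect_true(any(tab$d == "Avg"))
  g100 <- tab[tab$rank == "genus" & tab$d == "100", ]
  expect_equal(as.numeric(g100$TPR), 100)
})
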