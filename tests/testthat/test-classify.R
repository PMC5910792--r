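test_that("top-hit classification copies the winning full lineage", {
  set.seed(50)
  s <- randomSeq(100)
  db <- makeDb(
    c(r1 = s, r2 = plantMut(s, 1:5), r3 = randomSeq(100)),
    list(fullLineage(genus = "gA", species = "sA"),
         fullLineage(genus = "gB", species = "sB"),
         fullLineage(genus = "gC", species = "sC", family = "f2")))
  q <- makeDb(c(q1 = s), list(fullLineage(genus = "gA", species = "sA")))
  pred <- topClassify(q, db)
  names <- predictedTaxa(pred)
  expect_equal(unname(names[1, "species"]), "sA")
  expect_false(any(is.na(names[1, ])))        # never a partial lineage
  expect_true(all(pred@confidence[1, ] == 1))
  # a query whose genus is absent still receives a lineage
  # (over-classification by construction)
  qNovel <- makeDb(c(qx = plantMut(s, 20:23)),
                   list(fullLineage(genus = "gNovel", species = "sNovel")))
  predN <- topClassify(qNovel, db)
  expect_false(any(is.na(predictedTaxa(predN)[1, ])))
  # equal-identity tie resolves to the earlier record
  db2 <- makeDb(c(t1 = plantMut(s, 1), t2 = plantMut(s, 2)),
                list(fullLineage(genus = "g1"), fullLineage(genus = "g2")))
  predT <- topClassify(q, db2)
  expect_equal(unname(predictedTaxa(predT)[1, "genus"]), "g1")
  # masking the only record gives an empty prediction
  predE <- topClassify(makeDb(c(r1 = s), list(fullLineage())), db["r1"],
                       excludeSelf = TRUE)
  expect_true(all(is.na(predictedTaxa(predE))))
})

test_that("NBC training computes add-half document frequencies", {
  set.seed(51)
  sA <- randomSeq(60)
  db1 <- makeDb(c(r1 = sA), list(fullLineage(genus = "gA")))
  m1 <- trainNbc(db1)
  expect_equal(m1@genera, "gA")
  # words of the single training sequence: P = (1 + .5)/(1 + 1)
  expect_equal(unname(exp(m1@logProb[1, "gA"])), 0.75)
  # unseen word: P = 0.5/(N_g + 1)
  expect_equal(unname(exp(m1@logP0)), 0.25)
  # two genera with disjoint words: foreign words get the unseen smoothing
  sB <- randomSeq(60)
  db2 <- makeDb(c(r1 = sA, r2 = sB),
                list(fullLineage(genus = "gA"),
                     fullLineage(genus = "gB", species = "s2")))
  m2 <- trainNbc(db2)
  wA <- taxcvi:::cpp_kmer_codes(sA, 8L)[[1]]
  wB <- taxcvi:::cpp_kmer_codes(sB, 8L)[[1]]
  onlyA <- setdiff(wA, wB)
  i <- match(onlyA[1], m2@vocab)
  expect_equal(unname(exp(m2@logProb[i, "gA"])), 1.5 / 2)
  expect_equal(unname(exp(m2@logProb[i, "gB"])), 0.5 / 2)
  # retraining is deterministic
  expect_equal(trainNbc(db2)@logProb, m2@logProb)
  # missing genus errors with the record named
  dbBad <- TaxRefDB(c(rX = "ACGTACGTACGT"),
                    data.frame(domain = "d1", phylum = "p1", class = "c1",
                               order = "o1", family = "f1",
                               genus = NA_character_,
                               species = NA_character_))
  expect_error(trainNbc(dbBad), "rX")
  # conflicting lineages for one genus name are rejected
  dbConf <- makeDb(c(a = sA, b = sB),
                   list(fullLineage(genus = "gA", family = "f1"),
                        fullLineage(genus = "gA", family = "f2")))
  expect_error(trainNbc(dbConf), "more than one lineage")
})

test_that("NBC bootstrap confidence separates well-resolved genera", {
  set.seed(52)
  base <- randomSeq(300)
  other <- plantMut(base, sample(300, 45))   # ~85% identity genus pair
  db <- makeDb(
    c(a1 = base, a2 = plantMut(base, 1:3), b1 = other,
      b2 = plantMut(other, 5:7)),
    list(fullLineage(genus = "gA", species = "sA1"),
         fullLineage(genus = "gA", species = "sA2"),
         fullLineage(genus = "gB", species = "sB1"),
         fullLineage(genus = "gB", species = "sB2")))
  model <- trainNbc(db)
  q <- makeDb(c(q1 = plantMut(base, c(20, 120, 220))),
              list(fullLineage(genus = "gA")))
  hits <- 0
  for (seed in 1:20) {
    pred <- nbcClassify(q, model, cutoff = 0.8, seed = seed)
    names <- predictedTaxa(pred)
    if (!is.na(names[1, "genus"]) && names[1, "genus"] == "gA" &&
        pred@confidence[1, "genus"] >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, 19)   # >= 95% of seeds
  # single-genus model: that genus with confidence 1 at all ranks
  m1 <- trainNbc(db[c("a1", "a2")])
  p1 <- nbcClassify(q, m1, cutoff = 0.8, seed = 1)
  expect_equal(unname(predictedTaxa(p1)[1, "genus"]), "gA")
  # confidence 1 at every predictable (genus-level) rank
  expect_true(all(p1@confidence[1, 1:6] == 1))
  expect_true(is.na(p1@confidence[1, "species"]))
  # bit-reproducible given (seed, nBoot), regardless of query order
  q2 <- makeDb(c(q1 = plantMut(base, c(20, 120, 220)),
                 q0 = plantMut(other, 10)),
               list(fullLineage(genus = "gA"), fullLineage(genus = "gB")))
  pA <- nbcClassify(q2, model, cutoff = 0, seed = 9)
  pB <- nbcClassify(q2[c(2, 1)], model, cutoff = 0, seed = 9)
  expect_equal(pA@confidence[1, ], pB@confidence[2, ])
})

test_that("sintax votes truncate ambiguous queries at the shared rank", {
  set.seed(53)
  sA <- randomSeq(200)
  sB <- randomSeq(200)
  db <- makeDb(c(a = sA, b = sB),
               list(fullLineage(genus = "gA", species = "sppA"),
                    fullLineage(genus = "gB", species = "sppB")))
  # chimera sharing about half its words with each genus
  q <- makeDb(c(q1 = paste0(substr(sA, 1, 100), substr(sB, 101, 200))),
              list(fullLineage()))
  pred <- sintaxClassify(q, db, cutoff = 0.8, seed = 4)
  conf <- pred@confidence[1, ]
  expect_lt(conf[["genus"]], 0.8)
  expect_equal(conf[["family"]], 1)   # both genera share the family
  names <- predictedTaxa(pred)
  expect_equal(unname(names[1, "family"]), "f1")
  expect_true(is.na(names[1, "genus"]))   # truncated at family
  # own record in the database: own lineage at confidence 1
  predSelf <- sintaxClassify(db[1], db, cutoff = 0.8, seed = 4)
  expect_equal(unname(predictedTaxa(predSelf)[1, "species"]), "sppA")
  expect_true(all(predSelf@confidence[1, ] == 1))
  # cutoff 0 reports the full candidate lineage
  pred0 <- sintaxClassify(q, db, cutoff = 0, seed = 4)
  expect_false(any(is.na(predictedTaxa(pred0)[1, ])))
  # reproducible for the same seed
  predR <- sintaxClassify(q, db, cutoff = 0.8, seed = 4)
  expect_identical(pred@confidence, predR@confidence)
})

test_that("predictions are gapless prefixes, monotone in the cutoff", {
  set.seed(54)
  db <- sharedDb()[1:30]
  q <- sharedDb()[31:40]
  for (pred in list(sintaxClassify(q, db, cutoff = 0.5, seed = 2),
                    nbcClassify(q, trainNbc(db), cutoff = 0.5, seed = 2))) {
    for (cut in c(0, 0.3, 0.6, 0.9)) {
      names <- predictedTaxa(pred, cutoff = cut)
      named <- !is.na(names)
      if (ncol(named) > 1)
        for (j in 2:ncol(named))
          expect_true(all(named[, j] <= named[, j - 1]),
                      label = sprintf("gapless prefix at cutoff %.1f", cut))
    }
    n0 <- rowSums(!is.na(predictedTaxa(pred, cutoff = 0)))
    n9 <- rowSums(!is.na(predictedTaxa(pred, cutoff = 0.9)))
    expect_true(all(n9 <= n0))   # raising the cutoff never adds ranks
  }
})
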