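test_that("planted reference reproduces the 0/2/6-of-8 pair example at 90%", {
  db <- plantedLcrDb()
  tab <- suppressWarnings(lcrTable(db))
  expect_true(90L %in% identities(tab))
  i <- match(90L, identities(tab))
  expect_equal(unname(pairTotals(tab)[i]), 8L)
  expect_equal(unname(lcrCounts(tab)[i, c("species", "genus", "family")]),
               c(0L, 2L, 6L))
  expect_equal(unname(lcrProb(tab)[i, "genus"]), 2 / 8)
  expect_equal(unname(lcrProb(tab)[i, "family"]), 6 / 8)
  # Eq-2 cumulation: P_CR(genus|90) = P(species) + P(genus)
  expect_equal(commonRankProb(tab, "genus", 90), 0.25)
  expect_equal(commonRankProb(tab, "species", 90), 0)
  # all pairs share the family, so P_CR is 1 from family upward
  expect_equal(commonRankProb(tab, "family", 90), 1)
  expect_equal(commonRankProb(tab, "domain", 90), 1)
  expect_equal(mlr(tab, 90), "family")
})

test_that("lcrTable equals a brute-force per-pair oracle", {
  set.seed(31)
  base <- randomSeq(120)
  db <- makeDb(
    c(a1 = base, a2 = plantMut(base, 1:2), b1 = plantMut(base, 10:17),
      c1 = plantMut(base, 30:49), d1 = plantMut(base, 60:99)),
    list(fullLineage(genus = "g1", species = "s1"),
         fullLineage(genus = "g1", species = "s1"),
         fullLineage(genus = "g1", species = "s2"),
         fullLineage(genus = "g2", species = "s3"),
         fullLineage(genus = "g3", species = "s4", family = "f2")))
  tab <- suppressWarnings(lcrTable(db))
  # oracle: loop over the 10 pairs with the scalar primitives
  ranks <- defaultRankOrder()
  counts <- list()
  ids <- refIds(db)
  for (i in 1:4) for (j in (i + 1):5) {
    d <- pairwiseIdentity(as.character(refSeqs(db))[i],
                          as.character(refSeqs(db))[j])$identityInt
    r <- lcr(taxonomyOf(db, i), taxonomyOf(db, j))
    key <- as.character(d)
    if (is.null(counts[[key]]))
      counts[[key]] <- stats::setNames(rep(0L, 8), c(ranks, "none"))
    r <- if (is.na(r)) "none" else r
    counts[[key]][r] <- counts[[key]][r] + 1L
  }
  expect_setequal(identities(tab), as.integer(names(counts)))
  for (key in names(counts)) {
    i <- match(as.integer(key), identities(tab))
    expect_equal(lcrCounts(tab)[i, ], counts[[key]],
                 label = paste("counts at d =", key))
  }
  # probabilities normalize including the virtual none rank
  expect_equal(unname(rowSums(lcrProb(tab))), rep(1, length(identities(tab))))
})

test_that("identical sequences with one lineage give P(species|100) = 1", {
  s <- randomSeq(80)
  db <- makeDb(c(r1 = s, r2 = s, r3 = s),
               replicate(3, fullLineage(), simplify = FALSE))
  tab <- suppressWarnings(lcrTable(db))
  expect_equal(identities(tab), 100L)
  expect_equal(unname(lcrProb(tab)[1, "species"]), 1)
})

test_that("common-rank probability is monotone from species toward domain", {
  tab <- suppressWarnings(lcrTable(sharedDb(), sharedIdMat()))
  ranks <- rev(defaultRankOrder())   # species first
  for (d in identities(tab)) {
    p <- vapply(ranks, function(r) commonRankProb(tab, r, d), 0)
    expect_true(all(diff(p) >= -1e-12), label = paste("monotone at d =", d))
  }
  expect_error(commonRankProb(tab, "genus", 101), "no pairs")
})

test_that("mlr takes the most probable named rank, ties to the lower rank", {
  # printed example shape: probabilities .30/.49/.19/.03 -> genus
  tab <- LcrTable(100, cbind(species = 30, genus = 49, family = 19,
                             order = 2, none = 0))
  expect_equal(mlr(tab, 100), "genus")
  # single occupied rank
  expect_equal(mlr(LcrTable(95, cbind(family = 4)), 95), "family")
  # exact tie genus/family resolves to genus (more specific)
  expect_equal(mlr(LcrTable(92, cbind(genus = 3, family = 3)), 92), "genus")
  # "none" never wins even with majority mass
  expect_equal(mlr(LcrTable(70, cbind(phylum = 1, none = 9)), 70), "phylum")
})

test_that("rank identity thresholds follow the printed MLR worked example", {
  # MLR(100)=species, MLR(94..99)=genus, MLR(93)=family
  rows <- rbind(
    cbind(d = 100, species = 6, genus = 3, family = 1),
    do.call(rbind, lapply(94:99, function(d)
      cbind(d = d, species = 1, genus = 7, family = 2))),
    cbind(d = 93, species = 0, genus = 2, family = 8))
  tab <- LcrTable(rows[, "d"], rows[, c("species", "genus", "family")])
  rit <- rankIdentityThresholds(tab)
  expect_equal(unname(rit["species"]), 100L)
  expect_equal(unname(rit["genus"]), 94L)
  expect_equal(unname(rit["family"]), 93L)
  expect_true(is.na(rit["order"]))   # never the MLR
  # constant MLR: threshold is the minimum occupied identity
  tab2 <- LcrTable(c(88, 92, 96), cbind(genus = c(5, 5, 5)))
  rit2 <- rankIdentityThresholds(tab2)
  expect_equal(unname(rit2["genus"]), 88L)
  expect_true(all(is.na(rit2[setdiff(names(rit2), "genus")])))
})

test_that("known/novel estimator applies P_CR x N_d and sums identities", {
  # worked example: 100 OTUs at 97%, P_CR(species|97) = 0.7 -> 70/30
  tab <- LcrTable(97, cbind(species = 7, genus = 3))
  expect_equal(commonRankProb(tab, "species", 97), 0.7)
  expect_equal(commonRankProb(tab, "genus", 97), 1.0)
  est <- estimateKnownNovel(data.frame(d = 97, N = 100), tab, "species")
  expect_equal(est$known, 70)
  expect_equal(est$novel, 30)
  # P_CR = 1 everywhere: no novel mass
  tabAll <- LcrTable(c(95, 100), cbind(species = c(4, 6)))
  estAll <- estimateKnownNovel(data.frame(d = c(95, 100), N = c(10, 20)),
                               tabAll, "species")
  expect_equal(estAll$novel, 0)
  # two bins: N_100 = 10 at P_CR 1, N_90 = 10 at P_CR 0.2 -> K = 12, L = 8
  tab2 <- LcrTable(c(90, 100), rbind(cbind(species = 2, genus = 8),
                                     cbind(species = 10, genus = 0)))
  est2 <- estimateKnownNovel(data.frame(d = c(100, 90), N = c(10, 10)),
                             tab2, "species")
  expect_equal(est2$known, 12)
  expect_equal(est2$novel, 8)
  # per-identity rows conserve N exactly
  per <- est2$perIdentity
  expect_equal(per$known + per$novel, per$N)
})

test_that("estimator interpolates and clamps at unoccupied identities", {
  tab <- LcrTable(c(90, 100), rbind(cbind(species = 0, genus = 10),
                                    cbind(species = 10, genus = 0)))
  # d = 95 sits midway: P_CR(species) interpolates 0 .. 1 -> 0.5
  expect_message(
    est <- estimateKnownNovel(data.frame(d = 95, N = 10), tab, "species"),
    "interpolated")
  expect_equal(est$known, 5)
  # below the table range: clamped to the nearest row (P_CR = 0)
  est2 <- suppressMessages(
    estimateKnownNovel(data.frame(d = 80, N = 10), tab, "species"))
  expect_equal(est2$known, 0)
  expect_true(est2$perIdentity$interpolated)
})
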