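#' Tally prediction outcomes at one rank
#'
#' Classifies every test sequence with a true name at the rank as known
#' (name present in the training set) or novel, and each prediction as a
#' true positive (known, predicted, equal), misclassification (known,
#' predicted, different), under-classification (known, unpredicted) or
#' over-classification (novel, predicted). A novel, unpredicted sequence is
#' no event. Test sequences unannotated at the rank are excluded from `N`.
#' Name equality is exact string match after whitespace trimming.
#'
#' @param truth [TaxRefDB-class] of test sequences with true annotations.
#' @param predictions A [TaxPredictions-class] covering the test ids.
#' @param trainingNames Character vector of names present in the training
#'   set at this rank.
#' @param rank Rank label.
#' @return List with `rank`, `N`, `K`, `L`, `TP`, `MC`, `OC`, `UC`
#'   (`TP + MC + UC = K`, `OC <= L`).
#' @export
tallyRank <- function(truth, predictions, trainingNames, rank) {
  .rankIndex(rank, truth@rankOrder)
  idx <- match(refIds(truth), predictions@queryIds)
  if (anyNA(idx))
    stop("missing prediction for test id(s): ",
         paste(utils::head(refIds(truth)[is.na(idx)], 5), collapse = ", "))
  trueName <- trimws(.taxMatrix(truth)[, rank])
  predName <- trimws(predictedTaxa(predictions)[idx, rank])
  trainingNames <- trimws(trainingNames[!is.na(trainingNames)])
  use <- !is.na(trueName)
  trueName <- trueName[use]; predName <- predName[use]
  known <- trueName %in% trainingNames
  predicted <- !is.na(predName)
  list(rank = rank,
       N = sum(use),
       K = sum(known),
       L = sum(!known),
       TP = sum(known & predicted & predName == trueName, na.rm = TRUE),
       MC = sum(known & predicted & predName != trueName, na.rm = TRUE),
       OC = sum(!known & predicted),
       UC = sum(known & !predicted))
}

#' Performance metrics from a tally
#'
#' Rates in percent: `TPR = TP/K`, `UCR = UC/K`, `MCR = MC/K`,
#' `OCR = OC/L`, `Acc = TP/(K + OC)` (correct predictions over predictions
#' whose correctness can be determined) and `AccRDP = TP/N` (whose maximum
#' is `K/N` when novel names are present). A metric is `NA` (unreported)
#' when its denominator is below `minDenominator` — by default the rule of
#' 10: at least 10 test cases are required to report a rate.
#'
#' @param tally Output of [tallyRank()].
#' @param minDenominator Reporting floor (set to 1 to disable the rule of
#'   10, e.g. in unit tests).
#' @return Named numeric vector `N,K,L,TP,MC,OC,UC,TPR,UCR,MCR,OCR,Acc,
#'   AccRDP`.
#' @export
metricsFromTally <- function(tally, minDenominator = 10L) {
  rate <- function(num, den)
    if (den >= max(1L, minDenominator)) 100 * num / den else NA_real_
  with(tally, c(
    N = N, K = K, L = L, TP = TP, MC = MC, OC = OC, UC = UC,
    TPR = rate(TP, K), UCR = rate(UC, K), MCR = rate(MC, K),
    OCR = rate(OC, L), Acc = rate(TP, K + OC), AccRDP = rate(TP, N)))
}

#' Average metric rows over identities
#'
#' Arithmetic mean of each rate over the identities where it is reported;
#' unreported (NA) rows are skipped and the number of contributing
#' identities is recorded per metric.
#'
#' @param rows data.frame with a `d` column and metric columns (e.g. the
#'   `perIdentity` element of [cviBenchmark()], filtered to one rank).
#' @param metrics Metric columns to average.
#' @return data.frame with columns `metric`, `mean`, `nIdentities`.
#' @export
averageOverIdentities <- function(rows,
                                  metrics = c("TPR", "UCR", "MCR", "OCR",
                                              "Acc", "AccRDP")) {
  do.call(rbind, lapply(metrics, function(mcol) {
    v <- rows[[mcol]]
    data.frame(metric = mcol,
               mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else
                 NA_real_,
               nIdentities = sum(!is.na(v)))
  }))
}

# names present in the training set at each rank
.trainingNamesByRank <- function(training) {
  m <- .taxMatrix(training)
  lapply(stats::setNames(colnames(m), colnames(m)),
         function(r) unique(stats::na.omit(m[, r])))
}

.classifySet <- function(queries, training, method, cutoff, seed, nBoot,
                         wordsPerBoot, excludeSelf, idMat = NULL) {
  switch(method,
    top = topClassify(queries, training, "global", excludeSelf, idMat),
    btop = topClassify(queries, training, "local", excludeSelf),
    ktop = topClassify(queries, training, "kmer", excludeSelf),
    nbc = {
      pred <- nbcClassify(queries, trainNbc(training), cutoff, nBoot, seed)
      pred
    },
    sintax = sintaxClassify(queries, training, cutoff, nBoot, wordsPerBoot,
                            seed, excludeSelf),
    stop("unknown method: ", method))
}

#' Evaluate a classifier on one CVI split
#'
#' Classifies the test set `S` against the training set `A = T` + `W` and
#' tallies every rank. For `method = "nbc"` the model is trained on the
#' training set only; leave-one-out style masking is unnecessary because
#' the sets are disjoint for `d < 100` (at `d = 100` test and training
#' coincide and self-hits are intentionally allowed).
#'
#' @param db The reference the split was built from.
#' @param split A [CviSplit-class].
#' @param method One of `"top"`, `"btop"`, `"ktop"`, `"nbc"`, `"sintax"`.
#' @param cutoff Confidence cutoff for the bootstrap classifiers.
#' @param seed Integer seed.
#' @param nBoot,wordsPerBoot Bootstrap parameters.
#' @param minDenominator Reporting floor for [metricsFromTally()].
#' @param idMat Optional precomputed identity matrix of `db`.
#' @return data.frame: one row per rank with the tally and rates.
#' @export
evaluateSplit <- function(db, split, method = "top", cutoff = 0,
                          seed = 1L, nBoot = 100L, wordsPerBoot = 32L,
                          minDenominator = 10L, idMat = NULL) {
  if (length(split@S) == 0)
    stop("split has an empty test set")
  test <- db[split@S]
  training <- db[trainingIds(split)]
  pred <- .classifySet(test, training, method, cutoff, seed, nBoot,
                       wordsPerBoot, excludeSelf = FALSE, idMat = idMat)
  namesByRank <- .trainingNamesByRank(training)
  rows <- lapply(db@rankOrder, function(r) {
    met <- metricsFromTally(tallyRank(test, pred, namesByRank[[r]], r),
                            minDenominator)
    cbind(data.frame(rank = r, d = split@d, delta = split@delta),
          as.data.frame(as.list(met)))
  })
  do.call(rbind, rows)
}

#' Cross-validation-by-identity benchmark
#'
#' The full sweep: builds a split at each identity target, classifies every
#' test sequence against its training set, tallies all ranks, and averages
#' each metric per rank over the identities where it is reported. The
#' all-vs-all identity matrix is computed once and reused by the splits and
#' the global top-hit classifier.
#'
#' @param db A [TaxRefDB-class].
#' @param method Classifier (`"top"`, `"btop"`, `"ktop"`, `"nbc"`,
#'   `"sintax"`).
#' @param specs data.frame of identity targets and tolerances (columns
#'   `d`, `delta`); defaults to [defaultSplitSpecs()].
#' @param cutoff Confidence cutoff for bootstrap classifiers.
#' @param seed Integer seed (drives split shuffles and bootstraps).
#' @param nBoot,wordsPerBoot Bootstrap parameters.
#' @param minDenominator Reporting floor (rule of 10).
#' @param idMat Optional precomputed [identityMatrix()].
#' @return List of class `cviBenchmark`: `perIdentity` (data.frame, one
#'   row per rank and identity), `average` (one row per rank and metric),
#'   `splits`, `method`.
#' @export
cviBenchmark <- function(db, method = "top", specs = defaultSplitSpecs(),
                         cutoff = 0, seed = 1L, nBoot = 100L,
                         wordsPerBoot = 32L, minDenominator = 10L,
                         idMat = NULL) {
  if (is.null(idMat)) idMat <- identityMatrix(db)
  splits <- lapply(seq_len(nrow(specs)), function(i)
    buildCviSplit(db, specs$d[i], specs$delta[i], seed, idMat))
  rows <- list()
  for (sp in splits) {
    if (length(sp@S) == 0) {
      warning("skipping empty split at d = ", sp@d)
      next
    }
    rows[[length(rows) + 1L]] <-
      evaluateSplit(db, sp, method, cutoff, seed, nBoot, wordsPerBoot,
                    minDenominator, idMat)
  }
  per <- do.call(rbind, rows)
  avg <- do.call(rbind, lapply(db@rankOrder, function(r) {
    a <- averageOverIdentities(per[per$rank == r, , drop = FALSE])
    cbind(data.frame(rank = r), a)
  }))
  out <- list(perIdentity = per, average = avg, splits = splits,
              method = method)
  class(out) <- "cviBenchmark"
  out
}

#' @export
print.cviBenchmark <- function(x, ...) {
  cat(sprintf("CVI benchmark (%s): %d splits\n", x$method,
              length(x$splits)))
  g <- x$average[x$average$rank == "genus", ]
  if (nrow(g)) {
    cat("genus averages:\n")
    for (i in seq_len(nrow(g)))
      cat(sprintf("  Avg%s = %s (over %d identities)\n", g$metric[i],
                  ifelse(is.na(g$mean[i]), "NA", sprintf("%.1f", g$mean[i])),
                  g$nIdentities[i]))
  }
  invisible(x)
}

#' Retrieve an averaged metric from a benchmark
#'
#' @param report Output of [cviBenchmark()].
#' @param metric Metric name, e.g. `"OCR"`.
#' @param rank Rank label.
#' @return The averaged value (percent), or `NA` if never reported.
#' @export
avgMetric <- function(report, metric, rank = "genus") {
  a <- report$average
  a$mean[a$rank == rank & a$metric == metric]
}

#' Leave-one-out benchmark
#'
#' Classifies every reference sequence against the reference minus itself
#' (masking by id) and tallies per rank. A sequence is known at a rank when
#' its name occurs in at least one other record; singletons are novel.
#'
#' @param db A [TaxRefDB-class] (>= 2 records).
#' @param method,cutoff,seed,nBoot,wordsPerBoot,minDenominator As in
#'   [cviBenchmark()]. `"nbc"` is supported only when every genus has at
#'   least 2 sequences or the query's genus simply competes without its
#'   own sequence (the model is retrained per query without it).
#' @return data.frame: one row per rank with the tally and rates.
#' @export
l1oBenchmark <- function(db, method = "top", cutoff = 0, seed = 1L,
                         nBoot = 100L, wordsPerBoot = 32L,
                         minDenominator = 10L) {
  n <- length(db)
  if (n < 2) stop("need at least 2 records")
  if (method == "nbc") {
    # no run-time masking inside the word model: retrain per query
    preds <- lapply(seq_len(n), function(i)
      nbcClassify(db[i], trainNbc(db[-i]), cutoff, nBoot, seed))
    lineage <- do.call(rbind, lapply(preds, function(p) p@lineage))
    confid <- do.call(rbind, lapply(preds, function(p) p@confidence))
    pred <- .newPredictions(refIds(db), lineage, confid, cutoff, "nbc",
                            db@rankOrder)
  } else {
    pred <- .classifySet(db, db, method, cutoff, seed, nBoot, wordsPerBoot,
                         excludeSelf = TRUE)
  }
  m <- .taxMatrix(db)
  rows <- lapply(db@rankOrder, function(r) {
    counts <- table(m[, r])
    nonSingleton <- names(counts)[counts >= 2]
    met <- metricsFromTally(tallyRank(db, pred, nonSingleton, r),
                            minDenominator)
    cbind(data.frame(rank = r, d = NA_real_, delta = NA_real_),
          as.data.frame(as.list(met)))
  })
  do.call(rbind, rows)
}

#' Write a metrics report as tab-separated text
#'
#' One row per rank and identity plus `Avg` rows; unreported metrics are
#' rendered as `NA`, rates with one decimal.
#'
#' @param report Output of [cviBenchmark()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMetricsReport <- function(report, path) {
  per <- report$perIdentity
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f", v))
  lines <- c(paste(c("rank", "d", "N", "K", "L", "TP", "MC", "OC", "UC",
                     "TPR", "UCR", "MCR", "OCR", "Acc", "AccRDP"),
                   collapse = "\t"))
  for (i in seq_len(nrow(per)))
    lines <- c(lines, paste(c(
      per$rank[i], per$d[i], per$N[i], per$K[i], per$L[i], per$TP[i],
      per$MC[i], per$OC[i], per$UC[i], fmt(per$TPR[i]), fmt(per$UCR[i]),
      fmt(per$MCR[i]), fmt(per$OCR[i]), fmt(per$Acc[i]),
      fmt(per$AccRDP[i])), collapse = "\t"))
  avg <- report$average
  for (r in unique(avg$rank)) {
    a <- avg[avg$rank == r, ]
    vals <- stats::setNames(a$mean, a$metric)
    lines <- c(lines, paste(c(
      r, "Avg", "", "", "", "", "", "", "",
      fmt(vals["TPR"]), fmt(vals["UCR"]), fmt(vals["MCR"]),
      fmt(vals["OCR"]), fmt(vals["Acc"]), fmt(vals["AccRDP"])),
      collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
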