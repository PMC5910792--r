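.newPredictions <- function(queryIds, lineage, confidence, cutoff, method,
                            rankOrder) {
  colnames(lineage) <- rankOrder
  colnames(confidence) <- rankOrder
  new("TaxPredictions", queryIds = queryIds, lineage = lineage,
      confidence = confidence, cutoff = cutoff, method = method,
      rankOrder = rankOrder)
}

.emptyRow <- function(rankOrder)
  list(lineage = rep(NA_character_, length(rankOrder)),
       conf = rep(NA_real_, length(rankOrder)))

#' Top-hit classification
#'
#' Predicts, for each query, the full lineage of its top database hit with
#' confidence 1 at every annotated rank. `mode = "global"` and `"local"`
#' use alignment identity (the TOP and BTOP baselines); `mode = "kmer"`
#' uses the count of shared distinct 8-mers (KTOP). Ties go to the earlier
#' database record. Queries with no hit after masking receive an empty
#' prediction. Novel taxa are over-classified by construction whenever a
#' hit is found.
#'
#' @param queries,db [TaxRefDB-class] objects (`db` non-empty).
#' @param mode `"global"`, `"local"` or `"kmer"`.
#' @param excludeSelf Mask the database record sharing each query's id.
#' @param idMat Optional precomputed identity matrix covering all query and
#'   database ids (used for `mode = "global"`).
#' @return A [TaxPredictions-class] with cutoff 0.
#' @export
topClassify <- function(queries, db, mode = c("global", "local", "kmer"),
                        excludeSelf = FALSE, idMat = NULL) {
  mode <- match.arg(mode)
  .assertSameRanks(queries, db)
  if (length(db) == 0) stop("empty reference database")
  ranks <- db@rankOrder
  dbTax <- .taxMatrix(db)
  dbIds <- refIds(db)
  nq <- length(queries)
  lineage <- matrix(NA_character_, nq, length(ranks))
  conf <- matrix(NA_real_, nq, length(ranks))
  useMat <- !is.null(idMat) && mode == "global" &&
    all(refIds(queries) %in% rownames(idMat)) &&
    all(dbIds %in% colnames(idMat))
  qIds <- refIds(queries)

  if (mode == "kmer") {
    dbCodes <- cpp_kmer_codes(.seqChar(db), 8L)
    qCodes <- cpp_kmer_codes(.seqChar(queries), 8L)
  }
  for (i in seq_len(nq)) {
    cand <- .maskSelf(dbIds, qIds[i], excludeSelf)
    if (length(cand) == 0) next
    best <- if (mode == "kmer") {
      shared <- vapply(dbCodes[cand],
                       function(tc) sum(qCodes[[i]] %in% tc), 0L)
      cand[which.max(shared)]
    } else if (useMat) {
      cand[which.max(idMat[qIds[i], dbIds[cand]])]
    } else {
      cand[which.max(cpp_identity_many(.seqChar(queries)[i],
                                       .seqChar(db)[cand],
                                       mode == "local"))]
    }
    lineage[i, ] <- dbTax[best, ]
    conf[i, !is.na(lineage[i, ])] <- 1
  }
  .newPredictions(qIds, lineage, conf, 0,
                  switch(mode, global = "top", local = "btop",
                         kmer = "ktop"), ranks)
}

#' Train the naive-Bayes word classifier
#'
#' Builds per-genus document frequencies of distinct 8-mers with add-half
#' smoothing `P(w|g) = (n_g(w) + 0.5) / (N_g + 1)`. Every training record
#' must be annotated to genus, and each genus name must map to a single
#' lineage.
#'
#' @param db A [TaxRefDB-class] annotated to genus.
#' @param k Word size (default 8).
#' @return An [NbcModel-class].
#' @export
trainNbc <- function(db, k = 8L) {
  tax <- .taxMatrix(db)
  if (!"genus" %in% colnames(tax)) stop("rank order lacks a genus rank")
  g <- tax[, "genus"]
  if (anyNA(g))
    stop("record(s) lacking genus annotation: ",
         paste(utils::head(refIds(db)[is.na(g)], 5), collapse = ", "))
  genera <- unique(g)
  gi <- match(g, genera)
  # the model is genus-level: each genus maps to one lineage down to the
  # genus rank (ranks below genus are not predictable and left blank)
  gIdx <- .rankIndex("genus", db@rankOrder)
  upper <- seq_len(gIdx)
  lineages <- tax[match(genera, g), , drop = FALSE]
  if (gIdx < ncol(lineages))
    lineages[, seq(gIdx + 1L, ncol(lineages))] <- NA_character_
  rownames(lineages) <- genera
  for (x in genera) {
    rows <- unique(tax[gi == match(x, genera), upper, drop = FALSE])
    if (nrow(rows) > 1)
      stop("genus '", x, "' maps to more than one lineage")
  }
  codes <- cpp_kmer_codes(.seqChar(db), as.integer(k))
  vocab <- sort(unique(unlist(codes)))
  counts <- matrix(0L, length(vocab), length(genera))
  for (i in seq_along(codes)) {
    idx <- match(codes[[i]], vocab)
    counts[idx, gi[i]] <- counts[idx, gi[i]] + 1L
  }
  nSeqs <- as.integer(tabulate(gi, length(genera)))
  logProb <- log(sweep(counts + 0.5, 2, nSeqs + 1, "/"))
  colnames(logProb) <- genera
  new("NbcModel", k = as.integer(k), vocab = as.integer(vocab),
      logProb = logProb, logP0 = log(0.5 / (nSeqs + 1)), genera = genera,
      lineages = lineages, nSeqs = nSeqs, rankOrder = db@rankOrder)
}

# log-likelihood of a multiset of word indices (into vocab; NA = unseen)
.nbcScores <- function(model, idx) {
  present <- idx[!is.na(idx)]
  s <- if (length(present))
    colSums(model@logProb[present, , drop = FALSE]) else
    rep(0, length(model@genera))
  s + sum(is.na(idx)) * model@logP0
}

#' Naive-Bayes bootstrap classification
#'
#' Scores each genus by the summed log word probabilities of the query's
#' distinct 8-mers; the full-word winner's lineage is the candidate
#' prediction. Confidence at each rank is the fraction of `nBoot`
#' bootstrap draws (each of `floor(V/8)` of the query's `V` distinct
#' words, with replacement) whose winning genus agrees with the candidate
#' at that rank. The reported lineage is truncated at the lowest rank
#' whose confidence reaches `cutoff`; at cutoff 0 the full candidate
#' lineage is reported.
#'
#' Each query draws from an independent RNG stream derived from
#' `(seed, query id)`, so results do not depend on query order.
#'
#' @param queries A [TaxRefDB-class] of queries.
#' @param model An [NbcModel-class].
#' @param cutoff Confidence threshold in [0, 1] (0.8 is the classical
#'   recommendation; 0.5 and 0 are common presets).
#' @param nBoot Number of bootstrap draws (default 100).
#' @param seed Integer seed.
#' @return A [TaxPredictions-class].
#' @export
nbcClassify <- function(queries, model, cutoff = 0.8, nBoot = 100L,
                        seed = 1L) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  ranks <- model@rankOrder
  nq <- length(queries)
  lineage <- matrix(NA_character_, nq, length(ranks))
  conf <- matrix(NA_real_, nq, length(ranks))
  qCodes <- cpp_kmer_codes(.seqChar(queries), model@k)
  qIds <- refIds(queries)
  for (i in seq_len(nq)) {
    codes <- qCodes[[i]]
    V <- length(codes)
    if (V == 0) next
    idx <- match(codes, model@vocab)
    winner <- which.max(.nbcScores(model, idx))
    lin <- model@lineages[winner, ]
    nDraw <- max(1L, V %/% 8L)
    set.seed(seedFrom(seed, "nbc", qIds[i]))
    agree <- matrix(0L, nBoot, length(ranks))
    for (b in seq_len(nBoot)) {
      bs <- idx[sample.int(V, nDraw, replace = TRUE)]
      w <- which.max(.nbcScores(model, bs))
      agree[b, ] <- !is.na(lin) & !is.na(model@lineages[w, ]) &
        model@lineages[w, ] == lin
    }
    lineage[i, ] <- lin
    conf[i, ] <- ifelse(is.na(lin), NA_real_, colMeans(agree))
  }
  .newPredictions(qIds, lineage, conf, cutoff, "nbc", ranks)
}

#' k-mer bootstrap classification
#'
#' Each of `nBoot` bootstrap rounds draws `wordsPerBoot` words (with
#' replacement) from the query's distinct 8-mers and votes the lineage of
#' the database record sharing most drawn words (ties to the earlier
#' record). The candidate prediction is the most-voted lineage (ties to
#' the lineage of the earliest record); confidence at each rank is the
#' fraction of votes agreeing with the candidate at that rank, and the
#' reported lineage is truncated at the cutoff as for [nbcClassify()].
#'
#' @param queries,db [TaxRefDB-class] objects.
#' @param cutoff Confidence threshold in [0, 1].
#' @param nBoot Bootstrap rounds (default 100).
#' @param wordsPerBoot Words drawn per round (default 32).
#' @param seed Integer seed (independent stream per query).
#' @param excludeSelf Mask the database record sharing each query's id.
#' @return A [TaxPredictions-class].
#' @export
sintaxClassify <- function(queries, db, cutoff = 0.8, nBoot = 100L,
                           wordsPerBoot = 32L, seed = 1L,
                           excludeSelf = FALSE) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  .assertSameRanks(queries, db)
  if (length(db) == 0) stop("empty reference database")
  ranks <- db@rankOrder
  dbTax <- .taxMatrix(db)
  dbIds <- refIds(db)
  nd <- length(db)
  dbCodes <- cpp_kmer_codes(.seqChar(db), 8L)
  # posting lists: for each distinct word, the records containing it
  allCodes <- unlist(dbCodes)
  postKey <- sort(unique(allCodes))
  postings <- split(rep(seq_len(nd), lengths(dbCodes)),
                    factor(allCodes, levels = postKey))
  nq <- length(queries)
  lineage <- matrix(NA_character_, nq, length(ranks))
  conf <- matrix(NA_real_, nq, length(ranks))
  qCodes <- cpp_kmer_codes(.seqChar(queries), 8L)
  qIds <- refIds(queries)
  for (i in seq_len(nq)) {
    codes <- qCodes[[i]]
    V <- length(codes)
    if (V == 0) next
    mask <- if (excludeSelf) which(dbIds == qIds[i]) else integer(0)
    set.seed(seedFrom(seed, "sintax", qIds[i]))
    votes <- rep(NA_integer_, nBoot)
    post <- postings[match(codes, postKey)]
    for (b in seq_len(nBoot)) {
      drawn <- sample.int(V, wordsPerBoot, replace = TRUE)
      counts <- numeric(nd)
      for (widx in drawn) {
        hits <- post[[widx]]
        if (!is.null(hits)) counts[hits] <- counts[hits] + 1
      }
      if (length(mask)) counts[mask] <- -Inf
      if (max(counts) > 0) votes[b] <- which.max(counts)
    }
    votes <- votes[!is.na(votes)]
    if (length(votes) == 0) next
    # candidate = most-voted lineage (full-lineage key); among tied
    # lineages, the one voted by the earliest database record
    keys <- apply(dbTax[votes, , drop = FALSE], 1, paste, collapse = "\r")
    tab <- table(keys)
    topKeys <- names(tab)[tab == max(tab)]
    winner <- min(votes[keys %in% topKeys])
    lin <- dbTax[winner, ]
    voteLin <- dbTax[votes, , drop = FALSE]
    agree <- !is.na(voteLin) &
      matrix(!is.na(lin), length(votes), length(ranks), byrow = TRUE) &
      voteLin == matrix(lin, length(votes), length(ranks), byrow = TRUE)
    lineage[i, ] <- lin
    conf[i, ] <- ifelse(is.na(lin), NA_real_, colMeans(agree))
  }
  .newPredictions(qIds, lineage, conf, cutoff, "sintax", ranks)
}

#' Write predictions as tab-separated text
#'
#' Columns: query id, the full candidate lineage with per-rank confidence
#' (e.g. `d:Bacteria(1.00),...,g:Foo(0.84)`), and the cutoff-truncated
#' lineage in sintax style.
#'
#' @param pred A [TaxPredictions-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePredictions <- function(pred, path) {
  prefixes <- .rankPrefixes(pred@rankOrder)
  trunc <- predictedTaxa(pred)
  rows <- vapply(seq_along(pred@queryIds), function(i) {
    named <- which(!is.na(pred@lineage[i, ]))
    full <- paste(sprintf("%s:%s(%.2f)", prefixes[named],
                          pred@lineage[i, named],
                          pred@confidence[i, named]), collapse = ",")
    kept <- which(!is.na(trunc[i, ]))
    cut <- paste(sprintf("%s:%s", prefixes[kept], trunc[i, kept]),
                 collapse = ",")
    paste(pred@queryIds[i], full, cut, sep = "\t")
  }, character(1))
  writeLines(c("query\tlineage_confidence\tprediction", rows), path)
  invisible(path)
}
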