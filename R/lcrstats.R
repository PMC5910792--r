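#' Lowest-common-rank probability table of a reference
#'
#' Enumerates all unordered distinct record pairs, computes each pair's
#' integer-rounded global identity `d` and lowest common rank, and tabulates
#' `P(LCR = r | d) = m_{d,r} / M_d` per occupied identity. Pairs sharing no
#' name at any rank are counted under the virtual `"none"` rank, which
#' occupies probability mass in the denominator but is excluded from
#' common-rank probabilities and from the MLR.
#'
#' Self-pairs are not counted: the table describes distinct-pair sampling
#' from the reference.
#'
#' @param db A [TaxRefDB-class] with at least 2 annotated records.
#' @param idMat Optional precomputed [identityMatrix()].
#' @param weakRowWarning Warn when rows rest on fewer than 10 pairs
#'   (statistically weak)?
#' @return An [LcrTable-class].
#' @export
lcrTable <- function(db, idMat = NULL, weakRowWarning = TRUE) {
  if (length(db) < 2) stop("need at least 2 records")
  if (is.null(idMat)) idMat <- identityMatrix(db)
  lcrM <- .lcrMatrix(db)
  ut <- upper.tri(idMat)
  d <- roundHalfUp(idMat[ut])
  lcrCode <- lcrM[ut]                      # 0 = none, else rank index
  rankNames <- c(db@rankOrder, "none")
  col <- ifelse(lcrCode == 0L, length(rankNames), lcrCode)
  dLevels <- sort(unique(d))
  counts <- matrix(0L, length(dLevels), length(rankNames),
                   dimnames = list(NULL, rankNames))
  tab <- table(factor(d, levels = dLevels),
               factor(col, levels = seq_along(rankNames)))
  counts[, ] <- as.integer(tab)
  out <- new("LcrTable", d = as.integer(dLevels),
             M = as.integer(rowSums(counts)), counts = counts,
             prob = counts / rowSums(counts), rankOrder = db@rankOrder)
  if (weakRowWarning && any(out@M < 10))
    warning(sum(out@M < 10), " identity row(s) rest on fewer than 10 pairs",
            " and are statistically weak")
  out
}

.requireRow <- function(table, d) {
  i <- match(as.integer(d), table@d)
  if (is.na(i))
    stop("no pairs observed at identity d = ", d)
  i
}

#' Common-rank probability
#'
#' Probability that a pair at identity `d` shares a name at rank `r`, i.e.
#' the cumulative LCR probability over ranks at or below `r` (the virtual
#' `"none"` rank is excluded). Non-decreasing as `r` moves from the lowest
#' rank toward the highest.
#'
#' @param table An [LcrTable-class].
#' @param rank Rank label.
#' @param d Integer identity with an occupied row.
#' @return Probability in [0, 1].
#' @export
commonRankProb <- function(table, rank, d) {
  i <- .requireRow(table, d)
  j <- .rankIndex(rank, table@rankOrder)
  # ranks at or below `rank` are columns j..R (rankOrder is highest-first)
  sum(table@prob[i, seq(j, length(table@rankOrder))])
}

# MLR per table row; NA when a row has mass only on "none"
.mlrAll <- function(table) {
  R <- length(table@rankOrder)
  vapply(seq_along(table@d), function(i) {
    p <- table@prob[i, seq_len(R)]
    if (all(p == 0)) return(NA_character_)
    best <- which(p == max(p))
    table@rankOrder[max(best)]   # tie -> lower (more specific) rank
  }, character(1))
}

#' Most probable lowest common rank
#'
#' The rank maximizing `P(LCR = r | d)` over the named ranks; ties break
#' toward the lower (more specific) rank, and the virtual `"none"` rank is
#' never returned.
#'
#' @inheritParams commonRankProb
#' @return A rank label (or `NA` if the row has no named-rank mass).
#' @export
mlr <- function(table, d) {
  i <- .requireRow(table, d)
  .mlrAll(table)[i]
}

#' Rank identity thresholds
#'
#' `RIT(r)` is the minimum identity whose MLR equals `r`; a rank that is
#' never the MLR has no threshold (`NA`).
#'
#' @param table An [LcrTable-class].
#' @return Named integer vector over the table's ranks.
#' @export
rankIdentityThresholds <- function(table) {
  m <- .mlrAll(table)
  vapply(table@rankOrder, function(r) {
    hit <- table@d[!is.na(m) & m == r]
    if (length(hit)) min(hit) else NA_integer_
  }, integer(1))
}

#' Estimate known and novel OTU counts at a rank
#'
#' Combines a top-hit identity distribution with common-rank probabilities:
#' at identity `d`, the estimated number of OTUs whose rank-`r` taxon is
#' present in the reference is `K_d = P_CR(r | d) * N_d`, and
#' `L_d = (1 - P_CR(r | d)) * N_d` is the estimated novel count. Totals sum
#' over identities. For an identity absent from the table, `P_CR` is
#' linearly interpolated from the nearest occupied rows (clamped outside
#' their range); such rows are flagged in the output.
#'
#' @param thid Output of [thid()] (or any data.frame with columns `d`,
#'   `N`).
#' @param table An [LcrTable-class].
#' @param rank Rank label.
#' @return List of class `knownNovelEstimate`: `rank`, `known`, `novel`
#'   (totals) and `perIdentity` (data.frame `d`, `N`, `pcr`, `known`,
#'   `novel`, `interpolated`).
#' @export
#' @examples
#' tab <- LcrTable(97, cbind(species = 7, genus = 3))
#' est <- estimateKnownNovel(data.frame(d = 97, N = 100), tab, "species")
#' est$known  # 70
estimateKnownNovel <- function(thid, table, rank) {
  .rankIndex(rank, table@rankOrder)
  pcrTab <- vapply(table@d, function(d) commonRankProb(table, rank, d), 0)
  interp <- !(thid$d %in% table@d)
  pcr <- if (length(table@d) == 1) rep(pcrTab, length(thid$d)) else
    stats::approx(table@d, pcrTab, xout = thid$d, rule = 2)$y
  if (any(interp))
    message("interpolated common-rank probabilities at d = ",
            paste(thid$d[interp], collapse = ", "))
  per <- data.frame(d = thid$d, N = thid$N, pcr = pcr,
                    known = pcr * thid$N, novel = (1 - pcr) * thid$N,
                    interpolated = interp)
  out <- list(rank = rank, known = sum(per$known), novel = sum(per$novel),
              perIdentity = per)
  class(out) <- "knownNovelEstimate"
  out
}

#' @export
print.knownNovelEstimate <- function(x, ...) {
  cat(sprintf(
    "Known/novel estimate at rank %s: %.1f known, %.1f novel (of %d OTUs)\n",
    x$rank, x$known, x$novel, sum(x$perIdentity$N)))
  invisible(x)
}

#' Write an LCR table as tab-separated text
#'
#' Emits one file with per-identity counts and probabilities (columns `d`,
#' `M_d`, `m_<rank>`, `p_<rank>`), and optionally a companion file with
#' cumulative common-rank probabilities and the MLR.
#'
#' @param table An [LcrTable-class].
#' @param path Output path for the counts table.
#' @param crPath Optional output path for the `P_CR`/MLR table.
#' @return Invisibly, `path`.
#' @export
writeLcrTable <- function(table, path, crPath = NULL) {
  ranks <- c(table@rankOrder, "none")
  out <- data.frame(d = table@d, M_d = table@M)
  for (r in ranks) out[[paste0("m_", r)]] <- table@counts[, r]
  for (r in ranks) out[[paste0("p_", r)]] <- signif(table@prob[, r], 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(crPath)) {
    cr <- data.frame(d = table@d)
    for (r in table@rankOrder)
      cr[[paste0("pcr_", r)]] <- signif(vapply(
        table@d, function(d) commonRankProb(table, r, d), 0), 6)
    cr$MLR <- .mlrAll(table)
    utils::write.table(cr, crPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write rank identity thresholds
#'
#' @param table An [LcrTable-class].
#' @param path Output path (two columns: rank, threshold; `NA` when a rank
#'   is never the MLR).
#' @return Invisibly, `path`.
#' @export
writeRit <- function(table, path) {
  rit <- rankIdentityThresholds(table)
  utils::write.table(
    data.frame(rank = names(rit), threshold = unname(rit)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
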