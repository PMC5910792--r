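#' Pairwise sequence identity
#'
#' Percent identity between two DNA sequences. Global mode uses an
#' end-gap-free global alignment: terminal gaps are unpenalized and excluded
#' from the counted columns, and identity is `100 * matches / columns` over
#' the remaining columns (internal gap columns count). Local mode takes the
#' best local alignment and computes identity over its columns. Scoring is
#' match +1, mismatch -2, gap open -10, gap extend -1 (a gap of length L
#' costs 10 + L); among equal-score alignments the one with more matches is
#' preferred. Ambiguity letters never match.
#'
#' @param a,b DNA strings (non-empty).
#' @param mode `"global"` (default) or `"local"`.
#' @return A list with `idA`, `idB` (set to `NA` here; filled by callers
#'   that know record ids), `identityRaw` (percent), `identityInt`
#'   (round-half-up integer percent), `score`, `matches` and `columns`.
#' @export
#' @examples
#' pairwiseIdentity("ACGTACGT", "ACGTACGA")$identityRaw  # 87.5
pairwiseIdentity <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  a <- as.character(a); b <- as.character(b)
  if (is.na(a) || is.na(b) || nchar(a) == 0 || nchar(b) == 0)
    stop("sequences must be non-empty")
  r <- cpp_align_identity(a, b, mode == "local")
  list(idA = NA_character_, idB = NA_character_,
       identityRaw = unname(r[["identity"]]),
       identityInt = roundHalfUp(r[["identity"]]),
       score = unname(r[["score"]]),
       matches = unname(r[["matches"]]),
       columns = unname(r[["columns"]]))
}

#' Distinct k-mers of a sequence
#'
#' The set of distinct k-length words over {A,C,G,T}; windows containing
#' any other letter are skipped. Sequences shorter than `k` yield an empty
#' set.
#'
#' @param s DNA string.
#' @param k Word length (default 8).
#' @return Character vector of distinct words (sorted).
#' @export
#' @examples
#' uniqueKmers("ACGTACGTAC", k = 8)
uniqueKmers <- function(s, k = 8L) {
  stopifnot(k >= 1)
  codes <- cpp_kmer_codes(as.character(s), as.integer(k))[[1]]
  .decodeKmers(codes, k)
}

.decodeKmers <- function(codes, k) {
  if (length(codes) == 0) return(character(0))
  bases <- c("A", "C", "G", "T")
  out <- vapply(codes, function(code) {
    chars <- character(k)
    for (i in seq_len(k)) {
      chars[k - i + 1L] <- bases[bitwAnd(code, 3L) + 1L]
      code <- bitwShiftR(code, 2L)
    }
    paste(chars, collapse = "")
  }, character(1))
  sort(out)
}

#' All-vs-all global identity matrix
#'
#' Raw (unrounded) end-gap-free global identities between every pair of
#' records; the expensive step behind [lcrTable()], [buildCviSplit()] and
#' the alignment classifiers, exposed so it can be computed once and
#' reused.
#'
#' @param db A [TaxRefDB-class].
#' @return Symmetric numeric matrix with record ids as dimnames (diagonal
#'   100).
#' @export
identityMatrix <- function(db) {
  m <- cpp_identity_matrix(.seqChar(db))
  dimnames(m) <- list(refIds(db), refIds(db))
  m
}

#' All distinct pair identities
#'
#' One row per unordered distinct pair of records (`n(n-1)/2` rows).
#'
#' @param db A [TaxRefDB-class] with at least 2 records.
#' @param idMat Optional precomputed [identityMatrix()].
#' @return data.frame with columns `idA`, `idB`, `identityRaw`,
#'   `identityInt`.
#' @export
allPairIdentities <- function(db, idMat = NULL) {
  n <- length(db)
  if (n < 2) stop("need at least 2 records")
  if (is.null(idMat)) idMat <- identityMatrix(db)
  ut <- which(upper.tri(idMat), arr.ind = TRUE)
  ids <- refIds(db)
  data.frame(idA = ids[ut[, 1]], idB = ids[ut[, 2]],
             identityRaw = idMat[ut],
             identityInt = roundHalfUp(idMat[ut]),
             stringsAsFactors = FALSE)
}

# indices of db records eligible as targets for a query id
.maskSelf <- function(ids, queryId, excludeSelf) {
  if (excludeSelf) which(ids != queryId) else seq_along(ids)
}

#' Top hit of a query against a reference
#'
#' Finds the database record maximizing either raw global-alignment identity
#' (`metric = "alignment"`) or the number of shared distinct 8-mers
#' (`metric = "kmer"`). Ties are broken toward the earliest database record.
#' `excludeSelf` masks the database record whose id equals the query id
#' (duplicate sequences under other ids remain eligible).
#'
#' @param query A single-record [TaxRefDB-class] (or an id into `db`).
#' @param db A non-empty [TaxRefDB-class].
#' @param metric `"alignment"` (default) or `"kmer"`.
#' @param excludeSelf Mask the record with the query's id?
#' @param mode Alignment mode for the alignment metric.
#' @return A list with `queryId`, `targetId`, `identityRaw`, `identityInt`
#'   and `score` (alignment matches, or the shared-word count), or `NULL`
#'   if masking empties the database.
#' @export
topHit <- function(query, db, metric = c("alignment", "kmer"),
                   excludeSelf = FALSE, mode = "global") {
  metric <- match.arg(metric)
  if (length(db) == 0) stop("empty reference database")
  if (is.character(query) && length(query) == 1 && !is.na(query) &&
      query %in% refIds(db)) query <- db[query]
  stopifnot(is(query, "TaxRefDB"), length(query) == 1)
  qid <- refIds(query)
  cand <- .maskSelf(refIds(db), qid, excludeSelf)
  if (length(cand) == 0) return(NULL)
  if (metric == "alignment") {
    idv <- cpp_identity_many(.seqChar(query), .seqChar(db)[cand],
                             identical(mode, "local"))
    best <- cand[which.max(idv)]
    pid <- pairwiseIdentity(.seqChar(query), .seqChar(db)[best], mode)
    list(queryId = qid, targetId = refIds(db)[best],
         identityRaw = pid$identityRaw, identityInt = pid$identityInt,
         score = pid$matches)
  } else {
    qcodes <- cpp_kmer_codes(.seqChar(query), 8L)[[1]]
    tcodes <- cpp_kmer_codes(.seqChar(db)[cand], 8L)
    shared <- vapply(tcodes, function(tc) sum(qcodes %in% tc), 0L)
    best <- cand[which.max(shared)]
    pid <- pairwiseIdentity(.seqChar(query), .seqChar(db)[best], "global")
    list(queryId = qid, targetId = refIds(db)[best],
         identityRaw = pid$identityRaw, identityInt = pid$identityInt,
         score = max(shared))
  }
}

#' Top-hit identity distribution (THID)
#'
#' For each query, the integer-rounded identity of its global-alignment top
#' hit against the reference; returned as a histogram of query counts
#' `N_d` per identity `d`. When an [LcrTable-class] is supplied, each
#' occupied identity is annotated with its most probable lowest common rank
#' (MLR).
#'
#' @param queries,db Non-empty [TaxRefDB-class] objects.
#' @param lcrTable Optional [LcrTable-class] for MLR annotation.
#' @param excludeSelf Mask same-id records (leave-one-out variant: the
#'   nearest-neighbor identity distribution of a reference against itself).
#' @return data.frame of class `thid` with columns `d`, `N` and `mlr`
#'   (`NA` without annotation).
#' @export
thid <- function(queries, db, lcrTable = NULL, excludeSelf = FALSE) {
  if (length(queries) == 0 || length(db) == 0)
    stop("queries and db must be non-empty")
  dbSeqs <- .seqChar(db)
  ids <- refIds(db)
  dInt <- vapply(seq_len(length(queries)), function(i) {
    cand <- .maskSelf(ids, refIds(queries)[i], excludeSelf)
    if (length(cand) == 0) return(NA_integer_)
    idv <- cpp_identity_many(.seqChar(queries)[i], dbSeqs[cand], FALSE)
    roundHalfUp(max(idv))
  }, integer(1))
  dInt <- dInt[!is.na(dInt)]
  tab <- table(dInt)
  out <- data.frame(d = as.integer(names(tab)), N = as.integer(tab))
  out$mlr <- if (is.null(lcrTable)) NA_character_ else
    vapply(out$d, function(d)
      if (d %in% lcrTable@d) mlr(lcrTable, d) else NA_character_,
      character(1))
  class(out) <- c("thid", "data.frame")
  out
}

#' Write a THID as tab-separated text
#'
#' @param x Output of [thid()].
#' @param path Output path (columns `d`, `N_d`, `MLR`).
#' @return Invisibly, `path`.
#' @export
writeThid <- function(x, path) {
  out <- data.frame(d = x$d, N_d = x$N,
                    MLR = ifelse(is.na(x$mlr), "NA", x$mlr))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
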