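#' Default identity targets and tolerances for CVI
#'
#' The representative top-hit identities 100, 99, 97, 95 and 90 percent,
#' with allowed deviation 0 at 100 (the constraint is trivially satisfied),
#' 0.5 at 99/97/95 and 1.0 at 90.
#'
#' @return data.frame with columns `d` and `delta`.
#' @export
defaultSplitSpecs <- function() {
  data.frame(d = c(100, 99, 97, 95, 90),
             delta = c(0, 0.5, 0.5, 0.5, 1.0))
}

#' @rdname defaultSplitSpecs
#' @param d Identity target.
#' @export
defaultDelta <- function(d) {
  specs <- defaultSplitSpecs()
  i <- match(d, specs$d)
  if (!is.na(i)) specs$delta[i] else if (d >= 95) 0.5 else 1.0
}

#' Build an identity-constrained test/training split
#'
#' Partitions a reference into the disjoint subsets `S` (test), `T`
#' (designated top hits), `W` (below-`d` bystanders) and `Z` (discards) so
#' that the raw top-hit identity of every test sequence against the
#' training set `A = T` \eqn{\cup} `W` lies in `[d - delta, d + delta]`.
#' At `d = 100` the split is degenerate (`S = T = R`).
#'
#' The builder is greedy and best-effort (no optimality claim): candidates
#' are visited in seeded-shuffled order; a candidate `q` enters `S` when
#' some eligible `t` has identity in range and no committed training member
#' exceeds `d + delta` with `q`; the in-range `t` closest to `d` (ties to
#' the earlier record) enters `T`, and every sequence above `d + delta`
#' identity to `q` is barred from the training set. Remaining sequences go
#' to `W` when their identity to every member of `S` is below `d`, else to
#' `Z`. The contract that matters is checked by [verifyCviSplit()].
#'
#' @param db A [TaxRefDB-class] (>= 2 records for `d < 100`).
#' @param d Target top-hit identity in percent.
#' @param delta Allowed deviation (default per [defaultDelta()]).
#' @param seed Integer seed for the candidate shuffle.
#' @param idMat Optional precomputed [identityMatrix()].
#' @return A [CviSplit-class].
#' @export
buildCviSplit <- function(db, d, delta = defaultDelta(d), seed = 1L,
                          idMat = NULL) {
  stopifnot(d > 0, d <= 100, delta >= 0)
  ids <- refIds(db)
  if (d == 100)
    return(new("CviSplit", d = 100, delta = 0, seed = as.integer(seed),
               S = ids, T = ids, W = character(0), Z = character(0)))
  n <- length(db)
  if (n < 2) stop("need at least 2 records for d < 100")
  if (is.null(idMat)) idMat <- identityMatrix(db)
  lo <- d - delta; hi <- d + delta

  inS <- inT <- forb <- rep(FALSE, n)
  set.seed(seedFrom(seed, "cvi", d, delta))
  for (q in sample.int(n)) {
    if (inS[q] || inT[q]) next
    tIdx <- which(inT)
    if (length(tIdx) && any(idMat[q, tIdx] > hi)) next
    cand <- which(!inS & !inT & !forb)
    cand <- cand[cand != q]
    iv <- idMat[q, cand]
    cand <- cand[iv >= lo & iv <= hi]
    if (length(cand) == 0) next
    t <- cand[order(abs(idMat[q, cand] - d), cand)][1]
    inS[q] <- TRUE
    inT[t] <- TRUE
    over <- idMat[q, ] > hi
    over[q] <- FALSE
    forb[over] <- TRUE
  }
  rest <- which(!inS & !inT)
  sIdx <- which(inS)
  toW <- vapply(rest, function(x)
    !forb[x] && (length(sIdx) == 0 || max(idMat[x, sIdx]) < d),
    logical(1))
  if (!any(inS))
    warning("no admissible test/training pair at d = ", d,
            " +/- ", delta, "; test set is empty")
  new("CviSplit", d = d, delta = delta, seed = as.integer(seed),
      S = ids[inS], T = ids[inT], W = ids[rest[toW]],
      Z = ids[rest[!toW]])
}

#' Training ids of a split
#'
#' @param split A [CviSplit-class].
#' @return Character vector `A = T` \eqn{\cup} `W` (input order is the
#'   order stored in the split).
#' @export
trainingIds <- function(split) c(split@T, split@W)

#' Verify the identity constraints of a split
#'
#' Recomputes, for every test sequence, the raw top-hit identity against
#' the training set and checks it lies in `[d - delta, d + delta]`; also
#' checks the partition invariants (all ids covered, subsets disjoint,
#' except the degenerate `d = 100` case where `S = T = R`). Violations are
#' reported, not thrown.
#'
#' @param db The [TaxRefDB-class] the split was built from.
#' @param split A [CviSplit-class].
#' @param idMat Optional precomputed [identityMatrix()].
#' @return List with `ok` (flag) and `violations` (data.frame `id`,
#'   `offender`, `identity`, `reason`).
#' @export
verifyCviSplit <- function(db, split, idMat = NULL) {
  ids <- refIds(db)
  viol <- data.frame(id = character(0), offender = character(0),
                     identity = numeric(0), reason = character(0),
                     stringsAsFactors = FALSE)
  add <- function(id, offender, identity, reason)
    rbind(viol, data.frame(id = id, offender = offender,
                           identity = identity, reason = reason,
                           stringsAsFactors = FALSE))
  parts <- list(S = split@S, T = split@T, W = split@W, Z = split@Z)
  if (!setequal(unlist(parts), ids))
    viol <- add(NA_character_, NA_character_, NA_real_,
                "subsets do not cover the reference exactly")
  degenerate <- split@d == 100 && identical(sort(split@S), sort(split@T))
  if (!degenerate) {
    lab <- rep(names(parts), lengths(parts))
    dup <- unlist(parts)[duplicated(unlist(parts))]
    if (length(dup))
      for (x in unique(dup))
        viol <- add(x, NA_character_, NA_real_, "id in multiple subsets")
  }
  A <- if (degenerate) split@T else c(split@T, split@W)
  if (length(split@S) && length(A)) {
    if (is.null(idMat)) idMat <- identityMatrix(db)
    for (s in split@S) {
      iv <- idMat[s, A]
      top <- which.max(iv)
      if (iv[top] < split@d - split@delta - 1e-9 ||
          iv[top] > split@d + split@delta + 1e-9)
        viol <- add(s, A[top], iv[top],
                    sprintf("top training hit %.3f outside %g +/- %g",
                            iv[top], split@d, split@delta))
    }
  }
  list(ok = nrow(viol) == 0, violations = viol)
}

#' Leave-one-out query/training pairs
#'
#' Yields one pair per record: the record as query and a view of the
#' reference with that record masked by id (subsetting a `DNAStringSet`
#' shares sequence data, so no sequence copies are made).
#'
#' @param db A [TaxRefDB-class] with at least 2 records.
#' @return List of length `length(db)`; each element has `query` (a
#'   single-record [TaxRefDB-class]) and `training` (the remaining
#'   records).
#' @export
l1oPairs <- function(db) {
  n <- length(db)
  if (n < 2) stop("need at least 2 records for leave-one-out")
  lapply(seq_len(n), function(i)
    list(query = db[i], training = db[-i]))
}

#' Write a split to disk
#'
#' Emits a tab-separated manifest (columns id, subset) and, optionally,
#' test (`S`) and training (`T` + `W`) FASTA files.
#'
#' @param db The source [TaxRefDB-class].
#' @param split A [CviSplit-class].
#' @param prefix Output path prefix; writes `<prefix>.manifest.tsv`,
#'   `<prefix>.test.fa`, `<prefix>.train.fa`.
#' @param fasta Write the FASTA files too?
#' @return Invisibly, the manifest path.
#' @export
writeSplit <- function(db, split, prefix, fasta = TRUE) {
  manifest <- data.frame(
    id = c(split@S, split@T, split@W, split@Z),
    subset = rep(c("S", "T", "W", "Z"),
                 c(length(split@S), length(split@T), length(split@W),
                   length(split@Z))),
    stringsAsFactors = FALSE)
  path <- paste0(prefix, ".manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (fasta && length(split@S)) {
    writeTaxFasta(db[split@S], paste0(prefix, ".test.fa"))
    A <- trainingIds(split)
    if (length(A)) writeTaxFasta(db[A], paste0(prefix, ".train.fa"))
  }
  invisible(path)
}

#' Read a split manifest
#'
#' @param path Manifest written by [writeSplit()].
#' @param d,delta,seed Split parameters to attach (the manifest stores only
#'   memberships).
#' @return A [CviSplit-class].
#' @export
readSplitManifest <- function(path, d, delta = defaultDelta(d), seed = 1L) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  new("CviSplit", d = d, delta = delta, seed = as.integer(seed),
      S = m$id[m$subset == "S"], T = m$id[m$subset == "T"],
      W = m$id[m$subset == "W"], Z = m$id[m$subset == "Z"])
}
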