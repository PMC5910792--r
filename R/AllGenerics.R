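#' @include AllClasses.R
NULL

#' @rdname TaxRefDB-class
#' @param x,object A `TaxRefDB`.
#' @export
setGeneric("refIds", function(x) standardGeneric("refIds"))

#' @rdname TaxRefDB-class
#' @export
setGeneric("refSeqs", function(x) standardGeneric("refSeqs"))

#' @rdname TaxRefDB-class
#' @export
setGeneric("taxTable", function(x) standardGeneric("taxTable"))

#' @rdname TaxRefDB-class
#' @export
setGeneric("rankOrder", function(x) standardGeneric("rankOrder"))

#' Taxonomy of a single record
#'
#' @param x A [TaxRefDB-class].
#' @param id A record id or integer index.
#' @return Named character vector (one element per rank, `NA` where
#'   unannotated).
#' @export
setGeneric("taxonomyOf", function(x, id) standardGeneric("taxonomyOf"))

#' @rdname LcrTable-class
#' @param x,object An `LcrTable`.
#' @export
setGeneric("lcrProb", function(x) standardGeneric("lcrProb"))

#' @rdname LcrTable-class
#' @export
setGeneric("lcrCounts", function(x) standardGeneric("lcrCounts"))

#' @rdname LcrTable-class
#' @export
setGeneric("pairTotals", function(x) standardGeneric("pairTotals"))

#' @rdname LcrTable-class
#' @export
setGeneric("identities", function(x) standardGeneric("identities"))

#' Cutoff-truncated predicted names
#'
#' Applies the confidence cutoff: for each query the reported lineage is the
#' longest gapless rank prefix whose confidences all reach the cutoff.
#' Raising the cutoff can only remove ranks, never add them.
#'
#' @param x A [TaxPredictions-class].
#' @param cutoff Confidence threshold in [0, 1]; defaults to the cutoff the
#'   predictions were made with.
#' @return Character matrix (queries x ranks); `NA` marks unpredicted
#'   ranks.
#' @export
setGeneric("predictedTaxa",
           function(x, cutoff = NULL) standardGeneric("predictedTaxa"))

#### TaxRefDB methods -------------------------------------------------------

#' @rdname TaxRefDB-class
#' @export
setMethod("refIds", "TaxRefDB", function(x) names(x@seqs))

#' @rdname TaxRefDB-class
#' @export
setMethod("refSeqs", "TaxRefDB", function(x) x@seqs)

#' @rdname TaxRefDB-class
#' @export
setMethod("taxTable", "TaxRefDB", function(x) x@taxa)

#' @rdname TaxRefDB-class
#' @export
setMethod("rankOrder", "TaxRefDB", function(x) x@rankOrder)

#' @rdname TaxRefDB-class
#' @export
setMethod("length", "TaxRefDB", function(x) length(x@seqs))

#' @rdname TaxRefDB-class
#' @param i Index: integer, logical or record ids.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "TaxRefDB", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, names(x@seqs))
    if (anyNA(idx))
      stop("unknown record id(s): ",
           paste(utils::head(i[is.na(idx)], 5), collapse = ", "))
    i <- idx
  }
  initialize(x, seqs = x@seqs[i], taxa = x@taxa[i, , drop = FALSE])
})

#' @rdname taxonomyOf
#' @export
setMethod("taxonomyOf", "TaxRefDB", function(x, id) {
  if (is.character(id)) {
    idx <- match(id, names(x@seqs))
    if (is.na(idx)) stop("unknown record id: ", id)
  } else idx <- id
  out <- as.character(as.data.frame(x@taxa[idx, , drop = FALSE]))
  names(out) <- x@rankOrder
  out
})

setMethod("show", "TaxRefDB", function(object) {
  n <- length(object)
  cat(sprintf("TaxRefDB with %d sequence%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf("  lengths: %d..%d nt\n", min(w), max(w)))
    m <- as.matrix(as.data.frame(object@taxa))
    ntax <- vapply(seq_len(ncol(m)),
                   function(j) length(unique(stats::na.omit(m[, j]))), 0L)
    cat("  taxa:", paste(sprintf("%d %s", ntax, colnames(m)),
                         collapse = ", "), "\n")
  }
  invisible(object)
})

#### LcrTable methods -------------------------------------------------------

#' @rdname LcrTable-class
#' @export
setMethod("lcrProb", "LcrTable", function(x) {
  out <- x@prob
  rownames(out) <- x@d
  out
})

#' @rdname LcrTable-class
#' @export
setMethod("lcrCounts", "LcrTable", function(x) {
  out <- x@counts
  rownames(out) <- x@d
  out
})

#' @rdname LcrTable-class
#' @export
setMethod("pairTotals", "LcrTable", function(x) stats::setNames(x@M, x@d))

#' @rdname LcrTable-class
#' @export
setMethod("identities", "LcrTable", function(x) x@d)

setMethod("show", "LcrTable", function(object) {
  cat(sprintf("LcrTable: %d occupied identities (%s), %d pairs\n",
              length(object@d),
              if (length(object@d)) paste0(min(object@d), "..",
                                           max(object@d)) else "-",
              sum(object@M)))
  invisible(object)
})

#### CviSplit methods -------------------------------------------------------

setMethod("show", "CviSplit", function(object) {
  cat(sprintf(
    "CviSplit d=%g%% (delta=%g): |S|=%d |T|=%d |W|=%d |Z|=%d\n",
    object@d, object@delta, length(object@S), length(object@T),
    length(object@W), length(object@Z)))
  invisible(object)
})

#### TaxPredictions methods -------------------------------------------------

#' @rdname predictedTaxa
#' @export
setMethod("predictedTaxa", "TaxPredictions", function(x, cutoff = NULL) {
  if (is.null(cutoff)) cutoff <- x@cutoff
  stopifnot(cutoff >= 0, cutoff <= 1)
  out <- x@lineage
  keep <- !is.na(x@lineage) & !is.na(x@confidence) & x@confidence >= cutoff
  # gapless prefix: stop at the first rank that fails
  if (ncol(keep) > 1) {
    for (j in seq(2L, ncol(keep))) keep[, j] <- keep[, j] & keep[, j - 1L]
  }
  out[!keep] <- NA_character_
  out
})

#' @rdname TaxPredictions-class
#' @param x,object A `TaxPredictions`.
#' @export
setMethod("length", "TaxPredictions", function(x) length(x@queryIds))

setMethod("show", "TaxPredictions", function(object) {
  named <- rowSums(!is.na(predictedTaxa(object)))
  cat(sprintf(
    "TaxPredictions (%s): %d queries, cutoff %.2f, mean predicted ranks %.2f\n",
    object@method, length(object@queryIds), object@cutoff,
    if (length(named)) mean(named) else 0))
  invisible(object)
})

setMethod("show", "NbcModel", function(object) {
  cat(sprintf("NbcModel: %d genera, %d training sequences, %d distinct %d-mers\n",
              length(object@genera), sum(object@nSeqs),
              length(object@vocab), object@k))
  invisible(object)
})
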