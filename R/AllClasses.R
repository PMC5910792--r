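#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Canonical rank order
#'
#' The seven-rank taxonomic hierarchy used throughout the package, from the
#' highest rank (domain) to the lowest (species). All rank comparisons
#' ("lower", "at or below") follow this ordering.
#'
#' @return Character vector of rank labels, highest to lowest.
#' @export
#' @examples
#' defaultRankOrder()
defaultRankOrder <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

# single-letter header prefixes for the sintax dialect, aligned with
# defaultRankOrder(); the lineage (Greengenes) dialect additionally accepts
# "k" for domain
.rankPrefixes <- function(rankOrder) {
  std <- c(domain = "d", phylum = "p", class = "c", order = "o",
           family = "f", genus = "g", species = "s")
  pre <- std[rankOrder]
  missing <- is.na(pre)
  pre[missing] <- substr(rankOrder[missing], 1L, 1L)
  names(pre) <- rankOrder
  pre
}

#' TaxRefDB: a taxonomy-annotated sequence collection
#'
#' An ordered collection of DNA sequences, each carrying a rank-prefixed
#' lineage. Input order is preserved and significant: ties in top-hit
#' searches are broken toward the earlier record.
#'
#' @slot seqs A [Biostrings::DNAStringSet] named by record id.
#' @slot taxa A [S4Vectors::DataFrame] with one character column per rank
#'   (in `rankOrder` order); `NA` marks an unannotated rank. Annotated ranks
#'   must form a gapless prefix from the highest rank down.
#' @slot rankOrder Character vector of rank labels, highest to lowest.
#' @slot metadata List of provenance entries (e.g., amplicon drop logs).
#' @export
setClass("TaxRefDB",
  slots = c(seqs = "DNAStringSet", taxa = "DataFrame",
            rankOrder = "character", metadata = "list"))

.checkLineageGaps <- function(m) {
  # named ranks must be contiguous from the highest rank down
  named <- !is.na(m) & m != ""
  if (ncol(m) < 2L) return(integer(0))
  bad <- rep(FALSE, nrow(m))
  for (j in seq(2L, ncol(m))) {
    bad <- bad | (named[, j] & !named[, j - 1L])
  }
  which(bad)
}

setValidity("TaxRefDB", function(object) {
  msg <- character(0)
  n <- length(object@seqs)
  ids <- names(object@seqs)
  if (n > 0 && (is.null(ids) || any(is.na(ids)) || any(ids == "")))
    msg <- c(msg, "every sequence must have a non-empty id")
  if (anyDuplicated(ids))
    msg <- c(msg, "record ids must be unique")
  if (nrow(object@taxa) != n)
    msg <- c(msg, "taxa table must have one row per sequence")
  if (anyDuplicated(object@rankOrder) || length(object@rankOrder) == 0)
    msg <- c(msg, "rankOrder labels must be unique and non-empty")
  if (!identical(colnames(object@taxa), object@rankOrder))
    msg <- c(msg, "taxa columns must match rankOrder exactly")
  if (n > 0 && any(Biostrings::width(object@seqs) == 0))
    msg <- c(msg, "sequences must be non-empty")
  if (n > 0) {
    m <- as.matrix(as.data.frame(object@taxa))
    if (any(!is.na(m) & m == ""))
      msg <- c(msg, "taxon names must be non-empty strings (use NA)")
    bad <- .checkLineageGaps(m)
    if (length(bad))
      msg <- c(msg, sprintf(
        "lineage gap (named rank below an unnamed one) in record(s): %s",
        paste(utils::head(ids[bad], 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TaxRefDB
#'
#' @param seqs A [Biostrings::DNAStringSet] (named by id) or a named
#'   character vector of DNA sequences.
#' @param taxa A data.frame/DataFrame with one character column per rank, or
#'   `NULL` for an unannotated collection. Missing rank columns are added
#'   as `NA`.
#' @param rankOrder Rank labels, highest to lowest.
#' @param metadata Optional list of provenance entries.
#' @return A [TaxRefDB-class] object.
#' @export
#' @examples
#' db <- TaxRefDB(c(r1 = "ACGTACGT"),
#'                data.frame(domain = "d1", phylum = "p1", class = "c1",
#'                           order = "o1", family = "f1", genus = "g1",
#'                           species = "s1"))
#' db
TaxRefDB <- function(seqs, taxa = NULL, rankOrder = defaultRankOrder(),
                     metadata = list()) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  n <- length(seqs)
  if (is.null(taxa)) {
    taxa <- as.data.frame(matrix(NA_character_, n, length(rankOrder),
                                 dimnames = list(NULL, rankOrder)))
  }
  taxa <- as.data.frame(taxa, stringsAsFactors = FALSE)
  for (r in rankOrder) {
    if (!r %in% colnames(taxa)) taxa[[r]] <- rep(NA_character_, n)
    taxa[[r]] <- as.character(taxa[[r]])
  }
  extra <- setdiff(colnames(taxa), rankOrder)
  if (length(extra))
    stop("taxa has columns outside rankOrder: ", paste(extra, collapse = ", "))
  taxa <- S4Vectors::DataFrame(taxa[, rankOrder, drop = FALSE])
  rownames(taxa) <- NULL
  new("TaxRefDB", seqs = seqs, taxa = taxa, rankOrder = rankOrder,
      metadata = metadata)
}

#' LcrTable: lowest-common-rank probabilities by identity
#'
#' For every occupied integer identity `d`, the number of sequence pairs
#' `M_d`, per-rank lowest-common-rank (LCR) counts `m_{d,r}` (including the
#' virtual "none" rank for pairs sharing no name), and the conditional
#' probabilities `P(LCR = r | d) = m_{d,r} / M_d`.
#'
#' @slot d Integer vector of occupied identities (sorted increasing).
#' @slot M Integer vector of pair totals per identity.
#' @slot counts Integer matrix, rows = identities, columns = ranks
#'   (highest to lowest) plus `"none"`.
#' @slot prob Numeric matrix of the same shape; rows sum to 1.
#' @slot rankOrder Character vector of rank labels.
#' @export
setClass("LcrTable",
  slots = c(d = "integer", M = "integer", counts = "matrix",
            prob = "matrix", rankOrder = "character"))

setValidity("LcrTable", function(object) {
  msg <- character(0)
  nr <- length(object@d)
  if (length(object@M) != nr) msg <- c(msg, "M must match d in length")
  if (nrow(object@counts) != nr || nrow(object@prob) != nr)
    msg <- c(msg, "counts/prob must have one row per identity")
  want <- c(object@rankOrder, "none")
  if (!identical(colnames(object@counts), want))
    msg <- c(msg, "counts columns must be rankOrder plus 'none'")
  if (nr > 0) {
    if (any(rowSums(object@counts) != object@M))
      msg <- c(msg, "per-rank counts must sum to M_d")
    if (any(object@M < 1L))
      msg <- c(msg, "rows with M_d = 0 must be omitted")
    if (any(abs(rowSums(object@prob) - 1) > 1e-9))
      msg <- c(msg, "probabilities must sum to 1 per identity")
    if (is.unsorted(object@d, strictly = TRUE))
      msg <- c(msg, "identities must be sorted and distinct")
    if (any(object@d < 0L) || any(object@d > 100L))
      msg <- c(msg, "identities must lie in [0, 100]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an LcrTable from pair counts
#'
#' Builds the probability table directly from per-identity LCR counts, e.g.
#' when the counts come from an external computation or a printed table.
#' Use [lcrTable()] to derive counts from a reference database.
#'
#' @param d Integer identities, one per row of `counts`.
#' @param counts Integer matrix of LCR counts; columns must be named by rank
#'   (a `"none"` column for pairs sharing no name is added if absent).
#'   Columns may be given in any order and omitted when all-zero.
#' @param rankOrder Rank labels, highest to lowest.
#' @return An [LcrTable-class] object.
#' @export
#' @examples
#' # 8 pairs at 90% identity: 0 species, 2 genus, 6 family
#' tab <- LcrTable(90, cbind(species = 0, genus = 2, family = 6))
#' lcrProb(tab)
LcrTable <- function(d, counts, rankOrder = defaultRankOrder()) {
  d <- as.integer(d)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have rank column names")
  full <- matrix(0L, length(d), length(rankOrder) + 1L,
                 dimnames = list(NULL, c(rankOrder, "none")))
  bad <- setdiff(colnames(counts), colnames(full))
  if (length(bad))
    stop("unknown rank column(s): ", paste(bad, collapse = ", "))
  full[, colnames(counts)] <- as.integer(counts)
  ord <- order(d)
  d <- d[ord]; full <- full[ord, , drop = FALSE]
  M <- as.integer(rowSums(full))
  keep <- M >= 1L
  d <- d[keep]; full <- full[keep, , drop = FALSE]; M <- M[keep]
  prob <- full / M
  new("LcrTable", d = d, M = M, counts = full, prob = prob,
      rankOrder = rankOrder)
}

#' CviSplit: an identity-constrained test/training partition
#'
#' The four disjoint subsets of a reference for a target top-hit identity
#' `d` with tolerance `delta`: `S` (test set), `T` (designated top hits of
#' `S`), `W` (sequences below `d` identity to all of `S`) and `Z`
#' (discards). The training set is `A = T` \eqn{\cup} `W`. At `d = 100` the
#' split is degenerate: `S = T = R`, `W = Z = {}`.
#'
#' @slot d Target top-hit identity in percent.
#' @slot delta Allowed deviation in percent.
#' @slot seed Integer seed used by the greedy builder.
#' @slot S,T,W,Z Character vectors of record ids.
#' @export
setClass("CviSplit",
  slots = c(d = "numeric", delta = "numeric", seed = "integer",
            S = "character", T = "character", W = "character",
            Z = "character"))

#' TaxPredictions: per-query taxonomy predictions with confidence
#'
#' Holds, for each query, the full candidate lineage proposed by a
#' classifier together with per-rank confidence values in [0, 1]. The
#' reported prediction is the lineage truncated at the lowest rank whose
#' confidence still reaches the cutoff (see [predictedTaxa()]).
#'
#' @slot queryIds Character vector of query ids.
#' @slot lineage Character matrix (queries x ranks) of candidate names;
#'   `NA` where the source lineage itself is unannotated or no hit was
#'   found.
#' @slot confidence Numeric matrix (queries x ranks) of confidences.
#' @slot cutoff Confidence threshold in [0, 1] applied by default.
#' @slot method Classifier label.
#' @slot rankOrder Character vector of rank labels.
#' @export
setClass("TaxPredictions",
  slots = c(queryIds = "character", lineage = "matrix",
            confidence = "matrix", cutoff = "numeric", method = "character",
            rankOrder = "character"))

setValidity("TaxPredictions", function(object) {
  msg <- character(0)
  n <- length(object@queryIds)
  if (nrow(object@lineage) != n || nrow(object@confidence) != n)
    msg <- c(msg, "lineage/confidence must have one row per query")
  if (!identical(colnames(object@lineage), object@rankOrder))
    msg <- c(msg, "lineage columns must match rankOrder")
  if (object@cutoff < 0 || object@cutoff > 1)
    msg <- c(msg, "cutoff must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' NbcModel: trained naive-Bayes word model
#'
#' Per-genus document frequencies of distinct 8-mers with add-half
#' smoothing: `P(w | g) = (n_g(w) + 0.5) / (N_g + 1)` where `n_g(w)` is the
#' number of training sequences of genus `g` containing word `w` and `N_g`
#' the number of training sequences of `g`.
#'
#' @slot k Word size.
#' @slot vocab Sorted integer codes of all words seen in training.
#' @slot logProb Matrix `|vocab| x genera` of log word probabilities.
#' @slot logP0 Per-genus log probability of an unseen word.
#' @slot genera Genus names, in order of first appearance.
#' @slot lineages Character matrix (genera x ranks): the lineage of each
#'   genus down to the genus rank (ranks below genus are blank — the model
#'   is genus-level and cannot predict them).
#' @slot nSeqs Integer vector of per-genus training sequence counts.
#' @slot rankOrder Character vector of rank labels.
#' @export
setClass("NbcModel",
  slots = c(k = "integer", vocab = "integer", logProb = "matrix",
            logP0 = "numeric", genera = "character", lineages = "matrix",
            nSeqs = "integer", rankOrder = "character"))
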