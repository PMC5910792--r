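#' Round half up to integer
#'
#' Integer rounding used for identities: 87.5 rounds to 88 (base R `round`
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
#' @examples
#' roundHalfUp(c(87.5, 86.5, 90.2))
roundHalfUp <- function(x) as.integer(floor(x + 0.5))

# Stable 31-bit hash of a seed plus arbitrary string tags, used to derive
# independent RNG streams per stage/query so results do not depend on
# processing order. Exact in double arithmetic (values stay < 2^36).
seedFrom <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (tag in unlist(list(...))) {
    for (code in utf8ToInt(as.character(tag))) {
      h <- (h * 31 + code) %% 2147483647
    }
    h <- (h * 31 + 7) %% 2147483647
  }
  as.integer(h)
}

.rankIndex <- function(rank, rankOrder) {
  i <- match(rank, rankOrder)
  if (anyNA(i))
    stop("rank(s) not in rank order: ",
         paste(rank[is.na(i)], collapse = ", "))
  i
}

.assertSameRanks <- function(a, b) {
  if (!identical(a@rankOrder, b@rankOrder))
    stop("rank orders differ between the two collections")
}

# lineage matrix (character, queries x ranks) from a TaxRefDB
.taxMatrix <- function(db) {
  m <- as.matrix(as.data.frame(db@taxa))
  if (length(db) == 0)
    m <- matrix(NA_character_, 0, length(db@rankOrder),
                dimnames = list(NULL, db@rankOrder))
  rownames(m) <- refIds(db)
  m
}

.seqChar <- function(db) as.character(db@seqs)
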