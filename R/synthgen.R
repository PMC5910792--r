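#' SimConfig: parameters of the synthetic reference generator
#'
#' Describes a clock-like taxonomy with per-rank divergence: two sequences
#' whose lowest common rank is `r` are separated by an expected
#' substitution fraction of twice `divergence[r]` (each lineage
#' accumulates `divergence[r]` below their common ancestor), so their
#' expected identity is roughly `100 * (1 - 2 * divergence[r])` before
#' multiple-hit saturation. Per-edge lognormal rate factors
#' (`rateSdLog`) add lineage rate heterogeneity, spreading pairwise
#' identities into continuous, overlapping bands as in real marker-gene
#' references.
#'
#' @slot rankOrder Rank labels, highest to lowest.
#' @slot branching Named integer vector of child counts per rank below the
#'   root (a single domain).
#' @slot divergence Named numeric vector of per-rank divergences, strictly
#'   increasing from the lowest rank to the highest.
#' @slot seqsPerSpecies Sequences drawn per species.
#' @slot seqLength Root sequence length (>= 50 nt).
#' @slot indelRate Per-site indel fraction relative to substitutions
#'   (0 disables indels; default).
#' @slot rateSdLog Standard deviation (log scale) of the per-edge rate
#'   factor.
#' @slot seed Integer seed.
#' @export
setClass("SimConfig",
  slots = c(rankOrder = "character", branching = "integer",
            divergence = "numeric", seqsPerSpecies = "integer",
            seqLength = "integer", indelRate = "numeric",
            rateSdLog = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  below <- object@rankOrder[-1L]
  if (!identical(names(object@branching), below))
    msg <- c(msg, "branching must name every rank below the root")
  if (any(object@branching < 1))
    msg <- c(msg, "branching counts must be >= 1")
  if (!all(below %in% names(object@divergence)))
    msg <- c(msg, "divergence must cover every rank below the root")
  dv <- object@divergence[rev(object@rankOrder)]
  dv <- dv[!is.na(dv)]
  if (any(diff(dv) <= 0))
    msg <- c(msg, "divergences must strictly increase from the lowest rank upward")
  if (any(object@divergence < 0) || any(object@divergence >= 0.75))
    msg <- c(msg, "divergences must lie in [0, 0.75)")
  if (object@indelRate < 0 || object@indelRate >= 0.75)
    msg <- c(msg, "indelRate must lie in [0, 0.75)")
  if (object@seqLength < 50) msg <- c(msg, "seqLength must be >= 50")
  if (object@seqsPerSpecies < 1)
    msg <- c(msg, "seqsPerSpecies must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a generator configuration
#'
#' Defaults describe a 192-sequence bacterial-style reference (2 phyla x 2
#' classes x 2 orders x 2 families x 3 genera x 2 species, 2 sequences per
#' species, 300 nt) whose identity bands cover the benchmark's identity
#' targets: within-species pairs near 99%, congeneric species near 96%,
#' confamilial genera near 91%, deeper pairs below.
#'
#' @param branching Named child counts per rank below the root.
#' @param divergence Named per-rank divergences (see [SimConfig-class]).
#' @param seqsPerSpecies Sequences per species.
#' @param seqLength Sequence length in nt.
#' @param indelRate Indel fraction relative to substitutions (default 0).
#' @param rateSdLog Lognormal sd of per-edge rate factors (default 0.6).
#' @param seed Integer seed.
#' @param rankOrder Rank labels, highest to lowest.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(branching = c(phylum = 2L, class = 2L, order = 2L,
                                    family = 2L, genus = 3L, species = 2L),
                      divergence = c(species = 0.005, genus = 0.02,
                                     family = 0.05, order = 0.09,
                                     class = 0.14, phylum = 0.20,
                                     domain = 0.28),
                      seqsPerSpecies = 2L, seqLength = 300L,
                      indelRate = 0, rateSdLog = 0.6, seed = 1L,
                      rankOrder = defaultRankOrder()) {
  if (!rankOrder[1L] %in% names(divergence))
    divergence[rankOrder[1L]] <- min(0.74, divergence[[rankOrder[2L]]] * 1.4)
  new("SimConfig", rankOrder = rankOrder,
      branching = stats::setNames(as.integer(branching), names(branching)),
      divergence = divergence,
      seqsPerSpecies = as.integer(seqsPerSpecies),
      seqLength = as.integer(seqLength), indelRate = indelRate,
      rateSdLog = rateSdLog, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %s; %d seq/species, %d nt, seed %d\n",
    paste(sprintf("%d %s", object@branching, names(object@branching)),
          collapse = " x "),
    object@seqsPerSpecies, object@seqLength, object@seed))
  invisible(object)
})

.BASES <- c("A", "C", "G", "T")

# mutate a character-vector sequence by an expected substitution fraction,
# with a lognormal rate factor and optional single-base indels
.evolve <- function(seq, div, indelRate, rateSdLog) {
  f <- if (rateSdLog > 0)
    stats::rlnorm(1, meanlog = -rateSdLog^2 / 2, sdlog = rateSdLog) else 1
  p <- min(0.7, div * f)
  L <- length(seq)
  nSub <- stats::rbinom(1, L, p)
  if (nSub > 0) {
    pos <- sample.int(L, nSub)
    shift <- sample.int(3, nSub, replace = TRUE)
    codes <- match(seq[pos], .BASES) - 1L
    seq[pos] <- .BASES[((codes + shift) %% 4L) + 1L]
  }
  if (indelRate > 0) {
    nInd <- stats::rbinom(1, L, p * indelRate)
    for (k in seq_len(nInd)) {
      at <- sample.int(length(seq), 1)
      if (stats::runif(1) < 0.5 && length(seq) > 50) {
        seq <- seq[-at]
      } else {
        seq <- append(seq, sample(.BASES, 1), after = at)
      }
    }
  }
  seq
}

#' Simulate a taxonomy-annotated reference
#'
#' Evolves a random root sequence down the configured taxonomy tree: each
#' child edge applies the substitution budget that separates its rank band
#' from the next, so the expected pairwise identity of two leaves reflects
#' their lowest common rank. Names are synthetic (`p1`, `c3`, `g17`,
#' `s42`, ...), record ids are `<species>_<replicate>`, and the result is
#' fully deterministic for a given seed.
#'
#' @param cfg A [SimConfig-class].
#' @return A [TaxRefDB-class].
#' @export
#' @examples
#' db <- simulateReference(simConfig(seed = 7))
#' db
simulateReference <- function(cfg) {
  validObject(cfg)
  set.seed(seedFrom(cfg@seed, "simref"))
  ranks <- cfg@rankOrder
  below <- ranks[-1L]
  # distance from a node at rank r down to a leaf; leaves sit at the
  # species edge
  nodeDepth <- c(stats::setNames(cfg@divergence[ranks[1L]], ranks[1L]),
                 cfg@divergence[below])
  counters <- stats::setNames(rep(0L, length(below)), below)
  prefixes <- .rankPrefixes(ranks)

  seqsOut <- list(); taxOut <- list(); idsOut <- character(0)

  recurse <- function(seq, level, lineage) {
    # level indexes ranks: the node is at ranks[level]
    if (level == length(ranks)) {   # species node: emit replicates
      for (k in seq_len(cfg@seqsPerSpecies)) {
        child <- .evolve(seq, cfg@divergence["species"], cfg@indelRate,
                         cfg@rateSdLog)
        idsOut[[length(idsOut) + 1L]] <<- paste0(lineage[["species"]],
                                                 "_", k)
        seqsOut[[length(seqsOut) + 1L]] <<- paste(child, collapse = "")
        taxOut[[length(taxOut) + 1L]] <<- lineage
      }
      return(invisible(NULL))
    }
    childRank <- ranks[level + 1L]
    edge <- nodeDepth[[ranks[level]]] - nodeDepth[[childRank]]
    for (b in seq_len(cfg@branching[[childRank]])) {
      counters[childRank] <<- counters[childRank] + 1L
      childName <- paste0(prefixes[[childRank]], counters[[childRank]])
      childSeq <- .evolve(seq, edge, cfg@indelRate, cfg@rateSdLog)
      lin <- lineage
      lin[[childRank]] <- childName
      recurse(childSeq, level + 1L, lin)
    }
  }

  root <- sample(.BASES, cfg@seqLength, replace = TRUE)
  lineage0 <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
  lineage0[[ranks[1L]]] <- paste0(prefixes[[ranks[1L]]], 1L)
  recurse(root, 1L, lineage0)

  taxa <- as.data.frame(do.call(rbind, taxOut), stringsAsFactors = FALSE)
  colnames(taxa) <- ranks
  seqs <- Biostrings::DNAStringSet(unlist(seqsOut))
  names(seqs) <- idsOut
  TaxRefDB(seqs, taxa, ranks)
}

#' Simulate query sequences at a target top-hit identity
#'
#' Picks `n` seeded source records and mutates each until its realigned
#' global identity to the source is within 1 point of `targetD`
#' (`targetD = 100` copies the source). Queries keep the source taxonomy;
#' ids are `q<i>_<sourceId>` and source ids are attached as the
#' `"sourceIds"` attribute.
#'
#' @param db A [TaxRefDB-class].
#' @param targetD Target integer identity in `[60, 100]`.
#' @param n Number of queries (0 gives an empty set).
#' @param seed Integer seed.
#' @param maxTries Resampling attempts per query before giving up.
#' @return A [TaxRefDB-class] of queries.
#' @export
simulateQueries <- function(db, targetD, n, seed = 1L, maxTries = 40L) {
  stopifnot(targetD >= 60, targetD <= 100, n >= 0)
  ranks <- db@rankOrder
  if (n == 0)
    return(TaxRefDB(Biostrings::DNAStringSet(), NULL, ranks))
  set.seed(seedFrom(seed, "simq", targetD))
  srcIdx <- sample.int(length(db), n, replace = n > length(db))
  tax <- .taxMatrix(db)
  outSeqs <- character(n); outIds <- character(n)
  for (i in seq_len(n)) {
    src <- strsplit(.seqChar(db)[srcIdx[i]], "")[[1]]
    L <- length(src)
    if (targetD == 100) {
      outSeqs[i] <- paste(src, collapse = "")
    } else {
      kTarget <- max(1L, round(L * (100 - targetD) / 100))
      done <- FALSE
      for (try in seq_len(maxTries)) {
        mut <- src
        pos <- sample.int(L, min(kTarget, L))
        shift <- sample.int(3, length(pos), replace = TRUE)
        codes <- match(mut[pos], .BASES) - 1L
        mut[pos] <- .BASES[((codes + shift) %% 4L) + 1L]
        s <- paste(mut, collapse = "")
        idRaw <- cpp_align_identity(s, paste(src, collapse = ""),
                                    FALSE)[["identity"]]
        if (abs(idRaw - targetD) <= 1) { outSeqs[i] <- s; done <- TRUE;
          break }
        kTarget <- max(1L, kTarget + as.integer(
          round(L * (idRaw - targetD) / 100 * 0.8)))
      }
      if (!done)
        stop("could not reach target identity ", targetD,
             " for source ", refIds(db)[srcIdx[i]])
    }
    outIds[i] <- paste0("q", i, "_", refIds(db)[srcIdx[i]])
  }
  seqs <- Biostrings::DNAStringSet(outSeqs)
  names(seqs) <- outIds
  out <- TaxRefDB(seqs, as.data.frame(tax[srcIdx, , drop = FALSE]),
                  ranks)
  attr(out, "sourceIds") <- refIds(db)[srcIdx]
  out
}
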