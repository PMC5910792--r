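# Small fixture builders used across test files. Everything is generated in
# code; no binary fixtures.

fullLineage <- function(genus = "g1", species = "s1", family = "f1",
                        order = "o1", class = "c1", phylum = "p1",
                        domain = "d1") {
  c(domain = domain, phylum = phylum, class = class, order = order,
    family = family, genus = genus, species = species)
}

# db from a named character vector of sequences and a list of lineages
makeDb <- function(seqs, lineages) {
  taxa <- as.data.frame(do.call(rbind, lineages), stringsAsFactors = FALSE)
  TaxRefDB(seqs, taxa)
}

randomSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                      replace = TRUE), collapse = "")

# plant exactly `at` substitutions at the given positions (deterministic
# base shift, so identical position sets give identical sequences)
plantMut <- function(seq, at, shift = 1L) {
  v <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  codes <- match(v[at], bases) - 1L
  v[at] <- bases[((codes + shift) %% 4L) + 1L]
  paste(v, collapse = "")
}

# shared mid-size synthetic reference: computed once per test run
sharedSimConfig <- function(seed = 42L)
  simConfig(branching = c(phylum = 2L, class = 1L, order = 2L,
                          family = 2L, genus = 2L, species = 2L),
            seqsPerSpecies = 2L, seqLength = 240L, seed = seed)

.shared <- new.env()
sharedDb <- function() {
  if (is.null(.shared$db)) .shared$db <- simulateReference(sharedSimConfig())
  .shared$db
}
sharedIdMat <- function() {
  if (is.null(.shared$im)) .shared$im <- identityMatrix(sharedDb())
  .shared$im
}

# reference with eight planted 90%-identity pairs: 2 congeneric (LCR genus)
# and 6 confamilial (LCR family); all other pair identities far from 90
plantedLcrDb <- function(seed = 5L) {
  set.seed(seed)
  base <- randomSeq(100)
  blockC <- 1:20; blockC2 <- 21:40
  u <- lapply(0:3, function(k) plantMut(base, 41:45 + 5 * k))
  w <- lapply(0:1, function(k)
    plantMut(plantMut(base, blockC), 61:65 + 5 * k))
  x <- lapply(0:1, function(k)
    plantMut(plantMut(base, blockC2), 71:75 + 5 * k))
  seqs <- c(u1 = u[[1]], u2 = u[[2]], u3 = u[[3]], u4 = u[[4]],
            w1 = w[[1]], w2 = w[[2]], x1 = x[[1]], x2 = x[[2]])
  lin <- list(
    fullLineage(genus = "g1", species = "s1"),
    fullLineage(genus = "g1", species = "s2"),
    fullLineage(genus = "g2", species = "s3"),
    fullLineage(genus = "g2", species = "s4"),
    fullLineage(genus = "g3", species = "s5"),
    fullLineage(genus = "g4", species = "s6"),
    fullLineage(genus = "g5", species = "s7"),
    fullLineage(genus = "g6", species = "s8"))
  makeDb(seqs, lin)
}

# build a TaxPredictions directly (for metric unit tests)
makePredictions <- function(queryIds, genusNames, cutoff = 0,
                            ranks = defaultRankOrder()) {
  n <- length(queryIds)
  lineage <- matrix(NA_character_, n, length(ranks),
                    dimnames = list(NULL, ranks))
  conf <- matrix(NA_real_, n, length(ranks),
                 dimnames = list(NULL, ranks))
  for (i in seq_len(n)) {
    if (!is.na(genusNames[i])) {
      lineage[i, ] <- fullLineage(genus = genusNames[i],
                                  species = paste0(genusNames[i], "_sp"))
      conf[i, ] <- 1
    }
  }
  taxcvi:::.newPredictions(queryIds, lineage, conf, cutoff, "fixture",
                           ranks)
}
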