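#' Read a taxonomy-annotated FASTA file
#'
#' Reads plain or gzip-compressed FASTA whose headers carry a rank-prefixed
#' lineage in one of the two dominant dialects:
#' \describe{
#'   \item{`sintax`}{`>id;tax=d:Bacteria,p:Firmicutes,...,s:Foo_bar;`}
#'   \item{`lineage`}{`>id k__Bacteria;p__Firmicutes;...;s__Foo_bar`
#'     (Greengenes style; `k__` and `d__` both map to domain; empty fields
#'     such as `s__` are treated as unannotated)}
#' }
#' Sequences are upper-cased and `U` is mapped to `T` on read. A named rank
#' below an unnamed one (a lineage gap) is a parse error.
#'
#' @param path FASTA file path.
#' @param dialect Header dialect, `"sintax"` (default) or `"lineage"`.
#' @param rankOrder Rank labels, highest to lowest.
#' @return A [TaxRefDB-class].
#' @export
readTaxFasta <- function(path, dialect = c("sintax", "lineage"),
                         rankOrder = defaultRankOrder()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  n <- length(raw)
  prefixes <- .rankPrefixes(rankOrder)
  taxa <- matrix(NA_character_, n, length(rankOrder),
                 dimnames = list(NULL, rankOrder))
  ids <- character(n)

  parseFields <- function(fields, prefMap, rec, hdr) {
    out <- stats::setNames(rep(NA_character_, length(rankOrder)), rankOrder)
    for (f in fields) {
      if (f == "") next
      pre <- prefMap$split(f)
      if (is.null(pre))
        stop(sprintf("record %d ('%s'): cannot parse lineage field '%s'",
                     rec, hdr, f))
      rank <- names(prefixes)[match(pre$prefix, prefixes)]
      if (pre$prefix == "k") rank <- rankOrder[1L]  # kingdom == domain here
      if (is.na(rank) || !rank %in% rankOrder)
        stop(sprintf(
          "record %d ('%s'): rank prefix '%s' not in rank order", rec, hdr,
          pre$prefix))
      if (pre$name != "") out[rank] <- pre$name
    }
    out
  }

  for (rec in seq_len(n)) {
    hdr <- headers[rec]
    if (dialect == "sintax") {
      if (!grepl(";tax=", hdr, fixed = TRUE))
        stop(sprintf("record %d ('%s'): missing 'tax=' annotation", rec, hdr))
      ids[rec] <- sub(";.*$", "", hdr)
      taxstr <- sub("^.*;tax=", "", hdr)
      taxstr <- sub(";.*$", "", taxstr)
      fields <- strsplit(taxstr, ",", fixed = TRUE)[[1]]
      prefMap <- list(split = function(f) {
        m <- regmatches(f, regexec("^([A-Za-z]):(.*)$", f))[[1]]
        if (length(m) != 3) NULL else list(prefix = m[2], name = m[3])
      })
    } else {
      ids[rec] <- sub("[ \t].*$", "", hdr)
      taxstr <- sub("^[^ \t]+[ \t]+", "", hdr)
      if (identical(taxstr, hdr))
        stop(sprintf("record %d ('%s'): missing lineage after id", rec, hdr))
      fields <- trimws(strsplit(taxstr, ";", fixed = TRUE)[[1]])
      prefMap <- list(split = function(f) {
        m <- regmatches(f, regexec("^([A-Za-z])__(.*)$", f))[[1]]
        if (length(m) != 3) NULL else list(prefix = m[2], name = m[3])
      })
    }
    tx <- parseFields(fields, prefMap, rec, hdr)
    named <- !is.na(tx)
    if (any(named) && any(named & !cumprod(named)))
      stop(sprintf(
        "record %d ('%s'): lineage gap (a named rank below an unnamed one)",
        rec, hdr))
    taxa[rec, ] <- tx
  }

  seqs <- Biostrings::DNAStringSet(chartr("U", "T",
            toupper(as.character(raw))))
  names(seqs) <- ids
  TaxRefDB(seqs, as.data.frame(taxa), rankOrder)
}

#' Write a taxonomy-annotated FASTA file
#'
#' Emits sintax-dialect headers (`>id;tax=d:...,g:...;`) with one sequence
#' line per record. Reading the result back with [readTaxFasta()] restores
#' the ids, lineages and sequences exactly.
#'
#' @param db A non-empty [TaxRefDB-class].
#' @param path Output path (`.gz` suffix writes gzip).
#' @return Invisibly, `path`.
#' @export
writeTaxFasta <- function(db, path) {
  if (length(db) == 0) stop("refusing to write an empty reference")
  headers <- vapply(seq_len(length(db)), function(i)
    paste0(refIds(db)[i], ";tax=", formatLineage(taxonomyOf(db, i),
                                                 db@rankOrder), ";"),
    character(1))
  out <- db@seqs
  names(out) <- headers
  Biostrings::writeXStringSet(out, path,
                              compress = grepl("\\.gz$", path),
                              width = max(Biostrings::width(out)) + 1L)
  invisible(path)
}

#' Format a lineage in sintax style
#'
#' @param taxonomy Named character vector (ranks as names, `NA` where
#'   unannotated).
#' @param rankOrder Rank labels, highest to lowest.
#' @return A string such as `"d:Bacteria,p:Firmicutes"`.
#' @export
formatLineage <- function(taxonomy, rankOrder = defaultRankOrder()) {
  prefixes <- .rankPrefixes(rankOrder)
  named <- rankOrder[!is.na(taxonomy[rankOrder])]
  paste(paste0(prefixes[named], ":", taxonomy[named]), collapse = ",")
}

#' Lowest common rank of two lineages
#'
#' The lowest rank at which both lineages carry the same taxon name,
#' comparing only ranks annotated in both. Returns `NA` if no rank matches
#' (treated downstream as a virtual rank strictly above the highest real
#' rank).
#'
#' @param a,b Named character vectors (ranks as names) or single-record
#'   [TaxRefDB-class] objects.
#' @param rankOrder Rank labels, highest to lowest.
#' @return A rank label, or `NA_character_`.
#' @export
#' @examples
#' a <- c(domain = "Bacteria", phylum = "Firmicutes", class = "Bacilli",
#'        order = "Lactobacillales", family = "Enterococcaceae",
#'        genus = "Enterococcus", species = "Enterococcus_avium")
#' b <- a; b["genus"] <- "Pilibacter"; b["species"] <- "Pilibacter_termitis"
#' lcr(a, b)  # "family"
lcr <- function(a, b, rankOrder = defaultRankOrder()) {
  if (is(a, "TaxRefDB")) a <- taxonomyOf(a, 1L)
  if (is(b, "TaxRefDB")) b <- taxonomyOf(b, 1L)
  for (r in rev(rankOrder)) {   # lowest rank first
    na <- a[[r]]; nb <- b[[r]]
    if (!is.null(na) && !is.null(nb) && !is.na(na) && !is.na(nb) &&
        na == nb)
      return(r)
  }
  NA_character_
}

# pairwise LCR codes for all records: integer matrix, entry = rank index in
# rankOrder (1 = highest) or 0L for no shared name
.lcrMatrix <- function(db) {
  m <- .taxMatrix(db)
  n <- nrow(m)
  out <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_along(db@rankOrder)) {   # highest to lowest; lowest wins
    v <- m[, j]
    eq <- !is.na(v) & outer(v, v, "==")
    eq[is.na(eq)] <- FALSE
    out[eq] <- j
  }
  out
}

#' Subsample a reference to at most `cap` sequences per taxon
#'
#' Per taxon at the given rank, randomly discards sequences until at most
#' `cap` remain; survivors keep their original relative order. Records
#' unannotated at the rank are kept unchanged.
#'
#' @param db A [TaxRefDB-class].
#' @param rank Rank at which to cap (default genus).
#' @param cap Maximum sequences per taxon (default 10).
#' @param seed Integer seed for the random discards.
#' @return A [TaxRefDB-class] subset.
#' @export
subsampleByTaxon <- function(db, rank = "genus", cap = 10L, seed = 1L) {
  .rankIndex(rank, db@rankOrder)
  stopifnot(cap >= 1)
  set.seed(seedFrom(seed, "subsample", rank, cap))
  names <- .taxMatrix(db)[, rank]
  keep <- rep(TRUE, length(db))
  for (tx in unique(stats::na.omit(names))) {
    idx <- which(!is.na(names) & names == tx)
    if (length(idx) > cap)
      keep[setdiff(idx, sort(sample(idx, cap)))] <- FALSE
  }
  db[which(keep)]
}

#' Extract the inter-primer amplicon from each reference sequence
#'
#' Locates the forward primer and the reverse complement of the reverse
#' primer in each sequence, allowing up to `maxMismatch` mismatches.
#' Degenerate IUPAC letters in the primers match their expansion sets;
#' ambiguity letters in the reference sequence count as mismatches. The
#' forward strand is scanned first; if no full site pair is found there the
#' record's reverse complement is scanned and the extracted segment is
#' re-oriented to the forward strand. Records without both sites (or with
#' an empty insert) are dropped and listed in the drop log
#' (`x@metadata$dropLog`).
#'
#' @param db A [TaxRefDB-class].
#' @param fwdPrimer,revPrimer Primer sequences (IUPAC DNA, length >= 10),
#'   both written 5'->3' as in a PCR protocol.
#' @param maxMismatch Maximum mismatches per primer site (default 2).
#' @return A [TaxRefDB-class] of inter-primer segments (primers excluded),
#'   with a drop log in its metadata.
#' @export
extractAmplicon <- function(db, fwdPrimer, revPrimer, maxMismatch = 2L) {
  if (nchar(fwdPrimer) < 10 || nchar(revPrimer) < 10)
    stop("primers must be at least 10 nt long")
  fwd <- Biostrings::DNAString(toupper(fwdPrimer))
  rcr <- Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(revPrimer)))
  fixedRule <- c(pattern = FALSE, subject = TRUE)

  findInsert <- function(seq) {
    m1 <- Biostrings::matchPattern(fwd, seq, max.mismatch = maxMismatch,
                                   fixed = fixedRule)
    if (length(m1) == 0) return(list(reason = "no_fwd_site"))
    m2 <- Biostrings::matchPattern(rcr, seq, max.mismatch = maxMismatch,
                                   fixed = fixedRule)
    if (length(m2) == 0) return(list(reason = "no_rev_site"))
    from <- BiocGenerics::end(m1)[1L] + 1L          # leftmost fwd site
    to <- BiocGenerics::start(m2)[length(m2)] - 1L  # rightmost rev site
    if (from > to) return(list(reason = "empty_or_inverted_insert"))
    list(insert = Biostrings::subseq(seq, from, to))
  }

  n <- length(db)
  inserts <- vector("list", n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    s <- db@seqs[[i]]
    hit <- findInsert(s)
    if (is.null(hit$insert)) {
      hitRc <- findInsert(Biostrings::reverseComplement(s))
      if (!is.null(hitRc$insert)) hit <- hitRc
    }
    if (is.null(hit$insert)) reasons[i] <- hit$reason
    else inserts[[i]] <- as.character(hit$insert)
  }

  kept <- which(reasons == "")
  dropLog <- data.frame(id = refIds(db)[reasons != ""],
                        reason = reasons[reasons != ""],
                        stringsAsFactors = FALSE)
  if (length(kept) == 0)
    warning("no record contained both primer sites; returning empty output")
  seqs <- Biostrings::DNAStringSet(unlist(inserts[kept], use.names = FALSE))
  names(seqs) <- refIds(db)[kept]
  out <- TaxRefDB(seqs,
                  as.data.frame(db@taxa[kept, , drop = FALSE]),
                  db@rankOrder,
                  metadata = c(db@metadata, list(dropLog = dropLog)))
  out
}

#' Write an amplicon drop log
#'
#' @param db Output of [extractAmplicon()].
#' @param path Output path for the tab-separated log (columns id, reason).
#' @return Invisibly, `path`.
#' @export
writeDropLog <- function(db, path) {
  log <- db@metadata$dropLog
  if (is.null(log)) log <- data.frame(id = character(0),
                                      reason = character(0))
  utils::write.table(log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
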