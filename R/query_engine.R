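.is_fastq <- function(path) {
  if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) return(TRUE)
  if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
    return(FALSE)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1)
  length(first) == 1 && startsWith(first, "@")
}

#' Read sequencing spots from a FASTA or FASTQ file
#'
#' A spot is the unit of one sequencing cluster: with a mate file, both
#' reads of a pair (matched by position) belong to one spot.  Quality
#' values are ignored.
#'
#' @param path FASTA or FASTQ file (optionally gzipped); format detected
#'   from the extension or the first byte.
#' @param mate_path optional second-mate file with records in the same
#'   order.
#' @return named list of character vectors, one element per spot (names
#'   are the record ids up to the first whitespace), each holding one or
#'   two read sequences.
#' @export
read_spots <- function(path, mate_path = NULL) {
  rd <- function(p) {
    fmt <- if (.is_fastq(p)) "fastq" else "fasta"
    s <- as.character(Biostrings::readDNAStringSet(p, format = fmt))
    names(s) <- sub("\\s.*$", "", names(s))
    s
  }
  r1 <- rd(path)
  spots <- lapply(seq_along(r1), function(i) unname(r1[i]))
  names(spots) <- names(r1)
  if (!is.null(mate_path)) {
    r2 <- rd(mate_path)
    if (length(r2) != length(r1))
      stop("mate file has ", length(r2), " records but ", path,
           " has ", length(r1))
    spots <- lapply(seq_along(r1), function(i) c(r1[[i]], r2[[i]]))
    names(spots) <- names(r1)
  }
  spots
}

#' Unique canonical query k-mers of one spot
#'
#' Every position of every read contributes its canonical k-mer -- no
#' minimizer sampling is applied at query time -- then the set is
#' deduplicated across the spot.  K-mers containing non-ACGT bases are
#' skipped; reads shorter than `k` contribute nothing.
#'
#' @param reads character vector of the spot's read sequences.
#' @param k k-mer length (must match the database; default 32).
#' @return character vector of distinct packed canonical k-mers.
#' @export
spot_query_kmers <- function(reads, k = 32L) {
  km <- unlist(lapply(as.character(reads), kt_seq_kmers, k = as.integer(k)),
               use.names = FALSE)
  unique(km)
}

#' Match a spot's query k-mers against a database lookup
#'
#' @param qkmers distinct packed canonical k-mers (see
#'   [spot_query_kmers()]).
#' @param lookup a `kmer_lookup` from [read_dbs()], [read_dbss_slice()],
#'   or [as_kmer_lookup()].
#' @return named integer vector: for each TaxId with at least one matching
#'   k-mer, the count of distinct query k-mers assigned to it; names are
#'   TaxIds in ascending order.  Empty when nothing matches.
#' @export
match_spot <- function(qkmers, lookup) {
  tx <- lookup_taxids(lookup, qkmers)
  tx <- tx[!is.na(tx)]
  if (!length(tx)) return(stats::setNames(integer(0), character(0)))
  tab <- table(tx)
  counts <- as.integer(tab)
  ids <- as.integer(names(tab))
  o <- order(ids)
  stats::setNames(counts[o], ids[o])
}

.format_hits_line <- function(id, hits) {
  tok <- ifelse(hits > 1L, paste0(names(hits), "x", hits), names(hits))
  paste(c(id, tok), collapse = "\t")
}

#' Query every spot of a run against a k-mer database
#'
#' The exact-match query engine: each spot's unique canonical k-mers are
#' matched against the database and spots with at least one hit are
#' reported.  With a dbss database a `tax_list` restricts which TaxIds'
#' k-mers are loaded.
#'
#' @param input path to FASTA/FASTQ reads, or a spot list from
#'   [read_spots()].
#' @param db a `kmer_lookup`, or a path to a dbs file.
#' @param dbss,annotation paths to a dbss k-mer file and its annotation
#'   (alternative to `db`); requires `tax_list`.
#' @param tax_list TaxIds to load in dbss mode (vector, or path to a file
#'   of one TaxId per line).  Must be nonempty.
#' @param out optional path for the hits file: one line per spot with
#'   hits, the spot id then TAB-separated `TaxId` or `TaxIdxN` tokens
#'   (N > 1 distinct matching k-mers), TaxIds ascending; spot order
#'   follows the input.
#' @param mate_path optional second-mate file (see [read_spots()]).
#' @param k k-mer length (default 32).
#' @param warn_missing passed to [read_dbss_slice()] in dbss mode.
#' @return named list of per-spot hit vectors (as [match_spot()]), spots
#'   without hits omitted; invisibly when `out` is written.
#' @export
run_aligns_to <- function(input, db = NULL, dbss = NULL, annotation = NULL,
                          tax_list = NULL, out = NULL, mate_path = NULL,
                          k = 32L, warn_missing = TRUE) {
  if (!is.null(dbss)) {
    if (is.null(tax_list))
      stop("dbss mode requires a tax_list of TaxIds to load")
    if (is.character(tax_list) && length(tax_list) == 1 &&
        file.exists(tax_list))
      tax_list <- as.integer(readLines(tax_list))
    tax_list <- as.integer(tax_list)
    if (!length(tax_list)) stop("tax_list is empty")
    lookup <- read_dbss_slice(dbss, annotation, tax_list,
                              warn_missing = warn_missing)
  } else if (is.character(db)) {
    lookup <- read_dbs(db)
  } else lookup <- db
  if (!inherits(lookup, "kmer_lookup")) stop("no database given")

  spots <- if (is.list(input)) input else read_spots(input, mate_path)
  hits <- lapply(spots, function(reads)
    match_spot(spot_query_kmers(reads, k = k), lookup))
  hits <- hits[vapply(hits, length, integer(1)) > 0]
  if (!is.null(out)) {
    lines <- vapply(names(hits), function(id)
      .format_hits_line(id, hits[[id]]), character(1))
    writeLines(lines, out)
    return(invisible(hits))
  }
  hits
}

#' Parse a hits file back into per-spot hit vectors
#'
#' @param path a hits file written by [run_aligns_to()].
#' @return named list of per-spot named integer hit vectors.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    tok <- f[-1]
    m <- regmatches(tok, regexec("^([0-9]+)(x([0-9]+))?$", tok))
    bad <- vapply(m, length, integer(1)) == 0
    if (any(bad)) stop("malformed hits token: ", tok[bad][1])
    ids <- vapply(m, function(x) as.integer(x[2]), integer(1))
    n <- vapply(m, function(x)
      if (x[4] == "") 1L else as.integer(x[4]), integer(1))
    stats::setNames(n, ids)
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}
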