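#' Build a host-read subtraction database
#'
#' A single-TaxId dense database for host-read scrubbing: one minimizer
#' per 32 bp window (twice as dense as the standard taxonomy databases),
#' no taxonomic merging, the low-complexity filter applied, and any k-mer
#' also present in the exclusion sets (typically the merged Bacteria and
#' Viruses kingdom databases, to protect clinical-pathogen signal)
#' subtracted.
#'
#' @param host host reference sequences: character vector, DNAStringSet,
#'   or FASTA path.
#' @param exclusions packed k-mers to subtract (character vector, a
#'   `taxon_kmer_set`, a list of them, or dbs file paths).
#' @param taxid TaxId recorded on the database (default 9606, human).
#' @param window minimizer window in bases (default 32).
#' @param filter apply [filter_low_complexity()] (default TRUE).
#' @param path optional output path; when given the database is also
#'   written as a dbs file.
#' @param k k-mer length (default 32).
#' @return a [taxon_kmer_set()]; an empty result after subtraction is an
#'   error (degenerate database).
#' @export
build_scrub_db <- function(host, exclusions = character(0), taxid = 9606L,
                           window = 32L, filter = TRUE, path = NULL,
                           k = 32L) {
  set <- build_taxon_set(host, taxid = taxid, window = window, k = k)
  if (filter) set <- filter_low_complexity(set)
  excl <- .exclusion_kmers(exclusions)
  set <- subtract_kmers(set, excl)
  if (!length(set$kmers))
    stop("scrub database is empty after filtering/subtraction")
  if (!is.null(path)) write_dbs(set, path)
  set
}

.exclusion_kmers <- function(x) {
  if (inherits(x, "taxon_kmer_set")) return(x$kmers)
  if (is.list(x))
    return(unique(unlist(lapply(x, .exclusion_kmers), use.names = FALSE)))
  if (is.character(x) && length(x) && all(file.exists(x)))
    return(unique(unlist(lapply(x, function(p) kt_read_dbs(p)$kmer),
                         use.names = FALSE)))
  as.character(x)
}

.read_fastq_records <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ '", path, "': ", length(lines),
         " lines is not a multiple of 4")
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  hdr <- lines[4 * idx - 3]
  seq <- lines[4 * idx - 2]
  plus <- lines[4 * idx - 1]
  qual <- lines[4 * idx]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+") |
                 nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in '", path, "'")
  list(n = n, hdr = hdr, seq = seq, plus = plus, qual = qual)
}

#' Remove host-matching reads from a FASTQ file
#'
#' Each spot's unique canonical query k-mers are matched against the
#' subtraction database; spots reaching `min_hits` matching k-mers are
#' removed, the rest are copied to the clean output byte-identically and
#' in input order.  With a mate file, removal is all-or-nothing per spot:
#' if either mate matches, both are removed.
#'
#' @param input FASTQ path (optionally gzipped).
#' @param db the subtraction database: a [taxon_kmer_set()], a
#'   `kmer_lookup`, or a dbs file path.
#' @param out clean-output path (default `<input>.clean`).
#' @param min_hits matching k-mers required to remove a spot (default 1,
#'   the aggressive setting appropriate for privacy scrubbing).
#' @param mate_input,mate_out optional second-mate FASTQ in/out paths.
#' @param k k-mer length (default 32).
#' @return invisible list of class `scrub_result`: `total_spots`,
#'   `removed_spots`, `retained_spots`, `output` (and `mate_output`).  A
#'   summary line `total/removed/retained` is emitted as a message.
#' @export
scrub_fastq <- function(input, db, out = paste0(input, ".clean"),
                        min_hits = 1L, mate_input = NULL, mate_out = NULL,
                        k = 32L) {
  stopifnot(min_hits >= 1)
  if (inherits(db, "taxon_kmer_set")) db <- as_kmer_lookup(db)
  if (is.character(db)) db <- read_dbs(db)
  r1 <- .read_fastq_records(input)
  r2 <- NULL
  if (!is.null(mate_input)) {
    r2 <- .read_fastq_records(mate_input)
    if (r2$n != r1$n)
      stop("mate FASTQ has ", r2$n, " spots but input has ", r1$n)
    if (is.null(mate_out)) mate_out <- paste0(mate_input, ".clean")
  }
  nhit <- vapply(seq_len(r1$n), function(i) {
    reads <- c(r1$seq[i], if (!is.null(r2)) r2$seq[i])
    q <- spot_query_kmers(reads, k = k)
    sum(!is.na(lookup_taxids(db, q)))
  }, integer(1))
  keep <- nhit < min_hits

  emit <- function(r, idx, path) {
    m <- rbind(r$hdr[idx], r$seq[idx], r$plus[idx], r$qual[idx])
    writeLines(as.vector(m), path)
  }
  emit(r1, keep, out)
  if (!is.null(r2)) emit(r2, keep, mate_out)

  res <- structure(list(total_spots = r1$n,
                        removed_spots = sum(!keep),
                        retained_spots = sum(keep),
                        output = out, mate_output = mate_out),
                   class = "scrub_result")
  message(sprintf("scrub: %d/%d/%d total/removed/retained",
                  res$total_spots, res$removed_spots, res$retained_spots))
  invisible(res)
}

#' @export
print.scrub_result <- function(x, ...) {
  cat(sprintf("scrub_result: %d spots, %d removed, %d retained -> %s\n",
              x$total_spots, x$removed_spots, x$retained_spots, x$output))
  invisible(x)
}
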