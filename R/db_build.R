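#' A deduplicated set of canonical k-mers attached to one TaxId
#'
#' @param taxid positive integer TaxId.
#' @param kmers character vector of packed canonical k-mers (16-hex-digit);
#'   duplicates are dropped and the set is kept sorted.
#' @param k k-mer length the set was built with.
#' @return an object of class `taxon_kmer_set`.
#' @export
taxon_kmer_set <- function(taxid, kmers = character(0), k = 32L) {
  structure(list(taxid = as.integer(taxid),
                 kmers = sort(unique(as.character(kmers)), method = "radix"),
                 k = as.integer(k)),
            class = "taxon_kmer_set")
}

#' @export
print.taxon_kmer_set <- function(x, ...) {
  cat("taxon_kmer_set: TaxId", x$taxid, "-", length(x$kmers),
      sprintf("%d-mers\n", x$k))
  invisible(x)
}

.as_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  as.character(x)
}

#' Build the minimizer k-mer set of one taxon
#'
#' Runs [minimize_sequence()] over every input sequence and takes the
#' union of the selected k-mers.
#'
#' @param sequences a character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a path to a (optionally gzipped) FASTA
#'   file.
#' @param taxid the TaxId the sequences are assigned to.
#' @param window minimizer window size W in bases.
#' @param k k-mer length (default 32).
#' @return a [taxon_kmer_set()].
#' @export
build_taxon_set <- function(sequences, taxid, window, k = 32L) {
  seqs <- .as_sequences(sequences)
  if (length(seqs) == 0) warning("no input sequences for TaxId ", taxid)
  km <- unlist(lapply(seqs, kt_minimize, W = as.integer(window),
                      k = as.integer(k)), use.names = FALSE)
  taxon_kmer_set(taxid, km, k = k)
}

#' Window size for a taxon by database mode
#'
#' Dense databases use a 64 bp window for every super-kingdom.  Sparse
#' (screening) databases use 64 bp for Viruses, 2000 bp for Bacteria and
#' Archaea, and 8000 bp for Eukaryota, roughly proportional to genome
#' size.
#'
#' @param tree a `tax_tree` with declared super-kingdom roots.
#' @param taxid the taxon whose window is wanted.
#' @param mode `"sparse"` or `"dense"`.
#' @param default window returned (with a warning) when the taxon is under
#'   no declared super-kingdom.
#' @return window size in bases.
#' @export
window_for <- function(tree, taxid, mode = c("dense", "sparse"),
                       default = 64L) {
  mode <- match.arg(mode)
  if (mode == "dense") return(64L)
  sk <- superkingdom_of(tree, taxid)
  if (is.na(sk)) {
    warning("TaxId ", taxid, " is under no declared super-kingdom; ",
            "using window ", default)
    return(as.integer(default))
  }
  switch(sk,
         Viruses = 64L,
         Bacteria = 2000L,
         Archaea = 2000L,
         Eukaryota = 8000L)
}

#' Merge per-taxon k-mer sets up the taxonomy
#'
#' Every k-mer in the input union is reassigned to the lowest common
#' ancestor of all the nodes whose sets contain it: k-mers unique to one
#' taxon stay there as diagnostic, k-mers shared by sibling species move
#' up to their common parent, and k-mers shared across super-kingdoms end
#' at the global root.  No k-mer is lost or duplicated.
#'
#' @param tree a `tax_tree`.
#' @param sets a list of [taxon_kmer_set()] objects (every TaxId must be
#'   in the tree).
#' @return a named list of `taxon_kmer_set` objects keyed by TaxId,
#'   containing every node that owns at least one k-mer after merging.
#' @export
merge_tree <- function(tree, sets) {
  if (inherits(sets, "taxon_kmer_set")) sets <- list(sets)
  taxids <- vapply(sets, function(s) s$taxid, integer(1))
  .tax_idx(tree, taxids)
  k <- if (length(sets)) sets[[1]]$k else 32L
  km <- unlist(lapply(sets, function(s) s$kmers), use.names = FALSE)
  tx <- rep(taxids, vapply(sets, function(s) length(s$kmers), integer(1)))
  # a k-mer may sit in several sets of the same taxid; collapse pairs first
  pair <- !duplicated(paste(km, tx))
  km <- km[pair]; tx <- tx[pair]

  owners <- split(tx, km)
  combo <- vapply(owners, function(t)
    paste(sort(t), collapse = ","), character(1))
  lca_of <- vapply(unique(combo), function(cb) {
    ids <- as.integer(strsplit(cb, ",", fixed = TRUE)[[1]])
    if (length(ids) == 1L) ids else tax_lca(tree, ids)
  }, integer(1))
  assigned <- unname(lca_of[combo])

  out <- split(names(owners), assigned)
  res <- lapply(names(out), function(t)
    taxon_kmer_set(as.integer(t), out[[t]], k = k))
  stats::setNames(res, names(out))
}

#' Remove low-complexity k-mers from a taxon set
#'
#' Deletes any k-mer in which a single homopolymer run or a single perfect
#' dinucleotide tandem repeat (two distinct alternating bases) spans
#' strictly more than 50% of the k-mer (more than 16 of 32 bases).
#'
#' @param set a [taxon_kmer_set()].
#' @return the filtered `taxon_kmer_set`.
#' @export
filter_low_complexity <- function(set) {
  keep <- !kt_low_complexity(set$kmers, set$k)
  taxon_kmer_set(set$taxid, set$kmers[keep], k = set$k)
}

#' Subtract an exclusion k-mer set from a taxon set
#'
#' @param set a [taxon_kmer_set()].
#' @param exclude character vector of packed k-mers to remove (or a
#'   `taxon_kmer_set`).
#' @return the reduced `taxon_kmer_set`.
#' @export
subtract_kmers <- function(set, exclude) {
  if (inherits(exclude, "taxon_kmer_set")) exclude <- exclude$kmers
  taxon_kmer_set(set$taxid, setdiff(set$kmers, exclude), k = set$k)
}

.flatten_sets <- function(sets) {
  if (inherits(sets, "taxon_kmer_set")) sets <- list(sets)
  km <- unlist(lapply(sets, function(s) s$kmers), use.names = FALSE)
  tx <- rep(vapply(sets, function(s) s$taxid, integer(1)),
            vapply(sets, function(s) length(s$kmers), integer(1)))
  if (anyDuplicated(km))
    stop("duplicate k-mer across taxa; run merge_tree() first")
  o <- order(km, method = "radix")
  list(kmer = unname(km[o]), taxid = unname(tx[o]))
}

#' Write merged k-mer sets as a binary dbs database
#'
#' Each record is 12 bytes: the 8-byte little-endian packed k-mer followed
#' by the 4-byte little-endian TaxId; records are sorted ascending by
#' k-mer so the file is binary-searchable.
#'
#' @param sets a `taxon_kmer_set` or list of them, post-merge (each k-mer
#'   at exactly one node; duplicates across nodes raise an error).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dbs <- function(sets, path) {
  fl <- .flatten_sets(sets)
  kt_write_dbs(path, fl$kmer, fl$taxid)
  invisible(path)
}

#' Read a dbs database into a k-mer lookup
#'
#' @param path path to a dbs file.
#' @return an object of class `kmer_lookup`: list with `kmer` (sorted
#'   packed k-mers) and `taxid` (parallel integer vector).  Corrupt files
#'   (size not a multiple of 12, unsorted records) raise an error.
#' @export
read_dbs <- function(path) {
  structure(kt_read_dbs(path), class = "kmer_lookup")
}

#' @export
print.kmer_lookup <- function(x, ...) {
  cat("kmer_lookup:", length(x$kmer), "k-mers,",
      length(unique(x$taxid)), "TaxIds\n")
  invisible(x)
}

#' Build an in-memory lookup from k-mer sets without touching disk
#' @inheritParams write_dbs
#' @return a `kmer_lookup`.
#' @export
as_kmer_lookup <- function(sets) {
  structure(.flatten_sets(sets), class = "kmer_lookup")
}

#' Split a lookup back into per-TaxId k-mer sets
#' @param lookup a `kmer_lookup`.
#' @param k k-mer length recorded on the resulting sets.
#' @return named list of [taxon_kmer_set()] keyed by TaxId.
#' @export
kmer_sets <- function(lookup, k = 32L) {
  spl <- split(lookup$kmer, lookup$taxid)
  lapply(stats::setNames(names(spl), names(spl)), function(t)
    taxon_kmer_set(as.integer(t), spl[[t]], k = k))
}

#' Look up the TaxId assigned to each query k-mer
#' @param lookup a `kmer_lookup`.
#' @param kmers character vector of packed canonical k-mers.
#' @return integer vector of TaxIds, `NA` where a k-mer is absent.
#' @export
lookup_taxids <- function(lookup, kmers) {
  lookup$taxid[match(kmers, lookup$kmer)]
}

#' Convert a dbs database to the k-mer-only dbss layout
#'
#' The dbss layout stores only the 8-byte k-mers -- a 33% size reduction
#' over the 12-byte dbs records -- grouped by TaxId (groups in ascending
#' TaxId order, k-mers ascending within each group), with an annotation
#' sidecar of `TaxId<TAB>count` lines in the same order.  Cumulative
#' counts give the byte offset of each TaxId's slice.
#'
#' @param dbs_path path to the input dbs file.
#' @param out_prefix output prefix: writes `<prefix>.dbss` and
#'   `<prefix>.dbss.annotation`.
#' @return invisible list with `kmer_path`, `annotation_path`, and the
#'   byte sizes of the dbs and dbss k-mer files.
#' @export
dbs_to_dbss <- function(dbs_path, out_prefix) {
  db <- kt_read_dbs(dbs_path)
  kmer_path <- paste0(out_prefix, ".dbss")
  annot_path <- paste0(out_prefix, ".dbss.annotation")
  o <- order(db$taxid, db$kmer, method = "radix")
  kt_write_u64(kmer_path, db$kmer[o])
  tx <- db$taxid[o]
  counts <- rle(tx)
  writeLines(paste(counts$values, counts$lengths, sep = "\t"), annot_path)
  invisible(list(kmer_path = kmer_path, annotation_path = annot_path,
                 dbs_bytes = file.size(dbs_path),
                 dbss_bytes = file.size(kmer_path)))
}

.read_annotation <- function(annot_path) {
  if (file.size(annot_path) == 0)
    return(data.frame(taxid = integer(0), count = numeric(0)))
  utils::read.table(annot_path, header = FALSE, sep = "\t",
                    col.names = c("taxid", "count"),
                    colClasses = c("integer", "numeric"))
}

#' Load only selected TaxIds' k-mers from a dbss database
#'
#' Uses the annotation counts as byte offsets to read just the requested
#' TaxIds' slices of the k-mer file.
#'
#' @param kmer_path path to the dbss k-mer file.
#' @param annotation_path path to its annotation sidecar.
#' @param taxids TaxIds to load; ids absent from the annotation are
#'   skipped with a warning.  `NULL` loads everything.
#' @param warn_missing warn about requested TaxIds absent from the
#'   annotation (interior tree nodes legitimately own no k-mers, so
#'   pipeline callers disable this).
#' @return a `kmer_lookup` identical to filtering a full load.
#' @export
read_dbss_slice <- function(kmer_path, annotation_path, taxids = NULL,
                            warn_missing = TRUE) {
  ann <- .read_annotation(annotation_path)
  offset <- cumsum(c(0, ann$count))[seq_len(nrow(ann))]
  if (is.null(taxids)) taxids <- ann$taxid
  taxids <- unique(as.integer(taxids))
  missing <- setdiff(taxids, ann$taxid)
  if (length(missing) && warn_missing)
    warning("TaxIds absent from dbss annotation, skipped: ",
            paste(utils::head(missing, 10), collapse = ", "))
  rows <- which(ann$taxid %in% taxids)
  km <- character(0); tx <- integer(0)
  for (r in rows) {
    slice <- kt_read_u64(kmer_path, offset[r], ann$count[r])
    km <- c(km, slice)
    tx <- c(tx, rep(ann$taxid[r], length(slice)))
  }
  o <- order(km, method = "radix")
  structure(list(kmer = km[o], taxid = tx[o]), class = "kmer_lookup")
}

#' Build a merged taxonomic k-mer database from a manifest
#'
#' End-to-end builder: per-taxon minimizer sets (window chosen per
#' super-kingdom by `mode`, or fixed by `window`), the low-complexity
#' filter, the LCA merge up the taxonomy, and optional dbs serialization.
#'
#' @param manifest a data.frame with columns `taxid` and `fasta` (or a
#'   path to a two-column TSV), one row per taxon.
#' @param tree a `tax_tree` containing every manifest TaxId.
#' @param mode `"dense"` (64 bp windows) or `"sparse"` (64/2000/8000 bp
#'   by super-kingdom); see [window_for()].
#' @param window fixed window override applied to every taxon (e.g. 1 for
#'   a complete non-redundant k-mer set build).
#' @param filter apply [filter_low_complexity()] before merging.
#' @param merge merge k-mer sets up the tree (see [merge_tree()]).
#' @param path optional dbs output path.
#' @param k k-mer length (default 32).
#' @return named list of post-merge [taxon_kmer_set()] keyed by TaxId.
#' @export
build_database <- function(manifest, tree, mode = c("dense", "sparse"),
                           window = NULL, filter = TRUE, merge = TRUE,
                           path = NULL, k = 32L) {
  mode <- match.arg(mode)
  if (is.character(manifest))
    manifest <- utils::read.table(manifest, header = FALSE, sep = "\t",
                                  col.names = c("taxid", "fasta"),
                                  colClasses = c("integer", "character"))
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    t <- manifest$taxid[i]
    W <- if (is.null(window)) window_for(tree, t, mode) else window
    s <- build_taxon_set(manifest$fasta[i], taxid = t, window = W, k = k)
    if (filter) s <- filter_low_complexity(s)
    s
  })
  merged <- if (merge) merge_tree(tree, sets)
            else stats::setNames(sets, vapply(sets, `[[`, 0L, "taxid"))
  if (!is.null(path)) write_dbs(merged, path)
  merged
}
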