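#' Screening thresholds for the first-pass sparse query
#'
#' A species is flagged for the quantitative second pass when it has
#' strictly more than 100 biological reads (Eukaryota), strictly more than
#' 10 (Bacteria, Archaea), or at least 1 (Viruses).
#'
#' @param eukaryote_min_reads,prokaryote_min_reads reads strictly above
#'   which a eukaryotic / prokaryotic species is selected.
#' @param virus_min_reads reads at or above which a viral species is
#'   selected.
#' @return a named list of thresholds.
#' @export
screen_thresholds <- function(eukaryote_min_reads = 100L,
                              prokaryote_min_reads = 10L,
                              virus_min_reads = 1L) {
  stopifnot(eukaryote_min_reads > 0, prokaryote_min_reads > 0,
            virus_min_reads > 0)
  list(eukaryote_min_reads = as.integer(eukaryote_min_reads),
       prokaryote_min_reads = as.integer(prokaryote_min_reads),
       virus_min_reads = as.integer(virus_min_reads))
}

#' Resolve a spot's hit set to a single taxon
#'
#' Keeps only the leaf-most hits (hit TaxIds with no other hit strictly
#' below them) and returns their lowest common ancestor -- conservatively
#' the most proximal unambiguous node.  A coherent lineage chain such as
#' {Mus musculus, Murinae, Mammalia} therefore resolves to the deepest
#' member, while hits to two sibling species resolve to their common
#' genus.
#'
#' @param hits named integer vector of per-TaxId k-mer hit counts (as from
#'   [match_spot()]), or a vector of hit TaxIds; must be nonempty.
#' @param tree a `tax_tree` containing every hit TaxId.
#' @return the resolved TaxId.
#' @export
resolve_spot <- function(hits, tree) {
  ids <- if (!is.null(names(hits))) as.integer(names(hits))
         else as.integer(hits)
  ids <- unique(ids)
  stopifnot(length(ids) >= 1)
  if (length(ids) == 1L) {
    .tax_idx(tree, ids)
    return(ids)
  }
  lins <- lapply(ids, function(t) tax_lineage(tree, t))
  # leaf-most: no other hit has this id as a strict ancestor
  is_below_other <- vapply(seq_along(ids), function(i)
    any(vapply(seq_along(ids), function(j)
      j != i && ids[i] %in% lins[[j]][-1], logical(1))), logical(1))
  tax_lca(tree, ids[!is_below_other])
}

#' Aggregate resolved spots into a run-level taxonomic report
#'
#' For every taxonomy node with at least one spot in its subtree the
#' report gives the spots resolved exactly to it (`self_count`), the
#' spots in its whole subtree (`total_count` -- never less than any
#' child's), and `self_percent`, the share of all resolved spots.
#'
#' @param resolved integer vector of resolved TaxIds, one per spot.
#' @param tree a `tax_tree`.
#' @return a `data.frame` with columns `taxid`, `rank`, `name`,
#'   `self_count`, `total_count`, `self_percent`, ordered root-first by
#'   depth then TaxId.
#' @export
aggregate_run <- function(resolved, tree) {
  resolved <- as.integer(resolved)
  n <- length(resolved)
  self <- stats::setNames(rep(0L, length(tree$ids)), tree$ids)
  if (n) {
    tab <- table(resolved)
    .tax_idx(tree, as.integer(names(tab)))
    self[names(tab)] <- as.integer(tab)
  }
  total <- self
  for (t in tax_postorder(tree)) {
    p <- tree$parent[.tax_idx(tree, t)]
    if (p != t)
      total[as.character(p)] <- total[as.character(p)] + total[as.character(t)]
  }
  keep <- total > 0L
  ids <- tree$ids[keep]
  i <- .tax_idx(tree, ids)
  out <- data.frame(
    taxid = ids,
    rank = tree$rank[i],
    name = ifelse(is.na(tree$name[i]), as.character(ids), tree$name[i]),
    self_count = unname(self[keep]),
    total_count = unname(total[keep]),
    self_percent = if (n) unname(self[keep]) / n * 100 else numeric(sum(keep)),
    stringsAsFactors = FALSE)
  out[order(tree$depth[i], out$taxid), , drop = FALSE]
}

#' Write a run report as TSV
#'
#' @param report a report from [aggregate_run()].
#' @param path output path; percentages are written with 2 decimal places
#'   and a `.` decimal separator.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  report$self_percent <- sprintf("%.2f", report$self_percent)
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Species nodes of a taxonomy
#'
#' Nodes whose rank is `"species"`; when the tree carries no rank
#' metadata, the leaves are used.
#'
#' @param tree a `tax_tree`.
#' @return integer vector of species TaxIds.
#' @export
tax_species <- function(tree) {
  sp <- tree$ids[!is.na(tree$rank) & tree$rank == "species"]
  if (length(sp)) sp else tax_leaves(tree)
}

#' Per-species biological read counts from resolved spots
#'
#' A spot counts toward a species when its resolved taxon lies in that
#' species' subtree (strain and subspecies resolutions count toward the
#' species).
#'
#' @param resolved integer vector of resolved TaxIds.
#' @param tree a `tax_tree`.
#' @param species species TaxIds to count (default [tax_species()]).
#' @return named integer vector of read counts keyed by species TaxId.
#' @export
species_read_counts <- function(resolved, tree, species = tax_species(tree)) {
  resolved <- as.integer(resolved)
  counts <- vapply(species, function(sp)
    sum(resolved %in% tax_subtree(tree, sp)), integer(1))
  stats::setNames(counts, species)
}

#' First-pass selection of species from sparse-screen read counts
#'
#' Applies the per-super-kingdom read-count thresholds (see
#' [screen_thresholds()]) to per-species counts from the sparse screening
#' database.
#'
#' @param counts named numeric vector of biological read counts keyed by
#'   species TaxId (see [species_read_counts()]).
#' @param tree a `tax_tree` with declared super-kingdom roots.
#' @param thresholds a [screen_thresholds()] list.
#' @return integer vector of selected species TaxIds.
#' @export
first_pass_select <- function(counts, tree,
                              thresholds = screen_thresholds()) {
  ids <- as.integer(names(counts))
  sel <- vapply(seq_along(ids), function(i) {
    sk <- superkingdom_of(tree, ids[i])
    n <- counts[i]
    if (is.na(sk)) return(FALSE)
    switch(sk,
           Eukaryota = n > thresholds$eukaryote_min_reads,
           Bacteria = ,
           Archaea = n > thresholds$prokaryote_min_reads,
           Viruses = n >= thresholds$virus_min_reads)
  }, logical(1))
  ids[sel]
}

#' Expand selected species into the TaxId list for the dense pass
#'
#' For each selected TaxId takes its whole subtree (to regain strain-level
#' k-mers) plus its ancestors up to the root (merged k-mers live at
#' interior nodes), then removes any explicitly excluded TaxIds -- e.g.
#' contamination identified during screening that should be withheld.
#'
#' @param selected integer vector of selected TaxIds.
#' @param tree a `tax_tree`.
#' @param exclusions TaxIds to withhold along with their subtrees.
#' @return sorted integer vector of TaxIds to load from the dbss database.
#' @export
expand_selection <- function(selected, tree, exclusions = integer(0)) {
  selected <- as.integer(selected)
  if (!length(selected)) return(integer(0))
  ids <- unique(unlist(lapply(selected, function(t)
    c(tax_subtree(tree, t), tax_lineage(tree, t)))))
  if (length(exclusions)) {
    drop <- unique(unlist(lapply(as.integer(exclusions), function(t)
      tax_subtree(tree, t))))
    ids <- setdiff(ids, drop)
  }
  sort(ids)
}

#' Two-phase sparse/dense classification of a sequencing run
#'
#' Phase 1 queries every spot against the sparse screening database,
#' resolves each spot, and selects species passing the per-kingdom read
#' thresholds.  Phase 2 loads only the selected TaxIds' k-mers from the
#' dense dbss database, re-queries the same spots quantitatively, resolves
#' them, and aggregates the run report.
#'
#' @param input reads path or spot list (see [run_aligns_to()]).
#' @param sparse_db sparse database: a `kmer_lookup` or dbs path.
#' @param dense_dbss,dense_annotation paths of the dense dbss k-mer file
#'   and its annotation sidecar.
#' @param tree a `tax_tree`.
#' @param thresholds a [screen_thresholds()] list.
#' @param exclusions TaxIds withheld from the dense pass.
#' @param mate_path optional second-mate reads file.
#' @param k k-mer length (default 32).
#' @return list with `report` (see [aggregate_run()]), `resolved` (named
#'   integer vector of per-spot taxa from the dense pass), `selected`
#'   (phase-1 species), and `tax_list` (TaxIds loaded in phase 2).  An
#'   empty selection yields an empty report: nothing detected.
#' @export
two_phase_classify <- function(input, sparse_db, dense_dbss,
                               dense_annotation, tree,
                               thresholds = screen_thresholds(),
                               exclusions = integer(0), mate_path = NULL,
                               k = 32L) {
  spots <- if (is.list(input)) input else read_spots(input, mate_path)
  h1 <- run_aligns_to(spots, db = sparse_db, k = k)
  r1 <- vapply(h1, resolve_spot, integer(1), tree = tree)
  counts <- species_read_counts(r1, tree)
  selected <- first_pass_select(counts, tree, thresholds)
  tax_list <- expand_selection(selected, tree, exclusions)
  empty <- list(report = aggregate_run(integer(0), tree),
                resolved = stats::setNames(integer(0), character(0)),
                selected = selected, tax_list = tax_list)
  if (!length(tax_list)) return(empty)
  h2 <- run_aligns_to(spots, dbss = dense_dbss,
                      annotation = dense_annotation, tax_list = tax_list,
                      k = k, warn_missing = FALSE)
  if (!length(h2)) return(empty)
  r2 <- vapply(h2, resolve_spot, integer(1), tree = tree)
  list(report = aggregate_run(r2, tree), resolved = r2,
       selected = selected, tax_list = tax_list)
}
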