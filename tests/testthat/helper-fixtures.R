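# fixtures and independent oracles shared across the suite

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

str_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# brute-force minimizer: enumerate every candidate substring, canonicalize
# and hash via the scalar primitives, pick min hash (ties: canon, position)
oracle_window_min <- function(seq, start, W, k = 32L) {
  len <- nchar(seq)
  pos <- seq(start, start + W - 1L)
  pos <- pos[pos + k <= len]
  if (!length(pos)) return(NA_character_)
  cand <- substring(seq, pos + 1L, pos + k)
  enc <- encode_kmer(cand, k)
  keep <- !is.na(enc)
  if (!any(keep)) return(NA_character_)
  canon <- canonical_kmer(enc[keep], k)
  h <- fnv1_64(canon)
  canon[order(h, canon, pos[keep])[1]]
}

# random rooted tree: node 1 is root, each later node's parent drawn
# among earlier nodes
random_tree <- function(n, superkingdoms = integer(0)) {
  child <- seq_len(n)
  parent <- c(1L, vapply(2:n, function(i)
    sample.int(i - 1L, 1), integer(1)))
  tax_tree(child, parent, superkingdoms = superkingdoms)
}

oracle_lineage <- function(tree, t) {
  out <- t
  repeat {
    p <- tree$parent[match(t, tree$ids)]
    if (p == t) break
    out <- c(out, p)
    t <- p
  }
  out
}

oracle_lca <- function(tree, ids) {
  lins <- lapply(ids, oracle_lineage, tree = tree)
  common <- Reduce(intersect, lins)
  common[1]  # lineages list deepest first
}

random_kmers <- function(n) {
  unique(vapply(seq_len(n), function(i)
    paste(sample(c(0:9, letters[1:6]), 16, replace = TRUE), collapse = ""),
    character(1)))
}

# two kingdoms, two genera each, two species per genus; fixed seed
toy_world <- function(seed = 7L, genome_length = 20000L,
                      mutation_rate = 0.02) {
  simulate_world(kingdoms = c("Bacteria", "Viruses"), n_genera = 2L,
                 species_per_genus = 2L, genome_length = genome_length,
                 mutation_rate = mutation_rate, seed = seed)
}

# embed a repeat run of exactly r bases inside complex flanks, 32 bases
# total; the GGT flank pattern cannot extend an A-homopolymer or an
# AC-dinucleotide run at either junction
embed_run <- function(r, unit = c("A", "AC")) {
  unit <- match.arg(unit)
  run <- substr(strrep(unit, 32L), 1L, r)
  flank <- strrep("GGT", 12L)
  nl <- (32L - r) %/% 2L
  nr <- 32L - r - nl
  paste0(substr(flank, 1L, nl), run, substr(flank, 1L, nr))
}

# brute-force resolver: LCA of hits that are maximal under the
# descendant ordering
oracle_resolve <- function(ids, tree) {
  ids <- unique(ids)
  leafmost <- Filter(function(t)
    !any(vapply(setdiff(ids, t), function(u)
      t %in% oracle_lineage(tree, u)[-1], logical(1))), ids)
  oracle_lca(tree, leafmost)
}
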