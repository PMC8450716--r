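.BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  if (length(hit)) {
    repl <- vapply(b[hit], function(x)
      sample(setdiff(.BASES, x), 1), character(1))
    b[hit] <- repl
  }
  paste(b, collapse = "")
}

#' Simulate a toy taxonomic world: tree, genomes, metadata
#'
#' Builds a taxonomy of a global root (TaxId 1), the requested
#' super-kingdom roots (reusing the real root TaxIds so window sizes and
#' screening thresholds apply unchanged), genera under each kingdom, and
#' species leaves under each genus.  Each genus has a random ancestral
#' genome; its species' genomes are derived from it by per-base
#' substitution at `mutation_rate`, so sibling species share k-mers and
#' exercise the merge step.  Everything is reproducible from `seed`.
#'
#' @param kingdoms super-kingdom names to include (subset of
#'   `names(default_superkingdoms())`).
#' @param n_genera genera per kingdom.
#' @param species_per_genus species leaves per genus.
#' @param genome_length genome length in bases; a single number, or a
#'   named vector per kingdom (viral genomes are typically much shorter).
#' @param mutation_rate per-base substitution rate between a species
#'   genome and its genus ancestor (0 = identical siblings).
#' @param seed RNG seed.
#' @return an object of class `synthetic_world`: list with `tree` (a
#'   `tax_tree` with names and ranks), `genomes` (named character vector
#'   keyed by species TaxId), and `seed`.
#' @export
simulate_world <- function(kingdoms = c("Bacteria", "Viruses"),
                           n_genera = 3L, species_per_genus = 2L,
                           genome_length = 20000L, mutation_rate = 0.02,
                           seed = 1L) {
  sk <- default_superkingdoms()
  stopifnot(all(kingdoms %in% names(sk)), n_genera >= 1,
            species_per_genus >= 1, all(genome_length >= 64))
  glen <- if (length(genome_length) == 1)
    stats::setNames(rep(genome_length, length(kingdoms)), kingdoms)
  else genome_length[kingdoms]

  set.seed(seed)
  child <- 1L; parent <- 1L
  name <- "root"; rank <- "no rank"
  genomes <- character(0)
  next_id <- 1000L
  for (kg in kingdoms) {
    child <- c(child, sk[[kg]]); parent <- c(parent, 1L)
    name <- c(name, kg); rank <- c(rank, "superkingdom")
    for (g in seq_len(n_genera)) {
      gid <- next_id; next_id <- next_id + 1L
      child <- c(child, gid); parent <- c(parent, sk[[kg]])
      name <- c(name, sprintf("%s_genus_%d", kg, g))
      rank <- c(rank, "genus")
      ancestor <- random_dna(glen[[kg]])
      for (s in seq_len(species_per_genus)) {
        sid <- next_id; next_id <- next_id + 1L
        child <- c(child, sid); parent <- c(parent, gid)
        name <- c(name, sprintf("%s_species_%d_%d", kg, g, s))
        rank <- c(rank, "species")
        genomes[as.character(sid)] <- mutate_seq(ancestor, mutation_rate)
      }
    }
  }
  structure(list(tree = tax_tree(child, parent, name = name, rank = rank),
                 genomes = genomes, seed = as.integer(seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", length(x$tree$ids), "taxa,",
      length(x$genomes), "genomes, seed", x$seed, "\n")
  invisible(x)
}

#' Simulate sequencing reads from a genome
#'
#' Uniform start positions, random strand, independent per-base
#' substitution errors at `error_rate`, fixed quality string.
#' Intentionally simpler than a full read simulator: no indels, no
#' quality model.
#'
#' @param genome a single genome sequence.
#' @param n number of reads (spots).
#' @param read_length read length in bases (must not exceed the genome).
#' @param error_rate per-base substitution error probability.
#' @param seed RNG seed.
#' @param prefix read id prefix.
#' @param paired also emit a second mate read from the opposite end of a
#'   fragment of `2 * read_length` bases.
#' @return data.frame with columns `id`, `seq`, `start` (1-based fragment
#'   start), `strand` (and `seq2` when paired).
#' @export
simulate_reads <- function(genome, n, read_length = 100L, error_rate = 0,
                           seed = 1L, prefix = "read", paired = FALSE) {
  glen <- nchar(genome)
  stopifnot(read_length <= glen)
  set.seed(seed)
  if (n == 0)
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  span <- if (paired) 2L * read_length else read_length
  span <- min(span, glen)
  start <- sample.int(glen - span + 1L, n, replace = TRUE)
  fwd <- stats::runif(n) < 0.5

  one_read <- function(s) {
    r <- substr(genome, s, s + read_length - 1L)
    mutate_seq(r, error_rate)
  }
  revcomp_str <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(s, function(x)
             paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
             character(1), USE.NAMES = FALSE))
  }
  r1 <- vapply(start, one_read, character(1))
  r1[!fwd] <- revcomp_str(r1[!fwd])
  out <- data.frame(id = sprintf("%s_%d", prefix, seq_len(n)), seq = r1,
                    start = start, strand = ifelse(fwd, "+", "-"),
                    stringsAsFactors = FALSE)
  if (paired) {
    s2 <- start + span - read_length
    r2 <- vapply(s2, one_read, character(1))
    r2[fwd] <- revcomp_str(r2[fwd])
    out$seq2 <- r2
  }
  out
}

#' Write simulated reads as FASTQ
#'
#' @param reads a data.frame from [simulate_reads()].
#' @param path FASTQ output path.
#' @param mate_path second-mate path, required when `reads` is paired.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, mate_path = NULL) {
  emit <- function(seqs, ids, p) {
    qual <- vapply(nchar(seqs), function(n)
      strrep("I", n), character(1))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", qual)), p)
  }
  emit(reads$seq, reads$id, path)
  if (!is.null(reads$seq2)) {
    if (is.null(mate_path)) stop("paired reads need a mate_path")
    emit(reads$seq2, reads$id, mate_path)
  }
  invisible(path)
}

#' Write a synthetic world to disk as package-standard fixtures
#'
#' Emits `parents.tsv`, `names.tsv`, one FASTA per species genome, and a
#' build manifest `manifest.tsv` (`TaxId<TAB>fasta`).
#'
#' @param world a [simulate_world()] result.
#' @param dir output directory (created if needed).
#' @return invisible list of the written paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parents <- file.path(dir, "parents.tsv")
  namesp <- file.path(dir, "names.tsv")
  write_parents(world$tree, parents, names_path = namesp)
  fasta <- vapply(names(world$genomes), function(t) {
    p <- file.path(dir, sprintf("taxon_%s.fasta", t))
    writeLines(c(sprintf(">taxon_%s", t), world$genomes[[t]]), p)
    p
  }, character(1))
  manifest <- file.path(dir, "manifest.tsv")
  writeLines(paste(names(world$genomes), fasta, sep = "\t"), manifest)
  invisible(list(parents = parents, names = namesp, manifest = manifest,
                 fasta = fasta))
}

#' Classification accuracy metrics from confusion counts
#'
#' The strain-exclusion convention distinguishes vague positives (VP):
#' reads assigned to a correct but higher-than-evaluation-rank ancestor.
#' Sensitivity = TP/(TP+VP+FN+FP); PPV = TP/(TP+FP); Recall = TP/(TP+FN);
#' F1 = 2 PPV Recall / (PPV + Recall).
#'
#' @param counts a named list or vector with elements `TP`, `TN`, `FP`,
#'   `FN`, `VP` (missing elements default to 0).
#' @return named list `sensitivity`, `ppv`, `recall`, `f1`; a metric with
#'   zero denominator is `NA`, except F1 which is guarded to 0 when TP is
#'   0 but some reads were classified.
#' @export
accuracy_metrics <- function(counts) {
  g <- function(nm) {
    v <- if (is.list(counts)) counts[[nm]] else unname(counts[nm])
    if (is.null(v) || length(v) != 1 || is.na(v)) 0 else as.numeric(v)
  }
  TP <- g("TP"); TN <- g("TN"); FP <- g("FP"); FN <- g("FN"); VP <- g("VP")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(TP, TP + VP + FN + FP)
  ppv <- rat(TP, TP + FP)
  recall <- rat(TP, TP + FN)
  f1 <- if (is.na(ppv) && is.na(recall)) {
    NA_real_
  } else {
    p <- if (is.na(ppv)) 0 else ppv
    r <- if (is.na(recall)) 0 else recall
    if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  list(sensitivity = sens, ppv = ppv, recall = recall, f1 = f1)
}

#' Categorize classifier output for a strain-exclusion evaluation
#'
#' For each read with a known source taxon, the truth is the source's
#' ancestor at `rank`; the prediction is TP when it equals the truth or
#' lies in its subtree, VP when it is a strict ancestor of the truth
#' (correct but vague), FP otherwise, and FN when the read is
#' unclassified.  Negative-control reads (source `NA`) are TN when
#' unclassified and FP when classified.  Reads whose lineage lacks the
#' evaluation rank are skipped and counted.
#'
#' @param truth integer vector of source TaxIds per read (`NA` for
#'   negative controls).
#' @param predicted integer vector of classifier output per read (`NA`
#'   when unclassified).
#' @param tree a `tax_tree` with rank metadata.
#' @param rank evaluation rank (default `"genus"`).
#' @return named integer vector with elements `TP`, `TN`, `FP`, `FN`,
#'   `VP`, `skipped`.
#' @export
strain_exclusion_eval <- function(truth, predicted, tree, rank = "genus") {
  stopifnot(length(truth) == length(predicted))
  rank_node <- function(t) {
    lin <- tax_lineage(tree, t)
    r <- tree$rank[.tax_idx(tree, lin)]
    lin[which(!is.na(r) & r == rank)[1]]
  }
  out <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L, VP = 0L, skipped = 0L)
  for (i in seq_along(truth)) {
    if (is.na(truth[i])) {
      out[if (is.na(predicted[i])) "TN" else "FP"] <-
        out[if (is.na(predicted[i])) "TN" else "FP"] + 1L
      next
    }
    tn <- rank_node(truth[i])
    if (is.na(tn)) { out["skipped"] <- out["skipped"] + 1L; next }
    p <- predicted[i]
    cat_i <- if (is.na(p)) "FN"
    else if (tn %in% tax_lineage(tree, p)) "TP"      # truth is ancestor-or-self
    else if (p %in% tax_lineage(tree, tn)[-1]) "VP"  # strict ancestor of truth
    else "FP"
    out[cat_i] <- out[cat_i] + 1L
  }
  out
}
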