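test_that("resolve_spot picks the most proximal unambiguous node", {
  # lineage chain resolves to its deepest member (the Mus musculus case)
  tr <- tax_tree(c(1, 40674, 39107, 10090, 10088, 10096),
                 c(1, 1, 40674, 39107, 39107, 10088),
                 name = c("root", "Mammalia", "Murinae", "Mus musculus",
                          "Mus", "Mus spretus"))
  chain <- c("10090" = 1L, "39107" = 2L, "40674" = 1L)
  expect_identical(resolve_spot(chain, tr), 10090L)
  # sibling species resolve to the common parent
  expect_identical(resolve_spot(c(10090, 10096), tr), 39107L)
  # singleton
  expect_identical(resolve_spot(c("10090" = 3L), tr), 10090L)
})

test_that("resolve_spot equals the leaf-most LCA oracle on random trees", {
  set.seed(40)
  for (rep in 1:30) {
    tr <- random_tree(sample(10:60, 1))
    ids <- sample(tr$ids, sample(1:6, 1))
    got <- resolve_spot(ids, tr)
    expect_identical(got, oracle_resolve(ids, tr))
    # bracketing invariant: between the LCA of all hits and every
    # leaf-most hit's lineage
    expect_true(all(vapply(ids, function(t)
      got %in% oracle_lineage(tr, t) || t %in% oracle_lineage(tr, got),
      logical(1))))
    expect_true(tax_lca(tr, ids) %in% oracle_lineage(tr, got))
  }
})

test_that("aggregate_run computes self/total counts and percentages", {
  tr <- tax_tree(c(1, 10, 11, 12), c(1, 1, 10, 10),
                 rank = c(NA, "genus", "species", "species"))
  rep1 <- aggregate_run(rep(11L, 4), tr)
  expect_identical(rep1$self_percent[rep1$taxid == 11], 100)
  r <- aggregate_run(c(11L, 11L, 11L, 10L), tr)
  expect_identical(r$total_count[r$taxid == 10], 4L)
  expect_identical(r$self_count[r$taxid == 10], 1L)
  expect_identical(r$self_count[r$taxid == 11], 3L)
  expect_false(12L %in% r$taxid)  # zero-count nodes omitted
  expect_identical(sum(r$self_count), 4L)
  expect_equal(sum(r$self_percent), 100)
  # random totals equal brute-force subtree sums; parent >= child
  set.seed(41)
  tr2 <- random_tree(40)
  res <- sample(tr2$ids, 200, replace = TRUE)
  r2 <- aggregate_run(res, tr2)
  for (i in sample(nrow(r2), 10)) {
    t <- r2$taxid[i]
    expect_identical(r2$total_count[i],
                     sum(vapply(res, function(x)
                       t %in% oracle_lineage(tr2, x), logical(1))))
  }
  nonroot <- r2$taxid[r2$taxid != 1L]
  par <- tr2$parent[match(nonroot, tr2$ids)]
  expect_true(all(r2$total_count[match(par, r2$taxid)] >=
                    r2$total_count[match(nonroot, r2$taxid)]))
})

test_that("first-pass thresholds select per super-kingdom read counts", {
  w <- simulate_world(kingdoms = c("Bacteria", "Viruses", "Eukaryota"),
                      n_genera = 1L, species_per_genus = 1L,
                      genome_length = 1000L, seed = 42)
  tr <- w$tree
  sp <- as.integer(names(w$genomes))
  sk <- vapply(sp, superkingdom_of, character(1), tree = tr)
  euk <- sp[sk == "Eukaryota"]; bact <- sp[sk == "Bacteria"]
  vir <- sp[sk == "Viruses"]
  thr <- screen_thresholds()
  sel <- function(t, n) t %in% first_pass_select(setNames(n, t), tr, thr)
  expect_false(sel(euk, 100)); expect_true(sel(euk, 101))
  expect_false(sel(bact, 10)); expect_true(sel(bact, 11))
  expect_false(sel(vir, 0));   expect_true(sel(vir, 1))
})

test_that("species counts accumulate over the species subtree", {
  # a strain below a species counts toward that species
  tr <- tax_tree(c(1, 2, 100, 101, 102), c(1, 1, 2, 100, 101),
                 rank = c(NA, "superkingdom", "genus", "species", "strain"))
  counts <- species_read_counts(c(102L, 102L, 101L, 100L), tr)
  expect_identical(counts, c("101" = 3L))
})

test_that("expand_selection takes subtree plus ancestry minus exclusions", {
  tr <- tax_tree(c(1, 2, 100, 101, 102, 103, 200),
                 c(1, 1, 2, 100, 100, 101, 2))
  got <- expand_selection(101L, tr)
  expect_identical(got, sort(c(101L, 103L, 100L, 2L, 1L)))
  expect_identical(expand_selection(integer(0), tr), integer(0))
  # excluding a selected species removes its subtree
  got2 <- expand_selection(c(101L, 102L), tr, exclusions = 101L)
  expect_false(any(c(101L, 103L) %in% got2))
  expect_true(102L %in% got2)
})

test_that("two-phase classification recovers a planted bacterial species", {
  set.seed(43)
  w <- simulate_world(kingdoms = "Bacteria", n_genera = 2L,
                      species_per_genus = 2L, genome_length = 60000L,
                      mutation_rate = 0.02, seed = 44)
  tr <- w$tree
  sp <- as.integer(names(w$genomes))
  sparse <- merge_tree(tr, lapply(sp, function(t)
    filter_low_complexity(build_taxon_set(w$genomes[[as.character(t)]], t,
                                          window_for(tr, t, "sparse")))))
  dense <- merge_tree(tr, lapply(sp, function(t)
    filter_low_complexity(build_taxon_set(w$genomes[[as.character(t)]], t,
                                          window_for(tr, t, "dense")))))
  dbs <- withr::local_tempfile(fileext = ".dbs")
  write_dbs(dense, dbs)
  conv <- dbs_to_dbss(dbs, withr::local_tempfile())
  planted <- sp[1]
  reads <- simulate_reads(w$genomes[[as.character(planted)]], 1000,
                          seed = 45)
  spots <- setNames(as.list(reads$seq), reads$id)
  res <- two_phase_classify(spots, sparse_db = as_kmer_lookup(sparse),
                            dense_dbss = conv$kmer_path,
                            dense_annotation = conv$annotation_path,
                            tree = tr)
  expect_true(planted %in% res$selected)
  top <- res$report[res$report$rank %in% "species", ]
  expect_identical(top$taxid[which.max(top$total_count)], planted)
  # a handful of eukaryote-free reads select nothing eukaryotic
  few <- two_phase_classify(spots[1:5], sparse_db = as_kmer_lookup(sparse),
                            dense_dbss = conv$kmer_path,
                            dense_annotation = conv$annotation_path,
                            tree = tr)
  expect_length(few$selected, 0)
  expect_identical(nrow(few$report), 0L)
})

test_that("two-phase report equals direct dense classification on a
           divergent world", {
  # siblings far apart (near-disjoint k-mer sets) so no hit falls outside
  # the phase-1 selection's tax_list; under that condition the two-phase
  # pipeline must reproduce a one-shot dense classification exactly
  w <- simulate_world(kingdoms = "Bacteria", n_genera = 2L,
                      species_per_genus = 2L, genome_length = 40000L,
                      mutation_rate = 0.35, seed = 46)
  tr <- w$tree
  sp <- as.integer(names(w$genomes))
  sparse <- merge_tree(tr, lapply(sp, function(t)
    build_taxon_set(w$genomes[[as.character(t)]], t,
                    window_for(tr, t, "sparse"))))
  dense <- merge_tree(tr, lapply(sp, function(t)
    build_taxon_set(w$genomes[[as.character(t)]], t,
                    window_for(tr, t, "dense"))))
  # sibling divergence: shared k-mers are (almost) gone
  j <- length(intersect(dense[[as.character(sp[1])]]$kmers,
                        dense[[as.character(sp[2])]]$kmers))
  expect_lte(j / length(dense[[as.character(sp[1])]]$kmers), 0.05)
  dbs <- withr::local_tempfile(fileext = ".dbs")
  write_dbs(dense, dbs)
  conv <- dbs_to_dbss(dbs, withr::local_tempfile())
  reads <- simulate_reads(w$genomes[[as.character(sp[1])]], 600, seed = 47)
  spots <- setNames(as.list(reads$seq), reads$id)
  res <- two_phase_classify(spots, sparse_db = as_kmer_lookup(sparse),
                            dense_dbss = conv$kmer_path,
                            dense_annotation = conv$annotation_path,
                            tree = tr)
  expect_identical(res$selected, sp[1])
  h <- run_aligns_to(spots, db = as_kmer_lookup(dense))
  direct <- aggregate_run(vapply(h, resolve_spot, integer(1), tree = tr),
                          tr)
  expect_identical(res$report, direct)
})
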