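test_that("build_taxon_set dedupes and honours the window budget", {
  set.seed(20)
  g <- random_seq(6400)
  s <- build_taxon_set(g, taxid = 562L, window = 64L)
  expect_s3_class(s, "taxon_kmer_set")
  expect_lte(length(s$kmers), 100L)            # at most 1 per 64 bp
  expect_false(anyDuplicated(s$kmers) > 0)
  # two identical records add nothing
  s2 <- build_taxon_set(c(g, g), taxid = 562L, window = 64L)
  expect_identical(s2$kmers, s$kmers)
  # window 1 gives the complete canonical k-mer set
  acgt <- strrep("ACGT", 100)
  s3 <- build_taxon_set(acgt, taxid = 562L, window = 1L)
  expect_setequal(s3$kmers,
                  unique(canonical_kmer(encode_kmer(
                    substring(acgt, 1:369, 32:400)))))
  expect_warning(build_taxon_set(character(0), 562L, 64L), "no input")
})

test_that("window_for implements the per-kingdom sparse/dense sizes", {
  w <- toy_world()
  sp <- as.integer(names(w$genomes))
  sk <- vapply(sp, superkingdom_of, character(1), tree = w$tree)
  bact <- sp[sk == "Bacteria"][1]
  vir <- sp[sk == "Viruses"][1]
  expect_identical(window_for(w$tree, bact, "dense"), 64L)
  expect_identical(window_for(w$tree, vir, "dense"), 64L)
  expect_identical(window_for(w$tree, bact, "sparse"), 2000L)
  expect_identical(window_for(w$tree, vir, "sparse"), 64L)
  # archaea / eukaryota roots resolve through a tree that declares them
  tr <- tax_tree(c(1, 2157, 2759, 5, 6), c(1, 1, 1, 2157, 2759))
  expect_identical(window_for(tr, 5L, "sparse"), 2000L)
  expect_identical(window_for(tr, 6L, "sparse"), 8000L)
  expect_warning(wd <- window_for(tr, 1L, "sparse"), "super-kingdom")
  expect_identical(wd, 64L)
})

test_that("merge_tree assigns every k-mer to the LCA of its owners", {
  # sibling example: shared k-mers move to the parent, unique ones stay
  tr <- tax_tree(c(1, 10, 11, 12), c(1, 1, 10, 10))
  km <- random_kmers(5)
  sets <- list(taxon_kmer_set(11, km[c(1, 2, 3)]),
               taxon_kmer_set(12, km[c(1, 2, 4)]))
  m <- merge_tree(tr, sets)
  expect_setequal(m[["10"]]$kmers, km[c(1, 2)])
  expect_identical(m[["11"]]$kmers, km[3])
  expect_identical(m[["12"]]$kmers, km[4])
  # single node input is unchanged
  one <- merge_tree(tr, list(taxon_kmer_set(11, km)))
  expect_setequal(one[["11"]]$kmers, km)
})

test_that("merge_tree equals the per-k-mer LCA oracle and conserves k-mers", {
  set.seed(21)
  tr <- random_tree(50)
  km <- random_kmers(120)
  owners <- lapply(km, function(x) sample(tr$ids, sample(1:4, 1)))
  taxids <- sort(unique(unlist(owners)))
  sets <- lapply(taxids, function(t)
    taxon_kmer_set(t, km[vapply(owners, function(o) t %in% o,
                                logical(1))]))
  sets <- sets[vapply(sets, function(s) length(s$kmers) > 0, logical(1))]
  m <- merge_tree(tr, sets)
  flat <- as_kmer_lookup(m)  # errors if any k-mer is duplicated
  expect_setequal(flat$kmer, km)
  for (i in seq_along(km)) {
    want <- oracle_lca(tr, unique(owners[[i]]))
    expect_identical(flat$taxid[match(km[i], flat$kmer)], want)
  }
  # idempotence: merging the merged assignment changes nothing
  m2 <- merge_tree(tr, m)
  expect_identical(lapply(m2, `[[`, "kmers")[order(names(m2))],
                   lapply(m, `[[`, "kmers")[order(names(m))])
})

test_that("k-mers planted under two super-kingdoms merge to the global root", {
  w <- toy_world()
  shared <- random_kmers(3)
  sp <- as.integer(names(w$genomes))
  sk <- vapply(sp, superkingdom_of, character(1), tree = w$tree)
  sets <- list(taxon_kmer_set(sp[sk == "Bacteria"][1], shared),
               taxon_kmer_set(sp[sk == "Viruses"][1], shared))
  m <- merge_tree(w$tree, sets)
  expect_setequal(m[["1"]]$kmers, shared)
})

test_that("low-complexity filter removes > 50% repeat k-mers exactly", {
  a32 <- encode_kmer(strrep("A", 32))
  ac16 <- encode_kmer(strrep("AC", 16))
  s <- taxon_kmer_set(1L, c(a32, ac16))
  expect_length(filter_low_complexity(s)$kmers, 0)
  # boundary: a run of exactly 16 bases is retained, 17 is removed
  for (unit in c("A", "AC")) {
    keep16 <- encode_kmer(embed_run(16L, unit))
    drop17 <- encode_kmer(embed_run(17L, unit))
    f <- filter_low_complexity(taxon_kmer_set(1L, c(keep16, drop17)))
    expect_identical(f$kmers, keep16)
  }
  # complex k-mers pass untouched
  set.seed(22)
  cx <- encode_kmer(strrep("ACGGTCAT", 4))
  expect_identical(filter_low_complexity(taxon_kmer_set(1L, cx))$kmers, cx)
})

test_that("subtract_kmers is exact set difference", {
  set.seed(23)
  a <- random_kmers(50)
  b <- c(sample(a, 20), random_kmers(10))
  s <- taxon_kmer_set(5L, a)
  expect_identical(subtract_kmers(s, character(0))$kmers, s$kmers)
  expect_length(subtract_kmers(s, a)$kmers, 0)
  expect_setequal(subtract_kmers(s, b)$kmers, setdiff(a, b))
})

test_that("dbs files hold sorted 12-byte records and round-trip", {
  set.seed(24)
  km <- random_kmers(100)
  sets <- list(taxon_kmer_set(562L, km[1:60]),
               taxon_kmer_set(9606L, km[61:100]))
  p <- withr::local_tempfile(fileext = ".dbs")
  write_dbs(sets, p)
  expect_identical(file.size(p), 12 * 100)
  db <- read_dbs(p)
  expect_identical(db$kmer, sort(km, method = "radix"))
  expect_setequal(db$taxid[match(km[1:60], db$kmer)], 562L)
  # duplicate k-mer across taxa violates the merge contract
  expect_error(write_dbs(list(taxon_kmer_set(1L, km[1]),
                              taxon_kmer_set(2L, km[1])), p),
               "duplicate")
  # empty database is a zero-byte file
  p0 <- withr::local_tempfile()
  write_dbs(taxon_kmer_set(1L, character(0)), p0)
  expect_identical(file.size(p0), 0)
  expect_length(read_dbs(p0)$kmer, 0)
  # corrupt sizes are rejected
  p13 <- withr::local_tempfile()
  writeBin(raw(13), p13)
  expect_error(read_dbs(p13), "multiple of 12")
  # lookups of absent k-mers miss
  expect_true(is.na(lookup_taxids(db, random_kmers(1))))
})

test_that("dbss conversion drops TaxIds from records and slices reload", {
  set.seed(25)
  km <- random_kmers(90)
  sets <- list(taxon_kmer_set(7L, km[1:30]), taxon_kmer_set(3L, km[31:55]),
               taxon_kmer_set(11L, km[56:90]))
  dbs <- withr::local_tempfile(fileext = ".dbs")
  write_dbs(sets, dbs)
  prefix <- withr::local_tempfile()
  res <- dbs_to_dbss(dbs, prefix)
  expect_identical(res$dbss_bytes, file.size(dbs) * 2 / 3)   # 33% smaller
  ann <- read.table(res$annotation_path, sep = "\t")
  expect_identical(ann[[1]], c(3L, 7L, 11L))                 # ascending TaxId
  expect_identical(sum(ann[[2]]) * 8, res$dbss_bytes)
  # full slice equals the dbs content
  full <- read_dbss_slice(res$kmer_path, res$annotation_path)
  db <- read_dbs(dbs)
  expect_identical(full$kmer, db$kmer)
  expect_identical(full$taxid, db$taxid)
  # arbitrary subset equals brute-force filtering of the full load
  sub <- read_dbss_slice(res$kmer_path, res$annotation_path, c(11L, 3L))
  keep <- db$taxid %in% c(3L, 11L)
  expect_identical(sub$kmer, db$kmer[keep])
  expect_identical(sub$taxid, db$taxid[keep])
  # absent TaxId skipped with warning; empty request gives empty lookup
  expect_warning(w <- read_dbss_slice(res$kmer_path, res$annotation_path,
                                      c(3L, 999L)), "skipped")
  expect_setequal(unique(w$taxid), 3L)
  none <- read_dbss_slice(res$kmer_path, res$annotation_path, integer(0))
  expect_length(none$kmer, 0)
})
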