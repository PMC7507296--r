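test_that("Laplace-smoothed probabilities match hand arithmetic", {
  spec1 <- kmer_spec(1)
  empty <- class_model(1, count_kmers("", spec1), n_genomes = 0L)
  expect_equal(log_smoothed_prob(empty, c("A", "C", "G", "T")),
               rep(log(1 / 4), 4))

  m <- class_model(1, count_kmers("AAA", spec1))  # {A:3}, T = 3, K = 4
  expect_equal(log_smoothed_prob(m, "A"), log(4 / 7))
  expect_equal(log_smoothed_prob(m, "C"), log(1 / 7))
  expect_error(log_smoothed_prob(m, "AA"), "length")
})

test_that("smoothed distribution sums to 1 over all 4^k k-mers", {
  set.seed(21)
  for (k in 1:6) {
    spec <- kmer_spec(k)
    m <- class_model(1, count_kmers(rand_dna(500), spec))
    all_kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)),
                       1, paste, collapse = "")
    expect_equal(sum(exp(log_smoothed_prob(m, all_kmers))), 1, tolerance = 1e-9)
  }
})

test_that("adding counts for one k-mer moves probabilities monotonically", {
  spec <- kmer_spec(2)
  before <- class_model(1, make_table(c(AA = 3, CC = 2), spec))
  after <- class_model(1, make_table(c(AA = 5, CC = 2), spec))
  expect_gt(log_smoothed_prob(after, "AA"), log_smoothed_prob(before, "AA"))
  expect_lt(log_smoothed_prob(after, "CC"), log_smoothed_prob(before, "CC"))
  expect_lt(log_smoothed_prob(after, "GG"), log_smoothed_prob(before, "GG"))
})

test_that("update_class creates, extends, and never touches other classes", {
  spec <- kmer_spec(1)
  store <- create_store(tempfile(), spec)
  store <- update_class(store, 7, make_table(c(A = 2), spec))
  m <- load_class(store, 7)
  expect_equal(m$counts, c(A = 2))
  expect_equal(m$total, 2)
  expect_equal(m$n_genomes, 1L)

  # second class; snapshot first class's file bytes
  store <- update_class(store, 3, make_table(c(C = 1), spec))
  f7 <- file.path(store$root, "7.nbc")
  bytes_before <- readBin(f7, "raw", file.size(f7))
  store <- update_class(store, 3, make_table(c(C = 4, G = 1), spec))
  expect_identical(readBin(f7, "raw", file.size(f7)), bytes_before)

  m3 <- load_class(store, 3)
  expect_equal(m3$counts, c(C = 5, G = 1))
  expect_equal(m3$n_genomes, 2L)

  expect_error(update_class(store, 7, make_table(c(AA = 1), kmer_spec(2))),
               "spec")
})

test_that("incremental updates equal batch training for any partition", {
  spec <- kmer_spec(3)
  set.seed(33)
  tables <- lapply(1:8, function(i) count_kmers(rand_dna(200), spec))
  species <- c(5, 5, 5, 9, 9, 2, 2, 2)

  batch <- create_store(tempfile(), spec)
  batch <- train_store(batch, tables, species)

  for (rep in 1:5) {
    ord <- sample(8)
    cuts <- sort(sample(0:8, sample(2:4, 1)))
    inc <- create_store(tempfile(), spec)
    start <- 1
    for (b in unique(c(cuts[cuts > 0], 8))) {
      if (start > b) next
      idx <- ord[start:b]
      for (sp in unique(species[idx]))
        inc <- update_class(inc, sp, tables[idx[species[idx] == sp]])
      start <- b + 1
    }
    expect_true(stores_identical(batch$root, inc$root))
  }
})

test_that("merge_classes applies the count-sum rule and removes the source", {
  spec <- kmer_spec(1)
  store <- create_store(tempfile(), spec)
  store <- update_class(store, 1, make_table(c(A = 1), spec))
  store <- update_class(store, 2, make_table(c(A = 2, C = 1), spec))
  store <- merge_classes(store, 1, 2)
  expect_equal(store$index, 2L)
  expect_false(file.exists(file.path(store$root, "1.nbc")))
  m <- load_class(store, 2)
  expect_equal(m$counts, c(A = 3, C = 1))
  expect_equal(m$n_genomes, 2L)

  # merged store equals scratch training of the pooled class
  scratch <- create_store(tempfile(), spec)
  scratch <- update_class(scratch, 2, list(make_table(c(A = 1), spec),
                                           make_table(c(A = 2, C = 1), spec)))
  expect_true(stores_identical(store$root, scratch$root))

  expect_error(merge_classes(store, 4, 2), "exist")
  expect_warning(store2 <- merge_classes(store, 2, 2), "no-op")
  expect_equal(load_class(store2, 2)$counts, m$counts)
})

test_that("savefiles round-trip exactly and are byte-deterministic", {
  spec <- kmer_spec(4)
  set.seed(14)
  tab <- count_kmers(rand_dna(300), spec)
  store <- create_store(tempfile(), spec)
  m <- class_model(11, tab, 2L)
  store <- save_class(m, store)
  m2 <- load_class(store, 11)
  expect_identical(m2$counts, m$counts)
  expect_identical(m2$total, m$total)
  expect_identical(m2$n_genomes, m$n_genomes)
  expect_identical(m2$species_taxid, m$species_taxid)

  f <- file.path(store$root, "11.nbc")
  b1 <- readBin(f, "raw", file.size(f))
  save_class(m, store)
  expect_identical(readBin(f, "raw", file.size(f)), b1)

  # keys are stored sorted
  body <- readLines(f)
  keys <- sub("\t.*", "", body[!startsWith(body, "#")])
  expect_identical(keys, sort(keys))
})

test_that("corrupted savefiles fail integrity checks", {
  spec <- kmer_spec(2)
  store <- create_store(tempfile(), spec)
  store <- update_class(store, 5, make_table(c(AA = 2, CC = 3), spec))
  f <- file.path(store$root, "5.nbc")
  lines <- readLines(f)
  # tamper with one count so total no longer matches
  lines[grep("^AA\t", lines)] <- "AA\t9"
  writeLines(lines, f)
  expect_error(load_class(store, 5), "integrity")
  # truncation drops a count line
  writeLines(head(readLines(f), -1), f)
  expect_error(load_class(store, 5), "integrity")
})

test_that("store manifest reopens consistently and flags spec mismatches", {
  spec <- kmer_spec(3, canonical = TRUE)
  store <- create_store(tempfile(), spec)
  store <- update_class(store, 8, count_kmers("ACGTACGT", spec))
  reopened <- open_store(store$root)
  expect_equal(reopened$index, 8L)
  expect_equal(reopened$spec$k, 3L)
  expect_true(reopened$spec$canonical)
  expect_error(save_class(class_model(9, count_kmers("AC", kmer_spec(2))), reopened),
               "spec")
  # a stray savefile invalidates the index
  writeLines("# bogus", file.path(store$root, "99.nbc"))
  expect_error(open_store(store$root), "index")
})

test_that("deleting a class removes its savefile and index entry", {
  spec <- kmer_spec(1)
  store <- create_store(tempfile(), spec)
  store <- update_class(store, 4, make_table(c(A = 1), spec))
  store <- update_class(store, 6, make_table(c(C = 1), spec))
  store <- delete_class(store, 4)
  expect_equal(store$index, 6L)
  expect_false(file.exists(file.path(store$root, "4.nbc")))
  expect_error(delete_class(store, 4), "no class")
})
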