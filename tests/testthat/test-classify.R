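test_that("score_read matches hand arithmetic in both modes", {
  spec <- kmer_spec(1)
  m <- class_model(1, count_kmers("AAA", spec))  # {A:3}, T = 3, K = 4
  rk <- count_kmers("AAC", spec)                 # distinct {A, C}, A twice
  expect_equal(score_read(m, rk, "unique"), log(4 / 7) + log(1 / 7))
  expect_equal(score_read(m, rk, "multiplicity"), 2 * log(4 / 7) + log(1 / 7))

  # read with no valid k-mers scores 0
  expect_equal(score_read(m, count_kmers("NNN", spec)), 0)
  expect_error(score_read(m, count_kmers("AA", kmer_spec(2))), "spec")
})

test_that("classify_read takes the argmax with smallest-taxid tie-break", {
  spec <- kmer_spec(2)
  store <- create_store(tempfile(), spec)
  store <- update_class(store, 20, count_kmers("AAAAAAAA", spec))  # AA-rich
  store <- update_class(store, 10, count_kmers("CCCCCCCC", spec))  # CC-rich
  p <- classify_read(store, "AAAA", read_id = "r1")
  expect_equal(p$predicted_species, 20)
  expect_lte(p$log_likelihood, 0)

  # all-N read: zero scores everywhere, smallest taxid wins
  p0 <- classify_read(store, "NNNNNN")
  expect_equal(p0$predicted_species, 10)
  expect_equal(p0$log_likelihood, 0)

  # single-class store always returns that class
  solo <- create_store(tempfile(), spec)
  solo <- update_class(solo, 77, count_kmers("ACGT", spec))
  expect_equal(classify_read(solo, "GGGG")$predicted_species, 77)

  empty <- create_store(tempfile(), kmer_spec(2))
  expect_error(classify_read(empty, "ACGT"), "empty")
})

test_that("classification matches brute-force enumeration on toy stores", {
  # independent oracle: direct per-kmer loop over (f+1)/(T+K) in plain R
  brute_score <- function(counts, total, k, read, mode) {
    kms <- naive_count(read, k)
    s <- 0
    for (x in names(kms)) {
      f <- if (x %in% names(counts)) counts[[x]] else 0
      w <- if (mode == "multiplicity") kms[[x]] else 1
      s <- s + w * log((f + 1) / (total + 4^k))
    }
    s
  }
  set.seed(8)
  for (k in 1:2) {
    spec <- kmer_spec(k)
    classes <- list(`3` = rand_dna(40), `12` = rand_dna(40), `7` = rand_dna(40))
    store <- create_store(tempfile(), spec)
    for (tx in names(classes))
      store <- update_class(store, as.integer(tx), count_kmers(classes[[tx]], spec))
    for (mode in c("unique", "multiplicity")) {
      for (i in 1:10) {
        read <- rand_dna(15)
        scores <- vapply(names(classes), function(tx)
          brute_score(count_kmers(classes[[tx]], spec)$counts,
                      nchar(classes[[tx]]) - k + 1, k, read, mode), numeric(1))
        taxids <- as.integer(names(classes))
        o <- order(taxids)
        want_tax <- taxids[o][which.max(scores[o])]
        got <- classify_batchwise(store, setNames(read, "r"), mode = mode)
        expect_equal(got$predicted_species, want_tax)
        expect_equal(got$log_likelihood, max(scores), tolerance = 1e-12)
      }
    }
  }
})

test_that("unique-mode batch scores equal the sum of per-kmer log-probs", {
  spec <- kmer_spec(3)
  set.seed(19)
  store <- create_store(tempfile(), spec)
  for (tx in c(4, 9)) store <- update_class(store, tx, count_kmers(rand_dna(300), spec))
  reads <- setNames(replicate(15, rand_dna(40)), sprintf("r%d", 1:15))
  preds <- classify_batchwise(store, reads, all_scores = TRUE)
  scores <- attr(preds, "scores")
  for (tx in c(4, 9)) {
    m <- load_class(store, tx)
    for (r in names(reads)) {
      distinct <- names(count_kmers(reads[[r]], spec)$counts)
      expect_equal(scores[r, as.character(tx)],
                   sum(vapply(distinct, function(x) log_smoothed_prob(m, x),
                              numeric(1))),
                   tolerance = 1e-12)
    }
  }
})

test_that("plan_batches is greedy under a cap and exact under n_per_batch", {
  expect_equal(plan_batches(c(4, 4, 4, 4), memory_cap_bytes = 10),
               list(c(1L, 2L), c(3L, 4L)))
  expect_equal(plan_batches(c(4, 4, 4, 4), memory_cap_bytes = 100),
               list(1:4))
  expect_warning(b <- plan_batches(c(12), memory_cap_bytes = 10), "cap")
  expect_equal(b, list(1L))
  expect_equal(plan_batches(rep(1, 7), n_per_batch = 3),
               list(1:3, 4:6, 7L))
  expect_equal(plan_batches(integer(0), n_per_batch = 3), list())
  expect_error(plan_batches(c(1), memory_cap_bytes = 0), "positive")
  expect_error(plan_batches(c(1)), "exactly one")
  expect_error(plan_batches(c(1), memory_cap_bytes = 5, n_per_batch = 2),
               "exactly one")
  # concatenation reproduces input order
  set.seed(2)
  sizes <- sample(50:500, 40, replace = TRUE)
  expect_equal(unlist(plan_batches(sizes, memory_cap_bytes = 1000)),
               seq_along(sizes))
})

test_that("batching and threading are pure scheduling (bit-equal predictions)", {
  spec <- kmer_spec(4)
  set.seed(27)
  store <- create_store(tempfile(), spec)
  for (tx in c(2, 11, 30)) store <- update_class(store, tx, count_kmers(rand_dna(600), spec))
  reads <- setNames(replicate(50, rand_dna(80)), sprintf("r%02d", 1:50))

  baseline <- classify_batchwise(store, reads, threads = 1)
  total_bytes <- sum(nchar(reads))
  combos <- list(
    list(threads = 1, memory_cap_bytes = ceiling(total_bytes / 5)),
    list(threads = 1, n_per_batch = 7),
    list(threads = 4, memory_cap_bytes = NULL),
    list(threads = 4, n_per_batch = 7))
  for (cb in combos) {
    got <- classify_batchwise(store, reads, threads = cb$threads,
                              memory_cap_bytes = cb$memory_cap_bytes,
                              n_per_batch = cb$n_per_batch)
    expect_identical(got, baseline)
  }

  expect_equal(nrow(classify_batchwise(store, character(0))), 0)
  expect_error(classify_batchwise(store, reads, threads = 0), "threads")
  expect_error(classify_batchwise(store, setNames(c("AC", "GT"), c("a", "a"))),
               "unique")
})

test_that("prediction TSVs round-trip", {
  preds <- data.frame(read_id = c("a", "b"), predicted_species = c(3L, 12L),
                      log_likelihood = c(-1.25, -370.123456),
                      stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_predictions(preds, f)
  back <- read_predictions(f)
  expect_equal(back$read_id, preds$read_id)
  expect_equal(back$predicted_species, preds$predicted_species)
  expect_equal(back$log_likelihood, preds$log_likelihood, tolerance = 1e-6)
})
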