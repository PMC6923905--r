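test_that("partition_read run-length encodes the thresholded coverage vector", {
  # chain AC->CG->GT->TA->AC with chosen coverages gives pattern [5,5,0,0,5]
  # for the read ACGTAC against a graph lacking GT and TA
  cov <- c(AC = 5L, CG = 5L, GG = 7L)
  g <- dbg_from_edges(cov, list(c("AC", "CG")))
  regions <- partition_read("ACGTAC", g, tau = 1)
  expect_equal(regions$label, c("strong", "weak", "strong"))
  expect_equal(regions$start, c(0L, 2L, 4L))
  expect_equal(regions$end, c(2L, 4L, 5L))

  all_strong <- partition_read("ACG", g, tau = 1)
  expect_equal(all_strong,
               data.frame(start = 0L, end = 2L, label = "strong"))
  all_weak <- partition_read("TTTT", g, tau = 1)
  expect_equal(all_weak$label, "weak")
  expect_equal(nrow(partition_read("A", g)), 0L)  # shorter than k
})

test_that("weak k-mer sets grow monotonically in tau", {
  set.seed(71)
  reads <- replicate(30, random_seq(40))
  g <- build_graph(reads, k = 9)
  read <- random_seq(60)
  prev <- integer(0)
  for (tau in c(1, 2, 3, 5, 10)) {
    regions <- partition_read(read, g, tau)
    weak <- unlist(mapply(function(s, e) seq(s, e - 1L),
                          regions$start[regions$label == "weak"],
                          regions$end[regions$label == "weak"],
                          SIMPLIFY = FALSE))
    expect_true(all(prev %in% weak))
    prev <- weak
  }
})

test_that("widest_path handles identity, chains and absent endpoints", {
  cov <- c(AC = 5L, CG = 2L, GT = 7L)
  g <- dbg_from_edges(cov, list(c("AC", "CG"), c("CG", "GT")))
  p <- widest_path(g, "AC", "AC", 8)
  expect_equal(p$kmers, "AC")
  expect_equal(p$width, 5L)
  expect_equal(p$length, 1L)

  p2 <- widest_path(g, "AC", "GT", 8)
  expect_equal(p2$kmers, c("AC", "CG", "GT"))
  expect_equal(p2$width, 2L)
  expect_equal(p2$seq, "ACGT")

  expect_error(widest_path(g, "AC", "TT", 8), "not present")
  expect_null(widest_path(g, "GT", "AC", 8))  # unreachable
})

test_that("widest and shortest disagree on a diamond as constructed", {
  # AA -> AT -> TT          (short, low coverage)
  # AA -> AC -> CG -> GT -> TT   (long, high coverage)
  cov <- c(AA = 9L, AT = 1L, TT = 9L, AC = 9L, CG = 9L, GT = 9L)
  g <- dbg_from_edges(cov, list(c("AA", "AT"), c("AT", "TT"),
                                c("AA", "AC"), c("AC", "CG"),
                                c("CG", "GT"), c("GT", "TT")))
  wp <- widest_path(g, "AA", "TT", 8)
  sp <- shortest_path(g, "AA", "TT", 8)
  expect_equal(wp$kmers, c("AA", "AC", "CG", "GT", "TT"))
  expect_equal(wp$width, 9L)
  expect_equal(sp$kmers, c("AA", "AT", "TT"))
  expect_equal(sp$width, 1L)
  # enumeration confirms both extremes
  st <- enum_path_stats(g, "AA", "TT", 8)
  expect_equal(wp$width, st$best_width)
  expect_equal(sp$length, st$min_len)

  expect_null(shortest_path(g, "TT", "AA", 8))
})

test_that("greedy descent backtracks out of high-coverage dead ends", {
  # from AA the greedy order is AC (cov 9, dead end) then AT (cov 2 -> TT)
  cov <- c(AA = 5L, AC = 9L, AT = 2L, TT = 5L)
  g <- dbg_from_edges(cov, list(c("AA", "AC"), c("AA", "AT"),
                                c("AT", "TT")))
  p <- greedy_path(g, "AA", "TT", b = 100, max_len = 8)
  expect_equal(p$kmers, c("AA", "AT", "TT"))
  expect_equal(p$width, 2L)

  # exhaustion: no branch reaches the (disconnected) destination
  cov2 <- c(AA = 5L, AC = 9L, TT = 5L)
  g2 <- dbg_from_edges(cov2, list(c("AA", "AC")))
  expect_null(greedy_path(g2, "AA", "TT", b = 100, max_len = 8))

  # linear chain: all strategies agree
  cov3 <- c(AC = 5L, CG = 2L, GT = 7L)
  g3 <- dbg_from_edges(cov3, list(c("AC", "CG"), c("CG", "GT")))
  expect_equal(greedy_path(g3, "AC", "GT", 100, 8)$kmers,
               widest_path(g3, "AC", "GT", 8)$kmers)
})

test_that("spell_path inverts k-mer overlap", {
  expect_equal(spell_path(c("ACG", "CGT")), "ACGT")
  expect_equal(spell_path("ACG"), "ACG")
  expect_error(spell_path(c("ACG", "GGT")), "overlap")
  set.seed(81)
  read <- random_seq(50)
  km <- extract_kmers(read, 7)$kmer
  expect_equal(spell_path(km), read)
})

test_that("a planted deletion is repaired to the exact reference substring", {
  fx <- tiling_fixture(ref_len = 400, seed = 91)
  g <- build_graph(fx$reads, k = 11)
  long <- substr(fx$ref, 51, 350)
  broken <- paste0(substr(long, 1, 149), substr(long, 151, 300))
  res <- correct_read_indels(broken, g, tau = 1)
  expect_equal(res$seq, long)
  expect_equal(res$report$n_replaced, 1L)
  expect_equal(res$report$n_weak_regions, 1L)
})

test_that("reads without weak regions or without boundaries pass through", {
  fx <- tiling_fixture(ref_len = 400, seed = 92)
  g <- build_graph(fx$reads, k = 11)
  clean <- substr(fx$ref, 101, 300)
  res <- correct_read_indels(clean, g, tau = 1)
  expect_identical(res$seq, clean)
  expect_equal(res$report$n_weak_regions, 0L)

  # weak region at a read end (single boundary): untouched, never trimmed
  tipped <- paste0("TTTTTTTTTTTT", substr(clean, 13, 200))
  res2 <- correct_read_indels(tipped, g, tau = 1)
  expect_identical(res2$seq, tipped)
  expect_equal(res2$report$regions$outcome[1], "missing_boundary")

  # no path between the boundary k-mers (disjoint graph components):
  # region unchanged, counted in n_unchanged
  set.seed(95)
  refB <- random_seq(200)
  gAB <- build_graph(c(fx$reads$seq, substring(refB, 1:161, 40:200)),
                     k = 11)
  chimera <- paste0(substr(clean, 1, 100), substr(refB, 50, 150))
  res3 <- correct_read_indels(chimera, gAB, tau = 1)
  expect_identical(res3$seq, chimera)
  expect_gte(res3$report$n_weak_regions, 1L)
  expect_equal(res3$report$n_replaced, 0L)
  expect_equal(res3$report$n_replaced + res3$report$n_unchanged,
               res3$report$n_weak_regions)

  # shorter than k: passed through and reported as skipped
  res4 <- correct_read_indels("ACGT", g)
  expect_identical(res4$seq, "ACGT")
  expect_true(res4$report$skipped)
})

test_that("per-read correction is independent of processing order and workers", {
  fx <- tiling_fixture(ref_len = 500, seed = 93)
  g <- build_graph(fx$reads, k = 11)
  set.seed(94)
  longs <- data.frame(
    id = sprintf("L%d", 1:6),
    seq = replicate(6, {
      s <- substr(fx$ref, 41, 440)
      p <- sample(100:300, 1)
      paste0(substr(s, 1, p), substr(s, p + 2, 400))  # one deletion
    }),
    qual = NA_character_, stringsAsFactors = FALSE)
  serial <- correct_indels(longs, g, tau = 1, workers = 1)
  shuffled <- correct_indels(longs[6:1, ], g, tau = 1, workers = 1)
  parallel <- correct_indels(longs, g, tau = 1, workers = 2)
  expect_identical(serial$reads$seq, rev(shuffled$reads$seq))
  expect_identical(serial$reads, parallel$reads)
})
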