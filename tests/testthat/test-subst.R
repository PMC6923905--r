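test_that("fragment_read tiles the read and labels the short tail", {
  f <- fragment_read(strrep("A", 250), frag_len = 100)
  expect_equal(f$start, c(0L, 100L, 200L))
  expect_equal(f$end, c(100L, 200L, 250L))
  expect_equal(f$klass, c("unclassified", "unclassified", "ignored_tail"))

  f2 <- fragment_read(strrep("A", 100), frag_len = 100)
  expect_equal(nrow(f2), 1L)
  expect_equal(f2$klass, "unclassified")

  f3 <- fragment_read(strrep("A", 99), frag_len = 100)
  expect_equal(f3$klass, "ignored_tail")

  expect_error(fragment_read("ACGT", frag_len = 3, k = 5), "at least k")
})

test_that("pearson_median_skew matches the population formula", {
  expect_equal(pearson_median_skew(c(4, 4, 4, 4)), 0)
  expect_equal(pearson_median_skew(c(1, 2, 3)), 0)
  x <- c(1, 1, 1, 10)
  expected <- 3 * (mean(x) - median(x)) / sqrt(mean((x - mean(x))^2))
  expect_equal(pearson_median_skew(x), expected)
  expect_equal(pearson_median_skew(x), 1.7320508, tolerance = 1e-6)
  expect_error(pearson_median_skew(numeric(0)), "non-empty")
})

test_that("classify_fragment reproduces the three coverage regimes", {
  for (k in c(17L, 21L, 25L)) {
    nwin <- 100L - k + 1L
    set.seed(k)
    balanced <- rep(c(10, 30), length.out = nwin)
    expect_equal(classify_fragment(balanced, graph_median = 20),
                 "true_balanced")
    low <- pmax(0, 5 + sample(-1:1, nwin, replace = TRUE))
    expect_equal(classify_fragment(low, graph_median = 20), "true_low")
    outliers <- c(rep(40, nwin - 5L), rep(2, 5L))
    expect_equal(classify_fragment(outliers, graph_median = 20),
                 "error_high")
  }
})

test_that("error fragments split into high and low coverage areas", {
  nwin <- 80L
  high <- c(rep(50, nwin - 4L), rep(0, 4L))
  expect_equal(classify_fragment(high, graph_median = 20), "error_high")
  lowarea <- c(rep(12, nwin - 4L), rep(0, 4L))
  expect_equal(classify_fragment(lowarea, graph_median = 20), "error_low")
})

subst_fixture <- function(seed = 101, ref_len = 600, k = 11) {
  fx <- tiling_fixture(ref_len = ref_len, seed = seed)
  list(fx = fx, g = build_graph(fx$reads, k = k), k = k)
}

test_that("locate_error_positions pinpoints an isolated substitution", {
  s <- subst_fixture()
  long <- substr(s$fx$ref, 101, 400)  # 300 bases, clean
  planted <- plant_sub(long, 150)
  pos <- locate_error_positions(planted$seq, 100, 200, s$g, tau_low = 1)
  expect_equal(pos, 150L)

  expect_equal(locate_error_positions(long, 100, 200, s$g, tau_low = 1),
               integer(0))

  # near the fragment edge the flagged set is ambiguous but contains the site
  planted_edge <- plant_sub(long, 103)
  pos_edge <- locate_error_positions(planted_edge$seq, 100, 200, s$g,
                                     tau_low = 1)
  expect_true(103L %in% pos_edge)
})

test_that("vote_base recovers the true base and refuses coverage holes", {
  s <- subst_fixture(seed = 102)
  long <- substr(s$fx$ref, 101, 400)
  planted <- plant_sub(long, 150)
  expect_equal(vote_base(planted$seq, 150, s$g, threshold = 2), planted$old)
  # a correct base already qualifying is returned unchanged
  expect_equal(vote_base(long, 150, s$g, threshold = 2),
               substr(long, 151, 151))
  # coverage hole: sequence from outside the graphed reference
  expect_null(vote_base(strrep("T", 30), 15, s$g, threshold = 2))
})

test_that("a planted substitution is corrected end-to-end, exactly once", {
  s <- subst_fixture(seed = 103)
  long <- substr(s$fx$ref, 101, 400)
  planted <- plant_sub(long, 137)
  res <- correct_read_substitutions(planted$seq, s$g, frag_len = 100,
                                    tau_low = 1, thresh_high = 2,
                                    thresh_low = 2)
  expect_identical(res$seq, long)
  expect_equal(res$report$n_positions_corrected, 1L)
  expect_equal(res$report$edits$pos, 137L)
  expect_equal(res$report$edits$new, planted$old)
  expect_equal(nchar(res$seq), nchar(planted$seq))

  # a clean read is untouched
  res2 <- correct_read_substitutions(long, s$g, frag_len = 100,
                                     tau_low = 1, thresh_high = 2,
                                     thresh_low = 2)
  expect_identical(res2$seq, long)
  expect_equal(res2$report$n_positions_corrected, 0L)

  # shorter than frag_len: skipped untouched
  stub <- substr(long, 1, 60)
  res3 <- correct_read_substitutions(stub, s$g, frag_len = 100)
  expect_identical(res3$seq, stub)
  expect_true(res3$report$skipped)
})

test_that("classification outcome is stable across k in {17, 21, 25}", {
  fx <- tiling_fixture(ref_len = 800, read_len = 60, seed = 104)
  long <- substr(fx$ref, 151, 550)
  planted <- plant_sub(long, 200)
  for (k in c(17L, 21L, 25L)) {
    g <- build_graph(fx$reads, k = k)
    gm <- spectrum_median(g, weighted = TRUE)
    # k-mer coverages of the fragment [200, 300) that holds the error
    starts <- 201:(301 - k)
    prof <- coverage(g, substring(planted$seq, starts, starts + k - 1))
    klass <- classify_fragment(prof, gm)
    expect_true(klass %in% c("error_high", "error_low"),
                label = paste("k =", k, "->", klass))
    res <- correct_read_substitutions(planted$seq, g, frag_len = 100,
                                      tau_low = 2)
    expect_identical(res$seq, long)
  }
})

test_that("genuinely low-coverage regions are protected from editing", {
  set.seed(105)
  ref <- random_seq(900)
  # deep tiling over the first 500 bases, sparse over the rest
  deep <- substring(ref, seq(1, 461, by = 2), seq(40, 500, by = 2))
  sparse <- substring(ref, seq(401, 861, by = 14), seq(440, 900, by = 14))
  g <- build_graph(c(deep, sparse), k = 11)
  long <- substr(ref, 101, 800)  # clean read spanning both areas
  res <- correct_read_substitutions(long, g, frag_len = 100, tau_low = 2)
  expect_identical(res$seq, long)  # zero false edits across both areas
  # and the sparse-area fragments classify as a protected class
  gm <- spectrum_median(g, weighted = TRUE)
  sparse_cov <- coverage(g, substring(ref, 601:690, 611:700))
  expect_true(classify_fragment(sparse_cov, gm) %in%
                c("true_low", "true_balanced"))
})
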