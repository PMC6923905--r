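test_that("global alignment scores match a brute-force enumeration", {
  al <- global_align("ACGT", "ACGT")
  expect_equal(al$identity, 1)
  expect_equal(al$score, 4)

  al2 <- global_align("ACGT", "ACT")  # one deletion: 3 matches - one gap
  expect_equal(al2$score, 1)

  set.seed(201)
  for (i in 1:25) {
    a <- random_seq(sample(3:12, 1))
    b <- random_seq(sample(3:12, 1))
    expect_equal(global_align(a, b)$score, brute_align_score(a, b),
                 label = paste(a, b))
  }
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("the banded aligner reproduces exact global alignment scores", {
  set.seed(202)
  for (i in 1:20) {
    ref <- random_seq(sample(100:300, 1))
    # mutate heavily: substitutions plus indels
    ch <- strsplit(ref, "")[[1]]
    sub <- runif(length(ch)) < 0.08
    ch[sub] <- sample(c("A", "C", "G", "T"), sum(sub), replace = TRUE)
    keep <- runif(length(ch)) > 0.05
    ins <- runif(length(ch)) < 0.06
    ch[ins] <- paste0(sample(c("A", "C", "G", "T"), sum(ins), TRUE), ch[ins])
    read <- paste(ch[keep], collapse = "")
    expect_equal(hylec:::banded_align(ref, read)$score,
                 global_align(ref, read)$score)
  }
})

# clean simulated long reads with isolated substitutions planted at spaced
# positions (adjacent substitution clusters admit equal-scoring indel
# representations, so only isolated substitutions have a unique alignment)
planted_sub_fixture <- function(ref, seed, n_subs = 25L) {
  sim <- simulate_long_reads(ref, 1500, 2, ins_rate = 0, del_rate = 0,
                             sub_rate = 0, seed = seed)
  set.seed(seed + 1L)
  events <- list()
  for (i in seq_len(nrow(sim$reads))) {
    s <- sim$reads$seq[i]
    iv <- sim$truth$intervals[i, ]
    offs <- sort(sample(seq(5L, nchar(s) - 5L, by = 9L), n_subs))
    old <- substring(s, offs, offs)
    new <- vapply(old, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1),
      USE.NAMES = FALSE)
    for (j in seq_along(offs)) substr(s, offs[j], offs[j]) <- new[j]
    sim$reads$seq[i] <- s
    events[[i]] <- data.frame(read_id = sim$reads$id[i],
                              ref_pos = iv$ref_start + offs - 1L,
                              type = "sub", ref_base = old, read_base = new,
                              stringsAsFactors = FALSE)
  }
  sim$truth$events <- do.call(rbind, events)
  sim
}

test_that("alignment-derived error sets reproduce ground truth on sub-only reads", {
  ref <- simulate_reference(20000, 0.5, seed = 203)
  sim <- planted_sub_fixture(ref, seed = 204)
  for (id in sim$reads$id) {
    iv <- sim$truth$intervals[sim$truth$intervals$read_id == id, ]
    e_m <- error_set_from_truth(sim$truth, id, ref)
    expect_length(e_m, 25L)
    e_r <- error_set_from_alignment(
      sim$reads$seq[sim$reads$id == id], ref, iv$ref_start, iv$ref_end)
    expect_setequal(e_r$keys, e_m)
  }
})

test_that("error sets behave on degenerate and single-event cases", {
  ref <- simulate_reference(2000, 0.5, seed = 205)
  sim <- simulate_long_reads(ref, 500, 1, ins_rate = 0, del_rate = 0,
                             sub_rate = 0, seed = 206)
  id <- sim$reads$id[1]
  iv <- sim$truth$intervals[1, ]
  expect_length(error_set_from_truth(sim$truth, id, ref), 0L)
  perfect <- error_set_from_alignment(sim$reads$seq[1], ref, iv$ref_start,
                                      iv$ref_end)
  expect_length(perfect$keys, 0L)
  expect_equal(perfect$identity, 1)

  # one residual deletion yields exactly one del record
  s <- sim$reads$seq[1]
  dels <- error_set_from_alignment(
    paste0(substr(s, 1, 200), substr(s, 202, nchar(s))),
    ref, iv$ref_start, iv$ref_end)
  expect_length(dels$keys, 1L)
  expect_match(dels$keys, ":del:")
  expect_error(error_set_from_truth(sim$truth, "nope", ref), "unknown")
})

test_that("a random truth log maps to one key per event", {
  set.seed(207)
  ref <- simulate_reference(30000, 0.5, seed = 208)
  sim <- simulate_long_reads(ref, 3000, 2, seed = 209)
  id <- sim$reads$id[1]
  n_events <- sum(sim$truth$events$read_id == id)
  expect_gte(n_events, 100L)
  expect_length(error_set_from_truth(sim$truth, id, ref), n_events)
})

test_that("compute_gain implements the error-set algebra verbatim", {
  perfect <- compute_gain(c("a", "b", "c"), character(0))
  expect_equal(perfect[c("TP", "FP", "FN", "gain")],
               list(TP = 3L, FP = 0L, FN = 0L, gain = 1))

  noop <- compute_gain(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(noop$gain, 0)
  expect_equal(noop$FN, 3L)

  mixed <- compute_gain(c("a", "b", "c", "d"), c("c", "e"))
  expect_equal(mixed[c("TP", "FP", "FN", "gain")],
               list(TP = 3L, FP = 1L, FN = 1L, gain = 0.5))

  degen <- compute_gain(character(0), character(0))
  expect_equal(degen$gain, 1)
  expect_true(degen$degenerate)
  expect_equal(compute_gain(character(0), "x")$gain, -1)
})

test_that("gain is bounded above by 1 and equals 1 only for perfect correction", {
  set.seed(210)
  universe <- sprintf("e%d", 1:40)
  for (i in 1:50) {
    e_m <- sample(universe, sample(1:30, 1))
    e_r <- sample(universe, sample(0:30, 1))
    g <- compute_gain(e_m, e_r)
    expect_lte(g$gain, 1)
    if (!g$degenerate && g$gain == 1)
      expect_length(intersect(e_r, e_m), 0L)
  }
})

test_that("n50 accumulates sorted lengths to half the total", {
  expect_equal(n50(10), 10L)
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4L)
  set.seed(211)
  lens <- sample.int(5000, 60)
  expect_equal(n50(lens), n50(sample(lens)))
  expect_error(n50(integer(0)), "non-empty")
})

test_that("aligned_fraction separates intact from scrambled reads", {
  ref <- simulate_reference(5000, 0.5, seed = 212)
  sim <- simulate_long_reads(ref, 1000, 1, ins_rate = 0, del_rate = 0,
                             sub_rate = 0, seed = 213)
  af <- aligned_fraction(sim$reads, sim$truth, ref)
  expect_equal(af$pct_reads, 100)
  expect_equal(af$pct_bases, 100)

  two <- sim$reads[1:2, ]
  two$seq[2] <- random_seq(nchar(two$seq[2]))  # unrelated sequence
  af2 <- aligned_fraction(two, sim$truth, ref)
  expect_equal(af2$pct_reads, 50)
  expect_equal(af2$pct_bases,
               100 * nchar(two$seq[1]) / sum(nchar(two$seq)))

  expect_error(aligned_fraction(data.frame(id = "zz", seq = "ACGT"),
                                sim$truth, ref), "missing truth")
})

test_that("evaluate_correction aggregates per-read counts into gain", {
  ref <- simulate_reference(10000, 0.5, seed = 214)
  sim <- planted_sub_fixture(ref, seed = 215, n_subs = 15L)
  # perfectly corrected reads: gain 1
  iv <- sim$truth$intervals
  corrected <- sim$reads
  corrected$seq <- substring(ref, iv$ref_start, iv$ref_end)
  m <- evaluate_correction(sim$reads, corrected, sim$truth, ref)
  expect_equal(m$gain, 1)
  expect_equal(m$FP, 0L)
  expect_equal(m$mean_identity, 1)
  # uncorrected sub-only reads: everything remains, gain 0
  m0 <- evaluate_correction(sim$reads, sim$reads, sim$truth, ref)
  expect_equal(m0$gain, 0)
  expect_equal(m0$TP, 0L)
  expect_equal(m0$n50_before, m0$n50_after)
})
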