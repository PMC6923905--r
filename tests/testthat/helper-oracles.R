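# Independent oracles and fixture builders used across the suite.

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# byte-order string minimum (locale-independent, matches 2-bit code order)
str_min <- function(a, b) {
  vapply(seq_along(a), function(i)
    sort(c(a[i], b[i]), method = "radix")[1L], character(1))
}

# brute-force multiset k-mer counter over all valid windows, independent of
# the package's graph machinery
brute_kmer_count <- function(seqs, k, canonical = FALSE) {
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, 1:(n - k + 1), k:n)
    w[!grepl("[^ACGT]", w)]
  }))
  if (canonical && length(all)) all <- str_min(all, revcomp(all))
  if (!length(all)) return(integer(0))
  tab <- table(all)
  setNames(as.integer(tab), names(tab))
}

brute_window_count <- function(seqs, k) {
  sum(vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(0L)
    w <- substring(s, 1:(n - k + 1), k:n)
    sum(!grepl("[^ACGT]", w))
  }, 1L))
}

# Build a small single-strand DBG fixture from named vertex coverages and an
# explicit edge list (each edge a c(u, v) pair with k-1 overlap).
dbg_from_edges <- function(coverages, edges, k = nchar(names(coverages)[1])) {
  vs <- names(coverages)
  inc <- setNames(rep("", length(vs)), vs)
  outc <- setNames(rep("", length(vs)), vs)
  for (e in edges) {
    u <- e[1]; v <- e[2]
    stopifnot(substr(u, 2, k) == substr(v, 1, k - 1))
    outc[u] <- paste0(outc[u], substr(v, k, k))
    inc[v] <- paste0(inc[v], substr(u, 1, 1))
  }
  clean <- function(x) {
    y <- vapply(strsplit(x, ""), function(ch)
      paste(sort(unique(ch)), collapse = ""), character(1))
    ifelse(y == "", "-", y)
  }
  tab <- data.frame(kmer = vs, count = as.integer(coverages),
                    in_chars = clean(inc), out_chars = clean(outc),
                    stringsAsFactors = FALSE)
  graph_from_table(tab, k, canonical = FALSE)
}

# Random valid DBG over 2-mers: every feasible (k-1)-overlap edge included
# with a probability drawn from [0.3, 0.7], coverages uniform on 1..10.
random_small_dbg <- function(n_max = 8L) {
  all2 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0))
  n <- sample(2:n_max, 1L)
  vs <- sample(all2, n)
  p <- runif(1, 0.3, 0.7)
  edges <- list()
  for (u in vs) for (v in vs) {
    if (substr(u, 2, 2) == substr(v, 1, 1) && runif(1) < p)
      edges[[length(edges) + 1L]] <- c(u, v)
  }
  cov <- setNames(sample.int(10L, n, replace = TRUE), vs)
  list(graph = dbg_from_edges(cov, edges, k = 2L), vertices = vs,
       coverages = cov, edges = edges)
}

# Exhaustive enumeration of simple paths src -> dst with at most max_len
# vertices, via the graph's successor queries.
enumerate_paths <- function(graph, src, dst, max_len) {
  paths <- list()
  walk <- function(path) {
    cur <- path[length(path)]
    if (cur == dst) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) >= max_len) return(invisible())
    nb <- successors(graph, cur)$kmer
    for (v in nb) if (!v %in% path) walk(c(path, v))
  }
  if (coverage(graph, src) > 0 && coverage(graph, dst) > 0) walk(src)
  paths
}

enum_path_stats <- function(graph, src, dst, max_len) {
  paths <- enumerate_paths(graph, src, dst, max_len)
  if (!length(paths))
    return(list(reachable = FALSE, best_width = NA, min_len = NA))
  widths <- vapply(paths, function(p) min(coverage(graph, p)), 1L)
  lens <- lengths(paths)
  best <- max(widths)
  list(reachable = TRUE, best_width = best,
       min_len = min(lens),
       min_len_at_best = min(lens[widths == best]))
}

# Exhaustive global-alignment score for short sequences (recursion over the
# three moves), independent of any DP implementation.
brute_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0 && j == 0) 0
    else {
      best <- -Inf
      if (i > 0 && j > 0)
        best <- max(best, f(i - 1, j - 1) +
                      if (substr(a, i, i) == substr(b, j, j)) match else
                        mismatch)
      if (i > 0) best <- max(best, f(i - 1, j) + gap)
      if (j > 0) best <- max(best, f(i, j - 1) + gap)
      best
    }
    memo[[key]] <- res
    res
  }
  f(nchar(a), nchar(b))
}

# A reference sequence plus perfectly tiling error-free short reads, giving
# every interior k-mer solid, near-uniform coverage.
tiling_fixture <- function(ref_len = 600L, read_len = 40L, step = 2L,
                           seed = 1L) {
  set.seed(seed)
  ref <- random_seq(ref_len)
  starts <- seq(1L, ref_len - read_len + 1L, by = step)
  reads <- data.frame(id = sprintf("t%d", seq_along(starts)),
                      seq = substring(ref, starts, starts + read_len - 1L),
                      qual = NA_character_, stringsAsFactors = FALSE)
  list(ref = ref, reads = reads)
}

# substitute one base (0-based position) with a different fixed base
plant_sub <- function(seq, pos0) {
  old <- substr(seq, pos0 + 1, pos0 + 1)
  new <- setdiff(c("A", "C", "G", "T"), old)[1L]
  substr(seq, pos0 + 1, pos0 + 1) <- new
  list(seq = seq, old = old, new = new)
}
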