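#' Simulate a random reference sequence
#'
#' I.i.d. bases with the requested GC content.  An optional repeat injection
#' copies a substring of the sequence to one or more other loci, which
#' creates branching in the de Bruijn graph the way genomic repeats do.
#'
#' @param length Sequence length in bases.
#' @param gc Fraction of G+C (0..1).
#' @param seed Optional integer seed (the generator is deterministic given
#'   the seed).
#' @param repeat_len Length of the repeated substring (0 disables).
#' @param repeat_copies Number of extra copies to paste at random loci.
#' @return A single character string.
#' @export
simulate_reference <- function(length, gc = 0.5, seed = NULL,
                               repeat_len = 0L, repeat_copies = 0L) {
  if (length < 1) stop("length must be >= 1")
  if (is.na(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = p)
  if (repeat_len > 0L && repeat_copies > 0L && repeat_len < length) {
    src <- sample.int(length - repeat_len + 1L, 1L)
    unit <- bases[src:(src + repeat_len - 1L)]
    for (i in seq_len(repeat_copies)) {
      dst <- sample.int(length - repeat_len + 1L, 1L)
      bases[dst:(dst + repeat_len - 1L)] <- unit
    }
  }
  paste(bases, collapse = "")
}

random_other_base <- function(current) {
  # uniformly random base different from `current`, vectorized
  alt <- matrix(c("C", "G", "T",  # A ->
                  "A", "G", "T",  # C ->
                  "A", "C", "T",  # G ->
                  "A", "C", "G"), # T ->
                nrow = 4L, byrow = TRUE,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pick <- sample.int(3L, length(current), replace = TRUE)
  alt[cbind(match(current, rownames(alt)), pick)]
}

empty_events <- function() {
  data.frame(read_id = character(0), ref_pos = integer(0),
             type = character(0), ref_base = character(0),
             read_base = character(0), stringsAsFactors = FALSE)
}

#' Simulate short reads with substitution errors
#'
#' Uniformly placed reads from both strands until the target coverage is
#' reached (`ceiling(coverage * ref_len / read_len)` reads); each base is
#' substituted with probability `sub_rate` to a uniformly random different
#' base, emulating the substitution-dominated ~1% error profile of
#' second-generation short reads.  Every planted error is logged with its
#' reference coordinate.
#'
#' @param ref Reference sequence (single string).
#' @param read_len Read length (default 100).
#' @param coverage Target fold coverage (default 50).
#' @param sub_rate Per-base substitution probability (default 0.01).
#' @param seed Optional integer seed.
#' @return A list with `reads` (read set `data.frame`) and `truth` (an error
#'   log: list of `intervals` — `read_id`, `ref_start`, `ref_end` 1-based
#'   inclusive, `strand` — and `events` — `read_id`, `ref_pos`, `type`,
#'   `ref_base`, `read_base`, all in the forward frame of the interval).
#'   Minus-strand reads are emitted reverse-complemented; their events stay
#'   in the forward frame.
#' @export
simulate_short_reads <- function(ref, read_len = 100L, coverage = 50,
                                 sub_rate = 0.01, seed = NULL) {
  L <- nchar(ref)
  if (read_len > L) stop("read_len must not exceed the reference length")
  if (sub_rate < 0 || sub_rate >= 0.5) stop("sub_rate must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(ceiling(coverage * L / read_len))
  starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(ref, starts, starts + read_len - 1L)
  err <- which(runif(n * read_len) < sub_rate)  # index over read x offset
  events <- empty_events()
  if (length(err)) {
    ri <- ((err - 1L) %/% read_len) + 1L   # read index
    off <- ((err - 1L) %% read_len) + 1L   # 1-based offset in forward frame
    old <- substring(seqs[ri], off, off)
    new <- random_other_base(old)
    for (j in seq_along(err)) {
      s <- seqs[ri[j]]
      substr(s, off[j], off[j]) <- new[j]
      seqs[ri[j]] <- s
    }
    events <- data.frame(read_id = sprintf("S%d", ri),
                         ref_pos = starts[ri] + off - 1L, type = "sub",
                         ref_base = old, read_base = new,
                         stringsAsFactors = FALSE)
  }
  minus <- strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  reads <- data.frame(id = sprintf("S%d", seq_len(n)), seq = seqs,
                      qual = NA_character_, stringsAsFactors = FALSE)
  intervals <- data.frame(read_id = reads$id, ref_start = starts,
                          ref_end = starts + read_len - 1L, strand = strand,
                          stringsAsFactors = FALSE)
  list(reads = reads, truth = new_error_log(intervals, events))
}

#' Simulate long reads with indel and substitution errors
#'
#' Read lengths are drawn from a lognormal distribution around `mean_len`;
#' each read derives from a uniformly placed reference interval.  Errors are
#' independent per reference base: a deletion drops the base, a substitution
#' replaces it, and an insertion adds one uniformly random base before it.
#' The defaults (insertion 6%, deletion 5%, substitution 2%) emulate the
#' ~13% indel-dominated error profile of raw third-generation long reads.
#' Every event is logged with its reference coordinate; replaying the log
#' over the interval reproduces the read exactly.  Reads are recorded on the
#' forward strand of their interval to keep the ground truth simple.
#'
#' @param ref Reference sequence (single string).
#' @param mean_len Mean read length (default 5000).
#' @param coverage Target fold coverage (default 10).
#' @param ins_rate,del_rate,sub_rate Per-base event probabilities, each in
#'   `[0, 0.5)`.
#' @param sdlog Lognormal sdlog of the length distribution (default 0.1).
#' @param seed Optional integer seed.
#' @return A list with `reads` and `truth` as in [simulate_short_reads()].
#' @export
simulate_long_reads <- function(ref, mean_len = 5000L, coverage = 10,
                                ins_rate = 0.06, del_rate = 0.05,
                                sub_rate = 0.02, sdlog = 0.1, seed = NULL) {
  L <- nchar(ref)
  if (mean_len > L) stop("mean_len must not exceed the reference length")
  for (r in c(ins_rate, del_rate, sub_rate))
    if (r < 0 || r >= 0.5) stop("error rates must each be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(ceiling(coverage * L / mean_len))
  lens <- pmin(L, pmax(50L, as.integer(round(
    rlnorm(n, log(mean_len) - sdlog^2 / 2, sdlog)))))
  starts <- vapply(lens, function(l) sample.int(L - l + 1L, 1L), 1L)
  seqs <- character(n)
  ev_list <- vector("list", n)
  for (i in seq_len(n)) {
    s <- starts[i]
    chars <- strsplit(substring(ref, s, s + lens[i] - 1L), "")[[1L]]
    m <- length(chars)
    u <- runif(m)
    del <- u < del_rate
    sub <- !del & u < del_rate + sub_rate
    ins <- runif(m) < ins_rate
    emitted <- chars
    if (any(sub)) emitted[sub] <- random_other_base(chars[sub])
    tok <- ifelse(del, "", emitted)
    ins_base <- character(0)
    if (any(ins)) {
      ins_base <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
      tok[ins] <- paste0(ins_base, tok[ins])
    }
    seqs[i] <- paste(tok, collapse = "")
    id <- sprintf("L%d", i)
    ev <- list()
    if (any(ins))
      ev[[length(ev) + 1L]] <- data.frame(
        read_id = id, ref_pos = s + which(ins) - 1L, type = "ins",
        ref_base = "", read_base = ins_base, stringsAsFactors = FALSE)
    if (any(del))
      ev[[length(ev) + 1L]] <- data.frame(
        read_id = id, ref_pos = s + which(del) - 1L, type = "del",
        ref_base = chars[del], read_base = "", stringsAsFactors = FALSE)
    if (any(sub))
      ev[[length(ev) + 1L]] <- data.frame(
        read_id = id, ref_pos = s + which(sub) - 1L, type = "sub",
        ref_base = chars[sub], read_base = emitted[sub],
        stringsAsFactors = FALSE)
    ev_list[[i]] <- if (length(ev)) do.call(rbind, ev) else empty_events()
  }
  events <- do.call(rbind, ev_list)
  events <- events[order(match(events$read_id, sprintf("L%d", seq_len(n))),
                         events$ref_pos,
                         match(events$type, c("ins", "del", "sub"))), ,
                   drop = FALSE]
  rownames(events) <- NULL
  reads <- data.frame(id = sprintf("L%d", seq_len(n)), seq = seqs,
                      qual = NA_character_, stringsAsFactors = FALSE)
  intervals <- data.frame(read_id = reads$id, ref_start = starts,
                          ref_end = starts + lens - 1L, strand = "+",
                          stringsAsFactors = FALSE)
  list(reads = reads, truth = new_error_log(intervals, events))
}

new_error_log <- function(intervals, events) {
  structure(list(intervals = intervals, events = events),
            class = "error_log")
}

#' @export
print.error_log <- function(x, ...) {
  cat(sprintf("error log: %d reads, %d events (%s)\n",
              nrow(x$intervals), nrow(x$events),
              paste(sprintf("%s %d", names(table(x$events$type)),
                            as.integer(table(x$events$type))),
                    collapse = ", ")))
  invisible(x)
}

#' Replay a truth log to reconstruct a read
#'
#' Applies the logged events of one read to its reference interval; the
#' result must equal the emitted read exactly (in the forward frame; a
#' minus-strand read is the reverse complement of the replay).
#'
#' @param truth An `error_log`.
#' @param read_id Read identifier.
#' @param ref Reference sequence.
#' @return The reconstructed forward-frame read sequence.
#' @export
replay_read <- function(truth, read_id, ref) {
  iv <- truth$intervals[truth$intervals$read_id == read_id, , drop = FALSE]
  if (nrow(iv) != 1L) stop("unknown read id: ", read_id)
  ev <- truth$events[truth$events$read_id == read_id, , drop = FALSE]
  s <- iv$ref_start
  chars <- strsplit(substring(ref, s, iv$ref_end), "")[[1L]]
  tok <- chars
  for (j in seq_len(nrow(ev))) {
    i <- ev$ref_pos[j] - s + 1L
    switch(ev$type[j],
           del = { tok[i] <- sub(".$", "", tok[i]) },
           sub = { tok[i] <- sub(".$", ev$read_base[j], tok[i]) },
           ins = { tok[i] <- paste0(ev$read_base[j], tok[i]) })
  }
  paste(tok, collapse = "")
}

#' Write / read a truth log as tab-separated text
#'
#' One row per event with the read's interval columns attached; reads
#' without any event get a single row with `type = "none"`.
#'
#' @param truth An `error_log`.
#' @param path Output path.
#' @return Invisibly the path; `read_truth` returns the `error_log`.
#' @export
write_truth <- function(truth, path) {
  iv <- truth$intervals
  ev <- truth$events
  merged <- merge(iv, ev, by = "read_id", all.x = TRUE, sort = FALSE)
  merged$type[is.na(merged$type)] <- "none"
  merged$ref_pos[is.na(merged$ref_pos)] <- 0L
  merged$ref_base[is.na(merged$ref_base)] <- ""
  merged$read_base[is.na(merged$read_base)] <- ""
  merged <- merged[order(match(merged$read_id, iv$read_id), merged$ref_pos), ]
  data.table::fwrite(merged, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  m <- as.data.frame(data.table::fread(path, sep = "\t",
                                       colClasses = list(
                                         character = c("read_id", "strand",
                                                       "type", "ref_base",
                                                       "read_base"))))
  iv <- unique(m[, c("read_id", "ref_start", "ref_end", "strand")])
  rownames(iv) <- NULL
  ev <- m[m$type != "none",
          c("read_id", "ref_pos", "type", "ref_base", "read_base")]
  rownames(ev) <- NULL
  new_error_log(iv, ev)
}
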