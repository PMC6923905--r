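#' Build a validated pipeline configuration
#'
#' Collects every tunable of the correction pipeline with its default,
#' validates the combination once, and is serialized into the run report
#' for provenance.
#'
#' @param short_reads,long_reads Input file paths (FASTA/FASTQ, optionally
#'   gzipped).
#' @param out_dir Output directory for all artifacts.
#' @param k K-mer length (default 21).
#' @param canonical Canonicalize k-mers (default `TRUE`).
#' @param tau Weak-coverage threshold for indel regions (default 3).
#' @param search Traversal strategy for weak-region reassembly.
#' @param b Greedy branching factor (default 100).
#' @param max_len_factor Path-length bound factor (default 2).
#' @param frag_len Substitution fragment length (default 100).
#' @param skew_low,skew_high True-fragment skew interval.
#' @param tau_low Error k-mer cutoff inside fragments (defaults to `tau`).
#' @param thresh_high,thresh_low Voting thresholds (`NULL` = derive from the
#'   spectrum median / `tau_low`).
#' @param run_subst Run the substitution phase on the indel-corrected reads
#'   (default `TRUE`).
#' @param ref Optional reference FASTA for evaluation.
#' @param truth Optional truth log (TSV from [write_truth()]) for
#'   evaluation.
#' @param workers Worker processes for the per-read stages.
#' @param seed Seed recorded for provenance (the correction itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(short_reads, long_reads, out_dir = ".",
                            k = 21L, canonical = TRUE, tau = 3L,
                            search = c("widest", "shortest", "greedy"),
                            b = 100L, max_len_factor = 2.0, frag_len = 100L,
                            skew_low = -0.3, skew_high = 0.3,
                            tau_low = tau, thresh_high = NULL,
                            thresh_low = NULL, run_subst = TRUE, ref = NULL,
                            truth = NULL, workers = 1L, seed = 1L) {
  search <- match.arg(search)
  k <- check_k(k)
  if (tau < 1) stop("tau must be a positive integer")
  if (frag_len < k) stop("frag_len must be at least k")
  if (skew_low > skew_high) stop("skew_low must not exceed skew_high")
  if (max_len_factor <= 0) stop("max_len_factor must be positive")
  if (b < 1) stop("b must be a positive integer")
  cfg <- list(short_reads = short_reads, long_reads = long_reads,
              out_dir = out_dir, k = k, canonical = canonical,
              tau = as.integer(tau), search = search, b = as.integer(b),
              max_len_factor = max_len_factor,
              frag_len = as.integer(frag_len), skew_low = skew_low,
              skew_high = skew_high, tau_low = as.integer(tau_low),
              thresh_high = thresh_high, thresh_low = thresh_low,
              run_subst = isTRUE(run_subst), ref = ref, truth = truth,
              workers = as.integer(workers), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full hybrid error-correction pipeline
#'
#' Stages in order: build the de Bruijn graph from the short reads, correct
#' long-read indel errors by weak-region reassembly, correct residual
#' substitution errors on the indel-corrected output, and (when a reference
#' and truth log are supplied) evaluate the correction.  Intermediate
#' artifacts are serialized to `out_dir` and reused when present, so an
#' interrupted run resumes; per-read results are independent of worker
#' count and processing order.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the output paths, the per-stage reports
#'   and (when evaluated) the metrics.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- list(
    graph = file.path(config$out_dir, "graph.tsv.gz"),
    indel = file.path(config$out_dir, "indel_corrected.fa"),
    final = file.path(config$out_dir, "final.fa"),
    indel_report = file.path(config$out_dir, "indel_report.tsv"),
    subst_report = file.path(config$out_dir, "subst_report.tsv"),
    metrics = file.path(config$out_dir, "metrics.json"),
    config = file.path(config$out_dir, "config.json"))
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)

  if (file.exists(paths$graph)) {
    say("stage build-graph: reusing %s", paths$graph)
    graph <- deserialize_graph(paths$graph)
    if (graph$k != config$k)
      stop("serialized graph has k = ", graph$k, " but config requests k = ",
           config$k)
  } else {
    say("stage build-graph: counting %d-mers", config$k)
    short <- read_sequences(config$short_reads)
    graph <- build_graph(short, k = config$k, canonical = config$canonical)
    serialize_graph(graph, paths$graph)
    say("stage build-graph: %d vertices, %.0f instances", n_vertices(graph),
        total_instances(graph))
  }

  long <- read_sequences(config$long_reads)
  if (file.exists(paths$indel)) {
    say("stage correct-indel: reusing %s", paths$indel)
    indel_reads <- read_sequences(paths$indel)
    indel_report <- NULL
  } else {
    say("stage correct-indel: %d long reads, %s search", nrow(long),
        config$search)
    ind <- correct_indels(long, graph, tau = config$tau,
                          search = config$search,
                          max_len_factor = config$max_len_factor,
                          b = config$b, workers = config$workers)
    indel_reads <- ind$reads
    indel_report <- ind$report
    write_sequences(indel_reads, paths$indel, "fasta")
    data.table::fwrite(indel_report, paths$indel_report, sep = "\t")
    say("stage correct-indel: replaced %d of %d weak regions",
        sum(ind$report$n_replaced), sum(ind$report$n_weak_regions))
  }

  subst_report <- NULL
  if (config$run_subst) {
    if (file.exists(paths$final)) {
      say("stage correct-subst: reusing %s", paths$final)
      final_reads <- read_sequences(paths$final)
    } else {
      say("stage correct-subst: fragment length %d", config$frag_len)
      sub <- correct_substitutions(indel_reads, graph,
                                   frag_len = config$frag_len,
                                   skew_low = config$skew_low,
                                   skew_high = config$skew_high,
                                   tau_low = config$tau_low,
                                   thresh_high = config$thresh_high,
                                   thresh_low = config$thresh_low,
                                   workers = config$workers)
      final_reads <- sub$reads
      subst_report <- sub$report
      write_sequences(final_reads, paths$final, "fasta")
      data.table::fwrite(subst_report, paths$subst_report, sep = "\t")
      say("stage correct-subst: corrected %d positions",
          sum(sub$report$n_positions_corrected))
    }
  } else {
    final_reads <- indel_reads
    write_sequences(final_reads, paths$final, "fasta")
  }

  metrics <- NULL
  if (!is.null(config$ref) && !is.null(config$truth)) {
    say("stage evaluate")
    ref <- read_sequences(config$ref)$seq[1L]
    truth <- if (is.character(config$truth)) read_truth(config$truth) else
      config$truth
    metrics <- evaluate_correction(long, final_reads, truth, ref)
    jsonlite::write_json(metrics[setdiff(names(metrics), "per_read")],
                         paths$metrics, auto_unbox = TRUE, digits = NA)
    say("stage evaluate: gain %.4f, mean identity %.4f", metrics$gain,
        metrics$mean_identity)
  }
  invisible(list(paths = paths, graph = graph,
                 indel_report = indel_report, subst_report = subst_report,
                 reads = final_reads, metrics = metrics))
}
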