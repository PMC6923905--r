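Package: hylec
Title: Hybrid Error Correction of Long Sequencing Reads Using Short-Read
    k-mer Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects the dominant indel errors and residual substitution
    errors of third-generation (PacBio-class) long sequencing reads using
    the k-mer coverage spectrum of accurate second-generation (Illumina-class)
    short reads. A coverage-annotated de Bruijn graph is built from the short
    reads; low-coverage (weak) regions of each long read are replaced by the
    widest path (maximum bottleneck, i.e. maximum minimum-coverage path)
    between the flanking solid k-mers, and substitution errors are then
    located by classifying read fragments with Pearson's median skew
    coefficient of their k-mer coverages and corrected by coverage-threshold
    voting. Includes a read simulator with per-base ground-truth error logs
    and an evaluation suite (correction gain, N50, aligned fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    jsonlite,
    parallel,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
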