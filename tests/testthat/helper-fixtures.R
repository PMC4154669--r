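# Shared fixture builders. Everything is generated in code; the "acceptance
# world" (the default simulated genome) is built once per test run and
# cached, since several suites interrogate the same discovery result.

tiny_genome <- function(n = 1, len = 1e6) {
  data.frame(chrom = paste0("chr", seq_len(n)), length = rep(len, n),
             stringsAsFactors = FALSE)
}

stack_reads <- function(n, chrom = "chr1", start = 1000, len = 200,
                        strand = "+") {
  genomic_intervals(rep(chrom, n), rep(start, n), rep(start + len, n),
                    name = sprintf("r%d", seq_len(n)), score = 1,
                    strand = strand)
}

random_reads <- function(n, genome, len = 200, seed = 1) {
  set.seed(seed)
  chrom <- sample(genome$chrom, n, replace = TRUE, prob = genome$length)
  maxlen <- chrom_lengths(genome)[chrom] - len
  start <- floor(runif(n) * maxlen)
  genomic_intervals(chrom, start, start + len,
                    name = sprintf("r%d", seq_len(n)), score = 1,
                    strand = sample(c("+", "-"), n, replace = TRUE))
}

random_intervals <- function(n, genome, max_w = 500, seed = 1) {
  set.seed(seed)
  chrom <- sample(genome$chrom, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  start <- floor(runif(n) * (chrom_lengths(genome)[chrom] - w))
  genomic_intervals(chrom, start, start + w)
}

# small but complete simulated world for fast end-to-end tests
small_config <- function(seed = 11, ...) {
  defaults <- list(chromosomes = c(chr1 = 3e5, chr2 = 3e5), n_genes = 6,
                   n_specific = 12, n_nonspecific = 12, n_genic_decoys = 4,
                   n_est = 4, rrna_loci = 1, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# default-scale world (the stated acceptance conditions), built once
.world <- new.env(parent = emptyenv())
acceptance_world <- function() {
  if (is.null(.world$sim)) {
    .world$sim <- simulate_bundle(sim_config(seed = 101))
    .world$fit <- suppressMessages(tstr_discover(
      .world$sim$readsets$A, .world$sim$readsets$B, .world$sim$genome,
      .world$sim$annotation$exclusions))
  }
  .world
}

# brute-force O(n^2) overlap oracle
brute_overlaps <- function(a, b) {
  hits <- which(outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
    a$chrom[i] == b$chrom[j] & a$start[i] < b$end[j] & b$start[j] < a$end[i]
  }), arr.ind = TRUE)
  data.frame(query = unname(hits[, 1]), subject = unname(hits[, 2]))
}

sort_pairs <- function(x) {
  x <- x[order(x$query, x$subject), , drop = FALSE]
  rownames(x) <- NULL
  x
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  md5 <- tools::md5sum(files)
  names(md5) <- basename(names(md5))
  md5
}
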