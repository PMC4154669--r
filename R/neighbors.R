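# Correlation of TSTR tissue specificity with nearby gene expression:
# exon-union gene RPKM, distance-ranked gene pairing (1st-5th nearest),
# the 20-genes-per-bin averaging procedure, and a random same-chromosome
# gene control.

#' Exon-union gene expression (RPKM) in both tissues
#'
#' Counts reads overlapping the union of a gene's exons (overlapping exons
#' merged; a read spanning two exons counts once) and converts to RPKM
#' using the exon-union length.
#'
#' @param genes Gene table (refFlat-like, with exon list columns).
#' @param rs_a,rs_b [read_set()] per tissue (extended reads).
#' @return `genes` with columns `exon_union_length`, `rpkm_a`, `rpkm_b`
#'   and strand-aware `tss`.
#' @export
gene_expression <- function(genes, rs_a, rs_b) {
  count_gene <- function(rs, exons) {
    sum(overlaps_any(rs$reads[rs$reads$chrom == exons$chrom[1], ,
                              drop = FALSE], exons))
  }
  res <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- IRanges::reduce(IRanges::IRanges(genes$exon_starts[[i]] + 1,
                                           genes$exon_ends[[i]]))
    exons <- genomic_intervals(rep(genes$chrom[i], length(ex)),
                               IRanges::start(ex) - 1, IRanges::end(ex))
    ulen <- sum(exons$end - exons$start)
    c(ulen, count_gene(rs_a, exons), count_gene(rs_b, exons))
  })
  res <- do.call(rbind, res)
  genes$exon_union_length <- res[, 1]
  genes$rpkm_a <- rpkm(res[, 2], res[, 1], rs_a$library_size)
  genes$rpkm_b <- rpkm(res[, 3], res[, 1], rs_b$library_size)
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  genes
}

#' Gene tissue-specificity index relative to a matching tissue
#'
#' @param gene_expr Output of [gene_expression()].
#' @param matching_is_a Logical vector: is tissue A the matching tissue of
#'   the paired TSTR?
#' @return SI values in `[-1, 1]` (0 with a warning when a gene is silent
#'   in both tissues).
#' @export
gene_specificity_index <- function(gene_expr, matching_is_a) {
  s <- ifelse(matching_is_a, gene_expr$rpkm_a, gene_expr$rpkm_b)
  u <- ifelse(matching_is_a, gene_expr$rpkm_b, gene_expr$rpkm_a)
  specificity_index(s, u)
}

#' Rank genes by distance to each TSTR
#'
#' Genes are ordered by `|TSTR center - TSS|` regardless of gene strand
#' (the TSS position itself is strand-aware); distance ties are broken by
#' gene id. Pairs are formed genome-wide (any chromosome), matching a
#' simple nearest-gene definition.
#'
#' @param tstrs Region data frame.
#' @param genes Gene table with a `tss` column (see [gene_expression()]).
#' @param k_max Number of ranks (default 5).
#' @return Data frame with columns `tstr` (row index), `rank`, `gene`
#'   (row index into `genes`), `distance`.
#' @export
rank_nearest_genes <- function(tstrs, genes, k_max = 5) {
  if (nrow(genes) < k_max)
    stop(sprintf("need at least %d genes for %d ranks", k_max, k_max))
  centers <- region_centers(tstrs)
  rows <- lapply(seq_len(nrow(tstrs)), function(i) {
    same <- which(genes$chrom == tstrs$chrom[i])
    cand <- if (length(same) >= k_max) same else seq_len(nrow(genes))
    d <- ifelse(genes$chrom[cand] == tstrs$chrom[i],
                abs(centers[i] - genes$tss[cand]), Inf)
    ord <- cand[order(d, genes$gene[cand])][seq_len(k_max)]
    data.frame(tstr = i, rank = seq_len(k_max), gene = ord,
               distance = d[match(ord, cand)])
  })
  do.call(rbind, rows)
}

#' Binned Pearson correlation of paired specificity indices
#'
#' Pairs are sorted by gene SI, grouped into consecutive bins of
#' `bin_size` (the final partial bin is kept when it holds at least half a
#' bin, otherwise merged into the previous one), and the Pearson
#' correlation is computed across bin means. `bin_size = 1` reduces to the
#' plain Pearson correlation over all pairs.
#'
#' @param gene_si,tstr_si Paired SI vectors.
#' @param bin_size Genes per bin (default 20).
#' @return List with `r` (Pearson correlation over bin means), `bins`
#'   (data frame of per-bin mean gene and TSTR SI), `bin_size`.
#' @export
bin_and_correlate <- function(gene_si, tstr_si, bin_size = 20) {
  stopifnot(length(gene_si) == length(tstr_si))
  n <- length(gene_si)
  # secondary sort key makes binning invariant to input pair order
  ord <- order(gene_si, tstr_si)
  g <- gene_si[ord]; t <- tstr_si[ord]
  n_full <- n %/% bin_size
  rem <- n %% bin_size
  sizes <- rep(bin_size, n_full)
  if (rem > 0) {
    if (rem >= bin_size / 2 || n_full == 0) sizes <- c(sizes, rem)
    else sizes[n_full] <- sizes[n_full] + rem
  }
  if (length(sizes) < 2) stop("fewer than 2 bins; decrease bin_size")
  grp <- rep(seq_along(sizes), sizes)
  bins <- data.frame(gene_si = as.numeric(tapply(g, grp, mean)),
                     tstr_si = as.numeric(tapply(t, grp, mean)))
  r <- if (stats::sd(bins$gene_si) == 0 || stats::sd(bins$tstr_si) == 0)
    NA_real_ else stats::cor(bins$gene_si, bins$tstr_si)
  list(r = r, bins = bins, bin_size = bin_size)
}

#' Random same-chromosome gene control pairing
#'
#' Pairs each TSTR with one uniformly chosen gene from the same
#' chromosome; TSTRs on chromosomes without genes are skipped with a
#' warning.
#'
#' @param tstrs Region data frame.
#' @param genes Gene table.
#' @param seed Integer seed.
#' @return Data frame with columns `tstr`, `gene`.
#' @export
random_gene_control <- function(tstrs, genes, seed = 1) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(tstrs)), function(i) {
      same <- which(genes$chrom == tstrs$chrom[i])
      if (!length(same)) return(NULL)
      data.frame(tstr = i, gene = same[sample.int(length(same), 1)])
    })
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    warning(sprintf("%d TSTR(s) on chromosomes without genes were skipped",
                    dropped))
  do.call(rbind, rows)
}

#' Per-rank correlation of TSTR and nearby-gene tissue specificity
#'
#' For each distance rank 1..`k_max` and for the random same-chromosome
#' control, pairs every TSTR with the corresponding gene, computes gene SI
#' relative to the TSTR's tissue, and applies the binned correlation.
#'
#' @param tstrs TSTR table with columns `si` and `tissue`.
#' @param gene_expr Output of [gene_expression()].
#' @param tissues The two tissue labels (A first).
#' @param k_max Number of distance ranks.
#' @param bin_size Genes per bin.
#' @param seed Seed for the random control.
#' @return Data frame with columns `rank` (`"1"`..`"5"`, `"random"`), `r`,
#'   `n_pairs`.
#' @export
neighbor_correlation <- function(tstrs, gene_expr, tissues = c("A", "B"),
                                 k_max = 5, bin_size = 20, seed = 1) {
  pairs <- rank_nearest_genes(tstrs, gene_expr, k_max)
  matching_is_a <- tstrs$tissue[pairs$tstr] == tissues[1]
  pairs$gene_si <- suppressWarnings(
    gene_specificity_index(gene_expr[pairs$gene, ], matching_is_a))
  pairs$tstr_si <- tstrs$si[pairs$tstr]
  rows <- lapply(seq_len(k_max), function(k) {
    sel <- pairs$rank == k
    bc <- bin_and_correlate(pairs$gene_si[sel], pairs$tstr_si[sel], bin_size)
    data.frame(rank = as.character(k), r = bc$r, n_pairs = sum(sel))
  })
  rnd <- suppressWarnings(random_gene_control(tstrs, gene_expr, seed))
  if (!is.null(rnd) && nrow(rnd) >= 2 * bin_size) {
    gsi <- suppressWarnings(gene_specificity_index(
      gene_expr[rnd$gene, ], tstrs$tissue[rnd$tstr] == tissues[1]))
    bc <- bin_and_correlate(gsi, tstrs$si[rnd$tstr], bin_size)
    rows <- c(rows, list(data.frame(rank = "random", r = bc$r,
                                    n_pairs = nrow(rnd))))
  }
  do.call(rbind, rows)
}
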