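# File formats: BED6 / BED5 (scored), bedGraph, refFlat-like gene tables,
# key-value manifests. All coordinates on disk are BED convention (0-based
# half-open). Readers are gzip-transparent (base connections) and report
# malformed input with the offending line number; writers use fixed
# formatting so identical inputs give byte-identical files.

#' @noRd
read_tab_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track")]
}

#' @noRd
split_fields <- function(lines, min_fields, what, path) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_fields)) {
    i <- which(nf < min_fields)[1]
    stop(sprintf("%s: malformed %s record at line %d (%d field(s), need >= %d)",
                 path, what, i, nf[i], min_fields))
  }
  fields
}

#' @noRd
num_field <- function(fields, k, what, path) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
  if (anyNA(v)) {
    i <- which(is.na(v))[1]
    stop(sprintf("%s: non-numeric %s field %d at line %d", path, what, k, i))
  }
  v
}

#' Read a BED file (3-6 columns)
#'
#' Missing name/score/strand columns are filled with `"."`, `0`, `"."`.
#' Records with a score other than 1 can optionally be dropped as
#' multi-mapped reads (read files carry score 1 = uniquely mapped).
#'
#' @param path File path (plain or gzip).
#' @param unique_only Drop records whose score != 1 and message the count.
#' @return Interval data frame.
#' @export
read_bed <- function(path, unique_only = FALSE) {
  lines <- read_tab_lines(path)
  if (length(lines) == 0) return(empty_intervals())
  fields <- split_fields(lines, 3L, "BED", path)
  nf <- lengths(fields)
  get <- function(k, default) {
    ifelse(nf >= k, vapply(fields, function(f) f[min(k, length(f))], ""),
           default)
  }
  x <- data.frame(chrom = vapply(fields, `[[`, "", 1),
                  start = num_field(fields, 2, "BED", path),
                  end = num_field(fields, 3, "BED", path),
                  name = get(4, "."),
                  score = suppressWarnings(as.numeric(get(5, "0"))),
                  strand = get(6, "."),
                  stringsAsFactors = FALSE)
  if (anyNA(x$score))
    stop(sprintf("%s: non-numeric BED score at line %d", path,
                 which(is.na(x$score))[1]))
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("%s: invalid BED interval at line %d", path, bad[1]))
  if (!all(x$strand %in% c("+", "-", ".")))
    stop(sprintf("%s: invalid strand at line %d", path,
                 which(!x$strand %in% c("+", "-", "."))[1]))
  if (unique_only) {
    drop <- x$score != 1
    if (any(drop))
      message(sprintf("%s: dropped %d non-unique record(s)", path, sum(drop)))
    x <- x[!drop, , drop = FALSE]
    rownames(x) <- NULL
  }
  x
}

#' Write intervals as BED6
#' @param x Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  lines <- if (nrow(x) == 0) character(0) else
    sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
            as.integer(x$end), x$name, format_score(x$score), x$strand)
  writeLines(lines, path)
  invisible(path)
}

#' @noRd
format_score <- function(s) {
  ifelse(s == round(s), sprintf("%d", as.integer(round(s))),
         sprintf("%.6f", s))
}

#' Read a bedGraph file
#' @param path File path (plain or gzip).
#' @return Interval data frame with `score` carrying the track value.
#' @export
read_bedgraph <- function(path) {
  lines <- read_tab_lines(path)
  if (length(lines) == 0) return(empty_intervals())
  fields <- split_fields(lines, 4L, "bedGraph", path)
  x <- data.frame(chrom = vapply(fields, `[[`, "", 1),
                  start = num_field(fields, 2, "bedGraph", path),
                  end = num_field(fields, 3, "bedGraph", path),
                  name = ".",
                  score = num_field(fields, 4, "bedGraph", path),
                  strand = ".",
                  stringsAsFactors = FALSE)
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("%s: invalid bedGraph interval at line %d", path, bad[1]))
  x
}

#' Write a bedGraph file (fixed 6-decimal values)
#'
#' Records must be sorted and non-overlapping within each chromosome.
#' @param x Interval data frame with `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  validate_intervals(x)
  if (nrow(x) > 1) {
    for (chrom in unique(x$chrom)) {
      xi <- x[x$chrom == chrom, , drop = FALSE]
      if (is.unsorted(xi$start) ||
          any(xi$start[-1] < xi$end[-nrow(xi)]))
        stop("bedGraph records must be sorted and non-overlapping")
    }
  }
  lines <- if (nrow(x) == 0) character(0) else
    sprintf("%s\t%d\t%d\t%.6f", x$chrom, as.integer(x$start),
            as.integer(x$end), x$score)
  writeLines(lines, path)
  invisible(path)
}

#' Read a refFlat-like gene table
#'
#' Tab-separated, one transcript per line: geneName, name, chrom, strand,
#' txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds
#' (comma-separated, trailing comma tolerated). Coordinates 0-based
#' half-open.
#'
#' @param path File path (plain or gzip).
#' @return Data frame with list columns `exon_starts`, `exon_ends`.
#' @export
read_refflat <- function(path) {
  lines <- read_tab_lines(path)
  if (length(lines) == 0) {
    return(data.frame(gene = character(), name = character(),
                      chrom = character(), strand = character(),
                      tx_start = numeric(), tx_end = numeric()))
  }
  fields <- split_fields(lines, 11L, "refFlat", path)
  parse_list <- function(k) {
    lapply(seq_along(fields), function(i) {
      v <- suppressWarnings(
        as.numeric(strsplit(fields[[i]][[k]], ",", fixed = TRUE)[[1]]))
      if (anyNA(v))
        stop(sprintf("%s: non-numeric exon list at line %d", path, i))
      v
    })
  }
  x <- data.frame(gene = vapply(fields, `[[`, "", 1),
                  name = vapply(fields, `[[`, "", 2),
                  chrom = vapply(fields, `[[`, "", 3),
                  strand = vapply(fields, `[[`, "", 4),
                  tx_start = num_field(fields, 5, "refFlat", path),
                  tx_end = num_field(fields, 6, "refFlat", path),
                  cds_start = num_field(fields, 7, "refFlat", path),
                  cds_end = num_field(fields, 8, "refFlat", path),
                  exon_count = num_field(fields, 9, "refFlat", path),
                  stringsAsFactors = FALSE)
  x$exon_starts <- parse_list(10)
  x$exon_ends <- parse_list(11)
  bad <- which(x$exon_count != lengths(x$exon_starts) |
                 x$exon_count != lengths(x$exon_ends))
  if (length(bad))
    stop(sprintf("%s: exonCount mismatch at line %d", path, bad[1]))
  x
}

#' Write a refFlat-like gene table
#' @param genes Gene table as returned by [read_refflat()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_refflat <- function(genes, path) {
  join <- function(v) paste0(paste(as.integer(v), collapse = ","), ",")
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    paste(genes$gene[i], genes$name[i], genes$chrom[i], genes$strand[i],
          as.integer(genes$tx_start[i]), as.integer(genes$tx_end[i]),
          as.integer(genes$cds_start[i]), as.integer(genes$cds_end[i]),
          as.integer(genes$exon_count[i]), join(genes$exon_starts[[i]]),
          join(genes$exon_ends[[i]]), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a key-value manifest
#' @param x Named list of scalar values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  writeLines(sprintf("%s\t%s", names(x),
                     vapply(x, function(v) paste(format(v), collapse = ","), "")),
             path)
  invisible(path)
}

#' Read a key-value manifest written by [write_manifest()]
#' @param path File path.
#' @return Named character vector.
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) paste(p[-1], collapse = "\t"), ""),
                  vapply(parts, `[[`, "", 1))
}

#' @noRd
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
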