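#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated text (UCSC chrom.sizes dialect):
#' chromosome name and length in bp.
#'
#' @param path file path.
#' @return named integer-ish numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                  col.names = c("chrom", "length"))
  stats::setNames(as.numeric(d$length), d$chrom)
}

#' Write a chrom.sizes file
#' @param genome named numeric vector (chrom -> length).
#' @param path destination.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(names(genome), as.numeric(genome)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a cells-by-features count matrix as (optionally gzipped) TSV
#'
#' First column \code{cell}, remaining columns features.
#'
#' @param m numeric matrix with rownames (cells) and colnames (features).
#' @param path destination; a \code{.gz} suffix triggers gzip compression.
#' @export
write_count_tsv <- function(m, path) {
  d <- data.frame(cell = rownames(m), m, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cells-by-features TSV written by \code{write_count_tsv}
#' @param path file path (plain or gzipped).
#' @return numeric matrix with cell rownames.
#' @export
read_count_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Intervals as a GRanges from a BED(-like) file
#'
#' Reads BED3+ (0-based half-open); extra columns kept as metadata.
#'
#' @param path BED file path.
#' @param extra_names optional names for columns beyond the first three.
#' @return a \code{GenomicRanges::GRanges}.
#' @export
read_bed <- function(path, extra_names = NULL) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  nm <- base[seq_len(min(ncol(d), 6))]
  if (ncol(d) > 6) {
    nm <- c(nm, extra_names %||% paste0("V", seq_len(ncol(d) - 6) + 6))
  } else if (!is.null(extra_names)) {
    nm[seq(4, length.out = length(extra_names))] <- extra_names
  }
  names(d)[seq_along(nm)] <- nm
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(start = d$start + 1, end = d$end))
  meta <- d[, setdiff(names(d), c("chrom", "start", "end")), drop = FALSE]
  if (ncol(meta)) S4Vectors::mcols(gr) <- meta
  gr
}

#' Write a GRanges (plus metadata columns) as BED6+
#'
#' Coordinates are written 0-based half-open; metadata columns beyond
#' name/score/strand become extra BED columns in order.
#'
#' @param gr a GRanges; optional mcols \code{name}, \code{score}, \code{strand}
#'   fill BED columns 4-6, any others are appended.
#' @param path destination.
#' @export
write_bed <- function(gr, path) {
  mc <- as.data.frame(S4Vectors::mcols(gr))
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                  start = GenomicRanges::start(gr) - 1L,
                  end = GenomicRanges::end(gr),
                  name = if ("name" %in% names(mc)) mc$name else ".",
                  score = if ("score" %in% names(mc)) mc$score else 0,
                  strand = if ("strand" %in% names(mc)) mc$strand else ".",
                  stringsAsFactors = FALSE)
  extra <- mc[, setdiff(names(mc), c("name", "score", "strand")), drop = FALSE]
  if (ncol(extra)) d <- cbind(d, extra)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## intervals given as data.frame(chrom,start,end[,...]) (0-based half-open)
## -> GRanges (1-based closed internally, the Bioconductor convention)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}
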