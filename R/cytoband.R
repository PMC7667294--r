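#' Read a UCSC-style cytoband table
#'
#' Parses the 5-column tab-separated cytoband format (chrom, chromStart,
#' chromEnd, name, gieStain) as distributed by the UCSC genome browser for
#' hg19. Coordinates in the file are 0-based half-open and are kept that way
#' internally; CNV calls use the 1-based inclusive clinical convention and are
#' converted at the query boundary (see [cytoband_label()]). The "chr" prefix
#' is normalised off. Within each chromosome bands must be sorted,
#' non-overlapping and contiguous; violations raise an error naming the
#' offending line.
#'
#' @param file path or connection to a cytoband file.
#' @return a `cytoband_table`: data.frame with columns chrom, start, end,
#'   band, stain.
#' @export
read_cytoband_table <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "band", "stain"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character"),
                          quote = "", comment.char = "")
  df$chrom <- sub("^chr", "", df$chrom)
  df$line <- seq_len(nrow(df))
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), ]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1) {
      gap <- which(sub$start[-1] != sub$end[-nrow(sub)])
      if (length(gap)) {
        bad <- sub$line[gap[1] + 1]
        stop(sprintf(
          "cytoband table not contiguous on chromosome %s at input line %d",
          ch, bad))
      }
    }
    if (any(sub$end <= sub$start)) {
      stop(sprintf("empty or inverted band on chromosome %s at input line %d",
                   ch, sub$line[which(sub$end <= sub$start)[1]]))
    }
  }
  df$line <- NULL
  rownames(df) <- NULL
  class(df) <- c("cytoband_table", "data.frame")
  df
}

#' Write a cytoband table in UCSC dialect
#'
#' @param cytobands a `cytoband_table`.
#' @param file destination path or connection.
#' @param chr_prefix prepend "chr" to chromosome names (UCSC convention).
#' @export
write_cytoband_table <- function(cytobands, file, chr_prefix = TRUE) {
  out <- as.data.frame(cytobands)
  if (chr_prefix) out$chrom <- paste0("chr", out$chrom)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Chromosome lengths implied by a cytoband table
#'
#' @param cytobands a `cytoband_table`.
#' @return named integer vector of chromosome lengths (bp).
#' @export
chromosome_lengths <- function(cytobands) {
  tapply(cytobands$end, cytobands$chrom, max)[unique(cytobands$chrom)]
}

#' Cytogenetic band label for a CNV
#'
#' Returns the cytoband containing a CNV given in 1-based inclusive
#' coordinates. A CNV spanning several bands is rendered ISCN-style as the
#' concatenation of the first and last band (e.g. `"p11.32p11.31"`).
#'
#' @param chrom chromosome name (without "chr").
#' @param start,end 1-based inclusive CNV coordinates.
#' @param cytobands a `cytoband_table`.
#' @return band label string, e.g. `"q11.23"` or `"q11q12"`.
#' @export
#' @examples
#' cb <- synthetic_cytobands()
#' cytoband_label("1", 1e6, 2e6, cb)
cytoband_label <- function(chrom, start, end, cytobands) {
  chrom <- sub("^chr", "", as.character(chrom))
  sub <- cytobands[cytobands$chrom == chrom, ]
  if (!nrow(sub)) stop(sprintf("chromosome %s absent from cytoband table", chrom))
  s0 <- start - 1L  # to 0-based half-open
  e0 <- end
  hit <- sub$start < e0 & sub$end > s0
  if (!any(hit)) stop(sprintf("region %s:%d-%d outside cytoband table extent",
                              chrom, start, end))
  bands <- sub$band[hit]
  if (length(bands) == 1) bands else paste0(bands[1], bands[length(bands)])
}

#' Deterministic synthetic cytoband genome
#'
#' Builds a 24-chromosome toy genome (1..22, X, Y) with hg19-like chromosome
#' lengths and ISCN-style band names (p-arm bands from pter to the
#' centromere, q-arm bands from the centromere to qter). This is a synthetic
#' stand-in used by the simulators and examples; the parser in
#' [read_cytoband_table()] accepts the real UCSC file when one is available.
#'
#' @param band_width approximate band width in bp (default 25 Mb).
#' @return a `cytoband_table`.
#' @export
synthetic_cytobands <- function(band_width = 25e6) {
  lens <- c(249e6, 243e6, 198e6, 191e6, 181e6, 171e6, 159e6, 146e6,
            141e6, 136e6, 135e6, 134e6, 115e6, 107e6, 103e6, 90e6,
            81e6, 78e6, 59e6, 63e6, 48e6, 51e6, 155e6, 59e6)
  chroms <- c(as.character(1:22), "X", "Y")
  rows <- list()
  for (i in seq_along(chroms)) {
    len <- lens[i]
    cen <- round(len * 0.4)
    np <- max(2L, round(cen / band_width))
    nq <- max(2L, round((len - cen) / band_width))
    pb <- round(seq(0, cen, length.out = np + 1))
    qb <- round(seq(cen, len, length.out = nq + 1))
    # p bands numbered outward from the centromere: pter carries the highest
    pnames <- paste0("p", rev(seq_len(np) + 10L))
    qnames <- paste0("q", seq_len(nq) + 10L)
    rows[[i]] <- data.frame(
      chrom = chroms[i],
      start = as.integer(c(pb[-length(pb)], qb[-length(qb)])),
      end = as.integer(c(pb[-1], qb[-1])),
      band = c(pnames, qnames),
      stain = rep_len(c("gneg", "gpos50"), np + nq),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  class(df) <- c("cytoband_table", "data.frame")
  df
}
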