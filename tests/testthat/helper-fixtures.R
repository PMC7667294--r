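# Small programmatic fixtures shared across test files.

# toy two-chromosome cytoband table: chr1 has q11 [0,1000) and q12
# [1000,2000); chr2 one band q11 [0,5000)
toy_cytobands <- function() {
  df <- data.frame(
    chrom = c("1", "1", "2"),
    start = c(0L, 1000L, 0L),
    end = c(1000L, 2000L, 5000L),
    band = c("q11", "q12", "q11"),
    stain = c("gneg", "gpos50", "gneg"),
    stringsAsFactors = FALSE)
  class(df) <- c("cytoband_table", "data.frame")
  df
}

# a tiny report archive with separable begin sentences, built by hand
toy_reports <- function() {
  mk <- function(id, chroms, starts, ends, types, paragraph) {
    list(report_id = id, sample_type = "prenatal",
         cnvs = cnv_calls(chroms, starts, ends, types,
                          validate_length = FALSE),
         paragraph = paragraph)
  }
  list(
    mk("T1", "1", 101, 700, "heterozygous_deletion",
       "analysis found a deletion on chr1 band q11. the finding was reviewed, no further remark"),
    mk("T2", "1", 1101, 1900, "duplication",
       "analysis found a duplication on chr1 band q12. described in the literature, patient follow up advised"),
    mk("T3", c("1", "2"), c(101, 1001), c(700, 4500),
       c("heterozygous_deletion", "duplication"),
       "analysis found a deletion on chr1 band q11, the syndrome region was noted. analysis found a duplication on chr2 band q11, described in the literature"),
    mk("T4", "2", 501, 4200, "duplication",
       "analysis found a duplication on chr2 band q11. the result was observed, this was stable"))
}

# brute-force overlap oracle: all-pairs scan (1-based inclusive)
brute_overlaps <- function(store, chrom, start, end) {
  hits <- store[store$chrom == chrom &
                store$start <= end & store$end >= start, , drop = FALSE]
  if (nrow(hits)) {
    hits$overlap_bp <- pmin(end, hits$end) - pmax(start, hits$start) + 1
  } else {
    hits$overlap_bp <- numeric(0)
  }
  hits[order(-hits$overlap_bp), , drop = FALSE]
}

# brute-force argmax-with-first-tie oracle for matching
brute_match <- function(score_matrix) {
  vapply(seq_len(nrow(score_matrix)), function(i) {
    row <- score_matrix[i, ]
    which(row == max(row))[1]
  }, integer(1))
}

# minimal interpreted-row scaffolding for compose_report tests: runs the
# real interpret path over a hand-built KB
toy_interpretation <- function(cnvs, kbs, cytobands,
                               filters = annotation_filters(),
                               config = scoring_config()) {
  interpret_cnvs(cnvs, kbs, cytobands, filters, config)
}
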