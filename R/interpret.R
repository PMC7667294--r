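#' Five-tier variant classification scale
#'
#' @format character vector: pathogenic, likely_pathogenic, VOUS,
#'   likely_benign, benign (reporting collapses the last two).
#' @export
FIVE_TIERS <- c("pathogenic", "likely_pathogenic", "VOUS", "likely_benign",
                "benign")

#' Overlap fractions between a query CNV and a database region
#'
#' Computes the exact base-pair overlap between two 1-based inclusive
#' regions together with the two normalised fractions used throughout the
#' evidence rules: `overlap_db` (overlap length over the knowledge-base
#' record length) and `overlap_query` (overlap length over the queried CNV
#' length). Regions on different chromosomes simply yield zeros.
#'
#' @param q_chrom,q_start,q_end query CNV region.
#' @param r_chrom,r_start,r_end knowledge-base record region.
#' @return list with `overlap_bp`, `overlap_db`, `overlap_query`.
#' @export
#' @examples
#' overlap_fractions("1", 101, 200, "1", 151, 250)
overlap_fractions <- function(q_chrom, q_start, q_end,
                              r_chrom, r_start, r_end) {
  q_chrom <- sub("^chr", "", as.character(q_chrom))
  r_chrom <- sub("^chr", "", as.character(r_chrom))
  if (q_chrom != r_chrom) {
    return(list(overlap_bp = 0, overlap_db = 0, overlap_query = 0))
  }
  ov <- max(0, min(q_end, r_end) - max(q_start, r_start) + 1)
  list(overlap_bp = ov,
       overlap_db = ov / (r_end - r_start + 1),
       overlap_query = ov / (q_end - q_start + 1))
}

#' Annotation filter configuration
#'
#' Per-store retrieval filters applied when annotating a CNV against the
#' knowledge bases. All thresholds are deliberately surfaced here as named,
#' documented defaults — they are operating points of this implementation,
#' not fixed biological constants — and every value can be overridden.
#'
#' * `syndrome_min_overlap_db`, `gene_min_overlap_db` (default 0.5): a
#'   syndrome region or dosage-sensitive gene must be at least half covered
#'   by the CNV before it counts.
#' * `polymorphism_min_overlap_query` (default 0.5): a population CNV must
#'   cover at least half of the query to speak to its benignity;
#'   `polymorphism_min_frequency` (0.01) and
#'   `polymorphism_min_sample_size` (1000) discard rare or under-powered
#'   population records.
#' * `paper_min_overlap_db` / `paper_min_overlap_query` (0.5/0.5):
#'   literature case regions must be reciprocally similar to the query.
#' * `patient_min_overlap_bp` (1): patient records are display-only, any
#'   intersection is shown.
#' * `incomplete_penetrance`: data.frame (chrom, start, end) of regions with
#'   incomplete penetrance; hits mostly inside one are annotated but flagged
#'   `excluded` and never scored.
#' * `whole_chromosome_fraction` (0.99): span fraction above which an event
#'   counts as a whole-chromosome aneuploidy.
#'
#' @param syndrome_min_overlap_db,gene_min_overlap_db,polymorphism_min_overlap_query,polymorphism_min_frequency,polymorphism_min_sample_size,paper_min_overlap_db,paper_min_overlap_query,patient_min_overlap_bp,incomplete_penetrance,whole_chromosome_fraction
#'   see description.
#' @return an `annotation_filters` list.
#' @export
annotation_filters <- function(syndrome_min_overlap_db = 0.5,
                               gene_min_overlap_db = 0.5,
                               polymorphism_min_overlap_query = 0.5,
                               polymorphism_min_frequency = 0.01,
                               polymorphism_min_sample_size = 1000,
                               paper_min_overlap_db = 0.5,
                               paper_min_overlap_query = 0.5,
                               patient_min_overlap_bp = 1,
                               incomplete_penetrance = NULL,
                               whole_chromosome_fraction = 0.99) {
  stopifnot(syndrome_min_overlap_db >= 0, syndrome_min_overlap_db <= 1,
            gene_min_overlap_db >= 0, gene_min_overlap_db <= 1,
            polymorphism_min_overlap_query >= 0,
            polymorphism_min_overlap_query <= 1,
            whole_chromosome_fraction > 0, whole_chromosome_fraction <= 1)
  structure(list(
    syndrome_min_overlap_db = syndrome_min_overlap_db,
    gene_min_overlap_db = gene_min_overlap_db,
    polymorphism_min_overlap_query = polymorphism_min_overlap_query,
    polymorphism_min_frequency = polymorphism_min_frequency,
    polymorphism_min_sample_size = polymorphism_min_sample_size,
    paper_min_overlap_db = paper_min_overlap_db,
    paper_min_overlap_query = paper_min_overlap_query,
    patient_min_overlap_bp = patient_min_overlap_bp,
    incomplete_penetrance = incomplete_penetrance,
    whole_chromosome_fraction = whole_chromosome_fraction),
    class = "annotation_filters")
}

in_penetrance_blocklist <- function(chrom, start, end, blocklist) {
  if (is.null(blocklist) || !nrow(blocklist)) {
    return(FALSE)
  }
  # a hit is blocked when most of it (>50%) lies inside a listed region
  len <- end - start + 1
  for (i in seq_len(nrow(blocklist))) {
    if (blocklist$chrom[i] != chrom) next
    ov <- max(0, min(end, blocklist$end[i]) - max(start, blocklist$start[i]) + 1)
    if (ov / len > 0.5) return(TRUE)
  }
  FALSE
}

#' Whole-chromosome event test
#'
#' An event whose span covers at least `min_fraction` of its chromosome
#' (default 0.99) is treated as a whole-chromosome aneuploidy: trisomy-style
#' gain for duplications, monosomy-style loss for deletions. Such events are
#' always reported pathogenic.
#'
#' @param chrom,start,end event region (1-based inclusive).
#' @param variation_type CNV copy-number state.
#' @param cytobands a `cytoband_table` supplying chromosome lengths.
#' @param min_fraction span fraction threshold.
#' @return list with `is_event` (logical) and `descriptor` (character; e.g.
#'   `"whole-chromosome gain (trisomy-like) of chromosome 21"`).
#' @export
is_whole_chromosome_event <- function(chrom, start, end, variation_type,
                                      cytobands, min_fraction = 0.99) {
  chrom <- sub("^chr", "", as.character(chrom))
  len <- chromosome_lengths(cytobands)[chrom]
  if (is.na(len)) stop(sprintf("chromosome %s absent from cytoband table", chrom))
  frac <- (end - start + 1) / len
  gain <- variation_type %in% c("duplication", "triplication")
  desc <- sprintf("whole-chromosome %s of chromosome %s",
                  if (gain) "gain (trisomy-like)" else "loss (monosomy-like)",
                  chrom)
  list(is_event = frac >= min_fraction,
       descriptor = if (frac >= min_fraction) desc else NA_character_,
       span_fraction = unname(frac))
}

#' Annotate a CNV against the knowledge bases
#'
#' Retrieves, for one CNV, every knowledge-base record that survives the
#' configured per-store filters, each carrying its exact overlap fractions.
#' Hits inside the incomplete-penetrance blocklist are kept in the
#' annotation (they remain reviewable) but flagged `excluded` so the
#' scoring layer ignores them. The whole annotation is a plain list of
#' data.frames, serialisable for expert review.
#'
#' @param cnv single-row `cnv_calls`.
#' @param kbs a `knowledge_base_set`.
#' @param filters an [annotation_filters()] configuration.
#' @param cytobands a `cytoband_table` (whole-chromosome test).
#' @return a `cnv_annotation` list: one data.frame per store plus the
#'   whole-chromosome descriptor.
#' @export
annotate_cnv <- function(cnv, kbs, filters = annotation_filters(),
                         cytobands) {
  stopifnot(inherits(kbs, "knowledge_base_set"))
  q <- list(chrom = cnv$chrom, start = cnv$start, end = cnv$end)
  add_fracs <- function(hits) {
    if (!nrow(hits)) {
      hits$overlap_db <- numeric(0); hits$overlap_query <- numeric(0)
      hits$excluded <- logical(0)
      return(hits)
    }
    fr <- lapply(seq_len(nrow(hits)), function(i) {
      overlap_fractions(q$chrom, q$start, q$end,
                        hits$chrom[i], hits$start[i], hits$end[i])
    })
    hits$overlap_db <- vapply(fr, `[[`, 0, "overlap_db")
    hits$overlap_query <- vapply(fr, `[[`, 0, "overlap_query")
    hits$excluded <- vapply(seq_len(nrow(hits)), function(i) {
      in_penetrance_blocklist(hits$chrom[i], hits$start[i], hits$end[i],
                              filters$incomplete_penetrance)
    }, TRUE)
    hits
  }
  poly <- add_fracs(query_region(kbs$polymorphism, q$chrom, q$start, q$end))
  poly <- poly[poly$overlap_query >= filters$polymorphism_min_overlap_query &
               poly$frequency >= filters$polymorphism_min_frequency &
               poly$sample_size >= filters$polymorphism_min_sample_size, ,
               drop = FALSE]
  synd <- add_fracs(query_region(kbs$syndrome, q$chrom, q$start, q$end))
  synd <- synd[synd$overlap_db >= filters$syndrome_min_overlap_db, ,
               drop = FALSE]
  gene <- add_fracs(query_region(kbs$gene, q$chrom, q$start, q$end))
  gene <- gene[gene$overlap_db >= filters$gene_min_overlap_db, ,
               drop = FALSE]
  pap <- add_fracs(query_region(kbs$paper, q$chrom, q$start, q$end))
  pap <- pap[pap$overlap_db >= filters$paper_min_overlap_db &
             pap$overlap_query >= filters$paper_min_overlap_query, ,
             drop = FALSE]
  pat <- add_fracs(query_region(kbs$patient, q$chrom, q$start, q$end))
  pat <- pat[pat$overlap_bp >= filters$patient_min_overlap_bp, ,
             drop = FALSE]
  wce <- is_whole_chromosome_event(cnv$chrom, cnv$start, cnv$end,
                                   cnv$variation_type, cytobands,
                                   filters$whole_chromosome_fraction)
  aneu <- if (wce$is_event) {
    query_region(kbs$aneuploid, q$chrom, q$start, q$end)
  } else {
    kbs$aneuploid[0, , drop = FALSE]
  }
  structure(list(cnv = as.list(cnv[c("chrom", "start", "end",
                                     "variation_type", "gender",
                                     "sample_type")]),
                 polymorphism = poly, syndrome = synd, gene = gene,
                 paper = pap, patient = pat, aneuploid = aneu,
                 whole_chromosome = wce),
            class = "cnv_annotation")
}

#' Evidence-scoring configuration
#'
#' Named defaults for turning an annotation into numeric evidence scores
#' and for the classification ladder. Invented operating points of this
#' implementation, all overridable:
#' `paper_lp_cases` 3 and `paper_p_cases` 10 (literature P/LP case counts
#' for likely-pathogenic/pathogenic), `syndrome_lp` 0.5 and `syndrome_p`
#' 0.75 (syndrome-coverage fractions), `gene_lp` 1 and `gene_p` 3 (counts
#' of dosage-matched genes), `benign_threshold` 0.01 (frequency-weighted
#' benign score).
#'
#' @param paper_lp_cases,paper_p_cases,syndrome_lp,syndrome_p,gene_lp,gene_p,benign_threshold
#'   see description.
#' @return a `scoring_config` list.
#' @export
scoring_config <- function(paper_lp_cases = 3, paper_p_cases = 10,
                           syndrome_lp = 0.5, syndrome_p = 0.75,
                           gene_lp = 1, gene_p = 3,
                           benign_threshold = 0.01) {
  structure(list(paper_lp_cases = paper_lp_cases,
                 paper_p_cases = paper_p_cases,
                 syndrome_lp = syndrome_lp, syndrome_p = syndrome_p,
                 gene_lp = gene_lp, gene_p = gene_p,
                 benign_threshold = benign_threshold),
            class = "scoring_config")
}

mechanism_matches <- function(mechanism, variation_type) {
  del <- grepl("deletion", variation_type)
  mechanism == "both" | (del & mechanism == "deletion") |
    (!del & mechanism == "duplication")
}

sensitivity_matches <- function(sensitivity, variation_type) {
  del <- grepl("deletion", variation_type)
  sensitivity == "both" | (del & sensitivity == "haploinsufficient") |
    (!del & sensitivity == "triplosensitive")
}

#' Evidence scores for an annotated CNV
#'
#' Collapses the filtered annotation into per-store numeric evidence:
#' * `benign_score`: max over polymorphism hits of
#'   `frequency * overlap_query` — common, well-covered population CNVs
#'   push towards benign;
#' * `syndrome_score`: max `overlap_db` over syndrome hits whose dosage
#'   mechanism matches the variant type;
#' * `gene_score`: number of dosage-matched sensitive genes sufficiently
#'   covered (hemizygous male X deletions count as loss of the single
#'   copy, so haploinsufficiency still applies);
#' * `paper_score`: total P/LP case count over qualifying literature hits
#'   (trios already collapsed in the store);
#' * `aneuploid_flag`: whole-chromosome event;
#' * `patient_annotations`: display-only, carries no score by construction.
#'
#' Hits flagged `excluded` (incomplete penetrance) never contribute. Every
#' score is monotone in overlap, frequency, sample size and case count.
#'
#' @param annotation a `cnv_annotation`.
#' @param config a [scoring_config()].
#' @return an `evidence_scores` list.
#' @export
evidence_scores <- function(annotation, config = scoring_config()) {
  stopifnot(inherits(annotation, "cnv_annotation"))
  vt <- annotation$cnv$variation_type
  poly <- annotation$polymorphism
  poly <- poly[!poly$excluded, , drop = FALSE]
  benign <- if (nrow(poly)) max(poly$frequency * poly$overlap_query) else 0
  synd <- annotation$syndrome
  synd <- synd[!synd$excluded &
               mechanism_matches(synd$dosage_mechanism, vt), , drop = FALSE]
  syndrome <- if (nrow(synd)) max(synd$overlap_db) else 0
  gene <- annotation$gene
  gene <- gene[!gene$excluded &
               sensitivity_matches(gene$dosage_sensitivity, vt), ,
               drop = FALSE]
  pap <- annotation$paper
  pap <- pap[!pap$excluded, , drop = FALSE]
  structure(list(benign_score = benign,
                 syndrome_score = syndrome,
                 gene_score = nrow(gene),
                 paper_score = if (nrow(pap)) sum(pap$plp_case_count) else 0,
                 aneuploid_flag = annotation$whole_chromosome$is_event,
                 patient_annotations = annotation$patient),
            class = "evidence_scores")
}

#' @export
print.evidence_scores <- function(x, ...) {
  cat(sprintf(
    "evidence: benign %.4f | syndrome %.3f | gene %d | paper %g | aneuploid %s | %d patient annotation(s)\n",
    x$benign_score, x$syndrome_score, x$gene_score, x$paper_score,
    x$aneuploid_flag, nrow(x$patient_annotations)))
  invisible(x)
}

#' Five-tier classification from evidence scores
#'
#' Deterministic rule ladder mapping evidence scores to the ACMG five-tier
#' scale. In order: a whole-chromosome aneuploidy is always pathogenic;
#' strong pathogenic evidence (syndrome coverage >= `syndrome_p`, or at
#' least `gene_p` dosage-matched genes, or >= `paper_p_cases` literature
#' cases) gives pathogenic; moderate evidence (>= `syndrome_lp`, `gene_lp`,
#' `paper_lp_cases`) gives likely_pathogenic; otherwise a benign score of
#' at least `benign_threshold` gives benign; anything else is VOUS.
#' `likely_benign` is representable but the default ladder emits `benign`
#' for both, matching reporting practice. Identical scores always produce
#' identical calls.
#'
#' @param scores an `evidence_scores`.
#' @param config a [scoring_config()].
#' @return one of `r paste(FIVE_TIERS, collapse=", ")`.
#' @export
classify_variant <- function(scores, config = scoring_config()) {
  stopifnot(inherits(scores, "evidence_scores"))
  if (isTRUE(scores$aneuploid_flag)) return("pathogenic")
  if (scores$syndrome_score >= config$syndrome_p ||
      scores$gene_score >= config$gene_p ||
      scores$paper_score >= config$paper_p_cases) {
    return("pathogenic")
  }
  if (scores$syndrome_score >= config$syndrome_lp ||
      scores$gene_score >= config$gene_lp ||
      scores$paper_score >= config$paper_lp_cases) {
    return("likely_pathogenic")
  }
  if (scores$benign_score >= config$benign_threshold) return("benign")
  "VOUS"
}

#' Interpret a table of CNV calls end to end
#'
#' Convenience wrapper running annotation, evidence scoring and five-tier
#' classification for every CNV in a call table.
#'
#' @param cnvs a `cnv_calls` table.
#' @param kbs a `knowledge_base_set`.
#' @param cytobands a `cytoband_table`.
#' @param filters an [annotation_filters()].
#' @param config a [scoring_config()].
#' @return data.frame: the calls plus evidence scores, `aneuploid_flag` and
#'   `classification`; annotations are attached as the `"annotations"`
#'   attribute for review/reporting.
#' @export
interpret_cnvs <- function(cnvs, kbs, cytobands,
                           filters = annotation_filters(),
                           config = scoring_config()) {
  anns <- lapply(seq_len(nrow(cnvs)), function(i) {
    annotate_cnv(cnvs[i, ], kbs, filters, cytobands)
  })
  scs <- lapply(anns, evidence_scores, config = config)
  out <- cbind(as.data.frame(cnvs),
               data.frame(
                 benign_score = vapply(scs, `[[`, 0, "benign_score"),
                 syndrome_score = vapply(scs, `[[`, 0, "syndrome_score"),
                 gene_score = vapply(scs, function(s) as.numeric(s$gene_score), 0),
                 paper_score = vapply(scs, `[[`, 0, "paper_score"),
                 aneuploid_flag = vapply(scs, `[[`, TRUE, "aneuploid_flag"),
                 classification = vapply(scs, classify_variant, "",
                                         config = config)))
  attr(out, "annotations") <- anns
  attr(out, "scores") <- scs
  out
}
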