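KB_STORES <- c("polymorphism", "aneuploid", "syndrome", "gene", "paper",
               "patient")

# required columns per store; aneuploid is chromosome-level, not interval
kb_schemas <- list(
  polymorphism = c("chrom", "start", "end", "frequency", "sample_size",
                   "source"),
  aneuploid = c("chrom", "event", "description", "source"),
  syndrome = c("chrom", "start", "end", "syndrome_name", "dosage_mechanism",
               "corpus", "source"),
  gene = c("gene_symbol", "chrom", "start", "end", "dosage_sensitivity",
           "corpus", "source"),
  paper = c("chrom", "start", "end", "plp_case_count", "citation", "corpus"),
  patient = c("chrom", "start", "end", "phenotype",
              "reported_classification", "source")
)

# column names that would smuggle a variant classification into an evidence
# store; the patient store legitimately carries reported_classification for
# display, every other store must not
forbidden_evidence_cols <- c("classification", "reported_classification",
                             "five_tier", "tier", "pathogenicity")

empty_store <- function(store) {
  cols <- kb_schemas[[store]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  num <- intersect(cols, c("start", "end", "frequency", "sample_size",
                           "plp_case_count"))
  for (cc in num) df[[cc]] <- numeric(0)
  df
}

validate_store <- function(store, df) {
  cols <- kb_schemas[[store]]
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s store is missing column(s): %s", store,
                 paste(miss, collapse = ", ")))
  }
  if (store != "patient") {
    bad <- intersect(forbidden_evidence_cols, names(df))
    if (length(bad)) {
      stop(sprintf(
        "%s store may only contain evidence, not variant classifications (found column %s)",
        store, bad[1]))
    }
  }
  if (store == "polymorphism" && nrow(df)) {
    stopifnot(all(df$frequency >= 0 & df$frequency <= 1),
              all(df$sample_size >= 1))
  }
  if (store == "paper" && nrow(df)) stopifnot(all(df$plp_case_count >= 0))
  if (store == "syndrome" && nrow(df)) {
    stopifnot(all(df$dosage_mechanism %in% c("deletion", "duplication",
                                             "both")))
  }
  if (store == "gene" && nrow(df)) {
    stopifnot(all(nzchar(df$gene_symbol)),
              all(df$dosage_sensitivity %in%
                    c("haploinsufficient", "triplosensitive", "both", "none")))
  }
  df[cols]
}

#' Assemble the six clinical knowledge bases
#'
#' Bundles the six evidence stores — Polymorphism (DGV-shaped population
#' CNVs), Aneuploid (whole-chromosome event descriptions), Syndrome
#' (dosage-sensitive regions), Gene (dosage-sensitive genes), Paper
#' (literature case counts) and Patient (previously reported carriers,
#' annotation display only) — into one versioned set. Stores hold evidence
#' only: any five-tier classification column outside the patient store is
#' rejected, so historical calls can never leak into current classification.
#'
#' @param polymorphism,aneuploid,syndrome,gene,paper,patient data.frames in
#'   the store schemas (see the package vignette); missing stores default to
#'   empty.
#' @param version version/date stamp string.
#' @return a `knowledge_base_set`.
#' @export
knowledge_base_set <- function(polymorphism = NULL, aneuploid = NULL,
                               syndrome = NULL, gene = NULL, paper = NULL,
                               patient = NULL, version = "0") {
  stores <- list(polymorphism = polymorphism, aneuploid = aneuploid,
                 syndrome = syndrome, gene = gene, paper = paper,
                 patient = patient)
  for (s in KB_STORES) {
    if (is.null(stores[[s]])) stores[[s]] <- empty_store(s)
    stores[[s]] <- validate_store(s, as.data.frame(stores[[s]]))
    if (!is.null(stores[[s]]$chrom)) {
      stores[[s]]$chrom <- sub("^chr", "", as.character(stores[[s]]$chrom))
    }
    rownames(stores[[s]]) <- NULL
  }
  structure(c(stores, list(version = version)), class = "knowledge_base_set")
}

#' @export
print.knowledge_base_set <- function(x, ...) {
  cat(sprintf("knowledge base set (version %s)\n", x$version))
  for (s in KB_STORES) cat(sprintf("  %-12s %5d records\n", s, nrow(x[[s]])))
  invisible(x)
}

#' Build knowledge bases from a labeled corpus and public tables
#'
#' Routes categorised corpus sentences into the six stores: Syndrome
#' sentences become syndrome records, Gene sentences gene records, Paper
#' sentences paper records, Aneuploid sentences whole-chromosome
#' descriptions, Patient sentences patient records; Basic sentences describe
#' key indices only and are not stored as evidence. Each sub-paragraph's
#' record takes its region from the CNV matched to that sub-paragraph;
#' sub-paragraphs with no matched CNV are skipped with a warning. Records on
#' identical regions are merged by corpus concatenation (paper records
#' additionally sum `plp_case_count` over distinct citations). Public
#' database extracts in the same schemas are then appended.
#'
#' @param labeled data.frame with columns `report_id`, `sub_index`,
#'   `sent_index`, `text`, `category`.
#' @param matched data.frame with columns `report_id`, `sub_index`, `chrom`,
#'   `start`, `end`, `variation_type`: the CNV matched to each
#'   sub-paragraph (unmatched sub-paragraphs absent or with NA chrom).
#' @param public optional named list of public-table data.frames, in store
#'   schemas, appended to the corpus-derived records.
#' @param version version stamp for the resulting set.
#' @return a `knowledge_base_set`.
#' @export
build_knowledge_bases <- function(labeled, matched, public = NULL,
                                  version = format(Sys.Date())) {
  stopifnot(all(c("report_id", "sub_index", "text", "category")
                %in% names(labeled)),
            all(c("report_id", "sub_index", "chrom", "start", "end",
                  "variation_type") %in% names(matched)))
  key <- function(d) paste(d$report_id, d$sub_index, sep = "\r")
  mkey <- key(matched)
  rows <- list(syndrome = list(), gene = list(), paper = list(),
               aneuploid = list(), patient = list())
  for (k in unique(key(labeled))) {
    sub <- labeled[key(labeled) == k, ]
    sub <- sub[order(sub$sent_index), ]
    mi <- match(k, mkey)
    if (is.na(mi) || is.na(matched$chrom[mi])) {
      warning(sprintf("sub-paragraph %s has no matched CNV; skipped",
                      gsub("\r", "/", k)))
      next
    }
    cnv <- matched[mi, ]
    mech <- if (grepl("deletion", cnv$variation_type)) "deletion"
            else "duplication"
    for (cat in setdiff(unique(sub$category), "Basic")) {
      corpus <- paste(sub$text[sub$category == cat], collapse = " ")
      rec <- switch(cat,
        Syndrome = data.frame(chrom = cnv$chrom, start = cnv$start,
                              end = cnv$end, syndrome_name = "corpus-derived",
                              dosage_mechanism = mech, corpus = corpus,
                              source = "labeled_corpus",
                              stringsAsFactors = FALSE),
        Gene = data.frame(gene_symbol = "corpus-derived", chrom = cnv$chrom,
                          start = cnv$start, end = cnv$end,
                          dosage_sensitivity = if (mech == "deletion")
                            "haploinsufficient" else "triplosensitive",
                          corpus = corpus, source = "labeled_corpus",
                          stringsAsFactors = FALSE),
        Paper = data.frame(chrom = cnv$chrom, start = cnv$start,
                           end = cnv$end, plp_case_count = 1,
                           citation = paste0("corpus:", gsub("\r", "/", k)),
                           corpus = corpus, stringsAsFactors = FALSE),
        Aneuploid = data.frame(chrom = cnv$chrom,
                               event = if (mech == "deletion") "loss"
                                       else "gain",
                               description = corpus,
                               source = "labeled_corpus",
                               stringsAsFactors = FALSE),
        Patient = data.frame(chrom = cnv$chrom, start = cnv$start,
                             end = cnv$end, phenotype = corpus,
                             reported_classification = NA_character_,
                             source = "in_house", stringsAsFactors = FALSE),
        NULL)
      if (!is.null(rec)) {
        nm <- tolower(cat)
        rows[[nm]] <- c(rows[[nm]], list(rec))
      }
    }
  }
  stores <- lapply(rows, function(r) if (length(r)) do.call(rbind, r)
                                     else NULL)
  stores$syndrome <- merge_region_store(stores$syndrome, "corpus")
  stores$gene <- merge_region_store(stores$gene, "corpus")
  stores$paper <- merge_paper_store(stores$paper)
  stores$aneuploid <- merge_aneuploid_store(stores$aneuploid)
  if (!is.null(public)) {
    for (s in intersect(names(public), KB_STORES)) {
      stores[[s]] <- rbind(
        if (is.null(stores[[s]])) empty_store(s)[names(public[[s]])]
        else stores[[s]][names(public[[s]])],
        public[[s]])
    }
  }
  knowledge_base_set(polymorphism = stores$polymorphism,
                     aneuploid = stores$aneuploid,
                     syndrome = stores$syndrome, gene = stores$gene,
                     paper = stores$paper, patient = stores$patient,
                     version = version)
}

merge_region_store <- function(df, corpus_col) {
  if (is.null(df) || !nrow(df)) return(df)
  k <- paste(df$chrom, df$start, df$end, sep = ":")
  out <- df[!duplicated(k), , drop = FALSE]
  out[[corpus_col]] <- vapply(unique(k), function(kk) {
    paste(df[[corpus_col]][k == kk], collapse = " ")
  }, character(1))
  out
}

merge_paper_store <- function(df) {
  if (is.null(df) || !nrow(df)) return(df)
  k <- paste(df$chrom, df$start, df$end, sep = ":")
  out <- df[!duplicated(k), , drop = FALSE]
  out$corpus <- vapply(unique(k), function(kk) {
    paste(df$corpus[k == kk], collapse = " ")
  }, character(1))
  out$plp_case_count <- vapply(unique(k), function(kk) {
    d <- df[k == kk, ]
    sum(d$plp_case_count[!duplicated(d$citation)])
  }, numeric(1))
  out$citation <- vapply(unique(k), function(kk) {
    paste(unique(df$citation[k == kk]), collapse = ";")
  }, character(1))
  out
}

merge_aneuploid_store <- function(df) {
  if (is.null(df) || !nrow(df)) return(df)
  k <- paste(df$chrom, df$event, sep = ":")
  out <- df[!duplicated(k), , drop = FALSE]
  out$description <- vapply(unique(k), function(kk) {
    paste(df$description[k == kk], collapse = " ")
  }, character(1))
  out
}

#' Query a knowledge-base store by genomic region
#'
#' Returns every record of an interval store intersecting the query region
#' (1-based inclusive coordinates), with the exact overlap length in bp,
#' sorted by decreasing overlap. The aneuploid store is chromosome-level and
#' is queried by chromosome name alone (overlap reported as the query
#' length). Interval lookup uses IRanges.
#'
#' @param store a store data.frame from a `knowledge_base_set` (or the set
#'   itself plus `store_name`).
#' @param chrom,start,end query region.
#' @param store_name when `store` is a `knowledge_base_set`, which store to
#'   query.
#' @return the matching records with an `overlap_bp` column (empty
#'   data.frame when nothing intersects).
#' @export
query_region <- function(store, chrom, start, end, store_name = NULL) {
  if (inherits(store, "knowledge_base_set")) {
    stopifnot(!is.null(store_name), store_name %in% KB_STORES)
    store <- store[[store_name]]
  }
  chrom <- sub("^chr", "", as.character(chrom))
  if (!"start" %in% names(store)) {  # aneuploid: chromosome-level
    hit <- store[store$chrom == chrom, , drop = FALSE]
    if (nrow(hit)) hit$overlap_bp <- end - start + 1
    else hit$overlap_bp <- numeric(0)
    return(hit)
  }
  cand <- store[store$chrom == chrom, , drop = FALSE]
  if (!nrow(cand)) {
    out <- store[0, , drop = FALSE]
    out$overlap_bp <- numeric(0)
    return(out)
  }
  q <- IRanges::IRanges(start = start, end = end)
  s <- IRanges::IRanges(start = cand$start, end = cand$end)
  ov <- IRanges::findOverlaps(q, s)
  idx <- S4Vectors::subjectHits(ov)
  out <- cand[idx, , drop = FALSE]
  out$overlap_bp <- pmin(end, out$end) - pmax(start, out$start) + 1
  out <- out[order(-out$overlap_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize / load a knowledge-base set
#'
#' One TSV per store plus a JSON manifest carrying the version stamp and
#' record counts. Stores are re-validated on read, so a hand-edited file
#' that sneaks a classification column into an evidence store is rejected.
#'
#' @param kbs a `knowledge_base_set`.
#' @param dir directory to write into (created if needed).
#' @return `write_kb` returns `dir` invisibly; `read_kb` returns the
#'   reconstructed `knowledge_base_set`.
#' @export
write_kb <- function(kbs, dir) {
  stopifnot(inherits(kbs, "knowledge_base_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in KB_STORES) {
    utils::write.table(kbs[[s]], file.path(dir, paste0(s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  manifest <- list(version = kbs$version,
                   stores = lapply(kbs[KB_STORES], nrow))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_kb
#' @export
read_kb <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  stores <- lapply(KB_STORES, function(s) {
    f <- file.path(dir, paste0(s, ".tsv"))
    df <- utils::read.table(f, sep = "\t", header = TRUE,
                            colClasses = "character", quote = "",
                            comment.char = "", na.strings = "NA")
    for (cc in intersect(names(df), c("start", "end", "frequency",
                                      "sample_size", "plp_case_count"))) {
      df[[cc]] <- as.numeric(df[[cc]])
    }
    df
  })
  names(stores) <- KB_STORES
  do.call(knowledge_base_set, c(stores, list(version = manifest$version)))
}
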