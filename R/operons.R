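# Putative operon calling: maximal same-strand gene runs with intergenic
# gaps strictly below a threshold (default 20 bp), plus keyword-based
# functional labelling.

#' Call putative operons on a plasmid record
#'
#' Partitions all CDS (pseudo included) into maximal runs of same-strand
#' genes where every adjacent intergenic gap — `start(next) - end(prev)` in
#' half-open coordinates — is strictly less than `max_gap`. Overlapping or
#' abutting same-strand genes (gap <= 0) always join; any opposite-strand
#' gene breaks a run. On circular records the first and last CDS join when
#' they satisfy the rule across the origin, so the clustering is invariant
#' under rotation of the origin.
#'
#' @param record a [plasmid_record()].
#' @param max_gap join threshold in bp; gap < `max_gap` joins (default 20,
#'   i.e. "less than 20 bp" is strict).
#' @return data frame with one row per cluster: `cluster_id`, `strand`,
#'   `start`, `end` (span of the run; `end` may exceed the record length for
#'   origin-wrapping clusters), `n_genes`, `members` (semicolon-joined locus
#'   tags in coordinate order), `label` (NA until [label_clusters()]).
#' @export
call_operons <- function(record, max_gap = 20) {
  cds <- record$cds
  n <- nrow(cds)
  if (!n) {
    return(data.frame(cluster_id = integer(), strand = character(),
                      start = integer(), end = integer(), n_genes = integer(),
                      members = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  # 'end' for gap purposes: wrapping features extend past length_bp already.
  joins <- if (n > 1) {
    vapply(seq_len(n - 1), function(i) {
      cds$strand[i + 1] == cds$strand[i] &&
        (cds$start[i + 1] - cds$end[i]) < max_gap
    }, logical(1))
  } else logical(0)
  grp <- cumsum(c(1L, !joins))
  # circular wrap-around join between last and first CDS
  wrapped <- FALSE
  if (record$topology == "circular" && n > 1 && max(grp) > 1) {
    gap <- (record$length_bp - cds$end[n]) + cds$start[1]
    if (cds$strand[1] == cds$strand[n] && gap < max_gap) {
      grp[grp == max(grp)] <- 1L
      wrapped <- TRUE
    }
  }
  ids <- unique(grp)
  rows <- lapply(seq_along(ids), function(k) {
    idx <- which(grp == ids[k])
    # keep members in run order: for the wrapped cluster the tail genes
    # precede the head genes along the run
    if (wrapped && ids[k] == 1L && any(diff(idx) > 1)) {
      brk <- which(diff(idx) > 1)
      idx <- c(idx[(brk + 1):length(idx)], idx[1:brk])
    }
    span_start <- cds$start[idx[1]]
    span_end <- if (wrapped && ids[k] == 1L && length(idx) > 1 &&
                    idx[1] > idx[length(idx)]) {
      record$length_bp + cds$end[idx[length(idx)]]
    } else max(cds$end[idx])
    data.frame(cluster_id = k, strand = cds$strand[idx[1]],
               start = span_start, end = span_end, n_genes = length(idx),
               members = paste(cds$locus_tag[idx], collapse = ";"),
               label = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default keyword table for functional labelling of operon clusters
#'
#' Maps product-description keywords to ~10 broad functional categories
#' (heavy-metal resistance, conjugation/T4SS, replication/partitioning,
#' mobile element, aromatic degradation, efflux, stress, regulation, ...).
#' A convenience starting point, not a curated functional annotation.
#'
#' @return data frame with columns `keyword`, `category`, in match priority
#'   order.
#' @export
default_keyword_table <- function() {
  path <- system.file("extdata", "keyword_table.tsv", package = "plasmidcomp")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Label operon clusters by product keywords
#'
#' A cluster's label is the category of the first keyword (in table order)
#' found in any member's product string; clusters with no match are labelled
#' `"hypothetical/unknown"`.
#'
#' @param clusters output of [call_operons()].
#' @param record the [plasmid_record()] the clusters came from.
#' @param keyword_table data frame with columns `keyword`, `category`
#'   (default [default_keyword_table()]).
#' @return `clusters` with the `label` column filled.
#' @export
label_clusters <- function(clusters, record,
                           keyword_table = default_keyword_table()) {
  stopifnot(nrow(keyword_table) > 0)
  products <- stats::setNames(record$cds$product, record$cds$locus_tag)
  clusters$label <- vapply(clusters$members, function(mem) {
    prods <- tolower(paste(products[strsplit(mem, ";", fixed = TRUE)[[1]]],
                           collapse = " | "))
    for (i in seq_len(nrow(keyword_table))) {
      if (grepl(tolower(keyword_table$keyword[i]), prods, fixed = TRUE))
        return(keyword_table$category[i])
    }
    "hypothetical/unknown"
  }, character(1), USE.NAMES = FALSE)
  clusters
}

#' Write operon clusters as TSV
#' @param clusters output of [call_operons()] / [label_clusters()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_operons <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write operon clusters as GFF3 operon features
#' @param clusters output of [call_operons()].
#' @param record the source [plasmid_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_operons_gff3 <- function(clusters, record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(clusters))) {
    cl <- clusters[i, ]
    writeLines(sprintf(
      "%s\tplasmidcomp\toperon\t%d\t%d\t.\t%s\t.\tID=operon%d;members=%s%s",
      record$id, cl$start + 1, min(cl$end, record$length_bp), cl$strand,
      cl$cluster_id, gsub(";", ",", cl$members),
      if (is.na(cl$label)) "" else paste0(";label=", cl$label)), con)
  }
  invisible(path)
}
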