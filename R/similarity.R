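# Relative-similarity scoring and ranking of a plasmid panel, the ring
# matrix behind circular comparison plots, and the within-plasmid gene
# duplication census.

self_score_cache <- new.env(parent = emptyenv())

# Self total: sum of self-alignment scores of all usable query proteins.
# Cached per (record id, matrix) because every panel comparison reuses it.
query_self_total <- function(query, params) {
  key <- paste(query$id, params$matrix_name, nrow(query$cds), query$length_bp,
               sep = "\r")
  hit <- self_score_cache[[key]]
  if (!is.null(hit)) return(hit)
  mat <- get_scoring_matrix(params$matrix_name)
  cds <- usable_cds(query)
  total <- sum(vapply(cds$protein, function(p) {
    v <- strsplit(p, "")[[1]]
    sum(mat[cbind(v, v)])
  }, numeric(1)))
  self_score_cache[[key]] <- total
  total
}

#' Relative similarity of a target plasmid to a query plasmid
#'
#' The headline comparison statistic: the summed best-hit alignment score of
#' all query CDS against the target, divided by the query's self-score,
#' expressed as a percentage and reported to 2 decimals. A plasmid scored
#' against itself gives exactly 100.00.
#'
#' @param query,target [plasmid_record()] objects; `query` needs at least one
#'   non-pseudo CDS.
#' @param params an [alignment_params()].
#' @return one-row data frame (class keeps columns `target_id`, `raw_total`,
#'   `self_total`, `relative_similarity_pct`, `n_hits`).
#' @export
relative_similarity <- function(query, target, params = alignment_params()) {
  if (!nrow(usable_cds(query))) stop("query has no usable (non-pseudo) CDS")
  hits <- best_hits(query, target, params)
  raw_total <- sum(hits$raw_score)
  self_total <- query_self_total(query, params)
  data.frame(target_id = target$id, raw_total = raw_total,
             self_total = self_total,
             relative_similarity_pct = round(100 * raw_total / self_total, 2),
             n_hits = nrow(hits), stringsAsFactors = FALSE)
}

#' Rank a panel of plasmids by relative similarity to a query
#'
#' @param query a [plasmid_record()].
#' @param panel list of [plasmid_record()] targets.
#' @param params an [alignment_params()].
#' @param top_n keep the best `top_n` rows (default all).
#' @return data frame sorted by descending `relative_similarity_pct` (ties:
#'   higher `raw_total`, then `target_id`), with a `rank` column.
#' @export
rank_panel <- function(query, panel, params = alignment_params(), top_n = Inf) {
  stopifnot(length(panel) >= 1)
  scores <- do.call(rbind, lapply(panel, function(t)
    relative_similarity(query, t, params)))
  ord <- order(-scores$relative_similarity_pct, -scores$raw_total,
               scores$target_id)
  scores <- scores[ord, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  if (is.finite(top_n)) scores <- scores[seq_len(min(top_n, nrow(scores))), ]
  rownames(scores) <- NULL
  scores[c("rank", "target_id", "raw_total", "self_total",
           "relative_similarity_pct", "n_hits")]
}

#' Ring matrix of per-CDS best-hit scores across a ranked panel
#'
#' One row per target (in rank order), one column per query CDS (in plasmid
#' coordinate order). A cell holds the raw score of the target's best hit for
#' that query CDS, or `NA` when no homologue was identified — the blank
#' wedge of a circular comparison plot.
#'
#' @param query a [plasmid_record()].
#' @param ranked output of [rank_panel()].
#' @param panel the same list of records that was ranked.
#' @param params an [alignment_params()].
#' @return list with `query_cds_order` (locus tags) and `matrix` (numeric
#'   matrix, rows named by target id in rank order, `NA` = blank).
#' @export
build_ring_matrix <- function(query, ranked, panel, params = alignment_params()) {
  qcds <- usable_cds(query)
  ids <- vapply(panel, function(p) p$id, character(1))
  m <- matrix(NA_real_, nrow = nrow(ranked), ncol = nrow(qcds),
              dimnames = list(ranked$target_id, qcds$locus_tag))
  for (r in seq_len(nrow(ranked))) {
    target <- panel[[match(ranked$target_id[r], ids)]]
    hits <- best_hits(query, target, params)
    m[r, hits$query_locus] <- hits$raw_score
  }
  list(query_cds_order = qcds$locus_tag, matrix = m)
}

#' Write a ring matrix as TSV (empty cell = no homologue)
#' @param ring output of [build_ring_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ring_matrix <- function(ring, path) {
  df <- as.data.frame(ring$matrix)
  df <- cbind(target_id = rownames(ring$matrix), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Census of duplicated genes within a plasmid
#'
#' Links every pair of non-pseudo CDS whose local alignment reaches
#' `dup_identity_pct` identity and `dup_coverage_pct` coverage of both
#' proteins; families are the connected components of that graph. Genes in a
#' family count as duplicated, the rest as single copy.
#'
#' @param record a [plasmid_record()].
#' @param dup_identity_pct,dup_coverage_pct thresholds (default 90/90,
#'   tuned to catch near-identical paralogs such as repeated transposases).
#' @param params an [alignment_params()].
#' @return list with `n_genes`, `n_single_copy`, `n_duplicated`, `families`
#'   (list of locus-tag character vectors, each of size >= 2).
#' @export
duplication_census <- function(record, dup_identity_pct = 90,
                               dup_coverage_pct = 90,
                               params = alignment_params()) {
  cds <- usable_cds(record)
  n_genes <- nrow(record$cds[!record$cds$pseudo, , drop = FALSE])
  if (!nrow(cds)) stop("record has no usable CDS")
  n <- nrow(cds)
  edges <- matrix(integer(0), ncol = 2)
  ksets <- lapply(cds$protein, kmer_set)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (params$use_prefilter && !prefilter_pass(ksets[[i]], ksets[[j]])) next
    al <- align_local(cds$protein[i], cds$protein[j], params)
    if (al$raw_score <= 0 || al$identity_pct < dup_identity_pct) next
    span_i <- al$intervals$a[2] - al$intervals$a[1] + 1
    span_j <- al$intervals$b[2] - al$intervals$b[1] + 1
    cov_i <- 100 * span_i / nchar(cds$protein[i])
    cov_j <- 100 * span_j / nchar(cds$protein[j])
    if (cov_i >= dup_coverage_pct && cov_j >= dup_coverage_pct)
      edges <- rbind(edges, c(i, j))
  }
  if (nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)
    fam_ids <- which(comp$csize >= 2)
    families <- lapply(fam_ids, function(f) cds$locus_tag[comp$membership == f])
  } else {
    families <- list()
  }
  n_dup <- sum(lengths(families))
  list(n_genes = n_genes, n_single_copy = n_genes - n_dup,
       n_duplicated = n_dup, families = families)
}
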