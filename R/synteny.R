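# Order-consistent homologue chaining between a query gene cluster and a
# target replicon: collinear synteny as a longest monotone subsequence of
# best-hit pairs.

# Longest strictly increasing subsequence; returns indices. O(n^2), fine at
# gene-cluster scale.
lis_indices <- function(x) {
  n <- length(x)
  if (!n) return(integer(0))
  best <- rep(1L, n)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      if (x[j] < x[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  out <- integer(best[i])
  k <- best[i]
  while (i > 0) { out[k] <- i; k <- k - 1L; i <- prev[i] }
  out
}

#' Chain collinear homologues of a gene cluster on a target replicon
#'
#' Each query gene gets its best target hit; the synteny chain is the
#' longest strictly monotone subsequence of those pairs in target coordinate
#' order, computed for both orientations (increasing = same, decreasing =
#' inverted) with ties resolved to `same`.
#'
#' @param query_cluster data frame of >= 2 CDS features (rows of a record's
#'   `$cds`, in cluster order).
#' @param target a [plasmid_record()].
#' @param params an [alignment_params()].
#' @return list of class `SyntenyChain`: `pairs` (data frame `query_locus`,
#'   `target_locus`), `orientation` (`same`/`inverted`), `chain_len`,
#'   `mean_identity_pct` (NA for an empty chain).
#' @export
match_cluster <- function(query_cluster, target, params = alignment_params()) {
  if (nrow(query_cluster) < 2) stop("query cluster must have >= 2 genes")
  hits <- best_hits(query_cluster, target, params)
  if (!nrow(hits)) {
    return(structure(list(pairs = data.frame(query_locus = character(),
                                             target_locus = character()),
                          orientation = "same", chain_len = 0L,
                          mean_identity_pct = NA_real_),
                     class = "SyntenyChain"))
  }
  # hits are in query-cluster order already (best_hits preserves query order)
  t_index <- match(hits$target_locus, target$cds$locus_tag)
  fwd <- lis_indices(t_index)
  rev_ <- lis_indices(-t_index)
  use_fwd <- length(fwd) >= length(rev_)
  sel <- if (use_fwd) fwd else rev_
  chain <- hits[sel, , drop = FALSE]
  structure(list(
    pairs = chain[c("query_locus", "target_locus")],
    orientation = if (use_fwd) "same" else "inverted",
    chain_len = nrow(chain),
    mean_identity_pct = mean(chain$identity_pct)),
    class = "SyntenyChain")
}

#' @export
print.SyntenyChain <- function(x, ...) {
  cat(sprintf("SyntenyChain: %d genes, orientation %s, mean identity %.1f%%\n",
              x$chain_len, x$orientation,
              if (is.na(x$mean_identity_pct)) 0 else x$mean_identity_pct))
  invisible(x)
}

#' Synteny report of gene clusters against target replicons
#'
#' One row per (cluster, target) combination, sorted by decreasing chain
#' length; combinations with no homologues are retained with `chain_len` 0.
#'
#' @param query_clusters named list of CDS data frames (>= 2 genes each).
#' @param targets list of [plasmid_record()] objects.
#' @param params an [alignment_params()].
#' @return data frame with `cluster_id`, `target_id`, `chain_len`,
#'   `orientation`, `mean_identity_pct`, `pairs` (semicolon-joined
#'   `query:target` locus pairs).
#' @export
synteny_report <- function(query_clusters, targets, params = alignment_params()) {
  stopifnot(length(query_clusters) >= 1, length(targets) >= 1)
  if (is.null(names(query_clusters)))
    names(query_clusters) <- sprintf("cluster%d", seq_along(query_clusters))
  rows <- list()
  for (ci in seq_along(query_clusters)) {
    for (t in targets) {
      ch <- match_cluster(query_clusters[[ci]], t, params)
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = names(query_clusters)[ci], target_id = t$id,
        chain_len = ch$chain_len, orientation = ch$orientation,
        mean_identity_pct = ch$mean_identity_pct,
        pairs = paste(paste0(ch$pairs$query_locus, ":", ch$pairs$target_locus),
                      collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$chain_len, out$cluster_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
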