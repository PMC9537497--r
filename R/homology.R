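# Pairwise local protein alignment and per-CDS best-hit scoring: the engine
# beneath the plasmid-vs-plasmid relative-similarity statistic.

#' Alignment and hit-acceptance parameters
#'
#' Defaults mirror the de-facto standard protein-search parameterization:
#' BLOSUM62 with affine gap penalties 11 (open) / 1 (extend). A best hit is
#' accepted when it reaches `min_identity_pct` percent identity over aligned
#' columns and `min_coverage_pct` percent of the query residues aligned.
#'
#' @param matrix_name substitution matrix name (shipped with Biostrings).
#' @param gap_open,gap_extend positive gap penalties.
#' @param min_identity_pct,min_coverage_pct hit-acceptance thresholds in
#'   `[0, 100]`.
#' @param use_prefilter logical; require candidate pairs to share at least 2
#'   exact 4-mers before running the alignment. The prefilter may skip pairs
#'   but never changes which accepted hit is maximal.
#' @return list of class `AlignmentParams`.
#' @export
alignment_params <- function(matrix_name = "BLOSUM62", gap_open = 11, gap_extend = 1,
                             min_identity_pct = 30, min_coverage_pct = 50,
                             use_prefilter = TRUE) {
  stopifnot(gap_open > 0, gap_extend > 0,
            min_identity_pct >= 0, min_identity_pct <= 100,
            min_coverage_pct >= 0, min_coverage_pct <= 100)
  structure(list(matrix_name = matrix_name, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct,
                 use_prefilter = isTRUE(use_prefilter)),
            class = "AlignmentParams")
}

# Substitution matrix with X neutralised: X scores 0 against everything.
scoring_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  mat <- get(name, envir = env)
  if ("X" %in% rownames(mat)) {
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
  }
  mat
}

the_matrix_cache <- new.env(parent = emptyenv())
get_scoring_matrix <- function(name) {
  if (is.null(the_matrix_cache[[name]]))
    the_matrix_cache[[name]] <- scoring_matrix(name)
  the_matrix_cache[[name]]
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps. Returns score 0 when no positive-scoring
#' alignment exists. `X` scores 0 against every residue.
#'
#' @param a,b non-empty amino-acid strings (20 amino acids plus X).
#' @param params an [alignment_params()].
#' @return list with `raw_score`, `identity_pct` (percent identical over
#'   aligned columns), `coverage_pct` (percent of `a`'s residues inside the
#'   aligned interval), and `intervals` (1-based aligned ranges in `a` and
#'   `b`).
#' @examples
#' align_local("MKT", "MKT")$raw_score  # 15 under BLOSUM62
#' @export
align_local <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in align_local")
  mat <- get_scoring_matrix(params$matrix_name)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(raw_score = 0, identity_pct = 0, coverage_pct = 0,
                intervals = list(a = c(0L, 0L), b = c(0L, 0L))))
  }
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  ident <- 100 * Biostrings::nmatch(aln) / width
  pa <- Biostrings::pattern(aln)
  cov <- 100 * (BiocGenerics::end(pa) - BiocGenerics::start(pa) + 1) / nchar(a)
  sb <- Biostrings::subject(aln)
  list(raw_score = sc, identity_pct = ident, coverage_pct = cov,
       intervals = list(a = c(BiocGenerics::start(pa), BiocGenerics::end(pa)),
                        b = c(BiocGenerics::start(sb), BiocGenerics::end(sb))))
}

# Distinct 4-mers of a protein string.
kmer_set <- function(s, k = 4) {
  if (nchar(s) < k) return(character(0))
  unique(substring(s, seq_len(nchar(s) - k + 1), seq(k, nchar(s))))
}

# TRUE for pairs sharing >= 2 distinct exact 4-mers.
prefilter_pass <- function(qset, tset) {
  length(intersect(qset, tset)) >= 2
}

#' Best target hit for each query CDS
#'
#' Aligns every non-pseudo query CDS against every non-pseudo target CDS and
#' keeps, per query locus, the single highest-raw-score target passing the
#' identity and coverage thresholds. Ties are broken by higher identity, then
#' lower target start coordinate. A 4-mer prefilter (candidate pairs must
#' share at least 2 exact 4-mers) skips hopeless pairs without changing which
#' hit is maximal.
#'
#' @param query data frame of CDS features (as in a record's `$cds`) or a
#'   [plasmid_record()].
#' @param target a [plasmid_record()].
#' @param params an [alignment_params()].
#' @return data frame with columns `query_locus`, `target_plasmid`,
#'   `target_locus`, `raw_score`, `identity_pct`, `coverage_pct`; zero rows
#'   when nothing passes.
#' @export
best_hits <- function(query, target, params = alignment_params()) {
  qcds <- if (inherits(query, "PlasmidRecord")) usable_cds(query) else
    query[!query$pseudo, , drop = FALSE]
  tcds <- usable_cds(target)
  empty <- data.frame(query_locus = character(), target_plasmid = character(),
                      target_locus = character(), raw_score = numeric(),
                      identity_pct = numeric(), coverage_pct = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(qcds) || !nrow(tcds)) return(empty)
  tk <- if (params$use_prefilter) lapply(tcds$protein, kmer_set) else NULL
  rows <- vector("list", nrow(qcds))
  for (qi in seq_len(nrow(qcds))) {
    qprot <- qcds$protein[qi]
    qset <- if (params$use_prefilter) kmer_set(qprot) else NULL
    best <- NULL
    for (ti in seq_len(nrow(tcds))) {
      if (params$use_prefilter && !prefilter_pass(qset, tk[[ti]])) next
      al <- align_local(qprot, tcds$protein[ti], params)
      if (al$raw_score <= 0) next
      if (al$identity_pct < params$min_identity_pct) next
      if (al$coverage_pct < params$min_coverage_pct) next
      cand <- list(ti = ti, score = al$raw_score, identity = al$identity_pct,
                   coverage = al$coverage_pct)
      if (is.null(best) ||
          cand$score > best$score ||
          (cand$score == best$score && cand$identity > best$identity) ||
          (cand$score == best$score && cand$identity == best$identity &&
           tcds$start[cand$ti] < tcds$start[best$ti])) {
        best <- cand
      }
    }
    if (!is.null(best)) {
      rows[[qi]] <- data.frame(
        query_locus = qcds$locus_tag[qi], target_plasmid = target$id,
        target_locus = tcds$locus_tag[best$ti], raw_score = best$score,
        identity_pct = best$identity, coverage_pct = best$coverage,
        stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summed best-hit score of a query plasmid against a target
#'
#' The numerator of the relative-similarity statistic: the sum of raw local
#' alignment scores over the best accepted hit of each query CDS.
#'
#' @inheritParams best_hits
#' @return numeric scalar, 0 when there are no hits.
#' @export
plasmid_raw_score <- function(query, target, params = alignment_params()) {
  sum(best_hits(query, target, params)$raw_score)
}

#' Write homology hits as TSV
#' @param hits output of [best_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
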