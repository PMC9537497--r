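#' Construct an annotated plasmid record
#'
#' The central container of the package: one (typically circular) plasmid
#' sequence together with its ordered CDS features. All coordinates are
#' 0-based, half-open, on the plus strand; GenBank's 1-based inclusive
#' positions are converted at the I/O boundary only.
#'
#' @param id character scalar, accession or synthetic name.
#' @param sequence DNA string over A,C,G,T,N.
#' @param cds data frame with columns `locus_tag`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `product`, `protein`, `pseudo`, `wraps_origin`. Features
#'   are sorted by `start`. A feature flagged `wraps_origin` on a circular
#'   record has a virtual `end > length_bp`; it is normalised modulo the
#'   length on output.
#' @param topology `"circular"` or `"linear"`.
#' @param metadata named list of free-text annotations (organism, taxid,
#'   inc_group, ...).
#' @return an object of class `PlasmidRecord`.
#' @export
plasmid_record <- function(id, sequence, cds = empty_cds(), topology = c("circular", "linear"),
                           metadata = list()) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  need <- c("locus_tag", "start", "end", "strand", "product", "protein", "pseudo", "wraps_origin")
  missing_cols <- setdiff(need, names(cds))
  for (m in missing_cols) {
    cds[[m]] <- switch(m,
      product = rep("", nrow(cds)), protein = rep("", nrow(cds)),
      pseudo = rep(FALSE, nrow(cds)), wraps_origin = rep(FALSE, nrow(cds)),
      stop("cds table lacks required column: ", m))
  }
  cds <- cds[need]
  cds <- cds[order(cds$start), , drop = FALSE]
  rownames(cds) <- NULL
  rec <- structure(list(
    id = id, length_bp = nchar(sequence), topology = topology,
    sequence = sequence, cds = cds, metadata = metadata
  ), class = "PlasmidRecord")
  validate_plasmid_record(rec)
  rec
}

empty_cds <- function() {
  data.frame(locus_tag = character(), start = integer(), end = integer(),
             strand = character(), product = character(), protein = character(),
             pseudo = logical(), wraps_origin = logical(), stringsAsFactors = FALSE)
}

validate_plasmid_record <- function(rec) {
  stopifnot(inherits(rec, "PlasmidRecord"))
  if (nchar(rec$sequence) != rec$length_bp)
    stop("sequence length does not match length_bp")
  if (grepl("[^ACGTN]", rec$sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  cds <- rec$cds
  if (nrow(cds)) {
    if (is.unsorted(cds$start)) stop("cds not sorted by start")
    bad <- !cds$wraps_origin & (cds$start >= cds$end | cds$start < 0 | cds$end > rec$length_bp)
    if (any(bad)) stop("CDS interval out of bounds: ", paste(cds$locus_tag[bad], collapse = ", "))
    if (any(cds$wraps_origin & rec$topology != "circular"))
      stop("wraps_origin feature on a linear record")
    if (any(!cds$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    no_prot <- !cds$pseudo & !nzchar(cds$protein)
    if (any(no_prot)) stop("non-pseudo CDS without protein: ",
                           paste(cds$locus_tag[no_prot], collapse = ", "))
  }
  invisible(rec)
}

#' @export
print.PlasmidRecord <- function(x, ...) {
  cat(sprintf("PlasmidRecord '%s': %d bp, %s, %d CDS (%d pseudo)\n",
              x$id, x$length_bp, x$topology, nrow(x$cds), sum(x$cds$pseudo)))
  invisible(x)
}

# Nucleotide span of CDS row i, strand-oriented (5'->3' of the gene).
cds_nt <- function(rec, i) {
  f <- rec$cds[i, ]
  if (f$wraps_origin) {
    s <- paste0(substr(rec$sequence, f$start + 1, rec$length_bp),
                substr(rec$sequence, 1, f$end - rec$length_bp))
  } else {
    s <- substr(rec$sequence, f$start + 1, f$end)
  }
  if (f$strand == "-") revcomp(s) else s
}

# Usable (non-pseudo) CDS of a record as a data.frame.
usable_cds <- function(rec) rec$cds[!rec$cds$pseudo, , drop = FALSE]
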