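# Hand-built record fixtures for tests that exercise protein-level logic
# without caring about the underlying nucleotide sequence.

make_protein_record <- function(id, proteins, strands = NULL,
                                topology = "linear", gap = 50) {
  n <- length(proteins)
  if (is.null(strands)) strands <- rep("+", n)
  width <- 300
  starts <- seq(0, by = width + gap, length.out = n)
  cds <- data.frame(
    locus_tag = names(proteins) %||% sprintf("%s_%03d", id, seq_len(n)),
    start = starts, end = starts + width, strand = strands,
    product = "hypothetical protein", protein = unname(proteins),
    pseudo = FALSE, wraps_origin = FALSE, stringsAsFactors = FALSE)
  if (is.null(names(proteins)))
    cds$locus_tag <- sprintf("%s_%03d", id, seq_len(n))
  seqlen <- max(cds$end) + gap
  plasmid_record(id, strrep("ACGT", ceiling(seqlen / 4)), cds, topology)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse-complement a whole record, re-coordinating its CDS.
revcomp_record <- function(rec) {
  len <- rec$length_bp
  cds <- rec$cds
  new_start <- len - cds$end
  new_end <- len - cds$start
  cds$start <- new_start
  cds$end <- new_end
  cds$strand <- ifelse(cds$strand == "+", "-", "+")
  cds <- cds[order(cds$start), ]
  plasmid_record(paste0(rec$id, "_rc"), rc(rec$sequence), cds, rec$topology)
}
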