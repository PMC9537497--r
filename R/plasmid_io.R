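# GenBank/FASTA/TSV I/O, CDS translation, and in-silico PCR.
# GenBank support is deliberately minimal: single-record flat files with
# source and CDS features, the subset the comparative pipeline needs.

#' Translate a coding sequence under a bacterial genetic code
#'
#' Standard translation (default table 11). Codons containing N translate to
#' X; an incomplete tail codon is trimmed; the terminal stop is stripped.
#' Internal stop codons are retained as `*` in the returned string and
#' reported via a warning of class `plasmidcomp_internal_stop` so callers can
#' flag the feature as pseudo.
#'
#' @param nt DNA string, length >= 3, bases in A,C,G,T,N.
#' @param table NCBI genetic-code table number (default 11, bacterial).
#' @return amino-acid string.
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(nt, table = 11) {
  if (!nzchar(nt)) stop("empty input to translate_cds")
  nt <- toupper(nt)
  nt <- substr(nt, 1, nchar(nt) - nchar(nt) %% 3)
  if (nchar(nt) < 3) stop("sequence shorter than one codon")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode(as.character(table)),
    if.fuzzy.codon = "solve"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("*", aa, fixed = TRUE)) {
    w <- simpleWarning(sprintf("internal stop codon in translation ('%s')",
                               substr(aa, 1, 20)))
    class(w) <- c("plasmidcomp_internal_stop", class(w))
    warning(w)
  }
  aa
}

## ---- GenBank parsing -------------------------------------------------------

parse_location <- function(loc, length_bp) {
  # Supports n..m, complement(...), join(a..b,c..d) for origin wrap, <, >.
  raw <- gsub("[<>]", "", gsub("\\s", "", loc))
  strand <- "+"
  x <- raw
  if (startsWith(x, "complement(")) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  wraps <- FALSE
  if (startsWith(x, "join(")) {
    x <- sub("^join\\((.*)\\)$", "\\1", x)
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    iv <- lapply(parts, function(p) as.numeric(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(iv) == 2 && iv[[1]][2] == length_bp && iv[[2]][1] == 1) {
      start <- iv[[1]][1] - 1
      end <- length_bp + iv[[2]][2]
      wraps <- TRUE
    } else {
      stop("unsupported join() location: ", loc)
    }
  } else {
    p <- as.numeric(strsplit(x, "..", fixed = TRUE)[[1]])
    if (length(p) == 1) p <- c(p, p)
    if (anyNA(p) || length(p) != 2) stop("unparseable location: ", loc)
    start <- p[1] - 1
    end <- p[2]
  }
  list(start = as.integer(start), end = as.integer(end),
       strand = strand, wraps_origin = wraps)
}

#' Read a single-record GenBank flat file
#'
#' Parses LOCUS (length, topology), source-feature metadata, CDS features
#' (location, strand, origin wrap, locus_tag, product, translation, pseudo)
#' and the ORIGIN sequence. CDS lacking a `/translation` qualifier are
#' translated from the sequence (table 11); CDS whose translation contains an
#' internal stop are flagged pseudo and excluded from protein-level analyses.
#'
#' @param path path to a GenBank flat file.
#' @return a [plasmid_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS")))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  locus <- lines[startsWith(lines, "LOCUS")][1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  length_bp <- suppressWarnings(as.integer(toks[3]))
  topology <- if (any(grepl("\\bcircular\\b", locus))) "circular" else "linear"

  # ORIGIN sequence
  oi <- which(startsWith(lines, "ORIGIN"))
  if (!length(oi)) stop("GenBank record without sequence (no ORIGIN): ", path)
  seq_lines <- lines[(oi[1] + 1):length(lines)]
  endi <- which(startsWith(seq_lines, "//"))
  if (length(endi)) seq_lines <- seq_lines[seq_len(endi[1] - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record without sequence: ", path)
  if (is.na(length_bp)) length_bp <- nchar(sequence)

  # FEATURES table
  fi <- which(startsWith(lines, "FEATURES"))
  feats <- list()
  metadata <- list()
  if (length(fi)) {
    block <- lines[(fi[1] + 1):(oi[1] - 1)]
    cur <- NULL
    i <- 1
    flush <- function(cur) if (!is.null(cur)) feats[[length(feats) + 1]] <<- cur
    while (i <= length(block)) {
      line <- block[i]
      key <- substr(line, 6, 20)
      body <- trimws(substr(line, 22, nchar(line)))
      if (nzchar(trimws(key))) {                 # new feature
        flush(cur)
        cur <- list(key = trimws(key), loc = body, quals = list(), line = i + fi[1])
      } else if (startsWith(body, "/")) {        # qualifier (may span lines)
        q <- body
        while (grepl('^/[^=]+="', q) && !grepl('"$', q) && i < length(block)) {
          i <- i + 1
          nxt <- trimws(substr(block[i], 22, nchar(block[i])))
          q <- paste0(q, if (grepl('/translation=', q, fixed = TRUE)) "" else " ", nxt)
        }
        if (grepl("=", q, fixed = TRUE)) {
          name <- sub("^/([^=]+)=.*$", "\\1", q)
          val <- sub('^/[^=]+=', "", q)
          val <- gsub('^"|"$', "", val)
        } else {
          name <- sub("^/", "", q)
          val <- TRUE
        }
        if (!is.null(cur)) cur$quals[[name]] <- val
      } else if (!is.null(cur) && !nzchar(cur$loc %||% "")) {
        cur$loc <- body
      } else if (!is.null(cur) && nzchar(body) && !length(cur$quals)) {
        cur$loc <- paste0(cur$loc, body)         # continued location line
      }
      i <- i + 1
    }
    flush(cur)
  }

  rows <- list()
  for (f in feats) {
    if (f$key == "source") {
      for (m in c("organism", "db_xref", "plasmid")) {
        if (!is.null(f$quals[[m]])) metadata[[m]] <- f$quals[[m]]
      }
      next
    }
    if (f$key != "CDS") next
    loc <- tryCatch(parse_location(f$loc, length_bp),
                    error = function(e) stop(sprintf(
                      "format error at line %d: %s", f$line, conditionMessage(e))))
    pseudo <- isTRUE(f$quals$pseudo)
    protein <- f$quals$translation %||% ""
    protein <- gsub("\\s", "", protein)
    if (!nzchar(protein) && !pseudo) {
      nt <- if (loc$wraps_origin) {
        paste0(substr(sequence, loc$start + 1, length_bp),
               substr(sequence, 1, loc$end - length_bp))
      } else substr(sequence, loc$start + 1, loc$end)
      if (loc$strand == "-") nt <- revcomp(nt)
      internal_stop <- FALSE
      protein <- withCallingHandlers(
        translate_cds(nt),
        plasmidcomp_internal_stop = function(w) {
          internal_stop <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (internal_stop) { pseudo <- TRUE; protein <- "" }
    }
    if (pseudo) protein <- ""
    rows[[length(rows) + 1]] <- data.frame(
      locus_tag = f$quals$locus_tag %||% sprintf("CDS_%05d", loc$start),
      start = loc$start, end = loc$end, strand = loc$strand,
      product = f$quals$product %||% "", protein = protein,
      pseudo = pseudo, wraps_origin = loc$wraps_origin,
      stringsAsFactors = FALSE)
  }
  cds <- if (length(rows)) do.call(rbind, rows) else empty_cds()
  plasmid_record(id = id, sequence = sequence, cds = cds,
                 topology = topology, metadata = metadata)
}

## ---- GenBank writing -------------------------------------------------------

format_location <- function(f, length_bp) {
  core <- if (f$wraps_origin) {
    sprintf("join(%d..%d,1..%d)", f$start + 1, length_bp, f$end - length_bp)
  } else {
    sprintf("%d..%d", f$start + 1, f$end)
  }
  if (f$strand == "-") sprintf("complement(%s)", core) else core
}

wrap_qualifier <- function(name, value, width = 58) {
  txt <- sprintf('/%s="%s"', name, value)
  out <- character()
  while (nchar(txt) > width) {
    out <- c(out, substr(txt, 1, width))
    txt <- substr(txt, width + 1, nchar(txt))
  }
  c(out, txt)
}

#' Write a plasmid record as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/FEATURES/ORIGIN with source and CDS features.
#' Round-trips through [read_genbank()] with identical coordinates, strands
#' and proteins.
#'
#' @param rec a [plasmid_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  validate_plasmid_record(rec)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-2024",
    rec$id, rec$length_bp, rec$topology)
  w("DEFINITION  %s.", rec$metadata$definition %||% rec$id)
  w("ACCESSION   %s", rec$id)
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", rec$length_bp)
  if (!is.null(rec$metadata$organism))
    writeLines(paste0("                     ",
                      wrap_qualifier("organism", rec$metadata$organism)), con)
  if (nrow(rec$cds)) for (i in seq_len(nrow(rec$cds))) {
    f <- rec$cds[i, ]
    w("     CDS             %s", format_location(f, rec$length_bp))
    pad <- "                     "
    writeLines(paste0(pad, wrap_qualifier("locus_tag", f$locus_tag)), con)
    if (nzchar(f$product))
      writeLines(paste0(pad, wrap_qualifier("product", f$product)), con)
    if (f$pseudo) writeLines(paste0(pad, "/pseudo"), con)
    if (nzchar(f$protein))
      writeLines(paste0(pad, wrap_qualifier("translation", f$protein)), con)
  }
  w("ORIGIN")
  s <- tolower(rec$sequence)
  for (off in seq(1, nchar(s), by = 60)) {
    chunk <- substr(s, off, min(off + 59, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w("%9d %s", off, paste(groups, collapse = " "))
  }
  writeLines("//", con)
  invisible(path)
}

## ---- FASTA and TSV ---------------------------------------------------------

#' Read a FASTA file of DNA sequences
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named DNA sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Write the CDS table of a record as TSV
#' @param rec a [plasmid_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_table <- function(rec, path) {
  utils::write.table(
    rec$cds[c("locus_tag", "start", "end", "strand", "product", "pseudo")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a primer-pair table
#'
#' TSV with header `name_fw, seq_fw, name_rv, seq_rv`, one primer pair per
#' row. Both sequences are 5'->3' and must be at least 15 nt.
#'
#' @param path TSV path.
#' @return data frame of primer pairs.
#' @export
read_primer_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name_fw", "seq_fw", "name_rv", "seq_rv")
  if (!all(need %in% names(tb)))
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  tb$seq_fw <- toupper(tb$seq_fw); tb$seq_rv <- toupper(tb$seq_rv)
  if (any(nchar(tb$seq_fw) < 15 | nchar(tb$seq_rv) < 15))
    stop("primers must be at least 15 nt")
  tb
}

## ---- in-silico PCR ---------------------------------------------------------

# Plus-strand binding sites of a primer with a strict 3-base 3' clamp.
# side = "right" means the primer's 3' end is the rightmost base of the site
# (primer read in plus orientation); side = "left" means the site is the
# reverse complement of the primer, so the 3' clamp sits at the site's start.
primer_sites <- function(primer, subject, max_mismatch, side) {
  pat <- if (side == "right") primer else revcomp(primer)
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(subject),
                                max.mismatch = max_mismatch, with.indels = FALSE)
  if (!length(m)) return(integer(0))
  st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
  keep <- vapply(seq_along(st), function(i) {
    site <- substr(subject, st[i], en[i])
    if (side == "right") {
      substr(site, nchar(site) - 2, nchar(site)) ==
        substr(pat, nchar(pat) - 2, nchar(pat))
    } else {
      substr(site, 1, 3) == substr(pat, 1, 3)
    }
  }, logical(1))
  st[keep] - 1L   # 0-based starts
}

#' Predict PCR amplicons on a plasmid record
#'
#' Finds binding sites of a primer pair allowing up to `max_mismatch`
#' substitutions (no indels) with an exact 3-base 3' clamp, and reports
#' products measured from the 5' end of the forward primer site to the 5' end
#' of the reverse primer site on the opposite strand, inclusive of both
#' primers. On circular records products may span the origin. Products longer
#' than 20 kb are suppressed.
#'
#' @param record a [plasmid_record()].
#' @param pair list or one-row data frame with `seq_fw` and `seq_rv`.
#' @param max_mismatch maximum substitutions per primer site (default 2).
#' @return data frame with columns `start`, `end`, `length_bp`
#'   (0-based half-open; `end` may exceed the record length for
#'   origin-spanning products). Empty when either primer has no site.
#' @export
in_silico_pcr <- function(record, pair, max_mismatch = 2) {
  fw <- toupper(pair$seq_fw); rv <- toupper(pair$seq_rv)
  if (nchar(fw) < 15 || nchar(rv) < 15) stop("primers must be at least 15 nt")
  max_prod <- 20000L
  len <- record$length_bp
  subject <- record$sequence
  if (record$topology == "circular")
    subject <- paste0(subject, substr(record$sequence, 1, min(max_prod, len)))

  out <- list()
  emit <- function(anchor_starts, closer_starts, closer_len) {
    # anchor = primer matching plus strand (5' end = site start)
    # closer = opposite-strand primer; its 5' end = rightmost base of rc site
    for (a in anchor_starts) {
      if (a >= len) next                       # avoid duplicates on the extension
      for (c0 in closer_starts) {
        five_prime <- c0 + closer_len          # 0-based pos after rc site
        size <- five_prime - a
        if (size >= nchar(fw) && size >= closer_len && size <= max_prod &&
            size <= len) {
          out[[length(out) + 1]] <<- data.frame(
            start = a %% len, end = a %% len + size, length_bp = size)
        }
      }
    }
  }
  fw_plus <- primer_sites(fw, subject, max_mismatch, side = "right")
  rv_rc <- primer_sites(rv, subject, max_mismatch, side = "left")
  emit(fw_plus, rv_rc, nchar(rv))
  rv_plus <- primer_sites(rv, subject, max_mismatch, side = "right")
  fw_rc <- primer_sites(fw, subject, max_mismatch, side = "left")
  emit(rv_plus, fw_rc, nchar(fw))
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), length_bp = integer()))
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$start, res$length_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}
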