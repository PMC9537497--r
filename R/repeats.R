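# Tandem direct repeats (iterons), terminal inverted-repeat pairs,
# target-site duplications, and Tn3-family element delineation.

COMP_MAP <- c(A = "T", C = "G", G = "C", T = "A", N = "?")

# Mask low-complexity stretches (mononucleotide runs >= 12, dinucleotide
# runs >= 16) with N so they can neither seed nor extend IR arms.
mask_low_complexity <- function(seq) {
  for (pat in c("([ACGT])\\1{11,}", "([ACGT][ACGT])\\1{7,}")) {
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] != -1) {
      for (k in seq_along(m)) {
        st <- m[k]; len <- attr(m, "match.length")[k]
        substr(seq, st, st + len - 1) <- strrep("N", len)
      }
    }
  }
  seq
}

vec_hamming <- function(v, i, j, L) sum(v[i:(i + L - 1)] != v[j:(j + L - 1)])

#' Find tandem direct-repeat arrays (iterons)
#'
#' Scans for arrays of >= 2 copies of a repeat unit, each copy within
#' `max_mismatch` Hamming distance of the first copy, with inter-copy
#' spacers of at most `max_spacer` nt. Arrays are maximal (not extendable by
#' another qualifying copy on either side) and are reported once, at the
#' longest qualifying unit length.
#'
#' @param seq DNA string.
#' @param unit_len_range integer pair `(min, max)` of unit lengths to try
#'   (default `c(15, 20)`, bracketing 17-mer iterons).
#' @param max_spacer maximum spacer between copies (default 10).
#' @param max_mismatch maximum Hamming distance of any copy to the first
#'   (default 1).
#' @return list of arrays; each a list with `unit_len`, `n_copies`,
#'   `positions` (0-based starts), `spacer_lens`, `max_mismatch_to_first`,
#'   `units` (copy sequences).
#' @export
find_direct_repeats <- function(seq, unit_len_range = c(15, 20),
                                max_spacer = 10, max_mismatch = 1) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2 * unit_len_range[1]) stop("sequence shorter than two minimal units")
  v <- strsplit(seq, "")[[1]]
  covered <- rep(FALSE, n)
  arrays <- list()
  for (L in seq(unit_len_range[2], unit_len_range[1])) {
    if (2 * L > n) next
    i <- 1
    while (i <= n - 2 * L + 1) {
      if (covered[i]) { i <- i + 1; next }
      copies <- i
      pos <- i
      repeat {
        found <- FALSE
        for (s in 0:max_spacer) {
          j <- pos + L + s
          if (j + L - 1 > n) break
          if (vec_hamming(v, i, j, L) <= max_mismatch) {
            copies <- c(copies, j); pos <- j; found <- TRUE; break
          }
        }
        if (!found) break
      }
      if (length(copies) >= 2) {
        # left maximality: an earlier qualifying first copy absorbs this array
        left_ext <- FALSE
        for (s in 0:max_spacer) {
          j0 <- i - L - s
          if (j0 < 1) break
          if (all(vapply(copies, function(c0) vec_hamming(v, j0, c0, L),
                         numeric(1)) <= max_mismatch)) { left_ext <- TRUE; break }
        }
        if (!left_ext) {
          units <- vapply(copies, function(c0) substr(seq, c0, c0 + L - 1),
                          character(1))
          arrays[[length(arrays) + 1]] <- list(
            unit_len = L, n_copies = length(copies), positions = copies - 1L,
            spacer_lens = diff(copies) - L,
            max_mismatch_to_first = max(vapply(
              copies, function(c0) vec_hamming(v, i, c0, L), numeric(1))),
            units = unname(units))
          covered[i:(pos + L - 1)] <- TRUE
        }
        i <- i + 1
      } else {
        i <- i + 1
      }
    }
    covered[] <- FALSE   # the cross-L selection below resolves duplicates
  }
  if (length(arrays) < 2) return(arrays)
  # Report each repeat region once: prefer more copies, then fewer total
  # mismatches to the first unit (a unit length that absorbs spacer bases
  # accrues extra mismatches), then the longer span; drop overlapping
  # runners-up.
  span <- vapply(arrays, function(a) {
    c(a$positions[1], a$positions[a$n_copies] + a$unit_len)
  }, numeric(2))
  total_mm <- vapply(arrays, function(a) {
    sum(vapply(a$units, function(u) hamming(u, a$units[1]), numeric(1)))
  }, numeric(1))
  ord <- order(-vapply(arrays, `[[`, numeric(1), "n_copies"),
               total_mm,
               -(span[2, ] - span[1, ]),
               -vapply(arrays, `[[`, numeric(1), "unit_len"))
  keep <- logical(length(arrays))
  for (i in ord) {
    clash <- which(keep)
    if (!any(span[1, i] < span[2, clash] & span[1, clash] < span[2, i]))
      keep[i] <- TRUE
  }
  arrays[sort(which(keep))]
}

# Maximal <=k-mismatch match-bounded runs on a logical vector M over indexes
# xs; returns matrix of (start, end) index positions into xs.
maximal_runs <- function(M, k) {
  m <- length(M)
  z <- which(!M)
  zp <- c(0L, z, m + 1L)
  nz <- length(z)
  nwin <- if (nz <= k) 1L else nz - k + 1L
  out <- matrix(integer(0), ncol = 2)
  for (j in seq_len(nwin)) {
    s <- zp[j] + 1L
    e <- zp[min(j + k + 1L, nz + 2L)] - 1L
    while (s <= e && !M[s]) s <- s + 1L
    while (e >= s && !M[e]) e <- e - 1L
    if (s <= e) out <- rbind(out, c(s, e))
  }
  out <- unique(out)
  if (nrow(out) > 1) {
    # trimming can leave a window nested inside a neighbour; drop it
    contained <- vapply(seq_len(nrow(out)), function(i) {
      any(out[, 1] <= out[i, 1] & out[, 2] >= out[i, 2] &
            (out[, 1] < out[i, 1] | out[, 2] > out[i, 2]))
    }, logical(1))
    out <- out[!contained, , drop = FALSE]
  }
  out
}

#' Find inverted-repeat pairs
#'
#' Exhaustive palindrome-center scan: for every center, the per-position
#' complementary-match profile is computed and maximal runs with at most
#' `max_mismatch` mismatches (ending on matches) become candidate IR arms.
#' Low-complexity stretches are masked before the scan. Overlapping reports
#' are merged to the longest.
#'
#' @param seq DNA string, longer than `2 * min_len`.
#' @param min_len,max_len arm-length bounds (defaults 20 / 48). Arms longer
#'   than `max_len` are trimmed on the inner side.
#' @param max_mismatch maximum mismatches between an arm and the reverse
#'   complement of its partner (default 2).
#' @param max_span maximum distance from left-arm start to right-arm end
#'   (default: whole sequence).
#' @param merge_overlaps merge overlapping reports to the longest
#'   (default TRUE).
#' @return data frame with columns `left_start`, `left_end`, `right_start`,
#'   `right_end` (0-based half-open), `ir_len`, `mismatches`, `left_seq`,
#'   `right_seq`.
#' @export
find_ir_pairs <- function(seq, min_len = 20, max_len = 48, max_mismatch = 2,
                          max_span = nchar(seq), merge_overlaps = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n <= 2 * min_len) stop("sequence too short for IR search")
  masked <- mask_low_complexity(seq)
  v <- strsplit(masked, "")[[1]]
  cv <- unname(COMP_MAP[v])
  cv[is.na(cv)] <- "?"
  res <- list()
  for (C in seq(2 * min_len + 1, 2 * n - 2 * min_len + 1)) {
    x_max <- (C - 1) %/% 2
    x_min <- max(1L, as.integer(ceiling((C + 1 - max_span) / 2)), C - n)
    if (x_max - x_min + 1 < min_len) next
    xs <- x_min:x_max
    M <- v[xs] == cv[C - xs]
    runs <- maximal_runs(M, max_mismatch)
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      s <- xs[runs[r, 1]]; e <- xs[runs[r, 2]]
      len <- e - s + 1
      if (len < min_len) next
      if (len > max_len) {               # trim inner side, keep match ends
        e <- s + max_len - 1L
        while (e > s && v[e] != cv[C - e]) e <- e - 1L
        len <- e - s + 1
        if (len < min_len) next
      }
      mism <- sum(v[s:e] != cv[C - (s:e)])
      res[[length(res) + 1]] <- data.frame(
        left_start = s - 1L, left_end = e,
        right_start = C - e - 1L, right_end = C - s,
        ir_len = len, mismatches = mism, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      ir_len = integer(), mismatches = integer(),
                      left_seq = character(), right_seq = character(),
                      stringsAsFactors = FALSE))
  }
  out <- unique(do.call(rbind, res))
  if (merge_overlaps && nrow(out) > 1) {
    out <- out[order(-out$ir_len, out$mismatches, out$left_start), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))[-1]) {
      for (j in which(keep[seq_len(i - 1)])) {
        overlap_left <- out$left_start[i] < out$left_end[j] &&
          out$left_start[j] < out$left_end[i]
        overlap_right <- out$right_start[i] < out$right_end[j] &&
          out$right_start[j] < out$right_end[i]
        if (overlap_left && overlap_right) { keep[i] <- FALSE; break }
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  out$left_seq <- substring(seq, out$left_start + 1, out$left_end)
  out$right_seq <- substring(seq, out$right_start + 1, out$right_end)
  out <- out[order(out$left_start, out$right_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Target-site duplication flanking an IR pair
#'
#' Returns the duplicated bases if the bases immediately left of the left IR
#' exactly equal the bases immediately right of the right IR, testing
#' lengths from the maximum down to the minimum of `tsd_len_range`.
#'
#' @param seq DNA string.
#' @param ir one row of [find_ir_pairs()] output (or a list with
#'   `left_start` and `right_end`, 0-based half-open).
#' @param tsd_len_range lengths to test, longest first (default `c(4, 6)`).
#' @return the TSD string, or `NULL` when flanks differ at every length.
#' @export
find_tsd <- function(seq, ir, tsd_len_range = c(4, 6)) {
  ls <- ir$left_start; re <- ir$right_end
  for (len in seq(tsd_len_range[2], tsd_len_range[1])) {
    if (ls - len < 0 || re + len > nchar(seq)) next
    left <- substr(seq, ls - len + 1, ls)
    right <- substr(seq, re + 1, re + len)
    if (left == right) return(left)
  }
  NULL
}

## ---- element descriptors and delineation -----------------------------------

#' Read transposable-element descriptors
#'
#' A descriptor bundle is a YAML file listing element families, each with a
#' terminal IR sequence and references (by name) to proteins in a companion
#' amino-acid FASTA (`proteins_fasta` field, path relative to the YAML).
#' Proteins carry a role: `transposase` (used as anchors) or `cargo`.
#'
#' The shipped bundle (`system.file("extdata/elements",
#' "synthetic_tn_descriptors.yaml", package = "plasmidcomp")`) holds
#' synthetic stand-ins for three Tn3-family elements at their published IR
#' lengths: Tn4656-like (39 bp), Tn5053-like (25 bp), Tn5563-like (38 bp).
#'
#' @param path YAML descriptor file.
#' @return list of descriptors: `family_label`, `ir`, `ir_len`, `proteins`
#'   (named character vector), `roles` (named character vector).
#' @export
read_element_descriptors <- function(path) {
  spec <- yaml::read_yaml(path)
  prot_path <- file.path(dirname(path), spec$proteins_fasta)
  aa <- Biostrings::readAAStringSet(prot_path)
  prots <- stats::setNames(as.character(aa), names(aa))
  lapply(spec$families, function(f) {
    if (is.null(f$ir) || !length(f$proteins))
      stop("descriptor '", f$label, "' needs an IR sequence and >= 1 protein")
    pn <- vapply(f$proteins, `[[`, "", "name")
    roles <- stats::setNames(vapply(f$proteins, `[[`, "", "role"), pn)
    missing <- setdiff(pn, names(prots))
    if (length(missing)) stop("proteins not in FASTA: ", paste(missing, collapse = ","))
    list(family_label = f$label, ir = toupper(f$ir), ir_len = nchar(f$ir),
         proteins = prots[pn], roles = roles)
  })
}

# All match positions of `pat` in `seq` with <= max_mismatch substitutions;
# returns data.frame(start0, mismatches) (0-based starts).
pattern_sites <- function(pat, seq, max_mismatch) {
  m <- Biostrings::matchPattern(pat, Biostrings::DNAString(seq),
                                max.mismatch = max_mismatch, with.indels = FALSE)
  if (!length(m)) {
    return(data.frame(start0 = integer(), mismatches = integer()))
  }
  st <- BiocGenerics::start(m)
  mm <- vapply(seq_along(st), function(i)
    hamming(substr(seq, st[i], st[i] + nchar(pat) - 1), pat), numeric(1))
  data.frame(start0 = st - 1L, mismatches = as.integer(mm))
}

#' Delineate transposable elements on a plasmid record
#'
#' For each descriptor family, transposase anchors are located by best-hit
#' protein homology against the record CDS; element boundaries are the IR
#' matches (forward for the left terminus, reverse complement for the right;
#' up to `ir_max_mismatch` substitutions) nearest the anchor within
#' `window` bp. An element with only one recoverable IR is flagged truncated
#' on the missing side, its boundary there taken at the outermost CDS
#' matching the family's proteins. Spans contained in another call's span
#' are marked nested (`parent`); a 4-6 bp target-site duplication is
#' reported for complete elements.
#'
#' @param record a [plasmid_record()].
#' @param descriptors list from [read_element_descriptors()].
#' @param params an [alignment_params()] for anchor homology.
#' @param ir_max_mismatch IR match tolerance (default 2).
#' @param window maximum anchor-to-IR distance in bp (default 100000,
#'   accommodating composite elements of ~77 kb).
#' @return data frame of calls: `element_id`, `family_label`, `start`, `end`
#'   (0-based half-open), `ir_len`, `ir_mismatches`, `tsd`,
#'   `truncated_side` (none/left/right), `parent`, `n_cargo`, `cargo`
#'   (semicolon-joined locus tags).
#' @export
delineate_elements <- function(record, descriptors, params = alignment_params(),
                               ir_max_mismatch = 2, window = 100000) {
  empty <- data.frame(element_id = character(), family_label = character(),
                      start = integer(), end = integer(), ir_len = integer(),
                      ir_mismatches = integer(), tsd = character(),
                      truncated_side = character(), parent = character(),
                      n_cargo = integer(), cargo = character(),
                      stringsAsFactors = FALSE)
  calls <- list()
  for (d in descriptors) {
    if (is.null(d[["ir"]]) || !length(d$proteins))
      stop("descriptor without IR or proteins: ", d$family_label)
    tn_prot <- d$proteins[d$roles == "transposase"]
    # match record CDS against the descriptor proteome so that every copy
    # of a multi-copy element anchors, not just the best-scoring one
    np <- length(d$proteins)
    dummy <- plasmid_record(
      id = d$family_label, sequence = strrep("A", 3 * np + 3),
      cds = data.frame(locus_tag = names(d$proteins),
                       start = 3 * (seq_len(np) - 1), end = 3 * seq_len(np),
                       strand = "+", product = "",
                       protein = unname(d$proteins), pseudo = FALSE,
                       wraps_origin = FALSE, stringsAsFactors = FALSE),
      topology = "linear")
    hits <- best_hits(record, dummy, params)
    if (!nrow(hits)) next
    fam_loci <- unique(hits$query_locus)
    anchor_loci <- unique(hits$query_locus[hits$target_locus %in% names(tn_prot)])
    if (!length(anchor_loci)) next
    left_sites <- pattern_sites(d[["ir"]], record$sequence, ir_max_mismatch)
    right_sites <- pattern_sites(revcomp(d[["ir"]]), record$sequence, ir_max_mismatch)
    fam_cds <- record$cds[record$cds$locus_tag %in% fam_loci, , drop = FALSE]
    for (al in anchor_loci) {
      a <- record$cds[record$cds$locus_tag == al, ]
      pick <- function(sites, side) {
        if (!nrow(sites)) return(NULL)
        if (side == "left") {
          cand <- sites[sites$start0 + d[["ir_len"]] <= a$start &
                          sites$start0 >= a$start - window, , drop = FALSE]
          if (!nrow(cand)) return(NULL)
          cand$dist <- a$start - cand$start0
        } else {
          cand <- sites[sites$start0 >= a$end &
                          sites$start0 + d[["ir_len"]] <= a$end + window, , drop = FALSE]
          if (!nrow(cand)) return(NULL)
          cand$dist <- cand$start0 - a$end
        }
        cand[order(cand$dist, cand$mismatches), ][1, ]
      }
      L <- pick(left_sites, "left")
      R <- pick(right_sites, "right")
      if (is.null(L) && is.null(R)) next
      truncated <- "none"
      if (is.null(R)) {
        truncated <- "right"
        inside <- fam_cds[fam_cds$start >= L$start0 &
                            fam_cds$start <= L$start0 + window, , drop = FALSE]
        span <- c(L$start0, max(inside$end))
        mism <- L$mismatches
      } else if (is.null(L)) {
        truncated <- "left"
        inside <- fam_cds[fam_cds$end <= R$start0 + d[["ir_len"]] &
                            fam_cds$end >= R$start0 - window, , drop = FALSE]
        span <- c(min(inside$start), R$start0 + d[["ir_len"]])
        mism <- R$mismatches
      } else {
        span <- c(L$start0, R$start0 + d[["ir_len"]])
        mism <- max(L$mismatches, R$mismatches)
      }
      calls[[length(calls) + 1]] <- list(
        family_label = d$family_label, start = span[1], end = span[2],
        ir_len = d[["ir_len"]], ir_mismatches = as.integer(mism),
        truncated_side = truncated, fam_loci = fam_loci,
        anchor_loci = anchor_loci)
    }
  }
  if (!length(calls)) return(empty)
  # dedupe identical spans from multiple anchors of the same element
  key <- vapply(calls, function(c0) paste(c0$family_label, c0$start, c0$end),
                character(1))
  calls <- calls[!duplicated(key)]
  ord <- order(vapply(calls, `[[`, numeric(1), "start"),
               -vapply(calls, `[[`, numeric(1), "end"))
  calls <- calls[ord]
  ids <- sprintf("%s_%02d", vapply(calls, `[[`, "", "family_label"),
                 seq_along(calls))
  rows <- lapply(seq_along(calls), function(i) {
    c0 <- calls[[i]]
    parent <- NA_character_
    for (j in seq_along(calls)) {
      if (j == i) next
      cj <- calls[[j]]
      if (cj$start < c0$start && c0$end < cj$end) {
        parent <- ids[j]; break
      }
    }
    tsd <- NA_character_
    if (c0$truncated_side == "none") {
      t0 <- find_tsd(record$sequence,
                     list(left_start = c0$start, right_end = c0$end))
      if (!is.null(t0)) tsd <- t0
    }
    inside <- record$cds[record$cds$start >= c0$start &
                           record$cds$end <= c0$end, , drop = FALSE]
    cargo <- setdiff(inside$locus_tag, c0$anchor_loci)
    # genes of a nested element are its cargo, not the parent's machinery
    data.frame(element_id = ids[i], family_label = c0$family_label,
               start = c0$start, end = c0$end, ir_len = c0$ir_len,
               ir_mismatches = c0$ir_mismatches, tsd = tsd,
               truncated_side = c0$truncated_side, parent = parent,
               n_cargo = length(cargo),
               cargo = paste(cargo, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write element calls as TSV
#' @param calls output of [delineate_elements()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_elements <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Write element calls as GFF3 mobile_genetic_element features
#' @param calls output of [delineate_elements()].
#' @param record the source [plasmid_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_elements_gff3 <- function(calls, record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(calls))) {
    e <- calls[i, ]
    attrs <- sprintf("ID=%s;family=%s;truncated=%s", e$element_id,
                     e$family_label, e$truncated_side)
    if (!is.na(e$parent)) attrs <- paste0(attrs, ";Parent=", e$parent)
    writeLines(sprintf(
      "%s\tplasmidcomp\tmobile_genetic_element\t%d\t%d\t.\t+\t.\t%s",
      record$id, e$start + 1, e$end, attrs), con)
  }
  invisible(path)
}
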