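# Seeded synthetic plasmid generator with planted, machine-readable ground
# truth for every pipeline stage: operon geometry, homologue divergence,
# transposable elements with IR/TSD structure, and iteron arrays.
#
# One integer seed governs everything; per-gene and per-step sub-seeds are
# derived by counter so adding items never perturbs earlier items.

#' Simulation configuration
#'
#' @param seed integer master seed.
#' @param n_genes number of CDS on the base plasmid (default 50).
#' @param run_sizes explicit same-strand run sizes (overrides `n_genes` /
#'   `mean_run_len` when given).
#' @param mean_run_len mean genes per same-strand run (default 4).
#' @param within_gap_range intergenic gaps inside a run, bounded below the
#'   operon-joining threshold (default `c(0, 19)`).
#' @param between_gap_range gaps between runs, at or above the threshold
#'   (default `c(25, 150)`).
#' @param protein_len_range protein lengths in residues (default
#'   `c(60, 200)`).
#' @param topology `"circular"` (default) or `"linear"`.
#' @param iterons optional list(`unit_len`, `n_copies`, `spacer_lens`,
#'   `mismatches`) or list(`units`, `spacer_lens`) with explicit unit
#'   sequences; planted in an intergenic region.
#' @param elements optional list of element specs for [plant_element()].
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(seed, n_genes = 50, run_sizes = NULL, mean_run_len = 4,
                       within_gap_range = c(0, 19), between_gap_range = c(25, 150),
                       protein_len_range = c(60, 200),
                       topology = c("circular", "linear"),
                       iterons = NULL, elements = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(seed = as.integer(seed), n_genes = n_genes,
                 run_sizes = run_sizes, mean_run_len = mean_run_len,
                 within_gap_range = within_gap_range,
                 between_gap_range = between_gap_range,
                 protein_len_range = protein_len_range,
                 topology = match.arg(topology),
                 iterons = iterons, elements = elements),
            class = "SimConfig")
}

# Codon table for back-translation: uniform synonymous codons, table 11.
codons_by_aa <- function() {
  code <- Biostrings::getGeneticCode("11")
  split(names(code), unname(code))
}

backtranslate <- function(protein, codons = codons_by_aa()) {
  aas <- strsplit(protein, "")[[1]]
  body <- vapply(aas, function(a) {
    cs <- codons[[a]]
    if (is.null(cs)) stop("cannot back-translate residue: ", a)
    cs[sample.int(length(cs), 1)]
  }, character(1))
  stopc <- codons[["*"]][sample.int(3, 1)]
  paste0(paste(body, collapse = ""), stopc)
}

# Assemble a record from a gene table (locus_tag, protein, run, strand) and
# gap geometry. Returns record plus per-gene coordinates.
assemble_record <- function(id, genes, config, seed_salt) {
  seed <- config$seed
  nts <- vapply(seq_len(nrow(genes)), function(i)
    with_subseed(seed, seed_salt + 7L * i, backtranslate(genes$protein[i])),
    character(1))
  pieces <- character()
  pos <- 0L
  lead <- with_subseed(seed, seed_salt + 1L, random_dna(sample(80:150, 1)))
  pieces <- c(pieces, lead); pos <- pos + nchar(lead)
  starts <- integer(nrow(genes)); ends <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (i > 1) {
      gap_range <- if (genes$run[i] == genes$run[i - 1]) {
        config$within_gap_range
      } else config$between_gap_range
      gap <- with_subseed(seed, seed_salt + 7L * i + 1L,
                          sample(gap_range[1]:gap_range[2], 1))
      if (gap > 0) {
        g <- with_subseed(seed, seed_salt + 7L * i + 2L, random_dna(gap))
        pieces <- c(pieces, g); pos <- pos + gap
      }
    }
    nt <- nts[i]
    placed <- if (genes$strand[i] == "-") revcomp(nt) else nt
    starts[i] <- pos
    ends[i] <- pos + nchar(placed)
    pieces <- c(pieces, placed)
    pos <- ends[i]
  }
  tail_ <- with_subseed(seed, seed_salt + 2L, random_dna(sample(150:300, 1)))
  pieces <- c(pieces, tail_)
  sequence <- paste(pieces, collapse = "")
  cds <- data.frame(locus_tag = genes$locus_tag, start = starts, end = ends,
                    strand = genes$strand, product = genes$product,
                    protein = genes$protein, pseudo = FALSE,
                    wraps_origin = FALSE, stringsAsFactors = FALSE)
  plasmid_record(id = id, sequence = sequence, cds = cds,
                 topology = config$topology,
                 metadata = list(organism = "synthetic construct"))
}

#' Generate a synthetic query plasmid with ground truth
#'
#' Genes are arranged in same-strand runs with within-run intergenic gaps
#' below the operon threshold and between-run gaps above it; proteins are
#' random and back-translated with uniform synonymous codons (table 11).
#' Iteron arrays and transposable elements are planted afterwards when the
#' config requests them. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @param descriptors element descriptors ([read_element_descriptors()]),
#'   required when `config$elements` is non-empty.
#' @return list with `record` (a [plasmid_record()]) and `truth` (list:
#'   `genes`, `operons`, `iterons`, `elements`).
#' @export
generate_query <- function(config, descriptors = NULL) {
  seed <- config$seed
  run_sizes <- config$run_sizes
  if (is.null(run_sizes)) {
    run_sizes <- with_subseed(seed, 11L, {
      out <- integer(0)
      while (sum(out) < config$n_genes)
        out <- c(out, 1L + stats::rpois(1, config$mean_run_len - 1))
      out[length(out)] <- out[length(out)] - (sum(out) - config$n_genes)
      out[out > 0]
    })
  }
  n <- sum(run_sizes)
  strands <- with_subseed(seed, 12L,
                          sample(c("+", "-"), length(run_sizes), replace = TRUE))
  plens <- with_subseed(seed, 13L,
    sample(config$protein_len_range[1]:config$protein_len_range[2], n,
           replace = TRUE))
  proteins <- vapply(seq_len(n), function(i)
    with_subseed(seed, 100L + i,
                 paste0("M", random_protein(plens[i] - 1))), character(1))
  genes <- data.frame(
    locus_tag = sprintf("SYN_%05d", seq_len(n) * 5L),
    protein = proteins,
    run = rep(seq_along(run_sizes), run_sizes),
    strand = rep(strands, run_sizes),
    product = "hypothetical protein",
    stringsAsFactors = FALSE)
  rec <- assemble_record(sprintf("synq%d", seed), genes, config,
                         seed_salt = 10000L)
  truth <- list(
    genes = cbind(rec$cds[c("locus_tag", "start", "end", "strand")],
                  run = genes$run, protein = genes$protein),
    operons = split(genes$locus_tag, genes$run),
    iterons = NULL, elements = NULL)
  if (!is.null(config$iterons)) {
    r <- plant_iterons(rec, truth, config$iterons, seed)
    rec <- r$record; truth <- r$truth
  }
  if (length(config$elements)) {
    if (is.null(descriptors)) stop("element specs given without descriptors")
    dlab <- vapply(descriptors, `[[`, "", "family_label")
    for (k in seq_along(config$elements)) {
      spec <- config$elements[[k]]
      d <- descriptors[[match(spec$family, dlab)]]
      if (is.null(d)) stop("no descriptor for family: ", spec$family)
      r <- plant_element(rec, truth, spec, d, subseed(seed, 5000L + k))
      rec <- r$record; truth <- r$truth
    }
    truth$operons <- NULL   # insertions invalidate the planted run geometry
  }
  validate_ground_truth(rec, truth)
  list(record = rec, truth = truth)
}

#' Derive a diverged target plasmid from a query
#'
#' Copies a planned fraction of the query's genes mutated to a planned
#' protein identity (amino-acid substitutions, then back-translation;
#' realized identity within 2 points of plan); remaining genes are replaced
#' by unrelated random proteins. Gene order is optionally shuffled with a
#' recorded permutation.
#'
#' @param query the query [plasmid_record()].
#' @param truth the query's ground truth (from [generate_query()]).
#' @param divergence_plan data frame with columns `fraction`,
#'   `identity_pct`; fractions must sum to at most 1.
#' @param seed integer seed.
#' @param shuffle logical: shuffle gene order (default FALSE).
#' @param id target record id.
#' @return list with `record` and `truth` (`genes` carries `query_partner`
#'   and `planted_identity`; `permutation` maps target gene order to query
#'   gene order).
#' @export
derive_target <- function(query, truth, divergence_plan, seed,
                          shuffle = FALSE, id = NULL) {
  stopifnot(sum(divergence_plan$fraction) <= 1 + 1e-9)
  qg <- truth$genes
  n <- nrow(qg)
  counts <- round(divergence_plan$fraction * n)
  pool <- with_subseed(seed, 21L, sample.int(n))
  assign_id <- rep(NA_integer_, n)
  off <- 0
  for (p in seq_along(counts)) {
    if (counts[p] > 0) assign_id[pool[(off + 1):(off + counts[p])]] <- p
    off <- off + counts[p]
  }
  proteins <- character(n)
  partner <- rep(NA_character_, n)
  planted <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(assign_id[i])) {
      proteins[i] <- with_subseed(seed, 300L + i,
        paste0("M", random_protein(nchar(qg$protein[i]) - 1)))
    } else {
      idp <- divergence_plan$identity_pct[assign_id[i]]
      proteins[i] <- with_subseed(seed, 300L + i,
                                  mutate_protein(qg$protein[i], idp))
      partner[i] <- qg$locus_tag[i]
      planted[i] <- idp
    }
  }
  perm <- if (shuffle) with_subseed(seed, 22L, sample.int(n)) else seq_len(n)
  genes <- data.frame(
    locus_tag = sprintf("TGT_%05d", seq_len(n) * 5L),
    protein = proteins[perm],
    run = rep(seq_len(ceiling(n / 4)), each = 4)[seq_len(n)],
    strand = qg$strand[perm],
    product = "hypothetical protein",
    stringsAsFactors = FALSE)
  cfg <- sim_config(seed = as.integer(seed %% 2147483629))
  rec <- assemble_record(id %||% sprintf("synt%d", seed), genes, cfg,
                         seed_salt = 20000L)
  tg <- cbind(rec$cds[c("locus_tag", "start", "end", "strand")],
              query_partner = partner[perm], planted_identity = planted[perm],
              protein = proteins[perm])
  out_truth <- list(genes = tg, permutation = perm, operons = NULL,
                    iterons = NULL, elements = NULL)
  validate_ground_truth(rec, out_truth)
  list(record = rec, truth = out_truth)
}

# Substitute residues to reach a target percent identity; never touches the
# initial M so the gene keeps a canonical start.
mutate_protein <- function(protein, identity_pct) {
  L <- nchar(protein)
  m <- round(L * (1 - identity_pct / 100))
  if (m == 0) return(protein)
  v <- strsplit(protein, "")[[1]]
  idx <- sample(2:L, min(m, L - 1))
  for (i in idx) v[i] <- sample(setdiff(AA20, v[i]), 1)
  paste(v, collapse = "")
}

# Insert `insert_seq` (with optional CDS rows) into a record at 0-based
# position pos0, duplicating tsd_len bases before pos0 after the insert.
# Shifts downstream CDS and all recorded truth coordinates.
insert_into_record <- function(rec, truth, pos0, insert_seq, insert_cds,
                               tsd_len = 0) {
  len_ins <- nchar(insert_seq)
  shift <- len_ins + tsd_len
  tsd <- if (tsd_len > 0) substr(rec$sequence, pos0 - tsd_len + 1, pos0) else ""
  sequence <- paste0(substr(rec$sequence, 1, pos0), insert_seq, tsd,
                     substr(rec$sequence, pos0 + 1, rec$length_bp))
  cds <- rec$cds
  if (any(cds$start < pos0 & cds$end > pos0))
    stop("insertion point lies inside a CDS")
  move <- cds$start >= pos0
  cds$start[move] <- cds$start[move] + shift
  cds$end[move] <- cds$end[move] + shift
  if (nrow(insert_cds)) {
    insert_cds$start <- insert_cds$start + pos0
    insert_cds$end <- insert_cds$end + pos0
    cds <- rbind(cds, insert_cds)
  }
  # shift recorded truth
  if (!is.null(truth$genes)) {
    mv <- truth$genes$start >= pos0
    truth$genes$start[mv] <- truth$genes$start[mv] + shift
    truth$genes$end[mv] <- truth$genes$end[mv] + shift
  }
  if (!is.null(truth$iterons)) {
    mv <- truth$iterons$positions >= pos0
    truth$iterons$positions[mv] <- truth$iterons$positions[mv] + shift
  }
  if (!is.null(truth$elements) && nrow(truth$elements)) {
    host <- truth$elements$start < pos0 & truth$elements$end > pos0
    after <- truth$elements$start >= pos0
    truth$elements$end[host] <- truth$elements$end[host] + shift
    truth$elements$start[after] <- truth$elements$start[after] + shift
    truth$elements$end[after] <- truth$elements$end[after] + shift
  }
  rec2 <- plasmid_record(rec$id, sequence, cds, rec$topology, rec$metadata)
  list(record = rec2, truth = truth, tsd = tsd)
}

# Candidate intergenic insertion positions (0-based), away from CDS edges.
intergenic_positions <- function(rec, margin = 10) {
  cds <- rec$cds[order(rec$cds$start), ]
  gaps <- list()
  prev_end <- 0
  for (i in seq_len(nrow(cds))) {
    if (cds$start[i] - prev_end > 2 * margin)
      gaps[[length(gaps) + 1]] <- c(prev_end + margin, cds$start[i] - margin)
    prev_end <- max(prev_end, cds$end[i])
  }
  if (rec$length_bp - prev_end > 2 * margin)
    gaps[[length(gaps) + 1]] <- c(prev_end + margin, rec$length_bp - margin)
  gaps
}

#' Plant a transposable element into a record
#'
#' Builds `left IR - machinery and cargo CDS - right IR` from a descriptor,
#' inserts it at an intergenic position, and creates the target-site
#' duplication by duplicating the insertion-site bases. `nested = TRUE`
#' inserts into an existing element's span (between two of its internal
#' CDS); `truncated = "right"`/`"left"` omits that IR (and the TSD), ending
#' the element at its outermost internal CDS.
#'
#' @param rec a [plasmid_record()].
#' @param truth its ground-truth list (updated in the return value).
#' @param spec list: `family`, and optionally `ir_mismatches` (0-2, planted
#'   in the right arm; default 0), `tsd_len` (default 5), `nested` (default
#'   FALSE), `truncated` (`"none"`, `"right"`, `"left"`; default "none"),
#'   `n_cargo` (default: all cargo proteins of the descriptor),
#'   `insert_at` (0-based position; default random intergenic).
#' @param descriptor one element of [read_element_descriptors()].
#' @param seed integer seed.
#' @return list with updated `record` and `truth` (`truth$elements` gains a
#'   row: family, span, tsd, truncated_side, parent, cargo loci).
#' @export
plant_element <- function(rec, truth, spec, descriptor, seed) {
  spec$ir_mismatches <- spec$ir_mismatches %||% 0L
  spec$tsd_len <- spec$tsd_len %||% 5L
  spec$nested <- isTRUE(spec$nested)
  spec$truncated <- spec$truncated %||% "none"
  if (isTRUE(spec$truncated)) spec$truncated <- "right"
  ir <- descriptor$ir
  L <- nchar(ir)
  tn <- descriptor$proteins[descriptor$roles == "transposase"]
  cargo_pool <- descriptor$proteins[descriptor$roles == "cargo"]
  n_cargo <- min(spec$n_cargo %||% length(cargo_pool), length(cargo_pool))
  cargo <- cargo_pool[seq_len(n_cargo)]
  elem_prots <- c(tn, cargo)

  existing <- if (is.null(truth$elements)) 0L else nrow(truth$elements)
  lab <- sprintf("%s_p%02d", descriptor$family_label, existing + 1L)

  # element body
  built <- with_subseed(seed, 31L, {
    pieces <- ir
    pos <- L
    starts <- integer(length(elem_prots)); ends <- integer(length(elem_prots))
    for (i in seq_along(elem_prots)) {
      gap <- sample(8:18, 1)
      pieces <- c(pieces, random_dna(gap)); pos <- pos + gap
      nt <- backtranslate(elem_prots[[i]])
      starts[i] <- pos; ends[i] <- pos + nchar(nt)
      pieces <- c(pieces, nt); pos <- ends[i]
    }
    right <- revcomp(ir)
    if (spec$ir_mismatches > 0) {
      v <- strsplit(right, "")[[1]]
      at <- sample(seq_len(L), spec$ir_mismatches)
      for (a in at) v[a] <- sample(setdiff(c("A", "C", "G", "T"), v[a]), 1)
      right <- paste(v, collapse = "")
    }
    list(starts = starts, ends = ends, pieces = pieces, pos = pos,
         right = right, tail_gap = sample(8:18, 1))
  })
  if (spec$truncated == "right") {
    elem_seq <- paste(built$pieces, collapse = "")
    ir_note <- "left_only"
  } else if (spec$truncated == "left") {
    # truncation removes the left IR and its spacer: the element's surviving
    # sequence begins at its first internal CDS
    drop_len <- built$starts[1]
    body <- paste(built$pieces[-(1:2)], collapse = "")
    elem_seq <- paste0(body,
                       with_subseed(seed, 32L, random_dna(built$tail_gap)),
                       built$right)
    built$starts <- built$starts - drop_len
    built$ends <- built$ends - drop_len
    ir_note <- "right_only"
  } else {
    elem_seq <- paste0(paste(built$pieces, collapse = ""),
                       with_subseed(seed, 32L, random_dna(built$tail_gap)),
                       built$right)
    ir_note <- "both"
  }

  elem_cds <- data.frame(
    locus_tag = sprintf("%s_c%02d", lab, seq_along(elem_prots)),
    start = built$starts, end = built$ends, strand = "+",
    product = ifelse(names(elem_prots) %in% names(tn),
                     "transposase", "element cargo protein"),
    protein = unname(unlist(elem_prots)), pseudo = FALSE, wraps_origin = FALSE,
    stringsAsFactors = FALSE)

  # choose insertion point
  if (!is.null(spec$insert_at)) {
    pos0 <- spec$insert_at
  } else if (spec$nested) {
    if (!existing) stop("nested=TRUE but no element planted yet")
    host <- truth$elements[existing, ]
    inside <- rec$cds[rec$cds$start >= host$start & rec$cds$end <= host$end, ]
    inside <- inside[order(inside$start), ]
    if (nrow(inside) < 2) stop("host element too small to nest into")
    k <- with_subseed(seed, 33L, sample(nrow(inside) - 1, 1))
    pos0 <- as.integer((inside$end[k] + inside$start[k + 1]) %/% 2)
  } else {
    gaps <- intergenic_positions(rec, margin = max(12, spec$tsd_len + 2))
    if (!is.null(truth$elements) && nrow(truth$elements)) {
      gaps <- Filter(function(g) {
        !any(g[1] < truth$elements$end & truth$elements$start < g[2])
      }, gaps)
    }
    if (!length(gaps)) stop("no intergenic space left for planting")
    g <- gaps[[with_subseed(seed, 34L, sample(length(gaps), 1))]]
    pos0 <- as.integer(with_subseed(seed, 35L, sample(g[1]:g[2], 1)))
  }

  host_id <- NA_character_
  if (!is.null(truth$elements) && nrow(truth$elements)) {
    hostrow <- which(truth$elements$start < pos0 & truth$elements$end > pos0)
    if (length(hostrow) && !spec$nested)
      stop("insertion overlaps an existing element; set nested = TRUE")
    if (length(hostrow)) host_id <- truth$elements$element[hostrow[1]]
  }

  tsd_len <- if (spec$truncated == "none") spec$tsd_len else 0L
  ins <- insert_into_record(rec, truth, pos0, elem_seq, elem_cds, tsd_len)
  truth <- ins$truth
  row <- data.frame(
    element = lab, family = descriptor$family_label,
    start = pos0, end = pos0 + nchar(elem_seq),
    ir_len = L, ir_mismatches = spec$ir_mismatches, ir_seq = ir,
    irs = ir_note, tsd = if (nzchar(ins$tsd)) ins$tsd else NA_character_,
    truncated_side = spec$truncated, parent = host_id,
    cargo = paste(elem_cds$locus_tag[-seq_along(tn)], collapse = ";"),
    stringsAsFactors = FALSE)
  truth$elements <- rbind(truth$elements, row)
  list(record = ins$record, truth = truth)
}

# Plant an iteron-style tandem direct-repeat array in an intergenic region.
plant_iterons <- function(rec, truth, spec, seed) {
  if (!is.null(spec$units)) {
    units <- toupper(spec$units)
    spacers <- spec$spacer_lens
  } else {
    unit <- with_subseed(seed, 41L, random_dna(spec$unit_len))
    units <- rep(unit, spec$n_copies)
    mm <- spec$mismatches %||% 1L
    if (mm > 0 && spec$n_copies > 1) {
      units[2] <- with_subseed(seed, 42L, {
        v <- strsplit(unit, "")[[1]]
        at <- sample(seq_along(v), mm)
        for (a in at) v[a] <- sample(setdiff(c("A", "C", "G", "T"), v[a]), 1)
        paste(v, collapse = "")
      })
    }
    spacers <- spec$spacer_lens %||%
      with_subseed(seed, 43L, sample(6:7, spec$n_copies - 1, replace = TRUE))
  }
  spacer_seqs <- with_subseed(seed, 44L,
    vapply(spacers, random_dna, character(1)))
  arr <- units[1]
  for (i in seq_along(spacer_seqs)) arr <- paste0(arr, spacer_seqs[i], units[i + 1])
  gaps <- intergenic_positions(rec, margin = 12)
  g <- gaps[[with_subseed(seed, 45L, sample(length(gaps), 1))]]
  pos0 <- as.integer(with_subseed(seed, 46L, sample(g[1]:g[2], 1)))
  ins <- insert_into_record(rec, truth, pos0, arr,
                            empty_cds(), tsd_len = 0)
  truth <- ins$truth
  offs <- cumsum(c(0L, nchar(units[-length(units)]) + spacers))
  truth$iterons <- list(positions = pos0 + offs,
                        unit_len = nchar(units[1]),
                        n_copies = length(units),
                        spacer_lens = as.integer(spacers),
                        units = units)
  list(record = ins$record, truth = truth)
}

#' Validate ground truth against its emitted record
#'
#' Re-checks every ground-truth assertion directly on the sequence: gene
#' coordinates translate to the recorded proteins; planted operon runs obey
#' the gap rule; iteron copies sit at their positions within the allowed
#' mismatch; element IRs, TSDs and nesting are present as recorded. Stops
#' on the first violation.
#'
#' @param rec a [plasmid_record()].
#' @param truth its ground-truth list.
#' @return TRUE, invisibly.
#' @export
validate_ground_truth <- function(rec, truth) {
  g <- truth$genes
  idx <- match(g$locus_tag, rec$cds$locus_tag)
  if (anyNA(idx)) stop("truth gene missing from record")
  if (!all(rec$cds$start[idx] == g$start & rec$cds$end[idx] == g$end))
    stop("truth gene coordinates disagree with record")
  for (i in seq_len(nrow(g))) {
    aa <- suppressWarnings(translate_cds(cds_nt(rec, idx[i])))
    if (aa != g$protein[i]) stop("translation mismatch at ", g$locus_tag[i])
  }
  if (!is.null(truth$operons)) {
    cds <- rec$cds
    for (run in truth$operons) {
      pos <- match(run, cds$locus_tag)
      if (length(unique(cds$strand[pos])) != 1) stop("operon strand mix")
      if (length(pos) > 1) {
        gaps <- cds$start[pos[-1]] - cds$end[pos[-length(pos)]]
        if (any(gaps >= 20)) stop("planted within-run gap >= 20")
      }
    }
  }
  if (!is.null(truth$iterons)) {
    it <- truth$iterons
    for (k in seq_along(it$positions)) {
      u <- substr(rec$sequence, it$positions[k] + 1,
                  it$positions[k] + it$unit_len)
      if (u != it$units[k]) stop("iteron copy not at recorded position")
    }
  }
  if (!is.null(truth$elements) && nrow(truth$elements)) {
    for (i in seq_len(nrow(truth$elements))) {
      e <- truth$elements[i, ]
      if (e$irs %in% c("both", "left_only")) {
        left <- substr(rec$sequence, e$start + 1, e$start + e$ir_len)
        if (left != e$ir_seq) stop("left IR not at recorded element start")
      }
      if (e$irs %in% c("both", "right_only")) {
        right <- substr(rec$sequence, e$end - e$ir_len + 1, e$end)
        if (hamming(revcomp(right), e$ir_seq) > e$ir_mismatches)
          stop("right IR arm exceeds recorded mismatches")
      }
      if (!is.na(e$tsd)) {
        t0 <- find_tsd(rec$sequence, list(left_start = e$start, right_end = e$end),
                       tsd_len_range = c(nchar(e$tsd), nchar(e$tsd)))
        if (is.null(t0) || t0 != e$tsd) stop("recorded TSD not present")
      }
      if (!is.na(e$parent)) {
        p <- truth$elements[truth$elements$element == e$parent, ]
        if (!(p$start < e$start && e$end < p$end))
          stop("nested element not contained in parent")
      }
    }
  }
  invisible(TRUE)
}

#' Write simulation ground truth as JSON
#' @param truth ground-truth list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
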