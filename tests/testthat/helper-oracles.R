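# Independent oracles and fixture builders used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_aa <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                    n, TRUE), collapse = "")
rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(x)))

blosum62_x0 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  mat <- env$BLOSUM62
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
})

# Plain-R affine-gap Smith-Waterman (Gotoh), written independently of the
# package's alignment path; a gap of length L costs open + L * ext.
gotoh_local_score <- function(a, b, mat = blosum62_x0, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
    F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
    H[i, j] <- max(0, H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]], E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

self_score <- function(p, mat = blosum62_x0) {
  v <- strsplit(p, "")[[1]]
  sum(mat[cbind(v, v)])
}

# Brute-force inverted-repeat enumeration: every palindrome center, every
# match-bounded window with <= k mismatches, containment-filtered. Compare
# against find_ir_pairs(..., merge_overlaps = FALSE) with a non-binding
# max_len.
ir_bruteforce <- function(seq, min_len, max_mismatch) {
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "?")
  rows <- list()
  for (C in 3:(2 * n - 1)) {
    xs <- max(1, C - n):((C - 1) %/% 2)
    if (length(xs) < 2) next
    M <- v[xs] == comp[v[C - xs]]
    idx <- which(M)
    if (length(idx) < 2) next
    cum <- cumsum(!M)
    qual <- list()
    for (si in seq_along(idx)) for (ei in si:length(idx)) {
      s <- idx[si]; e <- idx[ei]
      mism <- cum[e] - cum[s] + as.integer(!M[s])
      if (mism <= max_mismatch) qual[[length(qual) + 1]] <- c(s, e, mism)
    }
    if (!length(qual)) next
    q <- do.call(rbind, qual)
    contained <- vapply(seq_len(nrow(q)), function(i) {
      any(q[, 1] <= q[i, 1] & q[, 2] >= q[i, 2] &
            (q[, 1] < q[i, 1] | q[, 2] > q[i, 2]))
    }, logical(1))
    q <- q[!contained, , drop = FALSE]
    for (r in seq_len(nrow(q))) {
      s <- xs[q[r, 1]]; e <- xs[q[r, 2]]
      if (e - s + 1 < min_len) next
      rows[[length(rows) + 1]] <- data.frame(
        left_start = s - 1L, left_end = e,
        right_start = C - e - 1L, right_end = C - s,
        ir_len = e - s + 1L, mismatches = q[r, 3])
    }
  }
  if (!length(rows)) {
    return(data.frame(left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      ir_len = integer(), mismatches = integer()))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$left_start, out$right_start, out$ir_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Longest strictly monotone (increasing or decreasing) subsequence length by
# exhaustive subset enumeration; n <= 15.
lms_bruteforce <- function(x) {
  n <- length(x)
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    sel <- x[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(sel) <= best) next
    if (all(diff(sel) > 0) || all(diff(sel) < 0)) best <- length(sel)
  }
  best
}

# Plant an IR pair with guard bases: the base pairs immediately inside and
# outside both arms are forced to non-complementary so maximal extension
# stops exactly at the planted arms.
plant_ir_fixture <- function(flank1, arm_len, insert_len, flank2,
                             mismatches = 0) {
  left <- rand_dna(arm_len)
  right <- rc(left)
  if (mismatches > 0) {
    v <- strsplit(right, "")[[1]]
    at <- sample(2:(arm_len - 1), mismatches)
    for (a in at) v[a] <- setdiff(c("A", "C", "G", "T"), v[a])[1]
    right <- paste(v, collapse = "")
  }
  # A opposite A never complements: three consecutive blocked pairs on each
  # side defeat extension for any mismatch budget <= 2
  pre <- rand_dna(flank1); mid <- rand_dna(insert_len); post <- rand_dna(flank2)
  substr(pre, flank1 - 2, flank1) <- "AAA"; substr(post, 1, 3) <- "AAA"
  substr(mid, 1, 3) <- "AAA"; substr(mid, insert_len - 2, insert_len) <- "AAA"
  seq <- paste0(pre, left, mid, right, post)
  list(seq = seq, left_start = flank1, left_end = flank1 + arm_len,
       right_start = flank1 + arm_len + insert_len,
       right_end = flank1 + arm_len + insert_len + arm_len,
       mismatches = mismatches)
}

# Rotate a circular record's origin by `off` bases (coordinates shift left).
rotate_record <- function(rec, off) {
  len <- rec$length_bp
  seq2 <- paste0(substr(rec$sequence, off + 1, len), substr(rec$sequence, 1, off))
  cds <- rec$cds
  cds$start <- (cds$start - off) %% len
  span <- rec$cds$end - rec$cds$start
  cds$end <- cds$start + span
  cds$wraps_origin <- cds$end > len
  plasmid_record(paste0(rec$id, "_rot", off), seq2, cds, rec$topology,
                 rec$metadata)
}

shipped_descriptors <- function() {
  read_element_descriptors(system.file("extdata", "elements",
                                       "synthetic_tn_descriptors.yaml",
                                       package = "plasmidcomp"))
}
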