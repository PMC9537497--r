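# Local alignment engine and best-hit scoring.

test_that("local alignment matches hand-computed BLOSUM62 scores", {
  al <- align_local("MKT", "MKT")
  expect_equal(al$raw_score, 15)  # M+K+T diagonal = 5+5+5
  expect_equal(al$identity_pct, 100)
  expect_equal(al$coverage_pct, 100)
  expect_error(align_local("", "MKT"), "empty")
})

test_that("self-alignment is perfect and X is score-neutral", {
  set.seed(1)
  for (k in 1:10) {
    s <- rand_aa(sample(20:80, 1))
    al <- align_local(s, s)
    expect_equal(al$identity_pct, 100)
    expect_equal(al$coverage_pct, 100)
    expect_equal(al$raw_score, self_score(s))
  }
  # X against anything contributes 0
  expect_equal(align_local("MKTX", "MKTW")$raw_score,
               align_local("MKT", "MKT")$raw_score)
})

test_that("alignment scores equal an independent Gotoh DP oracle", {
  set.seed(2)
  ab <- c("A", "R", "N", "D")
  for (k in 1:60) {
    a <- paste(sample(ab, sample(1:8, 1), TRUE), collapse = "")
    b <- paste(sample(ab, sample(1:8, 1), TRUE), collapse = "")
    expect_equal(align_local(a, b)$raw_score, gotoh_local_score(a, b),
                 info = paste(a, b))
  }
  for (k in 1:15) {  # longer, full alphabet
    a <- rand_aa(25); b <- rand_aa(25)
    expect_equal(align_local(a, b)$raw_score, gotoh_local_score(a, b))
  }
})

test_that("scores are bounded by the smaller self-score (diagonal dominance)", {
  set.seed(3)
  for (k in 1:25) {
    a <- rand_aa(sample(10:60, 1)); b <- rand_aa(sample(10:60, 1))
    expect_lte(align_local(a, b)$raw_score,
               min(self_score(a), self_score(b)))
  }
})

test_that("mutating a target protein never raises its score against the query", {
  set.seed(4)
  viol <- 0; trials <- 120
  q <- rand_aa(60)
  base <- align_local(q, q)$raw_score
  for (k in seq_len(trials)) {
    v <- strsplit(q, "")[[1]]
    at <- sample(60, sample(1:10, 1))
    for (i in at) v[i] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                         v[i]), 1)
    if (align_local(q, paste(v, collapse = ""))$raw_score > base)
      viol <- viol + 1
  }
  expect_lte(viol / trials, 0.01)
})

test_that("best hits recover planted partners and respect thresholds", {
  set.seed(5)
  prots <- setNames(vapply(1:10, function(i) rand_aa(80), ""),
                    sprintf("Q_%02d", 1:10))
  query <- make_protein_record("query", prots)

  # exact copy: every locus hits its twin at 100% identity
  copy <- make_protein_record("copy", prots)
  h <- best_hits(query, copy)
  expect_equal(nrow(h), 10)
  expect_true(all(h$identity_pct == 100))

  # diverged copies of 6 of 10 at ~80% identity -> exactly those 6 hit
  mut <- function(p, nmut) {
    v <- strsplit(p, "")[[1]]
    at <- sample(length(v), nmut)
    for (i in at) v[i] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                         v[i]), 1)
    paste(v, collapse = "")
  }
  tprots <- c(setNames(vapply(prots[1:6], function(p) mut(p, 16), ""),
                       sprintf("T_%02d", 1:6)),
              setNames(vapply(1:4, function(i) rand_aa(80), ""),
                       sprintf("T_%02d", 7:10)))
  target <- make_protein_record("target", tprots)
  h2 <- best_hits(query, target)
  expect_equal(sort(h2$query_locus), sprintf("Q_%02d", 1:6))
  expect_equal(h2$target_locus[order(h2$query_locus)], sprintf("T_%02d", 1:6))

  # zero shared 4-mers: empty hit list
  poly <- make_protein_record("poly", c(P1 = strrep("W", 60)))
  expect_equal(nrow(best_hits(query, poly)), 0)
})

test_that("the k-mer prefilter never changes the result", {
  set.seed(6)
  for (k in 1:50) {
    np <- sample(3:5, 1)
    qp <- setNames(vapply(seq_len(np), function(i) rand_aa(120), ""),
                   sprintf("q%d", seq_len(np)))
    tp <- setNames(c(vapply(qp[seq_len(np - 1)], function(p) {
      v <- strsplit(p, "")[[1]]
      at <- sample(120, 20)
      for (i in at) v[i] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                           v[i]), 1)
      paste(v, collapse = "")
    }, ""), rand_aa(120)), sprintf("t%d", seq_len(np)))
    q <- make_protein_record("q", qp)
    t <- make_protein_record("t", tp)
    with_f <- best_hits(q, t, alignment_params(use_prefilter = TRUE))
    without <- best_hits(q, t, alignment_params(use_prefilter = FALSE))
    expect_equal(with_f, without)
  }
})

test_that("plasmid raw score sums best hits; half a proteome scores half", {
  set.seed(7)
  p <- setNames(replicate(6, rand_aa(70)), sprintf("G_%d", 1:6))
  q <- make_protein_record("q", p)
  expect_equal(plasmid_raw_score(q, q), sum(vapply(p, self_score, 0)))
  half <- make_protein_record("h", p[1:3])
  expect_equal(plasmid_raw_score(q, half), sum(vapply(p[1:3], self_score, 0)))
  unrelated <- make_protein_record("u", setNames(replicate(4, rand_aa(70)),
                                                 sprintf("U_%d", 1:4)))
  expect_equal(plasmid_raw_score(q, unrelated), 0)
})
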