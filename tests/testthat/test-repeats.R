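# Direct repeats (iterons), inverted-repeat pairs, TSDs, element calls.

iteron_units <- c("TCGTGCTATCAGGAGTA", "TCGTGCTATCGGGAGTA", "TCGTGCTATCAGGAGTA")

test_that("the three-copy iteron array is recovered with its spacers", {
  set.seed(21)
  seq <- paste0(rand_dna(60), iteron_units[1], rand_dna(7), iteron_units[2],
                rand_dna(6), iteron_units[3], rand_dna(60))
  arr <- find_direct_repeats(seq)
  expect_equal(length(arr), 1)
  expect_equal(arr[[1]]$unit_len, 17)
  expect_equal(arr[[1]]$n_copies, 3)
  expect_equal(arr[[1]]$spacer_lens, c(7, 6))
  expect_equal(arr[[1]]$max_mismatch_to_first, 1)
  expect_equal(arr[[1]]$units, iteron_units)
})

test_that("random sequence contains no qualifying long-unit array", {
  set.seed(22)
  expect_equal(length(find_direct_repeats(rand_dna(1000))), 0)
})

test_that("reported arrays are maximal (brute-force extension fails)", {
  set.seed(23)
  unit <- rand_dna(16)
  seq <- paste0(rand_dna(80), unit, rand_dna(4), unit, rand_dna(9), unit,
                rand_dna(80))
  arr <- find_direct_repeats(seq, unit_len_range = c(15, 20), max_spacer = 10)
  expect_equal(length(arr), 1)
  a <- arr[[1]]
  expect_equal(a$n_copies, 3)
  L <- a$unit_len
  first <- a$units[1]
  v <- strsplit(seq, "")[[1]]
  ham <- function(i, j) sum(v[i:(i + L - 1)] != v[j:(j + L - 1)])
  # no qualifying copy right of the last copy or left of the first
  last_end <- a$positions[a$n_copies] + 1 + L
  for (s in 0:10) {
    j <- last_end + s
    if (j + L - 1 <= nchar(seq))
      expect_gt(ham(a$positions[1] + 1, j), 1)
    j0 <- a$positions[1] + 1 - L - s
    if (j0 >= 1) expect_gt(ham(j0, a$positions[1] + 1), 1)
  }
})

test_that("planted IR pairs are recovered at exact coordinates", {
  set.seed(24)
  # 25 bp arms, 0 mismatches, flanking a 5 kb insert
  f <- plant_ir_fixture(300, 25, 5000, 300, mismatches = 0)
  got <- find_ir_pairs(f$seq, min_len = 20, max_len = 48, max_mismatch = 2)
  expect_equal(nrow(got), 1)
  expect_equal(got$left_start, f$left_start)
  expect_equal(got$left_end, f$left_end)
  expect_equal(got$right_start, f$right_start)
  expect_equal(got$right_end, f$right_end)
  expect_equal(got$mismatches, 0)

  # 39 bp arms with one internal mismatch
  f2 <- plant_ir_fixture(200, 39, 2000, 200, mismatches = 1)
  got2 <- find_ir_pairs(f2$seq, min_len = 20, max_len = 48, max_mismatch = 2)
  expect_equal(nrow(got2), 1)
  expect_equal(got2$ir_len, 39)
  expect_equal(got2$mismatches, 1)
  expect_equal(got2$left_start, f2$left_start)
  expect_equal(got2$right_end, f2$right_end)
})

test_that("every reported IR pair satisfies its own invariant", {
  set.seed(25)
  f <- plant_ir_fixture(150, 30, 800, 150, mismatches = 2)
  got <- find_ir_pairs(f$seq, min_len = 20, max_mismatch = 2)
  for (i in seq_len(nrow(got))) {
    expect_lte(got$left_end[i], got$right_start[i])
    # recheck independently of the search path
    d <- sum(strsplit(rc(got$right_seq[i]), "")[[1]] !=
               strsplit(got$left_seq[i], "")[[1]])
    expect_equal(d, got$mismatches[i])
  }
})

test_that("low-complexity runs are masked out of the IR search", {
  set.seed(26)
  seq <- paste0(rand_dna(100), strrep("A", 60), rand_dna(500),
                strrep("T", 60), rand_dna(100))
  got <- find_ir_pairs(seq, min_len = 20, max_mismatch = 2)
  # the poly-A / poly-T pair would be a perfect 60 bp IR without masking
  expect_false(any(grepl("AAAAAAAAAA", got$left_seq)))
  pure <- paste0(rand_dna(30), strrep("A", 120), rand_dna(30))
  expect_equal(nrow(find_ir_pairs(pure, min_len = 20)), 0)
})

test_that("IR search agrees exactly with a brute-force oracle", {
  for (seed in c(31, 32)) {
    set.seed(seed)
    seq <- rand_dna(120)
    for (k in c(1, 2)) {
      got <- find_ir_pairs(seq, min_len = 6, max_len = 160, max_mismatch = k,
                           merge_overlaps = FALSE)
      ref <- ir_bruteforce(seq, min_len = 6, max_mismatch = k)
      got <- got[order(got$left_start, got$right_start, got$ir_len),
                 c("left_start", "left_end", "right_start", "right_end",
                   "ir_len", "mismatches")]
      rownames(got) <- NULL
      expect_equal(got, ref, info = paste("seed", seed, "k", k))
    }
  }
})

test_that("target-site duplications resolve longest-first", {
  set.seed(27)
  core <- plant_ir_fixture(100, 20, 400, 100, mismatches = 0)
  seq <- core$seq
  # plant a 5 bp TSD, making sure length 6 does not match by accident
  substr(seq, core$left_start - 4, core$left_start) <- "GATCC"
  substr(seq, core$right_end + 1, core$right_end + 5) <- "GATCC"
  substr(seq, core$left_start - 5, core$left_start - 5) <- "C"
  substr(seq, core$right_end + 6, core$right_end + 6) <- "G"
  expect_equal(find_tsd(seq, core), "GATCC")

  # no duplication at any length
  seq2 <- core$seq
  substr(seq2, core$left_start - 5, core$left_start) <- "AAAAAA"
  substr(seq2, core$right_end + 1, core$right_end + 6) <- "CCCCCC"
  expect_null(find_tsd(seq2, core))

  # duplication present at length 5 and (coincidentally) at 4:
  # the longest length wins
  seq3 <- core$seq
  substr(seq3, core$left_start - 5, core$left_start) <- "CAAAAA"
  substr(seq3, core$right_end + 1, core$right_end + 6) <- "AAAAAG"
  expect_equal(find_tsd(seq3, core, tsd_len_range = c(4, 6)), "AAAAA")
})

test_that("planted elements are delineated with exact spans and TSDs", {
  desc <- shipped_descriptors()
  cfg <- sim_config(seed = 11, n_genes = 12,
                    elements = list(list(family = "Tn5053-like",
                                         ir_mismatches = 1, tsd_len = 5)))
  sim <- generate_query(cfg, descriptors = desc)
  calls <- delineate_elements(sim$record, desc)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, sim$truth$elements$start)
  expect_equal(calls$end, sim$truth$elements$end)
  expect_equal(calls$ir_mismatches, 1L)
  expect_equal(calls$truncated_side, "none")
  expect_true(is.na(calls$parent))
  expect_equal(substr(calls$tsd, 1, 5), sim$truth$elements$tsd)
  # cargo excludes the element's transposase machinery
  expect_equal(sort(strsplit(calls$cargo, ";")[[1]]),
               sort(strsplit(sim$truth$elements$cargo, ";")[[1]]))
})

test_that("nested insertion and truncation mirror the composite geometry", {
  desc <- shipped_descriptors()
  cfg <- sim_config(seed = 13, n_genes = 12, elements = list(
    list(family = "Tn4656-like", truncated = "right"),
    list(family = "Tn5053-like", nested = TRUE, tsd_len = 5)))
  sim <- generate_query(cfg, descriptors = desc)
  calls <- delineate_elements(sim$record, desc)
  expect_equal(nrow(calls), 2)
  parent <- calls[calls$family_label == "Tn4656-like", ]
  child <- calls[calls$family_label == "Tn5053-like", ]
  expect_equal(parent$truncated_side, "right")
  expect_true(is.na(parent$parent))
  expect_equal(child$truncated_side, "none")
  expect_equal(child$parent, parent$element_id)
  tr <- sim$truth$elements
  expect_equal(sort(calls$start), sort(tr$start))
  expect_equal(sort(calls$end), sort(tr$end))
})

test_that("descriptors must carry an IR and at least one protein", {
  desc <- shipped_descriptors()
  broken <- desc[[1]]
  broken$ir <- NULL
  sim <- generate_query(sim_config(seed = 3, n_genes = 4))
  expect_error(delineate_elements(sim$record, list(broken)), "IR")
})
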