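# GenBank / FASTA / primer I/O, CDS translation, in-silico PCR.

test_that("bacterial translation handles stops and ambiguity", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("ATGNNTTAA"), "MX")
  # incomplete tail codon trimmed
  expect_equal(translate_cds("ATGAAATAAGG"), "MK")
  expect_warning(translate_cds("ATGTAAAAATAA"),
                 class = "plasmidcomp_internal_stop")
  expect_error(translate_cds(""), "empty")
})

test_that("GenBank round-trip preserves coordinates, strands and proteins", {
  set.seed(101)
  sim <- generate_query(sim_config(seed = 101, n_genes = 8))
  rec <- sim$record
  expect_equal(nrow(rec$cds), 8)
  expect_false(is.unsorted(rec$cds$start))
  # add an origin-wrapping minus-strand feature and a pseudo gene
  cds <- rec$cds
  cds <- rbind(cds, data.frame(
    locus_tag = "WRAP_1", start = rec$length_bp - 90, end = rec$length_bp + 60,
    strand = "-", product = "wrap test", protein = "MAAA", pseudo = FALSE,
    wraps_origin = TRUE))
  cds$pseudo[2] <- TRUE; cds$protein[2] <- ""
  rec2 <- plasmid_record(rec$id, rec$sequence, cds, "circular", rec$metadata)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec2, path)
  back <- read_genbank(path)
  expect_equal(back$topology, "circular")
  expect_equal(back$length_bp, rec2$length_bp)
  for (col in c("locus_tag", "start", "end", "strand", "pseudo", "wraps_origin"))
    expect_equal(back$cds[[col]], rec2$cds[[col]], info = col)
  # non-pseudo proteins identical; the pseudo gene stays protein-less
  expect_equal(back$cds$protein[!back$cds$pseudo],
               rec2$cds$protein[!rec2$cds$pseudo])
  expect_equal(back$sequence, rec2$sequence)
})

test_that("reverse-strand CDS translate from the reverse complement", {
  sim <- generate_query(sim_config(seed = 57, n_genes = 6))
  rec <- sim$record
  minus <- which(rec$cds$strand == "-")
  expect_gte(length(minus), 1)
  for (i in minus) {
    span <- substr(rec$sequence, rec$cds$start[i] + 1, rec$cds$end[i])
    expect_equal(suppressWarnings(translate_cds(rc(span))),
                 rec$cds$protein[i])
  }
})

test_that("a CDS lacking /translation is translated; internal stops mark pseudo", {
  sim <- generate_query(sim_config(seed = 77, n_genes = 3))
  rec <- sim$record
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  lines <- readLines(path)
  # strip every /translation qualifier (they wrap over multiple lines)
  drop <- grepl("/translation=", lines)
  k <- which(drop)
  for (i in k) {
    j <- i
    while (!grepl("\"$", lines[j])) { j <- j + 1; drop[j] <- TRUE }
  }
  writeLines(lines[!drop], path)
  back <- read_genbank(path)
  expect_equal(back$cds$protein, rec$cds$protein)

  # corrupt one gene with an in-frame internal stop
  rec3 <- rec
  i <- 1
  s <- rec3$cds$start[i]
  nt <- substr(rec3$sequence, s + 1, rec3$cds$end[i])
  if (rec3$cds$strand[i] == "-") nt <- rc(nt)
  substr(nt, 4, 6) <- "TAA"
  if (rec3$cds$strand[i] == "-") nt <- rc(nt)
  substr(rec3$sequence, s + 1, rec3$cds$end[i]) <- nt
  rec3$cds$protein[i] <- ""
  rec3$cds$pseudo[i] <- TRUE   # placeholder so the record validates
  write_genbank(rec3, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("/pseudo", lines)], path)
  back3 <- read_genbank(path)
  expect_true(back3$cds$pseudo[1])
  expect_equal(back3$cds$protein[1], "")
})

test_that("unparseable or sequence-less files raise format errors", {
  p <- withr::local_tempfile(fileext = ".gb")
  writeLines("this is not genbank", p)
  expect_error(read_genbank(p), "LOCUS")
  writeLines(c("LOCUS       x 10 bp DNA linear", "FEATURES", "//"), p)
  expect_error(read_genbank(p), "ORIGIN|sequence")
})

test_that("coordinates and translations agree with Biopython", {
  sim <- generate_query(sim_config(seed = 2024, n_genes = 6))
  gb <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$record, gb)
  py <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "from Bio import SeqIO",
    "rec = SeqIO.read(sys.argv[1], 'genbank')",
    "for f in rec.features:",
    "    if f.type != 'CDS': continue",
    "    aa = str(f.extract(rec.seq).translate(table=11)).rstrip('*')",
    "    tag = f.qualifiers['locus_tag'][0]",
    "    strand = '+' if f.location.strand == 1 else '-'",
    "    print(f'{tag}\\t{int(f.location.start)}\\t{int(f.location.end)}\\t{strand}\\t{aa}')"
  ), py)
  out <- system2("python", c(py, gb), stdout = TRUE)
  ref <- read.delim(text = out, header = FALSE,
                    col.names = c("locus_tag", "start", "end", "strand", "aa"))
  expect_equal(ref$locus_tag, sim$record$cds$locus_tag)
  expect_equal(ref$start, sim$record$cds$start)
  expect_equal(ref$end, sim$record$cds$end)
  expect_equal(ref$strand, sim$record$cds$strand)
  expect_equal(ref$aa, sim$record$cds$protein)
})

test_that("in-silico PCR follows the 5'-to-5' length convention", {
  set.seed(8)
  fw <- rand_dna(20); rv <- rand_dna(20)
  base <- rand_dna(5000)
  s <- paste0(substr(base, 1, 1000), fw, substr(base, 1021, 3480),
              rc(rv), substr(base, 3501, 5000))
  rec <- plasmid_record("pcr1", s, topology = "circular")
  prod <- in_silico_pcr(rec, list(seq_fw = fw, seq_rv = rv))
  expect_equal(nrow(prod), 1)
  expect_equal(prod$start, 1000)
  expect_equal(prod$length_bp, 2500)  # fw 5' at 1000, rv 5' at 3499

  # absent primers: empty, not an error
  none <- in_silico_pcr(plasmid_record("r", rand_dna(5000)),
                        list(seq_fw = rand_dna(20), seq_rv = rand_dna(20)))
  expect_equal(nrow(none), 0)
})

test_that("PCR product lengths are invariant under circular rotation", {
  set.seed(9)
  fw <- rand_dna(20); rv <- rand_dna(20)
  base <- rand_dna(6000)
  s <- paste0(substr(base, 1, 2000), fw, substr(base, 2021, 4980),
              rc(rv), substr(base, 5001, 6000))
  rec <- plasmid_record("pcr2", s, topology = "circular")
  ref <- in_silico_pcr(rec, list(seq_fw = fw, seq_rv = rv))$length_bp
  for (off in c(500, 2500, 4100, 5900)) {
    rot <- plasmid_record("rot", paste0(substr(s, off + 1, 6000),
                                        substr(s, 1, off)),
                          topology = "circular")
    got <- in_silico_pcr(rot, list(seq_fw = fw, seq_rv = rv))$length_bp
    expect_equal(sort(got), sort(ref), info = paste("offset", off))
  }
})

test_that("the 3' clamp rejects mismatches in the last three bases", {
  set.seed(10)
  fw <- rand_dna(20); rv <- rand_dna(20)
  s <- paste0(rand_dna(500), fw, rand_dna(800), rc(rv), rand_dna(500))
  rec <- plasmid_record("pcr3", s)
  bad <- fw
  substr(bad, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(fw, 20, 20))[1]
  expect_equal(nrow(in_silico_pcr(rec, list(seq_fw = bad, seq_rv = rv))), 0)
  # the same single mismatch away from the clamp is tolerated
  ok <- fw
  substr(ok, 5, 5) <- setdiff(c("A", "C", "G", "T"), substr(fw, 5, 5))[1]
  expect_equal(nrow(in_silico_pcr(rec, list(seq_fw = ok, seq_rv = rv))), 1)
})

test_that("primer tables validate their schema", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name_fw\tseq_fw\tname_rv\tseq_rv",
               "a_fw\tACTTCGACCAATGCCCCATT\ta_rv\tGGACACCCTCATCCTTAGCG"), p)
  tb <- read_primer_table(p)
  expect_equal(nrow(tb), 1)
  writeLines(c("name_fw\tseq_fw\tname_rv\tseq_rv",
               "a_fw\tACGT\ta_rv\tGGACACCCTCATCCTTAGCG"), p)
  expect_error(read_primer_table(p), "15")
})
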