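A5 <- "ATCGTAGGCACCTGAAA"
A3 <- "ACTGTAGGCACCATCAAT"

test_that("454 adapter excision returns the insert between both linkers", {
  ins <- "ACGTACGTACGTACGTACGTACGT"
  tr <- trim_454_adapters(paste0(A5, ins, A3))
  expect_true(is.na(tr$reason))
  expect_equal(tr$insert, ins)
  expect_equal(nchar(tr$insert), 24L)
})

test_that("adapter matches tolerate up to 3 missing terminal bases", {
  # insert chosen so no truncated adapter variant can borrow its bases:
  # it neither starts with the 5' adapter's next base nor ends with a
  # prefix of the 3' adapter
  ins <- "CGGTCGGTCGGTCGGTCGGT"
  # 5' adapter truncated by 3 (missing AAA at its 3' end): accepted
  tr3 <- trim_454_adapters(paste0(substr(A5, 1, 14), ins, A3))
  expect_true(is.na(tr3$reason))
  expect_equal(tr3$insert, ins)
  # truncated by 4: rejected
  tr4 <- trim_454_adapters(paste0(substr(A5, 1, 13), ins, A3))
  expect_equal(tr4$reason, "no-5-adapter")
  # same boundary at the 3' adapter (missing from its 3' end)
  tr3b <- trim_454_adapters(paste0(A5, ins, substr(A3, 1, 15)))
  expect_true(is.na(tr3b$reason))
  tr4b <- trim_454_adapters(paste0(A5, ins, substr(A3, 1, 14)))
  expect_equal(tr4b$reason, "no-3-adapter")
  # leading truncation of the 5' adapter (its 5' terminal bases)
  tr5 <- trim_454_adapters(paste0(substr(A5, 4, 17), ins, A3))
  expect_true(is.na(tr5$reason))
})

test_that("adapter-only reads are rejected as empty inserts", {
  tr <- trim_454_adapters(paste0(A5, A3))
  expect_equal(tr$reason, "empty-insert")
})

test_that("alignment-trimming recovers the exact insert length", {
  sim <- small_sim_cache()
  bundle <- sim$gen$bundle
  chrom <- names(bundle$seq)[1]
  g <- as.character(bundle$seq[[chrom]])
  # a read whose first 22 nt are genomic and whose tail is adapter;
  # pick a start whose genomic continuation differs from the adapter's
  # first base, so trimming cannot extend past the true junction
  p <- 5001L
  while (substr(g, p + 22L, p + 22L) == substr(A3, 1, 1)) p <- p + 1L
  ins <- substr(g, p, p + 21L)
  read <- substr(paste0(ins, A3, A3), 1, 35)
  at <- align_trim_solid(read, bundle)
  expect_true(is.na(at$reason))
  expect_equal(at$insert, ins)
  expect_equal(at$start, p)
  expect_equal(at$end, p + 21L)
  expect_equal(at$strand, "+")
  expect_equal(at$mismatches, 0L)
})

test_that("minus-strand inserts are located and trimmed", {
  sim <- small_sim_cache()
  bundle <- sim$gen$bundle
  chrom <- names(bundle$seq)[2]
  g <- as.character(bundle$seq[[chrom]])
  # in read orientation the genomic continuation is the complement of
  # the base just before the locus; require it to differ from the
  # adapter's first base so the junction is unambiguous
  q <- 7001L
  while (substr(g, q - 1L, q - 1L) ==
    chartr("ACGT", "TGCA", substr(A3, 1, 1))) q <- q + 1L
  ins <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(g, q, q + 23L))
  ))
  read <- substr(paste0(ins, A3, A3), 1, 35)
  at <- align_trim_solid(read, bundle)
  expect_true(is.na(at$reason))
  expect_equal(at$chrom, chrom)
  expect_equal(at$start, q)
  expect_equal(at$end, q + 23L)
  expect_equal(at$strand, "-")
})

test_that("a full-length read with one mismatch is rescued", {
  sim <- small_sim_cache()
  bundle <- sim$gen$bundle
  chrom <- names(bundle$seq)[1]
  g <- as.character(bundle$seq[[chrom]])
  read <- substr(g, 9001, 9035)
  mid <- substr(read, 18, 18)
  substr(read, 18, 18) <- c(A = "C", C = "A", G = "T", T = "G")[[mid]]
  at <- align_trim_solid(read, bundle)
  expect_true(is.na(at$reason))
  expect_equal(at$mismatches, 1L)
  expect_equal(nchar(at$insert), 35L)
  expect_equal(at$start, 9001L)
})

test_that("reads with no genomic origin are rejected", {
  sim <- small_sim_cache()
  set.seed(99)
  at <- align_trim_solid(rand_dna_str(35), sim$gen$bundle)
  expect_equal(at$reason, "no-genome-match")
})

test_that("clustering respects the 0.8 length-similarity boundary", {
  s20 <- "ACGTACGTACGTACGTACGT"
  p16 <- substr(s20, 1, 16) # 16/20 = 0.8: co-clusters
  p15 <- substr(s20, 1, 15) # 15/20 = 0.75: separate
  t1 <- cluster_unique(c(s20, p16), c("A", "A"))
  expect_equal(nrow(t1$tags), 1L)
  expect_equal(t1$tags$sequence, s20)
  expect_equal(unname(t1$counts[1, "A"]), 2L)
  t2 <- cluster_unique(c(s20, p15), c("A", "A"))
  expect_equal(nrow(t2$tags), 2L)
  # n identical sequences collapse to one tag with count n
  t3 <- cluster_unique(rep(s20, 5), rep(c("A", "B"), c(3, 2)))
  expect_equal(nrow(t3$tags), 1L)
  expect_equal(unname(t3$counts[1, ]), c(3L, 2L))
})

test_that("clustering equals the brute-force pairwise check", {
  set.seed(11)
  pool <- vapply(1:60, function(i) rand_dna_str(sample(18:30, 1)),
    character(1))
  # engineered boundary pairs: exact prefixes at and below 0.8
  pool <- c(
    pool, substr(pool[1], 1, ceiling(nchar(pool[1]) * 0.8)),
    substr(pool[2], 1, floor(nchar(pool[2]) * 0.75))
  )
  inserts <- sample(pool, 300, replace = TRUE)
  libs <- sample(c("A", "B"), 300, replace = TRUE)
  got <- cluster_unique(inserts, libs, lib_levels = c("A", "B"))
  want <- oracle_cluster(inserts, libs)
  expect_setequal(got$tags$sequence, names(want))
  for (i in seq_len(nrow(got$tags))) {
    s <- got$tags$sequence[i]
    expect_equal(got$counts[i, c("A", "B")], want[[s]][c("A", "B")],
      info = s
    )
  }
})

test_that("degradation filtering removes rRNA fragments, keeps miRNA hits", {
  ref <- Biostrings::DNAStringSet(c(
    "rr1 class=rRNA" = rand_dna_str(300),
    "tt1 class=tRNA" = rand_dna_str(80),
    "mm1 class=miRNA" = "ACGGATTTCAGGCACCTGGACTA"
  ))
  set.seed(21)
  frag <- substr(as.character(ref[[1]]), 41, 70) # exact 30-nt rRNA piece
  # 20 nt of rRNA followed by the complement of the next 10 reference
  # bases: every extension position mismatches, so the local alignment
  # cannot reach past 20/30 coverage
  part <- paste0(
    substr(as.character(ref[[1]]), 101, 120),
    chartr("ACGT", "TGCA", substr(as.character(ref[[1]]), 121, 130))
  )
  mirna_tag <- "ACGGATTTCAGGCACCTGGAC"
  clean <- rand_dna_str(25)
  tags <- cluster_unique(
    c(frag, part, mirna_tag, clean),
    rep("A", 4)
  )
  fd <- filter_degradation(tags, ref)
  expect_true(frag %in% fd$removed$tags$sequence) # 100% coverage
  expect_true(part %in% fd$kept$tags$sequence) # 20/30 = 66.7% < 70%
  expect_true(mirna_tag %in% fd$kept$tags$sequence) # best hit is miRNA
  expect_true(clean %in% fd$kept$tags$sequence)
  # kept and removed partition the input
  expect_setequal(
    c(fd$kept$tags$sequence, fd$removed$tags$sequence),
    tags$tags$sequence
  )
  expect_length(
    intersect(fd$kept$tags$sequence, fd$removed$tags$sequence), 0L
  )
})

test_that("genome mapping records all occurrences at <= 1 mismatch", {
  set.seed(31)
  unit <- rand_dna_str(400)
  tag1 <- substr(unit, 101, 122)
  tag2 <- rand_dna_str(22)
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0(rand_dna_str(200), unit, rand_dna_str(100), unit,
      rand_dna_str(50)),
    chr2 = paste0(rand_dna_str(120), unit, rand_dna_str(80))
  ))
  bundle <- structure(list(
    seq = genome, genes = list(),
    repeats = GenomicRanges::GRanges(), ncrna = GenomicRanges::GRanges()
  ), class = "GenomeBundle")
  tags <- cluster_unique(c(tag1, tag2), c("A", "A"))
  mp <- map_to_genome(tags, bundle)
  # tag inside a 3-copy unit aligns three times
  expect_equal(sum(mp$mapped$alignments$sequence == tag1), 3L)
  expect_true(tag2 %in% mp$unmapped$tags$sequence)
  # a two-mismatch variant is dropped
  tag3 <- tag1
  substr(tag3, 3, 3) <- c(A = "C", C = "A", G = "T", T = "G")[[substr(tag3, 3, 3)]]
  substr(tag3, 12, 12) <- c(A = "C", C = "A", G = "T", T = "G")[[substr(tag3, 12, 12)]]
  mp3 <- map_to_genome(cluster_unique(tag3, "A"), bundle)
  expect_equal(nrow(mp3$mapped$tags), 0L)
  # one mismatch is kept and flagged
  tag4 <- tag1
  substr(tag4, 12, 12) <- c(A = "C", C = "A", G = "T", T = "G")[[substr(tag4, 12, 12)]]
  mp4 <- map_to_genome(cluster_unique(tag4, "A"), bundle)
  expect_equal(nrow(mp4$mapped$tags), 1L)
  expect_true(all(mp4$mapped$alignments$mismatches == 1L))
})

test_that("tag statistics recover a known composition", {
  counts <- matrix(c(1L, 1L, 0L, 1L, 0L, 1L),
    nrow = 3,
    dimnames = list(NULL, c("A", "B"))
  )
  tags <- tag_set(
    c("TGCAGCAGCAGCAGCAGCAGC", "GCAGCAGCAGCAGCAGCAGCAGC",
      "ACAGCAGCAGCAGCAGCAGCA"),
    counts
  )
  st <- tag_stats(tags)
  a_len <- st$length[st$length$library == "A", ]
  expect_equal(sum(a_len$count), 2L)
  a_nt <- st$first_nt[st$first_nt$library == "A", ]
  expect_equal(sum(a_nt$freq), 1, tolerance = 1e-9)
  expect_equal(a_nt$freq[a_nt$nt == "U"], 0.5) # T reported as U
  expect_equal(a_nt$freq[a_nt$nt == "G"], 0.5)
  b_nt <- st$first_nt[st$first_nt$library == "B", ]
  expect_equal(sum(b_nt$freq), 1, tolerance = 1e-9)
  # single 21-nt tag starting T: length table {21: 1}, 5' table {U: 1}
  one <- tag_set("TGCAGCAGCAGCAGCAGCAGC",
    matrix(1L, 1, 1, dimnames = list(NULL, "A")))
  st1 <- tag_stats(one)
  expect_equal(st1$length$length, 21L)
  expect_equal(st1$length$count, 1L)
  expect_equal(st1$first_nt$freq[st1$first_nt$nt == "U"], 1)
})

test_that("zero-error preprocessing keeps exactly the genome-derived reads", {
  sim <- small_sim_cache()
  d <- write_sim_data(sim$gen$bundle, sim$gen$truth, sim$reads,
    withr::local_tempdir())
  pp <- preprocess_reads(sim$gen$bundle,
    reads_454 = sim$reads$reads_454, solid = sim$reads$solid,
    ncrna_ref = d[["ncrna_ref"]]
  )
  # all simulated reads originate from the genome: none rejected
  expect_equal(sum(pp$log$rejected), 0L)
  expect_equal(pp$log$reads_in, pp$log$kept + pp$log$rejected)
  # no tag is both kept and removed as degradation
  expect_length(
    intersect(pp$tags$tags$sequence, pp$removed$tags$sequence), 0L
  )
})
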