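make_sirna_fixture <- function() {
  set.seed(77)
  genome <- Biostrings::DNAStringSet(c(chr1 = rand_dna_str(6000)))
  repeats <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1001, 2001, 3001), width = 400),
    strand = "+"
  )
  repeats$family <- c("Copia", "Gypsy", "Harbinger")
  repeats$class <- repeat_class_label(repeats$family)
  genes <- list(
    gA = list(
      gene_id = "gA", transcript_id = "mA", chrom = "chr1", strand = "+",
      exons = IRanges::IRanges(4001, 4600), cds = IRanges::IRanges(4051, 4520),
      utr5 = IRanges::IRanges(4001, 4050), utr3 = IRanges::IRanges(4521, 4600),
      has_utr = TRUE
    )
  )
  bundle <- structure(
    list(seq = genome, genes = genes, repeats = repeats,
      ncrna = GenomicRanges::GRanges()),
    class = "GenomeBundle"
  )
  g <- as.character(genome[[1]])
  seqs <- c(
    inside = substr(g, 1100, 1121), # fully inside Copia
    edge = substr(g, 981, 1001), # overlaps Copia by exactly 1 nt
    outside = substr(g, 531, 551), # intergenic
    sense = substr(g, 4101, 4121), # within gA, plus strand
    anti = substr(g, 4201, 4221) # within gA, will align minus
  )
  aln <- data.frame(
    sequence = unname(seqs),
    chrom = "chr1",
    start = c(1100L, 981L, 531L, 4101L, 4201L),
    end = c(1121L, 1001L, 551L, 4121L, 4221L),
    strand = c("+", "+", "+", "+", "-"),
    mismatches = 0L, stringsAsFactors = FALSE
  )
  counts <- matrix(1L, 5, 2, dimnames = list(NULL, c("A", "B")))
  counts[3, "B"] <- 0L
  list(
    bundle = bundle,
    tags = tag_set(unname(seqs), counts, aln), seqs = seqs
  )
}

test_that("repeat overlap of >= 1 nt defines a rasiRNA", {
  fx <- make_sirna_fixture()
  ras <- call_rasirna(fx$tags, fx$bundle$repeats)
  expect_setequal(
    ras$calls$sequence,
    unname(fx$seqs[c("inside", "edge")])
  )
  expect_equal(
    ras$calls$families[ras$calls$sequence == fx$seqs[["inside"]]],
    "LTR/Copia"
  )
  # zero-overlap when requiring 2 nt of the 1-nt-edge tag
  ras2 <- call_rasirna(fx$tags, fx$bundle$repeats, min_overlap = 2L)
  expect_setequal(ras2$calls$sequence, unname(fx$seqs["inside"]))
})

test_that("family percentages sum to 100 and follow the counts", {
  set.seed(88)
  reps <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 101, 201, 301), width = 50)
  )
  reps$family <- c("Copia", "Copia", "Gypsy", "Harbinger")
  reps$class <- repeat_class_label(reps$family)
  seqs <- vapply(1:4, function(i) rand_dna_str(21), character(1))
  aln <- data.frame(
    sequence = seqs, chrom = "chr1",
    start = c(10L, 110L, 210L, 310L), end = c(30L, 130L, 230L, 330L),
    strand = "+", mismatches = 0L, stringsAsFactors = FALSE
  )
  tags <- tag_set(seqs, matrix(1L, 4, 1, dimnames = list(NULL, "A")), aln)
  ras <- call_rasirna(tags, reps)
  ft <- ras$family_table
  expect_equal(sum(ft$percentage), 100)
  expect_equal(ft$percentage[ft$class == "LTR/Copia"], 50)
  expect_equal(ft$percentage[ft$class == "LTR/Gypsy"], 25)
  expect_equal(ft$percentage[ft$class == "DNA/Harbinger"], 25)
})

test_that("cross-library matching is reflexive and E-value driven", {
  set.seed(99)
  a <- vapply(1:6, function(i) rand_dna_str(25), character(1))
  self <- cross_library_match(a, a)
  expect_equal(self$fraction, 1.0)
  # disjoint random sets share no long words: no matches
  b <- vapply(1:6, function(i) rand_dna_str(25), character(1))
  stopifnot(!any(a %in% b))
  ab <- cross_library_match(a, b)
  expect_equal(ab$fraction, 0)
  # one shared sequence matches exactly that element
  mixed <- cross_library_match(c(a[1], b[1]), b)
  expect_equal(mixed$matched, c(FALSE, TRUE))
  expect_warning(cross_library_match(a, character(0)), "empty")
})

test_that("E-values agree with the brute-force alignment oracle", {
  set.seed(111)
  a <- vapply(1:4, function(i) rand_dna_str(22), character(1))
  b <- vapply(1:4, function(i) rand_dna_str(24), character(1))
  b[2] <- paste0(substr(a[3], 4, 20), rand_dna_str(5)) # shared 17-mer
  res <- cross_library_match(a, b, evalue_max = 1e-5)
  n_db <- sum(nchar(b))
  for (i in seq_along(a)) {
    best <- max(vapply(b, function(x) oracle_ungapped_score(a[i], x), 1))
    ev <- 0.621 * nchar(a[i]) * n_db * exp(-1.33 * best)
    expect_equal(res$matched[i], ev <= 1e-5, info = i)
  }
  expect_true(res$matched[3])
})

test_that("orientation classes follow strand overlap with gene spans", {
  fx <- make_sirna_fixture()
  non_ras <- srnapipe:::.subset_tags(
    fx$tags, !fx$tags$tags$sequence %in%
      call_rasirna(fx$tags, fx$bundle$repeats)$calls$sequence
  )
  nat <- classify_nat_sirna(non_ras, fx$bundle)
  lab <- setNames(nat$class, nat$sequence)
  expect_equal(unname(lab[fx$seqs[["sense"]]]), "nat-sense")
  expect_equal(unname(lab[fx$seqs[["anti"]]]), "nat-antisense")
  expect_equal(unname(lab[fx$seqs[["outside"]]]), "intergenic")
})

test_that("a tag with genic and intergenic alignments is mixed", {
  fx <- make_sirna_fixture()
  s <- fx$seqs[["sense"]]
  aln <- rbind(
    fx$tags$alignments[fx$tags$alignments$sequence == s, ],
    data.frame(
      sequence = s, chrom = "chr1", start = 200L, end = 220L,
      strand = "+", mismatches = 1L, stringsAsFactors = FALSE
    )
  )
  tags <- tag_set(s, matrix(1L, 1, 1, dimnames = list(NULL, "A")), aln)
  nat <- classify_nat_sirna(tags, fx$bundle)
  expect_equal(nat$class, "mixed")
})

test_that("every mapped tag receives exactly one class summing to 100%", {
  sim <- small_sim_cache()
  d <- write_sim_data(sim$gen$bundle, sim$gen$truth, sim$reads,
    withr::local_tempdir())
  pp <- preprocess_reads(sim$gen$bundle,
    reads_454 = sim$reads$reads_454, solid = sim$reads$solid,
    ncrna_ref = d[["ncrna_ref"]]
  )
  calls <- predict_mirnas(pp$tags, sim$gen$bundle)
  dist <- sirna_distribution(pp$tags, sim$gen$bundle,
    mirna_sequences = c(
      calls$sequence, calls$star_sequence[!is.na(calls$star_sequence)]
    )
  )
  expect_false(anyNA(dist$classes$class))
  expect_equal(nrow(dist$classes), nrow(pp$tags$tags))
  for (L in unique(dist$summary_tags$library)) {
    expect_equal(
      sum(dist$summary_tags$percentage[dist$summary_tags$library == L]),
      100,
      tolerance = 1e-9
    )
  }
  # planted truth recovered: all antisense loci classified nat-antisense
  truth <- sim$gen$truth$loci
  nat_truth <- truth[truth$type == "natsirna", ]
  cls <- setNames(dist$classes$class, dist$classes$sequence)
  aln <- pp$tags$alignments
  for (i in seq_len(nrow(nat_truth))) {
    hit <- aln$chrom == nat_truth$chrom[i] &
      aln$strand == nat_truth$strand[i] &
      aln$start <= nat_truth$end[i] & aln$end >= nat_truth$start[i]
    expect_true(any(cls[aln$sequence[hit]] == "nat-antisense"),
      info = nat_truth$locus_id[i]
    )
  }
})
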