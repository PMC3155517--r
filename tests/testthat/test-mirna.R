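# A clean constructed precursor: GC-only stem, A-only loop and pads,
# so the minimum-energy structure is the designed hairpin (no A:U or
# G:U partner exists anywhere in the sequence).
make_precursor <- function(mature = NULL, loop_len = 12L,
                           bulge_at = integer(0), pad = 15L) {
  if (is.null(mature)) {
    mature <- "GCGGCGGCGCGGCGGCGCGGC"
  }
  star <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mature)
  ))
  for (b in bulge_at) substr(star, b, b) <- "A"
  prec <- paste0(
    strrep("A", pad), mature, strrep("A", loop_len), star, strrep("A", pad)
  )
  list(
    precursor = prec, mature_start = pad + 1L,
    mature_len = nchar(mature), star = star
  )
}

test_that("a designed hairpin passes and its measures are exact", {
  fx <- make_precursor()
  a <- assess_precursor(fx$precursor, fx$mature_start, fx$mature_len)
  expect_true(a$pass)
  expect_equal(a$loop_len, 12L)
  expect_equal(a$max_bulge, 0L)
  expect_true(a$one_arm)
  expect_equal(a$mfe, 21 * -3 + 4)
  # star interval: the pairing partners with a 2-nt 3' extension
  expect_equal(a$star_start, fx$mature_start + 21L + 12L)
  expect_equal(a$star_end, fx$mature_start + 21L + 12L + 20L + 2L)
})

test_that("loop length 9 versus 10 flips the verdict", {
  ok <- assess_precursor(
    make_precursor(loop_len = 10L)$precursor, 16L, 21L
  )
  bad <- assess_precursor(
    make_precursor(loop_len = 9L)$precursor, 16L, 21L
  )
  expect_true(ok$pass)
  expect_equal(ok$loop_len, 10L)
  expect_false(bad$pass)
  expect_equal(bad$loop_len, 9L)
  expect_true("loop<min" %in% bad$reasons)
})

test_that("bulge 3 versus 4 flips the verdict", {
  # consecutive star-side defects produce an unpaired run of that size
  ok <- assess_precursor(
    make_precursor(bulge_at = 9:11)$precursor, 16L, 21L
  )
  bad <- assess_precursor(
    make_precursor(bulge_at = 8:11)$precursor, 16L, 21L
  )
  expect_true(ok$pass)
  expect_equal(ok$max_bulge, 3L)
  expect_false(bad$pass)
  expect_equal(bad$max_bulge, 4L)
  expect_true("bulge>max" %in% bad$reasons)
})

test_that("the MFE threshold is strict at -20 kcal/mol", {
  v_in <- hairpin_verdict(-20.1, 12L, 1L, TRUE)
  v_out <- hairpin_verdict(-19.9, 12L, 1L, TRUE)
  v_at <- hairpin_verdict(-20, 12L, 1L, TRUE)
  expect_true(v_in$pass)
  expect_false(v_out$pass)
  expect_false(v_at$pass) # "less than -20": equality fails
  expect_true("mfe>=threshold" %in% v_out$reasons)
  # a weak stem above the threshold fails end to end: 5 GC pairs
  weak <- paste0(
    strrep("A", 10), "GCGCGCGCGCGCGCGCGCGCG", strrep("A", 12),
    "CGCAAAAAAAAAAAAAAAAGC", strrep("A", 10)
  )
  a <- assess_precursor(weak, 11L, 21L)
  expect_false(a$pass && a$mfe < -20)
})

test_that("a mature spanning the loop is rejected", {
  # place the 'mature' across the loop centre of a symmetric hairpin
  fx <- make_precursor()
  a <- assess_precursor(fx$precursor, 16L + 15L, 21L)
  expect_false(a$one_arm)
  expect_false(a$pass)
  expect_true("mature-not-on-one-arm" %in% a$reasons)
})

test_that("evaluate_hairpin works on both genomic strands", {
  fx <- make_precursor()
  plus_seq <- paste0(strrep("A", 200), fx$precursor, strrep("A", 200))
  minus_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(plus_seq)
  ))
  n <- nchar(plus_seq)
  mat_s <- 200L + fx$mature_start
  mat_e <- mat_s + fx$mature_len - 1L
  bundle_p <- structure(list(
    seq = Biostrings::DNAStringSet(c(chr1 = plus_seq)),
    genes = list(), repeats = GenomicRanges::GRanges(),
    ncrna = GenomicRanges::GRanges()
  ), class = "GenomeBundle")
  bundle_m <- structure(list(
    seq = Biostrings::DNAStringSet(c(chr1 = minus_seq)),
    genes = list(), repeats = GenomicRanges::GRanges(),
    ncrna = GenomicRanges::GRanges()
  ), class = "GenomeBundle")
  hp <- evaluate_hairpin(
    data.frame(chrom = "chr1", start = mat_s, end = mat_e, strand = "+"),
    bundle_p
  )
  hm <- evaluate_hairpin(
    data.frame(
      chrom = "chr1", start = n - mat_e + 1L, end = n - mat_s + 1L,
      strand = "-"
    ),
    bundle_m
  )
  expect_true(hp$pass)
  expect_true(hm$pass)
  expect_equal(hm$mfe, hp$mfe)
  expect_equal(hm$loop_len, hp$loop_len)
  # star intervals mirror each other
  expect_equal(hm$star_gend, n - hp$star_gstart + 1L)
  expect_equal(hm$star_gstart, n - hp$star_gend + 1L)
})

test_that("the expression-evidence rule follows its truth table", {
  # all 8 presence patterns over 3 libraries, with and without a star
  for (a in c(FALSE, TRUE)) {
    for (b in c(FALSE, TRUE)) {
      for (c3 in c(FALSE, TRUE)) {
        pres <- c(a, b, c3)
        expect_equal(
          mirna_evidence(pres, star_in_any = FALSE), sum(pres) >= 2,
          info = paste(pres, collapse = "/")
        )
        expect_true(mirna_evidence(pres, star_in_any = TRUE))
      }
    }
  }
})

test_that("relaxing thresholds can only grow the call set", {
  sim <- small_sim_cache()
  d <- write_sim_data(sim$gen$bundle, sim$gen$truth, sim$reads,
    withr::local_tempdir())
  pp <- preprocess_reads(sim$gen$bundle,
    reads_454 = sim$reads$reads_454, solid = sim$reads$solid,
    ncrna_ref = d[["ncrna_ref"]]
  )
  grid <- list(
    strict = mirna_thresholds(mfe_max = -30, loop_min = 12L, bulge_max = 1L),
    default = mirna_thresholds(),
    loose = mirna_thresholds(mfe_max = -10, loop_min = 8L, bulge_max = 5L)
  )
  calls <- lapply(grid, function(th) {
    cl <- predict_mirnas(pp$tags, sim$gen$bundle, thresholds = th)
    union(cl$sequence, cl$star_sequence[!is.na(cl$star_sequence)])
  })
  expect_true(all(calls$strict %in% calls$default))
  expect_true(all(calls$default %in% calls$loose))
})

test_that("repeat-overlapping tags are never called miRNA", {
  sim <- small_sim_cache()
  d <- write_sim_data(sim$gen$bundle, sim$gen$truth, sim$reads,
    withr::local_tempdir())
  pp <- preprocess_reads(sim$gen$bundle,
    reads_454 = sim$reads$reads_454, solid = sim$reads$solid,
    ncrna_ref = d[["ncrna_ref"]]
  )
  calls <- predict_mirnas(pp$tags, sim$gen$bundle)
  aln <- pp$tags$alignments
  gr <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start, aln$end)
  )
  in_rep <- unique(aln$sequence[IRanges::overlapsAny(
    gr, sim$gen$bundle$repeats,
    ignore.strand = TRUE
  )])
  expect_length(intersect(calls$sequence, in_rep), 0L)
})

test_that("known-miRNA seed matching allows at most one mismatch", {
  calls <- data.frame(
    sequence = "TGAGGTAGTAGGTTGTATAGT", stringsAsFactors = FALSE
  )
  exact <- c(k1 = paste0(substr(calls$sequence, 1, 10), "CCCCCCCCCCC"))
  hit <- match_known_mirnas(calls, exact)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$mismatches, 0L)
  one <- exact
  substr(one, 5, 5) <- "C" # G -> C inside the 10-nt seed
  h1 <- match_known_mirnas(calls, c(k2 = unname(one)))
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mismatches, 1L)
  two <- one
  substr(two, 8, 8) <- "A"
  h2 <- match_known_mirnas(calls, c(k3 = unname(two)))
  expect_equal(nrow(h2), 0L)
  expect_equal(nrow(match_known_mirnas(calls, character(0))), 0L)
})
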