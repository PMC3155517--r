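test_that("animal seed sites are exact 6-mer matches to nt 2-7", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"
  # seed nt 2-7 = GAGGUA; its reverse complement in DNA is TACCTC
  tx <- paste0("AAAAAA", "TACCTC", "AAAAAA")
  hits <- scan_animal_sites(mir, tx)
  expect_equal(hits$tx_start, 7L)
  expect_equal(hits$tx_end, 12L)
  # a transcript lacking the 6-mer yields nothing
  expect_equal(nrow(scan_animal_sites(mir, "GGGGGGGGGGGG")), 0L)
  # tandem duplication doubles the hits
  h2 <- scan_animal_sites(mir, paste0(tx, tx))
  expect_equal(nrow(h2), 2L)
  expect_equal(h2$tx_start, c(7L, 25L))
  # shorter than 6 nt: empty
  expect_equal(nrow(scan_animal_sites(mir, "ACGU")), 0L)
})

test_that("plant sites follow the defect budgets and energy cutoff", {
  # perfect 21-nt complement, 13 GC + 8 AU pairs: E = -55
  mir <- "GGCGGCGGCGGCGAUAUAUAU"
  stopifnot(sum(strsplit(mir, "")[[1]] %in% c("G", "C")) == 13)
  site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", mir))
  ))
  tx <- paste0("CCAACC", site, "CCAACC")
  hits <- scan_plant_sites(mir, tx)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$tx_start, 7L)
  expect_equal(hits$energy, 13 * -3 + 8 * -2)
  expect_equal(hits$mismatches_seed + hits$mismatches_rest, 0L)
  # two mismatches inside the 8-nt seed region: rejected
  site2 <- site
  # miRNA positions 2 and 5 pair with site positions 20 and 17
  for (p in c(20L, 17L)) {
    substr(site2, p, p) <-
      c(A = "C", C = "A", G = "T", T = "G")[[substr(site2, p, p)]]
  }
  expect_equal(nrow(scan_plant_sites(mir, paste0("CC", site2, "CC"))), 0L)
  # an all-AU 18-mer complement: E = 18 * (-2) = -36, still a hit
  mir_au <- paste(rep(c("A", "U"), 9), collapse = "")
  site_au <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", mir_au))
  ))
  h_au <- scan_plant_sites(mir_au, paste0("CCCC", site_au, "CCCC"),
    resolve_overlaps = FALSE
  )
  expect_true(any(h_au$energy == -36))
  # below 18 nt the scan refuses to run
  expect_error(scan_plant_sites("ACGUACGUACGU", "ACGT"), "18")
})

test_that("plant and animal scans equal the exhaustive checker", {
  set.seed(404)
  for (i in 1:12) {
    mir <- rand_dna_str(sample(19:23, 1), c("A", "C", "G", "U"))
    tx <- rand_dna_str(300)
    # plant a near-complement at a random position to have signal
    site <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(chartr("U", "T", mir))
    ))
    pos <- sample(50:200, 1)
    substr(tx, pos, pos + nchar(site) - 1L) <- site
    an <- scan_animal_sites(mir, tx)
    expect_equal(an$tx_start, oracle_animal_sites(mir, tx), info = i)
    pl <- scan_plant_sites(mir, tx, resolve_overlaps = FALSE)
    or <- oracle_plant_sites(mir, tx)
    expect_equal(nrow(pl), length(or), info = i)
    if (length(or)) {
      om <- do.call(rbind, or)
      expect_equal(pl$tx_start, unname(om[, "start"]), info = i)
      expect_equal(pl$energy, unname(om[, "energy"]), info = i)
      expect_equal(pl$mismatches_seed, unname(om[, "seed"]), info = i)
      expect_equal(pl$mismatches_rest, unname(om[, "rest"]), info = i)
    }
  }
})

test_that("site coordinates shift with a prepended transcript prefix", {
  set.seed(505)
  mir <- rand_dna_str(21, c("A", "C", "G", "U"))
  site <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", mir))
  ))
  tx <- paste0(rand_dna_str(40), site, rand_dna_str(40))
  k <- 17L
  tx2 <- paste0(rand_dna_str(k), tx)
  h1 <- scan_plant_sites(mir, tx, resolve_overlaps = FALSE)
  h2 <- scan_plant_sites(mir, tx2, resolve_overlaps = FALSE)
  expect_equal(h2$tx_start, h1$tx_start + k)
  a1 <- scan_animal_sites(mir, tx)
  a2 <- scan_animal_sites(mir, tx2)
  expect_equal(a2$tx_start, a1$tx_start + k)
})

test_that("regions are assigned by site midpoint against the CDS", {
  expect_equal(assign_region(5L, 25L, 51L, 500L), "five-utr")
  expect_equal(assign_region(100L, 120L, 51L, 500L), "cds")
  expect_equal(assign_region(495L, 515L, 51L, 500L), "three-utr")
  expect_equal(assign_region(100L, 120L, NA_integer_, NA_integer_), "unknown")
  # midpoint rule at the boundary: site straddling the start codon
  expect_equal(assign_region(45L, 57L, 51L, 500L), "cds")
  expect_equal(assign_region(40L, 56L, 51L, 500L), "five-utr")
})

test_that("GO ratios rank functional bias", {
  go_map <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6", "g7", "g8", "g9", "g10"),
    term = c(rep("GO:0000001", 2), rep("GO:0000002", 8)),
    stringsAsFactors = FALSE
  )
  all_genes <- go_map$gene_id
  # term 1 covers 20% of genome; both targets hit it -> ratio 5
  ratios <- go_ratio(c("g1", "g2"), go_map, all_genes)
  expect_equal(ratios$ratio[ratios$term == "GO:0000001"], 5)
  # equal representation gives ratio 1
  r2 <- go_ratio(c("g1", "g3", "g4", "g5", "g6"), go_map, all_genes)
  expect_equal(
    r2$target_fraction[r2$term == "GO:0000002"] /
      r2$genome_fraction[r2$term == "GO:0000002"],
    r2$ratio[r2$term == "GO:0000002"]
  )
  expect_equal(r2$ratio, sort(r2$ratio, decreasing = TRUE))
  # unknown terms are excluded with a warning
  gm <- rbind(go_map, data.frame(gene_id = "gX", term = "GO:0000099"))
  expect_warning(
    go_ratio(c("g1", "gX"), gm, all_genes), "absent"
  )
  expect_equal(nrow(go_ratio(character(0), go_map, all_genes)), 0L)
})

test_that("planted target sites are found in transcript space", {
  sim <- small_sim_cache()
  ts <- sim$gen$truth$target_sites
  expect_gt(nrow(ts), 0L)
  tx <- transcript_sequences(sim$gen$bundle)
  mir <- sim$gen$truth$loci
  for (i in seq_len(nrow(ts))) {
    m <- mir$mature[mir$locus_id == ts$mirna_locus[i]]
    seq <- tx$sequence[tx$transcript_id == ts$transcript_id[i]]
    pl <- scan_plant_sites(m, seq)
    hit <- pl[pl$tx_start == ts$tx_start[i], ]
    expect_equal(nrow(hit), 1L, info = i)
    expect_lte(hit$energy, -20)
    an <- scan_animal_sites(m, seq)
    expect_true(any(
      an$tx_start >= ts$tx_start[i] & an$tx_end <= ts$tx_end[i]
    ), info = i)
    # the planted site sits in the CDS
    row <- tx[tx$transcript_id == ts$transcript_id[i], ]
    expect_equal(
      assign_region(ts$tx_start[i], ts$tx_end[i], row$cds_start, row$cds_end),
      "cds"
    )
  }
})
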