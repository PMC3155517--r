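# Synthetic genome + multi-library small-RNA read simulator with a
# planted-truth manifest. The generator defines the study conditions
# the pipeline is validated under: a compact genome carrying gene
# models with introns/UTRs, repeat families, rRNA/tRNA loci, designed
# miRNA hairpins expressing mature (and optionally star) reads,
# repeat-derived and antisense tags, plus ncRNA degradation background.

ADAPTER_5P <- "ATCGTAGGCACCTGAAA" # 5' linker ("Nelson")
ADAPTER_3P <- "ACTGTAGGCACCATCAAT" # 3' linker ("Modban")
SOLID_READ_COLORS <- 35L

#' Simulation configuration
#'
#' All randomness in the simulator flows from `seed`; the same
#' configuration always yields byte-identical outputs.
#'
#' @param seed integer seed for all simulator randomness.
#' @param n_chrom,chrom_length chromosome count and length (nt).
#' @param n_genes number of gene models.
#' @param intron_rate fraction of genes carrying an intron.
#' @param utr_rate fraction of genes with annotated UTRs (start/stop
#'   codon evidence); only these can receive transcript-region calls
#'   in target prediction.
#' @param n_repeat_loci number of repeat loci (families cycled).
#' @param repeat_families repeat family labels.
#' @param n_mirna_loci planted miRNA hairpin loci.
#' @param n_antisense_loci planted natural-antisense tag loci.
#' @param n_rrna,n_trna ncRNA loci (degradation sources).
#' @param n_target_sites planted miRNA binding sites in CDS regions.
#' @param mature_len,loop_len mature arm and hairpin loop length (nt).
#' @param depth_mirna,depth_rasirna,depth_antisense,depth_star mean
#'   read counts per expressing library per locus.
#' @param degradation_fraction fraction of each library made of ncRNA
#'   degradation fragments.
#' @param color_error_rate per-color i.i.d. error rate for SOLiD reads.
#' @param solid_truncate_frac fraction of SOLiD inserts truncated to
#'   18 nt before encoding (models the short-read-length artifact seen
#'   in real SOLiD small-RNA data; off by default, no mechanistic claim).
#' @param libraries library labels; the first is the 454-style library,
#'   the rest are SOLiD libraries.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 17L,
                       n_chrom = 4L, chrom_length = 30000L,
                       n_genes = 40L, intron_rate = 0.6, utr_rate = 0.6,
                       n_repeat_loci = 30L,
                       repeat_families = c("Copia", "Gypsy", "Harbinger", "MuDR"),
                       n_mirna_loci = 20L, n_antisense_loci = 20L,
                       n_rrna = 4L, n_trna = 4L,
                       n_target_sites = 10L,
                       mature_len = 21L, loop_len = 12L,
                       depth_mirna = 6, depth_rasirna = 4,
                       depth_antisense = 4, depth_star = 3,
                       degradation_fraction = 0.10,
                       color_error_rate = 0,
                       solid_truncate_frac = 0,
                       libraries = c("L454", "EF", "EC")) {
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_length = as.integer(chrom_length), n_genes = as.integer(n_genes),
    intron_rate = intron_rate, utr_rate = utr_rate,
    n_repeat_loci = as.integer(n_repeat_loci),
    repeat_families = repeat_families,
    n_mirna_loci = as.integer(n_mirna_loci),
    n_antisense_loci = as.integer(n_antisense_loci),
    n_rrna = as.integer(n_rrna), n_trna = as.integer(n_trna),
    n_target_sites = as.integer(n_target_sites),
    mature_len = as.integer(mature_len), loop_len = as.integer(loop_len),
    depth_mirna = depth_mirna, depth_rasirna = depth_rasirna,
    depth_antisense = depth_antisense, depth_star = depth_star,
    degradation_fraction = degradation_fraction,
    color_error_rate = color_error_rate,
    solid_truncate_frac = solid_truncate_frac,
    libraries = libraries,
    platforms = c("454", rep("solid", length(libraries) - 1L))
  )
  rates <- c(
    cfg$intron_rate, cfg$utr_rate, cfg$degradation_fraction,
    cfg$color_error_rate, cfg$solid_truncate_frac
  )
  if (any(rates < 0 | rates > 1)) {
    stop("sim_config: rates must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(cfg$depth_mirna, cfg$depth_rasirna, cfg$depth_antisense,
            cfg$depth_star) < 0)) {
    stop("sim_config: depths must be >= 0", call. = FALSE)
  }
  if (cfg$loop_len < 10L) {
    stop("sim_config: loop_len below the 10-nt hairpin filter", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

.rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Designed hairpin with a provably optimal stem under the package's
# additive pair-energy model. The arms use only G/C; the loop and the
# surrounding spacers use only A (plus a leading loop C so that the
# genomic continuation of the mature arm never begins like the 3'
# sequencing adapter). An excised precursor therefore contains no
# pairable letter outside the arms (no U at all, so neither A·U nor
# G·U pairs exist), and the designed antiparallel stem realises the
# maximum possible number of G:C pairs: the folding engine cannot do
# better than the planted structure. Two interior star G's are
# replaced by inert A's; these designed defects (a) leave the bound
# unchanged, (b) appear as 1-nt bulges, and (c) keep the mature from
# cross-mapping onto the star arm under a <=1-mismatch mapper.
.design_hairpin <- function(mature_len, loop_len, n_defects = 2L) {
  repeat {
    mature <- paste(
      sample(c("C", "G"), mature_len, replace = TRUE), collapse = ""
    )
    n_c <- lengths(regmatches(mature, gregexpr("C", mature)))
    # interior star G's (= interior mature C's) must exist for defects
    inner_c <- gregexpr("C", mature)[[1]]
    inner_c <- inner_c[inner_c >= 3L & inner_c <= mature_len - 2L]
    if (n_c >= 8L && n_c <= 13L && length(inner_c) >= n_defects) break
  }
  loop <- paste0("C", strrep("A", loop_len - 1L))
  star <- .revcomp(mature)
  if (n_defects > 0L) {
    g_pos <- which(strsplit(star, "", fixed = TRUE)[[1]] == "G")
    g_pos <- g_pos[g_pos >= 3L & g_pos <= nchar(star) - 2L]
    want <- round(seq(1L, nchar(star), length.out = n_defects + 2L))
    want <- want[-c(1L, n_defects + 2L)]
    at <- integer(0)
    for (w in want) {
      cand <- setdiff(g_pos, at)
      at <- c(at, cand[which.min(abs(cand - w))])
    }
    for (mid in at) substr(star, mid, mid) <- "A"
  }
  list(mature = mature, loop = loop, star = star,
       hairpin = paste0(mature, loop, star))
}

# sequential placement keeping a cursor per chromosome; round-robin
.place_loci <- function(lengths, n_chrom, chrom_length, min_gap = 100L,
                        max_gap = 300L, margin = 250L) {
  cursor <- rep(margin, n_chrom)
  chrom <- integer(length(lengths))
  start <- integer(length(lengths))
  ci <- 1L
  for (i in seq_along(lengths)) {
    placed <- FALSE
    for (trial in seq_len(n_chrom)) {
      cand <- ((ci - 1L + trial - 1L) %% n_chrom) + 1L
      gap <- sample(min_gap:max_gap, 1L)
      s <- cursor[cand] + gap
      if (s + lengths[i] - 1L <= chrom_length - margin) {
        chrom[i] <- cand
        start[i] <- s
        cursor[cand] <- s + lengths[i] - 1L
        ci <- cand + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("generate_genome: infeasible packing, loci exceed genome length",
        call. = FALSE
      )
    }
  }
  data.frame(chrom = chrom, start = start, end = start + lengths - 1L)
}

#' Generate a synthetic genome with planted small-RNA loci
#'
#' Builds random chromosomes, places gene models (with introns and,
#' for a subset, UTR annotation), repeat loci, rRNA/tRNA loci, and
#' miRNA hairpins designed so that folding the flank-extended precursor
#' passes the structural filters (strong stem, loop >= 10 nt, bulges
#' <= 1 nt, MFE far below -20 kcal/mol). Repeat-derived and antisense
#' tag loci are chosen inside repeats and antisense to exons. A subset
#' of CDS regions receives planted miRNA binding sites (complement of
#' a planted mature with two non-seed mismatches, so no extra genomic
#' alignment for the mature tag arises).
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (a `GenomeBundle`) and `truth` (list with
#'   `loci` data.frame manifest, `target_sites`, `known_mirnas`,
#'   `go_map`, `config`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  libs <- config$libraries
  n_solid <- sum(config$platforms == "solid")

  chrom_names <- paste0("chr", seq_len(config$n_chrom))
  seqs <- vapply(
    seq_len(config$n_chrom),
    function(i) .rand_dna(config$chrom_length), character(1)
  )
  names(seqs) <- chrom_names

  # ---- gene models ----
  gene_len_exon <- sample(300:600, config$n_genes, replace = TRUE)
  has_intron <- runif(config$n_genes) < config$intron_rate
  intron_len <- ifelse(has_intron, sample(80:180, config$n_genes,
    replace = TRUE
  ), 0L)
  gene_span <- 2L * gene_len_exon + intron_len
  ncrna_len <- c(
    sample(400:700, config$n_rrna, replace = TRUE),
    sample(70:90, config$n_trna, replace = TRUE)
  )
  rep_len <- sample(300:700, config$n_repeat_loci, replace = TRUE)
  # hairpins are embedded inside low-complexity A/C spacer flanks the
  # size of the precursor excision window, so the minimum-energy
  # structure of the excised precursor is the designed hairpin itself
  hp_flank <- 100L
  hp_core <- config$mature_len * 2L + config$loop_len
  hp_len <- hp_core + 2L * hp_flank

  all_len <- c(
    gene_span, rep_len, ncrna_len,
    rep(hp_len, config$n_mirna_loci)
  )
  pl <- .place_loci(all_len, config$n_chrom, config$chrom_length)
  pl$chrom_name <- chrom_names[pl$chrom]
  idx_gene <- seq_len(config$n_genes)
  idx_rep <- config$n_genes + seq_len(config$n_repeat_loci)
  idx_nc <- config$n_genes + config$n_repeat_loci + seq_along(ncrna_len)
  idx_hp <- config$n_genes + config$n_repeat_loci + length(ncrna_len) +
    seq_len(config$n_mirna_loci)

  gene_strand <- sample(c("+", "-"), config$n_genes,
    replace = TRUE, prob = c(0.6, 0.4)
  )
  has_utr <- runif(config$n_genes) < config$utr_rate
  genes <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    s <- pl$start[idx_gene[g]]
    e1 <- gene_len_exon[g]
    if (has_intron[g]) {
      exons <- IRanges::IRanges(
        c(s, s + e1 + intron_len[g]),
        width = c(e1, e1)
      )
    } else {
      exons <- IRanges::IRanges(s, width = 2L * e1)
    }
    tx_len <- sum(width(exons))
    if (has_utr[g]) {
      u5 <- 50L
      u3 <- 80L
    } else {
      u5 <- 0L
      u3 <- 0L
    }
    # transcript coordinates -> genomic, strand-aware
    tx2gen <- .transcript_to_genome_map(exons, gene_strand[g])
    cds_tx <- IRanges::IRanges(u5 + 1L, tx_len - u3)
    cds <- .project_tx_interval(cds_tx, tx2gen)
    utr5 <- if (u5 > 0L) .project_tx_interval(IRanges::IRanges(1L, u5), tx2gen) else IRanges::IRanges()
    utr3 <- if (u3 > 0L) {
      .project_tx_interval(IRanges::IRanges(tx_len - u3 + 1L, tx_len), tx2gen)
    } else {
      IRanges::IRanges()
    }
    genes[[g]] <- list(
      gene_id = sprintf("gene%02d", g),
      transcript_id = sprintf("mRNA%02d", g),
      chrom = pl$chrom_name[idx_gene[g]],
      strand = gene_strand[g],
      exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
      has_utr = has_utr[g]
    )
  }

  # ---- repeats ----
  fam <- rep(config$repeat_families,
    length.out = config$n_repeat_loci
  )
  repeats <- GenomicRanges::GRanges(
    pl$chrom_name[idx_rep],
    IRanges::IRanges(pl$start[idx_rep], pl$end[idx_rep]),
    strand = sample(c("+", "-"), config$n_repeat_loci, replace = TRUE)
  )
  repeats$family <- fam
  repeats$class <- repeat_class_label(fam)

  # ---- ncRNA ----
  nc_class <- c(rep("rRNA", config$n_rrna), rep("tRNA", config$n_trna))
  ncrna <- GenomicRanges::GRanges(
    pl$chrom_name[idx_nc],
    IRanges::IRanges(pl$start[idx_nc], pl$end[idx_nc]),
    strand = "+"
  )
  ncrna$class <- nc_class

  # ---- miRNA hairpins: embed designed sequence ----
  hp_strand <- sample(c("+", "-"), config$n_mirna_loci, replace = TRUE)
  # evidence patterns cycled over loci:
  #  1 all libraries; 2 both SOLiD; 3 454 + first SOLiD;
  #  4 first SOLiD only, rescued by a star read
  pattern <- rep(1:4, length.out = config$n_mirna_loci)
  loci <- list()
  for (m in seq_len(config$n_mirna_loci)) {
    hp <- .design_hairpin(config$mature_len, config$loop_len)
    i <- idx_hp[m]
    chrom <- pl$chrom_name[i]
    s <- pl$start[i]
    e <- pl$end[i]
    cassette <- paste0(
      strrep("A", hp_flank), hp$hairpin, strrep("A", hp_flank)
    )
    emb <- if (hp_strand[m] == "+") cassette else .revcomp(cassette)
    substr(seqs[chrom], s, e) <- emb
    hs <- s + hp_flank # hairpin core bounds on the genome
    he <- e - hp_flank
    if (hp_strand[m] == "+") {
      mat_iv <- c(hs, hs + config$mature_len - 1L)
      star_iv <- c(he - config$mature_len + 1L, he)
    } else {
      mat_iv <- c(he - config$mature_len + 1L, he)
      star_iv <- c(hs, hs + config$mature_len - 1L)
    }
    expressing <- switch(pattern[m],
      libs,
      libs[config$platforms == "solid"],
      libs[c(1L, 2L)],
      libs[2L]
    )
    counts <- setNames(integer(length(libs)), libs)
    counts[expressing] <- 2L + stats::rpois(length(expressing),
      max(config$depth_mirna - 2, 0))
    star_counts <- setNames(integer(length(libs)), libs)
    if (pattern[m] %in% c(1L, 4L)) {
      star_counts[libs[2L]] <- 1L + stats::rpois(1L, max(config$depth_star - 1, 0))
    }
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = sprintf("mir%02d", m), type = "mirna",
      chrom = chrom, start = mat_iv[1], end = mat_iv[2],
      strand = hp_strand[m],
      mature = hp$mature, star = hp$star,
      star_start = star_iv[1], star_end = star_iv[2],
      t(counts), t(setNames(star_counts, paste0("star_", libs))),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }

  # ---- planted target sites in CDS (2 mismatches outside the seed) ----
  # done before tag fragments are extracted so the genome is final from
  # here on; the mismatches guarantee no extra genomic alignment for
  # the mature tag arises from a planted site
  target_sites <- data.frame(
    mirna_locus = character(), transcript_id = character(),
    tx_start = integer(), tx_end = integer(), stringsAsFactors = FALSE
  )
  if (config$n_target_sites > 0L && config$n_mirna_loci > 0L) {
    plus_genes <- which(gene_strand == "+" & has_utr)
    # successive sites on the same gene are packed left to right with a
    # fixed gap so planted sites never overwrite one another
    site_cursor <- integer(length(genes))
    for (t in seq_len(config$n_target_sites)) {
      g <- plus_genes[(t - 1L) %% length(plus_genes) + 1L]
      gm <- genes[[g]]
      mir <- loci[[(t - 1L) %% config$n_mirna_loci + 1L]]
      site <- .revcomp(mir$mature) # DNA complement of the mature
      # two mismatches outside the 8-nt seed of the miRNA: the seed is
      # the miRNA 5' end, which pairs with the site's 3' end
      for (off in c(2L, 4L)) {
        cur <- substr(site, off, off)
        substr(site, off, off) <- c(A = "C", C = "A", G = "T", T = "G")[[cur]]
      }
      w <- nchar(site)
      cds_ex <- gm$cds[which.max(width(gm$cds))]
      s <- start(cds_ex) + 10L + site_cursor[g]
      if (s + w - 1L > end(cds_ex) - 10L) {
        stop("infeasible packing: too many target sites for the CDS space")
      }
      site_cursor[g] <- site_cursor[g] + w + 7L
      substr(seqs[gm$chrom], s, s + w - 1L) <- site
      tx_pos <- .genome_to_tx_pos(s, gm)
      target_sites <- rbind(target_sites, data.frame(
        mirna_locus = mir$locus_id, transcript_id = gm$transcript_id,
        tx_start = tx_pos, tx_end = tx_pos + w - 1L,
        stringsAsFactors = FALSE
      ))
    }
  }

  mk_counts <- function(expressing, depth) {
    counts <- setNames(integer(length(libs)), libs)
    counts[expressing] <- 1L + stats::rpois(length(expressing), max(depth - 1, 0))
    counts
  }

  # a tag locus is resampled while the genomic continuation past its
  # 3' end begins like the sequencing adapter: alignment-trimming of a
  # 35-cycle read would otherwise extend the recovered insert into the
  # adapter-matching genome bases, blurring the planted interval
  pick_frag_start <- function(chrom, lo, hi, w, strand) {
    repeat {
      s <- sample(seq(lo, hi), 1L)
      after <- if (strand == "+") {
        substr(seqs[chrom], s + w, s + w)
      } else {
        chartr("ACGT", "TGCA", substr(seqs[chrom], s - 1L, s - 1L))
      }
      if (after != "A") {
        return(s)
      }
    }
  }

  # ---- rasiRNA source tags inside repeats ----
  for (r in seq_len(config$n_repeat_loci)) {
    w <- sample(21:24, 1L)
    strand <- sample(c("+", "-"), 1L)
    chrom <- as.character(seqnames(repeats))[r]
    s <- pick_frag_start(
      chrom, start(repeats)[r], end(repeats)[r] - w + 1L, w, strand
    )
    frag <- substr(seqs[chrom], s, s + w - 1L)
    if (strand == "-") frag <- .revcomp(frag)
    counts <- mk_counts(libs, config$depth_rasirna)
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = sprintf("ras%02d", r), type = "rasirna",
      chrom = chrom, start = s, end = s + w - 1L, strand = strand,
      mature = frag, star = NA_character_,
      star_start = NA_integer_, star_end = NA_integer_,
      t(counts), t(setNames(rep(0L, length(libs)), paste0("star_", libs))),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }

  # ---- natural antisense tags over exons ----
  # a locus planted as nat-siRNA must genuinely be one: positions whose
  # excised precursor happens to satisfy the miRNA hairpin filters are
  # rejected and resampled, so the truth manifest stays truthful
  vet_bundle <- list(seq = Biostrings::DNAStringSet(seqs))
  cand_genes <- seq_len(config$n_genes)
  for (a in seq_len(config$n_antisense_loci)) {
    g <- cand_genes[(a - 1L) %% length(cand_genes) + 1L]
    gm <- genes[[g]]
    ex <- gm$exons[which.max(width(gm$exons))]
    w <- 21L
    strand <- if (gm$strand == "+") "-" else "+"
    repeat {
      s <- pick_frag_start(
        gm$chrom, start(ex) + 5L, end(ex) - w - 5L, w, strand
      )
      hc <- evaluate_hairpin(
        data.frame(
          chrom = gm$chrom, start = s, end = s + w - 1L,
          strand = strand, stringsAsFactors = FALSE
        ),
        vet_bundle
      )
      if (!hc$pass) break
    }
    frag <- substr(seqs[gm$chrom], s, s + w - 1L)
    if (strand == "-") frag <- .revcomp(frag)
    counts <- mk_counts(libs, config$depth_antisense)
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = sprintf("nat%02d", a), type = "natsirna",
      chrom = gm$chrom, start = s, end = s + w - 1L, strand = strand,
      mature = frag, star = NA_character_,
      star_start = NA_integer_, star_end = NA_integer_,
      t(counts), t(setNames(rep(0L, length(libs)), paste0("star_", libs))),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }

  # ---- degradation background: per ncRNA locus, planned counts ----
  signal_per_lib <- Reduce(`+`, lapply(loci, function(x) unlist(x[libs])))
  n_deg_lib <- round(config$degradation_fraction /
    max(1 - config$degradation_fraction, 1e-9) * signal_per_lib)
  n_nc <- length(ncrna)
  for (k in seq_len(n_nc)) {
    counts <- setNames(integer(length(libs)), libs)
    for (L in seq_along(libs)) {
      base <- n_deg_lib[L] %/% n_nc
      extra <- as.integer(k <= n_deg_lib[L] %% n_nc)
      counts[L] <- base + extra
    }
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = sprintf("deg%02d", k), type = "degradation",
      chrom = as.character(seqnames(ncrna))[k],
      start = start(ncrna)[k], end = end(ncrna)[k], strand = "+",
      mature = NA_character_, star = NA_character_,
      star_start = NA_integer_, star_end = NA_integer_,
      t(counts), t(setNames(rep(0L, length(libs)), paste0("star_", libs))),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  manifest <- do.call(rbind, loci)

  # ---- known miRNA reference (decoys + planted seed matches) ----
  mir_rows <- manifest[manifest$type == "mirna", , drop = FALSE]
  known <- character(0)
  if (nrow(mir_rows)) {
    planted <- vapply(seq_len(min(3L, nrow(mir_rows))), function(i) {
      paste0(substr(mir_rows$mature[i], 1L, 10L), .rand_dna(11L))
    }, character(1))
    names(planted) <- paste0("known-planted-", seq_along(planted))
    known <- planted
  }
  decoys <- vapply(seq_len(8L), function(i) .rand_dna(21L), character(1))
  names(decoys) <- paste0("known-decoy-", seq_len(8L))
  known <- c(known, decoys)

  # ---- GO map ----
  terms <- sprintf("GO:%07d", 1:8)
  go_map <- data.frame(
    gene_id = vapply(genes, `[[`, "", "transcript_id"),
    term = terms[((seq_len(config$n_genes) - 1L) %% 8L) + 1L],
    stringsAsFactors = FALSE
  )
  if (nrow(target_sites)) {
    go_map$term[match(
      unique(target_sites$transcript_id), go_map$gene_id
    )] <- terms[1L]
  }

  bundle <- structure(
    list(
      seq = Biostrings::DNAStringSet(seqs),
      genes = setNames(genes, vapply(genes, `[[`, "", "transcript_id")),
      repeats = repeats, ncrna = ncrna
    ),
    class = "GenomeBundle"
  )
  .validate_bundle(bundle)
  truth <- list(
    loci = manifest, target_sites = target_sites,
    known_mirnas = known, go_map = go_map, config = config
  )
  list(bundle = bundle, truth = truth)
}

# map transcript coordinate -> list of genomic blocks (strand aware)
.transcript_to_genome_map <- function(exons, strand) {
  ex <- if (strand == "+") exons else rev(exons)
  list(exons = ex, strand = strand)
}

.project_tx_interval <- function(tx_iv, map) {
  ex <- map$exons
  w <- width(ex)
  offs <- cumsum(c(0L, w[-length(w)]))
  out <- IRanges::IRanges()
  for (k in seq_along(ex)) {
    lo <- max(start(tx_iv), offs[k] + 1L)
    hi <- min(end(tx_iv), offs[k] + w[k])
    if (lo > hi) next
    if (map$strand == "+") {
      gs <- start(ex)[k] + (lo - offs[k] - 1L)
      ge <- start(ex)[k] + (hi - offs[k] - 1L)
    } else {
      ge <- end(ex)[k] - (lo - offs[k] - 1L)
      gs <- end(ex)[k] - (hi - offs[k] - 1L)
    }
    out <- c(out, IRanges::IRanges(gs, ge))
  }
  sort(out)
}

# genomic position -> transcript coordinate (plus-strand genes only)
.genome_to_tx_pos <- function(gpos, gm) {
  stopifnot(gm$strand == "+")
  w <- width(gm$exons)
  offs <- cumsum(c(0L, w[-length(w)]))
  for (k in seq_along(gm$exons)) {
    if (gpos >= start(gm$exons)[k] && gpos <= end(gm$exons)[k]) {
      return(offs[k] + (gpos - start(gm$exons)[k]) + 1L)
    }
  }
  stop("position not exonic", call. = FALSE)
}

#' Simulate reads for all libraries
#'
#' 454-style reads are the insert flanked by the 5' linker
#' `ATCGTAGGCACCTGAAA` and the 3' linker `ACTGTAGGCACCATCAAT`. SOLiD
#' reads are a `T` primer followed by exactly 35 colors encoding the
#' insert and then the 3' linker continuation (shorter inserts run into
#' the adapter, which is why alignment-based trimming is needed), with
#' i.i.d. color errors at the configured rate. Degradation background
#' reads are random fragments (18-30 nt) of the ncRNA loci.
#'
#' @param bundle `GenomeBundle` from [generate_genome()].
#' @param truth truth manifest from [generate_genome()].
#' @param config the same [sim_config()].
#' @return list with `reads_454` (named list library -> character vector
#'   of reads) and `solid` (named list library -> data.frame id, primer,
#'   colors).
#' @export
simulate_reads <- function(bundle, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  libs <- config$libraries
  platforms <- config$platforms
  manifest <- truth$loci
  chrom_seq <- setNames(as.character(bundle$seq), names(bundle$seq))

  inserts <- setNames(vector("list", length(libs)), libs)
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    for (L in libs) {
      n <- row[[L]]
      if (n == 0L) next
      if (row$type == "degradation") {
        frags <- vapply(seq_len(n), function(j) {
          w <- sample(18:30, 1L)
          s <- sample(seq(row$start, row$end - w + 1L), 1L)
          substr(chrom_seq[row$chrom], s, s + w - 1L)
        }, character(1))
        inserts[[L]] <- c(inserts[[L]], frags)
      } else {
        inserts[[L]] <- c(inserts[[L]], rep(row$mature, n))
      }
      ns <- row[[paste0("star_", L)]]
      if (!is.null(ns) && ns > 0L && !is.na(row$star)) {
        inserts[[L]] <- c(inserts[[L]], rep(row$star, ns))
      }
    }
  }
  # star reads for libraries beyond their mature counts handled above
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    for (L in libs) {
      ns <- row[[paste0("star_", L)]]
      if (ns > 0L && row[[L]] == 0L && !is.na(row$star)) {
        inserts[[L]] <- c(inserts[[L]], rep(row$star, ns))
      }
    }
  }

  reads_454 <- list()
  solid <- list()
  for (k in seq_along(libs)) {
    L <- libs[k]
    ins <- inserts[[L]]
    if (is.null(ins)) ins <- character(0)
    ids <- sprintf("%s_%06d", L, seq_along(ins))
    if (platforms[k] == "454") {
      reads_454[[L]] <- setNames(
        paste0(ADAPTER_5P, ins, ADAPTER_3P), ids
      )
    } else {
      if (config$solid_truncate_frac > 0 && length(ins)) {
        trunc <- runif(length(ins)) < config$solid_truncate_frac
        ins[trunc] <- substr(ins[trunc], 1L, 18L)
      }
      payload <- substr(
        paste0(ins, strrep(ADAPTER_3P, 3L)), 1L, SOLID_READ_COLORS
      )
      colors <- solid_encode(payload, primer = "T")
      if (config$color_error_rate > 0 && length(colors)) {
        cmat <- do.call(rbind, strsplit(colors, "", fixed = TRUE))
        flip <- matrix(
          runif(length(cmat)) < config$color_error_rate,
          nrow = nrow(cmat)
        )
        if (any(flip)) {
          shift <- sample(1:3, sum(flip), replace = TRUE)
          old <- as.integer(cmat[flip])
          cmat[flip] <- as.character((old + shift) %% 4L)
        }
        colors <- apply(cmat, 1L, paste, collapse = "")
      }
      solid[[L]] <- data.frame(
        id = ids, primer = "T", colors = colors, stringsAsFactors = FALSE
      )
    }
  }
  list(reads_454 = reads_454, solid = solid)
}

#' Write a simulated dataset to disk
#'
#' Emits genome.fa, genes.gff3, repeats.bed, ncrna.bed, ncrna_ref.fa,
#' known_mirnas.fa, go_map.tsv, truth.tsv and the per-library read
#' files (reads_<lib>.fa for the 454 library, reads_<lib>.csfasta for
#' SOLiD libraries).
#'
#' @param bundle,truth,reads outputs of [generate_genome()] and
#'   [simulate_reads()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths.
#' @export
write_sim_data <- function(bundle, truth, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    repeats = file.path(dir, "repeats.bed"),
    ncrna = file.path(dir, "ncrna.bed"),
    ncrna_ref = file.path(dir, "ncrna_ref.fa"),
    known = file.path(dir, "known_mirnas.fa"),
    go = file.path(dir, "go_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  Biostrings::writeXStringSet(bundle$seq, paths["genome"])
  write_gff3(bundle$genes, paths["genes"])
  .write_bed6(bundle$repeats, bundle$repeats$family, paths["repeats"])
  .write_bed6(bundle$ncrna, bundle$ncrna$class, paths["ncrna"])
  # ncRNA reference: the locus sequences, class in the header
  nc <- bundle$ncrna
  if (length(nc)) {
    nc_seq <- Biostrings::DNAStringSet(vapply(seq_along(nc), function(k) {
      substr(
        as.character(bundle$seq[[as.character(seqnames(nc))[k]]]),
        start(nc)[k], end(nc)[k]
      )
    }, character(1)))
    names(nc_seq) <- sprintf("ncref%02d class=%s", seq_along(nc), nc$class)
  } else {
    nc_seq <- Biostrings::DNAStringSet()
  }
  Biostrings::writeXStringSet(nc_seq, paths["ncrna_ref"])
  known <- Biostrings::DNAStringSet(truth$known_mirnas)
  Biostrings::writeXStringSet(known, paths["known"])
  write.table(truth$go_map, paths["go"],
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  write.table(truth$loci, paths["truth"],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  for (L in names(reads$reads_454)) {
    p <- file.path(dir, sprintf("reads_%s.fa", L))
    rs <- Biostrings::DNAStringSet(reads$reads_454[[L]])
    Biostrings::writeXStringSet(rs, p)
    paths[paste0("reads_", L)] <- p
  }
  for (L in names(reads$solid)) {
    p <- file.path(dir, sprintf("reads_%s.csfasta", L))
    df <- reads$solid[[L]]
    write_csfasta(df$id, df$primer, df$colors, p)
    paths[paste0("reads_", L)] <- p
  }
  paths
}

#' Write gene models as GFF3
#'
#' @param genes list of gene models (as held in a `GenomeBundle`).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  fmt <- function(chrom, type, s, e, strand, attrs) {
    sprintf(
      "%s\tsrnapipe\t%s\t%d\t%d\t.\t%s\t.\t%s",
      chrom, type, s, e, strand, attrs
    )
  }
  for (gm in genes) {
    span_s <- min(start(gm$exons))
    span_e <- max(end(gm$exons))
    writeLines(fmt(
      gm$chrom, "gene", span_s, span_e, gm$strand,
      sprintf("ID=%s", gm$gene_id)
    ), con)
    writeLines(fmt(
      gm$chrom, "mRNA", span_s, span_e, gm$strand,
      sprintf("ID=%s;Parent=%s", gm$transcript_id, gm$gene_id)
    ), con)
    emit <- function(iv, type) {
      for (k in seq_along(iv)) {
        writeLines(fmt(
          gm$chrom, type, start(iv)[k], end(iv)[k], gm$strand,
          sprintf("Parent=%s", gm$transcript_id)
        ), con)
      }
    }
    emit(gm$exons, "exon")
    emit(gm$cds, "CDS")
    emit(gm$utr5, "five_prime_UTR")
    emit(gm$utr3, "three_prime_UTR")
  }
  invisible(path)
}

.write_bed6 <- function(gr, name, path) {
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L, # BED is 0-based half-open
    end = end(gr),
    name = name,
    score = 0L,
    strand = as.character(strand(gr))
  )
  write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE
  )
  invisible(path)
}
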