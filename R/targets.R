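# miRNA target prediction: animal-like 6-mer seed sites, plant-like
# near-full-length complementarity with a duplex energy cutoff,
# transcript-region assignment and GO functional-bias ranking.

.COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A")

#' Spliced transcript sequences and CDS bounds
#'
#' @param bundle a `GenomeBundle`.
#' @return data.frame with `transcript_id`, `sequence` (mRNA sense),
#'   `tx_len`, `cds_start`, `cds_end` (transcript coordinates; NA when
#'   the model has no UTR/codon annotation), `has_utr`.
#' @export
transcript_sequences <- function(bundle) {
  rows <- lapply(bundle$genes, function(gm) {
    ex <- sort(gm$exons)
    parts <- vapply(seq_along(ex), function(k) {
      as.character(Biostrings::subseq(
        bundle$seq[[gm$chrom]], start(ex)[k], end(ex)[k]
      ))
    }, character(1))
    tx <- paste(parts, collapse = "")
    if (gm$strand == "-") tx <- .revcomp(tx)
    tx_len <- nchar(tx)
    if (gm$has_utr) {
      u5 <- sum(width(gm$utr5))
      u3 <- sum(width(gm$utr3))
      cds_start <- u5 + 1L
      cds_end <- tx_len - u3
    } else {
      cds_start <- NA_integer_
      cds_end <- NA_integer_
    }
    data.frame(
      transcript_id = gm$transcript_id, sequence = tx, tx_len = tx_len,
      cds_start = cds_start, cds_end = cds_end, has_utr = gm$has_utr,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}

#' Animal-style 6-mer seed sites
#'
#' One hit per transcript position where the reverse complement of
#' miRNA nucleotides 2-7 (the animal seed) occurs exactly.
#'
#' @param mirna miRNA sequence (RNA or DNA, 5'->3').
#' @param transcript transcript sequence (mRNA sense).
#' @return data.frame with `tx_start`, `tx_end` (1-based, inclusive).
#' @export
scan_animal_sites <- function(mirna, transcript) {
  m <- chartr("U", "T", toupper(mirna))
  tx <- chartr("U", "T", toupper(transcript))
  if (nchar(tx) < 6L || nchar(m) < 7L) {
    return(data.frame(tx_start = integer(), tx_end = integer()))
  }
  seed <- substr(m, 2L, 7L)
  motif <- .revcomp(seed)
  hits <- integer(0)
  p <- 1L
  repeat {
    r <- regexpr(motif, substr(tx, p, nchar(tx)), fixed = TRUE)
    if (r < 0L) break
    hits <- c(hits, p + r - 1L)
    p <- p + r # allow overlapping occurrences
    if (p > nchar(tx)) break
  }
  data.frame(tx_start = hits, tx_end = hits + 5L)
}

#' Plant-style near-full-length sites
#'
#' Scans every transcript position for an ungapped antiparallel duplex
#' of the full miRNA against the site: at most `seed_defects_max`
#' mismatches in the miRNA's 8-nt 5' seed region (positions 1-8) and
#' at most `rest_defects_max` in the remainder, and duplex energy at
#' most `energy_max` kcal/mol under the pair-energy model
#' (GC -3, AU -2, GU -1; G:U wobble counts as a mismatch in the defect
#' budget but still contributes -1 kcal/mol).
#'
#' @param mirna miRNA sequence (>= 18 nt, 5'->3').
#' @param transcript transcript sequence (mRNA sense).
#' @param energy_max duplex energy cutoff, kcal/mol (default -20).
#' @param seed_defects_max,rest_defects_max defect budgets (1 and 3).
#' @param resolve_overlaps keep only the lowest-energy site among
#'   mutually overlapping ones (default TRUE).
#' @return data.frame with `tx_start`, `tx_end`, `mismatches_seed`,
#'   `mismatches_rest`, `gaps`, `energy`.
#' @export
scan_plant_sites <- function(mirna, transcript, energy_max = -20,
                             seed_defects_max = 1L, rest_defects_max = 3L,
                             resolve_overlaps = TRUE) {
  m <- chartr("U", "T", toupper(mirna))
  if (nchar(m) < 18L) {
    stop("scan_plant_sites: miRNA shorter than 18 nt", call. = FALSE)
  }
  tx <- chartr("U", "T", toupper(transcript))
  L <- nchar(m)
  n <- nchar(tx)
  empty <- data.frame(
    tx_start = integer(), tx_end = integer(),
    mismatches_seed = integer(), mismatches_rest = integer(),
    gaps = integer(), energy = numeric()
  )
  if (n < L) {
    return(empty)
  }
  mch <- strsplit(m, "", fixed = TRUE)[[1]]
  tch <- strsplit(tx, "", fixed = TRUE)[[1]]
  comp_ok <- function(mb, tb) .COMP[[mb]] == tb # Watson-Crick only
  wobble <- function(mb, tb) {
    (mb == "G" && tb == "T") || (mb == "T" && tb == "G")
  }
  rows <- list()
  for (o in 0:(n - L)) {
    # miRNA position j pairs with transcript position o + (L - j + 1)
    seed_mm <- 0L
    rest_mm <- 0L
    energy <- 0
    for (j in seq_len(L)) {
      tb <- tch[o + L - j + 1L]
      mb <- mch[j]
      if (comp_ok(mb, tb)) {
        energy <- energy + if (mb %in% c("G", "C")) -3 else -2
      } else if (wobble(mb, tb)) {
        energy <- energy - 1
        if (j <= 8L) seed_mm <- seed_mm + 1L else rest_mm <- rest_mm + 1L
      } else {
        if (j <= 8L) seed_mm <- seed_mm + 1L else rest_mm <- rest_mm + 1L
      }
      if (seed_mm > seed_defects_max || rest_mm > rest_defects_max) break
    }
    if (seed_mm <= seed_defects_max && rest_mm <= rest_defects_max &&
      energy <= energy_max) {
      rows[[length(rows) + 1L]] <- data.frame(
        tx_start = o + 1L, tx_end = o + L,
        mismatches_seed = seed_mm, mismatches_rest = rest_mm,
        gaps = 0L, energy = energy
      )
    }
  }
  if (!length(rows)) {
    return(empty)
  }
  hits <- do.call(rbind, rows)
  if (resolve_overlaps && nrow(hits) > 1L) {
    ord <- order(hits$energy, hits$tx_start)
    keep <- logical(nrow(hits))
    taken <- IRanges::IRanges()
    for (i in ord) {
      iv <- IRanges::IRanges(hits$tx_start[i], hits$tx_end[i])
      if (!any(IRanges::overlapsAny(iv, taken))) {
        keep[i] <- TRUE
        taken <- c(taken, iv)
      }
    }
    hits <- hits[keep, , drop = FALSE]
    hits <- hits[order(hits$tx_start), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Assign a site to a transcript region
#'
#' Region by site midpoint relative to the CDS bounds; `unknown` when
#' the transcript lacks start/stop codon annotation.
#'
#' @param tx_start,tx_end site interval in transcript coordinates.
#' @param cds_start,cds_end CDS bounds in transcript coordinates (NA
#'   when unannotated).
#' @return `"five-utr"`, `"cds"`, `"three-utr"` or `"unknown"`.
#' @export
assign_region <- function(tx_start, tx_end, cds_start, cds_end) {
  if (is.na(cds_start) || is.na(cds_end)) {
    return("unknown")
  }
  mid <- (tx_start + tx_end) / 2
  if (mid < cds_start) {
    "five-utr"
  } else if (mid > cds_end) {
    "three-utr"
  } else {
    "cds"
  }
}

#' Predict targets for a set of miRNAs
#'
#' Runs both binding modes over every transcript and assigns regions.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts data.frame from [transcript_sequences()].
#' @param energy_max plant-mode duplex energy cutoff (default -20).
#' @return list with `hits` (TargetHit table: `mirna_id`,
#'   `transcript_id`, `tx_start`, `tx_end`, `mode`, `mismatches_seed`,
#'   `mismatches_rest`, `gaps`, `energy`, `region`) and `summary`
#'   (per mode: fraction of transcripts with >= 1 site, and region
#'   percentages).
#' @export
predict_targets <- function(mirnas, transcripts, energy_max = -20) {
  if (is.null(names(mirnas))) {
    names(mirnas) <- paste0("mir", seq_along(mirnas))
  }
  rows <- list()
  for (mi in seq_along(mirnas)) {
    for (ti in seq_len(nrow(transcripts))) {
      tx <- transcripts[ti, ]
      an <- scan_animal_sites(mirnas[mi], tx$sequence)
      if (nrow(an)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = names(mirnas)[mi], transcript_id = tx$transcript_id,
          tx_start = an$tx_start, tx_end = an$tx_end, mode = "animal",
          mismatches_seed = 0L, mismatches_rest = 0L, gaps = 0L,
          energy = NA_real_, stringsAsFactors = FALSE
        )
      }
      if (nchar(mirnas[mi]) >= 18L) {
        pl <- scan_plant_sites(mirnas[mi], tx$sequence,
          energy_max = energy_max
        )
        if (nrow(pl)) {
          rows[[length(rows) + 1L]] <- data.frame(
            mirna_id = names(mirnas)[mi], transcript_id = tx$transcript_id,
            tx_start = pl$tx_start, tx_end = pl$tx_end, mode = "plant",
            mismatches_seed = pl$mismatches_seed,
            mismatches_rest = pl$mismatches_rest, gaps = pl$gaps,
            energy = pl$energy, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  hits <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(
      mirna_id = character(), transcript_id = character(),
      tx_start = integer(), tx_end = integer(), mode = character(),
      mismatches_seed = integer(), mismatches_rest = integer(),
      gaps = integer(), energy = numeric(), stringsAsFactors = FALSE
    )
  }
  tx_row <- match(hits$transcript_id, transcripts$transcript_id)
  hits$region <- vapply(seq_len(nrow(hits)), function(i) {
    assign_region(
      hits$tx_start[i], hits$tx_end[i],
      transcripts$cds_start[tx_row[i]], transcripts$cds_end[tx_row[i]]
    )
  }, character(1))

  summ <- lapply(c("animal", "plant"), function(md) {
    h <- hits[hits$mode == md, , drop = FALSE]
    frac <- length(unique(h$transcript_id)) / max(nrow(transcripts), 1L)
    reg <- h$region[h$region != "unknown"]
    reg_tab <- if (length(reg)) {
      tab <- table(factor(reg, levels = c("five-utr", "cds", "three-utr")))
      100 * as.numeric(tab) / sum(tab)
    } else {
      c(NA_real_, NA_real_, NA_real_)
    }
    data.frame(
      mode = md, frac_transcripts = frac,
      pct_five_utr = reg_tab[1], pct_cds = reg_tab[2],
      pct_three_utr = reg_tab[3], stringsAsFactors = FALSE
    )
  })
  list(
    hits = hits,
    summary = do.call(rbind, c(summ, list(make.row.names = FALSE)))
  )
}

#' GO functional-bias ratios for target genes
#'
#' Per GO term: (fraction of target genes annotated with the term) /
#' (fraction of all genes annotated with the term), ranked descending.
#' Terms absent from the genome-wide set are excluded with a warning.
#'
#' @param target_genes character vector of target gene/transcript ids.
#' @param go_map data.frame with columns `gene_id`, `term`.
#' @param all_genes character vector of all gene ids in the genome.
#' @return data.frame `term`, `target_fraction`, `genome_fraction`,
#'   `ratio`, sorted by decreasing ratio.
#' @export
go_ratio <- function(target_genes, go_map, all_genes) {
  target_genes <- unique(target_genes)
  all_genes <- unique(all_genes)
  n_t <- length(target_genes)
  n_g <- length(all_genes)
  if (!n_t) {
    return(data.frame(
      term = character(), target_fraction = numeric(),
      genome_fraction = numeric(), ratio = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  tmap <- go_map[go_map$gene_id %in% target_genes, , drop = FALSE]
  terms <- unique(tmap$term)
  rows <- list()
  for (tm in terms) {
    in_genome <- sum(all_genes %in% go_map$gene_id[go_map$term == tm])
    if (in_genome == 0L) {
      warning("go_ratio: term ", tm, " absent from the genome set")
      next
    }
    in_targets <- length(unique(tmap$gene_id[tmap$term == tm]))
    tf <- in_targets / n_t
    gf <- in_genome / n_g
    rows[[length(rows) + 1L]] <- data.frame(
      term = tm, target_fraction = tf, genome_fraction = gf,
      ratio = tf / gf, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(
      term = character(), target_fraction = numeric(),
      genome_fraction = numeric(), ratio = numeric(),
      stringsAsFactors = FALSE
    )
  }
  out[order(-out$ratio, out$term), , drop = FALSE]
}
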