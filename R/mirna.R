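# miRNA candidate prediction: precursor excision, hairpin folding,
# structural filtering, expression-evidence rules, repeat exclusion,
# genomic-context classification, known-miRNA seed matching.

#' Structural and evidence thresholds for miRNA prediction
#'
#' Defaults are the standard acceptance thresholds for hairpin-derived
#' small RNAs: precursor MFE strictly below -20 kcal/mol, terminal loop
#' of at least 10 nt, at most 3 unpaired nucleotides in any bulge of
#' the mature-arm stem, mature length 18-24 nt.
#'
#' @param mfe_max MFE threshold, kcal/mol (pass requires `mfe < mfe_max`).
#' @param loop_min minimum loop length, nt.
#' @param bulge_max maximum unpaired run in the mature-arm stem, nt.
#' @param len_range mature tag length range.
#' @param flank precursor flank, nt, beyond the mature arm.
#' @param pad short pad on the mature's outer side of the precursor, nt.
#' @param star_tol tolerance (nt) on star-read boundary agreement.
#' @return list of thresholds.
#' @export
mirna_thresholds <- function(mfe_max = -20, loop_min = 10L, bulge_max = 3L,
                             len_range = c(18L, 24L), flank = 100L,
                             pad = 10L, star_tol = 3L) {
  list(
    mfe_max = mfe_max, loop_min = as.integer(loop_min),
    bulge_max = as.integer(bulge_max), len_range = as.integer(len_range),
    flank = as.integer(flank), pad = as.integer(pad),
    star_tol = as.integer(star_tol)
  )
}

#' Verdict of the hairpin structural filters
#'
#' @param mfe minimum free energy of the precursor, kcal/mol.
#' @param loop_len loop length, nt.
#' @param max_bulge largest unpaired run in the mature-arm stem, nt.
#' @param one_arm does the mature lie entirely on one hairpin arm?
#' @param thresholds a [mirna_thresholds()] list.
#' @return list with `pass` (logical) and `reasons` (character vector
#'   of failed filters, empty when passing).
#' @export
hairpin_verdict <- function(mfe, loop_len, max_bulge, one_arm,
                            thresholds = mirna_thresholds()) {
  reasons <- character(0)
  if (!isTRUE(one_arm)) reasons <- c(reasons, "mature-not-on-one-arm")
  if (!(mfe < thresholds$mfe_max)) reasons <- c(reasons, "mfe>=threshold")
  if (is.na(loop_len) || loop_len < thresholds$loop_min) {
    reasons <- c(reasons, "loop<min")
  }
  if (is.na(max_bulge) || max_bulge > thresholds$bulge_max) {
    reasons <- c(reasons, "bulge>max")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Assess a precursor sequence around a mature arm
#'
#' Folds the precursor and measures, on the predicted structure, the
#' quantities the hairpin filters are defined on: the loop length of
#' the stem containing the mature arm, the largest unpaired run within
#' the mature-arm pairing region (on either strand of the stem), and
#' whether the mature arm stays on one arm of the hairpin.
#'
#' @param precursor precursor sequence (DNA or RNA).
#' @param mature_start,mature_len 1-based position and length of the
#'   mature arm within the precursor.
#' @param engine folding engine, signature `function(seq)` returning
#'   `list(structure=, mfe=)` (default [fold_hairpin()]).
#' @param thresholds a [mirna_thresholds()] list.
#' @return list with `structure`, `mfe`, `loop_len`, `max_bulge`,
#'   `one_arm`, `star_start`, `star_end` (precursor coordinates of the
#'   predicted star arm, 2-nt 3' extension included), `pass`, `reasons`.
#' @export
assess_precursor <- function(precursor, mature_start, mature_len,
                             engine = fold_hairpin,
                             thresholds = mirna_thresholds()) {
  fold <- engine(precursor)
  p <- pairing_table(fold$structure)
  n <- length(p)
  m1 <- mature_start
  m2 <- mature_start + mature_len - 1L
  stopifnot(m1 >= 1L, m2 <= n)
  mat <- m1:m2
  pm <- mat[!is.na(p[mat])]
  out <- list(
    structure = fold$structure, mfe = fold$mfe,
    loop_len = NA_integer_, max_bulge = NA_integer_, one_arm = FALSE,
    star_start = NA_integer_, star_end = NA_integer_
  )
  if (length(pm) >= 2L) {
    q <- p[pm]
    all_left <- all(q < m1)
    all_right <- all(q > m2)
    out$one_arm <- all_left || all_right
    if (out$one_arm) {
      # innermost pair of the mature-arm stem, loop = unpaired span
      if (all_right) {
        a <- max(pm)
        b <- p[a]
      } else {
        b <- min(pm)
        a <- p[b]
      }
      span <- if (b - a > 1L) (a + 1L):(b - 1L) else integer(0)
      out$loop_len <- sum(is.na(p[span]))
      # largest interruption of the mature-arm duplex: on the mature
      # side, unpaired runs between consecutive paired positions plus
      # frayed (unpaired) mature termini; on the star side, the total
      # span between consecutive pairing partners (intervening bases,
      # paired elsewhere or not, interrupt the stem either way)
      gaps <- function(pos) {
        pos <- sort(pos)
        if (length(pos) < 2L) {
          return(0L)
        }
        max(diff(pos) - 1L)
      }
      fray <- max(min(pm) - m1, m2 - max(pm))
      out$max_bulge <- max(gaps(pm), gaps(q), fray)
      out$star_start <- min(q)
      out$star_end <- min(max(q) + 2L, n) # 2-nt 3' overhang
    }
  }
  v <- hairpin_verdict(out$mfe, out$loop_len, out$max_bulge, out$one_arm,
    thresholds = thresholds
  )
  out$pass <- v$pass
  out$reasons <- v$reasons
  out
}

# precursor coordinate -> genome coordinate for an excision
.prec_to_genome <- function(prec_pos, gstart, gend, strand) {
  if (strand == "+") gstart + prec_pos - 1L else gend - prec_pos + 1L
}

#' Evaluate the hairpin context of one tag alignment
#'
#' Excises both candidate precursors (mature on the 5' arm: flank
#' downstream in transcription direction; mature on the 3' arm: flank
#' upstream), folds each, and keeps the better-scoring passing excision
#' (or, if none passes, the lower-energy one with its failure reasons).
#'
#' @param alignment one-row data.frame (or list) with `chrom`, `start`,
#'   `end`, `strand` of the mature tag.
#' @param bundle a `GenomeBundle`.
#' @param thresholds a [mirna_thresholds()] list.
#' @param engine folding engine (default [fold_hairpin()]).
#' @return a `HairpinCandidate`: the [assess_precursor()] result plus
#'   `precursor`, `prec_start`, `prec_end`, `arm` (`"5p"`/`"3p"`) and
#'   genomic `star` interval (`star_chrom`, `star_gstart`, `star_gend`,
#'   `star_strand`).
#' @export
evaluate_hairpin <- function(alignment, bundle,
                             thresholds = mirna_thresholds(),
                             engine = fold_hairpin) {
  chrom <- alignment$chrom
  s <- alignment$start
  e <- alignment$end
  strand <- alignment$strand
  clen <- width(bundle$seq)[match(chrom, names(bundle$seq))]
  chrom_seq <- bundle$seq[[chrom]]
  flank <- thresholds$flank
  pad <- thresholds$pad

  excise <- function(gs, ge) {
    gs <- max(1L, gs)
    ge <- min(clen, ge)
    seqc <- as.character(Biostrings::subseq(chrom_seq, gs, ge))
    if (strand == "-") seqc <- .revcomp(seqc)
    # mature offset within the (transcription-oriented) precursor
    off <- if (strand == "+") s - gs + 1L else ge - e + 1L
    list(seq = seqc, gstart = gs, gend = ge, offset = off)
  }
  # mature on 5' arm: flank extends 3' of the mature (downstream)
  ex5 <- if (strand == "+") {
    excise(s - pad, e + flank)
  } else {
    excise(s - flank, e + pad)
  }
  # mature on 3' arm: flank extends 5' of the mature (upstream)
  ex3 <- if (strand == "+") {
    excise(s - flank, e + pad)
  } else {
    excise(s - pad, e + flank)
  }
  cands <- list(`5p` = ex5, `3p` = ex3)
  assessed <- lapply(names(cands), function(arm) {
    ex <- cands[[arm]]
    a <- assess_precursor(ex$seq, ex$offset, e - s + 1L,
      engine = engine, thresholds = thresholds
    )
    a$arm <- arm
    a$precursor <- ex$seq
    a$prec_start <- ex$gstart
    a$prec_end <- ex$gend
    if (!is.na(a$star_start)) {
      g1 <- .prec_to_genome(a$star_start, ex$gstart, ex$gend, strand)
      g2 <- .prec_to_genome(a$star_end, ex$gstart, ex$gend, strand)
      a$star_chrom <- chrom
      a$star_gstart <- min(g1, g2)
      a$star_gend <- max(g1, g2)
      a$star_strand <- strand
    } else {
      a$star_chrom <- NA_character_
      a$star_gstart <- NA_integer_
      a$star_gend <- NA_integer_
      a$star_strand <- NA_character_
    }
    a
  })
  passing <- vapply(assessed, `[[`, TRUE, "pass")
  mfes <- vapply(assessed, `[[`, 1, "mfe")
  pick <- if (any(passing)) {
    which(passing)[which.min(mfes[passing])]
  } else {
    which.min(mfes)
  }
  structure(assessed[[pick]], class = "HairpinCandidate")
}

#' Expression-evidence rule for miRNA candidates
#'
#' A candidate needs its mature sequence in the same polarity in at
#' least two libraries, or a star-arm read in at least one library.
#'
#' @param mature_in_lib logical vector: mature present per library.
#' @param star_in_any logical scalar: star read found in any library.
#' @return logical.
#' @export
mirna_evidence <- function(mature_in_lib, star_in_any) {
  sum(mature_in_lib) >= 2L || isTRUE(star_in_any)
}

# locus context of an alignment: exon > intron > intergenic
.locus_class <- function(aln_gr, bundle) {
  ex <- exon_ranges(bundle)
  sp <- gene_spans(bundle)
  cls <- rep("intergenic", length(aln_gr))
  if (length(sp)) {
    hit_gene <- IRanges::overlapsAny(aln_gr, sp, ignore.strand = TRUE)
    cls[hit_gene] <- "intron"
  }
  if (length(ex)) {
    hit_ex <- IRanges::overlapsAny(aln_gr, ex, ignore.strand = TRUE)
    cls[hit_ex] <- "exon"
  }
  cls
}

#' Predict miRNA candidates from a mapped tag set
#'
#' A call is emitted for a tag iff: its length is in the mature range;
#' none of its alignments overlaps a repeat; some alignment's excised
#' precursor passes the hairpin filters; and the evidence rule holds
#' (mature in >= 2 libraries, or a tag overlapping the predicted star
#' arm on the same strand within the boundary tolerance in >= 1
#' library). Locus context (exon/intron/intergenic) is assigned per
#' alignment and the majority class reported.
#'
#' @param tags a mapped `tag_set`.
#' @param bundle a `GenomeBundle`.
#' @param thresholds a [mirna_thresholds()] list.
#' @param engine folding engine (default [fold_hairpin()]).
#' @return data.frame of calls (`MirnaCall` table): one row per called
#'   tag, with mature sequence, per-library counts, evidence fields,
#'   best alignment, structure, MFE, loop, precursor length, star
#'   interval and locus class. Attribute `"candidates"` holds the
#'   `HairpinCandidate` of every called tag.
#' @export
predict_mirnas <- function(tags, bundle, thresholds = mirna_thresholds(),
                           engine = fold_hairpin) {
  libs <- tags$libraries
  aln <- tags$alignments
  empty <- data.frame(
    sequence = character(), length = integer(), chrom = character(),
    start = integer(), end = integer(), strand = character(),
    n_libraries = integer(), star_found = logical(),
    mfe = numeric(), loop_len = integer(), max_bulge = integer(),
    precursor_length = integer(), locus_class = character(),
    structure = character(), stringsAsFactors = FALSE
  )
  if (!nrow(tags$tags)) {
    attr(empty, "candidates") <- list()
    return(empty)
  }
  len_ok <- tags$tags$length >= thresholds$len_range[1] &
    tags$tags$length <= thresholds$len_range[2]
  aln_gr <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start, aln$end),
    strand = aln$strand
  )
  rep_hit <- if (length(bundle$repeats)) {
    IRanges::overlapsAny(aln_gr, bundle$repeats, ignore.strand = TRUE)
  } else {
    rep(FALSE, nrow(aln))
  }
  repeat_tag <- unique(aln$sequence[rep_hit])

  calls <- list()
  cands <- list()
  for (i in which(len_ok)) {
    s <- tags$tags$sequence[i]
    if (s %in% repeat_tag) next
    rows <- which(aln$sequence == s)
    if (!length(rows)) next
    best <- NULL
    for (r in rows) {
      hc <- evaluate_hairpin(aln[r, ], bundle,
        thresholds = thresholds,
        engine = engine
      )
      if (hc$pass && (is.null(best) || hc$mfe < best$hc$mfe)) {
        best <- list(hc = hc, row = r)
      }
    }
    if (is.null(best)) next
    hc <- best$hc
    r <- best$row
    # star evidence: any tag alignment matching the predicted star arm
    star_found <- FALSE
    if (!is.na(hc$star_gstart)) {
      tol <- thresholds$star_tol
      cand <- aln$chrom == hc$star_chrom &
        aln$strand == hc$star_strand &
        abs(aln$start - hc$star_gstart) <= tol &
        abs(aln$end - hc$star_gend) <= tol &
        aln$sequence != s
      star_found <- any(cand)
    }
    mature_in_lib <- tags$counts[i, ] > 0L
    if (!mirna_evidence(mature_in_lib, star_found)) next
    cls <- .locus_class(aln_gr[rows], bundle)
    tab <- table(factor(cls, levels = c("exon", "intron", "intergenic")))
    locus <- names(tab)[which.max(tab)]
    calls[[length(calls) + 1L]] <- data.frame(
      sequence = s, length = tags$tags$length[i],
      chrom = aln$chrom[r], start = aln$start[r], end = aln$end[r],
      strand = aln$strand[r],
      n_libraries = sum(mature_in_lib), star_found = star_found,
      mfe = hc$mfe, loop_len = hc$loop_len, max_bulge = hc$max_bulge,
      precursor_length = nchar(hc$precursor),
      locus_class = locus, structure = hc$structure,
      stringsAsFactors = FALSE
    )
    cands[[s]] <- hc
  }
  out <- if (length(calls)) {
    do.call(rbind, c(calls, list(make.row.names = FALSE)))
  } else {
    empty
  }
  # the two arms of one hairpin both satisfy the filters; report the
  # duplex as a single locus with the higher-expressed arm as mature
  # and the other as its observed star
  out$star_sequence <- NA_character_
  if (nrow(out) > 1L) {
    tol <- thresholds$star_tol
    total <- rowSums(tags$counts[
      match(out$sequence, tags$tags$sequence), ,
      drop = FALSE
    ])
    drop <- logical(nrow(out))
    for (i in seq_len(nrow(out))) {
      if (drop[i]) next
      hci <- cands[[out$sequence[i]]]
      if (is.na(hci$star_gstart)) next
      for (j in seq_len(nrow(out))) {
        if (i == j || drop[j] || drop[i]) next
        if (out$chrom[j] == hci$star_chrom &&
          out$strand[j] == hci$star_strand &&
          abs(out$start[j] - hci$star_gstart) <= tol &&
          abs(out$end[j] - hci$star_gend) <= tol) {
          # i's predicted star arm is j: keep the better-expressed arm
          keep <- if (total[i] > total[j] ||
            (total[i] == total[j] && out$sequence[i] <= out$sequence[j])) {
            i
          } else {
            j
          }
          lose <- if (keep == i) j else i
          out$star_sequence[keep] <- out$sequence[lose]
          out$star_found[keep] <- TRUE
          drop[lose] <- TRUE
        }
      }
    }
    cands <- cands[out$sequence[!drop]]
    out <- out[!drop, , drop = FALSE]
    rownames(out) <- NULL
  }
  cnt <- tags$counts[match(out$sequence, tags$tags$sequence), ,
    drop = FALSE
  ]
  colnames(cnt) <- paste0("count_", libs)
  out <- cbind(out, as.data.frame(cnt))
  attr(out, "candidates") <- cands
  out
}

#' Seed-match miRNA calls against a known-miRNA set
#'
#' A hit is recorded when the first 10 nt of a known mature miRNA align
#' ungapped to the candidate with at most one mismatch (>= 90 %
#' identity over the 10-nt seed), at any offset.
#'
#' @param calls data.frame from [predict_mirnas()] (needs `sequence`).
#' @param known named character vector, `DNAStringSet`, or FASTA path
#'   of known mature miRNAs.
#' @return data.frame with `sequence`, `known`, `offset`, `mismatches`.
#' @export
match_known_mirnas <- function(calls, known) {
  if (is.character(known) && length(known) == 1L && file.exists(known)) {
    known <- Biostrings::readDNAStringSet(known)
  }
  known <- setNames(
    chartr("U", "T", toupper(as.character(known))),
    names(known)
  )
  hits <- list()
  for (ci in seq_len(nrow(calls))) {
    cand <- chartr("U", "T", toupper(calls$sequence[ci]))
    cch <- strsplit(cand, "", fixed = TRUE)[[1]]
    for (ki in seq_along(known)) {
      seed <- substr(known[ki], 1L, 10L)
      if (nchar(seed) < 10L || nchar(cand) < 10L) next
      sch <- strsplit(seed, "", fixed = TRUE)[[1]]
      best_off <- NA_integer_
      best_mm <- Inf
      for (off in 0:(nchar(cand) - 10L)) {
        mm <- sum(sch != cch[(off + 1L):(off + 10L)])
        if (mm < best_mm) {
          best_mm <- mm
          best_off <- off + 1L
        }
      }
      if (best_mm <= 1L) {
        hits[[length(hits) + 1L]] <- data.frame(
          sequence = calls$sequence[ci],
          known = names(known)[ki],
          offset = best_off, mismatches = as.integer(best_mm),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits)) {
    do.call(rbind, c(hits, list(make.row.names = FALSE)))
  } else {
    data.frame(
      sequence = character(), known = character(),
      offset = integer(), mismatches = integer(), stringsAsFactors = FALSE
    )
  }
}
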