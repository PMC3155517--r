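# Endogenous siRNA classification: repeat-associated siRNAs (with
# per-family tabulation and cross-library matching) and natural
# antisense / sense / intergenic classification.

.aln_granges <- function(aln) {
  GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start, aln$end),
    strand = aln$strand
  )
}

#' Call repeat-associated siRNAs
#'
#' A tag is a rasiRNA when at least one of its alignments overlaps a
#' repeat interval by at least `min_overlap` nt. The family table gives,
#' per library, the percentage of that library's rasiRNA tags assigned
#' to each repeat class (a tag takes the class of the repeat its
#' alignments overlap; multi-family tags count once per family).
#'
#' @param tags a mapped `tag_set`.
#' @param repeats GRanges with a `class` metadata column (as held in a
#'   `GenomeBundle`).
#' @param min_overlap minimum overlap in nt (default 1).
#' @return list with `calls` (data.frame sequence/family set) and
#'   `family_table` (data.frame library, class, percentage; percentages
#'   sum to 100 per library).
#' @export
call_rasirna <- function(tags, repeats, min_overlap = 1L) {
  aln <- tags$alignments
  libs <- tags$libraries
  if (!nrow(aln) || !length(repeats)) {
    return(list(
      calls = data.frame(
        sequence = character(), families = character(),
        stringsAsFactors = FALSE
      ),
      family_table = data.frame(
        library = character(), class = character(),
        percentage = numeric(), stringsAsFactors = FALSE
      )
    ))
  }
  gr <- .aln_granges(aln)
  ov <- GenomicRanges::findOverlaps(gr, repeats,
    minoverlap = min_overlap,
    ignore.strand = TRUE
  )
  fam_by_aln <- split(
    repeats$class[subjectHits(ov)], aln$sequence[queryHits(ov)]
  )
  calls <- data.frame(
    sequence = names(fam_by_aln),
    families = vapply(fam_by_aln, function(f) {
      paste(sort(unique(f)), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(calls) <- NULL

  rows <- list()
  all_classes <- sort(unique(repeats$class))
  for (L in libs) {
    present <- tags$tags$sequence[tags$counts[, L] > 0L]
    seqs <- intersect(calls$sequence, present)
    fam <- unlist(lapply(seqs, function(s) unique(fam_by_aln[[s]])))
    if (!length(fam)) next
    tab <- table(factor(fam, levels = all_classes))
    rows[[L]] <- data.frame(
      library = L, class = names(tab),
      percentage = 100 * as.numeric(tab) / sum(tab),
      stringsAsFactors = FALSE
    )
  }
  list(
    calls = calls,
    family_table = if (length(rows)) {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    } else {
      data.frame(
        library = character(), class = character(),
        percentage = numeric(), stringsAsFactors = FALSE
      )
    }
  )
}

# best ungapped local alignment score between two sequences
# (match +1, mismatch -3), over both relative orientations of b
.best_ungapped_score <- function(a, b, try_revcomp = TRUE) {
  score_pair <- function(x, y) {
    if (grepl(x, y, fixed = TRUE) || grepl(y, x, fixed = TRUE)) {
      return(min(nchar(x), nchar(y))) # exact containment
    }
    xc <- strsplit(x, "", fixed = TRUE)[[1]]
    yc <- strsplit(y, "", fixed = TRUE)[[1]]
    nx <- length(xc)
    ny <- length(yc)
    best <- 0
    for (off in (-(nx - 1L)):(ny - 1L)) {
      i0 <- max(1L, 1L - off)
      i1 <- min(nx, ny - off)
      if (i1 < i0) next
      s <- ifelse(xc[i0:i1] == yc[(i0:i1) + off], 1, -3)
      cs <- cumsum(s)
      run_best <- max(0, cs - cummin(c(0, cs[-length(cs)])))
      if (run_best > best) best <- run_best
    }
    best
  }
  s <- score_pair(a, b)
  if (try_revcomp) s <- max(s, score_pair(a, .revcomp(b)))
  s
}

#' Cross-library matching of rasiRNA candidate sets
#'
#' For each sequence in set A, searches set B for a local ungapped
#' alignment whose E-value `K * m * n * exp(-lambda * S)` is at most
#' `evalue_max`, with m the query length and n the total length of B.
#' Scoring is match +1 / mismatch -3 with the standard ungapped
#' nucleotide statistics (lambda = 1.33, K = 0.621). Returns the
#' fraction of A with a match in B (asymmetric by construction).
#'
#' @param set_a,set_b character vectors of tag sequences.
#' @param evalue_max E-value cutoff (default 1e-5).
#' @param lambda,k Karlin-Altschul constants for the +1/-3 scoring.
#' @return list with `fraction`, `matched` (logical per element of A),
#'   and `evalues` (best E-value per element of A).
#' @export
cross_library_match <- function(set_a, set_b, evalue_max = 1e-5,
                                lambda = 1.33, k = 0.621) {
  if (!length(set_b)) {
    warning("cross_library_match: empty subject set")
    return(list(
      fraction = 0,
      matched = rep(FALSE, length(set_a)),
      evalues = rep(NA_real_, length(set_a))
    ))
  }
  n_db <- sum(nchar(set_b))
  matched <- logical(length(set_a))
  evalues <- rep(NA_real_, length(set_a))
  for (i in seq_along(set_a)) {
    m <- nchar(set_a[i])
    # score needed to reach the cutoff; stop early once attained
    s_needed <- ceiling(log(k * m * n_db / evalue_max) / lambda)
    best_s <- 0
    for (b in set_b) {
      s <- .best_ungapped_score(set_a[i], b)
      if (s > best_s) best_s <- s
      if (best_s >= s_needed) break
    }
    ev <- k * m * n_db * exp(-lambda * best_s)
    evalues[i] <- ev
    matched[i] <- ev <= evalue_max
  }
  list(
    fraction = if (length(set_a)) mean(matched) else 0,
    matched = matched, evalues = evalues
  )
}

#' Classify non-miRNA, non-rasiRNA tags by orientation
#'
#' Per alignment: `sense` when it overlaps a gene span on the same
#' strand, `antisense` when on the opposite strand, `intergenic`
#' otherwise. The tag-level class is the single per-alignment label, or
#' `mixed` when alignments disagree. Orientation uses the full gene
#' span (exons plus introns), since antisense pairing with the pre-mRNA
#' is the relevant mechanism.
#'
#' @param tags a mapped `tag_set` with miRNA and rasiRNA tags removed.
#' @param bundle a `GenomeBundle`.
#' @return data.frame: `sequence`, `class`
#'   (`nat-sense`/`nat-antisense`/`intergenic`/`mixed`), `sub_labels`.
#' @export
classify_nat_sirna <- function(tags, bundle) {
  aln <- tags$alignments
  if (!nrow(aln)) {
    return(data.frame(
      sequence = character(), class = character(),
      sub_labels = character(), stringsAsFactors = FALSE
    ))
  }
  gr <- .aln_granges(aln)
  sp <- gene_spans(bundle)
  lab <- rep("intergenic", nrow(aln))
  if (length(sp)) {
    ss <- GenomicRanges::findOverlaps(gr, sp, ignore.strand = FALSE)
    lab[unique(queryHits(ss))] <- "sense"
    flip <- gr
    strand(flip) <- ifelse(as.character(strand(gr)) == "+", "-", "+")
    as_hit <- GenomicRanges::findOverlaps(flip, sp, ignore.strand = FALSE)
    lab[setdiff(unique(queryHits(as_hit)), unique(queryHits(ss)))] <- "antisense"
    both <- intersect(unique(queryHits(ss)), unique(queryHits(as_hit)))
    lab[both] <- "sense" # overlapping genes on both strands: sense wins
  }
  by_tag <- split(lab, aln$sequence)
  cls <- vapply(by_tag, function(v) {
    u <- unique(v)
    if (length(u) == 1L) {
      switch(u,
        sense = "nat-sense",
        antisense = "nat-antisense",
        intergenic = "intergenic"
      )
    } else {
      "mixed"
    }
  }, character(1))
  data.frame(
    sequence = names(by_tag), class = unname(cls),
    sub_labels = vapply(by_tag, function(v) {
      paste(v, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Top-level distribution of mapped tags across small-RNA classes
#'
#' Partitions every mapped tag into exactly one class — `mirna`,
#' `rasirna` (repeat overlap, unless called as miRNA), or its
#' orientation class from [classify_nat_sirna()] — and tabulates
#' percentages per library (over unique tags present in the library)
#' and per alignment occurrence.
#'
#' @param tags a mapped `tag_set`.
#' @param bundle a `GenomeBundle`.
#' @param mirna_sequences character vector of sequences called miRNA.
#' @param min_overlap minimum repeat overlap in nt.
#' @return list with `classes` (data.frame sequence/class),
#'   `summary_tags` and `summary_alignments` (data.frames library,
#'   class, percentage).
#' @export
sirna_distribution <- function(tags, bundle, mirna_sequences = character(0),
                               min_overlap = 1L) {
  libs <- tags$libraries
  seqs <- tags$tags$sequence
  cls <- setNames(rep(NA_character_, length(seqs)), seqs)
  cls[seqs %in% mirna_sequences] <- "mirna"
  ras <- call_rasirna(tags, bundle$repeats, min_overlap = min_overlap)
  is_ras <- seqs %in% ras$calls$sequence & is.na(cls)
  cls[is_ras] <- "rasirna"
  rest <- seqs[is.na(cls)]
  if (length(rest)) {
    sub <- .subset_tags(tags, seqs %in% rest)
    nat <- classify_nat_sirna(sub, bundle)
    cls[nat$sequence] <- nat$class
  }
  classes <- data.frame(
    sequence = seqs, class = unname(cls),
    stringsAsFactors = FALSE
  )
  lv <- c("mirna", "rasirna", "nat-sense", "nat-antisense", "intergenic", "mixed")
  tag_rows <- list()
  aln_rows <- list()
  aln_cls <- cls[tags$alignments$sequence]
  for (L in libs) {
    present <- tags$counts[, L] > 0L
    if (any(present)) {
      tab <- table(factor(cls[seqs[present]], levels = lv))
      tag_rows[[L]] <- data.frame(
        library = L, class = names(tab),
        percentage = 100 * as.numeric(tab) / sum(tab),
        stringsAsFactors = FALSE
      )
    }
    sel <- tags$alignments$sequence %in% seqs[present]
    if (any(sel)) {
      tab <- table(factor(aln_cls[sel], levels = lv))
      aln_rows[[L]] <- data.frame(
        library = L, class = names(tab),
        percentage = 100 * as.numeric(tab) / sum(tab),
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    classes = classes,
    summary_tags = do.call(rbind, c(tag_rows, list(make.row.names = FALSE))),
    summary_alignments = do.call(
      rbind, c(aln_rows, list(make.row.names = FALSE))
    )
  )
}
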