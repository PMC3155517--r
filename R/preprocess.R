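# Raw reads -> unique insert consensus tags: adapter excision (454),
# colorspace decode + alignment-trimming rescue (SOLiD), redundancy
# clustering, degradation filtering, genome mapping, summary stats.

# all contiguous substrings of an adapter missing at most `max_missing`
# characters in total from the two ends, longest first
.adapter_variants <- function(adapter, max_missing = 3L) {
  L <- nchar(adapter)
  out <- character(0)
  for (total in 0:max_missing) {
    for (k1 in 0:total) {
      out <- c(out, substr(adapter, k1 + 1L, L - (total - k1)))
    }
  }
  out[nchar(out) > 0L]
}

#' Excise the insert from adapter-flanked 454-style reads
#'
#' A read must carry both the 5' and the 3' adapter; an adapter match
#' may lack up to `max_missing - 1` terminal nucleotides (internal
#' mismatches are not tolerated). The insert is the subsequence
#' strictly between the two adapter matches.
#'
#' @param reads character vector of read sequences.
#' @param five_adapter,three_adapter adapter sequences, 5'->3'.
#' @param max_missing a read is rejected when an adapter match would
#'   require this many or more missing nucleotides (default 4, i.e. up
#'   to 3 missing are tolerated).
#' @return data.frame with columns `read`, `insert`, `reason`
#'   (`NA` for accepted reads; `"no-5-adapter"`, `"no-3-adapter"`,
#'   `"empty-insert"` otherwise).
#' @export
trim_454_adapters <- function(reads, five_adapter = ADAPTER_5P,
                              three_adapter = ADAPTER_3P,
                              max_missing = 4L) {
  v5 <- .adapter_variants(five_adapter, max_missing - 1L)
  v3 <- .adapter_variants(three_adapter, max_missing - 1L)
  insert <- rep(NA_character_, length(reads))
  reason <- rep(NA_character_, length(reads))
  for (i in seq_along(reads)) {
    r <- reads[i]
    end5 <- NA_integer_
    for (v in v5) {
      p <- regexpr(v, r, fixed = TRUE)
      if (p > 0L) {
        end5 <- p + nchar(v) - 1L
        break
      }
    }
    if (is.na(end5)) {
      reason[i] <- "no-5-adapter"
      next
    }
    rest <- substr(r, end5 + 1L, nchar(r))
    start3 <- NA_integer_
    for (v in v3) {
      p <- regexpr(v, rest, fixed = TRUE)
      if (p > 0L) {
        start3 <- p
        break
      }
    }
    if (is.na(start3)) {
      reason[i] <- "no-3-adapter"
      next
    }
    ins <- substr(rest, 1L, start3 - 1L)
    if (!nzchar(ins)) {
      reason[i] <- "empty-insert"
      next
    }
    insert[i] <- ins
  }
  data.frame(
    read = reads, insert = insert, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Decode SOLiD reads held in a csfasta data.frame
#'
#' @param csf data.frame with `primer` and `colors` columns, as
#'   returned by [read_csfasta()].
#' @return character vector of decoded base sequences (primer excluded).
#' @export
decode_colorspace <- function(csf) {
  primers <- unique(csf$primer)
  out <- character(nrow(csf))
  for (p in primers) {
    sel <- csf$primer == p
    out[sel] <- solid_decode(csf$colors[sel], primer = p)
  }
  out
}

# k-mer position index over the genome, both strands; "chrom" entries
# named <chrom> for plus and <chrom>.rc for the reverse complement
.kmer_index <- function(bundle, k) {
  seqs <- setNames(as.character(bundle$seq), names(bundle$seq))
  rc <- setNames(
    vapply(seqs, .revcomp, character(1)),
    paste0(names(seqs), ".rc")
  )
  all_seqs <- c(seqs, rc)
  kmers <- character(0)
  where <- character(0)
  pos <- integer(0)
  for (nm in names(all_seqs)) {
    s <- all_seqs[[nm]]
    n <- nchar(s)
    if (n < k) next
    km <- substring(s, 1:(n - k + 1L), k:n)
    kmers <- c(kmers, km)
    where <- c(where, rep(nm, length(km)))
    pos <- c(pos, seq_along(km))
  }
  list(
    map = split(seq_along(kmers), kmers),
    where = where, pos = pos,
    seqs = all_seqs,
    lens = setNames(nchar(all_seqs), names(all_seqs))
  )
}

# fill one result row of align_trim_solid
.at_accept <- function(row, nm, p, L, read, ins_len, mism, idx) {
  if (endsWith(nm, ".rc")) {
    g <- .rc_to_genome(nm, p, L, idx$lens)
    row[c("chrom", "start", "end", "strand")] <-
      list(sub("\\.rc$", "", nm), g[["start"]], g[["end"]], "-")
  } else {
    row[c("chrom", "start", "end", "strand")] <-
      list(nm, p, p + L - 1L, "+")
  }
  row$insert <- substr(read, 1L, ins_len)
  row$mismatches <- mism
  row
}

.rc_to_genome <- function(name, p, L, lens) {
  # position p (1-based) with extent L on the reverse-complement strand
  chrom <- sub("\\.rc$", "", name)
  n <- lens[[name]]
  c(start = n - (p + L - 1L) + 1L, end = n - p + 1L)
}

#' Alignment-based trimming of decoded SOLiD reads
#'
#' Every sequencing read spans 35 cycles even though the small-RNA
#' insert is usually shorter, so the decoded read runs from the insert
#' into the ligation adapter; single color errors corrupt the decoded
#' tail. Each read is therefore anchored at its first base and matched
#' against the genome on both strands: it is kept either when a perfect
#' prefix match of at least `min_insert` nt exists (the read is trimmed
#' to the matched extent) or when the full read matches end-to-end with
#' exactly one mismatch. Everything else is rejected.
#'
#' @param decoded character vector of decoded base-space reads.
#' @param bundle a `GenomeBundle`.
#' @param min_insert minimum perfect-match extent (default 16).
#' @return data.frame with one row per read: `read`, `insert`, `chrom`,
#'   `start`, `end`, `strand`, `mismatches`, `reason` (`NA` if kept,
#'   `"no-genome-match"` otherwise).
#' @export
align_trim_solid <- function(decoded, bundle, min_insert = 16L) {
  k <- as.integer(min_insert)
  idx <- .kmer_index(bundle, k)
  uniq <- unique(decoded)
  res <- data.frame(
    read = uniq, insert = NA_character_, chrom = NA_character_,
    start = NA_integer_, end = NA_integer_, strand = NA_character_,
    mismatches = NA_integer_, reason = NA_character_,
    stringsAsFactors = FALSE
  )
  lookup <- function(kmer) {
    hits <- idx$map[[kmer]]
    if (is.null(hits)) integer(0) else hits
  }
  for (i in seq_along(uniq)) {
    r <- uniq[i]
    n <- nchar(r)
    rch <- strsplit(r, "", fixed = TRUE)[[1]]
    pref_hits <- lookup(substr(r, 1L, k))
    best_len <- 0L
    best <- NULL
    for (h in pref_hits) {
      nm <- idx$where[h]
      p <- idx$pos[h]
      s <- idx$seqs[[nm]]
      maxext <- min(n, idx$lens[[nm]] - p + 1L)
      gch <- strsplit(substr(s, p, p + maxext - 1L), "", fixed = TRUE)[[1]]
      mism <- which(gch != rch[seq_len(maxext)])
      ext <- if (length(mism)) mism[1] - 1L else maxext
      if (ext > best_len) {
        best_len <- ext
        best <- list(nm = nm, p = p)
      }
    }
    if (best_len == n) {
      # the whole read matches perfectly
      res[i, ] <- .at_accept(res[i, ], best$nm, best$p, n, r, n, 0L, idx)
      next
    }
    # full-length rescue with exactly one mismatch: the mismatch leaves
    # an exact run of >= 16 nt either at the prefix or from offset 20;
    # this outranks a truncating exact-prefix match because the read
    # then has a genomic origin over its whole extent
    suf_hits <- lookup(substr(r, 20L, 20L + k - 1L))
    cand <- unique(rbind(
      data.frame(nm = idx$where[pref_hits], p = idx$pos[pref_hits]),
      data.frame(nm = idx$where[suf_hits], p = idx$pos[suf_hits] - 19L)
    ))
    found <- FALSE
    if (nrow(cand)) {
      cand <- cand[order(cand$nm, cand$p), , drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        nm <- cand$nm[j]
        p <- cand$p[j]
        if (p < 1L || p + n - 1L > idx$lens[[nm]]) next
        gch <- strsplit(substr(idx$seqs[[nm]], p, p + n - 1L), "",
          fixed = TRUE
        )[[1]]
        if (sum(gch != rch) == 1L) {
          res[i, ] <- .at_accept(res[i, ], nm, p, n, r, n, 1L, idx)
          found <- TRUE
          break
        }
      }
    }
    if (found) next
    if (best_len >= k) {
      # trim the read to the exact extent of the insert
      res[i, ] <- .at_accept(
        res[i, ], best$nm, best$p, best_len, r, best_len, 0L, idx
      )
      next
    }
    res$reason[i] <- "no-genome-match"
  }
  res[match(decoded, res$read), , drop = FALSE]
}

#' Cluster inserts into unique consensus tags
#'
#' Two sequences co-cluster when the shorter is an exact substring of
#' the longer and the length ratio is at least `len_sim` (CD-HIT-style
#' 100 % identity clustering with a length-similarity cutoff). The
#' cluster representative is the longest member (ties broken by
#' lexicographic order); per-library read counts are aggregated.
#'
#' @param inserts character vector of insert sequences.
#' @param libraries character vector of the same length: library label
#'   of each insert.
#' @param len_sim minimum shorter/longer length ratio (default 0.8).
#' @param lib_levels library labels fixing the column order of the
#'   count matrix (default: unique labels in order of appearance).
#' @return a `tag_set` (no alignments yet).
#' @export
cluster_unique <- function(inserts, libraries, len_sim = 0.8,
                           lib_levels = unique(libraries)) {
  stopifnot(length(inserts) == length(libraries))
  df <- data.frame(seq = inserts, lib = libraries, stringsAsFactors = FALSE)
  agg <- table(df$seq, factor(df$lib, levels = lib_levels))
  seqs <- rownames(agg)
  counts <- matrix(as.integer(agg),
    nrow = nrow(agg),
    dimnames = list(NULL, lib_levels)
  )
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  counts <- counts[ord, , drop = FALSE]

  rep_idx <- integer(0) # indices (into seqs) of representatives
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    ln <- nchar(s)
    hit <- 0L
    for (rj in rep_idx) {
      if (ln / nchar(seqs[rj]) >= len_sim &&
        grepl(s, seqs[rj], fixed = TRUE)) {
        hit <- rj
        break
      }
    }
    if (hit == 0L) {
      rep_idx <- c(rep_idx, i)
      assign[i] <- i
    } else {
      assign[i] <- hit
    }
  }
  out_counts <- matrix(0L, length(rep_idx), length(lib_levels),
    dimnames = list(NULL, lib_levels)
  )
  for (i in seq_along(seqs)) {
    r <- match(assign[i], rep_idx)
    out_counts[r, ] <- out_counts[r, ] + counts[i, ]
  }
  tag_set(seqs[rep_idx], out_counts)
}

.parse_ref_classes <- function(ref) {
  nm <- names(ref)
  cls <- rep("other", length(nm))
  has <- grepl("class=", nm)
  cls[has] <- sub(".*class=([^ ]+).*", "\\1", nm[has])
  # functional-description style labels also map to the rRNA bucket
  cls[grepl("ribosomal", nm, ignore.case = TRUE)] <- "rRNA"
  cls
}

#' Remove ncRNA degradation products from a tag set
#'
#' A tag is removed when a local alignment against any rRNA/tRNA (or
#' "ribosomal") reference covers at least `min_cov` of the tag length
#' at `min_identity` identity or better. Tags whose best-scoring
#' reference hit is annotated as miRNA are always kept.
#'
#' @param tags a `tag_set`.
#' @param ncrna_ref `DNAStringSet` (or FASTA path) whose names carry
#'   `class=rRNA|tRNA|miRNA` labels.
#' @param min_cov minimum alignment coverage of the tag (default 0.70).
#' @param min_identity minimum alignment identity (default 0.90).
#' @return list with `kept` and `removed` tag_sets.
#' @export
filter_degradation <- function(tags, ncrna_ref, min_cov = 0.70,
                               min_identity = 0.90) {
  if (is.character(ncrna_ref) && length(ncrna_ref) == 1L &&
    file.exists(ncrna_ref)) {
    ncrna_ref <- Biostrings::readDNAStringSet(ncrna_ref)
  }
  n <- nrow(tags$tags)
  if (!length(ncrna_ref) || n == 0L) {
    return(list(kept = tags, removed = .subset_tags(tags, logical(n))))
  }
  cls <- .parse_ref_classes(ncrna_ref)
  seqs <- Biostrings::DNAStringSet(tags$tags$sequence)
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE
  )
  best_score <- rep(-Inf, n)
  best_class <- rep(NA_character_, n)
  degraded <- logical(n)
  for (j in seq_along(ncrna_ref)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = seqs, subject = ncrna_ref[[j]],
      type = "local", substitutionMatrix = sm,
      gapOpening = 5, gapExtension = 2
    )
    sc <- Biostrings::score(aln)
    alen <- nchar(aln)
    cov <- Biostrings::nchar(Biostrings::pattern(aln)) / width(seqs)
    ident <- ifelse(alen > 0, Biostrings::nmatch(aln) / alen, 0)
    better <- sc > best_score
    best_score[better] <- sc[better]
    best_class[better] <- cls[j]
    if (cls[j] %in% c("rRNA", "tRNA")) {
      degraded <- degraded | (cov >= min_cov & ident >= min_identity)
    }
  }
  keep <- !degraded | (best_class == "miRNA" & !is.na(best_class))
  list(
    kept = .subset_tags(tags, keep),
    removed = .subset_tags(tags, !keep)
  )
}

.subset_tags <- function(tags, keep) {
  seqs <- tags$tags$sequence[keep]
  aln <- tags$alignments[tags$alignments$sequence %in% seqs, , drop = FALSE]
  rownames(aln) <- NULL
  tag_set(seqs, tags$counts[keep, , drop = FALSE],
    alignments = aln,
    class = tags$tags$class[keep]
  )
}

#' Map tags to the genome
#'
#' Records every genomic occurrence of each tag with at most
#' `max_mismatch` mismatches, on both strands. Tags without any such
#' occurrence are dropped with reason "unmapped".
#'
#' @param tags a `tag_set`.
#' @param bundle a `GenomeBundle`.
#' @param max_mismatch maximum mismatches per occurrence (default 1).
#' @return list with `mapped` (tag_set with `alignments` filled) and
#'   `unmapped` (tag_set).
#' @export
map_to_genome <- function(tags, bundle, max_mismatch = 1L) {
  seqs <- tags$tags$sequence
  chroms <- names(bundle$seq)
  rows <- list()
  for (s in seqs) {
    pat <- Biostrings::DNAString(s)
    rcp <- Biostrings::reverseComplement(pat)
    for (ch in chroms) {
      subj <- bundle$seq[[ch]]
      for (strand in c("+", "-")) {
        p <- if (strand == "+") pat else rcp
        m <- Biostrings::matchPattern(p, subj,
          max.mismatch = max_mismatch, with.indels = FALSE
        )
        if (!length(m)) next
        mm <- Biostrings::neditStartingAt(p, subj,
          starting.at = start(m)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = s, chrom = ch, start = start(m), end = end(m),
          strand = strand, mismatches = as.integer(mm),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  aln <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      sequence = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), mismatches = integer(),
      stringsAsFactors = FALSE
    )
  }
  mapped_seq <- unique(aln$sequence)
  keep <- seqs %in% mapped_seq
  mapped <- tag_set(seqs[keep], tags$counts[keep, , drop = FALSE],
    alignments = aln, class = tags$tags$class[keep]
  )
  list(mapped = mapped, unmapped = .subset_tags(tags, !keep))
}

#' Per-library tag length and 5' nucleotide statistics
#'
#' Tabulated over unique tag sequences (a tag contributes to a library
#' when it has at least one read there); nucleotides are reported in
#' RNA alphabet. Frequencies sum to 1 per library.
#'
#' @param tags a `tag_set`.
#' @return list with `length` (data.frame library/length/count) and
#'   `first_nt` (data.frame library/nt/freq).
#' @export
tag_stats <- function(tags) {
  libs <- tags$libraries
  len_rows <- list()
  nt_rows <- list()
  for (L in libs) {
    sel <- tags$counts[, L] > 0L
    if (!any(sel)) next
    lens <- tags$tags$length[sel]
    tl <- table(lens)
    len_rows[[L]] <- data.frame(
      library = L, length = as.integer(names(tl)),
      count = as.integer(tl), stringsAsFactors = FALSE
    )
    first <- chartr("T", "U", substr(tags$tags$sequence[sel], 1L, 1L))
    ft <- table(factor(first, levels = c("A", "C", "G", "U")))
    nt_rows[[L]] <- data.frame(
      library = L, nt = names(ft),
      freq = as.numeric(ft) / sum(ft), stringsAsFactors = FALSE
    )
  }
  list(
    length = do.call(rbind, c(len_rows, list(make.row.names = FALSE))),
    first_nt = do.call(rbind, c(nt_rows, list(make.row.names = FALSE)))
  )
}

#' Full preprocessing stage
#'
#' Runs adapter excision on the 454-style libraries, colorspace decode
#' plus alignment-trimming on the SOLiD libraries, joint redundancy
#' clustering, degradation filtering and genome mapping.
#'
#' @param bundle a `GenomeBundle`.
#' @param reads_454 named list: library label -> character vector of
#'   adapter-flanked reads.
#' @param solid named list: library label -> data.frame(id, primer,
#'   colors).
#' @param ncrna_ref `DNAStringSet` or FASTA path with class labels.
#' @param min_insert,max_mismatch,len_sim,degr_cov,degr_identity stage
#'   thresholds (defaults: 16, 1, 0.8, 0.70, 0.90).
#' @return list with `tags` (mapped tag_set), `stats`, `log`
#'   (per-stage counts), `rejected` (per-read reasons), `removed`
#'   (degradation tag_set), `unmapped` (tag_set).
#' @export
preprocess_reads <- function(bundle, reads_454 = list(), solid = list(),
                             ncrna_ref = NULL, min_insert = 16L,
                             max_mismatch = 1L, len_sim = 0.8,
                             degr_cov = 0.70, degr_identity = 0.90) {
  inserts <- character(0)
  libs <- character(0)
  rejected <- list()
  log <- list()
  for (L in names(reads_454)) {
    tr <- trim_454_adapters(reads_454[[L]])
    ok <- is.na(tr$reason)
    inserts <- c(inserts, tr$insert[ok])
    libs <- c(libs, rep(L, sum(ok)))
    rejected[[L]] <- data.frame(
      library = rep(L, sum(!ok)), read = tr$read[!ok],
      reason = tr$reason[!ok],
      stringsAsFactors = FALSE
    )
    log[[L]] <- data.frame(
      library = L, reads_in = nrow(tr), kept = sum(ok),
      rejected = sum(!ok), stringsAsFactors = FALSE
    )
  }
  for (L in names(solid)) {
    dec <- decode_colorspace(solid[[L]])
    at <- align_trim_solid(dec, bundle, min_insert = min_insert)
    ok <- is.na(at$reason)
    inserts <- c(inserts, at$insert[ok])
    libs <- c(libs, rep(L, sum(ok)))
    rejected[[L]] <- data.frame(
      library = rep(L, sum(!ok)), read = at$read[!ok],
      reason = at$reason[!ok],
      stringsAsFactors = FALSE
    )
    log[[L]] <- data.frame(
      library = L, reads_in = nrow(at), kept = sum(ok),
      rejected = sum(!ok), stringsAsFactors = FALSE
    )
  }
  lib_levels <- c(names(reads_454), names(solid))
  clustered <- cluster_unique(inserts, libs,
    len_sim = len_sim,
    lib_levels = lib_levels
  )
  fd <- if (!is.null(ncrna_ref)) {
    filter_degradation(clustered, ncrna_ref,
      min_cov = degr_cov,
      min_identity = degr_identity
    )
  } else {
    list(kept = clustered, removed = .subset_tags(clustered, logical(nrow(clustered$tags))))
  }
  mp <- map_to_genome(fd$kept, bundle, max_mismatch = max_mismatch)
  list(
    tags = mp$mapped,
    stats = tag_stats(mp$mapped),
    log = do.call(rbind, c(log, list(make.row.names = FALSE))),
    rejected = do.call(rbind, c(rejected, list(make.row.names = FALSE))),
    removed = fd$removed,
    unmapped = mp$unmapped
  )
}
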