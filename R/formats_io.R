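# Readers/writers for the external formats and the in-memory genome model.
#
# Internal convention: all intervals are held as GRanges/IRanges, i.e.
# 1-based closed coordinates, the native convention of the Bioconductor
# stack. Conversion happens only at I/O boundaries (GFF3 is already
# 1-based closed; BED start coordinates are shifted by rtracklayer).

#' Controlled vocabulary for repeat families
#'
#' Maps a bare repeat family name (as found in RepeatMasker output or in
#' the name field of a BED file) to a `class/family` label drawn from a
#' controlled vocabulary. Families already containing a `/` are kept
#' verbatim; unknown families are filed under `Unknown/`.
#'
#' @param family character vector of family names.
#' @return character vector of `class/family` labels.
#' @examples
#' repeat_class_label(c("Copia", "Gypsy", "Harbinger", "LTR/Copia"))
#' @export
repeat_class_label <- function(family) {
  map <- c(
    Copia = "LTR/Copia", Gypsy = "LTR/Gypsy",
    Harbinger = "DNA/Harbinger", MuDR = "DNA/MuDR",
    hAT = "DNA/hAT", Mariner = "DNA/Mariner",
    LINE = "LINE/L1", SINE = "SINE/tRNA"
  )
  out <- ifelse(grepl("/", family, fixed = TRUE), family,
    ifelse(family %in% names(map), map[family],
      paste0("Unknown/", family)
    )
  )
  unname(out)
}

# quick structural pre-validation so parse failures name file and line
.check_tabular <- function(path, min_fields, comment = "#") {
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, comment) & nzchar(trimws(lines))
  idx <- which(keep)
  nf <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  bad <- idx[nf < min_fields]
  if (length(bad)) {
    stop(sprintf(
      "malformed record in %s at line %d (expected >= %d tab-separated fields)",
      path, bad[1], min_fields
    ), call. = FALSE)
  }
  invisible(TRUE)
}

.read_gff3_genes <- function(gff_path) {
  .check_tabular(gff_path, 9L)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(gr$Parent, function(p) {
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))

  mrna_idx <- which(typ == "mRNA")
  if (!length(mrna_idx)) mrna_idx <- which(typ == "gene")
  models <- vector("list", length(mrna_idx))
  names(models) <- ids[mrna_idx]
  mrna_gene <- parents[mrna_idx]
  for (k in seq_along(mrna_idx)) {
    i <- mrna_idx[k]
    tid <- ids[i]
    child <- which(parents == tid)
    pick <- function(what) {
      j <- child[typ[child] == what]
      r <- IRanges::IRanges(start(gr)[j], end(gr)[j])
      sort(r)
    }
    exons <- pick("exon")
    cds <- pick("CDS")
    if (!length(exons)) exons <- IRanges::IRanges(start(gr)[i], end(gr)[i])
    utr5 <- pick("five_prime_UTR")
    utr3 <- pick("three_prime_UTR")
    models[[k]] <- list(
      gene_id = if (!is.na(mrna_gene[k])) mrna_gene[k] else tid,
      transcript_id = tid,
      chrom = as.character(seqnames(gr))[i],
      strand = as.character(strand(gr))[i],
      exons = exons,
      cds = cds,
      utr5 = utr5,
      utr3 = utr3,
      has_utr = length(utr5) > 0L || length(utr3) > 0L
    )
  }
  models
}

.read_repeats <- function(path) {
  if (grepl("\\.out$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[-seq_len(min(3L, length(lines)))] # header block
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      return(GenomicRanges::GRanges(family = character(), class = character()))
    }
    fields <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(fields) < 11L)
    if (length(bad)) {
      stop(sprintf("malformed record in %s at line %d", path, bad[1] + 3L),
        call. = FALSE
      )
    }
    chrom <- vapply(fields, `[`, "", 5L)
    beg <- as.integer(vapply(fields, `[`, "", 6L))
    end <- as.integer(vapply(fields, `[`, "", 7L))
    strand <- ifelse(vapply(fields, `[`, "", 9L) == "C", "-", "+")
    fam <- vapply(fields, `[`, "", 10L)
    cls <- vapply(fields, `[`, "", 11L)
    lab <- ifelse(grepl("/", cls, fixed = TRUE), cls, repeat_class_label(fam))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(beg, end),
      strand = strand
    )
  } else {
    .check_tabular(path, 6L, comment = "track")
    gr <- rtracklayer::import(path, format = "bed")
    lab <- repeat_class_label(as.character(gr$name))
    fam <- sub("^[^/]+/", "", lab)
  }
  mcols(gr) <- NULL
  gr$family <- sub("^[^/]+/", "", lab)
  gr$class <- lab
  gr
}

.read_ncrna <- function(path) {
  .check_tabular(path, 6L, comment = "track")
  gr <- rtracklayer::import(path, format = "bed")
  cls <- as.character(gr$name)
  cls[!cls %in% c("rRNA", "tRNA", "miRNA")] <- "other"
  mcols(gr) <- NULL
  gr$class <- cls
  gr
}

.validate_bundle <- function(bundle) {
  lens <- setNames(width(bundle$seq), names(bundle$seq))
  check_gr <- function(gr, what) {
    chroms <- as.character(seqnames(gr))
    unknown <- setdiff(unique(chroms), names(lens))
    if (length(unknown)) {
      stop(sprintf(
        "%s annotation references unknown chromosome '%s'",
        what, unknown[1]
      ), call. = FALSE)
    }
    over <- which(start(gr) < 1L | end(gr) > lens[chroms])
    if (length(over)) {
      stop(sprintf(
        "%s interval %s:%d-%d exceeds chromosome bounds",
        what, chroms[over[1]], start(gr)[over[1]], end(gr)[over[1]]
      ), call. = FALSE)
    }
  }
  check_gr(bundle$repeats, "repeat")
  check_gr(bundle$ncrna, "ncRNA")
  for (gm in bundle$genes) {
    sp <- range(c(gm$exons, gm$cds))
    if (!gm$chrom %in% names(lens)) {
      stop(sprintf(
        "gene %s references unknown chromosome '%s'",
        gm$transcript_id, gm$chrom
      ), call. = FALSE)
    }
    if (length(sp) && (min(start(sp)) < 1L || max(end(sp)) > lens[gm$chrom])) {
      stop(sprintf(
        "gene %s interval exceeds chromosome bounds", gm$transcript_id
      ), call. = FALSE)
    }
  }
  invisible(bundle)
}

#' Load a genome with its annotations
#'
#' Reads the reference FASTA, gene models (GFF3 with exon/CDS and
#' optional UTR features), a repeat annotation (RepeatMasker `.out` or
#' BED6 with the family in the name field) and an ncRNA annotation
#' (BED6 with class rRNA/tRNA/miRNA in the name field) into a single
#' `GenomeBundle`.
#'
#' @param fasta_path genome FASTA.
#' @param gff_path gene models, GFF3 (1-based closed coordinates).
#' @param repeat_path repeat annotation (`.out` or `.bed`); `NULL` for none.
#' @param ncrna_path ncRNA annotation BED; `NULL` for none.
#' @return a `GenomeBundle`: list with `seq` (DNAStringSet), `genes`
#'   (list of gene models), `repeats` and `ncrna` (GRanges).
#' @export
read_genome <- function(fasta_path, gff_path, repeat_path = NULL,
                        ncrna_path = NULL) {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  names(seq) <- sub("\\s.*$", "", names(seq))
  empty <- GenomicRanges::GRanges()
  bundle <- structure(
    list(
      seq = seq,
      genes = if (!is.null(gff_path)) .read_gff3_genes(gff_path) else list(),
      repeats = if (!is.null(repeat_path)) .read_repeats(repeat_path) else {
        g <- empty
        g$family <- character(0)
        g$class <- character(0)
        g
      },
      ncrna = if (!is.null(ncrna_path)) .read_ncrna(ncrna_path) else {
        g <- empty
        g$class <- character(0)
        g
      }
    ),
    class = "GenomeBundle"
  )
  .validate_bundle(bundle)
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat(sprintf(
    "GenomeBundle: %d chromosome(s), %s nt; %d gene model(s), %d repeat(s), %d ncRNA locus/loci\n",
    length(x$seq), format(sum(width(x$seq)), big.mark = ","),
    length(x$genes), length(x$repeats), length(x$ncrna)
  ))
  invisible(x)
}

#' Gene spans of a bundle as GRanges
#'
#' One range per gene model, covering exons and introns, with
#' `transcript_id` metadata. Used for orientation classification and
#' genomic-context assignment.
#'
#' @param bundle a `GenomeBundle`.
#' @return GRanges.
#' @export
gene_spans <- function(bundle) {
  if (!length(bundle$genes)) {
    return(GenomicRanges::GRanges())
  }
  gr <- GenomicRanges::GRanges(
    vapply(bundle$genes, `[[`, "", "chrom"),
    IRanges::IRanges(
      vapply(bundle$genes, function(g) min(start(g$exons)), 1L),
      vapply(bundle$genes, function(g) max(end(g$exons)), 1L)
    ),
    strand = vapply(bundle$genes, `[[`, "", "strand")
  )
  gr$transcript_id <- vapply(bundle$genes, `[[`, "", "transcript_id")
  gr
}

#' Exon ranges of a bundle as GRanges
#'
#' @param bundle a `GenomeBundle`.
#' @return GRanges with `transcript_id` metadata.
#' @export
exon_ranges <- function(bundle) {
  if (!length(bundle$genes)) {
    return(GenomicRanges::GRanges())
  }
  n_ex <- vapply(bundle$genes, function(g) length(g$exons), 1L)
  gr <- GenomicRanges::GRanges(
    rep(vapply(bundle$genes, `[[`, "", "chrom"), n_ex),
    do.call(c, unname(lapply(bundle$genes, `[[`, "exons"))),
    strand = rep(vapply(bundle$genes, `[[`, "", "strand"), n_ex)
  )
  gr$transcript_id <- rep(
    vapply(bundle$genes, `[[`, "", "transcript_id"), n_ex
  )
  gr
}

# ---- tag sets -------------------------------------------------------------

#' Construct a set of unique small-RNA tags
#'
#' A tag is a unique insert consensus sequence with per-library read
#' counts and (after mapping) its genomic alignments.
#'
#' @param sequences character vector of tag sequences (DNA, uppercase).
#' @param counts integer matrix, one row per tag, one column per library.
#' @param alignments data.frame with columns `sequence`, `chrom`,
#'   `start`, `end`, `strand`, `mismatches` (1-based closed), or `NULL`.
#' @param class optional per-tag classification label.
#' @return object of class `tag_set`.
#' @export
tag_set <- function(sequences, counts, alignments = NULL, class = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(sequences))
  if (is.null(alignments)) {
    alignments <- data.frame(
      sequence = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), mismatches = integer(),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      tags = data.frame(
        sequence = as.character(sequences),
        length = if (length(sequences)) nchar(sequences) else integer(0),
        class = if (is.null(class)) {
          rep(NA_character_, length(sequences))
        } else {
          class
        },
        stringsAsFactors = FALSE
      ),
      counts = counts,
      alignments = alignments,
      libraries = colnames(counts)
    ),
    class = "tag_set"
  )
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf(
    "tag_set: %d unique tag(s), %d alignment(s), libraries: %s\n",
    nrow(x$tags), nrow(x$alignments), paste(x$libraries, collapse = ", ")
  ))
  invisible(x)
}

#' Write a tag table as TSV
#'
#' One row per (tag, alignment); tags without alignments get a single
#' row with empty alignment fields. Rows are ordered by
#' (chrom, start, sequence) so output is stable across runs.
#'
#' @param tags a `tag_set`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tag_table <- function(tags, path) {
  tg <- tags$tags
  cnt <- as.data.frame(tags$counts)
  names(cnt) <- paste0("count_", tags$libraries)
  base <- cbind(tg[, c("sequence", "length")], cnt, class = tg$class)
  aln <- tags$alignments
  if (nrow(aln)) {
    merged <- merge(base, aln, by = "sequence", all.x = TRUE, sort = FALSE)
  } else {
    n <- nrow(base)
    merged <- cbind(base, data.frame(
      chrom = rep(NA_character_, n), start = rep(NA_integer_, n),
      end = rep(NA_integer_, n), strand = rep(NA_character_, n),
      mismatches = rep(NA_integer_, n), stringsAsFactors = FALSE
    ))
  }
  ord <- order(
    !is.na(merged$chrom) * 0, merged$chrom, merged$start,
    merged$sequence,
    na.last = TRUE
  )
  merged <- merged[ord, , drop = FALSE]
  write.table(merged, path,
    sep = "\t", quote = FALSE, row.names = FALSE,
    na = ""
  )
  invisible(path)
}

#' Read a tag table written by [write_tag_table()]
#'
#' @param path TSV path.
#' @return a `tag_set`.
#' @export
read_tag_table <- function(path) {
  df <- read.delim(path,
    sep = "\t", stringsAsFactors = FALSE,
    na.strings = ""
  )
  cnt_cols <- grep("^count_", names(df), value = TRUE)
  libs <- sub("^count_", "", cnt_cols)
  first <- !duplicated(df$sequence)
  seqs <- df$sequence[first]
  counts <- as.matrix(df[first, cnt_cols, drop = FALSE])
  colnames(counts) <- libs
  rownames(counts) <- NULL
  cls <- df$class[first]
  has_aln <- !is.na(df$chrom)
  aln <- df[has_aln, c("sequence", "chrom", "start", "end", "strand", "mismatches")]
  rownames(aln) <- NULL
  tag_set(seqs, counts, alignments = aln, class = cls)
}
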