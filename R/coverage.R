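# Strand-aware chromosome coverage: binning, normalization, export.

#' Bin tag alignments along the chromosomes
#'
#' Each alignment occurrence increments the bin containing its start
#' coordinate on its strand, weighted by the tag's read count in the
#' library (`weighting = "reads"`) or by 1 (`weighting = "unique"`).
#' Multi-mapped occurrences are each counted. Bin values are normalized
#' by the total number of sequences in the library (reads for
#' `"reads"`, unique tags for `"unique"`).
#'
#' @param tags a mapped `tag_set`.
#' @param bundle a `GenomeBundle`.
#' @param bin_size bin width in nt (default 10000).
#' @param weighting `"reads"` (default) or `"unique"`.
#' @return list of `BinProfile`s, one per library: each a list with
#'   `library`, `bin_size`, `total`, and `profile` — per chromosome a
#'   list with `plus` and `minus` numeric vectors of normalized bin
#'   values (attribute `"raw"` holds the unnormalized counts).
#' @export
bin_alignments <- function(tags, bundle, bin_size = 10000L,
                           weighting = c("reads", "unique")) {
  weighting <- match.arg(weighting)
  if (bin_size < 1L) {
    stop("bin_alignments: bin_size must be >= 1", call. = FALSE)
  }
  lens <- setNames(width(bundle$seq), names(bundle$seq))
  nbin <- ceiling(lens / bin_size)
  aln <- tags$alignments
  tag_row <- match(aln$sequence, tags$tags$sequence)
  profiles <- list()
  for (L in tags$libraries) {
    w <- if (weighting == "reads") {
      as.numeric(tags$counts[tag_row, L])
    } else {
      as.numeric(tags$counts[tag_row, L] > 0L)
    }
    total <- if (weighting == "reads") {
      sum(tags$counts[, L])
    } else {
      sum(tags$counts[, L] > 0L)
    }
    prof <- list()
    for (ch in names(lens)) {
      nb <- nbin[[ch]]
      plus <- numeric(nb)
      minus <- numeric(nb)
      sel <- aln$chrom == ch & w > 0
      if (any(sel)) {
        bins <- floor((aln$start[sel] - 1L) / bin_size) + 1L
        str <- aln$strand[sel]
        ww <- w[sel]
        for (tgt in c("+", "-")) {
          ss <- str == tgt
          if (any(ss)) {
            acc <- tapply(ww[ss], bins[ss], sum)
            v <- numeric(nb)
            v[as.integer(names(acc))] <- acc
            if (tgt == "+") plus <- v else minus <- v
          }
        }
      }
      raw <- list(plus = plus, minus = minus)
      norm <- if (total > 0) {
        list(plus = plus / total, minus = minus / total)
      } else {
        raw
      }
      attr(norm, "raw") <- raw
      prof[[ch]] <- norm
    }
    profiles[[L]] <- structure(
      list(
        library = L, bin_size = as.integer(bin_size), total = total,
        profile = prof
      ),
      class = "BinProfile"
    )
  }
  profiles
}

#' Export coverage profiles as TSV matrices
#'
#' Writes, per chromosome, a histogram TSV (`bin_start`, then one
#' signed column per library and strand: plus-strand values are
#' positive, minus-strand values negative) and a heatmap matrix TSV
#' (rows = libraries in input order, columns = bins, value =
#' plus + minus magnitude).
#'
#' @param profiles list of `BinProfile`s sharing a bin size.
#' @param out_dir output directory.
#' @return named character vector of written paths.
#' @export
export_profiles <- function(profiles, out_dir) {
  sizes <- unique(vapply(profiles, `[[`, 1L, "bin_size"))
  if (length(sizes) != 1L) {
    stop("export_profiles: profiles have mixed bin sizes", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chroms <- names(profiles[[1]]$profile)
  libs <- vapply(profiles, `[[`, "", "library")
  paths <- character(0)
  for (ch in chroms) {
    nb <- length(profiles[[1]]$profile[[ch]]$plus)
    hist_df <- data.frame(bin_start = (seq_len(nb) - 1L) * sizes + 1L)
    hm <- matrix(0, length(libs), nb,
      dimnames = list(libs, paste0("bin", seq_len(nb)))
    )
    for (k in seq_along(profiles)) {
      pr <- profiles[[k]]$profile[[ch]]
      hist_df[[paste0(libs[k], "_plus")]] <- pr$plus
      hist_df[[paste0(libs[k], "_minus")]] <- -pr$minus
      hm[k, ] <- pr$plus + pr$minus
    }
    hp <- file.path(out_dir, sprintf("histogram_%s.tsv", ch))
    write.table(hist_df, hp, sep = "\t", quote = FALSE, row.names = FALSE)
    mp <- file.path(out_dir, sprintf("heatmap_%s.tsv", ch))
    write.table(
      data.frame(library = libs, hm, check.names = FALSE),
      mp,
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    paths[paste0("histogram_", ch)] <- hp
    paths[paste0("heatmap_", ch)] <- mp
  }
  paths
}
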