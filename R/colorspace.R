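# SOLiD colorspace (csfasta) encoding and decoding.
#
# Each color encodes a dinucleotide transition under the standard table
#   0: AA/CC/GG/TT   1: AC/CA/GT/TG   2: AG/GA/CT/TC   3: AT/TA/CG/GC
# which is XOR over the 2-bit base codes A=0, C=1, G=2, T=3. A read is
# a primer base followed by one color per sequencing cycle.

.BASE2BIT <- c(A = 0L, C = 1L, G = 2L, T = 3L)
.BIT2BASE <- c("A", "C", "G", "T")

#' Encode base sequences into SOLiD colorspace
#'
#' @param seqs character vector of DNA sequences (ACGT).
#' @param primer single primer base prepended before the first color
#'   (default `"T"`, the standard csfasta primer).
#' @return character vector of color strings (`[0-3]+`), one color per
#'   input base: color i encodes the transition from base i-1 (or the
#'   primer) to base i.
#' @export
solid_encode <- function(seqs, primer = "T") {
  stopifnot(primer %in% names(.BASE2BIT))
  vapply(seqs, function(s) {
    b <- .BASE2BIT[strsplit(s, "", fixed = TRUE)[[1]]]
    if (anyNA(b)) stop("solid_encode: sequence contains non-ACGT characters")
    prev <- c(.BASE2BIT[[primer]], b[-length(b)])
    paste(bitwXor(prev, b), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Decode SOLiD colorspace reads to base space
#'
#' Applies the dibase transition table cumulatively from the primer
#' base. The returned sequence excludes the primer.
#'
#' @param colors character vector of color strings (`[0-3]+`).
#' @param primer primer base (default `"T"`).
#' @return character vector of decoded DNA sequences, same lengths as
#'   the color strings.
#' @export
solid_decode <- function(colors, primer = "T") {
  stopifnot(primer %in% names(.BASE2BIT))
  vapply(colors, function(cs) {
    cc <- strsplit(cs, "", fixed = TRUE)[[1]]
    ci <- match(cc, c("0", "1", "2", "3")) - 1L
    if (anyNA(ci)) stop("solid_decode: invalid color symbol in '", cs, "'")
    b <- integer(length(ci))
    prev <- .BASE2BIT[[primer]]
    for (i in seq_along(ci)) {
      prev <- bitwXor(prev, ci[i])
      b[i] <- prev
    }
    paste(.BIT2BASE[b + 1L], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read a csfasta file
#'
#' @param path csfasta path (header lines starting with `#` are
#'   skipped; each record is a `>id` line followed by primer+colors).
#' @return data.frame with columns `id`, `primer`, `colors`.
#' @export
read_csfasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  hdr <- startsWith(lines, ">")
  ids <- sub("^>", "", lines[hdr])
  payload <- lines[!hdr]
  if (length(ids) != length(payload)) {
    stop("malformed csfasta: ", path, call. = FALSE)
  }
  data.frame(
    id = ids,
    primer = substr(payload, 1L, 1L),
    colors = substr(payload, 2L, nchar(payload)),
    stringsAsFactors = FALSE
  )
}

#' Write a csfasta file
#'
#' @param ids record identifiers.
#' @param primer primer base (recycled).
#' @param colors color strings.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_csfasta <- function(ids, primer, colors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# csfasta", con)
  writeLines(paste0(">", ids, "\n", primer, colors), con)
  invisible(path)
}
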