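# Hairpin folding: R surface over the dynamic-programming engine.

.normalize_rna <- function(seq) {
  s <- toupper(seq)
  s <- chartr("T", "U", s)
  if (grepl("[^ACGU]", s)) {
    stop("fold_hairpin: sequence contains characters outside ACGU/ACGT",
      call. = FALSE
    )
  }
  s
}

#' Fold a sequence into its minimum-energy hairpin structure
#'
#' Predicts a pseudoknot-free secondary structure under a simple
#' additive energy model: each base pair contributes GC -3.0, AU -2.0
#' or GU -1.0 kcal/mol, and every hairpin loop closure costs
#' +4.0 kcal/mol; interior loops, bulges and multiloop junctions are
#' free. The minimum hairpin loop is 3 unpaired nucleotides. The engine
#' is pluggable: any function with the same signature returning
#' `list(structure=, mfe=)` (e.g. a wrapper around a thermodynamic
#' folder) can be substituted wherever an `engine` argument is accepted.
#'
#' @param seq a DNA or RNA sequence (character scalar).
#' @return list with `structure` (dot-bracket string) and `mfe`
#'   (kcal/mol; 0 for an unpaired structure).
#' @examples
#' fold_hairpin("GGGGGGAAAAAAAAAACCCCCC") # 6 GC pairs closing a 10-nt loop
#' @export
fold_hairpin <- function(seq) {
  s <- .normalize_rna(seq)
  if (nchar(s) > 400L) {
    stop("fold_hairpin: sequence longer than 400 nt", call. = FALSE)
  }
  .fold_mfe_cpp(s)
}

#' Pairing table of a dot-bracket structure
#'
#' @param structure dot-bracket string (balanced `(`/`)`, `.` unpaired).
#' @return integer vector p where p[i] is the 1-based partner of
#'   position i, or NA if unpaired.
#' @export
pairing_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  p <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string", call. = FALSE)
  p
}

#' Energy of a given structure under the package energy model
#'
#' Independent re-scoring of a dot-bracket structure: sum of pair
#' energies plus +4 kcal/mol per hairpin loop (a pair with no pairs
#' nested inside it).
#'
#' @param seq sequence (DNA or RNA).
#' @param structure dot-bracket string of the same length.
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, structure) {
  s <- strsplit(.normalize_rna(seq), "", fixed = TRUE)[[1]]
  stopifnot(length(s) == nchar(structure))
  p <- pairing_table(structure)
  pe <- c(
    "GC" = -3, "CG" = -3, "AU" = -2, "UA" = -2, "GU" = -1, "UG" = -1
  )
  e <- 0
  paired <- which(!is.na(p) & p > seq_along(p))
  for (i in paired) {
    j <- p[i]
    key <- paste0(s[i], s[j])
    if (is.na(pe[key])) stop("non-canonical pair ", key, call. = FALSE)
    e <- e + pe[[key]]
    inner <- if (j - i > 1) p[(i + 1):(j - 1)] else integer(0)
    if (all(is.na(inner))) e <- e + 4 # hairpin loop closure
  }
  e
}
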