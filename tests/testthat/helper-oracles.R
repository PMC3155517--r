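# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive re-implementations kept separate from the package
# code paths they check.

.ORACLE_PAIRS <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)

oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% names(.ORACLE_PAIRS)
}

# exhaustive enumeration of all pseudoknot-free structures (minimum
# hairpin loop 3) as 2 x npairs matrices
oracle_enum_structs <- function(ch, i, j) {
  if (j - i < 4L) {
    return(list(matrix(integer(), 2L, 0L)))
  }
  out <- list()
  for (s1 in oracle_enum_structs(ch, i + 1L, j)) {
    out[[length(out) + 1L]] <- s1
  }
  for (k in (i + 4L):j) {
    if (!oracle_can_pair(ch[i], ch[k])) next
    inner <- oracle_enum_structs(ch, i + 1L, k - 1L)
    right <- oracle_enum_structs(ch, k + 1L, j)
    for (si in inner) {
      for (sr in right) {
        out[[length(out) + 1L]] <- cbind(matrix(c(i, k), 2L), si, sr)
      }
    }
  }
  out
}

# energy of one enumerated structure: pair energies plus +4 per
# hairpin loop (pair with nothing nested inside)
oracle_score_struct <- function(ch, pm) {
  if (!ncol(pm)) {
    return(0)
  }
  e <- 0
  for (c1 in seq_len(ncol(pm))) {
    i <- pm[1L, c1]
    j <- pm[2L, c1]
    e <- e + .ORACLE_PAIRS[[paste0(ch[i], ch[j])]]
    inside <- pm[1L, ] > i & pm[2L, ] < j
    if (!any(inside)) e <- e + 4
  }
  e
}

oracle_fold_min <- function(seq) {
  ch <- strsplit(chartr("T", "U", toupper(seq)), "", fixed = TRUE)[[1]]
  st <- oracle_enum_structs(ch, 1L, length(ch))
  min(vapply(st, function(x) oracle_score_struct(ch, x), 1))
}

# brute-force greedy substring clustering, plain double loop
oracle_cluster <- function(inserts, libraries, len_sim = 0.8) {
  agg <- table(inserts, libraries)
  seqs <- rownames(agg)
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]
  reps <- character(0)
  assign <- character(length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    found <- NA_character_
    for (r in reps) {
      if (nchar(s) / nchar(r) >= len_sim && grepl(s, r, fixed = TRUE)) {
        found <- r
        break
      }
    }
    if (is.na(found)) {
      reps <- c(reps, s)
      assign[i] <- s
    } else {
      assign[i] <- found
    }
  }
  # per-representative per-library counts
  out <- list()
  for (r in reps) {
    members <- seqs[assign == r]
    cnt <- colSums(agg[members, , drop = FALSE])
    out[[r]] <- cnt
  }
  out
}

# brute-force best ungapped local alignment score (+1/-3), both
# orientations of b, plain loops
oracle_ungapped_score <- function(a, b) {
  one <- function(x, y) {
    xc <- strsplit(x, "", fixed = TRUE)[[1]]
    yc <- strsplit(y, "", fixed = TRUE)[[1]]
    best <- 0
    for (off in (-(length(xc) - 1L)):(length(yc) - 1L)) {
      run <- 0
      for (i in seq_along(xc)) {
        j <- i + off
        if (j < 1L || j > length(yc)) next
        run <- run + if (xc[i] == yc[j]) 1 else -3
        if (run < 0) run <- 0
        if (run > best) best <- run
      }
    }
    best
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  max(one(a, b), one(a, rc))
}

# exhaustive position-by-position target-site checker
oracle_animal_sites <- function(mirna, transcript) {
  m <- chartr("U", "T", toupper(mirna))
  tx <- chartr("U", "T", toupper(transcript))
  motif <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(m, 2L, 7L))
  ))
  tch <- strsplit(tx, "", fixed = TRUE)[[1]]
  mch <- strsplit(motif, "", fixed = TRUE)[[1]]
  hits <- integer(0)
  if (length(tch) >= 6L) {
    for (o in 0:(length(tch) - 6L)) {
      if (all(tch[(o + 1L):(o + 6L)] == mch)) hits <- c(hits, o + 1L)
    }
  }
  hits
}

oracle_plant_sites <- function(mirna, transcript, energy_max = -20) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- strsplit(chartr("U", "T", toupper(mirna)), "", fixed = TRUE)[[1]]
  tx <- strsplit(chartr("U", "T", toupper(transcript)), "", fixed = TRUE)[[1]]
  L <- length(m)
  res <- list()
  if (length(tx) >= L) {
    for (o in 0:(length(tx) - L)) {
      seed_mm <- 0L
      rest_mm <- 0L
      e <- 0
      for (j in seq_len(L)) {
        tb <- tx[o + L - j + 1L]
        mb <- m[j]
        if (comp[[mb]] == tb) {
          e <- e + if (mb %in% c("G", "C")) -3 else -2
        } else if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) {
          e <- e - 1
          if (j <= 8L) seed_mm <- seed_mm + 1L else rest_mm <- rest_mm + 1L
        } else {
          if (j <= 8L) seed_mm <- seed_mm + 1L else rest_mm <- rest_mm + 1L
        }
      }
      if (seed_mm <= 1L && rest_mm <= 3L && e <= energy_max) {
        res[[length(res) + 1L]] <- c(
          start = o + 1L, seed = seed_mm,
          rest = rest_mm, energy = e
        )
      }
    }
  }
  res
}

rand_dna_str <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
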