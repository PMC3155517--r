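# End-to-end orchestration: run every stage in order on a config,
# write per-stage TSVs, and score recovery against a truth manifest.

#' Pipeline configuration
#'
#' Paths to all inputs plus every stage threshold. Defaults are the
#' package's standard thresholds: precursor flank 100 nt, loop >= 10,
#' bulge <= 3, MFE < -20 kcal/mol, clustering at 100 % identity with
#' 0.8 length similarity, degradation coverage 0.70, at most 1
#' alignment mismatch, 10 kb bins, 9-of-10 seed matching, E-value
#' 1e-5, hybrid energy <= -20 kcal/mol.
#'
#' @param genome,gff,repeats,ncrna,ncrna_ref,known_mirnas,go_map input
#'   paths (`NULL` entries are allowed where a stage can be skipped).
#' @param reads_454 named list: library -> FASTA path.
#' @param reads_solid named list: library -> csfasta path.
#' @param out_dir output directory.
#' @param truth optional truth manifest TSV (enables recovery scoring).
#' @param min_insert,max_mismatch,len_sim,degr_cov,degr_identity,bin_size,
#'   evalue_max,hybrid_max stage thresholds.
#' @param thresholds a [mirna_thresholds()] list.
#' @param seed random seed recorded with the run (the analysis itself
#'   is deterministic; only simulation consumes randomness).
#' @return object of class `run_config`.
#' @export
run_config <- function(genome, gff, repeats = NULL, ncrna = NULL,
                       ncrna_ref = NULL, known_mirnas = NULL,
                       go_map = NULL, reads_454 = list(),
                       reads_solid = list(), out_dir = "srna_out",
                       truth = NULL,
                       min_insert = 16L, max_mismatch = 1L,
                       len_sim = 0.8, degr_cov = 0.70,
                       degr_identity = 0.90, bin_size = 10000L,
                       evalue_max = 1e-5, hybrid_max = -20,
                       thresholds = mirna_thresholds(), seed = 17L) {
  cfg <- list(
    genome = genome, gff = gff, repeats = repeats, ncrna = ncrna,
    ncrna_ref = ncrna_ref, known_mirnas = known_mirnas, go_map = go_map,
    reads_454 = reads_454, reads_solid = reads_solid, out_dir = out_dir,
    truth = truth, min_insert = min_insert, max_mismatch = max_mismatch,
    len_sim = len_sim, degr_cov = degr_cov, degr_identity = degr_identity,
    bin_size = bin_size, evalue_max = evalue_max, hybrid_max = hybrid_max,
    thresholds = thresholds, seed = as.integer(seed)
  )
  structure(cfg, class = "run_config")
}

.check_config <- function(config) {
  need <- c(config$genome, config$gff, unlist(config$reads_454),
    unlist(config$reads_solid))
  opt <- c(
    config$repeats, config$ncrna, config$ncrna_ref,
    config$known_mirnas, config$go_map, config$truth
  )
  missing <- c(need, opt)[!file.exists(c(need, opt))]
  if (length(missing)) {
    stop("run_all: missing input file(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Run the whole pipeline
#'
#' Executes preprocess -> coverage -> miRNA -> siRNA -> targets in
#' order, writing every per-stage TSV under `config$out_dir`. The run
#' is deterministic for a fixed configuration. Per-stage input/output
#' counts are collected in the returned `log`.
#'
#' @param config a [run_config()].
#' @return list with `tags`, `stats`, `profiles`, `mirna_calls`,
#'   `known_hits`, `sirna`, `rasirna`, `cross_match`, `targets`,
#'   `go_ratios`, `recovery` (if a truth manifest was given), `log`,
#'   and `files` (paths of everything written).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .check_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  bundle <- read_genome(config$genome, config$gff, config$repeats,
    config$ncrna)

  reads_454 <- lapply(config$reads_454, function(p) {
    as.character(Biostrings::readDNAStringSet(p))
  })
  solid <- lapply(config$reads_solid, read_csfasta)

  pp <- preprocess_reads(bundle,
    reads_454 = reads_454, solid = solid,
    ncrna_ref = config$ncrna_ref, min_insert = config$min_insert,
    max_mismatch = config$max_mismatch, len_sim = config$len_sim,
    degr_cov = config$degr_cov, degr_identity = config$degr_identity
  )
  tags <- pp$tags
  files["tags"] <- file.path(out, "tags.tsv")
  write_tag_table(tags, files["tags"])
  files["rejected"] <- file.path(out, "rejected.tsv")
  write.table(pp$rejected, files["rejected"],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  for (nm in c("length", "first_nt")) {
    f <- file.path(out, sprintf("stats_%s.tsv", nm))
    write.table(pp$stats[[nm]], f, sep = "\t", quote = FALSE,
      row.names = FALSE)
    files[paste0("stats_", nm)] <- f
  }

  profiles <- bin_alignments(tags, bundle, bin_size = config$bin_size)
  cov_files <- export_profiles(profiles, file.path(out, "coverage"))
  files <- c(files, cov_files)

  calls <- predict_mirnas(tags, bundle, thresholds = config$thresholds)
  files["mirna_calls"] <- file.path(out, "mirna_calls.tsv")
  write.table(calls, files["mirna_calls"],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  known_hits <- if (!is.null(config$known_mirnas) && nrow(calls)) {
    match_known_mirnas(calls, config$known_mirnas)
  } else {
    data.frame(
      sequence = character(), known = character(), offset = integer(),
      mismatches = integer(), stringsAsFactors = FALSE
    )
  }
  files["known_hits"] <- file.path(out, "known_hits.tsv")
  write.table(known_hits, files["known_hits"],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )

  sirna <- sirna_distribution(tags, bundle,
    mirna_sequences = c(
      calls$sequence,
      calls$star_sequence[!is.na(calls$star_sequence)]
    )
  )
  files["sirna_classes"] <- file.path(out, "sirna_calls.tsv")
  write.table(sirna$classes, files["sirna_classes"],
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  files["distribution"] <- file.path(out, "distribution_summary.tsv")
  write.table(sirna$summary_tags, files["distribution"],
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  rasirna <- call_rasirna(tags, bundle$repeats)
  files["family_table"] <- file.path(out, "family_table.tsv")
  write.table(rasirna$family_table, files["family_table"],
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  # cross-library matching of the per-library rasiRNA candidate sets
  ras_by_lib <- lapply(tags$libraries, function(L) {
    present <- tags$tags$sequence[tags$counts[, L] > 0L]
    intersect(rasirna$calls$sequence, present)
  })
  names(ras_by_lib) <- tags$libraries
  cm_rows <- list()
  for (a in tags$libraries) {
    for (b in tags$libraries) {
      if (a == b) next
      if (!length(ras_by_lib[[a]]) || !length(ras_by_lib[[b]])) next
      cm <- cross_library_match(ras_by_lib[[a]], ras_by_lib[[b]],
        evalue_max = config$evalue_max
      )
      cm_rows[[paste(a, b)]] <- data.frame(
        query = a, subject = b, fraction = cm$fraction,
        stringsAsFactors = FALSE
      )
    }
  }
  cross_match <- if (length(cm_rows)) {
    do.call(rbind, c(cm_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(
      query = character(), subject = character(), fraction = numeric(),
      stringsAsFactors = FALSE
    )
  }
  files["cross_match"] <- file.path(out, "cross_match.tsv")
  write.table(cross_match, files["cross_match"],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )

  transcripts <- transcript_sequences(bundle)
  mirseqs <- setNames(calls$sequence, paste0("cand", seq_len(nrow(calls))))
  targets <- predict_targets(mirseqs, transcripts,
    energy_max = config$hybrid_max
  )
  files["targets"] <- file.path(out, "targets.tsv")
  write.table(targets$hits, files["targets"],
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  files["target_summary"] <- file.path(out, "target_summary.tsv")
  write.table(targets$summary, files["target_summary"],
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  go_ratios <- NULL
  if (!is.null(config$go_map) && nrow(targets$hits)) {
    gm <- read.delim(config$go_map,
      header = FALSE,
      col.names = c("gene_id", "term"), stringsAsFactors = FALSE
    )
    go_ratios <- go_ratio(
      unique(targets$hits$transcript_id), gm,
      transcripts$transcript_id
    )
    files["go_ratio"] <- file.path(out, "go_ratio.tsv")
    write.table(go_ratios, files["go_ratio"],
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }

  recovery <- NULL
  if (!is.null(config$truth)) {
    truth_loci <- read.delim(config$truth, stringsAsFactors = FALSE)
    recovery <- score_recovery(calls, sirna$classes, tags, truth_loci)
    files["recovery"] <- file.path(out, "recovery.tsv")
    write.table(recovery, files["recovery"],
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }

  log <- pp$log
  log$unique_tags <- nrow(tags$tags)
  res <- list(
    tags = tags, stats = pp$stats, profiles = profiles,
    mirna_calls = calls, known_hits = known_hits, sirna = sirna,
    rasirna = rasirna, cross_match = cross_match, targets = targets,
    go_ratios = go_ratios, recovery = recovery, log = log,
    preprocess = pp, files = files
  )
  invisible(res)
}

.reciprocal_overlap <- function(s1, e1, s2, e2) {
  inter <- min(e1, e2) - max(s1, s2) + 1L
  if (inter <= 0L) {
    return(0)
  }
  min(inter / (e1 - s1 + 1L), inter / (e2 - s2 + 1L))
}

#' Score pipeline calls against a planted-truth manifest
#'
#' A planted miRNA locus counts as recovered when a miRNA call's
#' mature interval overlaps the truth interval reciprocally by at
#' least `min_overlap` on the same chromosome and strand; planted
#' rasiRNA and antisense loci count as recovered when a tag classified
#' `rasirna` / `nat-antisense` has an alignment passing the same
#' reciprocal-overlap rule. False positives are calls matching no
#' planted locus of the class.
#'
#' @param mirna_calls data.frame from [predict_mirnas()].
#' @param sirna_classes data.frame from [sirna_distribution()] (`classes`).
#' @param tags the mapped `tag_set` (for alignments).
#' @param truth_loci truth manifest data.frame (`loci` of
#'   [generate_genome()], or the TSV re-read).
#' @param min_overlap reciprocal overlap threshold (default 0.9).
#' @return data.frame with one row per class: tp, fn, fp, precision,
#'   recall (NA precision when no calls were made).
#' @export
score_recovery <- function(mirna_calls, sirna_classes, tags, truth_loci,
                           min_overlap = 0.9) {
  aln <- tags$alignments
  cls_of <- setNames(sirna_classes$class, sirna_classes$sequence)

  match_truth <- function(calls_df, truth_df) {
    # calls_df: chrom/start/end/strand rows
    recovered <- logical(nrow(truth_df))
    call_hit <- logical(nrow(calls_df))
    for (ti in seq_len(nrow(truth_df))) {
      tr <- truth_df[ti, ]
      for (ci in seq_len(nrow(calls_df))) {
        cr <- calls_df[ci, ]
        if (cr$chrom != tr$chrom || cr$strand != tr$strand) next
        if (.reciprocal_overlap(cr$start, cr$end, tr$start, tr$end) >=
          min_overlap) {
          recovered[ti] <- TRUE
          call_hit[ci] <- TRUE
        }
      }
    }
    list(recovered = recovered, call_hit = call_hit)
  }

  rows <- list()
  # --- miRNA ---
  truth_mir <- truth_loci[truth_loci$type == "mirna", , drop = FALSE]
  mc <- mirna_calls[, c("chrom", "start", "end", "strand"), drop = FALSE]
  mm <- match_truth(mc, truth_mir)
  rows$mirna <- data.frame(
    class = "mirna", planted = nrow(truth_mir),
    tp = sum(mm$recovered), fn = sum(!mm$recovered),
    fp = sum(!mm$call_hit),
    stringsAsFactors = FALSE
  )
  # --- rasiRNA and antisense: calls are classified tag alignments ---
  for (spec in list(
    list(class = "rasirna", truth_type = "rasirna", call_class = "rasirna"),
    list(
      class = "natsirna", truth_type = "natsirna",
      call_class = "nat-antisense"
    )
  )) {
    truth_df <- truth_loci[truth_loci$type == spec$truth_type, ,
      drop = FALSE
    ]
    call_seqs <- names(cls_of)[cls_of == spec$call_class]
    calls_df <- aln[aln$sequence %in% call_seqs, , drop = FALSE]
    mm <- match_truth(calls_df, truth_df)
    # fp counted over tags (not alignments): a tag is a false positive
    # when none of its alignments matches a planted locus
    hit_seq <- unique(calls_df$sequence[mm$call_hit])
    fp <- length(setdiff(call_seqs, hit_seq))
    rows[[spec$class]] <- data.frame(
      class = spec$class, planted = nrow(truth_df),
      tp = sum(mm$recovered), fn = sum(!mm$recovered), fp = fp,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$recall <- ifelse(out$planted > 0, out$tp / out$planted, NA_real_)
  n_calls <- out$tp + out$fp
  out$precision <- ifelse(n_calls > 0, out$tp / n_calls, NA_real_)
  out
}

#' One-command synthetic demonstration run
#'
#' Generates the synthetic dataset for `config`, writes it under
#' `dir/sim`, runs the full pipeline on it under `dir/out`, and scores
#' recovery against the planted truth.
#'
#' @param config a [sim_config()].
#' @param dir working directory for the demo.
#' @return the [run_all()] result (with `recovery` filled in).
#' @export
run_synthetic_demo <- function(config = sim_config(), dir = tempfile("srna_demo")) {
  gen <- generate_genome(config)
  reads <- simulate_reads(gen$bundle, gen$truth, config)
  paths <- write_sim_data(gen$bundle, gen$truth, reads, file.path(dir, "sim"))
  libs454 <- config$libraries[config$platforms == "454"]
  libssol <- config$libraries[config$platforms == "solid"]
  rc <- run_config(
    genome = paths[["genome"]], gff = paths[["genes"]],
    repeats = paths[["repeats"]], ncrna = paths[["ncrna"]],
    ncrna_ref = paths[["ncrna_ref"]], known_mirnas = paths[["known"]],
    go_map = paths[["go"]],
    reads_454 = setNames(
      as.list(paths[paste0("reads_", libs454)]), libs454
    ),
    reads_solid = setNames(
      as.list(paths[paste0("reads_", libssol)]), libssol
    ),
    out_dir = file.path(dir, "out"),
    truth = paths[["truth"]],
    seed = config$seed
  )
  run_all(rc)
}
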