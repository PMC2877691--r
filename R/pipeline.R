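.as_reference <- function(reference) {
  if (inherits(reference, "bs_reference")) return(reference)
  if (is.list(reference) && all(c("id", "sequence") %in% names(reference))) {
    return(convert_reference(reference$id, reference$sequence))
  }
  if (is.character(reference) && length(reference) == 1L) {
    if (file.exists(reference)) {
      r <- read_reference(reference)
      return(convert_reference(r$id, r$sequence))
    }
    return(convert_reference("reference", reference))
  }
  stop("cannot interpret `reference`: give a path, a (id, sequence) list, ",
       "or a bs_reference", call. = FALSE)
}

.as_reads <- function(reads, ab1 = FALSE) {
  if (is.character(reads) && length(reads) == 1L) return(read_reads(reads, ab1 = ab1))
  if (is.data.frame(reads) && all(c("read_id", "sequence") %in% names(reads))) {
    tbl <- tibble::as_tibble(reads)
    if (!"source" %in% names(tbl)) tbl$source <- "fasta"
    tbl$sequence <- vapply(tbl$sequence, .clean_read_seq, character(1),
                           USE.NAMES = FALSE)
    return(tbl)
  }
  stop("cannot interpret `reads`: give a path or a data frame with ",
       "read_id and sequence columns", call. = FALSE)
}

.empty_calls <- function(ref) {
  structure(
    list(sites = ref$cpg_pos, clone_ids = character(0),
         calls = matrix("X", 0L, length(ref$cpg_pos),
                        dimnames = list(NULL, as.character(ref$cpg_pos)))),
    class = "bs_calls"
  )
}

.subset_calls <- function(calls, ids) {
  calls$clone_ids <- ids
  calls$calls <- calls$calls[ids, , drop = FALSE]
  calls
}

.subset_alignment <- function(aln, ids) {
  aln$rows <- aln$rows[ids]
  aln$orientations <- aln$orientations[ids]
  aln
}

#' Run the unique-sequence analysis pipeline
#'
#' End-to-end analysis of subcloned bisulfite-PCR reads against a unique
#' genomic reference: read orientation and vector trimming, shared alignment
#' frame construction, quality filtering (identity, conversion rate, gaps,
#' N-at-cytosine), CpG methylation calling, clonal duplicate filtering, and
#' summary statistics.
#'
#' @param reference Reference input: a FASTA path, a `list(id, sequence)`, a
#'   bare sequence string, or a `bs_reference`.
#' @param reads Reads input: a path accepted by [read_reads()] or a data
#'   frame with `read_id` and `sequence` columns.
#' @param filter A [filter_config()] (default unique-mode thresholds
#'   90/95/20, N-at-cytosine <= 3).
#' @param align [align_params()].
#' @param align_mode `"auto"`, `"stitched"`, or `"msa"` (see
#'   [build_alignment()]).
#' @param sort Sort clones by descending methylation level (default `TRUE`).
#' @param min_site_n Minimal informative reads for per-site reporting
#'   (default 5).
#' @param outdir If non-`NULL`, result files are written there via
#'   [write_outputs()].
#' @param ab1 Enable AB1 trace input.
#' @return A `bs_result` object: list with `ref`, `alignment`
#'   (`bs_alignment` or `NULL` if nothing aligned), `quality` (metrics +
#'   filter decisions tibble), `clonal` (clonal decisions tibble),
#'   `calls_all` (pre-clonal-filter `bs_calls`), `calls` (final
#'   `bs_calls`), `summary` (`bs_summary`), `filter_log` (tibble), `config`.
#' @export
run_unique <- function(reference, reads, filter = filter_config("unique"),
                       align = align_params(),
                       align_mode = c("auto", "stitched", "msa"),
                       sort = TRUE, min_site_n = 5L, outdir = NULL,
                       ab1 = FALSE) {
  align_mode <- match.arg(align_mode)
  ref <- .as_reference(reference)
  reads_tbl <- .as_reads(reads, ab1)

  oriented <- purrr::pmap(reads_tbl[c("read_id", "sequence")], function(read_id, sequence) {
    orient_and_trim(read_id, sequence, ref, align)
  })
  ok <- purrr::keep(oriented, `[[`, "ok")
  aln_log <- tibble::tibble(
    read_id = vapply(oriented, `[[`, character(1), "read_id"),
    stage = "alignment",
    passed = vapply(oriented, `[[`, logical(1), "ok"),
    reasons = ifelse(vapply(oriented, `[[`, logical(1), "ok"), "", "unalignable")
  )

  config <- list(filter = filter, align = align, align_mode = align_mode,
                 sort = sort, min_site_n = as.integer(min_site_n))

  if (length(ok) == 0L) {
    res <- .finalize_unique(ref, NULL, NULL,
                            quality = tibble::tibble(),
                            clonal = classify_clonal(list(), filter$clonal_mode),
                            calls_all = .empty_calls(ref),
                            kept_ids = character(0),
                            filter_log = aln_log, config = config)
    if (!is.null(outdir)) write_outputs(res, outdir)
    return(res)
  }

  aln <- build_alignment(ok, ref, align_mode, align)
  quality <- apply_filters(compute_metrics(aln), filter)
  qual_log <- tibble::tibble(read_id = quality$read_id, stage = "quality",
                             passed = quality$passed, reasons = quality$reasons)
  passed_ids <- quality$read_id[quality$passed]

  calls_all <- if (length(passed_ids) > 0) call_all(aln, passed_ids) else .empty_calls(ref)
  clonal <- classify_clonal(cytosine_patterns(aln, calls_all), filter$clonal_mode)
  clonal_log <- tibble::tibble(read_id = clonal$read_id, stage = "clonal",
                               passed = clonal$kept,
                               reasons = ifelse(clonal$kept, "", clonal$reason))
  kept_ids <- clonal$read_id[clonal$kept]

  res <- .finalize_unique(ref, aln, oriented, quality, clonal, calls_all, kept_ids,
                          dplyr::bind_rows(aln_log, qual_log, clonal_log), config)
  if (!is.null(outdir)) write_outputs(res, outdir)
  res
}

.finalize_unique <- function(ref, aln, oriented, quality, clonal, calls_all,
                             kept_ids, filter_log, config) {
  calls <- if (length(kept_ids) > 0) .subset_calls(calls_all, kept_ids) else .empty_calls(ref)
  if (config$sort) calls <- sort_by_methylation(calls)
  structure(
    list(ref = ref, alignment = aln, oriented = oriented, quality = quality,
         clonal = clonal, calls_all = calls_all, calls = calls,
         summary = summarize_methylation(calls, config$min_site_n),
         filter_log = filter_log, config = config),
    class = "bs_result"
  )
}

#' @export
print.bs_result <- function(x, ...) {
  cat(sprintf("<bs_result> %s: %d reads in, %d passed quality, %d kept after clonal filter\n",
              x$ref$id,
              sum(x$filter_log$stage == "alignment"),
              if (nrow(x$quality)) sum(x$quality$passed) else 0L,
              length(x$calls$clone_ids)))
  print(x$summary)
  invisible(x)
}

#' Run the repeat (consensus) analysis pipeline
#'
#' Analysis of bisulfite reads from a repetitive element against a family
#' consensus: alignment and quality filtering with repeat-mode thresholds,
#' per-read methylated-CpG extraction at consensus and non-consensus
#' positions (strategy 1), and the mutation-corrected overall methylation
#' estimate from consensus-CpG dinucleotide tallies (strategy 2). The frame
#' is always built by stitched pairwise alignment (the consensus is the
#' center); clonal filtering is not applied, since repeat reads originate
#' from thousands of genomic copies.
#'
#' @param consensus Consensus input (as `reference` in [run_unique()]).
#' @param reads Reads input (as in [run_unique()]).
#' @param filter A [filter_config()] (default repeat-mode thresholds 70 /
#'   3-per-100bp / 20).
#' @param align [align_params()].
#' @param outdir If non-`NULL`, write result files.
#' @param ab1 Enable AB1 trace input.
#' @return A `bs_repeat_result`: list with `ref`, `alignment`, `quality`,
#'   `repeat_reads` (list of `bs_repeat_read`), `summaries` (see
#'   [repeat_summaries()]), `tally` (`bs_dinuc_tally`), `yang_pct`,
#'   `naive_pct`, `filter_log`, `config`.
#' @export
run_repeat <- function(consensus, reads, filter = filter_config("repeat"),
                       align = align_params(), outdir = NULL, ab1 = FALSE) {
  ref <- .as_reference(consensus)
  reads_tbl <- .as_reads(reads, ab1)

  oriented <- purrr::pmap(reads_tbl[c("read_id", "sequence")], function(read_id, sequence) {
    orient_and_trim(read_id, sequence, ref, align)
  })
  ok <- purrr::keep(oriented, `[[`, "ok")
  aln_log <- tibble::tibble(
    read_id = vapply(oriented, `[[`, character(1), "read_id"),
    stage = "alignment",
    passed = vapply(oriented, `[[`, logical(1), "ok"),
    reasons = ifelse(vapply(oriented, `[[`, logical(1), "ok"), "", "unalignable")
  )
  config <- list(filter = filter, align = align)

  aln <- NULL
  quality <- tibble::tibble()
  passed_ids <- character(0)
  if (length(ok) > 0L) {
    aln <- build_alignment(ok, ref, "stitched", align)
    quality <- apply_filters(compute_metrics(aln), filter)
    passed_ids <- quality$read_id[quality$passed]
  }
  qual_log <- if (nrow(quality)) {
    tibble::tibble(read_id = quality$read_id, stage = "quality",
                   passed = quality$passed, reasons = quality$reasons)
  } else tibble::tibble()

  repeat_reads <- list()
  summaries <- NULL
  tally <- NULL
  yang_pct <- NA_real_
  naive_pct <- NA_real_
  if (length(passed_ids) > 0L) {
    sub <- .subset_alignment(aln, passed_ids)
    repeat_reads <- lapply(passed_ids, function(id) extract_methylated_cpgs(sub, id))
    summaries <- repeat_summaries(repeat_reads)
    tally <- tally_consensus_dinucleotides(sub)
    yang_pct <- tryCatch(yang_overall_methylation(tally), error = function(e) NA_real_)
    naive_pct <- tryCatch(naive_overall_methylation(tally), error = function(e) NA_real_)
  }

  res <- structure(
    list(ref = ref, alignment = aln, quality = quality,
         repeat_reads = repeat_reads, summaries = summaries, tally = tally,
         yang_pct = yang_pct, naive_pct = naive_pct,
         filter_log = dplyr::bind_rows(aln_log, qual_log), config = config),
    class = "bs_repeat_result"
  )
  if (!is.null(outdir)) write_outputs(res, outdir)
  res
}

#' @export
print.bs_repeat_result <- function(x, ...) {
  cat(sprintf("<bs_repeat_result> %s: %d reads analyzed\n",
              x$ref$id, length(x$repeat_reads)))
  if (!is.null(x$tally)) {
    cat(sprintf("  tallies CG=%d TG=%d CA=%d TA=%d other=%d\n",
                x$tally$n_CG, x$tally$n_TG, x$tally$n_CA, x$tally$n_TA,
                x$tally$n_other))
    cat(sprintf("  overall methylation: %.1f%% (mutation-corrected), %.1f%% (naive)\n",
                x$yang_pct, x$naive_pct))
  }
  invisible(x)
}

# ---- output writing -------------------------------------------------------

.write_alignment_fasta <- function(aln, path) {
  if (is.null(aln)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- c(paste0(">", aln$ref$id, "|reference"), aln$ref_row,
             unlist(lapply(names(aln$rows), function(id) c(paste0(">", id), aln$rows[[id]]))))
  writeLines(lines, path)
  invisible(path)
}

.json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Write result files
#'
#' Writes the analysis artifacts to a directory and returns a manifest. For
#' a unique-mode result: the gapped alignment (FASTA), a plain-text
#' annotation of calls and conversion artifacts, the call matrix TSV
#' (clones x CpG positions, cells M/U/X), per-site and per-clone summary
#' TSVs, a run summary JSON, the filter log, and the clonal report. For a
#' repeat-mode result: the alignment, per-read TSV, count histogram TSV,
#' estimator JSON, and filter log. All TSVs are tab-delimited with `.`
#' decimals and `NA` for suppressed values; outputs are byte-identical
#' across reruns on identical inputs.
#'
#' @param result A `bs_result` or `bs_repeat_result`.
#' @param outdir Output directory (created if missing).
#' @param ... Unused.
#' @return A tibble manifest (`artifact`, `file`), invisibly.
#' @export
write_outputs <- function(result, outdir, ...) UseMethod("write_outputs")

#' @export
write_outputs.bs_result <- function(result, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  .write_alignment_fasta(result$alignment, p("alignment.fasta"))

  calls <- result$calls
  ann <- vapply(seq_along(calls$clone_ids), function(i) {
    id <- calls$clone_ids[i]
    pat <- paste(calls$calls[i, ], collapse = "")
    arts <- if (!is.null(result$alignment)) {
      pt <- cytosine_pattern(result$alignment, id, calls)
      paste(pt$positions[!pt$is_cpg & pt$symbols == "C"], collapse = ";")
    } else ""
    sprintf("%s\tcalls:%s\tartifacts:%s", id, pat, arts)
  }, character(1))
  writeLines(c("# clone\tCpG calls (M/U/X, reference order)\tunconverted non-CpG cytosine positions", ann),
             p("annotation.txt"))

  mat <- tibble::as_tibble(calls$calls, .name_repair = ~ paste0("pos_", calls$sites))
  mat <- dplyr::bind_cols(tibble::tibble(clone_id = calls$clone_ids), mat)
  readr::write_tsv(mat, p("calls.tsv"))

  s <- result$summary
  readr::write_tsv(s$per_site, p("per_site.tsv"))
  readr::write_tsv(s$per_clone, p("per_clone.tsv"))
  readr::write_tsv(result$filter_log, p("filter_log.tsv"))
  readr::write_tsv(result$clonal, p("clonal.tsv"))

  cfg <- result$config$filter
  .json_write(list(
    reference = result$ref$id,
    mode = "unique",
    n_reads_input = sum(result$filter_log$stage == "alignment"),
    n_unalignable = sum(result$filter_log$stage == "alignment" & !result$filter_log$passed),
    n_passed_quality = if (nrow(result$quality)) sum(result$quality$passed) else 0L,
    n_kept = length(calls$clone_ids),
    n_cpg_sites = length(calls$sites),
    overall_methylation_pct = s$overall_pct,
    informative_pct = s$informative_pct,
    min_site_n = s$min_site_n,
    alignment_mode = if (!is.null(result$alignment)) result$alignment$mode else NA,
    thresholds = list(min_identity = cfg$min_identity,
                      min_conversion = cfg$min_conversion,
                      max_gap_pct = cfg$max_gap_pct,
                      max_n_at_cytosine = cfg$max_n_at_cytosine,
                      clonal_mode = cfg$clonal_mode)
  ), p("summary.json"))

  manifest <- tibble::tibble(
    artifact = c("alignment", "annotation", "call_matrix", "per_site_summary",
                 "per_clone_summary", "run_summary", "filter_log", "clonal_report"),
    file = c(p("alignment.fasta"), p("annotation.txt"), p("calls.tsv"),
             p("per_site.tsv"), p("per_clone.tsv"), p("summary.json"),
             p("filter_log.tsv"), p("clonal.tsv"))
  )
  invisible(manifest)
}

#' @export
write_outputs.bs_repeat_result <- function(result, outdir, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  .write_alignment_fasta(result$alignment, p("alignment.fasta"))
  if (!is.null(result$summaries)) {
    readr::write_tsv(result$summaries$per_read, p("per_read.tsv"))
    readr::write_tsv(result$summaries$histogram, p("histogram.tsv"))
  } else {
    readr::write_tsv(tibble::tibble(read_id = character(), meth_count = integer(),
                                    per100bp = double(), aligned_span = integer(),
                                    positions = character()), p("per_read.tsv"))
    readr::write_tsv(tibble::tibble(meth_count = integer(), n_reads = integer()),
                     p("histogram.tsv"))
  }
  readr::write_tsv(result$filter_log, p("filter_log.tsv"))
  .json_write(list(
    consensus = result$ref$id,
    mode = "repeat",
    n_reads_input = sum(result$filter_log$stage == "alignment"),
    n_analyzed = length(result$repeat_reads),
    mean_meth_cpg_per_100bp = if (!is.null(result$summaries)) result$summaries$mean_per100bp else NA,
    tallies = if (!is.null(result$tally)) {
      list(CG = result$tally$n_CG, TG = result$tally$n_TG, CA = result$tally$n_CA,
           TA = result$tally$n_TA, other = result$tally$n_other)
    } else NULL,
    overall_methylation_pct_corrected = result$yang_pct,
    overall_methylation_pct_naive = result$naive_pct
  ), p("estimator.json"))

  manifest <- tibble::tibble(
    artifact = c("alignment", "per_read", "histogram", "estimator", "filter_log"),
    file = c(p("alignment.fasta"), p("per_read.tsv"), p("histogram.tsv"),
             p("estimator.json"), p("filter_log.tsv"))
  )
  invisible(manifest)
}
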