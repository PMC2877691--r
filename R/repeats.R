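#' Extract methylated CpGs from one repeat read
#'
#' In consensus (repeat) mode a genomic reference does not exist, so
#' methylated CpGs are detected in read space: every read C whose next
#' non-gap read base is G counts as a methylated CpG, whether or not the
#' consensus carries a CpG at that column. Each hit is annotated with its
#' alignment column and whether that column is a consensus CpG cytosine
#' position.
#'
#' @param aln A `bs_alignment` against the consensus.
#' @param read_id Read row.
#' @return A list of class `bs_repeat_read`: `read_id`, `meth_positions`
#'   (tibble: `column`, `ref_position` (`NA` for inserted columns),
#'   `is_consensus_cpg`), `meth_count`, `aligned_span`, `per100bp`.
#' @export
extract_methylated_cpgs <- function(aln, read_id) {
  stopifnot(inherits(aln, "bs_alignment"))
  chars <- .row_chars(aln, read_id)
  covered <- which(chars != "-")
  cpg_c_cols <- aln$col_of_refpos[aln$ref$cpg_pos]
  refpos_of_col <- rep(NA_integer_, aln$n_cols)
  refpos_of_col[aln$col_of_refpos] <- seq_len(aln$ref$length)

  hits_col <- integer(0)
  if (length(covered) >= 2L) {
    b <- chars[covered]
    is_cg <- b[-length(b)] == "C" & b[-1] == "G"
    hits_col <- covered[which(is_cg)]
  }
  span_pos <- refpos_of_col[covered]
  span_pos <- span_pos[!is.na(span_pos)]
  aligned_span <- if (length(span_pos) > 0) max(span_pos) - min(span_pos) + 1L else 0L
  meth_positions <- tibble::tibble(
    column = hits_col,
    ref_position = refpos_of_col[hits_col],
    is_consensus_cpg = hits_col %in% cpg_c_cols
  )
  structure(
    list(
      read_id = read_id,
      meth_positions = meth_positions,
      meth_count = nrow(meth_positions),
      aligned_span = as.integer(aligned_span),
      per100bp = if (aligned_span > 0) 100 * nrow(meth_positions) / aligned_span else 0
    ),
    class = "bs_repeat_read"
  )
}

#' Summarise repeat-read methylation results
#'
#' @param results List of `bs_repeat_read` (one per read, input order).
#' @return A list: `per_read` (tibble, sorted by `meth_count` descending,
#'   stable: `read_id`, `meth_count`, `per100bp`, `aligned_span`,
#'   `positions` semicolon-joined columns with a `*` marking non-consensus
#'   hits), `histogram` (tibble `meth_count`, `n_reads`),
#'   `mean_per100bp`.
#' @export
repeat_summaries <- function(results) {
  if (length(results) == 0L) stop("no repeat read results to summarise", call. = FALSE)
  per_read <- dplyr::bind_rows(purrr::map(results, function(r) {
    pos <- r$meth_positions
    lab <- if (nrow(pos) == 0) "" else {
      paste(paste0(pos$column, ifelse(pos$is_consensus_cpg, "", "*")), collapse = ";")
    }
    tibble::tibble(read_id = r$read_id, meth_count = r$meth_count,
                   per100bp = r$per100bp, aligned_span = r$aligned_span,
                   positions = lab)
  }))
  ord <- order(-per_read$meth_count, method = "radix")  # stable
  per_read <- per_read[ord, ]
  histogram <- per_read |>
    dplyr::count(.data$meth_count, name = "n_reads") |>
    dplyr::arrange(.data$meth_count)
  list(
    per_read = per_read,
    histogram = histogram,
    mean_per100bp = mean(per_read$per100bp)
  )
}

#' Tally read dinucleotides at consensus CpG positions
#'
#' For every read and every consensus CpG site, reads the base aligned to the
#' CpG guanine column and the read's next base in 5' direction (same
#' convention as the methylation caller). Pairs are tallied as CG
#' (methylated), TG (unmethylated or strand-mutated), CA (methylated with a
#' CG-to-TG mutation on the opposite strand), TA (mutated on both readings),
#' or other (gap, N, no coverage, anything else).
#'
#' @param aln A `bs_alignment` against the consensus, rows already
#'   quality-filtered.
#' @return A list of class `bs_dinuc_tally`: `n_CG`, `n_TG`, `n_CA`,
#'   `n_TA`, `n_other`.
#' @export
tally_consensus_dinucleotides <- function(aln) {
  stopifnot(inherits(aln, "bs_alignment"))
  counts <- c(CG = 0L, TG = 0L, CA = 0L, TA = 0L, other = 0L)
  for (id in names(aln$rows)) {
    chars <- .row_chars(aln, id)
    for (p in aln$ref$cpg_pos) {
      g_col <- aln$col_of_refpos[p + 1L]
      b2 <- chars[g_col]
      b1 <- .prev_read_base(chars, g_col)
      key <- if (!is.na(b1) && b1 %in% c("C", "T") && b2 %in% c("G", "A")) {
        paste0(b1, b2)
      } else "other"
      counts[key] <- counts[key] + 1L
    }
  }
  structure(
    list(n_CG = counts[["CG"]], n_TG = counts[["TG"]], n_CA = counts[["CA"]],
         n_TA = counts[["TA"]], n_other = counts[["other"]]),
    class = "bs_dinuc_tally"
  )
}

#' Mutation-corrected overall methylation of a repeat family
#'
#' At consensus CpG positions an unmethylated CpG and a CG-to-TG mutation
#' both read TG, so the naive estimate `CG / (CG + TG)` is biased low in
#' mutation-rich repeat families. The CG-to-CA count reflects CG-to-TG
#' mutations on the opposite strand; assuming equal mutation rates on both
#' strands, the unmethylated count is corrected to `TG - CA` (clamped at
#' zero, with a warning) before computing the methylation percentage.
#'
#' @param tally A `bs_dinuc_tally`.
#' @param use_ta If `TRUE`, also subtract the TA count (unmethylated and
#'   opposite-strand-mutated) from the TG correction, i.e. use
#'   `TG - CA - TA`. Default `FALSE`.
#' @return Corrected overall methylation percent.
#' @export
yang_overall_methylation <- function(tally, use_ta = FALSE) {
  stopifnot(inherits(tally, "bs_dinuc_tally"))
  if (tally$n_CG + tally$n_TG == 0L) {
    stop("no informative CG/TG observations at consensus CpG positions", call. = FALSE)
  }
  corr <- tally$n_CA + if (use_ta) tally$n_TA else 0L
  u <- tally$n_TG - corr
  if (u < 0) {
    warning("mutation correction exceeds the TG count; clamping unmethylated count at 0")
    u <- 0
  }
  if (tally$n_CG + u == 0) {
    stop("no informative observations left after mutation correction", call. = FALSE)
  }
  100 * tally$n_CG / (tally$n_CG + u)
}

#' Naive (uncorrected) overall methylation at consensus CpG positions
#'
#' @param tally A `bs_dinuc_tally`.
#' @return `100 * CG / (CG + TG)`.
#' @export
naive_overall_methylation <- function(tally) {
  stopifnot(inherits(tally, "bs_dinuc_tally"))
  if (tally$n_CG + tally$n_TG == 0L) {
    stop("no informative CG/TG observations at consensus CpG positions", call. = FALSE)
  }
  100 * tally$n_CG / (tally$n_CG + tally$n_TG)
}
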