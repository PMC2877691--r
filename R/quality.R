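#' Quality filter configuration
#'
#' Default thresholds for the two analysis modes. Unique-sequence mode:
#' sequence identity >= 90%, bisulfite conversion rate >= 95%, gaps <= 20%.
#' Repeat (consensus) mode: identity >= 70%, gaps <= 20%, and the conversion
#' criterion is replaced by an unconverted-cytosine rate rule — reads with 3
#' or more unconverted cytosines per 100 bp of aligned span are excluded.
#' Thresholds are inclusive for passing (identity exactly at the minimum
#' passes) except the repeat unconverted rule, which excludes at the stated
#' count and above. Reads are additionally filtered on unresolved bases (N)
#' at reference cytosine positions.
#'
#' @param mode `"unique"` or `"repeat"`.
#' @param min_identity Minimal percent identity (default 90 unique /
#'   70 repeat).
#' @param min_conversion Minimal percent conversion rate, unique mode
#'   (default 95).
#' @param max_unconverted_per_100bp Unconverted cytosines per 100 aligned bp
#'   at and above which a read fails, repeat mode (default 3).
#' @param max_gap_pct Maximal percent gap columns within the aligned span
#'   (default 20).
#' @param max_n_at_cytosine Maximal N count at reference cytosine positions
#'   (default 3).
#' @param clonal_mode Clonal duplicate filtering mode passed downstream:
#'   `"suggested"`, `"strict"`, or `"off"` (default `"suggested"`).
#' @return A list of class `bs_filter_config`.
#' @export
filter_config <- function(mode = c("unique", "repeat"),
                          min_identity = NULL,
                          min_conversion = 95,
                          max_unconverted_per_100bp = 3,
                          max_gap_pct = 20,
                          max_n_at_cytosine = 3L,
                          clonal_mode = c("suggested", "strict", "off")) {
  mode <- match.arg(mode)
  clonal_mode <- match.arg(clonal_mode)
  if (is.null(min_identity)) min_identity <- if (mode == "unique") 90 else 70
  structure(
    list(
      mode = mode,
      min_identity = min_identity,
      min_conversion = min_conversion,
      max_unconverted_per_100bp = max_unconverted_per_100bp,
      max_gap_pct = max_gap_pct,
      max_n_at_cytosine = as.integer(max_n_at_cytosine),
      clonal_mode = clonal_mode
    ),
    class = "bs_filter_config"
  )
}

#' Per-read quality metrics against the reference
#'
#' Computes, for every read row of the frame, within the read's aligned span
#' (first to last read-covered column, ignoring columns gapped in both rows):
#' \describe{
#'   \item{identity}{matching columns / columns where both rows carry a base,
#'     counting C *or* T opposite a reference CpG cytosine as a match
#'     (methylation state must not depress identity) and excluding N columns.}
#'   \item{conversion_rate}{among non-CpG reference cytosine positions, the
#'     fraction read as T out of those read as C or T; `NA` when no position
#'     is assessable.}
#'   \item{unconverted_per_100bp}{unconverted (C-reading) non-CpG cytosines
#'     per 100 bp of reference span.}
#'   \item{gap_fraction}{columns gapped in exactly one row / span columns.}
#'   \item{n_at_cytosine}{N bases at reference cytosine positions (CpG and
#'     non-CpG).}
#'   \item{aligned_span}{reference bp between the first and last covered
#'     reference position.}
#' }
#'
#' @param aln A `bs_alignment`.
#' @return A tibble with one row per read: `read_id`, `identity`,
#'   `conversion_rate`, `unconverted_per_100bp`, `gap_fraction`,
#'   `n_at_cytosine`, `aligned_span`.
#' @export
compute_metrics <- function(aln) {
  stopifnot(inherits(aln, "bs_alignment"))
  rc <- .ref_chars(aln)
  cpg_cols <- aln$col_of_refpos[aln$ref$cpg_pos]
  noncpg_cols <- aln$col_of_refpos[aln$ref$noncpg_c_pos]
  refpos_of_col <- rep(NA_integer_, aln$n_cols)
  refpos_of_col[aln$col_of_refpos] <- seq_len(aln$ref$length)

  rows <- purrr::map(names(aln$rows), function(id) {
    q <- .row_chars(aln, id)
    covered <- which(q != "-")
    if (length(covered) == 0L) {
      return(tibble::tibble(read_id = id, identity = NA_real_,
                            conversion_rate = NA_real_,
                            unconverted_per_100bp = NA_real_,
                            gap_fraction = NA_real_, n_at_cytosine = 0L,
                            aligned_span = 0L))
    }
    span <- seq(min(covered), max(covered))
    span <- span[!(q[span] == "-" & rc[span] == "-")]  # other reads' insertions

    both <- span[q[span] != "-" & rc[span] != "-" & q[span] != "N" & rc[span] != "N"]
    is_match <- q[both] == rc[both] | (both %in% cpg_cols & q[both] %in% c("C", "T"))
    identity <- if (length(both) > 0) mean(is_match) else NA_real_

    ncc <- intersect(noncpg_cols, span)
    conv <- sum(q[ncc] == "T")
    unconv <- sum(q[ncc] == "C")
    conversion_rate <- if (conv + unconv > 0) conv / (conv + unconv) else NA_real_

    ref_span_pos <- refpos_of_col[span]
    ref_span_pos <- ref_span_pos[!is.na(ref_span_pos)]
    aligned_span <- if (length(ref_span_pos) > 0) {
      max(ref_span_pos) - min(ref_span_pos) + 1L
    } else 0L

    gap_fraction <- mean(q[span] == "-" | rc[span] == "-")
    n_at_cyt <- sum(q[intersect(c(cpg_cols, noncpg_cols), span)] == "N")
    tibble::tibble(
      read_id = id,
      identity = identity,
      conversion_rate = conversion_rate,
      unconverted_per_100bp = if (aligned_span > 0) 100 * unconv / aligned_span else NA_real_,
      gap_fraction = gap_fraction,
      n_at_cytosine = as.integer(n_at_cyt),
      aligned_span = as.integer(aligned_span)
    )
  })
  dplyr::bind_rows(rows)
}

#' Apply quality filters to read metrics
#'
#' Pure decision function: unique mode fails a read on identity, conversion
#' rate, gap fraction, or N-at-cytosine count; repeat mode replaces the
#' conversion-rate criterion with the unconverted-per-100bp rule (fail at the
#' configured count and above). An unassessable conversion rate (`NA`, no
#' non-CpG cytosine covered) does not fail the conversion criterion.
#'
#' @param metrics Tibble from [compute_metrics()] (percent-free fractions).
#' @param cfg A [filter_config()].
#' @return The metrics tibble with `passed` (logical) and `reasons`
#'   (semicolon-joined failed criteria, `""` when passed) appended.
#' @export
apply_filters <- function(metrics, cfg) {
  stopifnot(inherits(cfg, "bs_filter_config"))
  decide <- function(identity, conversion_rate, unconverted_per_100bp,
                     gap_fraction, n_at_cytosine) {
    reasons <- character(0)
    if (is.na(identity) || 100 * identity < cfg$min_identity) {
      reasons <- c(reasons, "identity")
    }
    if (cfg$mode == "unique") {
      if (!is.na(conversion_rate) && 100 * conversion_rate < cfg$min_conversion) {
        reasons <- c(reasons, "conversion")
      }
    } else {
      if (!is.na(unconverted_per_100bp) &&
          unconverted_per_100bp >= cfg$max_unconverted_per_100bp) {
        reasons <- c(reasons, "conversion")
      }
    }
    if (is.na(gap_fraction) || 100 * gap_fraction > cfg$max_gap_pct) {
      reasons <- c(reasons, "gaps")
    }
    if (n_at_cytosine > cfg$max_n_at_cytosine) {
      reasons <- c(reasons, "n_sites")
    }
    paste(reasons, collapse = ";")
  }
  reasons <- purrr::pmap_chr(
    metrics[c("identity", "conversion_rate", "unconverted_per_100bp",
              "gap_fraction", "n_at_cytosine")],
    decide
  )
  dplyr::mutate(metrics, passed = reasons == "", reasons = reasons)
}
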