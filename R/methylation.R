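#' Call the methylation state of one CpG site in one read
#'
#' Guanine-anchored calling: the read must show a G in the column aligned to
#' the reference CpG guanine; only then is the read's next base in 5'
#' direction (skipping alignment gaps, i.e. in read coordinates) used to
#' determine the state — C means methylated, T unmethylated, anything else
#' (A, G, N, or no preceding base) is unknown. If the G column itself shows
#' anything but G (mutation, N, gap, no coverage) the site is unknown. Using
#' the read's own previous base rather than the reference C column makes the
#' call robust to thymine insertions or deletions at T-stretches, where the
#' informative C/T drifts out of the reference C column.
#'
#' @param aln A `bs_alignment`.
#' @param read_id Read row to call.
#' @param site 1-based reference position of the CpG cytosine (must be in
#'   `aln$ref$cpg_pos`).
#' @return One of `"M"` (methylated), `"U"` (unmethylated), `"X"` (unknown).
#' @export
call_cpg <- function(aln, read_id, site) {
  stopifnot(inherits(aln, "bs_alignment"))
  if (!(site %in% aln$ref$cpg_pos)) {
    stop("position ", site, " is not a CpG site of the reference", call. = FALSE)
  }
  chars <- .row_chars(aln, read_id)
  .call_cpg_chars(chars, aln$col_of_refpos, site)
}

.call_cpg_chars <- function(chars, col_of_refpos, site) {
  g_col <- col_of_refpos[site + 1L]
  if (chars[g_col] != "G") return("X")
  b <- .prev_read_base(chars, g_col)
  if (is.na(b)) return("X")
  if (b == "C") return("M")
  if (b == "T") return("U")
  "X"
}

#' Call all CpG sites for all reads
#'
#' @param aln A `bs_alignment` whose rows have passed quality filtering.
#' @param read_ids Optional subset/order of rows to call (default all rows in
#'   frame order).
#' @return A `bs_calls` object: list with `sites` (1-based reference CpG
#'   positions), `clone_ids`, and `calls`, a clones x sites character matrix
#'   over `M`/`U`/`X`.
#' @export
call_all <- function(aln, read_ids = names(aln$rows)) {
  stopifnot(inherits(aln, "bs_alignment"))
  sites <- aln$ref$cpg_pos
  calls <- matrix("X", nrow = length(read_ids), ncol = length(sites),
                  dimnames = list(read_ids, as.character(sites)))
  for (id in read_ids) {
    chars <- .row_chars(aln, id)
    calls[id, ] <- vapply(sites, function(s) {
      .call_cpg_chars(chars, aln$col_of_refpos, s)
    }, character(1))
  }
  structure(
    list(sites = sites, clone_ids = read_ids, calls = calls),
    class = "bs_calls"
  )
}

#' @export
print.bs_calls <- function(x, ...) {
  cat(sprintf("<bs_calls> %d clones x %d CpG sites\n",
              length(x$clone_ids), length(x$sites)))
  if (length(x$clone_ids) > 0) {
    inf <- mean(x$calls != "X") * 100
    cat(sprintf("  informative calls: %.1f%%\n", inf))
  }
  invisible(x)
}

#' Summarise a call matrix
#'
#' Per-site methylation is reported only where at least `min_site_n` reads
#' were informative (called M or U) at that site; weaker sites are suppressed
#' (`NA`) to avoid over-interpreting thinly covered positions. Per-clone
#' means are computed over each clone's informative sites with no minimum.
#' The overall percentage pools all informative cells; the informative
#' percentage is the fraction of matrix cells carrying an M or U call.
#'
#' @param calls A `bs_calls`.
#' @param min_site_n Minimal informative reads for a per-site value
#'   (default 5).
#' @return A `bs_summary`: list with tibbles `per_site` (`position`,
#'   `n_informative`, `n_methylated`, `pct_methylated`) and `per_clone`
#'   (`clone_id`, `n_informative`, `pct_methylated`), plus `overall_pct`,
#'   `informative_pct`, `n_clones`, `n_sites`, `min_site_n`.
#' @export
summarize_methylation <- function(calls, min_site_n = 5L) {
  stopifnot(inherits(calls, "bs_calls"))
  m <- calls$calls
  n_m <- unname(colSums(m == "M"))
  n_u <- unname(colSums(m == "U"))
  n_inf <- n_m + n_u
  per_site <- tibble::tibble(
    position = calls$sites,
    n_informative = as.integer(n_inf),
    n_methylated = as.integer(n_m),
    pct_methylated = ifelse(n_inf >= min_site_n, 100 * n_m / pmax(n_inf, 1L), NA_real_)
  )
  cm <- unname(rowSums(m == "M"))
  cu <- unname(rowSums(m == "U"))
  per_clone <- tibble::tibble(
    clone_id = calls$clone_ids,
    n_informative = as.integer(cm + cu),
    pct_methylated = ifelse(cm + cu > 0, 100 * cm / pmax(cm + cu, 1L), NA_real_)
  )
  tot_m <- sum(n_m)
  tot_u <- sum(n_u)
  n_cells <- length(m)
  structure(
    list(
      per_site = per_site,
      per_clone = per_clone,
      overall_pct = if (tot_m + tot_u > 0) 100 * tot_m / (tot_m + tot_u) else NA_real_,
      informative_pct = if (n_cells > 0) 100 * (tot_m + tot_u) / n_cells else NA_real_,
      n_clones = length(calls$clone_ids),
      n_sites = length(calls$sites),
      min_site_n = as.integer(min_site_n)
    ),
    class = "bs_summary"
  )
}

#' @export
print.bs_summary <- function(x, ...) {
  cat(sprintf("<bs_summary> %d clones x %d sites\n", x$n_clones, x$n_sites))
  cat(sprintf("  overall methylation: %s%%\n",
              if (is.na(x$overall_pct)) "NA" else sprintf("%.1f", x$overall_pct)))
  cat(sprintf("  informative calls:   %s%%\n",
              if (is.na(x$informative_pct)) "NA" else sprintf("%.1f", x$informative_pct)))
  invisible(x)
}

#' Sort clones by their methylation level
#'
#' Reorders a call matrix by per-clone methylation percentage, descending by
#' default; ties keep the input order (stable sort). Clones with no
#' informative site sort last.
#'
#' @param calls A `bs_calls`.
#' @param decreasing Sort direction (default `TRUE`).
#' @return The reordered `bs_calls`.
#' @export
sort_by_methylation <- function(calls, decreasing = TRUE) {
  stopifnot(inherits(calls, "bs_calls"))
  m <- calls$calls
  cm <- rowSums(m == "M")
  cu <- rowSums(m == "U")
  pct <- ifelse(cm + cu > 0, 100 * cm / pmax(cm + cu, 1L), -Inf)
  ord <- order(if (decreasing) -pct else pct, method = "radix")  # stable
  calls$clone_ids <- calls$clone_ids[ord]
  calls$calls <- m[ord, , drop = FALSE]
  calls
}
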