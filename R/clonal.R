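#' Cytosine pattern of one read
#'
#' The pattern used for clonal duplicate detection spans every cytosine
#' position of the reference, in order. CpG positions carry the methylation
#' call (`M`/`U`/`X`); non-CpG cytosine positions carry `t` (converted, read
#' T), `C` (conversion artifact, read C), or `.` (anything else: gap,
#' mutation, no coverage). Positions where the read shows an N (for a CpG,
#' at either the C or the G column) are recorded in the N mask and ignored
#' during pattern comparison — N indicates bad sequencing quality, not a
#' different template molecule.
#'
#' @param aln A `bs_alignment`.
#' @param read_id Read row.
#' @param calls A `bs_calls` containing this read.
#' @return A list of class `bs_pattern`: `read_id`, `positions` (1-based
#'   reference cytosine positions), `symbols` (character vector),
#'   `is_cpg` (logical), `mask` (logical N mask).
#' @export
cytosine_pattern <- function(aln, read_id, calls) {
  stopifnot(inherits(aln, "bs_alignment"), inherits(calls, "bs_calls"))
  positions <- sort(c(aln$ref$cpg_pos, aln$ref$noncpg_c_pos))
  is_cpg <- positions %in% aln$ref$cpg_pos
  chars <- .row_chars(aln, read_id)
  symbols <- character(length(positions))
  mask <- logical(length(positions))
  call_row <- calls$calls[read_id, ]
  for (k in seq_along(positions)) {
    p <- positions[k]
    c_col <- aln$col_of_refpos[p]
    if (is_cpg[k]) {
      g_col <- aln$col_of_refpos[p + 1L]
      symbols[k] <- call_row[[as.character(p)]]
      mask[k] <- chars[c_col] == "N" || chars[g_col] == "N"
    } else {
      b <- chars[c_col]
      symbols[k] <- if (b == "T") "t" else if (b == "C") "C" else "."
      mask[k] <- b == "N"
    }
  }
  structure(
    list(read_id = read_id, positions = positions, symbols = symbols,
         is_cpg = is_cpg, mask = mask),
    class = "bs_pattern"
  )
}

#' Cytosine patterns for all reads of a frame
#'
#' @param aln A `bs_alignment`.
#' @param calls A `bs_calls` over (a subset of) the frame's rows.
#' @return A list of `bs_pattern`, one per clone in `calls`, in call order.
#' @export
cytosine_patterns <- function(aln, calls) {
  lapply(calls$clone_ids, function(id) cytosine_pattern(aln, id, calls))
}

#' Do two cytosine patterns match?
#'
#' Patterns match when their symbols agree at every position outside the
#' union of the two N masks. Symmetric; errors if the patterns cover
#' different position sets.
#'
#' @param p,q `bs_pattern` objects over the same reference.
#' @return Logical.
#' @export
patterns_match <- function(p, q) {
  if (length(p$symbols) != length(q$symbols) ||
      !identical(p$positions, q$positions)) {
    stop("patterns cover different cytosine position sets", call. = FALSE)
  }
  ok <- !(p$mask | q$mask)
  all(p$symbols[ok] == q$symbols[ok])
}

#' Classify reads as clonal duplicates
#'
#' Groups reads whose cytosine patterns match (transitive closure, since
#' N-wildcarded matching is not transitive) and decides which to keep.
#' `strict` keeps only the first read (input order) of each group.
#' `suggested` additionally requires evidence of clonal PCR before removing:
#' a group member is removed only if it shares at least one conversion
#' artifact (unconverted non-CpG cytosine) with the group representative at
#' the same position, outside both N masks; members matching on CpG pattern
#' alone are kept — identical methylation patterns in different template
#' molecules are expected in highly (un)methylated regions. `off` keeps
#' everything.
#'
#' @param patterns List of `bs_pattern` in input order.
#' @param mode `"suggested"`, `"strict"`, or `"off"`.
#' @return A tibble: `read_id`, `group_id` (integer; one id per pattern
#'   group), `group_size`, `kept` (logical), `reason` (one of
#'   `unique_pattern`, `kept_representative`, `removed_clonal`,
#'   `kept_cpg_only_match`).
#' @export
classify_clonal <- function(patterns, mode = c("suggested", "strict", "off")) {
  mode <- match.arg(mode)
  n <- length(patterns)
  ids <- vapply(patterns, `[[`, character(1), "read_id")
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), group_id = integer(),
                          group_size = integer(), kept = logical(),
                          reason = character()))
  }
  # union-find over pairwise matches
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (mode != "off" && n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (patterns_match(patterns[[i]], patterns[[j]])) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group_id <- match(root, unique(root))
  group_size <- as.integer(table(group_id)[as.character(group_id)])

  kept <- rep(TRUE, n)
  reason <- rep("unique_pattern", n)
  if (mode != "off") {
    for (g in unique(group_id)) {
      members <- which(group_id == g)
      if (length(members) == 1L) next
      rep_i <- members[1L]  # earliest in input order
      reason[rep_i] <- "kept_representative"
      for (j in members[-1L]) {
        if (mode == "strict") {
          kept[j] <- FALSE
          reason[j] <- "removed_clonal"
        } else {
          p <- patterns[[rep_i]]; q <- patterns[[j]]
          ok <- !(p$mask | q$mask)
          shared_artifact <- any(ok & !p$is_cpg & p$symbols == "C" & q$symbols == "C")
          if (shared_artifact) {
            kept[j] <- FALSE
            reason[j] <- "removed_clonal"
          } else {
            reason[j] <- "kept_cpg_only_match"
          }
        }
      }
    }
  }
  tibble::tibble(read_id = ids, group_id = group_id, group_size = group_size,
                 kept = kept, reason = reason)
}
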