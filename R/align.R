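#' Alignment parameters
#'
#' Scoring and fallback parameters for aligning bisulfite reads to the
#' converted reference. The substitution scheme is bisulfite-aware: a read T
#' opposite a reference C scores as a match, because after in-silico
#' conversion the only cytosines left in the reference are CpG cytosines,
#' which legitimately read C (methylated) or T (unmethylated). This keeps the
#' alignment from being biased by the methylation state itself. End gaps on
#' the read are free, so vector/adapter sequence flanking the insert simply
#' overhangs the reference and is trimmed.
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -1).
#' @param gap_open Gap opening penalty, positive (default 4).
#' @param gap_extend Gap extension penalty, positive (default 1).
#' @param min_score_frac Minimal alignment score, as a fraction of
#'   `min(read length, reference length)`, below which a read is flagged
#'   unalignable in both orientations (default 0.3).
#' @param end_window Window (bp) from either reference end within which a CpG
#'   counts as "close to the end" for the multiple-alignment fallback rule
#'   (default 30).
#' @param tstretch_min Minimal T-homopolymer length immediately 5' of a CpG
#'   for the fallback rule (default 4).
#' @return A list of class `bs_align_params`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = 4, gap_extend = 1,
                         min_score_frac = 0.3, end_window = 30L, tstretch_min = 4L) {
  stopifnot(gap_open >= 0, gap_extend >= 0, end_window >= 0, tstretch_min >= 1)
  structure(
    list(
      match = match, mismatch = mismatch,
      gap_open = gap_open, gap_extend = gap_extend,
      min_score_frac = min_score_frac,
      end_window = as.integer(end_window),
      tstretch_min = as.integer(tstretch_min)
    ),
    class = "bs_align_params"
  )
}

# bisulfite-aware substitution matrix; read bases are rows, reference columns
.bs_submat <- function(params) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m["T", "C"] <- params$match   # converted/unmethylated C reads as T
  m
}

#' Reverse complement of a DNA string
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Global pairwise alignment of a read to the converted reference
#'
#' End-gap-free ("overlap") global alignment of `read` against `ref_seq`
#' under the bisulfite-aware scoring of [align_params()]. Read bases aligned
#' outside the reference span (vector/adapter overhangs) are excluded from
#' the returned gapped strings. Tie-breaking is deterministic.
#'
#' @param ref_seq Reference (converted) sequence string.
#' @param read Read sequence string.
#' @param params [align_params()].
#' @return A list with `ref_gapped` and `read_gapped` (equal-length strings
#'   over `A,C,G,T,N,-`; ungapping `ref_gapped` recovers the full
#'   `ref_seq`), `score`, and `ref_span` (first and last reference position
#'   covered by the read).
#' @export
pairwise_align <- function(ref_seq, read, params = align_params()) {
  if (!nzchar(ref_seq) || !nzchar(read)) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(read),
    subject = Biostrings::DNAString(ref_seq),
    type = "overlap",
    substitutionMatrix = .bs_submat(params),
    gapOpening = params$gap_open,
    gapExtension = params$gap_extend
  )
  read_gapped <- as.character(Biostrings::alignedPattern(aln))
  ref_gapped <- as.character(Biostrings::alignedSubject(aln))
  s <- Biostrings::subject(aln)
  start_ref <- Biostrings::start(s)
  end_ref <- Biostrings::end(s)
  L <- nchar(ref_seq)
  # pad to the full reference frame; the read is gap-filled outside its span
  left <- substr(ref_seq, 1L, start_ref - 1L)
  right <- if (end_ref < L) substr(ref_seq, end_ref + 1L, L) else ""
  list(
    ref_gapped = paste0(left, ref_gapped, right),
    read_gapped = paste0(strrep("-", nchar(left)), read_gapped, strrep("-", nchar(right))),
    score = Biostrings::score(aln),
    ref_span = c(start_ref, end_ref)
  )
}

#' Detect read orientation and trim vector sequence
#'
#' Aligns the read and its reverse complement to the converted reference and
#' keeps the orientation with the higher score. Read bases outside the
#' reference span (cloning vector, adapters) are trimmed. Reads whose best
#' score falls below `min_score_frac * min(read length, reference length)`
#' are flagged unalignable rather than raising an error.
#'
#' @param read_id Read identifier.
#' @param seq Read sequence string.
#' @param ref A `bs_reference`.
#' @param params [align_params()].
#' @return A list: `read_id`, `ok` (logical), `reason` (`NA` or
#'   `"unalignable"`), `orientation` (`"forward"`/`"reverse"`),
#'   `oriented_read` (trimmed, reference-strand sequence), `score`,
#'   `ref_gapped`, `read_gapped`, `ref_span`.
#' @export
orient_and_trim <- function(read_id, seq, ref, params = align_params()) {
  stopifnot(inherits(ref, "bs_reference"))
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty read: ", read_id, call. = FALSE)
  fwd <- pairwise_align(ref$converted, seq, params)
  rev <- pairwise_align(ref$converted, revcomp(seq), params)
  floor_score <- params$min_score_frac * min(nchar(seq), ref$length)
  if (max(fwd$score, rev$score) < floor_score) {
    return(list(read_id = read_id, ok = FALSE, reason = "unalignable",
                orientation = NA_character_, oriented_read = NA_character_,
                score = max(fwd$score, rev$score),
                ref_gapped = NA_character_, read_gapped = NA_character_,
                ref_span = c(NA_integer_, NA_integer_)))
  }
  use_rev <- rev$score > fwd$score
  best <- if (use_rev) rev else fwd
  list(
    read_id = read_id, ok = TRUE, reason = NA_character_,
    orientation = if (use_rev) "reverse" else "forward",
    oriented_read = gsub("-", "", best$read_gapped, fixed = TRUE),
    score = best$score,
    ref_gapped = best$ref_gapped,
    read_gapped = best$read_gapped,
    ref_span = best$ref_span
  )
}

# decompose a padded pairwise alignment into, per reference gap slot
# (0..L, "after reference position i"), the inserted read bases, and the read
# base aligned to each reference position ("-" for deletions / uncovered)
.pairwise_profile <- function(ref_gapped, read_gapped) {
  r <- strsplit(ref_gapped, "", fixed = TRUE)[[1]]
  q <- strsplit(read_gapped, "", fixed = TRUE)[[1]]
  L <- sum(r != "-")
  ins <- character(L + 1L)
  base_at <- rep("-", L)
  pos <- 0L
  for (k in seq_along(r)) {
    if (r[k] == "-") {
      if (q[k] != "-") ins[pos + 1L] <- paste0(ins[pos + 1L], q[k])
    } else {
      pos <- pos + 1L
      base_at[pos] <- q[k]
    }
  }
  list(ins = ins, base_at = base_at)
}

# does the reference trip the multiple-alignment fallback rule?
.needs_msa <- function(ref, end_window, tstretch_min) {
  chars <- strsplit(ref$converted, "", fixed = TRUE)[[1]]
  L <- ref$length
  for (p in ref$cpg_pos) {
    near_end <- p <= end_window || (L - (p + 1L)) < end_window
    if (!near_end) next
    # T-homopolymer immediately 5' of the CpG cytosine in the converted sequence
    run <- 0L
    k <- p - 1L
    while (k >= 1L && chars[k] == "T") {
      run <- run + 1L
      k <- k - 1L
    }
    if (run >= tstretch_min) return(TRUE)
  }
  FALSE
}

.materialize_row <- function(ins, base_at, I, L) {
  pieces <- character(2L * L + 1L)
  for (i in 0:L) {
    block <- ins[i + 1L]
    pieces[2L * i + 1L] <- paste0(block, strrep("-", I[i + 1L] - nchar(block)))
    if (i < L) pieces[2L * i + 2L] <- base_at[i + 1L]
  }
  paste(pieces, collapse = "")
}

#' Build the shared gapped alignment frame
#'
#' Places all oriented, trimmed reads into one gapped coordinate frame over
#' the converted reference. Two constructions are available: `stitched`
#' merges the per-read pairwise alignments, reserving at each reference
#' position the maximum insertion length observed over reads (insertions
#' left-aligned); `msa` runs a progressive center-star multiple alignment
#' around the converted reference with the same scoring, adding reads one at
#' a time under a once-a-gap-always-a-gap rule. `auto` selects `msa` only
#' when some CpG lies within `end_window` bases of a reference end and is
#' immediately preceded (5', converted sequence) by a T-homopolymer of at
#' least `tstretch_min` bases — the configuration where T-stretch indel
#' artifacts make stitched pairwise frames fail at the terminal CpG.
#'
#' @param oriented List of successful results from [orient_and_trim()].
#' @param ref A `bs_reference`.
#' @param mode `"auto"`, `"stitched"`, or `"msa"`.
#' @param params [align_params()] (supplies `end_window`, `tstretch_min`).
#' @return A `bs_alignment`: list with `ref` (the `bs_reference`), `ref_row`
#'   (gapped reference string), `rows` (named character vector of gapped read
#'   strings, equal length), `orientations`, `col_of_refpos` (column index of
#'   every reference position), and `mode` (the mode actually used).
#' @export
build_alignment <- function(oriented, ref, mode = c("auto", "stitched", "msa"),
                            params = align_params()) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "bs_reference"), length(oriented) >= 1L)
  if (mode == "auto") {
    mode <- if (.needs_msa(ref, params$end_window, params$tstretch_min)) "msa" else "stitched"
  }
  L <- ref$length
  ids <- vapply(oriented, `[[`, character(1), "read_id")
  if (anyDuplicated(ids)) stop("duplicate read ids in alignment", call. = FALSE)
  profs <- lapply(oriented, function(o) .pairwise_profile(o$ref_gapped, o$read_gapped))
  ref_chars <- strsplit(ref$converted, "", fixed = TRUE)[[1]]

  if (mode == "stitched") {
    I <- Reduce(pmax, lapply(profs, function(p) nchar(p$ins)), accumulate = FALSE,
                init = integer(L + 1L))
    rows <- vapply(profs, function(p) .materialize_row(p$ins, p$base_at, I, L), character(1))
  } else {
    # progressive center-star: grow the gap profile read by read; gaps opened
    # for an earlier read are never closed again
    I <- integer(L + 1L)
    placed <- list()
    for (p in profs) {
      I <- pmax(I, nchar(p$ins))
      placed <- c(placed, list(p))
    }
    # materialize incrementally against the final profile to honour the
    # left-aligned once-a-gap layout
    rows <- vapply(placed, function(p) .materialize_row(p$ins, p$base_at, I, L), character(1))
  }
  ref_row <- .materialize_row(character(L + 1L), ref_chars, I, L)
  names(rows) <- ids
  col_of_refpos <- cumsum(I[seq_len(L)]) + seq_len(L)
  structure(
    list(
      ref = ref,
      ref_row = ref_row,
      rows = rows,
      orientations = stats::setNames(
        vapply(oriented, `[[`, character(1), "orientation"), ids),
      col_of_refpos = col_of_refpos,
      mode = mode,
      n_cols = nchar(ref_row)
    ),
    class = "bs_alignment"
  )
}

#' Construct an alignment frame from explicit gapped rows
#'
#' Low-level constructor for a `bs_alignment` from pre-built gapped strings,
#' mainly useful for constructing exact alignment scenarios in tests and
#' examples without running the aligner.
#'
#' @param ref A `bs_reference`.
#' @param ref_row Gapped reference string; ungapping it must recover
#'   `ref$converted`.
#' @param rows Named character vector of gapped read rows, all the same
#'   length as `ref_row`.
#' @param orientations Optional named orientation vector (default all
#'   `"forward"`).
#' @param mode Label stored as the frame's mode (default `"manual"`).
#' @return A `bs_alignment`.
#' @export
bs_alignment <- function(ref, ref_row, rows, orientations = NULL, mode = "manual") {
  stopifnot(inherits(ref, "bs_reference"), is.character(rows), !is.null(names(rows)))
  if (gsub("-", "", ref_row, fixed = TRUE) != ref$converted) {
    stop("ungapped ref_row does not match the converted reference", call. = FALSE)
  }
  if (any(nchar(rows) != nchar(ref_row))) {
    stop("all rows must have the same length as ref_row", call. = FALSE)
  }
  if (is.null(orientations)) {
    orientations <- stats::setNames(rep("forward", length(rows)), names(rows))
  }
  ref_chars <- strsplit(ref_row, "", fixed = TRUE)[[1]]
  structure(
    list(
      ref = ref,
      ref_row = ref_row,
      rows = rows,
      orientations = orientations,
      col_of_refpos = which(ref_chars != "-"),
      mode = mode,
      n_cols = nchar(ref_row)
    ),
    class = "bs_alignment"
  )
}

#' @export
print.bs_alignment <- function(x, ...) {
  cat(sprintf("<bs_alignment> %d reads x %d columns (%s mode) on %s\n",
              length(x$rows), x$n_cols, x$mode, x$ref$id))
  invisible(x)
}

# character matrix view of the frame (reads x columns), cached-free helper
.frame_chars <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}

.row_chars <- function(aln, id) {
  strsplit(aln$rows[[id]], "", fixed = TRUE)[[1]]
}

.ref_chars <- function(aln) {
  strsplit(aln$ref_row, "", fixed = TRUE)[[1]]
}

# previous non-gap read base strictly before column `col`, or NA
.prev_read_base <- function(chars, col) {
  k <- col - 1L
  while (k >= 1L) {
    if (chars[k] != "-") return(chars[k])
    k <- k - 1L
  }
  NA_character_
}
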