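#' Build an in-silico bisulfite-converted reference
#'
#' Bisulfite treatment converts unmethylated cytosines to uracil (read as T
#' after PCR) while 5-methylcytosines remain C. Because CpG cytosines may
#' legitimately read either C (methylated) or T (unmethylated), the converted
#' reference keeps CpG cytosines as C and replaces every cytosine *not*
#' followed by G with T. The returned record indexes both classes of cytosine
#' positions; non-CpG cytosines are the substrate for the conversion-rate
#' quality control and for clonal pattern comparison.
#'
#' @param id Reference identifier.
#' @param seq Reference DNA sequence, a single string over `A,C,G,T,N`
#'   (lower case accepted).
#' @return An object of class `bs_reference`: a list with elements `id`,
#'   `original`, `converted` (equal-length strings), `cpg_pos` and
#'   `noncpg_c_pos` (1-based cytosine positions), and `length`.
#' @examples
#' ref <- convert_reference("r", "TTCGCCG")
#' ref$converted   # "TTCGTCG"
#' ref$cpg_pos     # 3 6
#' @export
convert_reference <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L, is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 2L) {
    stop("reference sequence must have length >= 2", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("reference contains invalid characters: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  is_c <- chars == "C"
  next_g <- c(chars[-1] == "G", FALSE)       # last base can never start a CpG
  cpg <- which(is_c & next_g)
  noncpg <- which(is_c & !next_g)
  conv <- chars
  conv[noncpg] <- "T"
  structure(
    list(
      id = id,
      original = seq,
      converted = paste(conv, collapse = ""),
      cpg_pos = as.integer(cpg),
      noncpg_c_pos = as.integer(noncpg),
      length = as.integer(n)
    ),
    class = "bs_reference"
  )
}

#' Locate CpG sites in a reference
#'
#' Returns the 1-based positions of CpG cytosines (a C immediately followed
#' by G in the original, unconverted sequence).
#'
#' @param ref A `bs_reference` from [convert_reference()].
#' @return Integer vector of CpG cytosine positions.
#' @export
find_cpg_sites <- function(ref) {
  stopifnot(inherits(ref, "bs_reference"))
  ref$cpg_pos
}

#' @export
print.bs_reference <- function(x, ...) {
  cat(sprintf(
    "<bs_reference> %s: %d bp, %d CpG sites, %d non-CpG cytosines\n",
    x$id, x$length, length(x$cpg_pos), length(x$noncpg_c_pos)
  ))
  invisible(x)
}
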