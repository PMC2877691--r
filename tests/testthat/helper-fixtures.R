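# shared fixture builders; everything is generated in code at test time

make_ref <- function(seq, id = "ref") convert_reference(id, seq)

# frame with explicit gapped rows (bypasses the aligner)
make_frame <- function(.ref, .ref_row, ...) {
  rows <- c(...)
  bs_alignment(.ref, .ref_row, rows)
}

# one-row quality metrics tibble for filter boundary tests
metrics_row <- function(identity = 1, conversion_rate = 1,
                        unconverted_per_100bp = 0, gap_fraction = 0,
                        n_at_cytosine = 0L, aligned_span = 100L,
                        read_id = "r1") {
  tibble::tibble(read_id = read_id, identity = identity,
                 conversion_rate = conversion_rate,
                 unconverted_per_100bp = unconverted_per_100bp,
                 gap_fraction = gap_fraction,
                 n_at_cytosine = as.integer(n_at_cytosine),
                 aligned_span = as.integer(aligned_span))
}

# construct a converted read sequence from a reference and a methylation
# vector (1 = methylated), with optional unconverted non-CpG positions
converted_read <- function(ref, meth, artifacts = integer(0)) {
  chars <- strsplit(ref$original, "", fixed = TRUE)[[1]]
  chars[ref$cpg_pos] <- ifelse(meth == 1, "C", "T")
  chars[ref$noncpg_c_pos] <- "T"
  chars[artifacts] <- "C"
  paste(chars, collapse = "")
}

# expected clonal-stage removals, computed from the simulator's truth
# manifest and the set of reads that actually reached the clonal stage:
# within each template-molecule group (chains of duplicate_of resolved to
# their root), every read after the first surviving member is removed iff
# the molecule carries at least one conversion artifact
expected_clonal_removals <- function(truth, passed_ids) {
  root_of <- function(id) {
    while (!is.na(truth$duplicate_of[[id]])) id <- truth$duplicate_of[[id]]
    id
  }
  roots <- vapply(passed_ids, root_of, character(1))
  unlist(lapply(split(passed_ids, roots), function(g) {
    if (length(g) > 1L && length(truth$artifact_pos[[g[1]]]) > 0L) g[-1] else character(0)
  }), use.names = FALSE)
}

# deterministic ZIP fixtures (STORED, fixed timestamps), base64-embedded:
# zip_good holds b.txt ("TTTTAAAA") and a.txt ("ACGTACGT");
# zip_empty_file holds an empty c.txt
.zip_good_b64 <- paste0(
  "UEsDBBQAAAAAAAAAIVChQIpmCQAAAAkAAAAFAAAAYi50eHRUVFRUQUFBQQpQSwMEFAAAAAAAAAAh",
  "UNOrpDkJAAAACQAAAAUAAABhLnR4dEFDR1RBQ0dUClBLAQIUAxQAAAAAAAAAIVChQIpmCQAAAAkA",
  "AAAFAAAAAAAAAAAAAACAAQAAAABiLnR4dFBLAQIUAxQAAAAAAAAAIVDTq6Q5CQAAAAkAAAAFAAAA",
  "AAAAAAAAAACAASwAAABhLnR4dFBLBQYAAAAAAgACAGYAAABYAAAAAAA=")
.zip_empty_b64 <- paste0(
  "UEsDBBQAAAAAAAAAIVAAAAAAAAAAAAAAAAAFAAAAYy50eHRQSwECFAMUAAAAAAAAACFQAAAAAAAA",
  "AAAAAAAABQAAAAAAAAAAAAAAgAEAAAAAYy50eHRQSwUGAAAAAAEAAQAzAAAAIwAAAAAA")

write_zip_fixture <- function(which = c("good", "empty_file")) {
  which <- match.arg(which)
  b64 <- if (which == "good") .zip_good_b64 else .zip_empty_b64
  path <- tempfile(fileext = ".zip")
  writeBin(jsonlite::base64_dec(b64), path)
  path
}

# ---- minimal ABIF (AB1) writer for fixture generation ---------------------

.int32be <- function(x) {
  as.raw(c(bitwAnd(bitwShiftR(x, 24L), 255L), bitwAnd(bitwShiftR(x, 16L), 255L),
           bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))
}
.int16be <- function(x) as.raw(c(bitwAnd(bitwShiftR(x, 8L), 255L), bitwAnd(x, 255L)))

.abif_entry_raw <- function(name, number, type, elsize, numel, datasize, offsetfield) {
  c(charToRaw(name), .int32be(number), .int16be(type), .int16be(elsize),
    .int32be(numel), .int32be(datasize), offsetfield, .int32be(0L))
}

# writes an ABIF file holding PBAS basecall tags; edited -> PBAS.1,
# primary -> PBAS.2; data <= 4 bytes is stored inline in the offset field
write_minimal_ab1 <- function(path, edited = NULL, primary = NULL) {
  tags <- list()
  if (!is.null(edited)) tags <- c(tags, list(list(number = 1L, data = edited)))
  if (!is.null(primary)) tags <- c(tags, list(list(number = 2L, data = primary)))
  stopifnot(length(tags) > 0)
  data_area <- raw(0)
  data_start <- 34L  # "ABIF" + version + 28-byte header entry
  entries <- raw(0)
  for (t in tags) {
    n <- nchar(t$data)
    if (n <= 4L) {
      off <- c(charToRaw(t$data), raw(4L - n))
    } else {
      off <- .int32be(data_start + length(data_area))
      data_area <- c(data_area, charToRaw(t$data))
    }
    entries <- c(entries,
                 .abif_entry_raw("PBAS", t$number, 2L, 1L, n, n, off))
  }
  dir_off <- data_start + length(data_area)
  header <- .abif_entry_raw("tdir", 1L, 1023L, 28L, length(tags),
                            28L * length(tags), .int32be(dir_off))
  writeBin(c(charToRaw("ABIF"), .int16be(101L), header, data_area, entries), path)
  path
}
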