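#' Read a single-record reference FASTA
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A list `(id, sequence)`; the id is the header up to the first
#'   whitespace, the sequence uppercased. IUPAC ambiguity codes other than N
#'   are rejected.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    stop("reference FASTA must contain exactly one record, found ",
         length(set), call. = FALSE)
  }
  seq <- toupper(as.character(set[[1]]))
  if (!nzchar(seq)) stop("reference sequence is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0L) {
    stop("reference contains disallowed characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  id <- sub("\\s.*$", "", names(set)[1])
  list(id = id, sequence = seq)
}

# sanitize a read sequence: uppercase, unexpected letters become N
.clean_read_seq <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  gsub("[^ACGTN]", "N", seq)
}

# parse one per-clone file (FASTA, plain text, or AB1) into a sequence
.read_clone_file <- function(path, ab1 = FALSE) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ab1") {
    if (!ab1) {
      stop("AB1 file encountered but trace support is disabled (set ab1 = TRUE): ",
           basename(path), call. = FALSE)
    }
    return(list(seq = .clean_read_seq(extract_basecalls_ab1(path)), source = "ab1"))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty sequence file: ", basename(path), call. = FALSE)
  }
  if (startsWith(trimws(lines[1]), ">")) {
    headers <- which(startsWith(trimws(lines), ">"))
    if (length(headers) > 1L) {
      stop("per-clone FASTA file has more than one record: ", basename(path),
           call. = FALSE)
    }
    seq <- paste(lines[-1], collapse = "")
    src <- "fasta"
  } else {
    seq <- paste(lines, collapse = "")
    src <- "text"
  }
  seq <- .clean_read_seq(seq)
  if (!nzchar(seq)) stop("empty sequence file: ", basename(path), call. = FALSE)
  list(seq = seq, source = src)
}

#' Read experimental clone reads
#'
#' Accepts a multi-FASTA file, a directory of per-clone files, or a ZIP
#' archive of per-clone files (FASTA, plain text, or AB1 traces when
#' `ab1 = TRUE`). For per-file inputs the read id is the file stem and reads
#' are ordered lexicographically by file name; for multi-FASTA input ids are
#' the headers up to the first whitespace, in record order. Input order is
#' preserved and used for deterministic tie-breaking downstream.
#'
#' @param path Input path.
#' @param ab1 Enable AB1 trace reading (default `FALSE`).
#' @return A tibble (`read_id`, `sequence`, `source`). Duplicate read ids
#'   are an error.
#' @export
read_reads <- function(path, ab1 = FALSE) {
  if (!file.exists(path)) stop("reads input not found: ", path, call. = FALSE)
  if (dir.exists(path)) {
    files <- list.files(path, recursive = TRUE, full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    tbl <- .read_clone_files(files, ab1)
  } else if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("bsclone_zip_")
    dir.create(exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    files <- tryCatch(utils::unzip(path, exdir = exdir),
                      error = function(e) character(0),
                      warning = function(w) character(0))
    files <- files[!dir.exists(files)]
    if (length(files) == 0L) stop("unreadable or empty ZIP archive: ", path, call. = FALSE)
    files <- files[order(basename(files), method = "radix")]
    tbl <- .read_clone_files(files, ab1)
  } else {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
    tbl <- tibble::tibble(
      read_id = sub("\\s.*$", "", names(set)),
      sequence = vapply(as.character(set), .clean_read_seq, character(1),
                        USE.NAMES = FALSE),
      source = "fasta"
    )
    empty <- !nzchar(tbl$sequence)
    if (any(empty)) {
      stop("empty FASTA record(s): ", paste(tbl$read_id[empty], collapse = ", "),
           call. = FALSE)
    }
  }
  dup <- unique(tbl$read_id[duplicated(tbl$read_id)])
  if (length(dup) > 0L) {
    stop("duplicate read ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  tbl
}

.read_clone_files <- function(files, ab1) {
  if (length(files) == 0L) stop("no sequence files found", call. = FALSE)
  rows <- purrr::map(files, function(f) {
    parsed <- .read_clone_file(f, ab1)
    tibble::tibble(
      read_id = tools::file_path_sans_ext(basename(f)),
      sequence = parsed$seq,
      source = parsed$source
    )
  })
  dplyr::bind_rows(rows)
}

# ---- minimal ABIF (AB1) reader -------------------------------------------

.abif_int <- function(raw, from, size) {
  b <- as.integer(raw[from:(from + size - 1L)])
  Reduce(function(acc, x) acc * 256L + x, b)  # big-endian
}

.abif_entry <- function(raw, off) {
  list(
    name = rawToChar(raw[off:(off + 3L)]),
    number = .abif_int(raw, off + 4L, 4L),
    elementtype = .abif_int(raw, off + 8L, 2L),
    elementsize = .abif_int(raw, off + 10L, 2L),
    numelements = .abif_int(raw, off + 12L, 4L),
    datasize = .abif_int(raw, off + 16L, 4L),
    offset_raw = raw[(off + 20L):(off + 23L)],
    dataoffset = .abif_int(raw, off + 20L, 4L)
  )
}

.abif_entry_data <- function(raw, e) {
  if (e$datasize <= 4L) {
    e$offset_raw[seq_len(e$datasize)]
  } else {
    raw[(e$dataoffset + 1L):(e$dataoffset + e$datasize)]
  }
}

#' Extract basecalls from an AB1 (ABIF) trace file
#'
#' Reads the basecall string from an ABIF trace: the edited basecalls
#' (`PBAS` tag number 1) when present, falling back to the primary basecalls
#' (`PBAS` tag number 2). Only the directory and the character-type `PBAS`
#' tags are parsed; chromatogram traces are ignored.
#'
#' @param path Path to an AB1/ABIF file.
#' @return The basecall string (uppercase).
#' @export
extract_basecalls_ab1 <- function(path) {
  if (!file.exists(path)) stop("AB1 file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 34L || rawToChar(raw[1:4]) != "ABIF") {
    stop("not an ABIF file (missing magic bytes): ", basename(path), call. = FALSE)
  }
  header <- .abif_entry(raw, 7L)   # the "tdir" entry describing the directory
  n <- header$numelements
  dir_off <- header$dataoffset
  entries <- lapply(seq_len(n), function(k) .abif_entry(raw, dir_off + 1L + (k - 1L) * 28L))
  pbas <- Filter(function(e) e$name == "PBAS", entries)
  if (length(pbas) == 0L) {
    stop("ABIF file has no PBAS basecall tag: ", basename(path), call. = FALSE)
  }
  nums <- vapply(pbas, `[[`, numeric(1), "number")
  pick <- if (1 %in% nums) pbas[[which(nums == 1)[1]]] else pbas[[which.min(nums)]]
  toupper(rawToChar(.abif_entry_data(raw, pick)))
}
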