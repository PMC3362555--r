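#' Read a species-labelled reference alignment from multi-FASTA
#'
#' Reads a pre-aligned multi-FASTA file into an alignment table. Sequences
#' are stored uppercase with `U` normalised to `T` and `?` converted to `N`;
#' the only gap character accepted is `-`. Every record must have the same
#' number of columns. A species label is parsed from each record identifier:
#' by default everything up to the last `species_delim` (records without the
#' delimiter keep their whole identifier as the label, so one-sequence-per-
#' species libraries work unchanged).
#'
#' @param path Path to an aligned multi-FASTA file.
#' @param species_delim Single character separating the species label from a
#'   specimen suffix in record identifiers. Default `"_"`.
#' @param species_fun Optional function mapping a character vector of
#'   identifiers to species labels; overrides `species_delim`.
#' @return A tibble with columns `id`, `species` and `sequence`, one row per
#'   record, in file order. The alignment length is `nchar(sequence)` and is
#'   identical across rows.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp1_a", "ACGTACGTAC", ">sp1_b", "ACGTACGTAC"), fa)
#' read_alignment(fa)
#' @export
read_alignment <- function(path, species_delim = "_", species_fun = NULL) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  names(seqs) <- ids
  new_alignment(ids, seqs, species_delim = species_delim,
                species_fun = species_fun)
}

#' Construct an alignment table from sequences in memory
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param species Optional character vector of species labels, recycled
#'   against `ids`; when `NULL`, labels are parsed from `ids`.
#' @inheritParams read_alignment
#' @return A tibble with columns `id`, `species`, `sequence`.
#' @export
new_alignment <- function(ids, seqs, species = NULL, species_delim = "_",
                          species_fun = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- normalise_sequences(as.character(seqs), ids)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("alignment is ragged: record '", bad, "' has ", nchar(seqs[bad]),
         " columns, expected ", lens[1L], call. = FALSE)
  }
  if (is.null(species)) {
    species <- if (is.null(species_fun)) {
      species_from_id(ids, species_delim)
    } else {
      as.character(species_fun(ids))
    }
  }
  tibble::tibble(id = ids, species = rep_len(as.character(species),
                                             length(ids)),
                 sequence = unname(seqs))
}

species_from_id <- function(ids, delim = "_") {
  vapply(ids, function(id) {
    parts <- strsplit(id, delim, fixed = TRUE)[[1L]]
    if (length(parts) <= 1L) id
    else paste(parts[-length(parts)], collapse = delim)
  }, character(1L), USE.NAMES = FALSE)
}

normalise_sequences <- function(seqs, ids) {
  seqs <- toupper(seqs)
  seqs <- chartr("U?", "TN", seqs)
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record '", ids[nchar(seqs) == 0L][1L], "'",
         call. = FALSE)
  bad <- regexpr(paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("illegal character '", substr(seqs[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i], call. = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write an alignment table to multi-FASTA
#'
#' @param aln Alignment tibble as returned by [read_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  check_alignment(aln)
  writeLines(paste0(">", aln$id, "\n", aln$sequence), path)
  invisible(path)
}

check_alignment <- function(aln, min_species = 1L) {
  stopifnot(is.data.frame(aln),
            all(c("id", "species", "sequence") %in% names(aln)))
  if (nrow(aln) == 0L) stop("alignment has no records", call. = FALSE)
  if (length(unique(nchar(aln$sequence))) != 1L)
    stop("alignment is ragged", call. = FALSE)
  if (length(unique(aln$species)) < min_species)
    stop("need at least ", min_species, " species", call. = FALSE)
  invisible(aln)
}

#' Read unaligned reads from FASTA or FASTQ
#'
#' The format is sniffed from the first non-empty character (`>` FASTA, `@`
#' FASTQ); FASTQ quality strings are discarded. A per-sample tag can be
#' parsed from the read identifier suffix.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param sample_delim Optional single character; when given, the text after
#'   its last occurrence in the identifier becomes `sample_id`.
#' @return A tibble with columns `read_id`, `sequence`, `sample_id`
#'   (`NA` when no delimiter is configured or present).
#' @export
read_reads <- function(path, sample_delim = NULL) {
  first <- substr(trimws(readLines(path, n = 1L, warn = FALSE)[1] %||% ""),
                  1L, 1L)
  if (is.na(first) || !nzchar(first)) stop("empty read file: ", path,
                                           call. = FALSE)
  fmt <- switch(first, ">" = "fasta", "@" = "fastq",
                stop("unrecognised read format in ", path,
                     " (expected FASTA or FASTQ)", call. = FALSE))
  if (fmt == "fastq") check_fastq_structure(path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = fmt),
    error = function(e) {
      stop("malformed ", toupper(fmt), " in ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (length(ss) == 0L) stop("empty read file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate read identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- normalise_sequences(as.character(ss), ids)
  sample_id <- rep(NA_character_, length(ids))
  if (!is.null(sample_delim)) {
    has <- grepl(sample_delim, ids, fixed = TRUE)
    sample_id[has] <- sub(paste0(".*\\", sample_delim), "",
                          ids[has])
    ids[has] <- sub(paste0("\\", sample_delim, "[^", sample_delim, "]*$"),
                    "", ids[has])
  }
  tibble::tibble(read_id = ids, sequence = unname(seqs),
                 sample_id = sample_id)
}

# Four lines per record: @id / sequence / + / qualities, with matching
# sequence and quality lengths.
check_fastq_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": truncated record ",
         ceiling(n / 4), call. = FALSE)
  rec <- matrix(lines, nrow = 4L)
  bad <- which(!startsWith(rec[1L, ], "@") | !startsWith(rec[3L, ], "+") |
                 nchar(rec[2L, ]) != nchar(rec[4L, ]))
  if (length(bad))
    stop("malformed FASTQ in ", path, ": record ", bad[1L], call. = FALSE)
  invisible(path)
}

#' Write reads to FASTA
#'
#' @param reads Read tibble as returned by [read_reads()].
#' @param path Output file path.
#' @param sample_delim Optional delimiter used to append `sample_id` to each
#'   identifier.
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path, sample_delim = NULL) {
  ids <- reads$read_id
  if (!is.null(sample_delim)) {
    has <- !is.na(reads$sample_id)
    ids[has] <- paste0(ids[has], sample_delim, reads$sample_id[has])
  }
  writeLines(paste0(">", ids, "\n", reads$sequence), path)
  invisible(path)
}
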