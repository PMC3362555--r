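#' Dereplicate reads into unique amplicons
#'
#' Collapses exact duplicate sequences after orienting every read to the
#' forward strand: a read that matches the forward primer in reverse
#' complement (but not forward) is flipped. Counts are pooled across
#' samples; the set of samples each amplicon was seen in is retained.
#'
#' @param reads Read tibble from [read_reads()] (columns `read_id`,
#'   `sequence`, `sample_id`).
#' @param pp Optional [primer_pair()] used for orientation; without it
#'   reads are taken as already oriented.
#' @return A tibble with columns `sequence`, `count` and `samples` (list
#'   column of sample ids), ordered by decreasing count then sequence.
#' @export
dereplicate <- function(reads, pp = NULL) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in%
                                        names(reads)))
  seqs <- toupper(reads$sequence)
  if (!is.null(pp)) {
    mm <- pp$max_mismatch
    flip <- vapply(seqs, function(s) {
      length(scan_primer(pp$forward, s, mm)) == 0L &&
        length(scan_primer(reverse_complement(pp$forward), s, mm)) > 0L
    }, logical(1L), USE.NAMES = FALSE)
    seqs[flip] <- reverse_complement(seqs[flip])
  }
  samples <- if ("sample_id" %in% names(reads)) reads$sample_id else
    rep(NA_character_, length(seqs))
  tibble::tibble(sequence = seqs, sample_id = samples) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(
      count = dplyr::n(),
      samples = list(sort(unique(stats::na.omit(.data$sample_id)))),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
}

#' Filter amplicons on length, primer presence and copy number
#'
#' Applies the degraded-DNA quality filters: amplicons are kept when their
#' length lies within `[min_len, max_len]` (both bounds inclusive), at
#' least one complete primer is found at a read end (when
#' `require_primer`), and they were observed at least `min_count` times —
#' the copy-number filter that removes singleton chimeras and PCR
#' artefacts. Every rejected amplicon is annotated with its first failing
#' reason, checked in that order.
#'
#' @param amps Amplicon tibble from [dereplicate()].
#' @param pp [primer_pair()] used for the primer check (`NULL` only
#'   allowed when `require_primer = FALSE`).
#' @param min_len,max_len Inclusive length bounds (defaults 120 and 160).
#' @param min_count Minimum pooled copy number (default 5).
#' @param require_primer Require a complete primer at a read end
#'   (default `TRUE`).
#' @return The input tibble with logical `kept` and character `reason`
#'   (`NA` for kept amplicons; otherwise `"too_short"`, `"too_long"`,
#'   `"no_primer"` or `"low_count"`).
#' @export
quality_filter <- function(amps, pp = NULL, min_len = 120L, max_len = 160L,
                           min_count = 5L, require_primer = TRUE) {
  stopifnot(min_len <= max_len, min_count >= 1L)
  if (require_primer && is.null(pp))
    stop("a primer pair is needed when require_primer = TRUE",
         call. = FALSE)
  len <- nchar(amps$sequence)
  reason <- rep(NA_character_, nrow(amps))
  reason[len < min_len] <- "too_short"
  reason[is.na(reason) & len > max_len] <- "too_long"
  if (require_primer) {
    idx <- which(is.na(reason))
    has <- vapply(amps$sequence[idx], has_terminal_primer, logical(1L),
                  pp = pp, USE.NAMES = FALSE)
    reason[idx[!has]] <- "no_primer"
  }
  reason[is.na(reason) & amps$count < min_count] <- "low_count"
  amps$kept <- is.na(reason)
  amps$reason <- reason
  amps
}

# A complete primer at a read end: the forward primer flush with the 5'
# end, or the reverse-complemented reverse primer flush with the 3' end
# (reads are oriented by dereplicate()).
has_terminal_primer <- function(seq, pp) {
  mm <- pp$max_mismatch
  L <- nchar(seq)
  flen <- nchar(pp$forward)
  if (L >= flen &&
      iupac_match(pp$forward, substr(seq, 1L, flen)) <= mm) return(TRUE)
  rc <- reverse_complement(pp$reverse)
  rlen <- nchar(rc)
  L >= rlen && iupac_match(rc, substr(seq, L - rlen + 1L, L)) <= mm
}

# p-distance between two unaligned sequences over the end-gap-free
# (overlap) pairwise alignment of their best-matching region; internal
# gaps are excluded from the comparison (pairwise deletion).
overlap_pdistance <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 5, gapExtension = 2)
  nm <- Biostrings::nmismatch(al)
  comp <- Biostrings::nmatch(al) + nm
  if (comp == 0L) return(list(distance = NA_real_, compared = 0L))
  list(distance = nm / comp, compared = comp)
}

#' Assign amplicons to a reference library
#'
#' Each amplicon is compared to every (gap-stripped) library sequence by
#' p-distance over an end-gap-free pairwise alignment of the overlapping
#' region. The amplicon is assigned to the species of its closest library
#' sequence when the distance is at most `max_assign_dist`; when two
#' different species tie exactly at the minimum the amplicon is
#' `"ambiguous"`, and when the minimum exceeds the threshold it is
#' `"unassigned"`.
#'
#' @param amps Amplicon tibble (column `sequence`; typically the kept rows
#'   of [quality_filter()]).
#' @param library Alignment tibble of reference sequences with species
#'   labels.
#' @param max_assign_dist Maximum distance for a species assignment
#'   (default 0.02, comfortably below typical inter-species divergence).
#' @return `amps` with columns `assignment` and `best_distance` added.
#' @export
assign_amplicons <- function(amps, library, max_assign_dist = 0.02) {
  check_alignment(library)
  refs <- gsub("-", "", library$sequence, fixed = TRUE)
  ref_species <- library$species
  res <- lapply(amps$sequence, function(s) {
    dd <- vapply(refs, function(r) overlap_pdistance(s, r)$distance,
                 numeric(1L), USE.NAMES = FALSE)
    if (all(is.na(dd)))
      return(list(assignment = "unassigned", best_distance = NA_real_))
    best <- min(dd, na.rm = TRUE)
    sp <- unique(ref_species[!is.na(dd) & dd == best])
    assignment <-
      if (best > max_assign_dist) "unassigned"
      else if (length(sp) > 1L) "ambiguous"
      else sp
    list(assignment = assignment, best_distance = best)
  })
  amps$assignment <- vapply(res, `[[`, character(1L), "assignment")
  amps$best_distance <- vapply(res, `[[`, numeric(1L), "best_distance")
  amps
}

#' Cluster unassigned amplicons into putative novel clades
#'
#' Single-linkage clustering of the `"unassigned"` amplicons at p-distance
#' `link_dist`: two amplicons fall in the same cluster when a chain of
#' pairwise distances of at most `link_dist` connects them. Clusters are
#' labelled `novel:1`, `novel:2`, ... in order of decreasing total read
#' count, and the labels replace `"unassigned"` in the `assignment`
#' column. Clusters of well-separated sequences correspond to species
#' missing from the reference library.
#'
#' @param amps Amplicon tibble after [assign_amplicons()].
#' @param link_dist Single-linkage threshold (default 0.04, a common
#'   species-delimitation floor for this kind of marker).
#' @return `amps` with novel-clade labels in `assignment`.
#' @export
cluster_novel <- function(amps, link_dist = 0.04) {
  un <- which(amps$assignment == "unassigned")
  if (length(un) == 0L) return(amps)
  seqs <- amps$sequence[un]
  n <- length(seqs)
  labels <- if (n == 1L) 1L else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- overlap_pdistance(seqs[i], seqs[j])$distance
    }
    d[is.na(d)] <- 1
    stats::cutree(stats::hclust(stats::as.dist(d), method = "single"),
                  h = link_dist)
  }
  counts <- if ("count" %in% names(amps)) amps$count[un] else
    rep(1L, length(un))
  totals <- tapply(counts, labels, sum)
  rank <- rank(-totals, ties.method = "first")
  amps$assignment[un] <- paste0("novel:", rank[as.character(labels)])
  amps
}

#' Percentage arithmetic for the run report
#'
#' @param raw Total raw reads.
#' @param good Reads passing the quality filters.
#' @param matched Reads assigned to a library species.
#' @return A list with `pct_good` (percentage of raw reads that were good,
#'   one decimal) and `pct_matched` (percentage of good reads matched to
#'   the library, nearest integer).
#' @export
report_percentages <- function(raw, good, matched = NA) {
  list(pct_good = if (raw > 0) round(100 * good / raw, 1) else NA_real_,
       pct_matched = if (!is.na(matched) && good > 0)
         round(100 * matched / good) else NA_real_)
}

#' Summarise an amplicon pipeline run
#'
#' @param amps Amplicon tibble after filtering, assignment and (optionally)
#'   novel-clade clustering; must carry `count`, `kept` and `assignment`.
#' @param n_raw Total number of raw reads entering the pipeline (defaults
#'   to the sum of all counts, i.e. no reads lost upstream).
#' @return An `amplicon_report` object with a `totals` tibble (raw, good,
#'   matched counts and the report percentages), a per-`species` table
#'   (read counts and sample incidence) and a `novel` clade table.
#' @export
summary_report <- function(amps, n_raw = sum(amps$count)) {
  stopifnot(all(c("count", "kept", "assignment") %in% names(amps)))
  if (!"best_distance" %in% names(amps)) amps$best_distance <- NA_real_
  if (!"samples" %in% names(amps)) amps$samples <- list(character())
  kept <- dplyr::filter(amps, .data$kept)
  good <- sum(kept$count)
  is_species <- !kept$assignment %in% c("unassigned", "ambiguous") &
    !startsWith(kept$assignment, "novel:")
  matched <- sum(kept$count[is_species])
  pct <- report_percentages(n_raw, good, matched)
  species <- kept[is_species, ] |>
    dplyr::group_by(species = .data$assignment) |>
    dplyr::summarise(
      reads = sum(.data$count),
      n_amplicons = dplyr::n(),
      n_samples = length(unique(unlist(.data$samples))),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$reads))
  novel <- kept[startsWith(kept$assignment, "novel:"), ] |>
    dplyr::group_by(clade = .data$assignment) |>
    dplyr::summarise(
      reads = sum(.data$count),
      n_amplicons = dplyr::n(),
      n_samples = length(unique(unlist(.data$samples))),
      min_library_distance = {
        bd <- .data$best_distance[!is.na(.data$best_distance)]
        if (length(bd)) min(bd) else NA_real_
      },
      .groups = "drop") |>
    dplyr::arrange(.data$clade)
  structure(list(
    totals = tibble::tibble(raw = n_raw, good = good, matched = matched,
                            pct_good = pct$pct_good,
                            pct_matched = pct$pct_matched,
                            n_species = nrow(species),
                            n_novel = nrow(novel)),
    species = species, novel = novel), class = "amplicon_report")
}

#' @export
print.amplicon_report <- function(x, ...) {
  t <- x$totals
  cat("Amplicon pipeline report\n")
  cat("  raw reads:            ", t$raw, "\n", sep = "")
  cat("  good-quality reads:   ", t$good, " (", t$pct_good, "% of raw)\n",
      sep = "")
  cat("  library-matched reads: ", t$matched, " (", t$pct_matched,
      "% of good)\n", sep = "")
  cat("  species detected:     ", t$n_species, "\n", sep = "")
  cat("  novel clades:         ", t$n_novel, "\n", sep = "")
  if (nrow(x$species)) { cat("\nPer-species counts:\n"); print(x$species) }
  if (nrow(x$novel)) { cat("\nNovel clades:\n"); print(x$novel) }
  invisible(x)
}

#' @rdname summary_report
#' @param x An `amplicon_report` object.
#' @param ... Unused.
#' @export
tidy.amplicon_report <- function(x, ...) x$species

#' @rdname summary_report
#' @export
glance.amplicon_report <- function(x, ...) x$totals

#' Run the full degraded-DNA amplicon pipeline
#'
#' Dereplication, quality filtering, library assignment and novel-clade
#' clustering in one call.
#'
#' @param reads Read tibble from [read_reads()].
#' @param library Reference alignment tibble.
#' @param pp A [primer_pair()].
#' @param min_len,max_len,min_count,require_primer See [quality_filter()].
#' @param max_assign_dist See [assign_amplicons()].
#' @param link_dist See [cluster_novel()].
#' @return A list with `amplicons` (the fully annotated amplicon tibble)
#'   and `report` (an `amplicon_report`).
#' @export
run_pipeline <- function(reads, library, pp, min_len = 120L,
                         max_len = 160L, min_count = 5L,
                         require_primer = TRUE, max_assign_dist = 0.02,
                         link_dist = 0.04) {
  amps <- dereplicate(reads, pp)
  amps <- quality_filter(amps, pp, min_len = min_len, max_len = max_len,
                         min_count = min_count,
                         require_primer = require_primer)
  kept_idx <- which(amps$kept)
  amps$assignment <- NA_character_
  amps$best_distance <- NA_real_
  if (length(kept_idx)) {
    assigned <- assign_amplicons(amps[kept_idx, ], library,
                                 max_assign_dist = max_assign_dist)
    assigned <- cluster_novel(assigned, link_dist = link_dist)
    amps$assignment[kept_idx] <- assigned$assignment
    amps$best_distance[kept_idx] <- assigned$best_distance
  }
  list(amplicons = amps, report = summary_report(amps,
                                                 n_raw = sum(amps$count)))
}
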