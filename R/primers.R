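#' IUPAC utilities and degenerate primer matching
#'
#' `iupac_match()` counts mismatches between a degenerate pattern and a
#' same-length stretch of sequence: a position matches when the sequence
#' base belongs to the expansion set of the pattern's IUPAC code (e.g. `R`
#' matches `A` or `G`). A gap or ambiguity code in the *sequence* never
#' matches and is counted as a mismatch.
#'
#' @param pattern IUPAC-degenerate string (the primer).
#' @param text Sequence stretch of the same length.
#' @return Integer mismatch count.
#' @examples
#' iupac_match("ACMGT", "ACAGT") # 0: M = A or C
#' iupac_match("ACMGT", "ACGGT") # 1
#' @export
iupac_match <- function(pattern, text) {
  if (nchar(pattern) != nchar(text))
    stop("pattern and text have different lengths", call. = FALSE)
  p <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  t <- strsplit(toupper(text), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(p), names(IUPAC_EXPANSION))
  if (length(bad))
    stop("invalid IUPAC code(s) in pattern: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sum(!iupac_hit(p, t))
}

# vectorised per-position test: does sequence base t fall in pattern code p?
iupac_hit <- function(p, t) {
  m <- iupac_match_table()
  ti <- match(t, c("A", "C", "G", "T"))
  pi <- match(p, rownames(m))
  hit <- !is.na(ti) & !is.na(pi)
  hit[hit] <- m[cbind(pi[hit], ti[hit])]
  hit
}

iupac_match_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- t(vapply(IUPAC_EXPANSION, function(ex)
        c("A", "C", "G", "T") %in% ex, logical(4L)))
      colnames(tab) <<- c("A", "C", "G", "T")
    }
    tab
  }
})

#' Reverse complement of an IUPAC sequence
#'
#' Complements ambiguity codes correctly (R to Y, B to V, ...) and keeps
#' gap characters.
#'
#' @param x Character vector of IUPAC sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Define a degenerate primer pair
#'
#' @param forward Forward primer, written 5' to 3'.
#' @param reverse Reverse primer, written 5' to 3' on the opposite strand.
#' @param max_mismatch Mismatches tolerated per primer site (default 0:
#'   group specificity relies on exact degenerate-site discrimination).
#' @return A `primer_pair` object.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 0L) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 10L)
      stop("primer '", p, "' is shorter than 10 nt", call. = FALSE)
    chars <- strsplit(p, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), names(IUPAC_EXPANSION))
    if (length(bad))
      stop("invalid IUPAC code(s) in primer: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  stopifnot(max_mismatch >= 0L)
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Degenerate primer pair\n  forward: 5'-", x$forward, "-3'\n",
      "  reverse: 5'-", x$reverse, "-3'\n",
      "  mismatches allowed per site: ", x$max_mismatch, "\n", sep = "")
  invisible(x)
}

# All start positions where `primer` matches `seq` with <= mm mismatches.
scan_primer <- function(primer, seq, mm = 0L) {
  k <- nchar(primer)
  L <- nchar(seq)
  if (L < k) return(integer())
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1L]]
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  hitmat <- iupac_hit(rep(p, times = L - k + 1L),
                      s[outer(seq_len(k), 0:(L - k), `+`)])
  dim(hitmat) <- c(k, L - k + 1L)
  which(colSums(!hitmat) <= mm)
}

#' In-silico PCR with degenerate primers
#'
#' Locates forward-primer sites and, downstream of each, sites matching the
#' reverse complement of the reverse primer, on both orientations of the
#' template. Gap characters in the template are stripped first. The
#' amplicon includes both primer binding sites, so the product length is
#' forward length + insert + reverse length. For each forward site the
#' shortest product within `max_product` is reported; several
#' non-overlapping products are all returned with `multiple = TRUE`.
#'
#' @param template Template sequence (may contain gaps, which are removed).
#' @param pp A [primer_pair()].
#' @param max_product Longest product considered (default 1000 nt).
#' @return A tibble with zero or more rows: `sequence` (amplicon, forward
#'   primer first), `start`, `end` (1-based span on the input template's
#'   forward strand), `length`, `strand` (`"+"`/`"-"`) and `multiple`.
#' @export
insilico_pcr <- function(template, pp, max_product = 1000L) {
  stopifnot(inherits(pp, "primer_pair"))
  tpl <- gsub("-", "", toupper(template), fixed = TRUE)
  L <- nchar(tpl)
  hits <- dplyr::bind_rows(
    pcr_one_strand(tpl, pp, max_product, "+", L),
    pcr_one_strand(reverse_complement(tpl), pp, max_product, "-", L))
  if (nrow(hits) > 1L) {
    hits <- dplyr::distinct(hits, .data$start, .data$end, .keep_all = TRUE)
    hits$multiple <- nrow(hits) > 1L
  }
  hits
}

pcr_one_strand <- function(seq, pp, max_product, strand, L) {
  mm <- pp$max_mismatch
  f_sites <- scan_primer(pp$forward, seq, mm)
  out <- list()
  if (length(f_sites)) {
    rc_rev <- reverse_complement(pp$reverse)
    r_sites <- scan_primer(rc_rev, seq, mm)
    flen <- nchar(pp$forward); rlen <- nchar(rc_rev)
    for (fs in f_sites) {
      cand <- r_sites[r_sites >= fs + flen]
      ends <- cand + rlen - 1L
      keep <- ends - fs + 1L <= max_product
      if (!any(keep)) next
      en <- min(ends[keep])
      span <- if (strand == "+") c(fs, en) else c(L - en + 1L, L - fs + 1L)
      out[[length(out) + 1L]] <- tibble::tibble(
        sequence = substr(seq, fs, en),
        start = span[1L], end = span[2L],
        length = en - fs + 1L, strand = strand, multiple = FALSE)
    }
  }
  dplyr::bind_rows(out)
}

#' Screen a primer pair for group specificity
#'
#' Runs [insilico_pcr()] against every target and non-target sequence and
#' summarises the fraction of each group amplified. Group-specific primers
#' should amplify all targets and no non-targets.
#'
#' @param pp A [primer_pair()].
#' @param targets Alignment tibble (gaps are stripped) or character vector
#'   of target sequences.
#' @param nontargets Character vector (or alignment tibble) of non-target
#'   sequences; may be empty.
#' @param max_product Passed to [insilico_pcr()].
#' @return A `specificity_screen` object: per-sequence verdict tibble plus
#'   `target_fraction` and `nontarget_fraction` (`NA` when no non-targets
#'   are supplied).
#' @export
specificity_screen <- function(pp, targets, nontargets = character(),
                               max_product = 1000L) {
  as_seqs <- function(x, prefix) {
    if (is.data.frame(x)) stats::setNames(x$sequence, x$id)
    else if (is.null(names(x)) && length(x))
      stats::setNames(x, paste0(prefix, seq_along(x)))
    else x
  }
  tg <- as_seqs(targets, "target")
  nt <- as_seqs(nontargets, "nontarget")
  verdict <- function(seqs, group) {
    if (length(seqs) == 0L)
      return(tibble::tibble(id = character(), group = character(),
                            amplified = logical(), n_products = integer(),
                            product_length = integer()))
    dplyr::bind_rows(lapply(names(seqs), function(id) {
      amp <- insilico_pcr(seqs[[id]], pp, max_product)
      tibble::tibble(id = id, group = group, amplified = nrow(amp) > 0L,
                     n_products = nrow(amp),
                     product_length = if (nrow(amp)) amp$length[1L] else
                       NA_integer_)
    }))
  }
  per_seq <- dplyr::bind_rows(verdict(tg, "target"),
                              verdict(nt, "nontarget"))
  structure(list(
    per_sequence = per_seq,
    target_fraction = if (length(tg))
      mean(per_seq$amplified[per_seq$group == "target"]) else NA_real_,
    nontarget_fraction = if (length(nt))
      mean(per_seq$amplified[per_seq$group == "nontarget"]) else NA_real_),
    class = "specificity_screen")
}

#' @export
print.specificity_screen <- function(x, ...) {
  cat("Primer specificity screen\n")
  cat("  targets amplified:    ",
      format_frac(x$target_fraction,
                  sum(x$per_sequence$group == "target")), "\n", sep = "")
  cat("  nontargets amplified: ",
      format_frac(x$nontarget_fraction,
                  sum(x$per_sequence$group == "nontarget")), "\n", sep = "")
  invisible(x)
}

format_frac <- function(f, n) {
  if (is.na(f)) "NA (none supplied)"
  else paste0(round(f * n), "/", n, " (", round(100 * f, 1), "%)")
}

#' @rdname specificity_screen
#' @param x A `specificity_screen` object.
#' @param ... Unused.
#' @export
tidy.specificity_screen <- function(x, ...) x$per_sequence

#' @rdname specificity_screen
#' @export
glance.specificity_screen <- function(x, ...) {
  tibble::tibble(target_fraction = x$target_fraction,
                 nontarget_fraction = x$nontarget_fraction)
}
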