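#' Uncorrected p-distance between two aligned sequences
#'
#' Computes the proportion of mismatching sites under pairwise deletion:
#' any column where either sequence carries a gap or an IUPAC ambiguity code
#' is excluded before counting. With no comparable site the distance is
#' undefined (`NA`) and `compared` is 0.
#'
#' @param a,b Aligned IUPAC sequences of equal length.
#' @return A list with `distance` (fraction in `[0, 1]`, or `NA` when no
#'   site is comparable) and `compared` (number of sites used).
#' @examples
#' pdistance("ACGT", "ACGT")
#' pdistance("AC-TN", "ACGTA") # gap and N columns are dropped
#' @export
pdistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  ea <- encode_acgt(toupper(a))[1L, ]
  eb <- encode_acgt(toupper(b))[1L, ]
  ok <- !is.na(ea) & !is.na(eb)
  compared <- sum(ok)
  if (compared == 0L) return(list(distance = NA_real_, compared = 0L))
  list(distance = sum(ea[ok] != eb[ok]) / compared, compared = compared)
}

#' All-pairs distance matrix over an alignment window
#'
#' Applies [pdistance()] to every pair of records over the selected columns.
#'
#' @param aln Alignment tibble (see [read_alignment()]).
#' @param window Optional integer vector `c(start, end)` of 1-based,
#'   inclusive column bounds; the whole alignment when `NULL`.
#' @return An object of class `mb_dist`: a list with `labels`, the symmetric
#'   matrix `d` of distances (`NA` marks pairs with no comparable site) and
#'   the symmetric matrix `sites` of compared-site counts.
#' @export
distance_matrix <- function(aln, window = NULL) {
  check_alignment(aln)
  enc <- encode_acgt(stats::setNames(aln$sequence, aln$id))
  L <- ncol(enc)
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    if (window[1L] < 1L || window[2L] > L || window[1L] > window[2L])
      stop("window [", window[1L], ", ", window[2L],
           "] outside alignment columns [1, ", L, "]", call. = FALSE)
    enc <- enc[, window[1L]:window[2L], drop = FALSE]
  }
  dist_from_encoded(enc, aln$id)
}

dist_from_encoded <- function(enc, labels) {
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  sites <- matrix(ncol(enc), n, n, dimnames = list(labels, labels))
  ok <- !is.na(enc)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        comp <- ok[i, ] & ok[j, ]
        nc <- sum(comp)
        sites[i, j] <- sites[j, i] <- nc
        d[i, j] <- d[j, i] <-
          if (nc == 0L) NA_real_ else sum(enc[i, comp] != enc[j, comp]) / nc
      }
    }
  }
  structure(list(labels = labels, d = d, sites = sites), class = "mb_dist")
}

#' @export
print.mb_dist <- function(x, ...) {
  cat("Pairwise p-distance matrix (pairwise deletion), ",
      length(x$labels), " sequences\n", sep = "")
  print(round(x$d, 4), ...)
  invisible(x)
}

#' Proportion of zero non-conspecific distances
#'
#' The identification criterion for a candidate window: among pairs of
#' sequences from *different* species with a defined distance, the fraction
#' whose distance is exactly zero. A value of 0 means every species pair is
#' distinguishable within the window; pairs with no comparable site are
#' excluded from both numerator and denominator.
#'
#' @param dm `mb_dist` object from [distance_matrix()].
#' @param species Character vector of species labels, one per matrix label
#'   (in the same order), or a named vector keyed by label.
#' @return A proportion in `[0, 1]`.
#' @export
zero_noncon_prop <- function(dm, species) {
  stopifnot(inherits(dm, "mb_dist"))
  sp <- align_species(dm$labels, species)
  if (length(unique(sp)) < 2L)
    stop("need at least 2 species", call. = FALSE)
  n <- length(dm$labels)
  idx <- which(upper.tri(dm$d), arr.ind = TRUE)
  noncon <- sp[idx[, 1L]] != sp[idx[, 2L]]
  dd <- dm$d[idx][noncon]
  dd <- dd[!is.na(dd)]
  if (length(dd) == 0L)
    stop("window uninformative: no non-conspecific pair with comparable sites",
         call. = FALSE)
  sum(dd == 0) / length(dd)
}

align_species <- function(labels, species) {
  if (!is.null(names(species))) {
    miss <- setdiff(labels, names(species))
    if (length(miss))
      stop("no species label for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    unname(species[labels])
  } else {
    stopifnot(length(species) == length(labels))
    as.character(species)
  }
}

#' Export a distance matrix as TSV
#'
#' Writes labels in the first row and column and distances to 6 decimals.
#'
#' @param dm `mb_dist` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path) {
  stopifnot(inherits(dm, "mb_dist"))
  m <- format(round(dm$d, 6), nsmall = 6, trim = TRUE)
  m[is.na(dm$d)] <- "NA"
  lines <- c(paste(c("", dm$labels), collapse = "\t"),
             vapply(seq_along(dm$labels), function(i)
               paste(c(dm$labels[i], m[i, ]), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}
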