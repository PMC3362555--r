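#' Enumerate candidate mini-barcode windows
#'
#' All contiguous windows of each requested width over an alignment of `L`
#' columns, advancing by `step` columns: for width `w` the starts are
#' `1, 1 + step, ...` up to `L - w + 1`.
#'
#' @param L Alignment length in columns.
#' @param widths Integer vector of window widths (bp). Widths larger than
#'   `L` are skipped with a warning.
#' @param step Start increment in columns (default 1).
#' @return A tibble with columns `start` and `width`, one row per window.
#' @examples
#' nrow(enumerate_windows(419, c(25, 50, 100, 150, 200, 250))) # 1745
#' @export
enumerate_windows <- function(L, widths = c(25, 50, 100, 150, 200, 250),
                              step = 1L) {
  stopifnot(L >= 1L, step >= 1L, all(widths >= 1L))
  widths <- as.integer(widths)
  if (any(widths > L)) {
    warning("width(s) ", paste(widths[widths > L], collapse = ", "),
            " exceed alignment length ", L, "; skipped")
    widths <- widths[widths <= L]
  }
  if (length(widths) == 0L)
    return(tibble::tibble(start = integer(), width = integer()))
  dplyr::bind_rows(lapply(widths, function(w)
    tibble::tibble(start = seq.int(1L, L - w + 1L, by = step), width = w)))
}

# When no reference clade lies strictly below the median depth the strict
# shallow rule would leave nothing to compare; fall back to the inclusive
# rule with a warning.
effective_shallow_rule <- function(ref_clades, shallow_rule) {
  if (shallow_rule == "strict" && nrow(ref_clades) > 0L &&
      !any(ref_clades$depth < stats::median(ref_clades$depth))) {
    warning("no reference clades lie strictly below the median depth; ",
            "using the inclusive shallow rule (depth <= median)",
            call. = FALSE)
    shallow_rule <- "inclusive"
  }
  shallow_rule
}

# Precompute per-pair cumulative mismatch/comparable-site counts and
# per-column summaries so any window's statistics are O(#pairs).
slide_precompute <- function(aln) {
  check_alignment(aln, min_species = 2L)
  enc <- encode_acgt(stats::setNames(aln$sequence, aln$id))
  n <- nrow(enc); L <- ncol(enc)
  ok <- !is.na(enc)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  np <- nrow(pairs)
  comp <- matrix(FALSE, np, L)
  mis <- matrix(FALSE, np, L)
  for (p in seq_len(np)) {
    i <- pairs[p, 1L]; j <- pairs[p, 2L]
    cc <- ok[i, ] & ok[j, ]
    comp[p, ] <- cc
    mis[p, cc] <- enc[i, cc] != enc[j, cc]
  }
  cum <- function(m) cbind(0L, t(apply(m, 1L, cumsum)))
  species <- aln$species
  gc_col <- colSums(enc == 2L | enc == 3L, na.rm = TRUE)
  valid_col <- colSums(ok)
  diag_col <- diagnostic_columns(enc, species)
  list(enc = enc, n = n, L = L, labels = aln$id, species = species,
       pairs = pairs, noncon = species[pairs[, 1L]] != species[pairs[, 2L]],
       ccomp = cum(comp), cmis = cum(mis),
       cgc = c(0, cumsum(gc_col)), cvalid = c(0, cumsum(valid_col)),
       cdiag = c(0L, cumsum(diag_col)))
}

# A column is species-diagnostic when some species is fixed for an
# unambiguous base that no sequence of any other species carries there;
# a gap or ambiguity code within the species disqualifies it.
diagnostic_columns <- function(enc, species) {
  sp <- unique(species)
  vapply(seq_len(ncol(enc)), function(cl) {
    col <- enc[, cl]
    for (s in sp) {
      mine <- col[species == s]
      if (anyNA(mine) || length(unique(mine)) != 1L) next
      if (!any(col[species != s] == mine[1L], na.rm = TRUE)) return(TRUE)
    }
    FALSE
  }, logical(1L))
}

# All metrics for one window, given the precompute; returns a one-row list.
window_metrics_one <- function(pre, start, width, ref_clades, shallow_rule) {
  e <- start + width - 1L
  compN <- pre$ccomp[, e + 1L] - pre$ccomp[, start]
  misN <- pre$cmis[, e + 1L] - pre$cmis[, start]
  defined <- compN > 0L
  dvec <- ifelse(defined, misN / pmax(compN, 1L), NA_real_)
  ncd <- pre$noncon & defined
  zero_noncon <- if (any(ncd)) sum(misN[ncd] == 0L) / sum(ncd) else NA_real_
  sum_dist <- sum(dvec[defined])
  nvalid <- pre$cvalid[e + 1L] - pre$cvalid[start]
  mean_gc <- if (nvalid > 0)
    (pre$cgc[e + 1L] - pre$cgc[start]) / nvalid else NA_real_
  n_diag <- pre$cdiag[e + 1L] - pre$cdiag[start]
  congr_all <- congr_shallow <- monophyly <- NA_real_
  tree_ok <- all(defined)
  if (tree_ok && !is.null(ref_clades)) {
    dm <- dist_from_vec(dvec, pre$pairs, pre$labels)
    wt <- root_midpoint(nj_tree(dm))
    wc <- clade_set(wt)
    congr_all <- congruence_from_clades(ref_clades, wc$clade, "all")
    congr_shallow <- congruence_from_clades(ref_clades, wc$clade, "shallow",
                                            shallow_rule)
    monophyly <- species_monophyly(wc$clade, pre$labels, pre$species)
  }
  list(start = start, width = width, zero_noncon = zero_noncon,
       congr_all = congr_all, congr_shallow = congr_shallow,
       monophyly = monophyly, sum_dist = sum_dist, mean_gc = mean_gc,
       n_diagnostic = n_diag, tree_ok = tree_ok)
}

dist_from_vec <- function(dvec, pairs, labels) {
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[pairs] <- dvec
  d[pairs[, c(2L, 1L), drop = FALSE]] <- dvec
  structure(list(labels = labels, d = d, sites = NULL), class = "mb_dist")
}

# Fraction of multi-representative species that are monophyletic (their tip
# set appears as a clade of the rooted tree); NA when every species has a
# single representative.
species_monophyly <- function(clade_strings, labels, species) {
  tab <- table(species)
  multi <- names(tab)[tab >= 2L]
  if (length(multi) == 0L) return(NA_real_)
  hits <- vapply(multi, function(s) {
    key <- paste(sort(labels[species == s]), collapse = "|")
    tab[[s]] == length(labels) || key %in% clade_strings
  }, logical(1L))
  mean(hits)
}

#' Identification metrics for a single alignment window
#'
#' Computes every per-window statistic used by [slide_analysis()] for one
#' window: the proportion of zero non-conspecific distances, clade
#' congruence of the window neighbour-joining tree against the full-data
#' tree (all nodes and shallow nodes), species monophyly, summed pairwise
#' distance, mean GC content, and the number of species-diagnostic columns.
#'
#' @param aln Alignment tibble.
#' @param start 1-based first column of the window.
#' @param width Window width in columns.
#' @param ref_tree Optional reference tree; built from the full alignment
#'   when `NULL`.
#' @param shallow_rule Passed to [congruence()].
#' @return A one-row tibble of window metrics.
#' @export
window_metrics <- function(aln, start, width, ref_tree = NULL,
                           shallow_rule = "strict") {
  pre <- slide_precompute(aln)
  if (start < 1L || start + width - 1L > pre$L)
    stop("window [", start, ", ", start + width - 1L,
         "] outside alignment columns [1, ", pre$L, "]", call. = FALSE)
  if (is.null(ref_tree)) ref_tree <- nj_tree(distance_matrix(aln))
  if (!ape::is.rooted(ref_tree)) ref_tree <- root_midpoint(ref_tree)
  rc <- clade_set(ref_tree)
  shallow_rule <- effective_shallow_rule(rc, shallow_rule)
  row <- window_metrics_one(pre, start, width, rc, shallow_rule)
  tibble::as_tibble(row[setdiff(names(row), "tree_ok")])
}

#' Sliding-window analysis for mini-barcode selection
#'
#' Scores every candidate window of the requested widths and selects the
#' shortest highly informative one. A window qualifies when its proportion
#' of zero non-conspecific distances is at most `max_zero_noncon` (default:
#' none allowed) and its shallow-node clade congruence with the full-data
#' neighbour-joining tree is strictly greater than `min_congr_shallow`
#' (default 0.85). Among qualifying windows the smallest width wins; ties
#' are broken by higher shallow congruence, then by the leftmost start.
#'
#' Windows whose tree cannot be built (some sequence pair shares no
#' comparable site) keep their distance metrics but are excluded from
#' selection, with one summary warning.
#'
#' @param aln Alignment tibble with at least 3 sequences and 2 species.
#' @param widths,step Window widths and start increment
#'   (see [enumerate_windows()]).
#' @param max_zero_noncon Maximum tolerated proportion of zero
#'   non-conspecific distances (default 0).
#' @param min_congr_shallow Shallow-clade congruence must exceed this value
#'   (strict inequality; default 0.85).
#' @param shallow_rule How clades at the median depth are handled
#'   (see [congruence()]).
#' @return An object of class `slide_analysis` with components `metrics`
#'   (one row per window, plus a `qualifies` flag), `selected` (one-row
#'   tibble, or `NULL` with `nearest_miss` populated), `ref_tree` (the
#'   midpoint-rooted full-data tree) and `criteria`.
#' @examples
#' sim <- simulate_reference(n_species = 6, length = 120,
#'                           blocks = data.frame(start = c(1, 41, 101),
#'                                               end = c(40, 100, 120),
#'                                               type = c("conserved",
#'                                                        "variable",
#'                                                        "conserved")),
#'                           seed = 1)
#' res <- slide_analysis(sim$alignment, widths = c(25, 50), step = 5)
#' res$selected
#' @export
slide_analysis <- function(aln, widths = c(25, 50, 100, 150, 200, 250),
                           step = 1L, max_zero_noncon = 0,
                           min_congr_shallow = 0.85,
                           shallow_rule = "strict") {
  pre <- slide_precompute(aln)
  if (pre$n < 3L) stop("need at least 3 sequences", call. = FALSE)
  ref <- root_midpoint(nj_tree(distance_matrix(aln)))
  ref_clades <- clade_set(ref)
  if (nrow(ref_clades) == 0L)
    stop("reference unresolved: the full-data tree has no clades",
         call. = FALSE)
  shallow_rule <- effective_shallow_rule(ref_clades, shallow_rule)
  wins <- enumerate_windows(pre$L, widths, step)
  rows <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    rows[[k]] <- window_metrics_one(pre, wins$start[k], wins$width[k],
                                    ref_clades, shallow_rule)
  }
  metrics <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  n_bad <- sum(!metrics$tree_ok)
  if (n_bad > 0L)
    warning(n_bad, " window(s) had sequence pairs with no comparable sites;",
            " their trees were not built and they cannot be selected")
  metrics$qualifies <- metrics$tree_ok &
    !is.na(metrics$zero_noncon) &
    metrics$zero_noncon <= max_zero_noncon &
    !is.na(metrics$congr_shallow) &
    metrics$congr_shallow > min_congr_shallow
  metrics <- dplyr::arrange(metrics, .data$width, .data$start)
  selected <- NULL
  nearest_miss <- NULL
  qual <- dplyr::filter(metrics, .data$qualifies)
  if (nrow(qual) > 0L) {
    qual <- dplyr::arrange(qual, .data$width,
                           dplyr::desc(.data$congr_shallow), .data$start)
    selected <- qual[1L, ]
  } else {
    cand <- dplyr::filter(metrics, .data$tree_ok)
    if (nrow(cand) > 0L) {
      deficit <- pmax(0, cand$zero_noncon - max_zero_noncon) +
        pmax(0, min_congr_shallow - cand$congr_shallow)
      cand <- cand[order(deficit, cand$width, cand$start), ]
      nearest_miss <- cand[1L, ]
    }
  }
  structure(list(metrics = metrics, selected = selected,
                 nearest_miss = nearest_miss, ref_tree = ref,
                 criteria = list(max_zero_noncon = max_zero_noncon,
                                 min_congr_shallow = min_congr_shallow,
                                 widths = widths, step = step,
                                 shallow_rule = shallow_rule),
                 L = pre$L, n_seq = pre$n,
                 n_species = length(unique(pre$species))),
            class = "slide_analysis")
}

#' @export
print.slide_analysis <- function(x, ...) {
  cat("Sliding-window mini-barcode analysis\n")
  cat("  alignment: ", x$n_seq, " sequences, ", x$n_species, " species, ",
      x$L, " columns\n", sep = "")
  cat("  windows scored: ", nrow(x$metrics), " (widths ",
      paste(x$criteria$widths, collapse = ", "), "; step ",
      x$criteria$step, ")\n", sep = "")
  cat("  criteria: zero non-conspecific <= ", x$criteria$max_zero_noncon,
      ", shallow congruence > ", x$criteria$min_congr_shallow, "\n", sep = "")
  if (!is.null(x$selected)) {
    s <- x$selected
    cat("  selected: ", s$width, " bp window starting at column ", s$start,
        " (zero non-conspecific ", signif(s$zero_noncon, 3),
        ", shallow congruence ", signif(s$congr_shallow, 3), ")\n", sep = "")
  } else {
    cat("  no window met the criteria\n")
    if (!is.null(x$nearest_miss)) {
      m <- x$nearest_miss
      cat("  nearest miss: ", m$width, " bp at column ", m$start,
          " (zero non-conspecific ", signif(m$zero_noncon, 3),
          ", shallow congruence ", signif(m$congr_shallow, 3), ")\n",
          sep = "")
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname slide_analysis
#' @param x A `slide_analysis` object.
#' @param ... Unused.
#' @export
tidy.slide_analysis <- function(x, ...) x$metrics

#' @rdname slide_analysis
#' @export
glance.slide_analysis <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$metrics),
    n_qualifying = sum(x$metrics$qualifies),
    selected_start = if (is.null(x$selected)) NA_integer_ else
      x$selected$start,
    selected_width = if (is.null(x$selected)) NA_integer_ else
      x$selected$width,
    alignment_length = x$L,
    n_species = x$n_species)
}

#' Plot per-window identification metrics
#'
#' One panel row per statistic, faceted by window width, with the selected
#' window (if any) marked; mirrors the customary presentation of
#' sliding-window barcode scans.
#'
#' @param object A `slide_analysis` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slide_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    c("zero_noncon", "congr_all", "congr_shallow"),
    names_to = "metric", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$start, y = .data$value,
                                          colour = .data$metric)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~width, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "window start (alignment column)", y = "proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$selected))
    p <- p + ggplot2::geom_vline(
      data = object$selected,
      ggplot2::aes(xintercept = .data$start), linetype = 2)
  p
}

#' Write the per-window metrics table as TSV
#'
#' @param x A `slide_analysis` object (or its `metrics` tibble).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  m <- if (inherits(x, "slide_analysis")) x$metrics else x
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
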