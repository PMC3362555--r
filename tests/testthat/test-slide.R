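block_aln <- function(seed = 5) {
  simulate_reference(
    n_species = 6, per_species = 2, length = 120,
    blocks = data.frame(start = c(1, 41, 101), end = c(40, 100, 120),
                        type = c("conserved", "variable", "conserved")),
    inter_div = 0.08, intra_div = 0.01, seed = seed)
}

test_that("window enumeration matches the closed form", {
  expect_equal(nrow(enumerate_windows(10, 5)), 6L)
  w <- enumerate_windows(10, 5)
  expect_equal(w$start, 1:6)

  # census over the standard width ladder
  expect_equal(nrow(enumerate_windows(419)), 1745L)
  expect_equal(nrow(enumerate_windows(430)), 1811L)

  # property: count equals the explicit sum for assorted L, widths, steps
  set.seed(31)
  for (k in 1:20) {
    L <- sample(30:300, 1)
    widths <- sample(5:200, sample(1:4, 1))
    step <- sample(1:7, 1)
    got <- suppressWarnings(enumerate_windows(L, widths, step))
    expected <- sum(vapply(widths[widths <= L], function(w)
      length(seq.int(1L, L - w + 1L, by = step)), 0L))
    expect_equal(nrow(got), expected)
  }
})

test_that("widths exceeding the alignment are skipped with a warning", {
  expect_warning(w <- enumerate_windows(40, c(25, 50)), "exceed")
  expect_equal(unique(w$width), 25L)
})

test_that("the full-alignment window is fully congruent with itself", {
  sim <- block_aln()
  m <- suppressWarnings(window_metrics(sim$alignment, 1, 120))
  expect_equal(m$congr_all, 1)
  expect_equal(m$congr_shallow, 1)
})

test_that("an invariant window is maximally uninformative", {
  sim <- block_aln()
  # conserved block, single representative per species: all identical
  one <- sim$alignment[!duplicated(sim$alignment$species), ]
  m <- suppressWarnings(window_metrics(one, 1, 30))
  expect_equal(m$zero_noncon, 1)
  expect_equal(m$n_diagnostic, 0L)
  expect_equal(m$sum_dist, 0)
})

test_that("window metrics equal independent brute-force computation", {
  set.seed(33)
  for (k in 1:5) {
    aln <- random_alignment(6, 40, 3, p_messy = 0)
    start <- sample(1:20, 1); width <- sample(10:20, 1)
    m <- suppressWarnings(window_metrics(aln, start, width))
    win <- c(start, start + width - 1)

    expect_equal(m$zero_noncon, bf_zero_noncon(aln, win))

    # summed distance over all defined pairs
    sub <- substr(aln$sequence, win[1], win[2])
    sd <- 0
    for (i in 1:5) for (j in (i + 1):6) {
      d <- bf_pdist(sub[i], sub[j])
      if (d$compared > 0) sd <- sd + d$distance
    }
    expect_equal(m$sum_dist, sd)

    # GC over unambiguous cells
    cells <- unlist(strsplit(sub, ""))
    expect_equal(m$mean_gc,
                 sum(cells %in% c("G", "C")) / sum(cells %in% UNAMBIG))

    # diagnostic columns by explicit per-column species-state tables
    ndiag <- 0L
    for (cl in seq_len(width)) {
      col <- substr(sub, cl, cl)
      hit <- FALSE
      for (s in unique(aln$species)) {
        mine <- col[aln$species == s]; rest <- col[aln$species != s]
        if (all(mine %in% UNAMBIG) && length(unique(mine)) == 1 &&
            !any(rest == mine[1])) hit <- TRUE
      }
      ndiag <- ndiag + hit
    }
    expect_equal(m$n_diagnostic, ndiag)

    # congruence against brute-force clade intersection
    ref <- root_midpoint(nj_tree(distance_matrix(aln)))
    wt <- root_midpoint(nj_tree(distance_matrix(aln, win)))
    expect_equal(m$congr_all, bf_congruence(ref, wt, "all"))
  }
})

test_that("species monophyly counts multi-representative species only", {
  aln <- new_alignment(
    c("sp1_a", "sp1_b", "sp2_a", "sp2_b", "sp3_a"),
    c("AAAAAAAAAA", "AAAAAAAAAC", "GGGGGAAAAA", "GGGGGAAAAC",
      "AAGGGTTTTT"))
  m <- suppressWarnings(window_metrics(aln, 1, 10))
  # in any tree of these data sp1 {a,b} and sp2 {a,b} may or may not be
  # clades; verify against the actual window tree
  wt <- root_midpoint(nj_tree(distance_matrix(aln)))
  keys <- vapply(bf_clades(wt), paste, "", collapse = "|")
  expected <- mean(c("sp1_a|sp1_b" %in% keys, "sp2_a|sp2_b" %in% keys))
  expect_equal(m$monophyly, expected)

  # all singletons: monophyly undefined
  one <- aln[!duplicated(aln$species), ]
  expect_true(is.na(suppressWarnings(window_metrics(one, 1, 10))$monophyly))
})

test_that("selection returns the shortest window inside the variable block", {
  sim <- block_aln()
  res <- suppressWarnings(
    slide_analysis(sim$alignment, widths = c(25, 50, 100), step = 1))
  expect_s3_class(res, "slide_analysis")
  expect_false(is.null(res$selected))
  s <- res$selected
  # a qualifying window must overlap the variable block: outside it no
  # species pair differs at all
  expect_lte(s$start, 100)
  expect_gte(s$start + s$width - 1, 41)
  expect_equal(s$zero_noncon, 0)
  expect_gt(s$congr_shallow, 0.85)
  # the winner is the smallest qualifying width
  qual <- res$metrics[res$metrics$qualifies, ]
  expect_equal(s$width, min(qual$width))
})

test_that("selection is invariant to the order widths are listed", {
  sim <- block_aln(seed = 6)
  a <- suppressWarnings(
    slide_analysis(sim$alignment, widths = c(25, 50, 100), step = 3))
  b <- suppressWarnings(
    slide_analysis(sim$alignment, widths = c(100, 25, 50), step = 3))
  expect_equal(a$selected, b$selected)
  expect_equal(dplyr::arrange(a$metrics, width, start),
               dplyr::arrange(b$metrics, width, start))
})

test_that("nested windows never get worse on the zero-distance criterion", {
  sim <- block_aln(seed = 7)
  pre_aln <- sim$alignment
  set.seed(34)
  for (k in 1:10) {
    s <- sample(1:80, 1)
    inner <- c(s + 5, s + 24)
    outer <- c(s, s + 39)
    zi <- bf_zero_noncon(pre_aln, inner)
    zo <- bf_zero_noncon(pre_aln, outer)
    if (is.na(zi) || is.na(zo)) next
    expect_lte(zo, zi)
  }
})

test_that("unattainable criteria yield no selection plus diagnostics", {
  sim <- block_aln(seed = 8)
  res <- suppressWarnings(
    slide_analysis(sim$alignment, widths = 25, step = 10,
                   min_congr_shallow = 1.0))
  expect_null(res$selected)
  expect_false(is.null(res$nearest_miss))
  expect_output(print(res), "no window met")
})

test_that("tidy, glance and the TSV export expose the metrics table", {
  sim <- block_aln(seed = 9)
  res <- suppressWarnings(
    slide_analysis(sim$alignment, widths = c(25, 50), step = 10))
  td <- tidy(res)
  expect_equal(nrow(td), nrow(enumerate_windows(120, c(25, 50), 10)))
  g <- glance(res)
  expect_equal(g$n_windows, nrow(td))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_metrics(res, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(td))
  expect_true(all(c("start", "width", "zero_noncon", "congr_shallow",
                    "qualifies") %in% names(back)))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
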