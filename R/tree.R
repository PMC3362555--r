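#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou–Nei neighbour joining with two determinism guarantees:
#' ties in the Q criterion are broken by the smallest pair of current matrix
#' indices, and any negative branch length produced by the estimation step
#' is clamped to zero with the deficit transferred to the branch of the
#' sister node, preserving the path length between the joined nodes. The
#' result is the unrooted tree as an [ape::phylo] object (trifurcating at
#' its internal "root").
#'
#' @param dm `mb_dist` object from [distance_matrix()], with no undefined
#'   entries and at least 3 labels.
#' @return An unrooted `phylo` tree whose tip labels equal `dm$labels`.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "mb_dist"))
  D <- dm$d
  labels <- dm$labels
  n <- length(labels)
  if (n < 3L) stop("neighbour joining needs at least 3 sequences",
                   call. = FALSE)
  if (any(is.na(D[upper.tri(D)])))
    stop("distance matrix has undefined entries (pairs with no comparable ",
         "sites); cannot build a tree", call. = FALSE)
  if (any(grepl("[,;:()'\\[\\]]|\\s", labels)))
    stop("tip labels contain characters not representable in newick",
         call. = FALSE)
  node <- labels # newick fragment per active node
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    adj <- clamp_pair(vi, vj)
    merged <- paste0("(", node[i], ":", fmt_bl(adj[1L]), ",",
                     node[j], ":", fmt_bl(adj[2L]), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node <- c(node[keep], merged)
    n <- n - 1L
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(va, vb, vc), 0)
  txt <- paste0("(", node[1L], ":", fmt_bl(v[1L]), ",",
                node[2L], ":", fmt_bl(v[2L]), ",",
                node[3L], ":", fmt_bl(v[3L]), ");")
  ape::read.tree(text = txt)
}

# Clamp a negative branch to 0, moving the deficit onto the sister branch so
# the joined-pair path length is unchanged; the sister is then floored at 0.
clamp_pair <- function(vi, vj) {
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- max(vi + vj, 0); vj <- 0 }
  c(vi, vj)
}

fmt_bl <- function(x) sprintf("%.9f", x)

#' Midpoint-root a tree
#'
#' Roots the tree at the midpoint of the longest tip-to-tip path. Ties on
#' the maximal path are broken by the lexicographically smallest pair of
#' endpoint labels. When every branch has zero length the tree is rooted at
#' its first internal node with a warning.
#'
#' @param tree A `phylo` tree with branch lengths (rooted input is unrooted
#'   first, so the operation is idempotent on topology).
#' @return A rooted `phylo` tree on the same tips.
#' @export
root_midpoint <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  dn <- ape::dist.nodes(tree)
  Dt <- dn[seq_len(ntip), seq_len(ntip), drop = FALSE]
  maxd <- max(Dt)
  if (maxd == 0) {
    warning("all branch lengths are zero; rooting at the first internal node")
    return(ape::root(tree, outgroup = tree$tip.label[1L],
                     resolve.root = TRUE))
  }
  hit <- which(Dt == maxd, arr.ind = TRUE)
  hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
  ends <- cbind(pmin(tree$tip.label[hit[, 1L]], tree$tip.label[hit[, 2L]]),
                pmax(tree$tip.label[hit[, 1L]], tree$tip.label[hit[, 2L]]))
  pick <- order(ends[, 1L], ends[, 2L])[1L]
  i <- hit[pick, 1L]; j <- hit[pick, 2L]
  path <- ape::nodepath(tree, i, j)
  # walk from tip i until the cumulative length reaches half the path
  half <- maxd / 2
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    u <- path[k]; v <- path[k + 1L]
    e <- which((tree$edge[, 1L] == u & tree$edge[, 2L] == v) |
                 (tree$edge[, 1L] == v & tree$edge[, 2L] == u))[1L]
    len <- tree$edge.length[e]
    if (cum + len >= half) {
      return(root_on_edge(tree, e, towards = v, pos = half - cum))
    }
    cum <- cum + len
  }
  root_on_edge(tree, length(tree$edge.length), tree$edge[nrow(tree$edge), 2L],
               0) # unreachable in practice
}

# Root `tree` on edge `e`, at distance `pos` from the endpoint of e that is
# NOT `towards` (walk direction), splitting the edge length accordingly.
root_on_edge <- function(tree, e, towards, pos) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[e, 2L]
  total <- tree$edge.length[e]
  below <- if (child <= ntip) tree$tip.label[child] else
    ape::extract.clade(tree, child)$tip.label
  rooted <- ape::root(tree, outgroup = below, resolve.root = TRUE)
  # distance from the stored child endpoint to the new root
  child_side <- if (towards == child) total - pos else pos
  rootnum <- ntip + 1L
  re <- which(rooted$edge[, 1L] == rootnum)
  # identify which root edge leads to the `below` tip set
  for (k in re) {
    kid <- rooted$edge[k, 2L]
    tips <- if (kid <= ntip) rooted$tip.label[kid] else
      ape::extract.clade(rooted, kid)$tip.label
    rooted$edge.length[k] <- if (setequal(tips, below)) child_side else
      total - child_side
  }
  rooted
}

#' Clades of a rooted tree
#'
#' One entry per internal node other than the root; the depth of a clade is
#' its number of member tips.
#'
#' @param tree A rooted `phylo` tree.
#' @return A tibble with columns `clade` (canonical `|`-joined sorted tip
#'   labels), `depth` (tip count) and `tips` (list column).
#' @export
clade_set <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  tips <- lapply(pp, function(ix) sort(tree$tip.label[ix]))
  sizes <- lengths(tips)
  keep <- sizes < ntip & sizes >= 2L
  tips <- tips[keep]
  tibble::tibble(
    clade = vapply(tips, paste, character(1L), collapse = "|"),
    depth = lengths(tips),
    tips = tips)
}

#' Clade congruence between a reference tree and a window tree
#'
#' The fraction of reference-tree clades that reappear (as identical tip
#' sets) in the comparison tree. With `scope = "shallow"` only reference
#' clades tipwards of the median clade depth count: clades whose tip count
#' is strictly below the median depth over all reference clades (clades at
#' the median are excluded; set `shallow_rule = "inclusive"` to keep them).
#' Unrooted inputs are midpoint-rooted before clades are extracted.
#'
#' @param ref Reference `phylo` tree (typically from the full alignment).
#' @param comp Comparison `phylo` tree on the same tips.
#' @param scope `"all"` or `"shallow"`.
#' @param shallow_rule `"strict"` (default, depth < median) or
#'   `"inclusive"` (depth <= median).
#' @return A proportion in `[0, 1]`.
#' @export
congruence <- function(ref, comp, scope = c("all", "shallow"),
                       shallow_rule = c("strict", "inclusive")) {
  scope <- match.arg(scope)
  shallow_rule <- match.arg(shallow_rule)
  if (!setequal(ref$tip.label, comp$tip.label))
    stop("trees have different tip sets", call. = FALSE)
  if (!ape::is.rooted(ref)) ref <- root_midpoint(ref)
  if (!ape::is.rooted(comp)) comp <- root_midpoint(comp)
  rc <- clade_set(ref)
  cc <- clade_set(comp)
  congruence_from_clades(rc, cc$clade, scope, shallow_rule)
}

congruence_from_clades <- function(ref_clades, comp_strings, scope,
                                   shallow_rule = "strict") {
  keep <- ref_clades
  if (nrow(keep) == 0L)
    stop("reference unresolved: no clades to compare", call. = FALSE)
  if (scope == "shallow") {
    med <- stats::median(ref_clades$depth)
    keep <- if (shallow_rule == "strict")
      ref_clades[ref_clades$depth < med, ] else
        ref_clades[ref_clades$depth <= med, ]
    if (nrow(keep) == 0L)
      stop("reference unresolved: no shallow clades below the median depth",
           call. = FALSE)
  }
  sum(keep$clade %in% comp_strings) / nrow(keep)
}

#' Write a tree to newick
#'
#' @param tree A `phylo` tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}
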