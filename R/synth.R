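#' Simulate a species-labelled reference alignment
#'
#' Generates an alignment shaped like a short mitochondrial marker library:
#' alternating conserved and variable blocks. Conserved blocks are shared
#' exactly by every species; inside each variable block every species
#' receives its own disjoint set of "private" mutated positions, which
#' guarantees that any two species differ at the requested fraction of
#' block positions (`inter_div`). Conspecific copies of a species mutate a
#' fraction `intra_div` of non-private positions of the consensus, so
#' intra-species divergence never erodes the inter-species guarantee.
#'
#' Defaults emulate a small-invertebrate 16S reference library: 15 species,
#' one representative each, 430 aligned columns with a central variable
#' block (columns 180-300) flanked by conserved stretches, and 4% minimum
#' inter-species divergence within the variable block.
#'
#' @param n_species Number of species.
#' @param per_species Conspecific copies per species.
#' @param length Alignment length in columns.
#' @param blocks Data frame with columns `start`, `end`, `type`
#'   (`"conserved"` or `"variable"`); blocks must tile `[1, length]`
#'   without overlap. Default: conserved 1-179, variable 180-300,
#'   conserved 301-`length`.
#' @param inter_div Minimum pairwise inter-species divergence within each
#'   variable block (fraction of block columns; default 0.04).
#' @param intra_div Mutation rate of conspecific copies (default 0).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return A list with `alignment` (tibble as from [read_alignment()]) and
#'   `truth`: block table, per-species private (diagnostic) positions, the
#'   realised minimum inter-species divergence within variable blocks and
#'   over the full alignment, and the seed.
#' @export
simulate_reference <- function(n_species = 15L, per_species = 1L,
                               length = 430L, blocks = NULL,
                               inter_div = 0.04, intra_div = 0,
                               seed = NULL) {
  stopifnot(n_species >= 2L, per_species >= 1L, length >= 10L,
            inter_div >= 0, inter_div < 1, intra_div >= 0, intra_div < 1)
  if (is.null(blocks)) {
    # central variable block flanked by conserved stretches; at the default
    # 430 columns this is exactly columns 180-300
    v1 <- max(2L, floor(length * 180 / 430))
    v2 <- min(length - 1L, floor(length * 300 / 430))
    blocks <- data.frame(start = c(1L, v1, v2 + 1L),
                         end = c(v1 - 1L, v2, length),
                         type = c("conserved", "variable", "conserved"))
  }
  blocks <- blocks[order(blocks$start), ]
  if (blocks$start[1L] != 1L || blocks$end[nrow(blocks)] != length ||
      any(blocks$start[-1L] != blocks$end[-nrow(blocks)] + 1L))
    stop("blocks must tile [1, length] without gaps or overlap",
         call. = FALSE)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ancestral <- sample(bases, length, replace = TRUE)
    consensus <- matrix(rep(ancestral, each = n_species), nrow = n_species)
    private <- vector("list", n_species)
    for (b in which(blocks$type == "variable")) {
      cols <- blocks$start[b]:blocks$end[b]
      blen <- length(cols)
      # Private sites guarantee >= 2m differences between any species pair;
      # hierarchical sites evolved along a random species tree add shared
      # derived states so the block carries genuine tree structure.
      m <- max(1L, ceiling(inter_div * blen / 2))
      if (n_species * m > blen)
        stop("infeasible divergence: block of ", blen, " columns cannot ",
             "host ", m, " private sites for each of ", n_species,
             " species", call. = FALSE)
      h <- floor((blen - n_species * m) / (2L * n_species - 2L))
      pos <- sample(cols)
      nxt <- 1L
      take <- function(k) {
        out <- pos[nxt:(nxt + k - 1L)]
        nxt <<- nxt + k
        out
      }
      for (s in seq_len(n_species)) {
        mine <- take(m)
        consensus[s, mine] <- vapply(ancestral[mine], function(bb)
          sample(setdiff(bases, bb), 1L), character(1L))
        private[[s]] <- sort(c(private[[s]], mine))
      }
      if (h > 0L) {
        # random recursive bipartition of the species set; every subset
        # (= tree edge) gets h positions mutated in all its members
        mutate_subset <- function(members) {
          if (length(members) < n_species) {
            sites <- take(h)
            for (p in sites) {
              nb <- sample(setdiff(bases, ancestral[p]), 1L)
              consensus[members, p] <<- nb
            }
            if (length(members) == 1L)
              private[[members]] <<- sort(c(private[[members]], sites))
          }
          if (length(members) >= 2L) {
            k <- if (length(members) == 2L) 1L else
              sample.int(length(members) - 1L, 1L)
            left <- sort(sample(members, k))
            mutate_subset(left)
            mutate_subset(setdiff(members, left))
          }
        }
        mutate_subset(seq_len(n_species))
      }
    }
    all_private <- sort(unlist(private))
    free <- setdiff(seq_len(length), all_private)
    n_mut <- round(intra_div * length)
    ids <- character(0); species <- character(0); seqs <- character(0)
    sp_names <- sprintf("sp%02d", seq_len(n_species))
    for (s in seq_len(n_species)) {
      for (k in seq_len(per_species)) {
        seqv <- consensus[s, ]
        if (n_mut > 0L && k > 1L) {
          hit <- sample(free, min(n_mut, length(free)))
          seqv[hit] <- vapply(seqv[hit], function(bb)
            sample(setdiff(bases, bb), 1L), character(1L))
        }
        ids <- c(ids, paste0(sp_names[s], "_", k))
        species <- c(species, sp_names[s])
        seqs <- c(seqs, paste(seqv, collapse = ""))
      }
    }
    aln <- tibble::tibble(id = ids, species = species, sequence = seqs)
    truth <- list(
      blocks = tibble::as_tibble(blocks),
      private_positions = stats::setNames(private, sp_names),
      consensus = stats::setNames(apply(consensus, 1L, paste,
                                        collapse = ""), sp_names),
      min_inter_divergence_block = realised_min_divergence(
        consensus, blocks[blocks$type == "variable", , drop = FALSE]),
      min_inter_divergence_full = realised_min_divergence(
        consensus, data.frame(start = 1L, end = length)),
      inter_div = inter_div, intra_div = intra_div, seed = seed)
    list(alignment = aln, truth = truth)
  })
}

realised_min_divergence <- function(consensus, blocks) {
  if (nrow(blocks) == 0L) return(NA_real_)
  cols <- unlist(lapply(seq_len(nrow(blocks)), function(b)
    blocks$start[b]:blocks$end[b]))
  n <- nrow(consensus)
  mn <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    mn <- min(mn, mean(consensus[i, cols] != consensus[j, cols]))
  }
  mn
}

#' Simulate degraded amplicon reads from a reference library
#'
#' Emulates a pooled amplicon sequencing run: each library species is
#' amplified in silico with the primer pair, reads are drawn from the
#' resulting template amplicons according to species abundances, per-base
#' substitution errors are applied, a fraction of reads are chimeras
#' spliced from two parent amplicons at a random breakpoint, and each read
#' is tagged with one of `n_samples` sample ids.
#'
#' @param library Alignment tibble of reference sequences (gaps stripped
#'   before amplification); every species must be amplifiable by `pp`.
#' @param pp A [primer_pair()].
#' @param n_reads Number of reads to generate.
#' @param error_rate Per-base substitution error probability (default 0).
#' @param chimera_rate Fraction of reads that are chimeras (default 0).
#' @param abundances Per-species weights (named, or in library species
#'   order); uniform when `NULL`.
#' @param n_samples Number of pooled samples (default 46).
#' @param seed Integer seed.
#' @return A list with `reads` (tibble as from [read_reads()]) and `truth`
#'   (tibble: `read_id`, `species` — `"chimera"` for spliced reads —,
#'   `sample_id`, `n_errors`).
#' @export
simulate_reads <- function(library, pp, n_reads = 1000L, error_rate = 0,
                           chimera_rate = 0, abundances = NULL,
                           n_samples = 46L, seed = NULL) {
  check_alignment(library)
  stopifnot(inherits(pp, "primer_pair"), n_reads >= 1L,
            error_rate >= 0, error_rate < 1,
            chimera_rate >= 0, chimera_rate < 1)
  sp <- unique(library$species)
  templates <- lapply(sp, function(s) {
    tpl <- library$sequence[library$species == s][1L]
    amp <- insilico_pcr(tpl, pp)
    if (nrow(amp) == 0L)
      stop("species '", s, "' is not amplified by the primer pair",
           call. = FALSE)
    amp$sequence[1L]
  })
  names(templates) <- sp
  w <- if (is.null(abundances)) rep(1, length(sp)) else {
    if (!is.null(names(abundances))) abundances[sp] else abundances
  }
  stopifnot(length(w) == length(sp), all(w >= 0), sum(w) > 0)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    origin <- sample(sp, n_reads, replace = TRUE, prob = w)
    is_chimera <- stats::runif(n_reads) < chimera_rate
    sample_id <- sprintf("S%02d", sample.int(n_samples, n_reads,
                                             replace = TRUE))
    seqs <- character(n_reads)
    n_err <- integer(n_reads)
    for (r in seq_len(n_reads)) {
      if (is_chimera[r]) {
        par <- sample(sp, 2L, replace = FALSE, prob = w)
        a <- templates[[par[1L]]]; b <- templates[[par[2L]]]
        bp <- sample.int(min(nchar(a), nchar(b)) - 1L, 1L)
        s <- paste0(substr(a, 1L, bp), substr(b, bp + 1L, nchar(b)))
      } else {
        s <- templates[[origin[r]]]
      }
      if (error_rate > 0) {
        v <- strsplit(s, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(v)) < error_rate)
        if (length(hit)) {
          v[hit] <- vapply(v[hit], function(bb)
            sample(setdiff(bases, bb), 1L), character(1L))
          s <- paste(v, collapse = "")
        }
        n_err[r] <- length(hit)
      }
      seqs[r] <- s
    }
    reads <- tibble::tibble(read_id = sprintf("read%06d", seq_len(n_reads)),
                            sequence = seqs, sample_id = sample_id)
    truth <- tibble::tibble(read_id = reads$read_id,
                            species = ifelse(is_chimera, "chimera", origin),
                            sample_id = sample_id, n_errors = n_err)
    list(reads = reads, truth = truth)
  })
}
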