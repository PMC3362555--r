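# Independent brute-force oracles, deliberately written as plain character
# loops so they share no code with the implementation under test.

UNAMBIG <- c("A", "C", "G", "T")

bf_pdist <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  mism <- 0L; comp <- 0L
  for (k in seq_along(av)) {
    if (av[k] %in% UNAMBIG && bv[k] %in% UNAMBIG) {
      comp <- comp + 1L
      if (av[k] != bv[k]) mism <- mism + 1L
    }
  }
  list(distance = if (comp == 0L) NA_real_ else mism / comp,
       compared = comp)
}

bf_zero_noncon <- function(aln, window = NULL) {
  seqs <- aln$sequence
  if (!is.null(window)) seqs <- substr(seqs, window[1], window[2])
  zero <- 0L; defined <- 0L
  n <- length(seqs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (aln$species[i] == aln$species[j]) next
    d <- bf_pdist(seqs[i], seqs[j])
    if (d$compared > 0) {
      defined <- defined + 1L
      if (d$distance == 0) zero <- zero + 1L
    }
  }
  if (defined == 0L) return(NA_real_)
  zero / defined
}

# Clade extraction by explicit recursive descent over the edge matrix.
bf_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], tips_under))
  }
  internal <- setdiff(unique(tree$edge[, 1]), root)
  out <- lapply(internal, function(nd) sort(tips_under(nd)))
  out[lengths(out) >= 2 & lengths(out) < ntip]
}

bf_congruence <- function(ref, comp, scope = "all",
                          shallow_rule = "strict") {
  rc <- bf_clades(ref)
  cc <- bf_clades(comp)
  key <- function(cl) vapply(cl, paste, "", collapse = "|")
  rk <- key(rc); ck <- key(cc)
  if (scope == "shallow") {
    depths <- lengths(rc)
    med <- stats::median(depths)
    keep <- if (shallow_rule == "strict") depths < med else depths <= med
    rk <- rk[keep]
  }
  sum(rk %in% ck) / length(rk)
}

# Random alignment with occasional gaps/ambiguities and >= 2 species.
random_alignment <- function(n_seq, n_col, n_species,
                             p_messy = 0.03) {
  chars <- c(UNAMBIG, "-", "N", "R")
  probs <- c(rep((1 - p_messy) / 4, 4), p_messy / 3, p_messy / 3,
             p_messy / 3)
  seqs <- vapply(seq_len(n_seq), function(i)
    paste(sample(chars, n_col, replace = TRUE, prob = probs),
          collapse = ""), "")
  sp <- paste0("sp", sort(rep_len(seq_len(n_species), n_seq)))
  new_alignment(paste0(sp, "_", seq_len(n_seq)), seqs, species = sp)
}

# Tiny deterministic reference library used across pipeline tests: species
# consensus sequences flanked by shared primer sites.
toy_library <- function(n_species = 4, core = 30, seed = 99) {
  minibar:::with_seed(seed, {
    flank5 <- paste(sample(UNAMBIG, 20, TRUE), collapse = "")
    flank3 <- paste(sample(UNAMBIG, 20, TRUE), collapse = "")
    cores <- replicate(n_species,
                       paste(sample(UNAMBIG, core, TRUE), collapse = ""))
    new_alignment(paste0("sp", seq_len(n_species), "_1"),
                  paste0(flank5, cores, flank3))
  })
}
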