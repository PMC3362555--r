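# Internal helpers shared across modules.

# IUPAC nucleotide codes (uppercase) plus gap.
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulations never perturb the session.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Split sequences into a character matrix (rows = records, cols = positions).
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  n <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = n, byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

# Encode A/C/G/T as 1..4; gaps and ambiguity codes become NA (treated as
# missing under pairwise deletion).
encode_acgt <- function(seqs) {
  m <- seq_char_matrix(seqs)
  e <- match(m, c("A", "C", "G", "T"))
  dim(e) <- dim(m)
  rownames(e) <- rownames(m)
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a
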