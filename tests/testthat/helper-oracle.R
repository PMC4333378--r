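# Independent oracles used by the alignment / normalization tests.
# These deliberately share no code with the package's alignment path.

# Brute-force 3-state affine-gap global DP (Gotoh). A gap run of length L
# scores gap_open + L * gap_extend, matching alignment_scoring().
oracle_affine_score <- function(ref, read, scoring = alignment_scoring()) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(read, "")[[1]]
  n <- length(r); m <- length(q)
  sub <- function(a, b) {
    if (a == "N" || b == "N") return(0)
    if (a == b) scoring$match else scoring$mismatch
  }
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last column aligned
  X <- matrix(NEG, n + 1, m + 1)   # gap in read (deletion from ref)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in ref (insertion in read)
  M[1, 1] <- 0
  for (i in seq_len(n))
    X[i + 1, 1] <- scoring$gap_open + i * scoring$gap_extend
  for (j in seq_len(m))
    Y[1, j + 1] <- scoring$gap_open + j * scoring$gap_extend
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sub(r[i], q[j])
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] + scoring$gap_open + scoring$gap_extend,
                           X[i, j + 1] + scoring$gap_extend)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + scoring$gap_open + scoring$gap_extend,
                           Y[i + 1, j] + scoring$gap_extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# All reference positions at which a single run-deletion of length L could
# be placed and still yield `read` (score-equivalent placements).
oracle_deletion_placements <- function(ref, read) {
  L <- nchar(ref) - nchar(read)
  stopifnot(L >= 1)
  which(vapply(seq_len(nchar(ref) - L + 1), function(p)
    paste0(substr(ref, 1, p - 1), substr(ref, p + L, nchar(ref))) == read,
    NA))
}

# All anchors (0-based allowed) at which an insertion could be placed to
# turn `ref` into `read`; returns the anchor positions.
oracle_insertion_placements <- function(ref, read) {
  L <- nchar(read) - nchar(ref)
  stopifnot(L >= 1)
  which0 <- integer(0)
  for (p in 0:nchar(ref)) {
    cand <- paste0(substr(ref, 1, p),
                   substr(read, p + 1, p + L),
                   substr(ref, p + 1, nchar(ref)))
    if (cand == read) which0 <- c(which0, p)
  }
  which0
}

# Build a pairwise_alignment object directly from gapped rows (bypasses
# the aligner so normalization can be tested on every equivalent form).
manual_alignment <- function(ref_row, read_row, score = 0) {
  polfid:::new_pairwise_alignment(ref_row, read_row, score)
}

# Random reference sequence
random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# Randomly mutate a sequence with n_sub substitutions and n_indel
# single-base indels (independent of the simulator module).
random_mutant <- function(ref, n_sub = 1, n_indel = 1) {
  s <- strsplit(ref, "")[[1]]
  for (k in seq_len(n_sub)) {
    i <- sample(length(s), 1)
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  }
  for (k in seq_len(n_indel)) {
    i <- sample(length(s), 1)
    if (stats::runif(1) < 0.5 && length(s) > 2) s <- s[-i]
    else s <- append(s, sample(c("A", "C", "G", "T"), 1), after = i)
  }
  paste(s, collapse = "")
}

# Literal loop evaluation of the multiple-error correction denominator
oracle_pol_ef_est <- function(pol_ef, counts, total) {
  denom <- 0
  for (n in 1:3) denom <- denom + (1 / n) * (counts[n] / total)
  pol_ef / denom
}

# Shared tiny fixture: a 64-nt reporter-gap-like reference with a [T]8 run
fixture_reference <- function() {
  reference_target(
    paste0("ATGACCATGATTACGCCAAGCTTGCATGCCTG",
           "TTTTTTTT", "GAGTCGACCTGCAGGCATGCAAGC"),
    id = "gap64",
    regions = data.frame(label = c("STR", "coding"),
                         start = c(33L, 41L), end = c(40L, 64L)))
}
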