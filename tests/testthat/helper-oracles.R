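# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the scanner oracle works per offset on character
# vectors, the statistical oracles enumerate or apply the textbook formula.

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Per-offset scanner: offset o matches iff every pattern position's allowed
# set contains the base at o + j - 1. Vectorised over offsets via shifted
# logicals; agrees with the literal double loop (checked below on small
# cases) but is fast enough for thousands of 2 kb sequences.
oracle_count_forward <- function(seq, iupac) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pat <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  P <- length(pat)
  if (L < P) return(0L)
  n_off <- L - P + 1L
  ok <- rep(TRUE, n_off)
  for (j in seq_len(P)) {
    allowed <- iupac_sets[[pat[[j]]]]
    if (pat[[j]] == "N") allowed <- c(allowed, "N")
    ok <- ok & (chars[j:(j + n_off - 1L)] %in% allowed)
  }
  sum(ok)
}

# The same check as an explicit double loop; used to validate the oracle
# itself on short sequences.
oracle_count_forward_loop <- function(seq, iupac) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pat <- strsplit(iupac, "", fixed = TRUE)[[1L]]
  n <- 0L
  if (length(chars) < length(pat)) return(0L)
  for (o in seq_len(length(chars) - length(pat) + 1L)) {
    hit <- TRUE
    for (j in seq_along(pat)) {
      allowed <- iupac_sets[[pat[[j]]]]
      if (pat[[j]] == "N") allowed <- c(allowed, "N")
      if (!(chars[[o + j - 1L]] %in% allowed)) {
        hit <- FALSE
        break
      }
    }
    if (hit) n <- n + 1L
  }
  n
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(rev(unname(comp[chars])), collapse = "")
}

# Reverse-strand count: scan the reverse complement of the sequence.
oracle_count_reverse <- function(seq, iupac) {
  oracle_count_forward(oracle_revcomp(seq), iupac)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive hypergeometric tail by enumerating every n-subset of N items of
# which the first K are carriers: P[X >= k].
enum_hyper_upper <- function(N, K, n, k) {
  if (n == 0L) return(if (k <= 0L) 1 else 0)
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  mean(marked >= k)
}

enum_hyper_lower <- function(N, K, n, k) {
  if (n == 0L) return(if (k >= 0L) 1 else 0)
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  mean(marked <= k)
}

# A gene set of size n containing exactly k of the first K background genes.
sample_set <- function(bg, K, n, k) {
  c(bg[seq_len(k)], bg[K + seq_len(n - k)])
}

# Textbook chi-square statistic on a 2x2 table: sum (O - E)^2 / E.
chisq_formula <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# Build a direction_summary data.frame by hand for one OG/treatment state
# combination (species roster At/Os/Hv).
states_summary <- function(states, og = "OG1", treatment = "T1",
                           roster = c("At", "Os", "Hv")) {
  structure(
    data.frame(og_id = og, species = roster, treatment = treatment,
               state = states,
               n_up = as.integer(states == "up"),
               n_down = as.integer(states == "down"),
               genes = ifelse(states %in% c("up", "down", "mixed_excluded"),
                              paste0(roster, "_g1"), "")),
    species = roster, treatments = treatment,
    class = c("direction_summary", "data.frame"))
}
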