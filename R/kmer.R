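#' Enumerate all k-words over an ordered alphabet
#'
#' Words are laid out in lexicographic order of the supplied alphabet, so
#' feature names are stable across runs and machines.
#'
#' @param alphabet Ordered character vector of single symbols.
#' @param k Word length (positive integer).
#' @return A `kmer_index` object with fields `alphabet`, `k`, `words`
#'   (length `|alphabet|^k`).
#' @export
kmer_index <- function(alphabet, k) {
  stopifnot(k >= 1L, length(alphabet) >= 1L, all(nchar(alphabet) == 1L))
  grids <- rev(expand.grid(rev(replicate(k, alphabet, simplify = FALSE)),
                           stringsAsFactors = FALSE))
  words <- do.call(paste0, grids)
  structure(list(alphabet = alphabet, k = as.integer(k), words = words),
            class = "kmer_index")
}

#' Start positions of every k-word occurring in a sequence
#'
#' Occurrences may overlap.  Positions are 1-based.
#'
#' @param seq A single string.
#' @param k Word length; must satisfy `k <= nchar(seq)`.
#' @return Named list: for each k-word present in `seq`, the sorted integer
#'   vector of start positions.  The position counts sum to
#'   `nchar(seq) - k + 1`.
#' @export
kword_positions <- function(seq, k) {
  m <- nchar(seq)
  if (k > m) stop("k (", k, ") exceeds sequence length (", m, ")")
  starts <- seq_len(m - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  split(starts, factor(words, levels = unique(words)))
}

#' k-word content feature vector (relative frequencies)
#'
#' Entry for word `w` is `c(w) / (m - k + 1)` where `c(w)` counts possibly
#' overlapping occurrences; the vector sums to 1.
#'
#' @param seq A single string.
#' @param k Word length.
#' @param index A [kmer_index()] over the sequence's alphabet; defaults to
#'   the 20-letter amino-acid alphabet.
#' @return Named numeric vector of length `|alphabet|^k`, names
#'   `scf<k>_<word>`.
#' @export
scf_vector <- function(seq, k, index = kmer_index(AA_ALPHABET20, k)) {
  stopifnot(index$k == k)
  pos <- kword_positions(seq, k)
  counts <- stats::setNames(numeric(length(index$words)), index$words)
  found <- lengths(pos)
  unknown <- setdiff(names(found), index$words)
  if (length(unknown) > 0L) {
    stop("sequence contains words outside the index alphabet: ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  }
  counts[names(found)] <- found
  out <- counts / (nchar(seq) - k + 1L)
  names(out) <- paste0("scf", k, "_", index$words)
  out
}

#' Empirical distribution of gaps between successive k-word occurrences
#'
#' The interval distance is the difference of successive 1-based start
#' positions, so adjacent overlapping occurrences give distance 1.
#'
#' @param positions Strictly increasing integer vector of start positions.
#' @return An `interval_pmf` object: list with integer `support` and
#'   `probs` summing to 1; both empty when fewer than 2 positions.
#' @export
interval_pmf <- function(positions) {
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  if (length(positions) < 2L) {
    return(structure(list(support = integer(0), probs = numeric(0)),
                     class = "interval_pmf"))
  }
  gaps <- diff(positions)
  tab <- table(gaps)
  structure(list(support = as.integer(names(tab)),
                 probs = as.numeric(tab) / length(gaps)),
            class = "interval_pmf")
}

#' Semi-mean and semi-variance of an interval distribution
#'
#' Semi-mean is `sum(t * p(t))`; semi-variance is
#' `sum(t^2 * p(t)) - semi_mean^2`.  The empty distribution maps to (0, 0).
#'
#' @param pmf An [interval_pmf()].
#' @return Numeric vector `c(semi_mean, semi_var)`.
#' @export
semi_moments <- function(pmf) {
  if (length(pmf$support) == 0L) return(c(semi_mean = 0, semi_var = 0))
  e1 <- sum(pmf$support * pmf$probs)
  e2 <- sum(pmf$support^2 * pmf$probs)
  c(semi_mean = e1, semi_var = max(e2 - e1^2, 0))
}

#' k-word position feature vector (semi-mean over semi-variance)
#'
#' For each word the statistic is `semi_mean / semi_var` of its interval
#' distribution.  Words with fewer than 2 occurrences, or zero
#' semi-variance, get 0 (the ratio is undefined there; 0 is the neutral
#' convention that keeps vectors finite).
#'
#' @inheritParams scf_vector
#' @return Named numeric vector of length `|alphabet|^k`, names
#'   `spf<k>_<word>`, all entries `>= 0`.
#' @export
spf_vector <- function(seq, k, index = kmer_index(AA_ALPHABET20, k)) {
  stopifnot(index$k == k)
  pos <- kword_positions(seq, k)
  out <- stats::setNames(numeric(length(index$words)), index$words)
  for (w in names(pos)) {
    mo <- semi_moments(interval_pmf(pos[[w]]))
    if (mo[["semi_var"]] > 0) out[[w]] <- mo[["semi_mean"]] / mo[["semi_var"]]
  }
  names(out) <- paste0("spf", k, "_", index$words)
  out
}
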