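# Independent brute-force oracles.  These deliberately avoid the package's
# own code paths: explicit loops, no shared helpers beyond base R.

oracle_count_word <- function(seq, w) {
  k <- nchar(w)
  n <- 0L
  for (i in seq_len(nchar(seq) - k + 1L)) {
    if (substr(seq, i, i + k - 1L) == w) n <- n + 1L
  }
  n
}

oracle_scf <- function(seq, k, words) {
  m <- nchar(seq)
  vapply(words, function(w) oracle_count_word(seq, w) / (m - k + 1L), 0)
}

oracle_spf <- function(seq, k, words) {
  vapply(words, function(w) {
    pos <- integer(0)
    for (i in seq_len(nchar(seq) - k + 1L)) {
      if (substr(seq, i, i + k - 1L) == w) pos <- c(pos, i)
    }
    if (length(pos) < 2L) return(0)
    gaps <- pos[-1L] - pos[-length(pos)]
    e1 <- mean(gaps)
    v <- mean(gaps^2) - e1^2
    if (v <= 0) 0 else e1 / v
  }, 0)
}

# Explicit-scan secondary-structure descriptors.
oracle_ss <- function(ss) {
  ch <- strsplit(ss, "")[[1]]
  n <- length(ch)
  out <- list()
  for (e in c("H", "E", "C")) {
    out[[paste0("content_", e)]] <- sum(ch == e) / n
    pos <- which(ch == e)
    out[[paste0("cmv1_", e)]] <-
      if (length(pos)) sum(pos) / (n - 1) else 0
    out[[paste0("cmv2_", e)]] <-
      if (length(pos)) sum(pos^2) / ((n - 1) * (n - 2)) else 0
    runs <- integer(0)
    len <- 0L
    for (i in seq_len(n)) {
      if (ch[i] == e) {
        len <- len + 1L
      } else if (len > 0L) {
        runs <- c(runs, len); len <- 0L
      }
    }
    if (len > 0L) runs <- c(runs, len)
    out[[paste0("maxseg_", e)]] <- if (length(runs)) max(runs) else 0
    out[[paste0("nmaxseg_", e)]] <- if (length(runs)) max(runs) / n else 0
    out[[paste0("avgseg_", e)]] <- if (length(runs)) mean(runs) else 0
    out[[paste0("navgseg_", e)]] <- if (length(runs)) mean(runs) / n else 0
  }
  he <- ch[ch != "C"]
  alt <- 0L
  if (length(he) >= 2L) {
    prev <- he[1L]
    for (i in 2L:length(he)) {
      if (he[i] != prev) alt <- alt + 1L
      prev <- he[i]
    }
  }
  out$nalt <- alt / n
  out
}

# Re-accumulate RI scores by walking every stored tree of an ri_result
# fitted with keep_trees = TRUE.
oracle_ri_from_trees <- function(ri_result, feature_names) {
  acc <- stats::setNames(numeric(length(feature_names)), feature_names)
  visit <- function(node, w, n_root) {
    if (isTRUE(node$leaf)) return(invisible(NULL))
    acc[node$feature] <<- acc[node$feature] +
      w * node$info_gain * node$n_samples / n_root
    visit(node$left, w, n_root)
    visit(node$right, w, n_root)
  }
  for (t in ri_result$trees) {
    visit(t$tree$root, t$w, t$tree$root$n_samples)
  }
  acc
}

random_aa_seq <- function(len) {
  paste(sample(strucclass::AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

random_ss_seq <- function(len) {
  paste(sample(c("H", "E", "C"), len, replace = TRUE), collapse = "")
}
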