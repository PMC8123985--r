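#' Hydrophobicity reduction map for the 20 standard residues
#'
#' Internal (hydrophobic) residues F,I,L,M,V map to `I`; external
#' (hydrophilic) D,E,H,K,N,Q,R map to `E`; the remaining eight ambivalent
#' residues A,C,G,P,S,T,W,Y map to `A`.  The three groups partition the
#' 20-letter alphabet (5 + 7 + 8).
#'
#' @return Named character vector: residue -> reduced letter.
#' @export
reduction_map <- function() {
  m <- c(stats::setNames(rep("I", 5L), c("F", "I", "L", "M", "V")),
         stats::setNames(rep("E", 7L), c("D", "E", "H", "K", "N", "Q", "R")),
         stats::setNames(rep("A", 8L), c("A", "C", "G", "P", "S", "T", "W", "Y")))
  m[order(names(m))]
}

#' Reduce a protein sequence to the 3-letter {I,E,A} alphabet
#'
#' @param seq Protein sequence over the 20 standard residues.
#' @param map Override hook for the group definitions; must map every
#'   residue that occurs in `seq`.
#' @return String of the same length over `{I,E,A}`.
#' @export
reduce_sequence <- function(seq, map = reduction_map()) {
  resid <- strsplit(toupper(seq), "")[[1]]
  out <- unname(map[resid])
  bad <- which(is.na(out))
  if (length(bad) > 0L) {
    stop("unmapped residue '", resid[bad[1L]], "' at position ", bad[1L])
  }
  paste(out, collapse = "")
}

#' Reduced-alphabet combined feature vector (length 24)
#'
#' Content and position features of the reduced sequence: scf1 (3), scf2
#' (9), spf1 (3), spf2 (9) over the alphabet `{I,E,A}`, in that order.
#' Names carry an `r_` prefix.
#'
#' @inheritParams reduce_sequence
#' @return Named numeric vector of length 24.
#' @export
reduced_feature_vector <- function(seq, map = reduction_map()) {
  red <- reduce_sequence(seq, map)
  alph <- c("I", "E", "A")
  idx1 <- kmer_index(alph, 1L)
  idx2 <- kmer_index(alph, 2L)
  v <- c(scf_vector(red, 1L, idx1), scf_vector(red, 2L, idx2),
         spf_vector(red, 1L, idx1), spf_vector(red, 2L, idx2))
  stats::setNames(v, paste0("r_", names(v)))
}
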