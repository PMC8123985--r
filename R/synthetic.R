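# Residue emission propensities under each secondary-structure state.
# Direction matters, exact values do not: helix formers are enriched under
# H, beta-branched/aromatic residues under E, flexible residues under C.
# Fixed and versioned with the package.
ss_emission_table <- function() {
  w <- matrix(1, 20L, 3L, dimnames = list(AA_ALPHABET20, SS_ALPHABET))
  w[c("A", "E", "L", "M"), "H"] <- 4
  w[c("Q", "K", "R"), "H"] <- 3
  w["H", "H"] <- 2
  w[c("V", "I"), "E"] <- 4
  w[c("F", "Y", "T"), "E"] <- 3
  w[c("C", "W"), "E"] <- 2
  w[c("G", "P"), "C"] <- 4
  w[c("N", "D", "S"), "C"] <- 3
  sweep(w, 2L, colSums(w), "/")
}

# Per-class segment grammar: ordered cycle of (state, mean run length)
# blocks.  Geometric run lengths (mean per type) give realistic
# MaxSeg/AvgSeg ranges; the alternation structure separates alpha/beta
# (strictly alternating H/E with short coils) from alpha+beta (an H-block
# region followed by an E-block region).
class_grammar <- function(label) {
  switch(label,
    "all-alpha" = list(cycle = list(c("C", 3), c("H", 10)), minority = "E",
                       minority_p = 0.05, minority_mean = 3),
    "all-beta" = list(cycle = list(c("C", 3), c("E", 6)), minority = "H",
                      minority_p = 0.05, minority_mean = 4),
    "alpha/beta" = list(cycle = list(c("C", 2), c("H", 8), c("C", 2), c("E", 5)),
                        minority = NULL),
    "alpha+beta" = list(two_phase = TRUE,
                        phase1 = list(c("C", 3), c("H", 9)),
                        phase2 = list(c("C", 3), c("E", 6))),
    stop("unknown class label: ", label))
}

rgeom_len <- function(mean_len) {
  1L + stats::rgeom(1L, 1 / mean_len)
}

simulate_ss <- function(label, len) {
  g <- class_grammar(label)
  emit <- function(blocks, target) {
    out <- character(0)
    i <- 1L
    while (sum(nchar(out)) < target) {
      blk <- blocks[[(i - 1L) %% length(blocks) + 1L]]
      state <- blk[1L]
      if (!is.null(g$minority) && state %in% c("H", "E") &&
          stats::runif(1L) < g$minority_p) {
        out <- c(out, strrep(g$minority, rgeom_len(g$minority_mean)))
      }
      out <- c(out, strrep(state, rgeom_len(as.numeric(blk[2L]))))
      i <- i + 1L
    }
    paste(out, collapse = "")
  }
  ss <- if (isTRUE(g$two_phase)) {
    half <- ceiling(len / 2)
    paste0(emit(g$phase1, half), emit(g$phase2, len - half))
  } else {
    emit(g$cycle, len)
  }
  substr(ss, 1L, len)
}

simulate_aa <- function(ss, emission = ss_emission_table()) {
  states <- strsplit(ss, "")[[1]]
  paste(vapply(states, function(st) {
    sample(AA_ALPHABET20, 1L, prob = emission[, st])
  }, ""), collapse = "")
}

#' Simulate a labelled synthetic protein dataset
#'
#' Generates `4 * n_per_class` records with balanced structural-class
#' labels.  Each record's secondary-structure string is drawn from a
#' class-specific segment grammar (all-alpha: helix-dominant; all-beta:
#' strand-dominant; alpha/beta: strictly alternating H/E blocks with short
#' coils; alpha+beta: a helix-block region followed by a strand-block
#' region), and the amino-acid sequence is then emitted residue-by-residue
#' from per-state propensity tables.  Deterministic given the seed.
#'
#' @param n_per_class Records per class (>= 1).
#' @param length_range Inclusive `c(min, max)` sequence length; the lower
#'   bound must be >= 30 so grammars have room for segments.
#' @param seed Integer seed.
#' @return A `protein_dataset` with ids `syn0001`, ..., in class-block
#'   order (all-alpha block first).
#' @export
simulate_protein_dataset <- function(n_per_class, length_range = c(100L, 300L),
                                     seed = 1L) {
  stopifnot(n_per_class >= 1L, length(length_range) == 2L)
  if (length_range[1L] < 30L) {
    stop("length_range lower bound must be >= 30")
  }
  labels <- rep(STRUCTURAL_CLASSES, each = n_per_class)
  n <- length(labels)
  local_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    ss <- vapply(seq_len(n), function(i) simulate_ss(labels[i], lens[i]), "")
    aa <- vapply(ss, simulate_aa, "")
  })
  new_protein_dataset(sprintf("syn%04d", seq_len(n)), unname(aa), unname(ss),
                      labels)
}

#' Planted-feature Gaussian matrix for feature-selection benchmarks
#'
#' All columns are unit-variance Gaussian noise; `n_informative` randomly
#' placed columns additionally receive class-dependent mean shifts of
#' `effect` pooled-SD units between consecutive classes, with the class
#' order independently permuted per informative column (so informative
#' columns are complementary, not redundant).  `effect = 0` makes every
#' column exchangeable noise.
#'
#' @param n Samples (must be >= `2 * n_classes`).
#' @param d Total columns.
#' @param n_informative Number of planted columns (<= d).
#' @param effect Between-consecutive-class mean separation in SD units.
#' @param n_classes Number of classes (balanced labels `c1..ck`).
#' @param seed Integer seed.
#' @return List with `X` (n x d named matrix, columns `f0001`...),
#'   `y` (character labels), `informative` (planted column names).
#' @export
planted_matrix <- function(n, d, n_informative, effect, n_classes = 4L,
                           seed = 1L) {
  stopifnot(n_informative <= d, effect >= 0)
  if (n < 2L * n_classes) stop("need n >= 2 * n_classes")
  y <- rep_len(paste0("c", seq_len(n_classes)), n)
  yi <- as.integer(factor(y))
  local_seed(seed, {
    X <- matrix(stats::rnorm(n * d), n, d,
                dimnames = list(NULL, sprintf("f%04d", seq_len(d))))
    inf_idx <- sort(sample.int(d, n_informative))
    for (j in inf_idx) {
      shift <- effect * (sample.int(n_classes) - 1L)
      X[, j] <- X[, j] + shift[yi]
    }
  })
  list(X = X, y = y, informative = colnames(X)[inf_idx])
}
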