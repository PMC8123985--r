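#' Build the combined named feature matrix for a dataset
#'
#' Concatenates the enabled feature families per record:
#' \describe{
#'   \item{PSF}{k-word content features, k = 1, 2 (20 + 400 columns)}
#'   \item{PPF}{k-word position features, k = 1, 2 (20 + 400 columns)}
#'   \item{RCF}{reduced-alphabet combined features (24 columns)}
#'   \item{PSSF}{secondary-structure descriptors (22, or 11 with the
#'     `"eleven"` preset)}
#' }
#' The default full layout has 886 columns.  Row order follows the
#' dataset; column names are globally unique and stable.
#'
#' @param ds A `protein_dataset` from [assemble_dataset()] or
#'   [simulate_protein_dataset()].
#' @param families Character subset of `c("PSF","PPF","RCF","PSSF")`.
#' @param ss_preset Secondary-structure preset, see [ss_feature_vector()].
#' @return A `feature_matrix`: list with `ids`, `X` (named numeric
#'   matrix), `family` (tag per column).
#' @export
build_feature_matrix <- function(ds, families = c("PSF", "PPF", "RCF", "PSSF"),
                                 ss_preset = c("full", "eleven")) {
  families <- match.arg(families, several.ok = TRUE)
  ss_preset <- match.arg(ss_preset)
  stopifnot(nrow(ds) >= 1L)
  if ("PSSF" %in% families) {
    miss <- ds$id[is.na(ds$ss_seq)]
    if (length(miss) > 0L) {
      stop("PSSF enabled but secondary structure missing for id(s): ",
           paste(miss, collapse = ", "))
    }
  }
  idx1 <- kmer_index(AA_ALPHABET20, 1L)
  idx2 <- kmer_index(AA_ALPHABET20, 2L)
  one <- function(i) {
    aa <- ds$aa_seq[i]
    blocks <- list()
    if ("PSF" %in% families) {
      blocks$PSF <- c(scf_vector(aa, 1L, idx1), scf_vector(aa, 2L, idx2))
    }
    if ("PPF" %in% families) {
      blocks$PPF <- c(spf_vector(aa, 1L, idx1), spf_vector(aa, 2L, idx2))
    }
    if ("RCF" %in% families) blocks$RCF <- reduced_feature_vector(aa)
    if ("PSSF" %in% families) {
      blocks$PSSF <- ss_feature_vector(ds$ss_seq[i], ss_preset)
    }
    blocks
  }
  first <- one(1L)
  family <- rep(names(first), times = lengths(first))
  X <- matrix(0, nrow(ds), sum(lengths(first)),
              dimnames = list(ds$id, unlist(lapply(first, names),
                                            use.names = FALSE)))
  X[1L, ] <- unlist(first, use.names = FALSE)
  if (nrow(ds) > 1L) {
    for (i in 2L:nrow(ds)) X[i, ] <- unlist(one(i), use.names = FALSE)
  }
  if (anyDuplicated(colnames(X))) stop("internal: duplicate feature names")
  if (!all(is.finite(X))) stop("internal: non-finite feature values")
  structure(list(ids = ds$id, X = X,
                 family = stats::setNames(family, colnames(X))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$X), "samples x", ncol(x$X), "features\n")
  print(table(x$family))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Layout: header row of feature names (first column `id`), a second
#' header row of family tags, then one row per sample.  Deterministic
#' full-precision formatting, so identical matrices give identical bytes.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @export
write_feature_csv <- function(fm, path) {
  num <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  rows <- vapply(seq_len(nrow(fm$X)), function(i) {
    paste(c(fm$ids[i], num(fm$X[i, ])), collapse = ",")
  }, "")
  writeLines(c(paste(c("id", colnames(fm$X)), collapse = ","),
               paste(c("family", unname(fm$family)), collapse = ","),
               rows), path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1]]
  fam <- strsplit(lines[2L], ",", fixed = TRUE)[[1]]
  stopifnot(hdr[1L] == "id", fam[1L] == "family")
  body <- strsplit(lines[-(1:2)], ",", fixed = TRUE)
  ids <- vapply(body, `[`, "", 1L)
  X <- do.call(rbind, lapply(body, function(r) as.numeric(r[-1L])))
  dimnames(X) <- list(ids, hdr[-1L])
  structure(list(ids = ids, X = X,
                 family = stats::setNames(fam[-1L], hdr[-1L])),
            class = "feature_matrix")
}
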