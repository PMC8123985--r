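#' Read a FASTA file of protein (or secondary-structure) sequences
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases,
#' strips whitespace, preserves record order, and rejects empty record
#' bodies (naming the offending id).
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (names are record ids,
#'   the first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(trimws(first), ">")) {
    stop("not a FASTA file (first line does not start with '>'): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty record body for id(s): ", paste(ids[empty], collapse = ", "))
  }
  stats::setNames(unname(seqs), ids)
}

#' Read a PSI-PRED VFORMAT .ss2 file into an H/E/C string
#'
#' A `.ss2` file has comment/blank header lines followed by rows of
#' `index residue state conf_C conf_H conf_E`.  Only the state column is
#' used.  Coil aliases `-` and `L` are normalized to `C`.
#'
#' @param path Path to a `.ss2` file.
#' @return A single string over `{H,E,C}` ("" for a header-only file).
#' @export
read_ss2 <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  body <- grepl("^[0-9]+[[:space:]]", lines)
  lines <- lines[body]
  if (length(lines) == 0L) return("")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed .ss2 row: ", lines[which(bad)[1L]])
  idx <- as.integer(vapply(parts, `[`, "", 1L))
  if (!identical(idx, seq_along(idx))) {
    stop("non-contiguous residue indices in ", path)
  }
  states <- toupper(vapply(parts, `[`, "", 3L))
  states[states %in% c("-", "L")] <- "C"
  unknown <- !(states %in% SS_ALPHABET)
  if (any(unknown)) {
    stop("secondary-structure state outside {H,E,C} at row ",
         which(unknown)[1L], ": '", states[which(unknown)[1L]], "'")
  }
  paste(states, collapse = "")
}

# Normalize a secondary-structure string: uppercase, coil aliases -> C.
normalize_ss <- function(ss) {
  ss <- toupper(ss)
  ss <- chartr("-L", "CC", ss)
  bad <- gsub("[HEC]", "", ss)
  if (any(nzchar(bad))) {
    stop("secondary-structure string contains non-{H,E,C} symbols: ",
         substr(bad[nzchar(bad)][1L], 1L, 10L))
  }
  ss
}

# Validate/normalize an amino-acid sequence against the 20-letter alphabet.
# `nonstandard` is NULL (reject B/Z/X/U/O etc.) or a single standard
# residue they are all mapped to.
normalize_aa <- function(seq, id = "?", nonstandard = NULL) {
  seq <- toupper(gsub("[[:space:]]", "", seq))
  if (!is.null(nonstandard)) {
    stopifnot(nonstandard %in% AA_ALPHABET20)
    seq <- gsub("[^ACDEFGHIKLMNPQRSTVWY]", nonstandard, seq)
  }
  resid <- strsplit(seq, "")[[1]]
  bad <- which(!(resid %in% AA_ALPHABET20))
  if (length(bad) > 0L) {
    stop("record '", id, "': non-standard residue '", resid[bad[1L]],
         "' at position ", bad[1L],
         " (set nonstandard= to map such residues)")
  }
  seq
}

#' Read a TSV label table (id -> structural class)
#'
#' Two tab-separated columns, UTF-8, `#` comments allowed.  Class tokens
#' are matched case-insensitively against a configurable alias table.
#'
#' @param path Path to the TSV file.
#' @param aliases Named character vector mapping extra spellings to the
#'   canonical classes in [STRUCTURAL_CLASSES].
#' @return A data.frame with columns `id`, `label` (canonical spelling).
#' @export
read_labels <- function(path, aliases = default_class_aliases()) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, col.names = c("id", "label"),
                          colClasses = "character")
  df$label <- canonical_class(df$label, aliases)
  df
}

#' Default alias table for structural-class labels
#' @return Named character vector (names are accepted spellings, values
#'   canonical classes).
#' @export
default_class_aliases <- function() {
  c("a" = "all-alpha", "all-a" = "all-alpha", "alpha" = "all-alpha",
    "all-alpha" = "all-alpha", "all-α" = "all-alpha",
    "b" = "all-beta", "all-b" = "all-beta", "beta" = "all-beta",
    "all-beta" = "all-beta", "all-β" = "all-beta",
    "a/b" = "alpha/beta", "alpha/beta" = "alpha/beta",
    "α/β" = "alpha/beta",
    "a+b" = "alpha+beta", "alpha+beta" = "alpha+beta",
    "α+β" = "alpha+beta")
}

canonical_class <- function(tokens, aliases = default_class_aliases()) {
  key <- tolower(trimws(tokens))
  out <- unname(aliases[key])
  if (anyNA(out)) {
    bad <- unique(tokens[is.na(out)])
    stop("unknown class token(s): ", paste(bad, collapse = ", "),
         "; accepted canonical spellings: ",
         paste(STRUCTURAL_CLASSES, collapse = ", "),
         " (plus aliases a, b, a/b, a+b)")
  }
  out
}

#' Assemble a validated dataset from FASTA, secondary structure, and labels
#'
#' @param fasta Path to the amino-acid FASTA file.
#' @param ss_source Either a path to a FASTA-of-H/E/C-strings file keyed by
#'   the same ids, a named character vector of H/E/C strings, or a named
#'   character vector of per-id `.ss2` file paths.  `NULL` for datasets
#'   without secondary structure.
#' @param labels Path to the TSV label table, or a data.frame with columns
#'   `id` and `label`.
#' @param nonstandard Policy for non-standard residues: `NULL` to reject
#'   (default) or one standard residue to substitute.
#' @param aliases Class alias table, see [read_labels()].
#' @return A `protein_dataset` object: a data.frame with columns `id`,
#'   `aa_seq`, `ss_seq` (possibly `NA`), `label`, ordered as in the label
#'   table.
#' @export
assemble_dataset <- function(fasta, ss_source = NULL, labels,
                             nonstandard = NULL,
                             aliases = default_class_aliases()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    read_fasta(fasta)
  } else {
    fasta  # already a named character vector
  }
  lab <- if (is.data.frame(labels)) {
    data.frame(id = as.character(labels$id),
               label = canonical_class(as.character(labels$label), aliases),
               stringsAsFactors = FALSE)
  } else {
    read_labels(labels, aliases)
  }
  if (anyDuplicated(lab$id)) {
    stop("duplicate ids in label table: ",
         paste(unique(lab$id[duplicated(lab$id)]), collapse = ", "))
  }
  ss <- NULL
  if (!is.null(ss_source)) {
    if (is.character(ss_source) && length(ss_source) == 1L &&
        file.exists(ss_source)) {
      ss <- read_fasta(ss_source)
    } else if (is.character(ss_source) && !is.null(names(ss_source)) &&
               all(file.exists(ss_source))) {
      ss <- vapply(ss_source, read_ss2, "")
    } else {
      ss <- ss_source
    }
  }
  missing_seq <- setdiff(lab$id, names(seqs))
  if (length(missing_seq) > 0L) {
    stop("ids in label table without a sequence: ",
         paste(missing_seq, collapse = ", "))
  }
  aa <- vapply(lab$id, function(i) normalize_aa(seqs[[i]], i, nonstandard), "")
  ss_col <- rep(NA_character_, nrow(lab))
  if (!is.null(ss)) {
    missing_ss <- setdiff(lab$id, names(ss))
    if (length(missing_ss) > 0L) {
      stop("ids in label table without a secondary-structure string: ",
           paste(missing_ss, collapse = ", "))
    }
    ss_col <- vapply(lab$id, function(i) normalize_ss(ss[[i]]), "")
    mism <- nchar(aa) != nchar(ss_col)
    if (any(mism)) {
      stop("sequence/secondary-structure length mismatch for id(s): ",
           paste(lab$id[mism], collapse = ", "))
    }
  }
  new_protein_dataset(lab$id, unname(aa), unname(ss_col), lab$label)
}

new_protein_dataset <- function(id, aa_seq, ss_seq, label) {
  stopifnot(!anyDuplicated(id), all(nchar(aa_seq) >= 1L))
  ds <- data.frame(id = id, aa_seq = aa_seq, ss_seq = ss_seq, label = label,
                   stringsAsFactors = FALSE)
  class(ds) <- c("protein_dataset", "data.frame")
  ds
}

#' @export
print.protein_dataset <- function(x, ...) {
  cat("protein_dataset:", nrow(x), "records\n")
  if (nrow(x) > 0L) {
    cat("  lengths:", min(nchar(x$aa_seq)), "-", max(nchar(x$aa_seq)), "\n")
    if (!all(is.na(x$label))) print(table(x$label))
  }
  invisible(x)
}

#' Write a dataset back to FASTA + SS-FASTA + TSV labels
#'
#' Emits exactly the three files [assemble_dataset()] consumes, so a
#' round-trip reproduces identical records.
#'
#' @param ds A `protein_dataset`.
#' @param dir Output directory (created if needed).
#' @param stem File stem; writes `<stem>.fasta`, `<stem>.ss.fasta`,
#'   `<stem>.labels.tsv`.
#' @return Invisibly, the three paths.
#' @export
write_dataset <- function(ds, dir, stem = "dataset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(stem, ".fasta"))
  ssfa <- file.path(dir, paste0(stem, ".ss.fasta"))
  labf <- file.path(dir, paste0(stem, ".labels.tsv"))
  writeLines(paste0(">", ds$id, "\n", ds$aa_seq), fa)
  paths <- c(fasta = fa, labels = labf)
  if (!all(is.na(ds$ss_seq))) {
    writeLines(paste0(">", ds$id, "\n", ds$ss_seq), ssfa)
    paths <- c(paths, ss = ssfa)
  }
  writeLines(c("# id\tclass", paste0(ds$id, "\t", ds$label)), labf)
  invisible(paths)
}
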