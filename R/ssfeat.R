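#' Maximal-run segments of a secondary-structure string
#'
#' @param ss String over `{H,E,C}`.
#' @param element One of `"H"`, `"E"`, `"C"`, or `NULL` for all elements.
#' @return data.frame with columns `element`, `start` (1-based), `length`,
#'   in string order.
#' @export
ss_segments <- function(ss, element = NULL) {
  stopifnot(nchar(ss) >= 1L)
  r <- rle(strsplit(ss, "")[[1]])
  start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  seg <- data.frame(element = r$values, start = start, length = r$lengths,
                    stringsAsFactors = FALSE)
  if (!is.null(element)) seg <- seg[seg$element == element, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Secondary-structure element content
#'
#' Fraction of residues in each of H, E, C; sums to 1.
#'
#' @param ss Non-empty string over `{H,E,C}`.
#' @return Named numeric vector `c(H=, E=, C=)`.
#' @export
ss_content <- function(ss) {
  n <- nchar(ss)
  if (n == 0L) stop("empty secondary-structure string")
  ch <- strsplit(ss, "")[[1]]
  vapply(stats::setNames(SS_ALPHABET, SS_ALPHABET),
         function(e) sum(ch == e) / n, 0)
}

#' Composition moment vector of a secondary-structure element
#'
#' Order-k moment of the element's 1-based occurrence positions:
#' `sum(pos^k) / prod((N - 1), ..., (N - k))`.
#'
#' @param ss String over `{H,E,C}` with `nchar(ss) >= order + 1`.
#' @param element One of `"H"`, `"E"`, `"C"`.
#' @param order Moment order, 1 or 2.
#' @return Non-negative scalar; 0 when the element is absent.
#' @export
cmv <- function(ss, element, order) {
  n <- nchar(ss)
  stopifnot(order %in% c(1L, 2L))
  if (n < order + 1L) {
    stop("sequence length ", n, " too short for CMV order ", order)
  }
  pos <- which(strsplit(ss, "")[[1]] == element)
  if (length(pos) == 0L) return(0)
  sum(as.numeric(pos)^order) / prod(n - seq_len(order))
}

#' Longest/average segment lengths of a secondary-structure element
#'
#' @inheritParams cmv
#' @return Named numeric vector `c(max_seg, nmax_seg, avg_seg, navg_seg)`:
#'   longest run length, longest/N, mean run length, mean/N.  All 0 when
#'   the element is absent.
#' @export
segment_stats <- function(ss, element) {
  n <- nchar(ss)
  if (n == 0L) stop("empty secondary-structure string")
  seg <- ss_segments(ss, element)
  if (nrow(seg) == 0L) {
    return(c(max_seg = 0, nmax_seg = 0, avg_seg = 0, navg_seg = 0))
  }
  mx <- max(seg$length)
  avg <- mean(seg$length)
  c(max_seg = mx, nmax_seg = mx / n, avg_seg = avg, navg_seg = avg / n)
}

#' Normalized helix/strand alternation frequency
#'
#' Coil runs are deleted, the string is collapsed to its ordered sequence
#' of H/E segments, adjacent unequal pairs are counted, and the count is
#' divided by the string length.  Always in `[0, 1)`.
#'
#' @param ss Non-empty string over `{H,E,C}`.
#' @return Scalar in `[0, 1)`.
#' @export
nalt <- function(ss) {
  n <- nchar(ss)
  if (n == 0L) stop("empty secondary-structure string")
  seg <- ss_segments(ss)
  he <- seg$element[seg$element != "C"]
  # collapse runs that become adjacent after coil removal
  he <- rle(he)$values
  if (length(he) < 2L) return(0)
  sum(he[-1L] != he[-length(he)]) / n
}

#' Full secondary-structure descriptor vector
#'
#' Default (`preset = "full"`): content (3) + CMV order 1 (3) + CMV order
#' 2 (3) + max_seg (3) + nmax_seg (3) + avg_seg (3) + navg_seg (3) +
#' nalt (1) = 22 named values.  `preset = "eleven"` restricts to the
#' H/E-only set: content, CMV1, CMV2, max_seg, nmax_seg (2 each) + nalt
#' = 11 values.
#'
#' @param ss Non-empty string over `{H,E,C}` with `nchar(ss) >= 3`.
#' @param preset `"full"` (22 features) or `"eleven"` (11 features).
#' @return Named numeric vector, names `ss_content_H`, `ss_cmv1_E`,
#'   `ss_maxseg_C`, ..., `ss_nalt`.
#' @export
ss_feature_vector <- function(ss, preset = c("full", "eleven")) {
  preset <- match.arg(preset)
  elems <- if (preset == "full") SS_ALPHABET else c("H", "E")
  cont <- ss_content(ss)[elems]
  cmv1 <- vapply(elems, function(e) cmv(ss, e, 1L), 0)
  cmv2 <- vapply(elems, function(e) cmv(ss, e, 2L), 0)
  segs <- vapply(elems, function(e) segment_stats(ss, e), numeric(4))
  out <- c(stats::setNames(cont, paste0("ss_content_", elems)),
           stats::setNames(cmv1, paste0("ss_cmv1_", elems)),
           stats::setNames(cmv2, paste0("ss_cmv2_", elems)),
           stats::setNames(segs["max_seg", ], paste0("ss_maxseg_", elems)),
           stats::setNames(segs["nmax_seg", ], paste0("ss_nmaxseg_", elems)))
  if (preset == "full") {
    out <- c(out,
             stats::setNames(segs["avg_seg", ], paste0("ss_avgseg_", elems)),
             stats::setNames(segs["navg_seg", ], paste0("ss_navgseg_", elems)))
  }
  c(out, ss_nalt = nalt(ss))
}
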