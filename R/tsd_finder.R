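#' Detect a target site duplication around an element
#'
#' Scans for a direct repeat shared by the end of the left flank and the
#' start of the right flank, the footprint left by target-primed reverse
#' transcription. Candidate lengths run from `max_len` down to `min_len`
#' with up to `max_offset` bp of slack on each side (annotated element
#' boundaries are imprecise); a candidate passes with at most
#' `max_mismatch` differences. Among candidates the longest wins, an exact
#' copy beats a one-mismatch copy of equal length, and smaller offsets
#' break remaining ties. The winning repeat is then extended outwards while
#' the copies keep matching exactly, so duplications longer than the search
#' band are reported at their true length (flagged `over_band`).
#'
#' @param left_flank sequence immediately 5' of the element (<= 30 bp used).
#' @param right_flank sequence immediately 3' of the element, after any
#'   residual poly-A tail (see [extract_tsd_flanks()]).
#' @param min_len,max_len search band for the duplication length
#'   (default 6-15 bp).
#' @param max_mismatch maximum differences between the two copies (0 or 1).
#' @param max_offset maximum bp between element boundary and each copy.
#' @return a `tsd_call`: list with `found`, `length`, `left_copy`,
#'   `right_copy`, `mismatches`, `left_offset`, `right_offset`,
#'   `over_band`, `reason`.
#' @export
find_tsd <- function(left_flank, right_flank, min_len = 6L, max_len = 15L,
                     max_mismatch = 1L, max_offset = 5L) {
  no <- function(reason) {
    structure(list(found = FALSE, length = 0L, left_copy = "",
                   right_copy = "", mismatches = NA_integer_,
                   left_offset = NA_integer_, right_offset = NA_integer_,
                   over_band = FALSE, reason = reason), class = "tsd_call")
  }
  if (nchar(left_flank) == 0L || nchar(right_flank) == 0L) {
    return(no("empty flank"))
  }
  l <- seq_chars(toupper(left_flank))
  r <- seq_chars(toupper(right_flank))
  nl <- length(l)
  nr <- length(r)
  best <- NULL
  for (len in seq(max_len, min_len)) {
    for (loff in 0:max_offset) {
      li <- nl - loff - len + 1L
      if (li < 1L) next
      lw <- l[li:(nl - loff)]
      for (roff in 0:max_offset) {
        if (roff + len > nr) next
        rw <- r[(roff + 1L):(roff + len)]
        mm <- sum(lw != rw)
        if (mm > max_mismatch) next
        cand <- list(len = len, mm = mm, loff = loff, roff = roff)
        if (is.null(best) ||
            cand$mm < best$mm ||
            (cand$mm == best$mm &&
             (cand$loff + cand$roff < best$loff + best$roff ||
              (cand$loff + cand$roff == best$loff + best$roff &&
               cand$loff < best$loff)))) {
          best <- cand
        }
      }
    }
    if (!is.null(best)) break  # lengths scanned longest-first
  }
  if (is.null(best)) return(no("no duplication in band"))
  # exact extension beyond the band: both copies can grow into the offset
  # slack (rightwards by consuming left offset, leftwards by consuming the
  # right offset), so duplications longer than max_len are reported at the
  # extent the 30 bp windows allow
  len <- best$len
  loff <- best$loff
  roff <- best$roff
  repeat {
    if (loff > 0L && roff + len + 1L <= nr &&
        l[nl - loff + 1L] == r[roff + len + 1L]) {
      len <- len + 1L
      loff <- loff - 1L
      next
    }
    if (roff > 0L && nl - loff - len >= 1L && l[nl - loff - len] == r[roff]) {
      len <- len + 1L
      roff <- roff - 1L
      next
    }
    break
  }
  lw <- l[(nl - loff - len + 1L):(nl - loff)]
  rw <- r[(roff + 1L):(roff + len)]
  structure(list(found = TRUE, length = len,
                 left_copy = paste(lw, collapse = ""),
                 right_copy = paste(rw, collapse = ""),
                 mismatches = sum(lw != rw),
                 left_offset = loff, right_offset = roff,
                 over_band = len > max_len, reason = "ok"),
            class = "tsd_call")
}

#' Extract the 30 bp flanks used for TSD detection
#'
#' Takes `window` bp immediately adjacent to the element span on each side.
#' Can-SINE poly-A tails sit between the element body and the 3' TSD copy;
#' when the annotation boundary leaves part of the tail outside the span,
#' a residual A-run (>= `polya_min_run` consecutive A allowing one other
#' base) at the element-proximal end of the 3'-side flank is trimmed before
#' the window is taken. For minus-strand elements the tail appears as a
#' T-run on the element's left, and the trimming is applied there.
#'
#' @param genome a `genome_assembly`.
#' @param annotation one-row `repeat_annotations` slice.
#' @param window flank length in bp (default 30).
#' @param trim_polya trim residual poly-A/T runs (default TRUE).
#' @param polya_min_run minimum run length treated as a tail remnant.
#' @return list with `left_flank`, `right_flank`, `trimmed_bp`.
#' @export
extract_tsd_flanks <- function(genome, annotation, window = 30L,
                               trim_polya = TRUE, polya_min_run = 5L) {
  seq <- genome$sequences[[annotation$scaffold]]
  if (is.null(seq)) stop("scaffold not in genome: ", annotation$scaffold)
  n <- nchar(seq)
  s <- annotation$start
  e <- annotation$end
  trimmed <- 0L
  if (trim_polya) {
    if (annotation$strand == "+") {
      run <- run_length(seq, e, "A", forward = TRUE)
      if (run >= polya_min_run) {
        e <- e + run
        trimmed <- run
      }
    } else {
      run <- run_length(seq, s, "T", forward = FALSE)
      if (run >= polya_min_run) {
        s <- s - run
        trimmed <- run
      }
    }
  }
  left <- seq_slice(seq, max(0L, s - window), s)
  right <- seq_slice(seq, e, min(n, e + window))
  list(left_flank = left, right_flank = right, trimmed_bp = trimmed)
}

# length of a run of `base` (allowing one other base) starting at 0-based
# position `pos` going forward, or ending just before `pos` going backward
run_length <- function(seq, pos, base, forward = TRUE) {
  n <- nchar(seq)
  run <- 0L
  misses <- 0L
  repeat {
    p <- if (forward) pos + run + 1L else pos - run
    if (p < 1L || p > n) break
    ch <- substr(seq, p, p)
    if (ch != base) {
      misses <- misses + 1L
      if (misses > 1L) break
      nxt <- if (forward) p + 1L else p - 1L
      if (nxt < 1L || nxt > n || substr(seq, nxt, nxt) != base) break
    }
    run <- run + 1L
  }
  # do not count a trailing tolerated non-A as part of the run
  if (run > 0L) {
    last <- if (forward) pos + run else pos - run + 1L
    if (substr(seq, last, last) != base) run <- run - 1L
  }
  run
}
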