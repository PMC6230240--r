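#' Globally align an element to its subfamily consensus
#'
#' Needleman-Wunsch global alignment with affine gap costs (defaults:
#' match +1, mismatch -1, gap open -4, gap extend -1), via
#' [Biostrings::pairwiseAlignment()]. Elements must be pre-oriented to the
#' consensus strand (use the annotation strand); a reverse-complemented
#' element will simply align poorly.
#'
#' @param element_seq element DNA string.
#' @param consensus_seq consensus DNA string.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`.
#' @param element_id,family optional identifiers carried into the result.
#' @return an `element_alignment`: list with `aligned_element` and
#'   `aligned_consensus` (equal-length gapped strings), `columns`
#'   (per-column class: match/mismatch/insertion/deletion), `cpg`
#'   (per-column flag, TRUE where the consensus column is part of a CG
#'   dinucleotide of the ungapped consensus), `score`, `element_id`,
#'   `family`.
#' @export
align_to_consensus <- function(element_seq, consensus_seq,
                               scoring = list(match = 1, mismatch = -1,
                                              gap_open = -4, gap_extend = -1),
                               element_id = NA, family = NA_character_) {
  if (nchar(element_seq) == 0L || nchar(consensus_seq) == 0L) {
    stop("empty sequence")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = element_seq, subject = consensus_seq, type = "global",
    substitutionMatrix = mat,
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  ae <- as.character(Biostrings::alignedPattern(aln))
  ac <- as.character(Biostrings::alignedSubject(aln))
  element_alignment(ae, ac, element_id = element_id, family = family,
                    score = Biostrings::score(aln))
}

#' Build an element_alignment from two gapped strings
#'
#' @param aligned_element,aligned_consensus equal-length gapped ('-') DNA
#'   strings.
#' @param element_id,family optional identifiers.
#' @param score optional alignment score.
#' @return an `element_alignment` (see [align_to_consensus()]).
#' @export
element_alignment <- function(aligned_element, aligned_consensus,
                              element_id = NA, family = NA_character_,
                              score = NA_real_) {
  e <- seq_chars(aligned_element)
  c <- seq_chars(aligned_consensus)
  if (length(e) != length(c)) stop("aligned strings must have equal length")
  cols <- ifelse(e == "-" & c == "-", "empty",
          ifelse(e == "-", "deletion",
          ifelse(c == "-", "insertion",
          ifelse(e == c, "match", "mismatch"))))
  # CpG status of each consensus column, assessed on the ungapped consensus
  unc <- c[c != "-"]
  mask_unc <- cpg_mask(unc)
  cpg <- rep(FALSE, length(c))
  cpg[c != "-"] <- mask_unc
  structure(list(aligned_element = aligned_element,
                 aligned_consensus = aligned_consensus,
                 columns = cols, cpg = cpg, score = score,
                 element_id = element_id, family = family),
            class = "element_alignment")
}

#' Divergence of an element from its consensus, stratified by CpG status
#'
#' Divergence is the mismatch proportion over substitution columns only
#' (columns where both sequences have a base; gap and N columns excluded),
#' reported overall and separately for CpG and non-CpG consensus columns.
#' `mode = "kimura2p"` applies the Kimura two-parameter correction
#' `K = -1/2 ln((1-2P-Q) sqrt(1-2Q))` to the same columns, with P and Q the
#' transition and transversion proportions.
#'
#' @param alignment an `element_alignment`.
#' @param mode `"raw"` (default) or `"kimura2p"`.
#' @return a `divergence_estimate`: list with `overall`, `cpg`, `non_cpg`
#'   fractions in `[0,1]` (NA when a class has no substitution columns,
#'   flagged in `undefined`), a `counts` table of matched/mismatched per
#'   class, and `mode`.
#' @export
compute_divergence <- function(alignment, mode = c("raw", "kimura2p")) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "element_alignment"))
  e <- seq_chars(alignment$aligned_element)
  c <- seq_chars(alignment$aligned_consensus)
  sub <- alignment$columns %in% c("match", "mismatch") &
    e %in% DNA_BASES & c %in% DNA_BASES
  one_class <- function(keep) {
    n <- sum(keep)
    if (n == 0L) {
      return(list(div = NA_real_, matched = 0L, mismatched = 0L))
    }
    mm <- sum(e[keep] != c[keep])
    d <- if (mode == "raw") mm / n else {
      ts <- sum(keep & e != c &
                  paste0(pmin(e, c), pmax(e, c)) %in% c("AG", "CT"))
      P <- ts / n
      Q <- (mm - ts) / n
      arg <- (1 - 2 * P - Q) * sqrt(1 - 2 * Q)
      if (arg <= 0) NA_real_ else -0.5 * log(arg)
    }
    list(div = d, matched = n - mm, mismatched = mm)
  }
  ov <- one_class(sub)
  cg <- one_class(sub & alignment$cpg)
  ncg <- one_class(sub & !alignment$cpg)
  structure(list(
    overall = ov$div, cpg = cg$div, non_cpg = ncg$div,
    counts = data.frame(class = c("overall", "cpg", "non_cpg"),
                        matched = c(ov$matched, cg$matched, ncg$matched),
                        mismatched = c(ov$mismatched, cg$mismatched,
                                       ncg$mismatched)),
    mode = mode,
    undefined = ov$matched + ov$mismatched == 0L),
    class = "divergence_estimate")
}

#' Filter annotations for young, relatively intact elements
#'
#' Keeps elements of the requested family whose summed fragment length is
#' at least `min_len_bp` and whose divergence is at most `max_div_pct`;
#' both boundaries are inclusive. This is the screen applied before the
#' cross-species presence/absence stage (e.g. length >= 150 bp and
#' divergence <= 10% for SINEC1_AMe-type elements, >= 170 bp and <= 15%
#' for SINEC1B_AMe-type).
#'
#' @param annotations a `repeat_annotations` table.
#' @param family family name to keep.
#' @param min_len_bp minimum total fragment length (bp).
#' @param max_div_pct maximum divergence (percent).
#' @return the filtered `repeat_annotations`, original order preserved.
#' @export
select_young_elements <- function(annotations, family, min_len_bp,
                                  max_div_pct) {
  stopifnot(min_len_bp >= 0, max_div_pct >= 0)
  if (!family %in% annotations$family) {
    warning("family not present in annotations: ", family)
  }
  keep <- annotations$family == family &
    element_length(annotations) >= min_len_bp &
    annotations$divergence_pct <= max_div_pct
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# major repeat type from a RepeatMasker class/family string
repeat_type <- function(class) {
  type <- toupper(sub("/.*$", "", class))
  ifelse(type %in% c("SINE", "LINE", "LTR"), type,
         ifelse(type %in% c("DNA", "RC"), "DNA", "Other"))
}

#' Genome-wide repeat content summary
#'
#' Per-family and per-class (SINE/LINE/LTR/DNA/Other) element counts,
#' total bp (fragment lengths summed), genome percentage and mean
#' divergence, plus a divergence-landscape histogram (1% bins over 0-50%)
#' of bp per class.
#'
#' @param annotations a `repeat_annotations` table.
#' @param genome_size_bp total genome size in bp (> 0).
#' @return list with data.frames `by_family`, `by_class`, and
#'   `divergence_histogram` (columns `bin_lo`, `bin_hi`, `class`, `bp`).
#' @export
summarize_te_content <- function(annotations, genome_size_bp) {
  stopifnot(genome_size_bp > 0)
  len <- element_length(annotations)
  type <- repeat_type(annotations$class)
  agg <- function(key) {
    if (nrow(annotations) == 0L) {
      return(data.frame(key = character(), count = integer(),
                        total_bp = integer(), genome_pct = numeric(),
                        mean_divergence_pct = numeric(),
                        stringsAsFactors = FALSE))
    }
    sp <- split(seq_len(nrow(annotations)), key)
    data.frame(
      key = names(sp),
      count = vapply(sp, length, integer(1)),
      total_bp = vapply(sp, function(i) sum(as.numeric(len[i])), numeric(1)),
      genome_pct = vapply(sp, function(i)
        100 * sum(as.numeric(len[i])) / genome_size_bp, numeric(1)),
      mean_divergence_pct = vapply(
        sp, function(i) mean(annotations$divergence_pct[i]), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  by_family <- agg(annotations$family)
  names(by_family)[1L] <- "family"
  by_class <- agg(type)
  names(by_class)[1L] <- "class"
  bins <- data.frame(bin_lo = 0:49, bin_hi = 1:50)
  classes <- sort(unique(type))
  hist <- do.call(rbind, lapply(classes, function(cl) {
    i <- type == cl
    b <- pmin(floor(annotations$divergence_pct[i]), 49)
    bp <- vapply(0:49, function(k) sum(len[i][b == k]), numeric(1))
    data.frame(bins, class = cl, bp = bp, stringsAsFactors = FALSE)
  }))
  if (is.null(hist)) {
    hist <- data.frame(bin_lo = integer(), bin_hi = integer(),
                       class = character(), bp = numeric())
  }
  list(by_family = by_family, by_class = by_class,
       divergence_histogram = hist)
}
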