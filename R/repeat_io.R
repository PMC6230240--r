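#' Read a genome assembly from FASTA
#'
#' Loads a (multi-)FASTA file into a `genome_assembly`: a named set of
#' uppercase DNA strings restricted to the A/C/G/T/N alphabet. The scaffold
#' id is the header up to the first whitespace.
#'
#' @param path path to a FASTA file.
#' @param species_label free-text label for the species/assembly; defaults to
#'   the file name without extension.
#' @return a `genome_assembly` object: a list with elements `sequences`
#'   (named character vector of uppercase DNA) and `species_label`.
#' @export
read_fasta <- function(path, species_label = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id in FASTA: ", ids[duplicated(ids)][1L])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    # locate the first offending line for the error message
    lines <- readLines(path)
    hit <- which(!startsWith(lines, ">") & grepl("[^ACGTNacgtn[:space:]]", lines))[1L]
    stop(sprintf("FASTA format error: non-ACGTN character at line %s", hit))
  }
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for scaffold: ", ids[nchar(seqs) == 0L][1L])
  }
  genome_assembly(seqs, species_label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a genome assembly from in-memory sequences
#'
#' @param sequences named character vector of DNA strings (A/C/G/T/N).
#' @param species_label free-text label.
#' @return a `genome_assembly`.
#' @export
genome_assembly <- function(sequences, species_label = "genome") {
  stopifnot(is.character(sequences), length(sequences) > 0L,
            !is.null(names(sequences)))
  if (anyDuplicated(names(sequences))) stop("scaffold ids must be unique")
  if (any(nchar(sequences) == 0L)) stop("scaffold sequences must be non-empty")
  structure(list(sequences = sequences, species_label = species_label),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("genome_assembly '%s': %d scaffold(s), %s bp total\n",
              x$species_label, length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' Write a genome assembly to FASTA
#'
#' @param assembly a `genome_assembly`.
#' @param path output path.
#' @export
write_fasta <- function(assembly, path) {
  set <- Biostrings::DNAStringSet(assembly$sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a consensus library from FASTA
#'
#' @param path path to a FASTA file of repeat consensus sequences.
#' @return named character vector of uppercase consensus sequences; the
#'   remainder of each header line (after the name) is kept in the
#'   `"metadata"` attribute.
#' @export
read_consensus_library <- function(path) {
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  meta <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  if (anyDuplicated(ids)) stop("duplicate consensus name: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) stop("empty consensus sequence")
  names(seqs) <- ids
  attr(seqs, "metadata") <- stats::setNames(meta, ids)
  seqs
}

# canonical empty annotation table (one row per element, fragments nested)
empty_annotations <- function() {
  df <- data.frame(
    scaffold = character(), start = integer(), end = integer(),
    strand = character(), family = character(), class = character(),
    divergence_pct = numeric(), deletion_pct = numeric(),
    insertion_pct = numeric(), consensus_start = integer(),
    consensus_end = integer(), consensus_left = integer(),
    element_id = integer(), stringsAsFactors = FALSE)
  df$fragments <- list()
  class(df) <- c("repeat_annotations", "data.frame")
  df
}

#' Assemble a repeat annotation table
#'
#' Low-level constructor used by the parser and the simulator. Each row is
#' one element; `fragments` is a list column of data.frames with columns
#' `start`, `end`, `consensus_start`, `consensus_end` (genome coordinates
#' 0-based half-open, consensus coordinates 1-based inclusive as in
#' RepeatMasker output).
#'
#' @param df data.frame with the element-level columns (see
#'   [parse_repeatmasker_out()]) and a `fragments` list column.
#' @return the same data.frame with class `repeat_annotations`, after
#'   invariant checks.
#' @export
repeat_annotations <- function(df) {
  req <- c("scaffold", "start", "end", "strand", "family", "class",
           "divergence_pct", "element_id", "fragments")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing annotation columns: ", paste(miss, collapse = ", "))
  if (any(df$start >= df$end)) stop("annotation with start >= end")
  if (any(df$divergence_pct < 0 | df$divergence_pct > 100)) {
    stop("divergence_pct outside [0,100]")
  }
  for (i in seq_len(nrow(df))) {
    fr <- df$fragments[[i]]
    if (nrow(fr) == 0L) stop("element with no fragments")
    if (is.unsorted(fr$start)) stop("fragments must be sorted by start")
    if (any(fr$end[-nrow(fr)] > fr$start[-1L])) {
      stop("overlapping fragments within element ", df$element_id[i])
    }
  }
  class(df) <- unique(c("repeat_annotations", class(df)))
  df
}

#' Total element length in bp (fragments summed)
#'
#' @param annotations a `repeat_annotations` table.
#' @return integer vector of summed fragment lengths, one per element.
#' @export
element_length <- function(annotations) {
  vapply(annotations$fragments, function(fr) as.integer(sum(fr$end - fr$start)),
         integer(1))
}

#' Parse RepeatMasker .out annotations
#'
#' Reads the 15-column RepeatMasker `.out` dialect (3 header lines, then one
#' whitespace-delimited row per aligned fragment). Rows that share the ID
#' column, scaffold and repeat family are joined into a single multi-fragment
#' element, as produced when a repeat is interrupted by a nested insertion.
#' 1-based inclusive genome coordinates are converted to 0-based half-open;
#' strand `C` becomes `-` and its consensus coordinates are normalised so
#' that `consensus_start < consensus_end`.
#'
#' @param path path to a `.out` file.
#' @return a `repeat_annotations` data.frame, one row per element, with
#'   columns `scaffold`, `start`, `end`, `strand`, `family`, `class`,
#'   `divergence_pct`, `deletion_pct`, `insertion_pct`, `consensus_start`,
#'   `consensus_end`, `consensus_left`, `element_id`, and a `fragments` list
#'   column. Element-level divergence is the fragment-length-weighted mean.
#' @export
parse_repeatmasker_out <- function(path) {
  if (!file.exists(path)) stop(".out file not found: ", path)
  lines <- readLines(path)
  body <- lines[grepl("^\\s*\\d", lines)]
  if (length(body) == 0L) return(empty_annotations())
  toks <- strsplit(trimws(body), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 15L)) {
    stop(sprintf(".out format error: line with %d fields (15 expected)", min(nt)))
  }
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", i)))
    if (anyNA(x)) stop(".out format error: non-numeric ", what, " field")
    x
  }
  paren <- function(i) {
    raw <- vapply(toks, `[[`, "", i)
    suppressWarnings(as.integer(gsub("[()]", "", raw)))
  }
  strand_raw <- vapply(toks, `[[`, "", 9)
  if (!all(strand_raw %in% c("+", "C"))) stop(".out format error: strand field")
  minus <- strand_raw == "C"
  rows <- data.frame(
    divergence_pct = num(2, "divergence"),
    deletion_pct = num(3, "deletion"),
    insertion_pct = num(4, "insertion"),
    scaffold = vapply(toks, `[[`, "", 5),
    start = as.integer(num(6, "begin")) - 1L,  # to 0-based half-open
    end = as.integer(num(7, "end")),
    strand = ifelse(minus, "-", "+"),
    family = vapply(toks, `[[`, "", 10),
    class = vapply(toks, `[[`, "", 11),
    element_id = as.integer(num(15, "ID")),
    stringsAsFactors = FALSE)
  # consensus coordinates: "+" rows are begin,end,(left); "C" rows (left),end,begin
  c12 <- paren(12); c13 <- paren(13); c14 <- paren(14)
  rows$consensus_start <- ifelse(minus, c14, c12)
  rows$consensus_end <- c13
  rows$consensus_left <- ifelse(minus, c12, c14)
  if (anyNA(rows$consensus_start) || anyNA(rows$consensus_end)) {
    stop(".out format error: non-numeric consensus coordinate")
  }
  if (any(rows$start < 0L | rows$start >= rows$end)) {
    stop(".out consistency error: begin > end in genome coordinates")
  }

  key <- paste(rows$scaffold, rows$element_id, rows$family, sep = "\r")
  out <- lapply(split(seq_len(nrow(rows)), key), function(idx) {
    r <- rows[idx, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$end[-nrow(r)] > r$start[-1L])) {
      stop(".out consistency error: overlapping fragments for ID ",
           r$element_id[1L])
    }
    len <- r$end - r$start
    el <- r[1L, , drop = FALSE]
    el$start <- min(r$start)
    el$end <- max(r$end)
    el$divergence_pct <- sum(r$divergence_pct * len) / sum(len)
    el$deletion_pct <- sum(r$deletion_pct * len) / sum(len)
    el$insertion_pct <- sum(r$insertion_pct * len) / sum(len)
    el$consensus_start <- min(r$consensus_start)
    el$consensus_end <- max(r$consensus_end)
    el$consensus_left <- min(r$consensus_left)
    el$fragments <- list(data.frame(
      start = r$start, end = r$end,
      consensus_start = r$consensus_start, consensus_end = r$consensus_end,
      consensus_left = r$consensus_left, stringsAsFactors = FALSE))
    el
  })
  df <- do.call(rbind, out)
  df <- df[order(df$scaffold, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df <- df[, c("scaffold", "start", "end", "strand", "family", "class",
               "divergence_pct", "deletion_pct", "insertion_pct",
               "consensus_start", "consensus_end", "consensus_left",
               "element_id", "fragments")]
  repeat_annotations(df)
}

#' Write annotations in RepeatMasker .out format
#'
#' Inverse of [parse_repeatmasker_out()]: emits one row per fragment with
#' 1-based inclusive coordinates and `C` for minus-strand hits, so that
#' re-parsing recovers the same elements.
#'
#' @param annotations a `repeat_annotations` table.
#' @param path output path.
#' @export
write_repeatmasker_out <- function(annotations, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query     matching  repeat        position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)   repeat    class/family  begin end   (left)  ID",
    "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    fr <- a$fragments[[1L]]
    for (j in seq_len(nrow(fr))) {
      if (a$strand == "+") {
        rcols <- c(fr$consensus_start[j], fr$consensus_end[j],
                   sprintf("(%d)", fr$consensus_left[j]))
      } else {
        rcols <- c(sprintf("(%d)", fr$consensus_left[j]),
                   fr$consensus_end[j], fr$consensus_start[j])
      }
      writeLines(paste(
        1000, sprintf("%.1f", a$divergence_pct), sprintf("%.1f", a$deletion_pct),
        sprintf("%.1f", a$insertion_pct), a$scaffold,
        fr$start[j] + 1L, fr$end[j], "(0)",
        if (a$strand == "+") "+" else "C",
        a$family, a$class, rcols[1L], rcols[2L], rcols[3L], a$element_id,
        sep = " "), con)
    }
  }
  invisible(path)
}

#' Export annotations as BED6 or GFF3 intervals
#'
#' One record per fragment; the element id is carried in the BED name column
#' (`family|element_id`) and in the GFF3 `ID`/`Name` attributes. BED uses
#' 0-based half-open coordinates, GFF3 1-based inclusive.
#'
#' @param annotations a `repeat_annotations` table.
#' @param path output path.
#' @param format `"BED"` or `"GFF3"`.
#' @export
write_intervals <- function(annotations, path, format = c("BED", "GFF3")) {
  format <- match.arg(format)
  gr <- annotations_to_granges(annotations)
  if (format == "BED") {
    lines <- if (length(gr) == 0L) character() else
      paste(GenomicRanges::seqnames(gr), GenomicRanges::start(gr) - 1L,
            GenomicRanges::end(gr), gr$name, 0L,
            as.character(GenomicRanges::strand(gr)), sep = "\t")
    writeLines(lines, path)
  } else {
    body <- if (length(gr) == 0L) character() else
      paste(GenomicRanges::seqnames(gr), "cansine", "dispersed_repeat",
            GenomicRanges::start(gr), GenomicRanges::end(gr), ".",
            as.character(GenomicRanges::strand(gr)), ".",
            sprintf("ID=%s;Name=%s", gr$name, gr$family), sep = "\t")
    writeLines(c("##gff-version 3", body), path)
  }
  invisible(path)
}

#' Convert annotations to a GRanges (one range per fragment)
#'
#' @param annotations a `repeat_annotations` table.
#' @return a [GenomicRanges::GRanges] with `name` (`family|element_id`) and
#'   `family` metadata columns; coordinates 1-based as usual for GRanges.
#' @export
annotations_to_granges <- function(annotations) {
  if (nrow(annotations) == 0L) {
    return(GenomicRanges::GRanges(name = character(), family = character()))
  }
  nfr <- vapply(annotations$fragments, nrow, integer(1))
  frs <- do.call(rbind, annotations$fragments)
  GenomicRanges::GRanges(
    seqnames = rep(annotations$scaffold, nfr),
    ranges = IRanges::IRanges(start = frs$start + 1L, end = frs$end),
    strand = rep(annotations$strand, nfr),
    name = rep(paste0(annotations$family, "|", annotations$element_id), nfr),
    family = rep(annotations$family, nfr))
}
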