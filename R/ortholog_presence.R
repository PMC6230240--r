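#' Parameters for the orthologous-locus presence/absence screen
#'
#' Defaults follow the screening rules used for lineage-specific SINE
#' calling: 500 bp flanks, hits kept when they cover >= 90% of the query
#' flank at >= 80% identity, and an empty (insertion-absent) site requires
#' the two flanks to map back-to-back with at most `empty_gap_max` bp
#' between their inner ends. The paralogy margin discards loci whose best
#' and second-best hits are nearly equally good. Identity is computed over
#' aligned bases (matches / (matches + mismatches)), so an element
#' inserted into one lineage's flank shows up as a bridged gap rather than
#' destroying the hit.
#'
#' @param flank_len flank length in bp.
#' @param min_identity minimum identity over aligned bases (fraction).
#' @param min_coverage minimum query coverage (fraction).
#' @param empty_gap_max maximum inter-flank gap (bp) for an absent call;
#'   tolerates TSD remnants and microindels.
#' @param empty_gap_min minimum (most negative) gap: flank alignments may
#'   overlap at an empty site because the single TSD copy aligns to both
#'   flanks.
#' @param present_cover_min fraction of the inter-flank span a same-family
#'   annotation must cover for a present call.
#' @param paralog_margin unresolved when second-best identity is within
#'   this margin of the best.
#' @param seed_k exact seed length for the k-mer seeding stage.
#' @param seed_stride spacing of seeds along the query flank.
#' @param band diagonal tolerance when clustering seed hits.
#' @param chain_gap_max largest insertion/deletion (bp) bridged when
#'   chaining seed clusters of one hit.
#' @param max_seed_hits seeds matching more places than this in a target
#'   are dropped as repetitive (they fall inside TE copies, not unique
#'   flanking sequence).
#' @param min_unmasked minimum unmasked bp a flank must retain to be
#'   mappable; below this the flank is treated as unalignable.
#' @param window_margin extra bp around the seeded window for the gapped
#'   extension alignment.
#' @return list of class `ortholog_params`.
#' @export
ortholog_params <- function(flank_len = 500L, min_identity = 0.80,
                            min_coverage = 0.90, empty_gap_max = 30L,
                            empty_gap_min = -60L, present_cover_min = 0.5,
                            paralog_margin = 0.02, seed_k = 13L,
                            seed_stride = 7L, band = 40L,
                            chain_gap_max = 2000L, max_seed_hits = 30L,
                            min_unmasked = 100L, window_margin = 600L) {
  structure(as.list(environment()), class = "ortholog_params")
}

#' Extract element flanks for orthologous-locus mapping
#'
#' When `mask_annotations` is supplied, flank positions covered by other
#' annotated repeats are recorded as masked intervals: a transposable
#' element inside the flank (possibly itself lineage-specific) is not
#' alignable sequence, so the query-coverage rule is applied to the
#' unmasked part of each flank.
#'
#' @param genome a `genome_assembly`.
#' @param annotation one-row `repeat_annotations` slice.
#' @param flank_len flank length (default 500 bp); flanks are truncated at
#'   scaffold ends and flagged.
#' @param mask_annotations optional `repeat_annotations` of the focal
#'   genome used to mask repeats inside the flanks.
#' @return a `locus_flanks`: list with `element_id`, `family`, `scaffold`,
#'   `start`, `end`, `left_flank`, `right_flank`, `element_seq`,
#'   `left_truncated`, `right_truncated`, and `left_mask`/`right_mask`
#'   (two-column matrices of 0-based flank-local masked intervals).
#'   Flanks are genome forward strand.
#' @export
extract_flanks <- function(genome, annotation, flank_len = 500L,
                           mask_annotations = NULL) {
  seq <- genome$sequences[[annotation$scaffold]]
  if (is.null(seq)) stop("scaffold not in genome: ", annotation$scaffold)
  n <- nchar(seq)
  s <- annotation$start
  e <- annotation$end
  if (s < 0 || e > n) stop("element span outside scaffold")
  ls <- max(0L, s - flank_len)
  re <- min(n, e + flank_len)
  mask_of <- function(lo, hi) {
    if (is.null(mask_annotations) || hi <= lo) {
      return(matrix(integer(), 0L, 2L))
    }
    i <- mask_annotations$scaffold == annotation$scaffold &
      mask_annotations$element_id != annotation$element_id &
      mask_annotations$start < hi & mask_annotations$end > lo
    if (!any(i)) return(matrix(integer(), 0L, 2L))
    cbind(pmax(mask_annotations$start[i], lo) - lo,
          pmin(mask_annotations$end[i], hi) - lo)
  }
  list(element_id = annotation$element_id, family = annotation$family,
       scaffold = annotation$scaffold, start = s, end = e,
       left_flank = seq_slice(seq, ls, s),
       right_flank = seq_slice(seq, e, re),
       element_seq = seq_slice(seq, s, e),
       left_truncated = s - ls < flank_len,
       right_truncated = re - e < flank_len,
       left_mask = mask_of(ls, s),
       right_mask = mask_of(e, re))
}

# bp of [lo, hi) not covered by mask intervals (two-column matrix; the
# intervals may overlap, e.g. a nested element inside its host's span)
unmasked_bp <- function(lo, hi, mask) {
  tot <- hi - lo
  if (tot <= 0L) return(0L)
  if (nrow(mask) == 0L) return(tot)
  m <- cbind(pmax(mask[, 1L], lo), pmin(mask[, 2L], hi))
  m <- m[m[, 2L] > m[, 1L], , drop = FALSE]
  if (nrow(m) == 0L) return(tot)
  m <- m[order(m[, 1L]), , drop = FALSE]
  covered <- 0L
  cur_lo <- m[1L, 1L]
  cur_hi <- m[1L, 2L]
  for (i in seq_len(nrow(m))[-1L]) {
    if (m[i, 1L] <= cur_hi) {
      cur_hi <- max(cur_hi, m[i, 2L])
    } else {
      covered <- covered + (cur_hi - cur_lo)
      cur_lo <- m[i, 1L]
      cur_hi <- m[i, 2L]
    }
  }
  covered <- covered + (cur_hi - cur_lo)
  tot - covered
}

#' Precompute the match structures for a target genome
#'
#' Builds forward and reverse-complement [Biostrings::DNAString] copies of
#' every scaffold once, so that repeated flank mapping against the same
#' target does not re-convert sequences.
#'
#' @param assembly a `genome_assembly`.
#' @return a `genome_index`.
#' @export
genome_index <- function(assembly) {
  fwd <- lapply(assembly$sequences, Biostrings::DNAString)
  rc <- lapply(fwd, Biostrings::reverseComplement)
  structure(list(fwd = fwd, rc = rc,
                 lengths = vapply(assembly$sequences, nchar, integer(1)),
                 species_label = assembly$species_label),
            class = "genome_index")
}

# N-mask the masked intervals of a flank so they contribute no seeds;
# the unmasked original is still used for the gapped extension
mask_query <- function(q, mask) {
  if (nrow(mask) == 0L || nchar(q) == 0L) return(q)
  ch <- seq_chars(q)
  for (i in seq_len(nrow(mask))) {
    lo <- max(0L, mask[i, 1L]) + 1L
    hi <- min(length(ch), mask[i, 2L])
    if (hi >= lo) ch[lo:hi] <- "N"
  }
  paste(ch, collapse = "")
}

# seed table for a set of query sequences: data.frame(query, qpos, seed)
seed_table <- function(queries, k, stride) {
  rows <- lapply(seq_along(queries), function(i) {
    q <- queries[[i]]
    qlen <- nchar(q)
    if (qlen < k) return(NULL)
    starts <- unique(c(seq(1L, qlen - k + 1L, by = stride), qlen - k + 1L))
    s <- substring(q, starts, starts + k - 1L)
    ok <- !grepl("N", s, fixed = TRUE)
    if (!any(ok)) return(NULL)
    data.frame(query = i, qpos = starts[ok], seed = s[ok],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# batch seed matching: one PDict over every seed of every query, one
# matchPDict per scaffold and orientation. Returns per-query hit tables.
batch_seed_hits <- function(queries, index, params) {
  st <- seed_table(queries, params$seed_k, params$seed_stride)
  if (is.null(st) || nrow(st) == 0L) {
    return(rep(list(NULL), length(queries)))
  }
  # deduplicate seed sequences so repetitive seeds are matched (and can be
  # masked) once, not once per query
  useq <- unique(st$seed)
  dict <- Biostrings::PDict(Biostrings::DNAStringSet(useq))
  st$uidx <- match(st$seed, useq)
  hits <- list()
  total_per_seed <- integer(length(useq))
  for (scaf in names(index$fwd)) {
    for (orient in c("+", "-")) {
      subj <- if (orient == "+") index$fwd[[scaf]] else index$rc[[scaf]]
      m <- Biostrings::matchPDict(dict, subj)
      sp <- IRanges::start(m)
      counts <- lengths(sp)
      total_per_seed <- total_per_seed + counts
      if (sum(counts) == 0L) next
      hits[[length(hits) + 1L]] <- data.frame(
        uidx = rep.int(seq_along(useq), counts),
        spos = unlist(sp, use.names = FALSE),
        scaffold = scaf, orient = orient, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(rep(list(NULL), length(queries)))
  seed_hits <- do.call(rbind, hits)
  # mask seeds hitting the target too often: they lie in repeats and only
  # blow up the placement search without localising anything
  keep <- total_per_seed[seed_hits$uidx] <= params$max_seed_hits
  seed_hits <- seed_hits[keep, , drop = FALSE]
  if (nrow(seed_hits) == 0L) return(rep(list(NULL), length(queries)))
  # join back to per-query seed occurrences
  j <- split(seq_len(nrow(seed_hits)), seed_hits$uidx)
  st_use <- st[st$uidx %in% as.integer(names(j)), , drop = FALSE]
  reps <- lengths(j)[as.character(st_use$uidx)]
  qq <- rep.int(st_use$query, reps)
  qp <- rep.int(st_use$qpos, reps)
  hi <- unlist(j[as.character(st_use$uidx)], use.names = FALSE)
  all_hits <- data.frame(query = qq, qpos = qp,
                         spos = seed_hits$spos[hi],
                         scaffold = seed_hits$scaffold[hi],
                         orient = seed_hits$orient[hi],
                         stringsAsFactors = FALSE)
  out <- rep(list(NULL), length(queries))
  by_q <- split(all_hits, all_hits$query)
  for (qname in names(by_q)) {
    out[[as.integer(qname)]] <- by_q[[qname]]
  }
  out
}

# group one query's seed hits into chained placements: hits on the same
# scaffold/orientation whose diagonals lie within chain_gap_max form one
# placement (tolerating indels between lineages); placements are ranked by
# the number of distinct supporting seed positions
chain_placements <- function(hits, params) {
  if (is.null(hits) || nrow(hits) == 0L) return(list())
  hits$diag <- hits$spos - hits$qpos
  placements <- list()
  for (key in unique(paste(hits$scaffold, hits$orient))) {
    h <- hits[paste(hits$scaffold, hits$orient) == key, , drop = FALSE]
    h <- h[order(h$diag), , drop = FALSE]
    brk <- c(0L, which(diff(h$diag) > params$chain_gap_max), nrow(h))
    for (b in seq_len(length(brk) - 1L)) {
      g <- h[(brk[b] + 1L):brk[b + 1L], , drop = FALSE]
      placements[[length(placements) + 1L]] <- list(
        scaffold = g$scaffold[1L], orient = g$orient[1L],
        n_seeds = length(unique(g$qpos)),
        diag_lo = min(g$diag), diag_hi = max(g$diag))
    }
  }
  placements[order(-vapply(placements, `[[`, numeric(1), "n_seeds"))]
}

# gapped extension of one placement; returns identity/coverage and the
# mapped interval in forward-strand 0-based half-open coordinates.
# Gap extension is cheap so that a TE inserted into either lineage's
# flank is bridged; identity is computed over aligned bases only.
extend_placement <- function(flank, pl, index, params) {
  subj <- if (pl$orient == "+") index$fwd[[pl$scaffold]] else
    index$rc[[pl$scaffold]]
  slen <- length(subj)
  qlen <- nchar(flank)
  w0 <- max(0L, as.integer(pl$diag_lo) - 1L - params$window_margin)
  w1 <- min(slen, as.integer(pl$diag_hi) - 1L + qlen + params$window_margin)
  if (w1 - w0 < params$seed_k) return(NULL)
  window <- subj[(w0 + 1L):w1]
  aln <- Biostrings::pairwiseAlignment(
    pattern = flank, subject = window, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1.5, baseOnly = FALSE),
    gapOpening = 6, gapExtension = 0.05)
  prange <- Biostrings::pattern(aln)
  srange <- Biostrings::subject(aln)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  identity <- nm / max(1L, nm + nmm)
  coverage <- (Biostrings::end(prange) - Biostrings::start(prange) + 1L) / qlen
  s0 <- w0 + Biostrings::start(srange) - 1L
  e0 <- w0 + Biostrings::end(srange)
  f0 <- s0
  f1 <- e0
  if (pl$orient == "-") {
    f0 <- slen - e0
    f1 <- slen - s0
  }
  list(scaffold = pl$scaffold, strand = pl$orient, start = f0, end = f1,
       o_start = s0, o_end = e0,
       identity = identity, coverage = coverage, n_seeds = pl$n_seeds,
       q_start = Biostrings::start(prange) - 1L,
       q_end = Biostrings::end(prange))
}

# coverage of a placement over the unmasked part of the query flank
masked_coverage <- function(ext, qlen, mask, params) {
  denom <- unmasked_bp(0L, qlen, mask)
  if (denom < params$min_unmasked) return(NA_real_)
  unmasked_bp(ext$q_start, ext$q_end, mask) / denom
}

# map one query given its seed hits: best passing placement with
# second-best identity attached, or NULL
place_query <- function(flank, hits, index, params,
                        mask = matrix(integer(), 0L, 2L)) {
  pls <- chain_placements(hits, params)
  if (!length(pls)) return(NULL)
  best <- extend_placement(flank, pls[[1L]], index, params)
  if (is.null(best)) return(NULL)
  qlen <- nchar(flank)
  best$coverage <- masked_coverage(best, qlen, mask, params)
  if (is.na(best$coverage)) return(NULL)  # flank almost entirely repeat
  # a competing placement matters only if it could itself pass the
  # coverage rule; stray single-seed hits inside repeats are not paralogs
  best$second_best_identity <- 0
  if (length(pls) > 1L &&
      pls[[2L]]$n_seeds >= 0.5 * pls[[1L]]$n_seeds) {
    second <- extend_placement(flank, pls[[2L]], index, params)
    if (!is.null(second)) {
      second$coverage <- masked_coverage(second, qlen, mask, params)
      if (!is.na(second$coverage) &&
          second$coverage >= params$min_coverage) {
        best$second_best_identity <- second$identity
      }
    }
  }
  if (best$coverage < params$min_coverage ||
      best$identity < params$min_identity) return(NULL)
  best
}

#' Map both flanks of a locus to a target genome
#'
#' Seed-and-extend similarity search (exact `seed_k`-mer seeding, chained
#' diagonal grouping, gapped extension) of each flank against the target.
#' Hits failing the coverage >= `min_coverage` or identity >=
#' `min_identity` rule are discarded. When both flanks survive on the same
#' scaffold and strand, the signed distance between their inner mapped
#' ends is reported as `inter_flank_gap_bp`.
#'
#' @param flanks a `locus_flanks` from [extract_flanks()].
#' @param target a `genome_assembly` or prebuilt [genome_index()].
#' @param params an [ortholog_params()].
#' @return a `flank_mapping`: list with `left`, `right` (best passing hit
#'   or NULL; fields scaffold, strand, start, end, identity, coverage,
#'   second_best_identity), and `inter_flank_gap_bp` (NA unless both
#'   flanks land on one scaffold and strand).
#' @export
map_flanks <- function(flanks, target, params = ortholog_params()) {
  index <- if (inherits(target, "genome_index")) target else {
    if (length(target$sequences) == 0L) stop("empty target genome")
    genome_index(target)
  }
  queries <- c(flanks$left_flank, flanks$right_flank)
  lm <- flanks$left_mask %||% matrix(integer(), 0L, 2L)
  rm <- flanks$right_mask %||% matrix(integer(), 0L, 2L)
  seed_qs <- c(mask_query(queries[1L], lm), mask_query(queries[2L], rm))
  hits <- batch_seed_hits(seed_qs, index, params)
  left <- if (nchar(queries[1L])) place_query(seed_qs[1L], hits[[1L]],
                                              index, params, lm) else NULL
  right <- if (nchar(queries[2L])) place_query(seed_qs[2L], hits[[2L]],
                                               index, params, rm) else NULL
  finish_mapping(left, right, flanks)
}

finish_mapping <- function(left, right, flanks) {
  gap <- NA_integer_
  if (!is.null(left) && !is.null(right) &&
      left$scaffold == right$scaffold && left$strand == right$strand) {
    # in the searched orientation the right flank must follow the left
    gap <- right$o_start - left$o_end
  }
  structure(list(left = left, right = right, inter_flank_gap_bp = gap,
                 element_id = flanks$element_id, family = flanks$family),
            class = "flank_mapping")
}

#' Call presence/absence of an element at the orthologous target locus
#'
#' An element is called `absent` when both flanks map collinearly with an
#' inter-flank gap of at most `empty_gap_max` bp and no same-family
#' annotation lies in the inter-flank span; `present` when both flanks map
#' and a same-family annotation covers at least `present_cover_min` of the
#' span between them. Everything else is `unresolved` with a reason code
#' (flank unmapped, discordant placement, paralogous ambiguity, or a span
#' that fits neither rule).
#'
#' @param mapping a `flank_mapping`.
#' @param target_annotations `repeat_annotations` of the target genome.
#' @param params an [ortholog_params()].
#' @return an `ortholog_call`: list with `status`
#'   (present/absent/unresolved), `reason`, `gap`, `span` (forward-strand
#'   0-based interval between the mapped flanks), and the `mapping`.
#' @export
call_presence <- function(mapping, target_annotations,
                          params = ortholog_params()) {
  res <- function(status, reason, span = NULL) {
    structure(list(status = status, reason = reason,
                   gap = mapping$inter_flank_gap_bp, span = span,
                   element_id = mapping$element_id,
                   family = mapping$family, mapping = mapping),
              class = "ortholog_call")
  }
  l <- mapping$left
  r <- mapping$right
  if (is.null(l) && is.null(r)) return(res("unresolved", "no_flank_mapped"))
  if (is.null(l) || is.null(r)) return(res("unresolved", "one_flank_mapped"))
  if (l$scaffold != r$scaffold || l$strand != r$strand) {
    return(res("unresolved", "discordant"))
  }
  if (max(l$second_best_identity, r$second_best_identity) >
      min(l$identity, r$identity) - params$paralog_margin) {
    return(res("unresolved", "paralog_ambiguity"))
  }
  gap <- mapping$inter_flank_gap_bp
  if (is.na(gap) || gap < params$empty_gap_min) {
    return(res("unresolved", "disordered_flanks"))
  }
  # forward-strand span between the inner mapped ends
  span <- if (l$strand == "+") c(l$end, r$start) else c(r$end, l$start)
  span <- c(min(span), max(span))
  # only same-family elements contained in the span (with slack for
  # boundary imprecision) testify to presence; an adjacent element merely
  # crossing a tiny span does not
  contained <- contained_family_bp(target_annotations, l$scaffold, span,
                                   mapping$family, slack = 20L)
  if (gap <= params$empty_gap_max) {
    if (contained == 0) return(res("absent", "empty_site", span))
    return(res("unresolved", "annotation_in_small_gap", span))
  }
  if (contained >= params$present_cover_min * (span[2L] - span[1L])) {
    return(res("present", "filled_site", span))
  }
  # a larger gap fully accounted for by the target lineage's own annotated
  # insertions of OTHER families is still an empty site for this element;
  # any same-family sequence in the span vetoes this
  overlap_same <- overlapping_any_bp(
    target_annotations[target_annotations$family == mapping$family, ,
                       drop = FALSE], l$scaffold, span)
  if (contained == 0 && overlap_same == 0) {
    any_bp <- overlapping_any_bp(target_annotations, l$scaffold, span)
    if (gap - any_bp <= params$empty_gap_max) {
      return(res("absent", "empty_site_with_target_insertion", span))
    }
  }
  res("unresolved", "large_gap_without_annotation", span)
}

# bp of same-family elements contained in [span) (slack bp of overhang
# tolerated) on a scaffold
contained_family_bp <- function(annotations, scaffold, span, family,
                                slack = 20L) {
  if (nrow(annotations) == 0L || span[2L] <= span[1L]) return(0)
  i <- annotations$scaffold == scaffold & annotations$family == family &
    annotations$start >= span[1L] - slack & annotations$end <= span[2L] + slack
  if (!any(i)) return(0)
  sum(pmin(annotations$end[i], span[2L]) -
        pmax(annotations$start[i], span[1L]))
}

# bp of any annotated element overlapping [span) on a scaffold
overlapping_any_bp <- function(annotations, scaffold, span) {
  if (nrow(annotations) == 0L || span[2L] <= span[1L]) return(0)
  i <- annotations$scaffold == scaffold &
    annotations$start < span[2L] & annotations$end > span[1L]
  if (!any(i)) return(0)
  sum(pmin(annotations$end[i], span[2L]) -
        pmax(annotations$start[i], span[1L]))
}

#' Identify lineage-specific insertions from per-species ortholog calls
#'
#' A locus is lineage-specific when it is called `absent` in every
#' non-focal species. Loci with any `unresolved` call are excluded from
#' the specific set and reported separately, a conservative rule that
#' keeps polymorphic or ambiguous loci out of the candidate list.
#'
#' @param calls_by_species named list (one entry per non-focal species) of
#'   data.frames with columns `element_id` and `status` (such as the
#'   `calls` component of [ortholog_screen()]).
#' @param focal_species name of the focal species (must not appear in
#'   `calls_by_species`).
#' @return list with `specific` (element ids absent everywhere),
#'   `ambiguous` (ids with >= 1 unresolved call), `shared` (ids present
#'   somewhere and never unresolved), and `report` (long data.frame of all
#'   calls).
#' @export
find_lineage_specific <- function(calls_by_species, focal_species) {
  if (length(calls_by_species) == 0L) stop("no target species calls")
  if (is.null(names(calls_by_species)) ||
      any(names(calls_by_species) == "")) {
    stop("calls_by_species must be a named list")
  }
  if (focal_species %in% names(calls_by_species)) {
    stop("focal species must not be among the targets")
  }
  report <- do.call(rbind, lapply(names(calls_by_species), function(sp) {
    df <- calls_by_species[[sp]]
    data.frame(species = sp, element_id = df$element_id,
               status = df$status, stringsAsFactors = FALSE)
  }))
  ids <- unique(report$element_id)
  n_targets <- length(calls_by_species)
  status_by_id <- split(report$status, factor(report$element_id,
                                              levels = ids))
  cls <- vapply(ids, function(id) {
    st <- status_by_id[[as.character(id)]]
    if (length(st) < n_targets || any(st == "unresolved")) {
      return("ambiguous")
    }
    if (all(st == "absent")) return("specific")
    "shared"
  }, character(1))
  list(specific = ids[cls == "specific"],
       ambiguous = ids[cls == "ambiguous"],
       shared = ids[cls == "shared"],
       report = report)
}

#' Screen candidate elements for lineage-specific insertions
#'
#' End-to-end presence/absence screen: extracts flanks for every candidate
#' element in the focal genome, maps them against each target genome
#' (seeding is batched over all candidate flanks for speed), calls
#' presence/absence at the orthologous locus, and classifies candidates
#' with [find_lineage_specific()].
#'
#' @param focal_genome `genome_assembly` of the focal species.
#' @param candidates `repeat_annotations` of candidate elements in the
#'   focal genome (typically the output of [select_young_elements()]).
#' @param targets named list, one entry per target species, each a list
#'   with `genome` (`genome_assembly` or `genome_index`) and `annotations`
#'   (`repeat_annotations`).
#' @param params an [ortholog_params()].
#' @return list with `specific`, `ambiguous`, `shared` (element id
#'   vectors), `calls` (named list of per-species call data.frames with
#'   columns element_id, status, reason, gap), and `report`.
#' @export
ortholog_screen <- function(focal_genome, candidates, targets,
                            params = ortholog_params(),
                            focal_annotations = candidates) {
  if (length(targets) == 0L) stop("no target genomes")
  n <- nrow(candidates)
  flanks <- lapply(seq_len(n), function(i) {
    extract_flanks(focal_genome, candidates[i, ],
                   flank_len = params$flank_len,
                   mask_annotations = focal_annotations)
  })
  queries <- unlist(lapply(flanks, function(f) {
    c(f$left_flank, f$right_flank)
  }))
  seed_qs <- unlist(lapply(flanks, function(f) {
    c(mask_query(f$left_flank, f$left_mask),
      mask_query(f$right_flank, f$right_mask))
  }))
  calls <- lapply(names(targets), function(sp) {
    index <- if (inherits(targets[[sp]]$genome, "genome_index")) {
      targets[[sp]]$genome
    } else {
      genome_index(targets[[sp]]$genome)
    }
    hits <- batch_seed_hits(seed_qs, index, params)
    rows <- lapply(seq_len(n), function(i) {
      left <- if (nchar(queries[2 * i - 1L])) {
        place_query(seed_qs[2 * i - 1L], hits[[2 * i - 1L]], index, params,
                    flanks[[i]]$left_mask)
      }
      right <- if (nchar(queries[2 * i])) {
        place_query(seed_qs[2 * i], hits[[2 * i]], index, params,
                    flanks[[i]]$right_mask)
      }
      mp <- finish_mapping(left, right, flanks[[i]])
      cl <- call_presence(mp, targets[[sp]]$annotations, params)
      data.frame(element_id = cl$element_id, status = cl$status,
                 reason = cl$reason,
                 gap = if (is.null(cl$gap)) NA_integer_ else cl$gap,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(calls) <- names(targets)
  out <- find_lineage_specific(calls, focal_species = "focal")
  out$calls <- calls
  out
}
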