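#' Two-rate substitution model over a time interval
#'
#' Applies the CpG-aware substitution model used throughout the package:
#' every site is substituted independently with probability `1 - exp(-r * t)`
#' where `r` is `cpg_rate` if the site is part of a CG dinucleotide of the
#' input sequence (both the C and the G), and `background_rate` otherwise.
#' The substituted base is drawn uniformly from the three alternatives.
#' Length is always preserved. CpG status is assessed once, on the sequence
#' at the start of the interval.
#'
#' Uses the current RNG stream; call `set.seed()` for reproducibility.
#'
#' @param seq DNA string (A/C/G/T/N; N sites are never mutated).
#' @param duration_My elapsed time in million years (>= 0).
#' @param background_rate substitutions/site/My at non-CpG sites
#'   (default 0.0013, a typical neutral rate for these genomes).
#' @param cpg_rate substitutions/site/My at CpG sites (default 0.0104).
#' @return the mutated DNA string, same length as the input.
#' @export
mutate_sequence <- function(seq, duration_My, background_rate = 0.0013,
                            cpg_rate = 0.0104) {
  if (duration_My < 0) stop("duration_My must be >= 0")
  if (background_rate < 0 || cpg_rate < 0) stop("rates must be >= 0")
  paste(mutate_chars(seq_chars(seq), duration_My, background_rate, cpg_rate),
        collapse = "")
}

# vectorised core on a character vector of bases
mutate_chars <- function(chars, duration_My, background_rate, cpg_rate) {
  n <- length(chars)
  if (n == 0L || duration_My == 0) return(chars)
  is_cpg <- cpg_mask(chars)
  p <- ifelse(is_cpg, 1 - exp(-cpg_rate * duration_My),
              1 - exp(-background_rate * duration_My))
  hit <- which(runif(n) < p & chars != "N")
  if (length(hit)) {
    # uniform over the three non-current bases
    cur <- match(chars[hit], DNA_BASES)
    off <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- DNA_BASES[((cur - 1L + off) %% 4L) + 1L]
  }
  chars
}

#' Plant a SINE insertion with a target site duplication
#'
#' Inserts `element_seq` at `site` (0-based, between-bases position) of
#' `scaffold_seq` and duplicates the `tsd_len` bases immediately 5' of the
#' site after the element, emulating target-primed reverse transcription:
#' `prefix + element + TSD + suffix`, where the prefix already ends with the
#' TSD sequence. The result is `len(element) + tsd_len` bp longer.
#'
#' @param scaffold_seq DNA string.
#' @param site 0-based insertion point in `[0, nchar(scaffold_seq)]`.
#' @param element_seq DNA string of the inserted element.
#' @param tsd_len requested TSD length; if `site < tsd_len` the TSD shrinks
#'   to the available bases and the result is flagged.
#' @return list with `sequence` (the new scaffold), `tsd` (the duplicated
#'   sequence actually used), and `shrunk` (TRUE when the TSD was shortened
#'   at a scaffold edge).
#' @export
plant_insertion <- function(scaffold_seq, site, element_seq, tsd_len) {
  n <- nchar(scaffold_seq)
  if (site < 0 || site > n) stop("site outside scaffold")
  if (tsd_len < 0) stop("tsd_len must be >= 0")
  shrunk <- site < tsd_len
  t <- min(site, tsd_len)
  tsd <- if (t > 0) substr(scaffold_seq, site - t + 1L, site) else ""
  list(
    sequence = paste0(substr(scaffold_seq, 1L, site), element_seq, tsd,
                      substr(scaffold_seq, site + 1L, n)),
    tsd = tsd,
    shrunk = shrunk)
}

#' Build a Can-SINE-like source sequence
#'
#' Constructs a synthetic master-element sequence with the canonical
#' Can-SINE layout: a tRNA-derived head, a (CT)n microsatellite, and the
#' AATAAA polyadenylation signal. The poly-A tail itself is appended per
#' insertion (its length varies between copies), so it is not part of the
#' source. Uses the current RNG stream.
#'
#' @param head_len length of the head region in bp (default 165).
#' @param ct_repeats number of CT dinucleotide repeats (default 8).
#' @param gc GC content of the random head.
#' @return DNA string.
#' @export
make_sine_source <- function(head_len = 165, ct_repeats = 8, gc = 0.5) {
  paste0(random_dna(head_len, gc = gc),
         strrep("CT", ct_repeats), "AATAAA")
}

#' Derive a daughter source carrying diagnostic mutations
#'
#' Applies the given substitutions to a source sequence, nudging any
#' position whose substitution would create or destroy a CG dinucleotide
#' when `avoid_cpg` is set, so that the diagnostics are non-CpG sites.
#'
#' @param source DNA string.
#' @param positions 1-based positions to substitute.
#' @param avoid_cpg keep diagnostic sites out of CpG context (default TRUE).
#' @return list with `sequence` and `diagnostics` (data.frame of position,
#'   from, to).
#' @export
derive_source <- function(source, positions, avoid_cpg = TRUE) {
  chars <- seq_chars(source)
  mask <- cpg_mask(chars)
  diag <- data.frame(position = integer(), from = character(),
                     to = character(), stringsAsFactors = FALSE)
  for (p in positions) {
    if (avoid_cpg) {
      while (p < length(chars) && (mask[p] || chars[p + 1L] == "G" ||
                                   chars[p - 1L] == "C")) {
        p <- p + 1L
      }
    }
    from <- chars[p]
    # transversion that cannot create a CG with either neighbour
    to <- setdiff(DNA_BASES, c(from, "C", "G"))[1L]
    chars[p] <- to
    diag <- rbind(diag, data.frame(position = p, from = from, to = to,
                                   stringsAsFactors = FALSE))
  }
  list(sequence = paste(chars, collapse = ""), diagnostics = diag)
}

#' Default four-taxon Caniformia-style species tree
#'
#' Rooted ultrametric tree with split times in million years: the dog
#' lineage branches at the root, then the ferret (mustelid) lineage, and
#' the panda / polar bear split is the most recent, matching the
#' panda-polar bear divergence calibration of 15.5 My used for dating.
#'
#' @param bear_split panda/polar-bear split time (My, default 15.5).
#' @param arctoid_split bears/mustelids split (My, default 40).
#' @param root_age dog split / root age (My, default 45).
#' @return nested-list tree usable as `sim_config()$tree`.
#' @export
caniform_tree <- function(bear_split = 15.5, arctoid_split = 40, root_age = 45) {
  list(age = root_age, label = "root", children = list(
    list(age = 0, label = "dog"),
    list(age = arctoid_split, label = "arctoidea", children = list(
      list(age = 0, label = "ferret"),
      list(age = bear_split, label = "bears", children = list(
        list(age = 0, label = "panda"),
        list(age = 0, label = "polar_bear")))))))
}

#' Convert an ultrametric ape tree to the simulator's nested-list form
#'
#' @param phy an [ape::phylo] ultrametric rooted tree with branch lengths
#'   in My, or a newick string.
#' @return nested-list tree (nodes carry `age` = time before present of the
#'   split, leaves have age 0 and `label` = tip label).
#' @export
tree_from_phylo <- function(phy) {
  if (is.character(phy)) phy <- ape::read.tree(text = phy)
  depths <- ape::node.depth.edgelength(phy)
  height <- max(depths)
  ntip <- length(phy$tip.label)
  build <- function(node) {
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (length(kids) == 0L) {
      return(list(age = 0, label = phy$tip.label[node]))
    }
    list(age = height - depths[node],
         label = if (node == ntip + 1L) "root" else paste0("node", node),
         children = lapply(kids, build))
  }
  build(ntip + 1L)
}

#' Per-subfamily simulation settings
#'
#' @param name subfamily name used in annotations and truth records.
#' @param source source (master) sequence copies are retrotransposed from.
#' @param window activity window `c(oldest, youngest)` in My before present.
#' @param rate insertion rate, insertions per My per lineage while active.
#' @param tsd_range TSD length range, uniform over `tsd_range[1]:tsd_range[2]`
#'   (default 8-15 bp, the typical Can-SINE TSD size).
#' @param polya_range poly-A tail length range appended to each copy.
#' @param trunc_prob probability a copy is 5'-truncated (uniform 0-50% of
#'   the source removed).
#' @param nesting may copies of this subfamily insert into earlier elements?
#' @param branches optional character vector of branch labels (a branch is
#'   labelled by its child node) on which the subfamily is active; NULL
#'   means every branch overlapping the time window.
#' @param class repeat class string used in annotations.
#' @return list of class `subfamily_config`.
#' @export
subfamily_config <- function(name, source, window, rate,
                             tsd_range = c(8L, 15L),
                             polya_range = c(8L, 30L),
                             trunc_prob = 0.05, nesting = TRUE,
                             branches = NULL,
                             class = "SINE/tRNA-Can") {
  stopifnot(rate >= 0, window[1] >= window[2],
            tsd_range[1] >= 1, tsd_range[2] >= tsd_range[1])
  structure(list(name = name, source = toupper(source), window = window,
                 rate = rate, tsd_range = as.integer(tsd_range),
                 polya_range = as.integer(polya_range),
                 trunc_prob = trunc_prob, nesting = nesting,
                 branches = branches, class = class),
            class = "subfamily_config")
}

#' Simulation configuration
#'
#' Assembles the full configuration for [simulate_caniform_genomes()]. When
#' `subfamilies` is NULL a default three-subfamily scenario is built from
#' the seed: an older broadly active subfamily, a second independent older
#' subfamily, and a young subfamily derived from the first by four non-CpG
#' diagnostic substitutions that is still active at present — the situation
#' the downstream subfamily-discovery and presence/absence stages are
#' designed to resolve.
#'
#' @param seed integer RNG seed; all simulator randomness derives from it.
#' @param genome_length ancestral genome length in bp (default 2e6).
#' @param tree nested-list species tree (default [caniform_tree()]).
#' @param background_rate,cpg_rate substitution rates per site per My
#'   (defaults 0.0013 and 0.0104).
#' @param gc GC content of the ancestral genome.
#' @param subfamilies list of [subfamily_config()] objects, or NULL for the
#'   default scenario.
#' @param scaffold_name scaffold id used for every species.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 2e6, tree = caniform_tree(),
                       background_rate = 0.0013, cpg_rate = 0.0104,
                       gc = 0.41, subfamilies = NULL,
                       scaffold_name = "scaffold_1") {
  if (genome_length <= 0) stop("genome_length must be positive")
  if (background_rate <= 0 || cpg_rate <= 0) stop("rates must be positive")
  if (is.null(subfamilies)) {
    set.seed(as.integer(seed) + 7L)  # sources fixed given the seed
    src_a <- make_sine_source()
    src_b <- make_sine_source(head_len = 180, ct_repeats = 10)
    drv <- derive_source(src_a, positions = c(30L, 62L, 95L, 130L))
    subfamilies <- list(
      subfamily_config("SINEC_simA", src_a, window = c(35, 5), rate = 6),
      subfamily_config("SINEC_simB", src_b, window = c(45, 12), rate = 4),
      subfamily_config("SINEC_simA2", drv$sequence, window = c(15.5, 0),
                       rate = 20))
    attr(subfamilies, "diagnostics") <- drv$diagnostics
  }
  names(subfamilies) <- vapply(subfamilies, `[[`, "", "name")
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 tree = tree, background_rate = background_rate,
                 cpg_rate = cpg_rate, gc = gc, subfamilies = subfamilies,
                 scaffold_name = scaffold_name),
            class = "sim_config")
}

# leaves below a tree node
tree_leaves <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, tree_leaves))
}

#' Simulate multi-species genomes with planted SINE insertions
#'
#' Evolves a random ancestral genome down the species tree. On each branch
#' the genome first accumulates substitutions under the two-rate CpG model
#' for the branch duration, then insertions are drawn as a Poisson process
#' from each subfamily's activity window: a copy of the subfamily source
#' (possibly 5'-truncated) plus a sampled poly-A tail is planted at a
#' uniform site with a sampled 8-15 bp TSD, and the copy itself is aged from
#' its insertion time to the end of the branch. Insertions may nest inside
#' earlier elements (fragmenting them) but never interrupt a recorded TSD.
#' Every insertion is recorded in a ground-truth table.
#'
#' @param config a [sim_config()].
#' @return list with
#'   * `assemblies`: named list of `genome_assembly`, one per species;
#'   * `annotations`: named list of `repeat_annotations` (truth-derived,
#'     divergence = true percent mismatch of each element against the copy
#'     that was inserted);
#'   * `truth`: list with `insertions` (one row per insertion event:
#'     id, subfamily, branch, time_My, species carrying it, tsd, flags) and
#'     `loci` (per species: id, scaffold, start, end in leaf coordinates),
#'     and `activity` (per branch x subfamily insertion counts);
#'   * `config`: the configuration used.
#' @export
simulate_caniform_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  reg <- new.env(parent = emptyenv())
  reg$records <- list()
  reg$next_id <- 1L
  reg$leaf_out <- list()
  reg$activity <- list()

  ancestral <- seq_chars(random_dna(config$genome_length, gc = config$gc))
  state <- list(
    chars = ancestral,
    frags = data.frame(elem = integer(), start = numeric(), end = numeric(),
                       cs = numeric(), ce = numeric(), strand = character(),
                       stringsAsFactors = FALSE),
    prot = data.frame(start = numeric(), end = numeric()))

  sim_branch <- function(state, t_top, node) {
    duration <- t_top - node$age
    if (duration < 0) stop("tree ages must decrease towards the tips")
    state$chars <- mutate_chars(state$chars, duration,
                                config$background_rate, config$cpg_rate)
    leaves_below <- tree_leaves(node)
    events <- sample_branch_events(config, t_top, node$age, node$label)
    if (nrow(events)) {
      for (k in seq_len(nrow(events))) {
        state <- plant_event(state, config, reg,
                             subfam = events$subfamily[k],
                             time_My = events$time[k],
                             branch_end = node$age,
                             branch = node$label,
                             species = leaves_below)
      }
      tab <- table(events$subfamily)
      reg$activity[[length(reg$activity) + 1L]] <- data.frame(
        branch = node$label, subfamily = names(tab),
        n_insertions = as.integer(tab), stringsAsFactors = FALSE)
    }
    if (is.null(node$children)) {
      reg$leaf_out[[node$label]] <- state
    } else {
      for (child in node$children) sim_branch(state, node$age, child)
    }
    invisible(NULL)
  }

  root <- config$tree
  for (child in root$children) sim_branch(state, root$age, child)

  emit_simulation(config, reg)
}

# Poisson insertion events on one branch, oldest first
sample_branch_events <- function(config, t_top, t_bottom, branch = NULL) {
  out <- list()
  for (sf in config$subfamilies) {
    if (!is.null(sf$branches) && !is.null(branch) &&
        !branch %in% sf$branches) next
    old <- min(t_top, sf$window[1])
    young <- max(t_bottom, sf$window[2])
    d <- old - young
    if (d <= 0 || sf$rate == 0) next
    n <- rpois(1L, sf$rate * d)
    if (n == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      subfamily = sf$name, time = runif(n, young, old),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(subfamily = character(), time = numeric()))
  }
  ev <- do.call(rbind, out)
  ev[order(-ev$time), , drop = FALSE]
}

# plant one insertion event into a lineage state
plant_event <- function(state, config, reg, subfam, time_My, branch_end,
                        branch, species) {
  sf <- config$subfamilies[[subfam]]
  n <- length(state$chars)

  # element copy: optional 5' truncation, poly-A tail, random orientation
  trunc_bp <- 0L
  if (runif(1) < sf$trunc_prob) {
    trunc_bp <- as.integer(floor(runif(1, 0, 0.5) * nchar(sf$source)))
  }
  body <- substr(sf$source, trunc_bp + 1L, nchar(sf$source))
  polya <- strrep("A", sample(sf$polya_range[1]:sf$polya_range[2], 1L))
  elem <- paste0(body, polya)
  strand <- if (runif(1) < 0.5) "+" else "-"
  # age the copy from insertion to the end of this branch
  aged <- mutate_chars(seq_chars(elem), time_My - branch_end,
                       config$background_rate, config$cpg_rate)
  inserted <- if (strand == "-") seq_chars(revcomp(paste(aged, collapse = "")))
              else aged
  pristine <- if (strand == "-") seq_chars(revcomp(elem)) else seq_chars(elem)
  m <- length(inserted)

  tsd_len <- sample(sf$tsd_range[1]:sf$tsd_range[2], 1L)
  # choose a site that interrupts no recorded TSD (and no element when the
  # subfamily does not nest); resampling keeps planted TSDs recoverable
  for (try in 1:200) {
    site <- floor(runif(1, tsd_len, n))
    in_prot <- any(state$prot$start < site & site < state$prot$end)
    in_elem <- any(state$frags$start < site & site < state$frags$end)
    if (!in_prot && (sf$nesting || !in_elem)) break
    if (try == 200L) return(state)  # pathologically full genome; skip
  }

  tsd <- paste(state$chars[(site - tsd_len + 1L):site], collapse = "")
  L <- m + tsd_len

  # nesting: the (at most one) fragment strictly containing the site splits
  fr <- state$frags
  nested_into <- NA_integer_
  hit <- which(fr$start < site & site < fr$end)
  if (length(hit) == 1L) {
    h <- fr[hit, ]
    nested_into <- h$elem
    off <- site - h$start
    if (h$strand == "+") {
      left <- data.frame(elem = h$elem, start = h$start, end = site,
                         cs = h$cs, ce = h$cs + off - 1, strand = h$strand)
      right <- data.frame(elem = h$elem, start = site, end = h$end,
                          cs = h$cs + off, ce = h$ce, strand = h$strand)
    } else {
      left <- data.frame(elem = h$elem, start = h$start, end = site,
                         cs = h$ce - off + 1, ce = h$ce, strand = h$strand)
      right <- data.frame(elem = h$elem, start = site, end = h$end,
                          cs = h$cs, ce = h$ce - off, strand = h$strand)
    }
    fr <- rbind(fr[-hit, , drop = FALSE], left, right)
  }
  shift <- fr$start >= site
  fr$start[shift] <- fr$start[shift] + L
  fr$end[fr$end > site] <- fr$end[fr$end > site] + L
  id <- reg$next_id
  fr <- rbind(fr, data.frame(elem = id, start = site, end = site + m,
                             cs = trunc_bp + 1, ce = trunc_bp + m,
                             strand = strand))
  state$frags <- fr

  pr <- state$prot
  pr$start[pr$start >= site] <- pr$start[pr$start >= site] + L
  pr$end[pr$end > site] <- pr$end[pr$end > site] + L
  state$prot <- rbind(pr,
    data.frame(start = site - tsd_len, end = site),
    data.frame(start = site + m, end = site + m + tsd_len))

  state$chars <- c(state$chars[seq_len(site)], inserted,
                   state$chars[(site - tsd_len + 1L):site],
                   if (site < n) state$chars[(site + 1L):n])

  reg$next_id <- id + 1L
  reg$records[[id]] <- list(
    id = id, subfamily = sf$name, class = sf$class, branch = branch,
    species = species, time_My = time_My, tsd = tsd, tsd_len = tsd_len,
    truncated = trunc_bp > 0L, trunc_bp = trunc_bp, strand = strand,
    nested_into = nested_into, pristine = pristine)
  state
}

# assemble leaf outputs: assemblies, truth-derived annotations, truth tables
emit_simulation <- function(config, reg) {
  species <- names(reg$leaf_out)
  assemblies <- list()
  annotations <- list()
  loci <- list()
  for (sp in species) {
    st <- reg$leaf_out[[sp]]
    seqs <- stats::setNames(paste(st$chars, collapse = ""),
                            config$scaffold_name)
    assemblies[[sp]] <- genome_assembly(seqs, species_label = sp)
    fr <- st$frags
    rows <- lapply(split(seq_len(nrow(fr)), fr$elem), function(idx) {
      f <- fr[idx, , drop = FALSE]
      f <- f[order(f$start), , drop = FALSE]
      rec <- reg$records[[f$elem[1L]]]
      cur <- st$chars[unlist(mapply(function(s, e) (s + 1L):e,
                                    f$start, f$end, SIMPLIFY = FALSE))]
      div <- 100 * mean(cur != rec$pristine)
      df <- data.frame(
        scaffold = config$scaffold_name, start = as.integer(min(f$start)),
        end = as.integer(max(f$end)), strand = rec$strand,
        family = rec$subfamily,
        class = rec$class, divergence_pct = div, deletion_pct = 0,
        insertion_pct = 0, consensus_start = as.integer(min(f$cs)),
        consensus_end = as.integer(max(f$ce)), consensus_left = 0L,
        element_id = rec$id, stringsAsFactors = FALSE)
      df$fragments <- list(data.frame(
        start = as.integer(f$start), end = as.integer(f$end),
        consensus_start = as.integer(f$cs),
        consensus_end = as.integer(f$ce), consensus_left = 0L,
        stringsAsFactors = FALSE))
      df
    })
    ann <- if (length(rows)) do.call(rbind, rows) else empty_annotations()
    ann <- ann[order(ann$start), , drop = FALSE]
    rownames(ann) <- NULL
    annotations[[sp]] <- repeat_annotations(ann)
    if (nrow(fr)) {
      spans <- do.call(rbind, lapply(split(fr, fr$elem), function(f) {
        data.frame(id = f$elem[1L], start = min(f$start), end = max(f$end))
      }))
      loci[[sp]] <- data.frame(species = sp, id = spans$id,
                               scaffold = config$scaffold_name,
                               start = as.integer(spans$start),
                               end = as.integer(spans$end),
                               stringsAsFactors = FALSE)
    }
  }
  recs <- reg$records
  insertions <- do.call(rbind, lapply(recs, function(r) data.frame(
    id = r$id, subfamily = r$subfamily, branch = r$branch,
    species = paste(r$species, collapse = ","), time_My = r$time_My,
    tsd = r$tsd, tsd_len = r$tsd_len, truncated = r$truncated,
    trunc_bp = r$trunc_bp, strand = r$strand,
    nested_into = r$nested_into, stringsAsFactors = FALSE)))
  if (is.null(insertions)) {
    insertions <- data.frame(id = integer(), subfamily = character(),
                             branch = character(), species = character(),
                             time_My = numeric(), tsd = character(),
                             tsd_len = integer(), truncated = logical(),
                             trunc_bp = integer(), strand = character(),
                             nested_into = integer(),
                             stringsAsFactors = FALSE)
  }
  rownames(insertions) <- NULL
  activity <- if (length(reg$activity)) do.call(rbind, reg$activity) else
    data.frame(branch = character(), subfamily = character(),
               n_insertions = integer(), stringsAsFactors = FALSE)
  rownames(activity) <- NULL
  lt <- if (length(loci)) do.call(rbind, loci) else
    data.frame(species = character(), id = integer(), scaffold = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  rownames(lt) <- NULL
  list(assemblies = assemblies, annotations = annotations,
       truth = list(insertions = insertions, loci = lt, activity = activity),
       config = config)
}
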