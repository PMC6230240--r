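#' Build the element-by-column mutation matrix against a template
#'
#' Globally aligns every element to the template consensus and records, for
#' each template column, the observed state in `{A,C,G,T,-,N}`. Insertions
#' relative to the template are dropped; deletions are recorded as `-`.
#' Elements whose alignment covers fewer than `min_cover` of the template
#' columns (heavily truncated or deleted copies) are excluded with a
#' warning, mirroring the practice of removing truncated elements before
#' subfamily analysis.
#'
#' @param elements named character vector of element sequences, pre-oriented
#'   to the template strand.
#' @param template_consensus template DNA string.
#' @param min_cover minimum fraction of template columns covered by
#'   non-gap element bases (default 0.5).
#' @param scoring alignment scoring, see [align_to_consensus()].
#' @return a `mutation_matrix`: list with `states` (character matrix,
#'   elements x template columns), `template` (character vector of template
#'   bases), `cpg` (per-column CpG flag of the template), `excluded`
#'   (names of dropped elements).
#' @export
build_mutation_matrix <- function(elements, template_consensus,
                                  min_cover = 0.5,
                                  scoring = list(match = 1, mismatch = -1,
                                                 gap_open = -4,
                                                 gap_extend = -1)) {
  if (nchar(template_consensus) == 0L) stop("empty template")
  if (is.null(names(elements))) names(elements) <- as.character(seq_along(elements))
  tchars <- seq_chars(toupper(template_consensus))
  L <- length(tchars)
  rows <- list()
  excluded <- character()
  for (id in names(elements)) {
    aln <- align_to_consensus(elements[[id]], template_consensus,
                              scoring = scoring, element_id = id)
    e <- seq_chars(aln$aligned_element)
    c <- seq_chars(aln$aligned_consensus)
    keep <- c != "-"           # template frame; insertions dropped
    row <- e[keep]
    if (sum(row != "-") < min_cover * L) {
      excluded <- c(excluded, id)
      next
    }
    rows[[id]] <- row
  }
  if (length(excluded)) {
    warning(length(excluded), " element(s) excluded: alignment covers <",
            round(100 * min_cover), "% of template columns")
  }
  states <- do.call(rbind, rows)
  if (is.null(states)) states <- matrix(character(), 0L, L)
  structure(list(states = states, template = tchars,
                 cpg = cpg_mask(tchars), excluded = excluded),
            class = "mutation_matrix")
}

#' Majority-rule consensus of a set of matrix rows
#'
#' Per column, the most frequent non-N state among the members; a majority
#' of `-` yields a deletion in the consensus. Ties break by the fixed state
#' order A < C < G < T < -.
#'
#' @param members row names (element ids) to use.
#' @param matrix a `mutation_matrix`.
#' @return character vector of per-column consensus states (template frame,
#'   may contain `-`).
#' @export
refine_consensus <- function(members, matrix) {
  stopifnot(length(members) >= 1L)
  sub <- matrix$states[members, , drop = FALSE]
  order_states <- c("A", "C", "G", "T", "-")
  apply(sub, 2L, function(col) {
    col <- col[col != "N"]
    if (!length(col)) return("N")
    tab <- table(factor(col, levels = order_states))
    order_states[which.max(tab)]   # which.max takes the first maximum
  })
}

# candidate diagnostic assertions: (column, state) with the state differing
# from the reference consensus and carried by >= min_size members
candidate_assertions <- function(states, consensus, cpg, min_size,
                                 exclude_cpg, allow_gap = FALSE) {
  out <- list()
  for (j in seq_len(ncol(states))) {
    if (exclude_cpg && cpg[j]) next
    col <- states[, j]
    for (s in setdiff(unique(col), c(consensus[j], "N"))) {
      if (!allow_gap && s == "-") next
      if (sum(col == s) >= min_size) {
        out[[length(out) + 1L]] <- list(column = j, state = s)
      }
    }
  }
  out
}

#' Discover subfamilies from significantly co-segregating mutations
#'
#' Recursive co-segregation splitting in the style of the COSEG program.
#' Within the current subfamily, every pair of candidate diagnostic
#' assertions (a non-consensus substitution state carried by at least
#' `min_size` members; CpG columns skipped when `exclude_cpg`) is tested
#' for association with a two-sided Fisher exact test on the 2x2 carrier
#' table. If the most significant pair survives a Bonferroni-corrected
#' `alpha`, the members carrying both states seed a child subfamily; both
#' consensuses are rebuilt by majority rule, every member is reassigned to
#' the nearest consensus (Hamming distance, ties to the larger subfamily),
#' and splitting recurses into both groups until no significant pair
#' remains.
#'
#' @param matrix a `mutation_matrix`.
#' @param min_size minimum subfamily size (default 10).
#' @param exclude_cpg skip CpG template columns when proposing diagnostics.
#' @param alpha family-wise significance level (default 1e-3), Bonferroni
#'   corrected over the pairs tested at each split.
#' @param allow_gap_diagnostics may `-` states be diagnostic (default
#'   FALSE; deletions are weak evidence of shared descent).
#' @return list of subfamilies, largest first. Each is a list with
#'   `members` (element ids), `size`, `consensus` (DNA string, deletions
#'   removed), `consensus_aligned` (template frame), and `diagnostics`
#'   (data.frame column/state of consensus differences from the template).
#' @export
detect_subfamilies <- function(matrix, min_size = 10L, exclude_cpg = FALSE,
                               alpha = 1e-3, allow_gap_diagnostics = FALSE) {
  stopifnot(min_size >= 2L)
  states <- matrix$states
  n <- nrow(states)
  ids <- rownames(states)
  if (n < min_size || n < 2L) {
    return(list(make_subfamily(ids, matrix)))
  }

  split_group <- function(members) {
    sub <- states[members, , drop = FALSE]
    cons <- refine_consensus(members, matrix)
    cand <- candidate_assertions(sub, cons, matrix$cpg, min_size,
                                 exclude_cpg, allow_gap_diagnostics)
    if (length(cand) < 2L) return(list(members))
    carriers <- lapply(cand, function(a) sub[, a$column] == a$state)
    pairs <- utils::combn(length(cand), 2L)
    # drop pairs on the same column (states are mutually exclusive there)
    same_col <- vapply(seq_len(ncol(pairs)), function(k) {
      cand[[pairs[1L, k]]]$column == cand[[pairs[2L, k]]]$column
    }, logical(1))
    pairs <- pairs[, !same_col, drop = FALSE]
    if (ncol(pairs) == 0L) return(list(members))
    pv <- vapply(seq_len(ncol(pairs)), function(k) {
      a <- carriers[[pairs[1L, k]]]
      b <- carriers[[pairs[2L, k]]]
      tab <- table(factor(a, c(FALSE, TRUE)), factor(b, c(FALSE, TRUE)))
      fisher.test(tab, alternative = "two.sided")$p.value
    }, numeric(1))
    # only positively associated pairs can seed a child: two diagnostic
    # states that co-occur MORE than expected descend from one source;
    # a significant negative association means the states mark the two
    # complementary groups and their carrier intersection is empty
    pos <- vapply(seq_len(ncol(pairs)), function(k) {
      a <- carriers[[pairs[1L, k]]]
      b <- carriers[[pairs[2L, k]]]
      sum(a & b) * length(a) > sum(a) * sum(b)
    }, logical(1))
    if (!any(pos)) return(list(members))
    pv[!pos] <- Inf
    best <- which.min(pv)
    if (pv[best] >= alpha / ncol(pairs)) return(list(members))
    a <- carriers[[pairs[1L, best]]]
    b <- carriers[[pairs[2L, best]]]
    child <- members[a & b]
    rest <- setdiff(members, child)
    if (length(child) < min_size || length(rest) < min_size) {
      return(list(members))
    }
    # consensus refinement + nearest-consensus reassignment
    for (it in 1:5) {
      cons_child <- refine_consensus(child, matrix)
      cons_rest <- refine_consensus(rest, matrix)
      d_child <- apply(states[members, , drop = FALSE], 1L,
                       function(r) sum(r != cons_child))
      d_rest <- apply(states[members, , drop = FALSE], 1L,
                      function(r) sum(r != cons_rest))
      bigger_child <- length(child) >= length(rest)
      to_child <- if (bigger_child) d_child <= d_rest else d_child < d_rest
      new_child <- members[to_child]
      if (setequal(new_child, child)) break
      child <- new_child
      rest <- setdiff(members, child)
      if (length(child) < min_size || length(rest) < min_size) {
        return(list(members))
      }
    }
    c(split_group(child), split_group(rest))
  }

  groups <- split_group(ids)
  subs <- lapply(groups, make_subfamily, matrix = matrix)
  subs[order(-vapply(subs, `[[`, numeric(1), "size"))]
}

make_subfamily <- function(members, matrix) {
  cons <- refine_consensus(members, matrix)
  diff <- which(cons != matrix$template & cons != "N")
  list(members = members, size = length(members),
       consensus = paste(cons[cons != "-"], collapse = ""),
       consensus_aligned = paste(cons, collapse = ""),
       diagnostics = data.frame(column = diff, state = cons[diff],
                                row.names = NULL,
                                stringsAsFactors = FALSE))
}

# ---- median-joining network ------------------------------------------------

# pairwise Hamming distances between rows of a state matrix
row_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# epsilon-relaxed minimum spanning network: an edge of weight w is kept if
# its endpoints are not already connected by edges of weight < w - epsilon
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) return(matrix(integer(), 0L, 3L))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w)
  comp_at <- function(maxw) {
    g <- igraph::graph_from_edgelist(
      pairs[w <= maxw, , drop = FALSE], directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    igraph::components(g)$membership
  }
  keep <- logical(length(w))
  for (k in ord) {
    memb <- comp_at(w[k] - 1 - epsilon)
    keep[k] <- memb[pairs[k, 1L]] != memb[pairs[k, 2L]]
  }
  cbind(pairs[keep, , drop = FALSE], w[keep])
}

# total MST length over a distance matrix
mst_length <- function(d) {
  n <- nrow(d)
  if (n < 2L) return(0)
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
}

# coordinatewise majority of three state vectors; ties keep the first
median_vector <- function(u, v, w) {
  out <- u
  agree <- v == w
  out[agree] <- v[agree]
  out
}

#' Median-joining network of consensus sequences
#'
#' Builds a haplotype network over aligned consensus sequences: duplicate
#' sequences are merged into one node with a multiplicity, the
#' epsilon-relaxed minimum spanning network (union of all minimum spanning
#' trees when `epsilon = 0`) connects the observed nodes, and inferred
#' median (Steiner) vectors of linked triplets are added greedily while
#' they reduce the total tree length, then pruned when obsolete. Edge
#' weights are Hamming distances over the analysed columns.
#'
#' @param consensuses named character vector of equal-length aligned
#'   sequences (gap `-` allowed, treated as a fifth state).
#' @param epsilon relaxation parameter of the minimum-spanning criterion
#'   (default 0).
#' @param exclude_cpg drop CpG columns before computing distances; CpG
#'   status is taken from `cpg_cols` if given, else from the first
#'   sequence.
#' @param cpg_cols optional logical vector of CpG columns.
#' @return a `consensus_network`: list with `graph` (igraph; vertex
#'   attributes `name`, `type` = observed/median, `multiplicity`,
#'   `sequence`; edge attribute `weight`), `nodes` (data.frame),
#'   `epsilon`, `total_length`.
#' @export
median_joining_network <- function(consensuses, epsilon = 0,
                                   exclude_cpg = FALSE, cpg_cols = NULL) {
  stopifnot(length(consensuses) >= 1L)
  if (is.null(names(consensuses))) {
    names(consensuses) <- paste0("seq", seq_along(consensuses))
  }
  lens <- nchar(consensuses)
  if (length(unique(lens)) != 1L) {
    stop("consensus sequences must be aligned to equal length")
  }
  m <- do.call(rbind, lapply(consensuses, seq_chars))
  if (exclude_cpg) {
    if (is.null(cpg_cols)) cpg_cols <- cpg_mask(m[1L, ])
    m <- m[, !cpg_cols, drop = FALSE]
  }
  # merge duplicates, record multiplicity
  key <- apply(m, 1L, paste, collapse = "")
  first <- !duplicated(key)
  mult <- as.integer(table(factor(key, levels = key[first])))
  labels <- vapply(split(names(consensuses), factor(key, levels = key[first])),
                   function(x) paste(x, collapse = ","), character(1))
  obs <- m[first, , drop = FALSE]
  rownames(obs) <- labels
  n_obs <- nrow(obs)
  if (n_obs == 1L) {
    g <- igraph::make_empty_graph(1L, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = labels)
    g <- igraph::set_vertex_attr(g, "type", value = "observed")
    g <- igraph::set_vertex_attr(g, "multiplicity", value = mult)
    g <- igraph::set_vertex_attr(g, "sequence",
                                 value = apply(obs, 1L, paste, collapse = ""))
    return(structure(list(graph = g,
                          nodes = data.frame(name = labels,
                                             type = "observed",
                                             multiplicity = mult),
                          epsilon = epsilon, total_length = 0),
                     class = "consensus_network"))
  }

  # median expansion: every pass adds all new median vectors of linked
  # triplets (two MSN edges sharing a node); superfluous medians are
  # removed afterwards. Adding whole batches rather than single improving
  # medians lets pairs of medians that only help jointly enter the network.
  nodes <- obs
  types <- rep("observed", n_obs)
  med_i <- 0L
  max_medians <- 16L + 8L * n_obs
  repeat {
    d <- row_dist(nodes)
    edges <- msn_edges(d, epsilon)
    cands <- list()
    if (nrow(nodes) >= 3L && nrow(edges) >= 2L) {
      have <- apply(nodes, 1L, paste, collapse = "")
      for (tri in utils::combn(nrow(nodes), 3L, simplify = FALSE)) {
        mvec <- median_vector(nodes[tri[1L], ], nodes[tri[2L], ],
                              nodes[tri[3L], ])
        keym <- paste(mvec, collapse = "")
        if (keym %in% have) next
        cands[[keym]] <- mvec
      }
    }
    if (!length(cands) || sum(types == "median") >= max_medians) break
    for (mvec in cands) {
      med_i <- med_i + 1L
      nodes <- rbind(nodes, mvec)
      rownames(nodes)[nrow(nodes)] <- paste0("median_", med_i)
      types <- c(types, "median")
      if (sum(types == "median") >= max_medians) break
    }
  }
  # keep the median subset that minimises the total tree length (fewest
  # medians on ties). First-found greedy pruning is order dependent and can
  # discard a median that only pays off once unrelated medians are gone.
  med_idx <- which(types == "median")
  obs_idx <- which(types == "observed")
  if (length(med_idx) > 0L && length(med_idx) <= 12L) {
    best_len <- Inf
    best_keep <- integer()
    for (mask in 0:(2^length(med_idx) - 1L)) {
      keep <- med_idx[bitwAnd(mask, 2^(seq_along(med_idx) - 1L)) > 0L]
      sel <- c(obs_idx, keep)
      len <- mst_length(row_dist(nodes[sel, , drop = FALSE]))
      if (len < best_len ||
          (len == best_len && length(keep) < length(best_keep))) {
        best_len <- len
        best_keep <- keep
      }
    }
    sel <- sort(c(obs_idx, best_keep))
    nodes <- nodes[sel, , drop = FALSE]
    types <- types[sel]
  } else if (length(med_idx) > 0L) {
    # too many medians to enumerate: steepest-descent removal
    repeat {
      d <- row_dist(nodes)
      base_len <- mst_length(d)
      meds <- which(types == "median")
      if (!length(meds)) break
      lens <- vapply(meds, function(i) {
        mst_length(d[-i, -i, drop = FALSE])
      }, numeric(1))
      if (min(lens) > base_len) break
      drop <- meds[which.min(lens)]
      nodes <- nodes[-drop, , drop = FALSE]
      types <- types[-drop]
    }
  }

  d <- row_dist(nodes)
  edges <- msn_edges(d, epsilon)
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = rownames(nodes))
  g <- igraph::set_vertex_attr(g, "type", value = types)
  g <- igraph::set_vertex_attr(
    g, "multiplicity",
    value = c(mult, rep(1L, sum(types == "median"))))
  g <- igraph::set_vertex_attr(g, "sequence",
                               value = apply(nodes, 1L, paste, collapse = ""))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, t(edges[, 1:2, drop = FALSE]),
                           weight = edges[, 3L])
  }
  structure(list(
    graph = g,
    nodes = data.frame(name = rownames(nodes), type = types,
                       multiplicity = c(mult,
                                        rep(1L, sum(types == "median"))),
                       stringsAsFactors = FALSE),
    epsilon = epsilon,
    total_length = mst_length(d)),
    class = "consensus_network")
}
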