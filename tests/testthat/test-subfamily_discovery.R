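test_that("mutation matrix rows mirror elements in template frame", {
  set.seed(14)
  template <- random_dna(120)
  elems <- c(e1 = template,
             e2 = local({
               ch <- strsplit(template, "")[[1]]
               ch[40] <- setdiff(c("A", "C", "G", "T"), ch[40])[1]
               paste(ch, collapse = "")
             }),
             # insertion relative to template is dropped
             e3 = paste0(substr(template, 1, 60), "GGGGG",
                         substr(template, 61, 120)))
  m <- build_mutation_matrix(elems, template)
  expect_equal(ncol(m$states), 120L)
  expect_equal(paste(m$states["e1", ], collapse = ""), template)
  expect_equal(sum(m$states["e2", ] != m$states["e1", ]), 1L)
  expect_equal(which(m$states["e2", ] != m$states["e1", ]), 40L)
  expect_equal(paste(m$states["e3", ], collapse = ""), template)
})

test_that("heavily truncated elements are excluded with a warning", {
  set.seed(15)
  template <- random_dna(150)
  elems <- c(full = template, trunc = substr(template, 100, 150))
  expect_warning(m <- build_mutation_matrix(elems, template), "excluded")
  expect_equal(rownames(m$states), "full")
  expect_equal(m$excluded, "trunc")
})

test_that("majority consensus applies the documented tie-break", {
  states <- rbind(e1 = c("A", "A", "-", "T"),
                  e2 = c("A", "G", "-", "T"),
                  e3 = c("G", "A", "C", "T"),
                  e4 = c("G", "G", "C", "T"))
  m <- list(states = states, template = c("T", "T", "T", "T"),
            cpg = rep(FALSE, 4))
  class(m) <- "mutation_matrix"
  cons <- refine_consensus(rownames(states), m)
  # ties A/G resolve to A (state order A<C<G<T<-); '-' ties with C resolve C
  expect_equal(cons, c("A", "A", "C", "T"))
  expect_equal(refine_consensus("e3", m), states["e3", ])
})

test_that("two planted sources are recovered with their diagnostics", {
  fx <- two_source_matrix(n = 200, noise = 0.02)
  m <- build_mutation_matrix(fx$elements, fx$template)
  subs <- detect_subfamilies(m, min_size = 10)
  expect_length(subs, 2L)
  # >= 95% of elements assigned to their true source
  grp2 <- subs[[which.max(vapply(subs, function(s)
    sum(fx$truth[match(s$members, names(fx$elements))] == 2), numeric(1)))]]
  correct <- sum(fx$truth[match(grp2$members, names(fx$elements))] == 2) +
    sum(fx$truth[match(setdiff(names(fx$elements), grp2$members),
                       names(fx$elements))] == 1)
  expect_gte(correct / 200, 0.95)
  # all diagnostic columns recovered in the derived subfamily's consensus
  expect_true(all(fx$diagnostics$position %in% grp2$diagnostics$column))
})

test_that("homogeneous elements stay one subfamily", {
  fx <- two_source_matrix(n = 120, noise = 0.02)
  # use only source-1 elements
  keep <- fx$elements[fx$truth == 1]
  m <- build_mutation_matrix(keep, fx$template)
  subs <- detect_subfamilies(m, min_size = 10)
  expect_length(subs, 1L)
  expect_equal(subs[[1]]$size, length(keep))
})

test_that("the minimum size bound suppresses small subfamilies", {
  fx <- two_source_matrix(n = 60, noise = 0.02)
  m <- build_mutation_matrix(fx$elements, fx$template)
  subs <- detect_subfamilies(m, min_size = 40)
  expect_true(all(vapply(subs, `[[`, numeric(1), "size") >= 40 |
                    length(subs) == 1L))
  expect_length(subs, 1L)
})

test_that("subfamily sizes partition the input and survive row shuffles", {
  fx <- two_source_matrix(n = 150, noise = 0.02, seed = 8)
  m <- build_mutation_matrix(fx$elements, fx$template)
  subs <- detect_subfamilies(m, min_size = 10)
  expect_equal(sum(vapply(subs, `[[`, numeric(1), "size")), 150)
  expect_setequal(unlist(lapply(subs, `[[`, "members")),
                  names(fx$elements))

  set.seed(99)
  perm <- sample(nrow(m$states))
  m2 <- m
  m2$states <- m$states[perm, ]
  subs2 <- detect_subfamilies(m2, min_size = 10)
  sets1 <- lapply(subs, function(s) sort(s$members))
  sets2 <- lapply(subs2, function(s) sort(s$members))
  expect_setequal(vapply(sets1, paste, "", collapse = ","),
                  vapply(sets2, paste, "", collapse = ","))
})

test_that("CpG exclusion ignores diagnostics at CpG columns", {
  set.seed(16)
  template <- random_dna(100, gc = 0.6)
  ch <- strsplit(template, "")[[1]]
  cg <- which(ch[-100] == "C" & ch[-1] == "G")
  skip_if(length(cg) < 2)
  # plant a 'subfamily' defined only by two CpG-site mutations
  mut <- ch
  mut[cg[1]] <- "T"
  mut[cg[2]] <- "T"
  elems <- c(
    stats::setNames(rep(template, 30), paste0("a", 1:30)),
    stats::setNames(rep(paste(mut, collapse = ""), 30), paste0("b", 1:30)))
  m <- build_mutation_matrix(elems, template)
  with_cpg <- detect_subfamilies(m, min_size = 10, exclude_cpg = FALSE)
  no_cpg <- detect_subfamilies(m, min_size = 10, exclude_cpg = TRUE)
  expect_length(with_cpg, 2L)
  expect_length(no_cpg, 1L)
})

test_that("median-joining reproduces forced chains and Steiner medians", {
  # chain: AAA - AAT - ATT
  net <- median_joining_network(c(x = "AAA", y = "AAT", z = "ATT"))
  expect_equal(igraph::vcount(net$graph), 3L)
  expect_equal(net$total_length, 2)
  deg <- igraph::degree(net$graph)
  expect_equal(sort(unname(deg)), c(1, 1, 2))

  # four haplotypes whose Steiner tree needs inferred medians
  net2 <- median_joining_network(c(a = "AAA", b = "TTA", c = "TAT",
                                   d = "ATT"))
  expect_true(any(net2$nodes$type == "median"))
  expect_lte(net2$total_length, 5)

  # duplicates merge with multiplicity
  net3 <- median_joining_network(c(p = "AAAA", q = "AAAA", r = "AATA"))
  expect_equal(igraph::vcount(net3$graph), 2L)
  expect_equal(sort(net3$nodes$multiplicity), c(1L, 2L))

  # single sequence: single-node network
  net4 <- median_joining_network(c(only = "ACGT"))
  expect_equal(igraph::vcount(net4$graph), 1L)
})

test_that("medians never lengthen the network beyond the observed MST", {
  set.seed(17)
  for (i in 1:15) {
    n <- sample(3:6, 1)
    len <- sample(4:8, 1)
    seqs <- vapply(seq_len(n), function(k)
      paste(sample(c("A", "T"), len, replace = TRUE), collapse = ""),
      character(1))
    names(seqs) <- paste0("h", seq_len(n))
    net <- median_joining_network(seqs)
    # MST over observed nodes only
    m <- do.call(rbind, lapply(unique(seqs), function(s)
      strsplit(s, "")[[1]]))
    d <- as.matrix(stats::dist(apply(m, 2, function(col)
      as.integer(factor(col, c("A", "C", "G", "T", "-")))), "manhattan"))
    d0 <- matrix(0, nrow(m), nrow(m))
    for (a in seq_len(nrow(m))) for (b in seq_len(nrow(m))) {
      d0[a, b] <- sum(m[a, ] != m[b, ])
    }
    g <- igraph::graph_from_adjacency_matrix(d0, mode = "undirected",
                                             weighted = TRUE)
    mst_w <- sum(igraph::E(igraph::mst(g))$weight)
    expect_lte(net$total_length, mst_w)
    expect_true(igraph::is_connected(net$graph))
  }
})
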