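test_that("global alignment recovers identity and clean deletion blocks", {
  set.seed(4)
  cons <- random_dna(100)
  a <- align_to_consensus(cons, cons)
  expect_true(all(a$columns == "match"))
  expect_equal(nchar(a$aligned_element), 100L)

  # middle 10 bp deleted -> one contiguous 10-column deletion block
  elem <- paste0(substr(cons, 1, 45), substr(cons, 56, 100))
  a2 <- align_to_consensus(elem, cons)
  expect_equal(sum(a2$columns == "deletion"), 10L)
  del <- which(a2$columns == "deletion")
  expect_equal(max(del) - min(del) + 1L, 10L)
  expect_equal(sum(a2$columns == "mismatch"), 0L)

  expect_error(align_to_consensus("", cons), "empty")
})

test_that("alignment ungapping recovers the inputs exactly", {
  set.seed(8)
  for (i in 1:10) {
    cons <- random_dna(80)
    elem <- mutate_sequence(cons, 30)
    if (i %% 2 == 0) elem <- paste0(substr(elem, 1, 40), substr(elem, 46, 80))
    a <- align_to_consensus(elem, cons)
    expect_equal(gsub("-", "", a$aligned_element), elem)
    expect_equal(gsub("-", "", a$aligned_consensus), cons)
  }
})

test_that("CpG column flags derive from the ungapped consensus", {
  a <- element_alignment("ACGTCGA", "ACGTCGA")
  expect_equal(which(a$cpg), c(2L, 3L, 5L, 6L))
  # a gap in the consensus shifts flags with the ungapped sequence
  b <- element_alignment("AACGT", "A-CGT")
  expect_equal(which(b$cpg), c(3L, 4L))
})

test_that("divergence counts mismatches over substitution columns only", {
  a <- element_alignment("ACGTACGTAC", "ACGTACGTAC")
  d <- compute_divergence(a)
  expect_equal(d$overall, 0)
  expect_equal(d$cpg, 0)
  expect_equal(d$non_cpg, 0)

  # 10 columns, 2 mismatches, no gaps, no CpG
  b <- element_alignment("TTTTTTTTAA", "TTTTTTTTTT")
  db <- compute_divergence(b)
  expect_equal(db$overall, 0.2)
  expect_equal(db$non_cpg, 0.2)
  expect_true(is.na(db$cpg))

  # gap columns are excluded from the denominator
  c <- element_alignment("TTTT--TTAA", "TTTTTTTTTT")
  dc <- compute_divergence(c)
  expect_equal(dc$overall, 2 / 8)

  # all-gap element: undefined, flagged not an error
  e <- element_alignment("----", "ACGT")
  de <- compute_divergence(e)
  expect_true(de$undefined)
  expect_true(is.na(de$overall))
})

test_that("kimura2p correction exceeds raw divergence and is finite", {
  set.seed(11)
  cons <- random_dna(2000)
  elem <- mutate_sequence(cons, 60)
  a <- align_to_consensus(elem, cons)
  raw <- compute_divergence(a, "raw")
  k2p <- compute_divergence(a, "kimura2p")
  expect_gt(k2p$overall, raw$overall)
  expect_lt(k2p$overall, 3 * raw$overall)
})

test_that("divergence is invariant under reverse-complementing both", {
  set.seed(12)
  cons <- random_dna(300)
  elem <- mutate_sequence(cons, 40)
  d1 <- compute_divergence(align_to_consensus(elem, cons))
  d2 <- compute_divergence(align_to_consensus(revcomp(elem), revcomp(cons)))
  expect_equal(d2$overall, d1$overall)
  # CpG is a palindromic context, so the class split is preserved too
  expect_equal(d2$cpg, d1$cpg)
  expect_equal(d2$non_cpg, d1$non_cpg)
})

test_that("class divergences recover the forward-model expectations", {
  set.seed(13)
  cons <- random_dna(400, gc = 0.5)
  n <- 400
  mm <- c(cpg = 0, non = 0)
  nn <- c(cpg = 0, non = 0)
  for (i in seq_len(n)) {
    elem <- mutate_sequence(cons, 10)
    a <- align_to_consensus(elem, cons)
    d <- compute_divergence(a)
    cnt <- d$counts
    mm["cpg"] <- mm["cpg"] + cnt$mismatched[cnt$class == "cpg"]
    nn["cpg"] <- nn["cpg"] + cnt$matched[cnt$class == "cpg"] +
      cnt$mismatched[cnt$class == "cpg"]
    mm["non"] <- mm["non"] + cnt$mismatched[cnt$class == "non_cpg"]
    nn["non"] <- nn["non"] + cnt$matched[cnt$class == "non_cpg"] +
      cnt$mismatched[cnt$class == "non_cpg"]
  }
  e_non <- 1 - exp(-0.0013 * 10)
  e_cpg <- 1 - exp(-0.0104 * 10)
  se_non <- sqrt(e_non * (1 - e_non) / nn["non"])
  se_cpg <- sqrt(e_cpg * (1 - e_cpg) / nn["cpg"])
  expect_lt(abs(mm["non"] / nn["non"] - e_non), 3 * se_non)
  expect_lt(abs(mm["cpg"] / nn["cpg"] - e_cpg), 3 * se_cpg)
})

make_ann <- function(family, len, div, start = 0L, scaffold = "s1",
                     id = NULL, class = "SINE/tRNA-Can") {
  n <- length(family)
  if (is.null(id)) id <- seq_len(n)
  df <- data.frame(scaffold = scaffold, start = start,
                   end = start + len, strand = "+", family = family,
                   class = class, divergence_pct = div, deletion_pct = 0,
                   insertion_pct = 0, consensus_start = 1L,
                   consensus_end = len, consensus_left = 0L,
                   element_id = id, stringsAsFactors = FALSE)
  df$fragments <- lapply(seq_len(n), function(i) {
    data.frame(start = df$start[i], end = df$end[i],
               consensus_start = 1L, consensus_end = len[i],
               consensus_left = 0L)
  })
  repeat_annotations(df)
}

test_that("young-element selection applies inclusive thresholds", {
  ann <- make_ann(rep("fam", 4), len = c(150L, 149L, 200L, 180L),
                  div = c(10, 5, 10.1, 0), start = c(0L, 300L, 600L, 900L))
  keep <- select_young_elements(ann, "fam", 150, 10)
  expect_equal(keep$element_id, c(1L, 4L))  # boundary kept, short/diverged out

  zero <- select_young_elements(ann, "fam", 150, 0)
  expect_equal(zero$element_id, 4L)

  expect_warning(out <- select_young_elements(ann, "nope", 150, 10),
                 "family")
  expect_equal(nrow(out), 0L)

  # idempotent and order-preserving
  again <- select_young_elements(keep, "fam", 150, 10)
  expect_equal(again$element_id, keep$element_id)
})

test_that("TE content summary computes percentages, means and landscape", {
  ann <- make_ann(c("famA", "famA", "famB"), len = c(100L, 100L, 50L),
                  div = c(4, 6, 30), start = c(0L, 200L, 400L),
                  class = c("SINE/tRNA-Can", "SINE/tRNA-Can", "LINE/L1"))
  s <- summarize_te_content(ann, 1000)
  fa <- s$by_family[s$by_family$family == "famA", ]
  expect_equal(fa$count, 2L)
  expect_equal(fa$total_bp, 200)
  expect_equal(fa$genome_pct, 20)
  expect_equal(fa$mean_divergence_pct, 5)
  cl <- s$by_class
  expect_equal(cl$genome_pct[cl$class == "SINE"], 20)
  expect_equal(cl$genome_pct[cl$class == "LINE"], 5)
  h <- s$divergence_histogram
  expect_equal(sum(h$bp), 250)
  expect_equal(h$bp[h$class == "SINE" & h$bin_lo == 4], 100)
  expect_equal(h$bp[h$class == "LINE" & h$bin_lo == 30], 50)

  empty <- summarize_te_content(ann[0, ], 1000)
  expect_equal(nrow(empty$by_family), 0L)
})

test_that("summary counts equal simulator truth per lineage", {
  cfg <- small_sim_config(seed = 77, genome_length = 5e4)
  sim <- simulate_caniform_genomes(cfg)
  tr <- sim$truth
  for (sp in c("panda", "dog")) {
    s <- summarize_te_content(sim$annotations[[sp]],
                              nchar(sim$assemblies[[sp]]$sequences[[1]]))
    carried <- tr$insertions[grepl(sp, tr$insertions$species, fixed = TRUE), ]
    truth_counts <- table(carried$subfamily)
    for (fam in names(truth_counts)) {
      expect_equal(s$by_family$count[s$by_family$family == fam],
                   as.integer(truth_counts[[fam]]))
    }
  }
})
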