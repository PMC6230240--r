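# build a tiny two-species fixture: a shared background with one element
# planted only in the focal genome
empty_site_fixture <- function(seed = 1, bg_len = 4000, elem_len = 200,
                               site = 2000, tsd = 10, revcomp_target = FALSE) {
  set.seed(seed)
  bg <- random_dna(bg_len)
  elem <- random_dna(elem_len)
  focal <- plant_insertion(bg, site, elem, tsd)
  target_seq <- if (revcomp_target) revcomp(bg) else bg
  ann <- data.frame(scaffold = "s1", start = site,
                    end = site + elem_len, strand = "+", family = "fam",
                    class = "SINE", divergence_pct = 0, deletion_pct = 0,
                    insertion_pct = 0, consensus_start = 1L,
                    consensus_end = elem_len, consensus_left = 0L,
                    element_id = 1L)
  ann$fragments <- list(data.frame(start = site, end = site + elem_len,
                                   consensus_start = 1L,
                                   consensus_end = elem_len,
                                   consensus_left = 0L))
  list(focal = genome_assembly(c(s1 = focal$sequence), "focal"),
       target = genome_assembly(c(s1 = target_seq), "target"),
       annotation = repeat_annotations(ann),
       element = elem)
}

test_that("flank extraction uses 0-based spans and flags truncation", {
  set.seed(2)
  g <- genome_assembly(c(s1 = random_dna(2000)), "toy")
  ann <- data.frame(scaffold = "s1", start = 600L, end = 800L, strand = "+",
                    family = "f", class = "SINE", divergence_pct = 0,
                    deletion_pct = 0, insertion_pct = 0,
                    consensus_start = 1L, consensus_end = 200L,
                    consensus_left = 0L, element_id = 1L)
  ann$fragments <- list(data.frame(start = 600L, end = 800L,
                                   consensus_start = 1L,
                                   consensus_end = 200L,
                                   consensus_left = 0L))
  ann <- repeat_annotations(ann)
  fl <- extract_flanks(g, ann[1, ], flank_len = 500)
  expect_equal(fl$left_flank, seq_slice(g$sequences[[1]], 100, 600))
  expect_equal(fl$right_flank, seq_slice(g$sequences[[1]], 800, 1300))
  expect_false(fl$left_truncated)

  ann2 <- ann
  ann2$start <- 200L
  ann2$fragments[[1]]$start <- 200L
  fl2 <- extract_flanks(g, ann2[1, ], flank_len = 500)
  expect_equal(nchar(fl2$left_flank), 200L)
  expect_true(fl2$left_truncated)

  fl0 <- extract_flanks(g, ann[1, ], flank_len = 0)
  expect_equal(nchar(fl0$left_flank), 0L)
})

test_that("a verbatim flank maps with full identity and coverage", {
  fx <- empty_site_fixture(seed = 3)
  fl <- extract_flanks(fx$focal, fx$annotation[1, ])
  mp <- map_flanks(fl, fx$target)
  expect_equal(mp$left$identity, 1)
  expect_equal(mp$left$coverage, 1)
  expect_equal(mp$right$identity, 1)
})

test_that("an absent element gives collinear flanks and a small gap", {
  for (sd in 3:5) {
    fx <- empty_site_fixture(seed = sd)
    fl <- extract_flanks(fx$focal, fx$annotation[1, ])
    mp <- map_flanks(fl, fx$target)
    cl <- call_presence(mp, fx$annotation[0, ])
    expect_equal(cl$status, "absent")
    expect_lte(cl$gap, 30)
    expect_gte(cl$gap, -60)
  }
})

test_that("a filled site with a same-family annotation is called present", {
  set.seed(6)
  fx <- empty_site_fixture(seed = 6)
  # target carries the same insertion (with its own TSD), annotated
  t2 <- plant_insertion(fx$target$sequences[[1]], 2000, fx$element, 10)
  target <- genome_assembly(c(s1 = t2$sequence), "target")
  tann <- fx$annotation
  fl <- extract_flanks(fx$focal, fx$annotation[1, ])
  mp <- map_flanks(fl, target)
  cl <- call_presence(mp, tann)
  expect_equal(cl$status, "present")
  expect_gt(cl$gap, 150)
})

test_that("mutated flanks still pass the identity threshold", {
  set.seed(7)
  fx <- empty_site_fixture(seed = 7)
  # ~5% substitutions on the target side, constructed directly
  ch <- strsplit(fx$target$sequences[[1]], "")[[1]]
  hit <- which(runif(length(ch)) < 0.05)
  ch[hit] <- c(A = "G", C = "T", G = "A", T = "C")[ch[hit]]
  target <- genome_assembly(c(s1 = paste(ch, collapse = "")), "target")
  fl <- extract_flanks(fx$focal, fx$annotation[1, ])
  mp <- map_flanks(fl, target)
  expect_false(is.null(mp$left))
  expect_gt(mp$left$identity, 0.9)
  expect_lt(mp$left$identity, 1)
  cl <- call_presence(mp, fx$annotation[0, ])
  expect_equal(cl$status, "absent")
})

test_that("calls are invariant under reverse-complementing the target", {
  fx <- empty_site_fixture(seed = 8, revcomp_target = TRUE)
  fl <- extract_flanks(fx$focal, fx$annotation[1, ])
  mp <- map_flanks(fl, fx$target)
  expect_equal(mp$left$strand, "-")
  cl <- call_presence(mp, fx$annotation[0, ])
  expect_equal(cl$status, "absent")
})

test_that("discordant flank placements are unresolved", {
  set.seed(9)
  bg <- random_dna(3000)
  elem <- random_dna(200)
  focal <- plant_insertion(bg, 1500, elem, 10)
  # target splits the locus across two scaffolds
  target <- genome_assembly(c(s1 = substr(bg, 1, 1500),
                              s2 = substr(bg, 1501, 3000)), "target")
  ann <- data.frame(scaffold = "s1", start = 1500L, end = 1700L,
                    strand = "+", family = "fam", class = "SINE",
                    divergence_pct = 0, deletion_pct = 0, insertion_pct = 0,
                    consensus_start = 1L, consensus_end = 200L,
                    consensus_left = 0L, element_id = 1L)
  ann$fragments <- list(data.frame(start = 1500L, end = 1700L,
                                   consensus_start = 1L,
                                   consensus_end = 200L,
                                   consensus_left = 0L))
  ann <- repeat_annotations(ann)
  fl <- extract_flanks(genome_assembly(c(s1 = focal$sequence), "focal"),
                       ann[1, ])
  mp <- map_flanks(fl, target)
  cl <- call_presence(mp, ann[0, ])
  expect_equal(cl$status, "unresolved")
  expect_equal(cl$reason, "discordant")
})

test_that("lineage-specific classification follows the all-absent rule", {
  calls <- list(
    sp1 = data.frame(element_id = 1:4,
                     status = c("absent", "absent", "present", "absent")),
    sp2 = data.frame(element_id = 1:4,
                     status = c("absent", "unresolved", "absent", "absent")),
    sp3 = data.frame(element_id = 1:4,
                     status = c("absent", "absent", "absent", "present")))
  out <- find_lineage_specific(calls, "focal")
  expect_equal(out$specific, 1L)
  expect_equal(out$ambiguous, 2L)
  expect_setequal(out$shared, c(3L, 4L))

  expect_error(find_lineage_specific(list(), "focal"), "no target")
  expect_error(find_lineage_specific(calls, "sp1"), "focal")
})

test_that("raising the identity threshold never turns absent into present", {
  cfg <- small_sim_config(seed = 60, genome_length = 6e4)
  sim <- simulate_caniform_genomes(cfg)
  ann <- sim$annotations$panda
  cand <- ann[element_length(ann) >= 150 & ann$divergence_pct <= 10, ]
  cand <- repeat_annotations(utils::head(cand, 15))
  targets <- list(polar_bear = list(genome = sim$assemblies$polar_bear,
                                    annotations = sim$annotations$polar_bear))
  lo <- ortholog_screen(sim$assemblies$panda, cand, targets,
                        ortholog_params(min_identity = 0.80),
                        focal_annotations = ann)
  hi <- ortholog_screen(sim$assemblies$panda, cand, targets,
                        ortholog_params(min_identity = 0.95),
                        focal_annotations = ann)
  a <- lo$calls$polar_bear
  b <- hi$calls$polar_bear
  was_absent <- a$element_id[a$status == "absent"]
  expect_false(any(b$status[b$element_id %in% was_absent] == "present"))
})
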