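# shared fixtures, all generated in code

# minimal RepeatMasker .out content (3 header lines + body rows)
rm_out_lines <- function(rows) {
  c(" SW perc perc perc query position in query matching repeat position in repeat",
    "score div. del. ins. sequence begin end (left) repeat class/family begin end (left) ID",
    "",
    rows)
}

write_rm_out <- function(rows) {
  path <- tempfile(fileext = ".out")
  writeLines(rm_out_lines(rows), path)
  path
}

# small simulation at 1/10 scale: insertion rates scaled with genome length
# so that TE density matches the full-size default scenario
small_sim_config <- function(seed, genome_length = 2e5, scale = 0.1,
                             a2_branches = NULL) {
  set.seed(1234)
  src_a <- make_sine_source()
  src_b <- make_sine_source(head_len = 180, ct_repeats = 10)
  drv <- derive_source(src_a, positions = c(30L, 62L, 95L, 130L))
  subs <- list(
    subfamily_config("SINEC_simA", src_a, window = c(35, 5),
                     rate = 6 * scale),
    subfamily_config("SINEC_simB", src_b, window = c(45, 12),
                     rate = 4 * scale),
    subfamily_config("SINEC_simA2", drv$sequence, window = c(15.5, 0),
                     rate = 20 * scale, branches = a2_branches))
  attr(subs, "diagnostics") <- drv$diagnostics
  sim_config(seed = seed, genome_length = genome_length, subfamilies = subs)
}

# mutation-matrix fixture: two source haplotypes differing at diagnostic
# columns, elements drawn with iid noise
two_source_matrix <- function(n = 200, len = 150, n_diag = 4, noise = 0.02,
                              seed = 5) {
  set.seed(seed)
  template <- random_dna(len, gc = 0.5)
  drv <- derive_source(template, positions = round(seq(20, len - 20,
                                                       length.out = n_diag)))
  sources <- c(template, drv$sequence)
  truth <- rep(1:2, each = n / 2)
  elements <- vapply(truth, function(k) {
    ch <- strsplit(sources[k], "")[[1]]
    hit <- which(runif(length(ch)) < noise)
    if (length(hit)) {
      cur <- match(ch[hit], c("A", "C", "G", "T"))
      ch[hit] <- c("A", "C", "G", "T")[((cur + sample.int(3L, length(hit),
                                                          TRUE) - 1L) %% 4L) + 1L]
    }
    paste(ch, collapse = "")
  }, character(1))
  names(elements) <- paste0("e", seq_len(n))
  list(elements = elements, template = template, truth = truth,
       diagnostics = drv$diagnostics)
}

# exhaustive TSD search used as an independent oracle for find_tsd
tsd_oracle <- function(left, right, min_len = 6L, max_len = 15L,
                       max_mm = 1L, max_off = 5L) {
  l <- strsplit(left, "")[[1]]
  r <- strsplit(right, "")[[1]]
  nl <- length(l)
  nr <- length(r)
  best <- NULL
  for (len in min_len:max_len) {
    for (loff in 0:max_off) {
      for (roff in 0:max_off) {
        li <- nl - loff - len + 1L
        if (li < 1L || roff + len > nr) next
        lw <- l[li:(nl - loff)]
        rw <- r[(roff + 1L):(roff + len)]
        mm <- sum(lw != rw)
        if (mm > max_mm) next
        cand <- list(len = len, mm = mm, loff = loff, roff = roff)
        if (is.null(best)) {
          best <- cand
        } else {
          # longest; then fewest mismatches; then smallest offset sum; then
          # smallest left offset
          better <- cand$len > best$len ||
            (cand$len == best$len && cand$mm < best$mm) ||
            (cand$len == best$len && cand$mm == best$mm &&
             cand$loff + cand$roff < best$loff + best$roff) ||
            (cand$len == best$len && cand$mm == best$mm &&
             cand$loff + cand$roff == best$loff + best$roff &&
             cand$loff < best$loff)
          if (better) best <- cand
        }
      }
    }
  }
  best
}

# brute-force minimum Steiner tree length by enumerating added medians
steiner_oracle_length <- function(seqs, max_extra = 2L) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  dist_of <- function(mat) {
    n <- nrow(mat)
    d <- matrix(0, n, n)
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
    }
    d
  }
  mstlen <- function(mat) {
    d <- dist_of(mat)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    sum(igraph::E(igraph::mst(g))$weight)
  }
  # candidate Steiner points: full product of observed states per column
  states <- apply(m, 2, unique, simplify = FALSE)
  sizes <- vapply(states, length, integer(1))
  stopifnot(prod(sizes) <= 20000)
  cand <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  key <- apply(m, 1, paste, collapse = "")
  ckey <- apply(cand, 1, paste, collapse = "")
  cand <- cand[!ckey %in% key, , drop = FALSE]
  best <- mstlen(m)
  if (max_extra >= 1L) {
    for (i in seq_len(nrow(cand))) {
      best <- min(best, mstlen(rbind(m, cand[i, ])))
    }
  }
  if (max_extra >= 2L && nrow(cand) >= 2L && nrow(cand) <= 220L) {
    for (i in 1:(nrow(cand) - 1L)) for (j in (i + 1L):nrow(cand)) {
      best <- min(best, mstlen(rbind(m, cand[i, ], cand[j, ])))
    }
  }
  best
}
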