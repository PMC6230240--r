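#' Rates and options for CpG-aware age estimation
#'
#' @param rate_non_cpg substitutions/site/My at non-CpG sites (default
#'   0.0013, the neutral rate used for these genomes).
#' @param rate_cpg substitutions/site/My at CpG sites (default 0.0104).
#' @param exclude_ct_microsatellite drop (CT)n microsatellite columns from
#'   divergence inputs before dating (low-quality alignments there).
#' @return list of class `age_config`.
#' @export
age_config <- function(rate_non_cpg = 0.0013, rate_cpg = 0.0104,
                       exclude_ct_microsatellite = FALSE) {
  if (rate_non_cpg <= 0 || rate_cpg <= 0) stop("rates must be positive")
  structure(list(rate_non_cpg = rate_non_cpg, rate_cpg = rate_cpg,
                 exclude_ct_microsatellite = exclude_ct_microsatellite),
            class = "age_config")
}

#' Estimate an insertion age from CpG and non-CpG divergence
#'
#' Each site class yields `age = -ln(1 - d) / r` (a saturation-guarded
#' inversion of the per-site substitution probability `1 - exp(-r t)`,
#' reducing to `d / r` for small `d`), and the reported age is the mean of
#' the two class estimates.
#'
#' @param divergence_cpg divergence fraction at CpG sites, in `[0, 1)`.
#' @param divergence_non_cpg divergence fraction at non-CpG sites.
#' @param config an [age_config()].
#' @param n_elements optional element count carried into the result.
#' @return an `age_estimate`: list with `age_cpg_My`, `age_non_cpg_My`,
#'   `age_mean_My`, `n_elements`, and the divergence inputs.
#' @export
estimate_age_cpg <- function(divergence_cpg, divergence_non_cpg,
                             config = age_config(), n_elements = NA_integer_) {
  for (d in c(divergence_cpg, divergence_non_cpg)) {
    if (is.na(d) || d < 0 || d >= 1) {
      stop("divergence must lie in [0, 1)")
    }
  }
  age_cpg <- -log(1 - divergence_cpg) / config$rate_cpg
  age_non <- -log(1 - divergence_non_cpg) / config$rate_non_cpg
  structure(list(age_cpg_My = age_cpg, age_non_cpg_My = age_non,
                 age_mean_My = (age_cpg + age_non) / 2,
                 n_elements = n_elements,
                 divergence_cpg = divergence_cpg,
                 divergence_non_cpg = divergence_non_cpg),
            class = "age_estimate")
}

#' Count nested (transposition-in-transposition) insertions
#'
#' A multi-fragment element whose consecutive fragments sandwich one or
#' more complete elements of another family records a nesting: the inner
#' family inserted into the outer one while the outer copy was already in
#' place. Both outer fragments adjacent to the interruption must span at
#' least `min_extension` bp and their consensus coordinates must be
#' collinear (the interruption resumes where the outer copy left off);
#' nestings failing these checks are skipped and counted.
#'
#' @param annotations a `repeat_annotations` table.
#' @param min_extension minimum bp of each outer fragment flanking the
#'   interruption (default 4).
#' @param collinear_slack bp of tolerated overlap/gap between the consensus
#'   coordinates of the two outer fragments.
#' @return a `tint_matrix`: list with `counts` (square matrix,
#'   `counts[outer, inner]` = inner elements found inside outer elements),
#'   `abundance` (elements per family), `skipped`.
#' @export
detect_nested_insertions <- function(annotations, min_extension = 4L,
                                     collinear_slack = 10L) {
  fams <- sort(unique(annotations$family))
  counts <- matrix(0L, length(fams), length(fams),
                   dimnames = list(outer = fams, inner = fams))
  skipped <- 0L
  multi <- which(vapply(annotations$fragments, nrow, integer(1)) >= 2L)
  for (i in multi) {
    a <- annotations[i, ]
    fr <- a$fragments[[1L]]
    for (k in seq_len(nrow(fr) - 1L)) {
      gap_lo <- fr$end[k]
      gap_hi <- fr$start[k + 1L]
      inner <- annotations$scaffold == a$scaffold &
        annotations$element_id != a$element_id &
        annotations$start >= gap_lo & annotations$end <= gap_hi
      if (!any(inner)) next
      ext_ok <- (fr$end[k] - fr$start[k]) >= min_extension &&
        (fr$end[k + 1L] - fr$start[k + 1L]) >= min_extension
      coll_ok <- if (a$strand == "+") {
        fr$consensus_start[k + 1L] >= fr$consensus_end[k] - collinear_slack
      } else {
        fr$consensus_end[k + 1L] <= fr$consensus_start[k] + collinear_slack
      }
      if (!ext_ok || !coll_ok) {
        skipped <- skipped + sum(inner)
        next
      }
      for (j in which(inner)) {
        counts[a$family, annotations$family[j]] <-
          counts[a$family, annotations$family[j]] + 1L
      }
    }
  }
  abundance <- table(factor(annotations$family, levels = fams))
  structure(list(counts = counts,
                 abundance = stats::setNames(as.integer(abundance), fams),
                 skipped = skipped),
            class = "tint_matrix")
}

#' Build a tint_matrix from a count matrix
#'
#' @param counts square named matrix of nesting counts
#'   (`counts[outer, inner]`).
#' @param abundance named vector of family abundances; defaults to equal.
#' @return a `tint_matrix`.
#' @export
tint_matrix <- function(counts, abundance = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            !is.null(rownames(counts)), all(counts >= 0))
  if (is.null(abundance)) {
    abundance <- stats::setNames(rep(1L, nrow(counts)), rownames(counts))
  }
  structure(list(counts = counts,
                 abundance = abundance[rownames(counts)], skipped = 0L),
            class = "tint_matrix")
}

#' Fit relative activity periods from a nesting matrix
#'
#' Models each family's insertion times as Gaussian on an arbitrary
#' relative timescale (larger = younger). A family can insert into another
#' only while the other's copies are already present, so the expected
#' nesting count is `E[N_fg] = k a_f a_g P(T_g > T_f)` with independent
#' `T_f ~ N(mu_f, sigma_f^2)` and `a` the relative family abundances. The
#' parameters are fitted by maximising the Poisson likelihood of the
#' observed counts from several deterministic and jittered starts
#' (quasi-Newton BFGS). The timescale gauge is fixed afterwards by
#' standardising the fitted means to mean 0, variance 1.
#'
#' @param tint a `tint_matrix`.
#' @param n_starts number of optimisation starts (default 8).
#' @param include_diagonal use the within-family counts (`P = 1/2`)?
#' @return list of `activity_estimate`s (one per family, input order),
#'   each with `family`, `mu`, `sigma`, `p75`, `p99` (interval vectors),
#'   and the shared `loglik`; also attributes `loglik` and `convergence`.
#' @export
estimate_activity_periods <- function(tint, n_starts = 8L,
                                      include_diagonal = TRUE) {
  counts <- tint$counts
  fams <- rownames(counts)
  nf <- length(fams)
  if (nf < 2L) stop("need >= 2 families")
  if (sum(counts) == 0) stop("no nesting signal")
  a <- tint$abundance / sum(tint$abundance)
  mask <- matrix(TRUE, nf, nf)
  if (!include_diagonal) diag(mask) <- FALSE

  nll <- function(par) {
    mu <- par[1:nf]
    sig <- exp(par[(nf + 1):(2 * nf)])
    logk <- par[2 * nf + 1]
    p <- outer(seq_len(nf), seq_len(nf), function(f, g) {
      pnorm((mu[g] - mu[f]) / sqrt(sig[f]^2 + sig[g]^2))
    })
    lam <- exp(logk) * outer(a, a) * p
    lam <- pmax(lam, 1e-12)
    -sum((counts * log(lam) - lam)[mask])
  }

  # deterministic start: families inserted into others more often than they
  # host are younger
  score <- colSums(counts) - rowSums(counts)
  s0 <- if (stats::sd(score) > 0) scale(score)[, 1L] else rep(0, nf)
  starts <- list(c(s0, rep(0, nf), log(max(1, sum(counts)))))
  for (r in seq_len(max(0L, n_starts - 1L))) {
    starts[[r + 1L]] <- starts[[1L]] +
      c(rnorm(nf, 0, 0.5 + r / 4), rnorm(nf, 0, 0.3), rnorm(1, 0, 0.5))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(optim(st, nll, method = "BFGS",
                          control = list(maxit = 500)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("activity fit failed from all starts")
  mu <- best$par[1:nf]
  sig <- exp(best$par[(nf + 1):(2 * nf)])
  # gauge: relative timescale standardised on the fitted means
  ctr <- mean(mu)
  scl <- if (nf > 1L && stats::sd(mu) > 0) stats::sd(mu) else 1
  mu <- (mu - ctr) / scl
  sig <- sig / scl
  q75 <- qnorm(0.875)
  q99 <- qnorm(0.995)
  out <- lapply(seq_len(nf), function(f) {
    structure(list(family = fams[f], mu = mu[f], sigma = sig[f],
                   p75 = c(mu[f] - q75 * sig[f], mu[f] + q75 * sig[f]),
                   p99 = c(mu[f] - q99 * sig[f], mu[f] + q99 * sig[f]),
                   loglik = -best$value),
              class = "activity_estimate")
  })
  names(out) <- fams
  attr(out, "loglik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Simulate nesting counts from known activity periods
#'
#' Forward simulation used to validate the activity fit: insertion times
#' are drawn per family from Gaussian activity periods (in My before
#' present, larger = older), events are applied young-to-old in reverse so
#' that each insertion may land, with probability proportional to the bp
#' already occupied, inside a copy of a family inserted earlier; landing
#' inside records a nesting.
#'
#' @param peaks named vector of activity peaks (My before present).
#' @param sds activity-period standard deviations (My); recycled.
#' @param n_per_family insertions per family.
#' @param genome_length genome size in bp; the default, together with
#'   `n_per_family` and `element_len`, leaves the genome roughly a quarter
#'   repeat-derived at the end of the simulation, the occupancy regime of
#'   repeat-rich carnivore genomes in which nesting is informative.
#' @param element_len element length in bp.
#' @return a `tint_matrix` with the simulated counts.
#' @export
simulate_tint_counts <- function(peaks, sds = 5, n_per_family = 150L,
                                 genome_length = 3e5, element_len = 200L) {
  fams <- names(peaks)
  stopifnot(!is.null(fams))
  sds <- rep_len(sds, length(peaks))
  ev <- do.call(rbind, lapply(seq_along(peaks), function(f) {
    data.frame(family = fams[f],
               time = rnorm(n_per_family, peaks[f], sds[f]))
  }))
  ev <- ev[order(-ev$time), , drop = FALSE]   # oldest first
  counts <- matrix(0L, length(fams), length(fams),
                   dimnames = list(outer = fams, inner = fams))
  present_bp <- stats::setNames(numeric(length(fams)), fams)
  total <- genome_length
  for (i in seq_len(nrow(ev))) {
    p_in <- present_bp / total
    hit <- runif(1) < sum(p_in)
    if (hit) {
      outer_f <- sample(fams, 1L, prob = p_in)
      counts[outer_f, ev$family[i]] <- counts[outer_f, ev$family[i]] + 1L
    }
    present_bp[ev$family[i]] <- present_bp[ev$family[i]] + element_len
    total <- total + element_len
  }
  tint_matrix(counts, abundance = stats::setNames(
    rep(n_per_family, length(fams)), fams))
}
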