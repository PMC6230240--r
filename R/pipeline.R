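#' Pipeline configuration
#'
#' Central configuration for [run_pipeline()]. Defaults equal the
#' screening thresholds used throughout the package: 500 bp flanks, >= 90%
#' flank coverage at >= 80% identity for orthologous-locus calls, a 6-15 bp
#' TSD search band with at most one mismatch, minimum subfamily size 10,
#' dating rates 0.0013 / 0.0104 substitutions/site/My, and TinT minimum
#' repeat extension 4 bp. Input genomes come either from the simulator
#' (`simulate = sim_config(...)`) or from FASTA/.out files on disk.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param simulate optional [sim_config()]; when given, genomes and
#'   annotations are simulated rather than read.
#' @param genome_paths named list species -> FASTA path (file mode).
#' @param annotation_paths named list species -> RepeatMasker .out path.
#' @param consensus_path FASTA of family consensus templates (file mode).
#' @param focal_species species screened for lineage-specific insertions.
#' @param young_filters named list family -> `list(min_len_bp, max_div_pct)`
#'   selecting candidate elements; NULL applies 150 bp / 10% to every
#'   family of the focal genome.
#' @param flank_len,min_identity,min_coverage,empty_gap_max
#'   orthologous-locus screen settings (see [ortholog_params()]).
#' @param tsd_band TSD length search band (default `c(6, 15)`).
#' @param tsd_max_mismatch maximum mismatches between TSD copies.
#' @param coseg_min_size,coseg_alpha,coseg_exclude_cpg subfamily-discovery
#'   settings (see [detect_subfamilies()]).
#' @param age_rates `c(non_cpg, cpg)` substitution rates for dating.
#' @param tint_min_extension minimum outer-fragment extension for nesting
#'   counts.
#' @param calibration_My divergence calibration recorded in the manifest
#'   (metadata only; default 15.5 My, the focal split used for absolute
#'   dating elsewhere).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("cansine_run_"),
                            seed = 1L,
                            simulate = NULL,
                            genome_paths = NULL,
                            annotation_paths = NULL,
                            consensus_path = NULL,
                            focal_species = "panda",
                            young_filters = NULL,
                            flank_len = 500L, min_identity = 0.80,
                            min_coverage = 0.90, empty_gap_max = 30L,
                            tsd_band = c(6L, 15L), tsd_max_mismatch = 1L,
                            coseg_min_size = 10L, coseg_alpha = 1e-3,
                            coseg_exclude_cpg = FALSE,
                            age_rates = c(non_cpg = 0.0013, cpg = 0.0104),
                            tint_min_extension = 4L,
                            calibration_My = 15.5) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @return character vector of problems ("field: rule"); empty when the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  p <- character()
  add <- function(msg) p <<- c(p, msg)
  frac <- function(x) !is.na(x) && x >= 0 && x <= 1
  if (!frac(config$min_identity)) add("min_identity: fraction out of range")
  if (!frac(config$min_coverage)) add("min_coverage: fraction out of range")
  if (config$flank_len < 0) add("flank_len: must be >= 0")
  if (config$empty_gap_max < 0) add("empty_gap_max: must be >= 0")
  if (length(config$tsd_band) != 2L || config$tsd_band[1] > config$tsd_band[2]) {
    add("tsd_band: min > max")
  }
  if (!config$tsd_max_mismatch %in% c(0L, 1L)) {
    add("tsd_max_mismatch: must be 0 or 1")
  }
  if (config$coseg_min_size < 2) add("coseg_min_size: must be >= 2")
  if (!(config$coseg_alpha > 0 && config$coseg_alpha < 1)) {
    add("coseg_alpha: must be in (0, 1)")
  }
  if (any(config$age_rates <= 0)) add("age_rates: rates must be positive")
  if (config$tint_min_extension < 0) add("tint_min_extension: must be >= 0")
  if (is.null(config$simulate)) {
    for (field in c("genome_paths", "annotation_paths")) {
      paths <- config[[field]]
      if (is.null(paths) || length(paths) == 0L) {
        add(paste0(field, ": required when not simulating"))
        next
      }
      missing <- unlist(paths)[!file.exists(unlist(paths))]
      for (m in missing) add(paste0(field, ": file not found: ", m))
    }
    if (!is.null(config$consensus_path) &&
        !file.exists(config$consensus_path)) {
      add("consensus_path: file not found")
    }
  } else if (!inherits(config$simulate, "sim_config")) {
    add("simulate: must be a sim_config")
  }
  p
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# per-class CpG / non-CpG divergence of subfamily members against their
# consensus, pooled over members, then inverted to an age
age_from_matrix <- function(matrix, members, consensus_aligned, config) {
  cons <- seq_chars(consensus_aligned)
  cpg <- matrix$cpg
  if (config$exclude_ct_microsatellite) {
    cpg_keep <- !ct_microsat_cols(matrix$template)
  } else {
    cpg_keep <- rep(TRUE, length(cons))
  }
  mm <- c(cpg = 0, non = 0)
  nn <- c(cpg = 0, non = 0)
  for (id in members) {
    row <- matrix$states[id, ]
    ok <- row %in% DNA_BASES & cons %in% DNA_BASES & cpg_keep
    cls <- ifelse(cpg[ok], "cpg", "non")
    dif <- row[ok] != cons[ok]
    mm["cpg"] <- mm["cpg"] + sum(dif[cls == "cpg"])
    nn["cpg"] <- nn["cpg"] + sum(cls == "cpg")
    mm["non"] <- mm["non"] + sum(dif[cls == "non"])
    nn["non"] <- nn["non"] + sum(cls == "non")
  }
  d_cpg <- if (nn["cpg"] > 0) mm["cpg"] / nn["cpg"] else 0
  d_non <- if (nn["non"] > 0) mm["non"] / nn["non"] else 0
  estimate_age_cpg(min(d_cpg, 0.999), min(d_non, 0.999), config,
                   n_elements = length(members))
}

# columns inside (CT)x3+ microsatellite runs of the template
ct_microsat_cols <- function(template_chars) {
  s <- paste(template_chars, collapse = "")
  out <- rep(FALSE, length(template_chars))
  hits <- gregexpr("(CT){3,}|(TC){3,}", s)[[1]]
  if (hits[1L] != -1L) {
    lens <- attr(hits, "match.length")
    for (k in seq_along(hits)) {
      out[hits[k]:(hits[k] + lens[k] - 1L)] <- TRUE
    }
  }
  out
}

#' Percentage summary of TSD detection
#'
#' @param n_found elements with a detected TSD.
#' @param n_total elements examined.
#' @return list with the counts and `pct` (percentage, 1 decimal place
#'   precision retained as a plain number).
#' @export
tsd_percentage <- function(n_found, n_total) {
  stopifnot(n_total > 0, n_found >= 0, n_found <= n_total)
  list(n_found = n_found, n_total = n_total,
       pct = 100 * n_found / n_total)
}

#' Run the full Can-SINE analysis pipeline
#'
#' Executes simulate (optional) -> parse -> TE summary -> young-element
#' selection -> orthologous presence/absence screen -> TSD scan ->
#' subfamily discovery -> consensus networks -> age estimation -> nested
#' insertion (TinT) analysis, writing one TSV per stage plus a JSON
#' manifest into `config$out_dir`. Identical configuration and seed give
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return a report bundle: list with `summaries`, `candidates`, `screen`,
#'   `tsd`, `subfamilies`, `networks`, `ages`, `tint`, `activity`,
#'   `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  # ---- inputs ----
  if (!is.null(config$simulate)) {
    sim <- simulate_caniform_genomes(config$simulate)
    assemblies <- sim$assemblies
    annotations <- sim$annotations
    templates <- vapply(config$simulate$subfamilies, `[[`, "", "source")
  } else {
    species <- names(config$genome_paths)
    assemblies <- lapply(species, function(sp) {
      read_fasta(config$genome_paths[[sp]], species_label = sp)
    })
    names(assemblies) <- species
    annotations <- lapply(species, function(sp) {
      parse_repeatmasker_out(config$annotation_paths[[sp]])
    })
    names(annotations) <- species
    templates <- if (!is.null(config$consensus_path)) {
      read_consensus_library(config$consensus_path)
    } else {
      character()
    }
    sim <- NULL
  }
  if (!config$focal_species %in% names(assemblies)) {
    stop("focal species not among inputs: ", config$focal_species)
  }

  # ---- genome-wide TE summaries ----
  summaries <- lapply(names(assemblies), function(sp) {
    summarize_te_content(annotations[[sp]],
                         sum(nchar(assemblies[[sp]]$sequences)))
  })
  names(summaries) <- names(assemblies)
  for (sp in names(summaries)) {
    write_tsv(summaries[[sp]]$by_family,
              file.path(config$out_dir, paste0("te_summary_", sp, ".tsv")))
    write_tsv(summaries[[sp]]$divergence_histogram,
              file.path(config$out_dir,
                        paste0("divergence_landscape_", sp, ".tsv")))
  }

  # ---- candidate selection ----
  focal_ann <- annotations[[config$focal_species]]
  filters <- config$young_filters
  if (is.null(filters)) {
    filters <- stats::setNames(
      rep(list(list(min_len_bp = 150, max_div_pct = 10)),
          length(unique(focal_ann$family))),
      unique(focal_ann$family))
  }
  candidates <- do.call(rbind, lapply(names(filters), function(fam) {
    select_young_elements(focal_ann, fam, filters[[fam]]$min_len_bp,
                          filters[[fam]]$max_div_pct)
  }))
  candidates <- repeat_annotations(candidates)

  # ---- orthologous presence/absence screen ----
  others <- setdiff(names(assemblies), config$focal_species)
  params <- ortholog_params(flank_len = config$flank_len,
                            min_identity = config$min_identity,
                            min_coverage = config$min_coverage,
                            empty_gap_max = config$empty_gap_max)
  targets <- lapply(others, function(sp) {
    list(genome = assemblies[[sp]], annotations = annotations[[sp]])
  })
  names(targets) <- others
  screen <- ortholog_screen(assemblies[[config$focal_species]], candidates,
                            targets, params, focal_annotations = focal_ann)
  write_tsv(screen$report, file.path(config$out_dir, "ortholog_calls.tsv"))
  specific <- candidates[candidates$element_id %in% screen$specific, ,
                         drop = FALSE]

  # ---- TSD scan on lineage-specific elements ----
  focal_genome <- assemblies[[config$focal_species]]
  tsd_rows <- lapply(seq_len(nrow(specific)), function(i) {
    fl <- extract_tsd_flanks(focal_genome, specific[i, ])
    call <- find_tsd(fl$left_flank, fl$right_flank,
                     min_len = config$tsd_band[1],
                     max_len = config$tsd_band[2],
                     max_mismatch = config$tsd_max_mismatch)
    data.frame(element_id = specific$element_id[i],
               family = specific$family[i], found = call$found,
               length = call$length, mismatches = call$mismatches,
               left_copy = call$left_copy, right_copy = call$right_copy,
               stringsAsFactors = FALSE)
  })
  tsd_report <- if (length(tsd_rows)) do.call(rbind, tsd_rows) else
    data.frame(element_id = integer(), family = character(),
               found = logical(), length = integer(),
               mismatches = integer(), left_copy = character(),
               right_copy = character(), stringsAsFactors = FALSE)
  write_tsv(tsd_report, file.path(config$out_dir, "tsd_report.tsv"))
  tsd_summary <- if (nrow(tsd_report)) {
    tsd_percentage(sum(tsd_report$found), nrow(tsd_report))
  } else {
    NULL
  }

  # ---- subfamily discovery, networks, ages ----
  age_cfg <- age_config(rate_non_cpg = config$age_rates[["non_cpg"]],
                        rate_cpg = config$age_rates[["cpg"]])
  subfam <- list()
  networks <- list()
  ages <- list()
  for (fam in unique(specific$family)) {
    if (!fam %in% names(templates)) next
    rows <- specific[specific$family == fam, , drop = FALSE]
    if (nrow(rows) < config$coseg_min_size) next
    seqs <- vapply(seq_len(nrow(rows)), function(i) {
      s <- seq_slice(focal_genome$sequences[[rows$scaffold[i]]],
                     rows$start[i], rows$end[i])
      if (rows$strand[i] == "-") revcomp(s) else s
    }, character(1))
    names(seqs) <- as.character(rows$element_id)
    mat <- suppressWarnings(build_mutation_matrix(seqs, templates[[fam]]))
    if (nrow(mat$states) < config$coseg_min_size) next
    subs <- detect_subfamilies(mat, min_size = config$coseg_min_size,
                               exclude_cpg = config$coseg_exclude_cpg,
                               alpha = config$coseg_alpha)
    subfam[[fam]] <- subs
    cons <- c(stats::setNames(paste(mat$template, collapse = ""), fam),
              stats::setNames(
                vapply(subs, `[[`, "", "consensus_aligned"),
                paste0(fam, "_sub", seq_along(subs))))
    networks[[fam]] <- median_joining_network(cons,
                                              exclude_cpg = TRUE,
                                              cpg_cols = mat$cpg)
    ages[[fam]] <- lapply(subs, function(s) {
      age_from_matrix(mat, s$members, s$consensus_aligned, age_cfg)
    })
  }
  if (length(subfam)) {
    sub_df <- do.call(rbind, lapply(names(subfam), function(fam) {
      do.call(rbind, lapply(seq_along(subfam[[fam]]), function(k) {
        s <- subfam[[fam]][[k]]
        est <- ages[[fam]][[k]]
        data.frame(family = fam, subfamily = paste0(fam, "_sub", k),
                   size = s$size,
                   n_diagnostics = nrow(s$diagnostics),
                   age_non_cpg_My = est$age_non_cpg_My,
                   age_cpg_My = est$age_cpg_My,
                   age_mean_My = est$age_mean_My,
                   stringsAsFactors = FALSE)
      }))
    }))
    write_tsv(sub_df, file.path(config$out_dir, "subfamilies.tsv"))
  }

  # ---- nested insertions / relative activity ----
  tint <- detect_nested_insertions(focal_ann,
                                   min_extension = config$tint_min_extension)
  activity <- tryCatch(
    estimate_activity_periods(tint),
    error = function(e) NULL)
  utils::write.table(tint$counts,
                     file.path(config$out_dir, "tint_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(activity)) {
    act_df <- do.call(rbind, lapply(activity, function(a) {
      data.frame(family = a$family, mu = a$mu, sigma = a$sigma,
                 p75_lo = a$p75[1], p75_hi = a$p75[2],
                 p99_lo = a$p99[1], p99_hi = a$p99[2],
                 stringsAsFactors = FALSE)
    }))
    write_tsv(act_df, file.path(config$out_dir, "activity.tsv"))
  }

  # ---- manifest ----
  manifest <- list(
    package = "cansine",
    version = as.character(utils::packageVersion("cansine")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("out_dir", "simulate", "genome_paths",
                                  "annotation_paths", "consensus_path"))],
    simulated = !is.null(config$simulate),
    n_candidates = nrow(candidates),
    n_specific = length(screen$specific),
    n_ambiguous = length(screen$ambiguous))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$md5 <- unname(tools::md5sum(manifest_path))

  list(summaries = summaries, candidates = candidates, screen = screen,
       specific = specific, tsd = tsd_report, tsd_summary = tsd_summary,
       subfamilies = subfam, networks = networks, ages = ages,
       tint = tint, activity = activity, manifest = manifest,
       truth = if (!is.null(sim)) sim$truth else NULL,
       out_dir = config$out_dir)
}
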