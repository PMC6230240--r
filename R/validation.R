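#' Evaluate the lineage-specific screen against simulation truth
#'
#' Runs the candidate selection and orthologous presence/absence screen on
#' a simulated data set and scores the calls against the recorded ground
#' truth: sensitivity is the fraction of screened candidates truly
#' inserted on the focal terminal branch that are recovered as
#' lineage-specific, and the false-specific rate is the fraction of
#' specific calls that are not truly focal-branch insertions.
#'
#' @param sim result of [simulate_caniform_genomes()].
#' @param focal focal species (default "panda").
#' @param min_len_bp,max_div_pct candidate filters applied per subfamily.
#' @param params an [ortholog_params()].
#' @return list with `sensitivity`, `false_specific_rate`, `n_specific`,
#'   `n_truth_screened`, `n_candidates`, and the raw `screen` result.
#' @export
evaluate_screen_recovery <- function(sim, focal = "panda",
                                     min_len_bp = 150, max_div_pct = 10,
                                     params = ortholog_params()) {
  ann <- sim$annotations[[focal]]
  cand <- do.call(rbind, lapply(unique(ann$family), function(fam) {
    select_young_elements(ann, fam, min_len_bp, max_div_pct)
  }))
  cand <- repeat_annotations(cand)
  others <- setdiff(names(sim$assemblies), focal)
  targets <- lapply(others, function(sp) {
    list(genome = sim$assemblies[[sp]],
         annotations = sim$annotations[[sp]])
  })
  names(targets) <- others
  screen <- ortholog_screen(sim$assemblies[[focal]], cand, targets, params,
                            focal_annotations = ann)
  truth <- sim$truth$insertions
  truth_specific <- truth$id[truth$branch == focal]
  screened_truth <- intersect(cand$element_id, truth_specific)
  tp <- sum(screen$specific %in% truth_specific)
  fp <- sum(!screen$specific %in% truth_specific)
  list(sensitivity = tp / length(screened_truth),
       false_specific_rate = if (length(screen$specific))
         fp / length(screen$specific) else 0,
       n_specific = length(screen$specific),
       n_truth_screened = length(screened_truth),
       n_candidates = nrow(cand),
       screen = screen)
}

#' Evaluate TSD recovery against simulation truth
#'
#' Scans every unfragmented element the focal genome carries whose
#' insertion is at most `max_age_My` old and reports the fraction with a
#' detected target site duplication.
#'
#' @param sim result of [simulate_caniform_genomes()].
#' @param focal focal species.
#' @param max_age_My age cutoff in My (default 10).
#' @return list with `recovery`, `n_found`, `n_scanned`.
#' @export
evaluate_tsd_recovery <- function(sim, focal = "panda", max_age_My = 10) {
  ann <- sim$annotations[[focal]]
  truth <- sim$truth$insertions
  young <- truth[grepl(focal, truth$species, fixed = TRUE) &
                   truth$time_My <= max_age_My, ]
  genome <- sim$assemblies[[focal]]
  found <- 0L
  tot <- 0L
  for (id in young$id) {
    a <- ann[ann$element_id == id, ]
    if (nrow(a) != 1L) next
    fl <- extract_tsd_flanks(genome, a)
    tot <- tot + 1L
    if (find_tsd(fl$left_flank, fl$right_flank)$found) found <- found + 1L
  }
  list(recovery = if (tot) found / tot else NA_real_,
       n_found = found, n_scanned = tot)
}
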