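# Orchestration of the simulation-based validation: generate planted-
# inversion pairs, realign, scan, and score, per inversion-size class.

#' Run one size class of the simulation study
#'
#' Generates \code{n_pairs} diverged sequence pairs, plants one inversion of
#' \code{inversion_length} bp in one sequence of each pair, realigns, scans
#' with the given difference densities, and scores calls against the truth.
#' The simulated divergence is calibrated so that the realised difference
#' density matches \code{p_d}: substitutions per site are
#' \code{p_d / (1 + indel_sub_ratio)}, which makes mismatches plus gap
#' blocks per site approach \code{p_d} and gap blocks per site approach
#' \code{indel_sub_ratio} times the substitution rate.
#'
#' @param inversion_length planted inversion length (bp).
#' @param n_pairs number of pairs.
#' @param root_length root sequence length (default 1000).
#' @param base_comp base composition (A, T, C, G); default human-chimp-like.
#' @param p_d,p_g difference densities used both to calibrate the simulator
#'   and as the scanner's null model (defaults 0.0100 and 0.00150).
#' @param engine realignment engine ("internal" or "mafft").
#' @param seed RNG seed.
#' @param cfg a \code{\link{detector_config}}.
#' @param alpha,extension candidate-region parameters.
#' @param scoring internal-aligner scoring.
#' @param keep_sets return the simulated records too?
#' @return an \code{eval_report} with extra fields \code{aligned_bp} (total
#'   alignment columns scanned) and, if requested, \code{sets}.
#' @export
run_sensitivity_study <- function(inversion_length, n_pairs,
                                  root_length = 1000L,
                                  base_comp = c(A = 0.289, T = 0.304,
                                                C = 0.203, G = 0.204),
                                  p_d = 0.0100, p_g = 0.00150,
                                  engine = c("internal", "mafft"),
                                  seed = NULL, cfg = detector_config(),
                                  alpha = 0.05, extension = 50L,
                                  scoring = align_scoring(),
                                  keep_sets = FALSE) {
  engine <- match.arg(engine)
  scfg <- sim_config(root_length = root_length, base_comp = base_comp,
                     subs_per_site = p_d / (1 + 0.159),
                     inversion_length = inversion_length,
                     n_pairs = n_pairs, seed = seed)
  sets <- make_simulation_set(scfg, engine = engine, scoring = scoring)
  rates <- rate_params(p_d, p_g)
  calls_list <- vector("list", length(sets))
  truths <- data.frame(pair = vapply(sets, function(s) s$pair$id, ""),
                       start = vapply(sets, function(s) s$sim$truth_start, 0),
                       end = vapply(sets, function(s) s$sim$truth_end, 0),
                       length = inversion_length, stringsAsFactors = FALSE)
  aligned_bp <- 0
  for (i in seq_along(sets)) {
    cl <- scan_pair(sets[[i]]$pair, rates, cfg, alpha, extension)
    aligned_bp <- aligned_bp + nchar(sets[[i]]$pair$text_a)
    if (nrow(cl) > 0L) cl$pair <- sets[[i]]$pair$id
    calls_list[[i]] <- cl
  }
  calls <- do.call(rbind, Filter(function(x) nrow(x) > 0L, calls_list))
  if (is.null(calls)) {
    calls <- empty_calls(); calls$pair <- character(0)
  }
  rep <- score_simulation(calls, truths,
                          inversion_length = as.integer(inversion_length))
  rep$aligned_bp <- aligned_bp
  rep$calls <- calls
  if (keep_sets) rep$sets <- sets
  rep
}

#' Summarise several size-class reports as a table
#'
#' @param reports list of \code{eval_report}.
#' @return data frame with one row per size class.
#' @export
study_table <- function(reports) {
  data.frame(inversion_length = vapply(reports, `[[`, 0L,
                                       "inversion_length"),
             n_pairs = vapply(reports, `[[`, 0L, "n_pairs"),
             tp = vapply(reports, `[[`, 0L, "true_positives"),
             fn = vapply(reports, `[[`, 0L, "false_negatives"),
             fp = vapply(reports, `[[`, 0L, "false_positives"),
             sensitivity = vapply(reports, `[[`, 0, "sensitivity"),
             ppv = vapply(reports, `[[`, 0, "ppv"),
             aligned_bp = vapply(reports, function(r)
               if (is.null(r$aligned_bp)) NA_real_ else r$aligned_bp, 0))
}
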