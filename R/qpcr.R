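#' ChIP-qPCR relative enrichment (input-corrected ddCt)
#'
#' Fold enrichment of a target over a reference (unmarked) gene from Ct
#' values, with the primer-pair difference corrected by the input-template
#' amplification:
#' `fold = E^-((Ct_IP,target - Ct_input,target) - (Ct_IP,ref - Ct_input,ref))`
#' with amplification efficiency `E` (default 2, perfect doubling).
#' Technical duplicate rows within one biological replicate are averaged
#' on the Ct scale first; fold values are then computed per biological
#' replicate and summarised as mean +/- standard error (SE undefined for a
#' single replicate).
#'
#' @param ct Ct table from [read_ct()].
#' @param target,reference gene labels present in `ct$target`.
#' @param antibody antibody/stage to use; may be omitted when the table
#'   holds a single antibody.
#' @param efficiency per-cycle amplification factor.
#' @return one-row data.frame: `target`, `reference`, `antibody`,
#'   `n_replicates`, `fold`, `se`.
#' @export
chip_enrichment <- function(ct, target, reference, antibody = NULL,
                            efficiency = 2) {
  if (is.null(antibody)) {
    ab <- unique(ct$antibody)
    if (length(ab) != 1L)
      stop("multiple antibodies present; specify 'antibody'")
    antibody <- ab
  }
  ct <- ct[ct$antibody == antibody, , drop = FALSE]
  cell <- function(gene, template, rep) {
    v <- ct$ct[ct$target == gene & ct$template == template &
                 ct$replicate == rep]
    if (length(v) == 0L)
      stop("missing Ct for (", gene, ", ", antibody, ", ", template,
           ", replicate ", rep, ")")
    mean(v)  # technical duplicates averaged on the Ct scale
  }
  reps <- sort(unique(ct$replicate[ct$target %in% c(target, reference)]))
  if (length(reps) == 0L) stop("no replicates found for target/reference")
  folds <- vapply(reps, function(r) {
    ddct <- (cell(target, "IP", r) - cell(target, "input", r)) -
      (cell(reference, "IP", r) - cell(reference, "input", r))
    efficiency^(-ddct)
  }, numeric(1))
  data.frame(target = target, reference = reference, antibody = antibody,
             n_replicates = length(folds), fold = mean(folds),
             se = if (length(folds) >= 2L) sd(folds) / sqrt(length(folds))
                  else NA_real_,
             stringsAsFactors = FALSE)
}

#' Sequential ChIP (reChIP) qPCR enrichment
#'
#' Identical input-corrected ddCt arithmetic applied to second-round
#' immunoprecipitate Cts, quantifying simultaneous presence of two marks
#' on the same chromatin against a gene carrying neither mark.
#'
#' @inheritParams chip_enrichment
#' @export
sequential_chip_enrichment <- function(ct, target, reference,
                                       antibody = NULL, efficiency = 2) {
  chip_enrichment(ct, target, reference, antibody = antibody,
                  efficiency = efficiency)
}
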