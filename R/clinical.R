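#' Published clinical branch counts
#'
#' Branch-level evaluation counts from a published ten-case clinical study
#' of pulmonary artery-vein separation on thoracic CT (five reported cases,
#' two lungs each): total and misjudged branch counts per lung together
#' with the accuracy percentages as printed. Used as worked examples of the
#' branch-accuracy arithmetic; note that several printed accuracy cells
#' deviate slightly from `100 * (total - misjudged) / total`, so only the
#' self-consistent cells serve as exact references.
#'
#' @return A tibble with columns `dataset`, `n_layers`, `left_total`,
#'   `left_misjudged`, `right_total`, `right_misjudged`,
#'   `left_acc_printed`, `right_acc_printed`, `runtime_s`.
#' @export
clinical_branch_counts <- function() {
  path <- system.file("extdata", "clinical_branch_counts.csv", package = "avsep",
                      mustWork = TRUE)
  as_tibble(utils::read.csv(path))
}
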