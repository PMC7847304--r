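#' Canonical ROI sets
#'
#' Region-of-interest label sets shipped with the package so that edge
#' identifiers are stable across runs. `roi_set("social")` returns the 16
#' regions implicated in pair-bond formation and maintenance (anterior
#' cingulate cortex through ventral hippocampus, in canonical order);
#' `roi_set("control")` returns the 9-region control set of structures not
#' expected to be involved in social behavior.
#'
#' @param which `"social"` (16 ROIs, the default) or `"control"` (9 ROIs).
#' @return Character vector of ROI labels.
#' @examples
#' roi_set()
#' length(roi_set("control"))
#' @export
roi_set <- function(which = c("social", "control")) {
  which <- match.arg(which)
  if (which == "social") {
    c("ACC", "AON", "BLA", "BNST", "LS", "MeA", "MOB", "mPFC",
      "NAcc", "RSC", "PVN", "VP", "VTA", "DG", "dHIP", "vHIP")
  } else {
    c("AUDp", "CBX", "fmi", "LD", "MOp", "MY", "SSs", "VISp", "Vent")
  }
}
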