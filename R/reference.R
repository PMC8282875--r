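#' Published per-slice evaluation table
#'
#' The per-slice object counts of the reference evaluation on the authors'
#' 14-slice in vivo stack (slices at depths 29-40, 45, 50 um): true
#' positives, false positives, and false negatives (certainty-split) at the
#' global relative quality threshold 0.970 and at each slice-specific
#' optimum. `best_without` marks the slice optimum excluding uncertain
#' objects, `best_with` the optimum including them. Shipped as plain CSV in
#' `inst/extdata/reference_thresholds.csv`.
#'
#' @return data.frame with columns `slice`, `threshold`, `tp`,
#'   `tp_uncertain`, `fp`, `fn`, `fn_uncertain`, `best_without`,
#'   `best_with`.
#' @export
reference_threshold_table <- function() {
  path <- system.file("extdata", "reference_thresholds.csv",
                      package = "msmseg", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Slice-specific optimal quality thresholds
#'
#' @param with_uncertain use the optima including uncertain objects
#'   (default) or excluding them.
#' @return named numeric vector of per-slice optimal thresholds.
#' @export
reference_optimal_thresholds <- function(with_uncertain = TRUE) {
  tab <- reference_threshold_table()
  sel <- if (with_uncertain) tab$best_with else tab$best_without
  stats::setNames(tab$threshold[sel], tab$slice[sel])
}
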