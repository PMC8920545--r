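#' Relative expression by the 2^-ddCt method
#'
#' Per record, `dCt = Ct_target - Ct_reference` (target cycles against
#' the housekeeping gene); `ddCt` is the mean treated `dCt` minus the
#' mean control `dCt`; the relative expression is `2^-ddCt`. Swapping the
#' groups inverts the fold change exactly, and any constant added to both
#' the target and reference Ct of every record cancels.
#'
#' Per-replicate fold changes (each treated replicate against the mean
#' control `dCt`) are returned alongside, with their mean and SD, for
#' mean-plus-minus-SD style summaries.
#'
#' @param treated,control data.frames with numeric columns `ct_target`
#'   and `ct_reference` (positive, finite), one row per replicate.
#' @return List with `fold_change`, `ddct`, `dct_treated`,
#'   `dct_control`, `per_replicate_fold`, `fold_mean`, `fold_sd`.
#' @export
fold_change_ddct <- function(treated, control) {
  dct <- function(x, what) {
    stopifnot(is.data.frame(x),
              all(c("ct_target", "ct_reference") %in% colnames(x)))
    if (nrow(x) == 0L) stop("empty ", what, " record list")
    ct_t <- as.numeric(x$ct_target)
    ct_r <- as.numeric(x$ct_reference)
    if (any(!is.finite(ct_t)) || any(!is.finite(ct_r)) ||
        any(ct_t <= 0) || any(ct_r <= 0)) {
      stop("Ct values must be positive and finite")
    }
    ct_t - ct_r
  }
  dct_t <- dct(treated, "treated")
  dct_c <- dct(control, "control")
  ddct <- mean(dct_t) - mean(dct_c)
  per_rep <- 2^-(dct_t - mean(dct_c))
  list(fold_change = 2^-ddct,
       ddct = ddct,
       dct_treated = dct_t,
       dct_control = dct_c,
       per_replicate_fold = per_rep,
       fold_mean = mean(per_rep),
       fold_sd = stats::sd(per_rep))
}
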