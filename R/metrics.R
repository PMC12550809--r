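# shared regression metrics (logB scale throughout)

#' Root mean squared error
#' @param truth,pred numeric vectors of equal length.
#' @export
rmse <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  sqrt(mean((truth - pred)^2))
}

#' Coefficient of determination
#'
#' R^2 = 1 - SS_res / SS_tot with SS_tot about the mean of `truth` on the
#' evaluated subset; can be negative for models worse than the mean.
#' @param truth,pred numeric vectors of equal length.
#' @export
r_squared <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / ss_tot
}

# seeded k-fold assignment, balanced sizes, reproducible under set.seed
make_folds <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep_len(seq_len(k), n))
}
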