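## Relative quantification of qPCR data by the delta-delta-Ct method.

check_ct_table <- function(ct) {
  need <- c("sample", "gene", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct)))
    stop_invalid("ct table must have columns sample, gene, ct")
  if (any(ct$ct <= 0)) stop_invalid("Ct values must be > 0")
  invisible(ct)
}

ct_cell <- function(ct, sample, gene) {
  v <- ct$ct[ct$sample == sample & ct$gene == gene]
  if (!length(v))
    stop_invalid(sprintf("no Ct values for sample '%s', gene '%s'",
                         sample, gene))
  v
}

#' Relative expression by the delta-delta-Ct method
#'
#' Replicate Ct values are averaged per (sample, gene);
#' `dCt_s = mean Ct(target, s) - mean Ct(reference, s)`,
#' `ddCt = dCt_test - dCt_calibrator`, and relative expression
#' `RQ = 2^(-ddCt)` (amplification efficiency fixed at 2). Replicate spread
#' is propagated to a standard error on ddCt.
#'
#' @param ct long-format data.frame with columns `sample`, `gene`, `ct` (one
#'   row per replicate well).
#' @param target target gene id.
#' @param reference reference gene id (e.g. GAPDH).
#' @param calibrator calibrator sample (e.g. "wildtype").
#' @param test test sample (e.g. "mutant").
#' @return one-row data.frame: `gene`, `ddct`, `rq`, `se_ddct`,
#'   `n_replicates`.
#' @examples
#' ct <- data.frame(
#'   sample = c("mutant", "mutant", "wildtype", "wildtype"),
#'   gene = c("ces1", "GAPDH", "ces1", "GAPDH"),
#'   ct = c(25, 20, 24, 20))
#' delta_delta_ct(ct, "ces1", "GAPDH", "wildtype", "mutant")  # ddct 1, rq 0.5
#' @export
delta_delta_ct <- function(ct, target, reference = "GAPDH",
                           calibrator = "wildtype", test = "mutant") {
  check_ct_table(ct)
  tt <- ct_cell(ct, test, target)
  tr <- ct_cell(ct, test, reference)
  ct_ <- ct_cell(ct, calibrator, target)
  cr <- ct_cell(ct, calibrator, reference)
  ddct <- (mean(tt) - mean(tr)) - (mean(ct_) - mean(cr))
  se2 <- function(v) if (length(v) > 1L) stats::var(v) / length(v) else 0
  se <- sqrt(se2(tt) + se2(tr) + se2(ct_) + se2(cr))
  data.frame(gene = target, ddct = ddct, rq = 2^(-ddct), se_ddct = se,
             n_replicates = length(tt), stringsAsFactors = FALSE)
}

#' delta-delta-Ct for every target gene in a table
#'
#' @inheritParams delta_delta_ct
#' @return data.frame, one row per non-reference gene.
#' @export
qpcr_relative_expression <- function(ct, reference = "GAPDH",
                                     calibrator = "wildtype",
                                     test = "mutant") {
  check_ct_table(ct)
  targets <- setdiff(unique(ct$gene), reference)
  out <- do.call(rbind, lapply(targets, delta_delta_ct, ct = ct,
                               reference = reference,
                               calibrator = calibrator, test = test))
  row.names(out) <- NULL
  out
}

#' Fold-direction report for relative expression results
#'
#' Each gene is reported as a fold value of at least 1 plus its direction:
#' RQ 0.5 becomes "2.0-fold lower" in the test sample, RQ 2.1 "2.1-fold
#' higher"; RQ 1 is "no change". The reciprocal relationship is exact.
#'
#' @param results data.frame with `gene` and `rq` (from
#'   [qpcr_relative_expression()]).
#' @return data.frame with `gene`, `rq`, `fold`, `direction`, `label`.
#' @export
fold_report <- function(results) {
  if (!nrow(results)) stop_invalid("results must be non-empty")
  rq <- results$rq
  fold <- ifelse(rq >= 1, rq, 1 / rq)
  direction <- ifelse(rq > 1, "higher", ifelse(rq < 1, "lower", "no change"))
  label <- ifelse(direction == "no change",
                  "1.0-fold (no change)",
                  sprintf("%.1f-fold %s", fold, direction))
  data.frame(gene = results$gene, rq = rq, fold = fold,
             direction = direction, label = label, stringsAsFactors = FALSE)
}

#' Read a long-format Ct table (CSV with sample, gene, ct columns)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  check_ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
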