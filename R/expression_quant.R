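## FPKM quantification and threshold-based expression / differential calls.

#' Fragments per kilobase per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length_nt * total_mapped)`. Plain FPKM on the
#' annotated transcript length; no effective-length correction.
#'
#' @param count fragment count(s), non-negative.
#' @param length_nt transcript length(s) in nucleotides, > 0.
#' @param total_mapped total mapped fragments in the library, > 0.
#' @return FPKM value(s).
#' @examples
#' compute_fpkm(50, 2000, 4e7)  # 0.625
#' @export
compute_fpkm <- function(count, length_nt, total_mapped) {
  if (any(length_nt <= 0)) stop_invalid("length_nt must be > 0")
  if (any(total_mapped <= 0)) stop_invalid("total_mapped must be > 0")
  as.double(count) * 1e9 / (as.double(length_nt) * as.double(total_mapped))
}

#' Strict FPKM expression call
#'
#' A gene counts as expressed when its FPKM strictly exceeds the threshold;
#' FPKM exactly at the threshold is not expressed.
#'
#' @param fpkm FPKM value(s), >= 0.
#' @param threshold expression cutoff (default 5).
#' @return logical vector.
#' @export
call_expressed <- function(fpkm, threshold = 5) {
  if (any(fpkm < 0)) stop_invalid("fpkm must be >= 0")
  fpkm > threshold
}

#' Two-direction fold-ratio differential call
#'
#' Genes expressed (strictly above `fpkm_threshold`) in neither condition are
#' `not_expressed`. Among the remainder, ratio mutant/wildtype strictly above
#' `ratio_threshold` is `up_in_mutant`, strictly below `1/ratio_threshold` is
#' `up_in_wildtype`, otherwise `unchanged`. A zero wildtype FPKM with an
#' expressed mutant side is the limiting ratio +Inf (up_in_mutant), and
#' symmetrically for the other side.
#'
#' @param fpkm_mut,fpkm_wt FPKM vectors for the two conditions.
#' @param ratio_threshold fold threshold, > 1 (default 2; the down direction
#'   is its reciprocal).
#' @param fpkm_threshold expression cutoff (default 5).
#' @return factor with levels up_in_mutant, up_in_wildtype, unchanged,
#'   not_expressed.
#' @export
call_differential <- function(fpkm_mut, fpkm_wt, ratio_threshold = 2,
                              fpkm_threshold = 5) {
  if (ratio_threshold <= 1) stop_invalid("ratio_threshold must exceed 1")
  expressed <- call_expressed(fpkm_mut, fpkm_threshold) |
    call_expressed(fpkm_wt, fpkm_threshold)
  ratio <- ifelse(fpkm_wt == 0,
                  ifelse(fpkm_mut == 0, 1, Inf),
                  fpkm_mut / fpkm_wt)
  call <- ifelse(!expressed, "not_expressed",
          ifelse(ratio > ratio_threshold, "up_in_mutant",
          ifelse(ratio < 1 / ratio_threshold, "up_in_wildtype", "unchanged")))
  factor(call, levels = c("up_in_mutant", "up_in_wildtype",
                          "unchanged", "not_expressed"))
}

#' Quantify a two-condition count table
#'
#' Computes per-condition FPKM from fragment counts and transcript lengths,
#' then applies the expression and differential calls. By default the library
#' size for each condition is the column sum of the supplied table.
#'
#' @param counts data.frame with columns `gene_id`, `length_nt`, `count_mut`,
#'   `count_wt`.
#' @param total_mut,total_wt library sizes (mapped fragments); default column
#'   sums.
#' @inheritParams call_differential
#' @return data.frame (class `gene_quant`) with FPKM, expression flags and
#'   the differential `call` per gene.
#' @export
quantify_expression <- function(counts, total_mut = NULL, total_wt = NULL,
                                ratio_threshold = 2, fpkm_threshold = 5) {
  need <- c("gene_id", "length_nt", "count_mut", "count_wt")
  if (!is.data.frame(counts) || !all(need %in% names(counts)))
    stop_invalid("counts must have gene_id, length_nt, count_mut, count_wt")
  total_mut <- total_mut %||% sum(counts$count_mut)
  total_wt <- total_wt %||% sum(counts$count_wt)
  fpkm_mut <- compute_fpkm(counts$count_mut, counts$length_nt, total_mut)
  fpkm_wt <- compute_fpkm(counts$count_wt, counts$length_nt, total_wt)
  out <- data.frame(
    gene_id = counts$gene_id,
    length_nt = counts$length_nt,
    count_mut = counts$count_mut,
    count_wt = counts$count_wt,
    fpkm_mut = fpkm_mut,
    fpkm_wt = fpkm_wt,
    expressed_mut = call_expressed(fpkm_mut, fpkm_threshold),
    expressed_wt = call_expressed(fpkm_wt, fpkm_threshold),
    call = call_differential(fpkm_mut, fpkm_wt, ratio_threshold,
                             fpkm_threshold),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_quant", "data.frame")
  out
}

#' Scatter table of expressed genes
#'
#' One row per gene expressed in at least one condition, mutant FPKM first
#' (the x axis of the comparative scatter plot).
#'
#' @param quants a `gene_quant` table from [quantify_expression()].
#' @return data.frame with `gene_id`, `fpkm_mut`, `fpkm_wt`.
#' @export
scatter_table <- function(quants) {
  keep <- quants$expressed_mut | quants$expressed_wt
  out <- quants[keep, c("gene_id", "fpkm_mut", "fpkm_wt"), drop = FALSE]
  row.names(out) <- NULL
  out
}

#' @export
print.gene_quant <- function(x, ...) {
  cat(sprintf("Gene quantification: %d genes\n", nrow(x)))
  print(table(call = x$call))
  invisible(x)
}

#' Read a two-condition count table (TSV)
#'
#' @param path TSV with columns gene_id, length_nt, count_mut, count_wt.
#' @return data.frame.
#' @export
read_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a table as TSV
#' @param x data.frame. @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
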