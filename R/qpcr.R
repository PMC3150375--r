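#' Fit a qPCR standard curve
#'
#' Least-squares line Ct = m log10(amount) + b over a dilution series,
#' fitted with `stats::lm`. Amplification efficiency is 10^(-1/m) - 1
#' (m = -3.3219 corresponds to perfect doubling, efficiency 1). Curves with
#' r^2 below `min_r2` or a non-negative slope (Ct must fall as template
#' rises) are rejected.
#'
#' @param standards data.frame with columns `log10_amount` and `ct`, at
#'   least 3 distinct dilutions.
#' @param min_r2 minimum admissible r^2 (default 0.98).
#' @return an object of class `standard_curve`: `slope`, `intercept`, `r2`,
#'   `efficiency`.
#' @export
fit_standard_curve <- function(standards, min_r2 = 0.98) {
  need <- c("log10_amount", "ct")
  if (!all(need %in% names(standards))) {
    stop_invalid("standards need columns %s", paste(need, collapse = ", "))
  }
  if (length(unique(standards$log10_amount)) < 3) {
    stop_invalid("standard curve needs >= 3 distinct dilutions")
  }
  fit <- stats::lm(ct ~ log10_amount, data = standards)
  slope <- unname(stats::coef(fit)[2]); intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0) {
    stop_invalid("standard-curve slope must be negative (got %.3f): Ct must fall with template amount", slope)
  }
  # r^2 from residuals directly (summary.lm warns on exact synthetic series)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((standards$ct - mean(standards$ct))^2)
  if (r2 < min_r2) {
    stop_invalid("standard curve rejected: r^2 = %.4f < %.2f (slope %.3f, intercept %.2f)",
                 r2, min_r2, slope, intercept)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' Standard-curve relative expression
#'
#' Converts Ct values to relative template amounts through each gene's
#' standard curve, amount = 10^((Ct - b)/m), normalizes each gene to the
#' reference gene within the same sample, and expresses each sample's ratio
#' as a fold over the control sample.
#'
#' @param records data.frame with columns `sample`, `gene`, `ct` (one row
#'   per reaction; technical replicates may repeat rows and are averaged on
#'   the Ct scale).
#' @param curves named list of [fit_standard_curve()] results, one per gene
#'   (reference gene included).
#' @param reference_gene normalizer gene, default `"Gapdh"`.
#' @param control_sample sample label whose ratio defines fold = 1.
#' @return data.frame with columns `sample`, `gene`, `amount`,
#'   `amount_over_reference`, `fold_vs_control`.
#' @export
relative_expression <- function(records, curves, reference_gene = "Gapdh",
                                control_sample) {
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(records))) {
    stop_invalid("records need columns %s", paste(need, collapse = ", "))
  }
  if (!control_sample %in% records$sample) {
    stop_invalid("control sample '%s' not present in records", control_sample)
  }
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = records, FUN = mean)
  amount_of <- function(gene, ct) {
    cur <- curves[[gene]]
    if (is.null(cur)) stop_invalid("no standard curve for gene '%s'", gene)
    10^((ct - cur$intercept) / cur$slope)
  }
  mean_ct$amount <- mapply(amount_of, mean_ct$gene, mean_ct$ct)
  ref <- mean_ct[mean_ct$gene == reference_gene, c("sample", "amount")]
  names(ref)[2] <- "ref_amount"
  out <- merge(mean_ct, ref, by = "sample", all.x = TRUE)
  missing_ref <- is.na(out$ref_amount)
  if (any(missing_ref)) {
    warning(sprintf("skipping %d record(s) without reference gene '%s' in their sample",
                    sum(missing_ref), reference_gene), call. = FALSE)
    out <- out[!missing_ref, ]
  }
  out$amount_over_reference <- out$amount / out$ref_amount
  ctrl <- out[out$sample == control_sample, c("gene", "amount_over_reference")]
  names(ctrl)[2] <- "ctrl_ratio"
  out <- merge(out, ctrl, by = "gene", all.x = TRUE)
  out$fold_vs_control <- out$amount_over_reference / out$ctrl_ratio
  out <- out[order(out$gene, out$sample),
             c("sample", "gene", "amount", "amount_over_reference", "fold_vs_control")]
  rownames(out) <- NULL
  out
}
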