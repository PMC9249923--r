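#' Livak relative expression with multi-reference normalization
#'
#' Classic delta-delta-Ct quantification with amplification efficiency
#' fixed at 2: per sample, delta-Ct is the target Ct minus the arithmetic
#' mean of the reference-gene Cts (equivalent to normalizing expression to
#' the geometric mean of the references); delta-delta-Ct subtracts the mean
#' delta-Ct over the calibrator condition's samples; fold change is
#' `2^(-ddCt)`.
#'
#' @param ct_table Data frame with columns `sample`, `condition`, `gene`,
#'   `ct` (as produced by [simulate_ct_table] or read from CSV).
#' @param target Target gene name.
#' @param refs Character vector of reference gene names (>= 1).
#' @param calibrator Calibrator condition label.
#' @return Data frame `sample`, `condition`, `fold_change`.
#' @export
livak_relative_expression <- function(ct_table, target, refs, calibrator) {
  stopifnot(all(c("sample", "condition", "gene", "ct") %in% names(ct_table)))
  if (!calibrator %in% ct_table$condition)
    stop("no samples for calibrator condition '", calibrator, "'")
  samples <- unique(ct_table$sample)
  dct <- vapply(samples, function(s) {
    sub <- ct_table[ct_table$sample == s, ]
    tg <- sub$ct[sub$gene == target]
    rf <- sub$ct[match(refs, sub$gene)]
    if (length(tg) != 1 || anyNA(rf))
      stop("target and all reference genes must be measured in sample ", s)
    tg - mean(rf)
  }, numeric(1))
  cond <- ct_table$condition[match(samples, ct_table$sample)]
  ddct <- dct - mean(dct[cond == calibrator])
  data.frame(sample = samples, condition = cond,
             fold_change = 2^(-ddct), row.names = NULL)
}
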