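#' Relative expression by the 2^-ddCt method
#'
#' ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl);
#' relative expression = 2^-ddCt.
#'
#' @param ct_target_case,ct_ref_case,ct_target_ctrl,ct_ref_ctrl Ct values
#'   (vectors recycle).
#' @return Relative expression (case vs control).
#' @export
#' @examples
#' delta_delta_ct(20, 15, 22, 15)  # 4
delta_delta_ct <- function(ct_target_case, ct_ref_case,
                           ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Per-gene qPCR log2 fold-changes from a Ct table
#'
#' Averages replicate Cts per gene and group, then applies the 2^-ddCt
#' method with tall as the control group.
#'
#' @param ct data.frame from [simulate_qpcr()] or [read_qpcr_csv()]:
#'   columns `gene`, `group`, `replicate`, `ct_target`, `ct_reference`.
#' @return data.frame `gene`, `log2fc` (dwarf vs tall).
#' @export
qpcr_log2fc <- function(ct) {
  agg <- stats::aggregate(cbind(ct_target, ct_reference) ~ gene + group,
                          data = ct, FUN = mean)
  tall <- agg[agg$group == "tall", ]
  dwarf <- agg[agg$group == "dwarf", ]
  dwarf <- dwarf[match(tall$gene, dwarf$gene), ]
  rel <- delta_delta_ct(dwarf$ct_target, dwarf$ct_reference,
                        tall$ct_target, tall$ct_reference)
  data.frame(gene = tall$gene, log2fc = log2(rel))
}

#' Concordance of qPCR and RNA-seq fold-changes
#'
#' Squared Pearson correlation of the paired log2 fold-changes.
#'
#' @param qpcr_lfc,rnaseq_lfc paired numeric vectors (>= 3 pairs).
#' @return R-squared.
#' @export
qpcr_concordance <- function(qpcr_lfc, rnaseq_lfc) {
  if (length(qpcr_lfc) != length(rnaseq_lfc) || length(qpcr_lfc) < 3L) {
    stop("need at least 3 paired fold-changes")
  }
  if (stats::sd(qpcr_lfc) == 0 || stats::sd(rnaseq_lfc) == 0) {
    stop("zero variance in a fold-change vector")
  }
  stats::cor(qpcr_lfc, rnaseq_lfc)^2
}
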