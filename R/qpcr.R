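# Comparative-CT (delta-delta-CT) relative quantification for qRT-PCR
# validation, with reference-gene normalization and two-group testing.
#
# dCT  = CT(target) - CT(reference gene, same sample)
# ddCT = dCT(sample) - mean dCT(calibrator)
# RQ   = E^(-ddCT), with amplification efficiency E = 2 in the classic
#        method (one cycle = one doubling).

validate_ct_table <- function(measurements) {
  need <- c("sample_id", "group", "gene", "replicate", "ct_target",
            "ct_reference")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements)))
    stop_input("CT table needs columns ", paste(need, collapse = ", "))
  if (nrow(measurements) == 0L) stop_input("CT table is empty")
  key <- paste(measurements$sample_id, measurements$gene)
  if (anyDuplicated(key))
    stop_input("duplicate (sample, gene) row: ", key[duplicated(key)][1L])
  miss <- is.na(measurements$ct_target) | is.na(measurements$ct_reference)
  if (any(miss))
    stop_input("missing CT for sample ", measurements$sample_id[which(miss)[1L]],
               ", gene ", measurements$gene[which(miss)[1L]])
  ok <- function(v) all(v > 0 & v < 45)
  if (!ok(measurements$ct_target) || !ok(measurements$ct_reference))
    stop_input("CT values must lie in (0, 45) cycles")
  invisible(measurements)
}

#' Relative quantities by the comparative-CT method
#'
#' Computes per-sample dCT, ddCT against a calibrator, and
#' RQ = efficiency^(-ddCT), gene by gene. The calibrator is either a group
#' label (ddCT is taken against that group's mean dCT, so the calibrator
#' group's geometric mean RQ is 1) or a single sample id.
#'
#' @param measurements Long-format data frame with columns `sample_id`,
#'   `group`, `gene`, `replicate`, `ct_target`, `ct_reference`; one row per
#'   biological replicate and gene (technical replicates should be averaged
#'   on the CT scale beforehand).
#' @param calibrator A group label or sample id present in the table.
#' @param efficiency Amplification efficiency per cycle; default 2
#'   (classic comparative-CT).
#' @return Data frame with `sample_id`, `group`, `gene`, `replicate`,
#'   `delta_ct`, `delta_delta_ct`, `rq`.
#' @export
ddct_rq <- function(measurements, calibrator, efficiency = 2) {
  validate_ct_table(measurements)
  if (efficiency <= 1) stop_config("efficiency must exceed 1")
  m <- measurements
  m$delta_ct <- m$ct_target - m$ct_reference
  out <- lapply(split(m, m$gene), function(g) {
    cal <- if (calibrator %in% g$group) g$group == calibrator
           else if (calibrator %in% g$sample_id) g$sample_id == calibrator
           else stop_input("calibrator '", calibrator,
                           "' matches no group or sample for gene ", g$gene[1L])
    cal_dct <- mean(g$delta_ct[cal])
    g$delta_delta_ct <- g$delta_ct - cal_dct
    g$rq <- efficiency^(-g$delta_delta_ct)
    g
  })
  out <- do.call(rbind, out)
  out <- out[order(match(paste(out$sample_id, out$gene),
                         paste(m$sample_id, m$gene))), ]
  rownames(out) <- NULL
  out[, c("sample_id", "group", "gene", "replicate", "delta_ct",
          "delta_delta_ct", "rq")]
}

#' Two-group comparison of relative quantities per gene
#'
#' Two-tailed two-sample t-test of per-replicate values between the two
#' groups, gene by gene. By default the test is on the RQ scale with pooled
#' variance (classic Student t); options give Welch variance or the log2-RQ
#' / dCT scales. Degenerate variance is handled explicitly: if every value
#' in both groups is identical, p = 1; if each group is internally constant
#' but the groups differ (exact separation, zero within-group variance),
#' p = 0 and the row is flagged `degenerate = TRUE` — the t statistic is
#' infinite and no finite p exists.
#'
#' @param rqs Output of [ddct_rq()] (needs `group`, `gene`, and the value
#'   column selected by `on`).
#' @param on Scale for the test: `"rq"` (default), `"log2_rq"`, or
#'   `"delta_ct"`.
#' @param alpha Significance level; default 0.05.
#' @param var_equal Pooled (TRUE, default) or Welch (FALSE) variance.
#' @return Data frame with one row per gene: `gene`, group names and mean
#'   RQs, `fold_change` (first group mean RQ over second), `t`, `df`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
compare_groups <- function(rqs, on = c("rq", "log2_rq", "delta_ct"),
                           alpha = 0.05, var_equal = TRUE) {
  on <- match.arg(on)
  groups <- unique(rqs$group)
  if (length(groups) != 2L)
    stop_input("need exactly two groups, got ", length(groups))
  value_of <- function(g) switch(on,
                                 rq = g$rq,
                                 log2_rq = log2(g$rq),
                                 delta_ct = g$delta_ct)
  out <- lapply(split(rqs, rqs$gene), function(g) {
    v1 <- value_of(g[g$group == groups[1L], , drop = FALSE])
    v2 <- value_of(g[g$group == groups[2L], , drop = FALSE])
    if (length(v1) < 2L || length(v2) < 2L)
      stop_input("gene ", g$gene[1L], ": each group needs >= 2 replicates")
    degenerate <- stats::sd(v1) == 0 && stats::sd(v2) == 0
    if (degenerate) {
      p <- if (mean(v1) == mean(v2)) 1 else 0
      tt <- list(statistic = c(t = if (p == 1) 0 else Inf * sign(mean(v1) - mean(v2))),
                 parameter = c(df = length(v1) + length(v2) - 2), p.value = p)
    } else {
      tt <- stats::t.test(v1, v2, var.equal = var_equal)
    }
    m1 <- mean(g$rq[g$group == groups[1L]])
    m2 <- mean(g$rq[g$group == groups[2L]])
    data.frame(gene = g$gene[1L], group_1 = groups[1L], group_2 = groups[2L],
               mean_rq_1 = m1, mean_rq_2 = m2, fold_change = m1 / m2,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value,
               significant = tt$p.value < alpha,
               degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
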