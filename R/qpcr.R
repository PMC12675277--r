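#' Relative expression level from qPCR crossing points
#'
#' Delta-Ct style relative expression of a target gene against the mean of
#' two reference genes, assuming amplification efficiency 2:
#'
#' \deqn{REL = 2^{(CP_{R1} + CP_{R2})/2} / 2^{CP} = 2^{(CP_{R1}+CP_{R2})/2 - CP}}
#'
#' A target crossing one cycle later than the reference mean halves REL;
#' equal crossing points give REL = 1. Vectorised over records.
#'
#' @param cp_target crossing point(s) of the target gene, cycles; finite,
#'   > 0.
#' @param cp_ref1,cp_ref2 crossing points of the two reference genes,
#'   cycles; finite, > 0.
#' @return Relative expression level(s), dimensionless, strictly positive.
#' @examples
#' compute_rel(18, 20, 22)  # 2^(21 - 18) = 8
#' @export
compute_rel <- function(cp_target, cp_ref1, cp_ref2) {
  if (missing(cp_ref1) || missing(cp_ref2) ||
      is.null(cp_ref1) || is.null(cp_ref2))
    validation_error("both reference crossing points are required")
  for (x in list(cp_target, cp_ref1, cp_ref2))
    if (any(!is.finite(x)) || any(x <= 0))
      validation_error("crossing points must be finite and > 0")
  2^((cp_ref1 + cp_ref2) / 2 - cp_target)
}

#' Nonparametric comparison of groups of measurements
#'
#' Kruskal-Wallis rank-sum comparison across two or more groups (delegated
#' to [stats::kruskal.test()]), with the significance classes used in
#' reporting: `n.s.` for P >= 0.05, `*` for P < 0.05, `**` for P < 0.01,
#' `***` for P < 0.001.
#'
#' @param values named list of numeric vectors, one per group; >= 2
#'   non-empty groups.
#' @return List with `statistic` (H), `df`, `p_value`, `signif`.
#' @export
group_compare <- function(values) {
  if (!is.list(values) || length(values) < 2L)
    validation_error("`values` must be a list of >= 2 groups")
  sizes <- lengths(values)
  if (any(sizes == 0L))
    validation_error("every group must be non-empty")
  kt <- stats::kruskal.test(unname(values))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, signif = significance_class(kt$p.value))
}

#' Significance class of a p-value
#'
#' @param p p-value(s) in [0, 1].
#' @return `"n.s."` for p >= 0.05, `"*"` for p < 0.05, `"**"` for p < 0.01,
#'   `"***"` for p < 0.001.
#' @export
significance_class <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    validation_error("`p` must be in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s.")))
}
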