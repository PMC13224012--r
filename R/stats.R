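#' Unpaired Student's t test
#'
#' Classic equal-variance two-sample t test (`df = n1 + n2 - 2`,
#' two-sided p); Welch's correction available via `var_equal = FALSE`.
#' Two identical constant groups return `t = 0, p = 1`; zero pooled
#' variance with unequal means is an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal pool variances (default TRUE, Student's test).
#' @return list with `t`, `df`, `p`.
#' @export
unpaired_t <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_ms("each group needs at least 2 finite values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2,
                                        p = 1))
    stop_ms("zero variance in both groups with unequal means")
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' One-way ANOVA
#'
#' Standard between/within mean-square decomposition with equal
#' variances assumed. All-identical input returns `F = 0, p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values)
#'   or a single numeric vector with `g` a grouping factor.
#' @param g optional grouping vector when `groups` is a vector.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups, g = NULL) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  if (length(groups) < 2) stop_ms("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop_ms("every group needs >= 2 values")
  values <- unlist(groups)
  df1 <- length(groups) - 1L
  df2 <- length(values) - length(groups)
  if (var(values) == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  ot <- oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ot$statistic), df1 = unname(ot$parameter[1]),
       df2 = unname(ot$parameter[2]), p = ot$p.value)
}

#' Relative qPCR quantification by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; `ddCt` is the
#' sample's dCt minus the mean dCt of the control group; the relative
#' expression level is `2^-ddCt`. The control group's mean ddCt is 0 by
#' construction.
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `Ct`.
#' @param target_gene,reference_gene gene labels (e.g. a mitochondrial
#'   target and a beta-actin-like reference).
#' @param control_group control group label.
#' @return data.frame, one row per sample: `sample`, `group`, `dCt`,
#'   `ddCt`, `rel_level`.
#' @export
ddct_quantify <- function(ct, target_gene, reference_gene, control_group) {
  need <- c("sample", "group", "gene", "Ct")
  if (!all(need %in% names(ct)))
    stop_ms("ct table must have columns ", paste(need, collapse = ", "))
  samples <- unique(ct$sample)
  getct <- function(s, gene) {
    v <- ct$Ct[ct$sample == s & ct$gene == gene]
    if (length(v) != 1 || !is.finite(v))
      stop_ms("sample '", s, "' lacks a single finite Ct for gene '",
              gene, "'")
    v
  }
  dct <- vapply(samples, function(s)
    getct(s, target_gene) - getct(s, reference_gene), 0)
  grp <- ct$group[match(samples, ct$sample)]
  if (!control_group %in% grp) stop_ms("control group is empty")
  ref <- mean(dct[grp == control_group])
  ddct <- dct - ref
  data.frame(sample = samples, group = grp, dCt = unname(dct),
             ddCt = unname(ddct), rel_level = 2^-unname(ddct),
             stringsAsFactors = FALSE, row.names = NULL)
}

.star_code <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Summarize groups of a measurement table against a control
#'
#' Per group: n, mean, median, SEM (`SD/sqrt(n)`), the chosen test vs
#' the control group, and the conventional star code (* p < 0.05,
#' ** p < 0.01, *** p < 0.001). With `test = "anova"` a global one-way
#' ANOVA across all groups is attached as an attribute while per-group
#' stars still come from pairwise comparisons to control. If an
#' `experiment` column is present, `n_experiments` is reported
#' alongside the per-cell n.
#'
#' @param df data.frame.
#' @param value name of the measurement column.
#' @param group name of the grouping column.
#' @param control control group label.
#' @param test `"t"` (unpaired Student's) or `"anova"`.
#' @return `GroupSummary` data.frame; control row has empty p/stars.
#' @export
summarize_groups <- function(df, value, group = "compound",
                             control = "control", test = c("t", "anova")) {
  test <- match.arg(test)
  if (!value %in% names(df)) stop_ms("no column '", value, "'")
  if (!control %in% df[[group]]) stop_ms("control label '", control,
                                         "' not present")
  sp <- split(df[[value]], df[[group]])
  sp <- lapply(sp, function(v) v[is.finite(v)])
  ctrl <- sp[[control]]
  out <- do.call(rbind, lapply(names(sp), function(gname) {
    v <- sp[[gname]]
    n <- length(v)
    p <- if (gname == control) NA_real_ else unpaired_t(v, ctrl)$p
    data.frame(group = gname, n = n, mean = mean(v), median = median(v),
               sem = sd(v) / sqrt(n), p = p, stars = .star_code(p),
               stringsAsFactors = FALSE)
  }))
  out$stars[out$group == control] <- ""
  if ("experiment" %in% names(df)) {
    ne <- vapply(names(sp), function(gname)
      length(unique(df$experiment[df[[group]] == gname])), 0L)
    out$n_experiments <- ne[out$group]
  }
  if (test == "anova")
    attr(out, "anova") <- one_way_anova(sp)
  rownames(out) <- NULL
  out
}
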