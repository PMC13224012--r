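#' Pearson correlation with pair count
#'
#' Product-moment correlation after dropping incomplete pairs.
#'
#' @param x,y numeric vectors.
#' @return list with `r` and `n`; `r` is `NA` with a `reason` attribute
#'   when either side has zero variance.
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_ms("need at least 3 complete pairs (got ", n, ")")
  if (sd(x) == 0 || sd(y) == 0) {
    r <- NA_real_
    attr(r, "reason") <- "zero variance"
    return(list(r = r, n = n))
  }
  list(r = cor(x, y), n = n)
}

#' Fisher r-to-z transform
#'
#' `z_r = atanh(r) = 0.5 * log((1 + r) / (1 - r))`; odd and strictly
#' increasing on (-1, 1).
#'
#' @param r correlation(s) with `|r| < 1`.
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop_ms("fisher_z requires |r| < 1")
  atanh(r)
}

#' Fisher z-test comparing two independent correlations
#'
#' `Z = (z_r1 - z_r2) / sqrt(1/(n1 - 3) + 1/(n2 - 3))`; the one-sided p
#' is the standard-normal tail beyond Z in the observed direction and
#' the two-sided p twice that. Z is antisymmetric under swapping the
#' sides.
#'
#' @param r1,n1,r2,n2 the two correlations and their sample sizes
#'   (`n >= 4`, `|r| < 1`).
#' @param label1,label2 optional side labels carried into the result.
#' @return object of class `CorrelationComparison`: a one-row data.frame
#'   with `r1, n1, r2, n2, Z, p_one_sided, p_two_sided` (+ labels).
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2,
                                             label1 = "side1",
                                             label2 = "side2") {
  if (n1 <= 3 || n2 <= 3) stop_ms("both sample sizes must be >= 4")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop_ms("|r| must be < 1")
  Z <- (fisher_z(r1) - fisher_z(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p1 <- pnorm(-abs(Z))
  out <- data.frame(label1 = label1, label2 = label2,
                    r1 = r1, n1 = n1, r2 = r2, n2 = n2, Z = Z,
                    p_one_sided = p1, p_two_sided = min(2 * p1, 1),
                    test = "fisher_z_independent",
                    stringsAsFactors = FALSE)
  class(out) <- c("CorrelationComparison", class(out))
  out
}

#' Fisher confidence interval for a correlation
#'
#' `z_r +/- qnorm(1 - alpha/2) / sqrt(n - 3)`, back-transformed.
#'
#' @param r correlation, `|r| < 1`.
#' @param n sample size (> 3).
#' @param level confidence level.
#' @return length-2 vector (lower, upper).
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3) return(c(NA_real_, NA_real_))
  zc <- qnorm(1 - (1 - level) / 2)
  tanh(atanh(r) + c(-1, 1) * zc / sqrt(n - 3))
}

#' Redox-coupling profile of a single-cell screen table
#'
#' For every (cell line, compound, dose) group computes the pooled
#' Pearson correlation and per-image correlations of the MMP--ROS and
#' MMP--mtROS pairs, with Fisher confidence intervals and violin summary
#' statistics (median, quartiles, mean of the per-image r values).
#' Comparisons via [compare_independent_correlations()] are emitted for
#' (i) MMP--ROS vs MMP--mtROS within each group, (ii) each pair across
#' cell lines for the same compound/dose, and (iii) each treatment vs
#' its cell line's control, per pair.
#'
#' Intensities are log1p-transformed before correlating by default:
#' fluorescence intensities are approximately log-normal, and the
#' normal-theory Fisher machinery is calibrated on that scale (set
#' `cor_scale = "linear"` for raw-intensity correlations). The within-
#' group contrast (i) shares the MMP variable between its two
#' correlations; the independent-sample test is still used, matching
#' standard practice, and the shared-variable caveat is flagged in the
#' `test` column metadata.
#'
#' @param cells pooled single-cell table from [pool_screen()].
#' @param value_cols named vector mapping `MMP`, `ROS`, `mtROS` to
#'   column names of `cells`.
#' @param control compound label of the control group.
#' @param cor_scale `"log"` (default, log1p) or `"linear"`.
#' @param min_n groups with fewer complete cells are skipped (with a
#'   message); must be >= 4.
#' @return list with `results` (one row per group x pair x scope,
#'   per-image r values nested in `per_image`), and `comparisons`.
#' @export
coupling_profile <- function(cells,
                             value_cols = c(MMP = "mmp_mito_corrected",
                                            ROS = "ros_corrected",
                                            mtROS = "mtros_mito_corrected"),
                             control = "control",
                             cor_scale = c("log", "linear"),
                             min_n = 4L) {
  cor_scale <- match.arg(cor_scale)
  need <- c(value_cols, "cell_line", "compound", "dose", "well", "field")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop_ms("missing columns: ", paste(miss, collapse = ", "))
  tf <- if (cor_scale == "log") function(x) log1p(x) else identity
  pairs <- list(`MMP-ROS` = c("MMP", "ROS"), `MMP-mtROS` = c("MMP", "mtROS"))
  gid <- interaction(cells$cell_line, cells$compound, cells$dose,
                     drop = TRUE, sep = "|")
  res <- list(); per_image <- list()
  for (g in levels(gid)) {
    sub <- cells[gid == g, , drop = FALSE]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    for (pn in names(pairs)) {
      a <- tf(sub[[value_cols[pairs[[pn]][1]]]])
      b <- tf(sub[[value_cols[pairs[[pn]][2]]]])
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) < min_n) {
        message("skipping group ", g, " pair ", pn, ": n = ", sum(ok))
        next
      }
      pr <- pearson_r(a[ok], b[ok])
      ci <- fisher_ci(pr$r, pr$n)
      img <- interaction(sub$well[ok], sub$field[ok], drop = TRUE)
      rimg <- vapply(levels(img), function(l) {
        sel <- img == l
        if (sum(sel) < min_n) return(NA_real_)
        if (sd(a[ok][sel]) == 0 || sd(b[ok][sel]) == 0) return(NA_real_)
        cor(a[ok][sel], b[ok][sel])
      }, 0)
      rimg <- rimg[!is.na(rimg)]
      key <- paste(g, pn, sep = "|")
      per_image[[key]] <- rimg
      res[[key]] <- data.frame(
        cell_line = parts[1], compound = parts[2],
        dose = as.numeric(parts[3]), pair = pn, scope = "pooled",
        n = pr$n, r = pr$r,
        z_r = if (is.na(pr$r)) NA_real_ else fisher_z(pr$r),
        ci_lo = ci[1], ci_hi = ci[2],
        n_images = length(rimg),
        img_r_mean = if (length(rimg)) mean(rimg) else NA_real_,
        img_r_median = if (length(rimg)) median(rimg) else NA_real_,
        img_r_q25 = if (length(rimg)) quantile(rimg, 0.25, names = FALSE)
                    else NA_real_,
        img_r_q75 = if (length(rimg)) quantile(rimg, 0.75, names = FALSE)
                    else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  comparisons <- .coupling_comparisons(results, control)
  list(results = results, per_image = per_image,
       comparisons = comparisons, cor_scale = cor_scale)
}

.coupling_comparisons <- function(res, control) {
  out <- list()
  gkey <- function(d) paste(d$cell_line, d$compound, d$dose)
  ## (i) within group: MMP-ROS vs MMP-mtROS (shared-variable caveat)
  for (g in unique(gkey(res))) {
    sub <- res[gkey(res) == g, ]
    a <- sub[sub$pair == "MMP-ROS", ]; b <- sub[sub$pair == "MMP-mtROS", ]
    if (nrow(a) == 1 && nrow(b) == 1 && !is.na(a$r) && !is.na(b$r)) {
      cmp <- compare_independent_correlations(
        a$r, a$n, b$r, b$n,
        label1 = paste(g, "MMP-ROS"), label2 = paste(g, "MMP-mtROS"))
      cmp$contrast <- "within_group_pair"
      cmp$test <- "fisher_z_independent (shared MMP variable)"
      out[[length(out) + 1]] <- cmp
    }
  }
  ## (ii) across cell lines, same compound/dose, per pair
  for (pn in unique(res$pair)) {
    sub <- res[res$pair == pn, ]
    for (cd in unique(paste(sub$compound, sub$dose))) {
      ss <- sub[paste(sub$compound, sub$dose) == cd, ]
      if (nrow(ss) == 2 && !anyNA(ss$r)) {
        cmp <- compare_independent_correlations(
          ss$r[1], ss$n[1], ss$r[2], ss$n[2],
          label1 = paste(ss$cell_line[1], cd, pn),
          label2 = paste(ss$cell_line[2], cd, pn))
        cmp$contrast <- "across_cell_lines"
        out[[length(out) + 1]] <- cmp
      }
    }
  }
  ## (iii) each treatment vs control within cell line, per pair
  for (pn in unique(res$pair)) for (cl in unique(res$cell_line)) {
    sub <- res[res$pair == pn & res$cell_line == cl, ]
    ctrl <- sub[sub$compound == control, ]
    if (nrow(ctrl) != 1 || is.na(ctrl$r)) next
    for (i in which(sub$compound != control)) {
      if (is.na(sub$r[i])) next
      cmp <- compare_independent_correlations(
        sub$r[i], sub$n[i], ctrl$r, ctrl$n,
        label1 = paste(cl, sub$compound[i], sub$dose[i], pn),
        label2 = paste(cl, control, pn))
      cmp$contrast <- "treatment_vs_control"
      out[[length(out) + 1]] <- cmp
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}
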