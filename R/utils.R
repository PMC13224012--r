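## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ms <- function(...) stop(..., call. = FALSE)

#' Expand a master seed into per-task child seeds
#'
#' Deterministic linear-congruential mixing of a master seed with a task
#' counter. Children are integers in `[1, 2^31 - 2]`, suitable for
#' `set.seed()`. The scheme is fixed so that a run is reproducible from
#' its master seed alone.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @param stream integer stream offset separating pipeline stages.
#' @return integer vector of `n` child seeds.
#' @export
child_seeds <- function(master, n, stream = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 0)
  if (n == 0) return(integer(0))
  m <- 2147483647 # 2^31 - 1, Mersenne prime (minstd modulus)
  x <- (as.double(master) %% m + 1) * 48271 %% m
  x <- (x + as.double(stream) * 69621) %% m
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (x * 48271 + 1) %% m
    out[i] <- x
  }
  as.integer(out %% (m - 2) + 1)
}

## check a correlation matrix: symmetric, unit diagonal, PSD
check_corr_matrix <- function(rho, name = "rho") {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho))
    stop_ms(name, " must be a square matrix")
  if (max(abs(rho - t(rho))) > 1e-8)
    stop_ms(name, " must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-8)
    stop_ms(name, " must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_ms(name, " is not positive semi-definite (min eigenvalue ",
            format(min(ev), digits = 4), "): ",
            paste(capture_matrix(rho), collapse = "; "))
  invisible(TRUE)
}

capture_matrix <- function(m) {
  apply(m, 1, function(r) paste(format(r, digits = 3), collapse = " "))
}

## disc brush cache (EBImage makeBrush discs are reused heavily)
.brush_cache <- new.env(parent = emptyenv())

disc_brush <- function(radius) {
  key <- as.character(radius)
  if (is.null(.brush_cache[[key]])) {
    .brush_cache[[key]] <- EBImage::makeBrush(2L * as.integer(radius) + 1L,
                                              shape = "disc")
  }
  .brush_cache[[key]]
}

## fast per-label sums over an integer label matrix (0 = background)
label_sums <- function(values, labels, nlab = max(labels)) {
  if (nlab == 0) return(numeric(0))
  idx <- labels > 0L
  rs <- rowsum(as.numeric(values[idx]), group = labels[idx])
  s <- numeric(nlab)
  s[as.integer(rownames(rs))] <- rs[, 1L]
  s
}

label_areas <- function(labels, nlab = max(labels)) {
  if (nlab == 0) return(integer(0))
  tab <- tabulate(labels[labels > 0L], nbins = nlab)
  tab
}

## bounding box (row/col ranges) per label
label_bboxes <- function(labels) {
  nlab <- max(labels)
  if (nlab == 0) return(list())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rr <- (idx - 1L) %% nrow(labels) + 1L
  cc <- (idx - 1L) %/% nrow(labels) + 1L
  lapply(seq_len(nlab), function(k) {
    sel <- lab == k
    if (!any(sel)) return(NULL)
    c(r0 = min(rr[sel]), r1 = max(rr[sel]),
      c0 = min(cc[sel]), c1 = max(cc[sel]))
  })
}

## renumber positive labels to contiguous 1..K preserving order of first
## appearance in label value (not raster order)
renumber_labels <- function(labels) {
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) == 0) return(labels)
  map <- integer(max(u))
  map[u] <- seq_along(u)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

is_blank <- function(x) all(x == x[1])

## strip EBImage's Image class down to a plain base matrix
ebi_mat <- function(img) {
  m <- EBImage::imageData(img)
  attributes(m) <- list(dim = dim(m)[1:2])
  m
}

## write a data.frame as CSV with fixed conventions (UTF-8, '.' decimal)
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
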