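#' The three pairwise group comparisons
#'
#' Comparison labels and their reference/test groups across the heart-failure
#' time course: Baseline vs HeartFailure (B_HF), HeartFailure vs Recovery
#' (HF_R), Baseline vs Recovery (B_R). Fold-change direction is reported
#' relative to the reference (first-listed) group.
#'
#' @return data.frame with columns label, reference, test.
#' @export
comparisons <- function() {
  data.frame(label = c("B_HF", "HF_R", "B_R"),
             reference = c("Baseline", "HeartFailure", "Baseline"),
             test = c("HeartFailure", "Recovery", "Recovery"),
             stringsAsFactors = FALSE)
}

#' Welch two-group test
#'
#' Unequal-variance (Welch) t-test between two groups of protein areas, with
#' Welch-Satterthwaite degrees of freedom. For two groups the Welch one-way
#' ANOVA F statistic equals the squared Welch t and yields the identical
#' p-value. Degenerate inputs (both groups constant) are resolved directly:
#' equal constants give statistic 0 and p 1; unequal constants an infinite
#' statistic and p 0.
#'
#' @param x,y numeric vectors of areas (NAs dropped); each group needs at
#'   least 2 values to be testable.
#' @return list with \code{statistic} (t), \code{df}, \code{p.value},
#'   \code{mean_x}, \code{mean_y}, \code{n_x}, \code{n_y} and
#'   \code{testable}. Untestable inputs give NA statistic and p.
#' @export
welch_pairwise <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  out <- list(statistic = NA_real_, df = NA_real_, p.value = NA_real_,
              mean_x = if (nx) mean(x) else NA_real_,
              mean_y = if (ny) mean(y) else NA_real_,
              n_x = nx, n_y = ny, testable = FALSE)
  if (nx < 2 || ny < 2) return(out)
  out$testable <- TRUE
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      out$statistic <- 0; out$df <- nx + ny - 2; out$p.value <- 1
    } else {
      out$statistic <- sign(mean(y) - mean(x)) * Inf
      out$df <- nx + ny - 2; out$p.value <- 0
    }
    return(out)
  }
  tt <- stats::t.test(y, x, var.equal = FALSE)
  out$statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p.value <- tt$p.value
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment of a family of p-values. NA entries (untestable
#' proteins) are excluded from the family: the family size m counts only the
#' non-missing p-values, and NAs are returned in place.
#'
#' @param pvalues numeric vector in [0, 1], NAs allowed.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Fold-change magnitude and direction
#'
#' The ratio r = mean_test / mean_ref reported as a magnitude max(r, 1/r)
#' (always >= 1) plus a direction: up when the test group is higher than the
#' reference, down when lower, none when equal.
#'
#' @param mean_ref,mean_test positive arithmetic group means.
#' @return list with numeric \code{magnitude} and character \code{direction};
#'   vectorized over the inputs.
#' @export
fold_change <- function(mean_ref, mean_test) {
  if (any(!is.finite(mean_ref)) || any(!is.finite(mean_test)) ||
      any(mean_ref <= 0) || any(mean_test <= 0))
    stop("fold_change requires positive group means")
  r <- mean_test / mean_ref
  list(magnitude = pmax(r, 1 / r),
       direction = ifelse(r > 1, "up", ifelse(r < 1, "down", "none")))
}

#' Differential protein abundance across the time course
#'
#' For each of the three pairwise comparisons, runs a Welch test per protein
#' on untransformed areas (optionally log-transformed for testing), adjusts
#' p-values with Benjamini-Hochberg within each comparison as its own family,
#' and reports directional fold-changes from the arithmetic group means of
#' the raw areas. Proteins with fewer than 2 non-missing areas in either
#' group are untestable: reported with NA p-values and excluded from the BH
#' family.
#'
#' @param quant a \code{protein_quant} long table from \code{\link{rollup}},
#'   or a protein-by-sample matrix (then \code{metadata} is required).
#' @param metadata data.frame with columns sample_id and group, required when
#'   \code{quant} is a matrix.
#' @param alpha significance level applied to adjusted p-values.
#' @param log_transform test on log-transformed areas (fold-changes are still
#'   ratios of arithmetic means of the raw areas).
#' @return data.table with one row per protein per comparison: protein_id,
#'   gene, comparison, n_ref, n_test, mean_ref, mean_test, fc_magnitude,
#'   direction, p_raw, p_adj, significant.
#' @export
run_differential <- function(quant, metadata = NULL, alpha = 0.05,
                             log_transform = FALSE) {
  if (is.matrix(quant)) {
    if (is.null(metadata)) stop("metadata required for matrix input")
    m <- quant
    genes <- stats::setNames(rep(NA_character_, nrow(m)), rownames(m))
  } else {
    q <- data.table::as.data.table(quant)
    m <- protein_matrix(q)
    meta <- unique(q[, c("sample_id", "group"), with = FALSE])
    genes <- stats::setNames(q$gene[match(rownames(m), q$protein_id)],
                             rownames(m))
    metadata <- as.data.frame(meta)
  }
  if (!all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata needs columns sample_id and group")
  metadata <- metadata[match(colnames(m), metadata$sample_id), ]
  if (anyNA(metadata$sample_id))
    stop("metadata does not cover all samples in the matrix")
  cmp <- comparisons()
  known <- unique(c(cmp$reference, cmp$test))
  if (any(!metadata$group %in% known))
    stop("unknown group labels: ",
         paste(setdiff(metadata$group, known), collapse = ", "))

  res <- lapply(seq_len(nrow(cmp)), function(k) {
    ref_cols <- metadata$group == cmp$reference[k]
    test_cols <- metadata$group == cmp$test[k]
    rows <- lapply(rownames(m), function(p) {
      xr <- m[p, ref_cols]; xt <- m[p, test_cols]
      xr_t <- if (log_transform) log(xr) else xr
      xt_t <- if (log_transform) log(xt) else xt
      w <- welch_pairwise(xr_t, xt_t)
      mr <- mean(xr, na.rm = TRUE); mt <- mean(xt, na.rm = TRUE)
      fc_ok <- is.finite(mr) && is.finite(mt) && mr > 0 && mt > 0
      fc <- if (fc_ok) fold_change(mr, mt) else
        list(magnitude = NA_real_, direction = NA_character_)
      data.table::data.table(
        protein_id = p, gene = unname(genes[p]), comparison = cmp$label[k],
        n_ref = sum(!is.na(xr)), n_test = sum(!is.na(xt)),
        mean_ref = mr, mean_test = mt,
        fc_magnitude = fc$magnitude, direction = fc$direction,
        p_raw = w$p.value)
    })
    out <- data.table::rbindlist(rows)
    out$p_adj <- bh_adjust(out$p_raw)
    out
  })
  res <- data.table::rbindlist(res)
  res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
  res[]
}
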