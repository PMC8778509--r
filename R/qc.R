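#' Quality-control configuration
#'
#' Parameters of the ion-level QC stages applied to an extracted SWATH-MS
#' intensity table, with the study defaults: an ion is excluded from a sample
#' when its intensity falls below the lower detection limit Q1 - 1.5 x IQR of
#' that ion's per-sample values, and excluded from the entire dataset when its
#' technical-replicate CV exceeds 25\% in at least 20\% of samples.
#'
#' @param cv_threshold_pct per-(ion, sample) CV flag threshold, percent.
#' @param cv_sample_fraction fraction of samples that must be flagged before
#'   an ion is excluded dataset-wide; the denominator counts samples where a
#'   CV is computable for that ion (set
#'   \code{cv_denominator = "design"} to use the full design size instead).
#' @param lod_iqr_multiplier multiplier of the IQR in the detection limit.
#' @param quartile_rule order-statistic interpolation used for quartiles:
#'   \code{"linear"} (linear interpolation between closest order statistics,
#'   the common default, \code{stats::quantile} type 7) or an integer type
#'   1-9 passed through to \code{stats::quantile}.
#' @param cv_denominator \code{"computable"} or \code{"design"}.
#' @return an object of class \code{qc_config}.
#' @export
qc_config <- function(cv_threshold_pct = 25,
                      cv_sample_fraction = 0.20,
                      lod_iqr_multiplier = 1.5,
                      quartile_rule = "linear",
                      cv_denominator = c("computable", "design")) {
  stopifnot(cv_threshold_pct > 0, lod_iqr_multiplier > 0,
            cv_sample_fraction > 0, cv_sample_fraction <= 1)
  cv_denominator <- match.arg(cv_denominator)
  structure(list(cv_threshold_pct = cv_threshold_pct,
                 cv_sample_fraction = cv_sample_fraction,
                 lod_iqr_multiplier = lod_iqr_multiplier,
                 quartile_rule = quartile_rule,
                 cv_denominator = cv_denominator),
            class = "qc_config")
}

.quantile_type <- function(rule) {
  if (identical(rule, "linear")) return(7L)
  if (is.numeric(rule) && rule %in% 1:9) return(as.integer(rule))
  stop("unknown quartile rule: ", rule)
}

#' Quartiles and interquartile range
#'
#' First and third quartiles of a numeric vector under a named interpolation
#' rule, as used by the lower-detection-limit filter.
#'
#' @param values numeric vector with at least one finite value.
#' @param rule interpolation rule, see \code{\link{qc_config}}.
#' @return list with \code{q1}, \code{q3}, \code{iqr}.
#' @export
quartiles <- function(values, rule = "linear") {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("quartiles need at least one finite value")
  type <- .quantile_type(rule)
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}

#' Total-intensity (AUC) normalization
#'
#' Scales every sample by the ratio of the mean total ion intensity over all
#' samples to that sample's own total, so that after scaling each sample's
#' total equals the pre-scaling grand mean. Only measurements present in the
#' table contribute (no imputation of missing rows).
#'
#' @param table ion intensity table (long format).
#' @return list with the scaled \code{table} and the named per-sample
#'   \code{factors}.
#' @export
auc_normalize <- function(table) {
  dt <- data.table::as.data.table(table)
  intensity <- sample_id <- NULL
  totals <- dt[, list(total = sum(intensity)), by = sample_id]
  zero <- totals$sample_id[totals$total <= 0]
  if (length(zero))
    stop("sample with zero total intensity: ", paste(zero, collapse = ", "))
  factors <- stats::setNames(mean(totals$total) / totals$total,
                             totals$sample_id)
  dt <- data.table::copy(dt)
  dt[, intensity := intensity * factors[sample_id]]
  list(table = dt[], factors = factors)
}

# per-(ion, sample) injection means, the value the LOD rule operates on
.injection_means <- function(dt) {
  intensity <- NULL
  dt[, list(value = mean(intensity), n_inj = .N),
     by = c("protein_id", "peptide_id", "ion_id", "sample_id")]
}

#' Lower-detection-limit filter
#'
#' For each ion, the lower detection limit is Q1 - k x IQR of its per-sample
#' values (the mean over each sample's injections), pooled over all groups.
#' Measurements of a sample strictly below the ion's limit are excluded from
#' that sample; values equal to the limit are retained. Ions observed in a
#' single sample have IQR 0 and are never excluded.
#'
#' @param table normalized ion table.
#' @param config a \code{\link{qc_config}}.
#' @return list with the filtered \code{table} and an \code{exclusions}
#'   data.table (one row per removed ion-sample unit, with the value and the
#'   limit).
#' @export
detection_limit_filter <- function(table, config = qc_config()) {
  dt <- data.table::as.data.table(table)
  value <- lod <- NULL
  per_sample <- .injection_means(dt)
  type <- .quantile_type(config$quartile_rule)
  k <- config$lod_iqr_multiplier
  per_sample[, lod := {
    q <- stats::quantile(value, c(0.25, 0.75), type = type, names = FALSE)
    q[1] - k * (q[2] - q[1])
  }, by = c("protein_id", "peptide_id", "ion_id")]
  below <- per_sample[value < lod]
  if (nrow(below)) {
    excl <- below[, c("protein_id", "peptide_id", "ion_id", "sample_id",
                      "value", "lod"), with = FALSE]
    excl[, c("stage", "reason") := list("detection_limit", "below_LOD")]
    dt <- dt[!below, on = c("protein_id", "peptide_id", "ion_id", "sample_id")]
  } else {
    excl <- data.table::data.table(
      protein_id = character(), peptide_id = character(),
      ion_id = character(), sample_id = character(),
      value = numeric(), lod = numeric(),
      stage = character(), reason = character())
  }
  list(table = dt[], exclusions = excl[])
}

#' Technical-replicate CV filter
#'
#' Computes, per (ion, sample), the percent coefficient of variation over
#' technical injections (requires >= 2 injections). An ion is removed from
#' the entire dataset when the fraction of samples whose CV exceeds
#' \code{cv_threshold_pct} reaches \code{cv_sample_fraction}; by default the
#' fraction's denominator is the number of samples where that ion has a
#' computable CV. Ions with no computable CV anywhere cannot be qualified and
#' are excluded with their own reason.
#'
#' @param table ion table after the detection-limit filter.
#' @param config a \code{\link{qc_config}}.
#' @param n_design_samples total number of samples in the design, used when
#'   \code{cv_denominator = "design"}; defaults to the samples present.
#' @return list with the filtered \code{table}, an \code{exclusions}
#'   data.table (one row per removed ion), and the per-(ion, sample)
#'   \code{cv} table.
#' @export
cv_filter <- function(table, config = qc_config(), n_design_samples = NULL) {
  dt <- data.table::as.data.table(table)
  intensity <- cv_pct <- flagged <- NULL
  cv <- dt[, list(n_inj = .N, mean_i = mean(intensity),
                  sd_i = stats::sd(intensity)),
           by = c("protein_id", "peptide_id", "ion_id", "sample_id")]
  cv[, cv_pct := ifelse(n_inj >= 2, 100 * sd_i / mean_i, NA_real_)]
  cv[, flagged := !is.na(cv_pct) & cv_pct > config$cv_threshold_pct]
  if (is.null(n_design_samples))
    n_design_samples <- length(unique(dt$sample_id))
  per_ion <- cv[, list(n_computable = sum(!is.na(cv_pct)),
                       n_flagged = sum(flagged)),
                by = c("protein_id", "peptide_id", "ion_id")]
  denom <- if (config$cv_denominator == "design") n_design_samples else
    per_ion$n_computable
  no_cv <- per_ion$n_computable == 0
  high <- !no_cv & per_ion$n_flagged / denom >= config$cv_sample_fraction
  drop <- per_ion[no_cv | high]
  drop_reason <- ifelse(no_cv[no_cv | high], "no_computable_cv", "high_CV")
  if (nrow(drop)) {
    excl <- drop[, c("protein_id", "peptide_id", "ion_id"), with = FALSE]
    excl[, c("sample_id", "value", "lod") :=
           list(NA_character_, NA_real_, NA_real_)]
    excl[, c("stage", "reason") := list("cv_filter", drop_reason)]
    dt <- dt[!drop, on = c("protein_id", "peptide_id", "ion_id")]
  } else {
    excl <- data.table::data.table(
      protein_id = character(), peptide_id = character(),
      ion_id = character(), sample_id = character(),
      value = numeric(), lod = numeric(),
      stage = character(), reason = character())
  }
  list(table = dt[], exclusions = excl[], cv = cv[])
}

#' Hierarchical rollup to protein areas
#'
#' Per (ion, sample) the median intensity over surviving injections is
#' selected; ion medians are summed to peptide areas and peptide areas to
#' protein areas. Proteins with no surviving ion in a sample yield a missing
#' cell (no row), never a zero.
#'
#' @param table QC-filtered ion table.
#' @return a \code{data.table} of class \code{protein_quant} with columns
#'   protein_id, gene, sample_id, group, area and n_ions (support count).
#' @export
rollup <- function(table) {
  dt <- data.table::as.data.table(table)
  intensity <- med <- area <- NULL
  ion_med <- dt[, list(med = stats::median(intensity),
                       gene = gene[1], group = group[1]),
                by = c("protein_id", "peptide_id", "ion_id", "sample_id")]
  pep <- ion_med[, list(pep_area = sum(med), n_ions = .N,
                        gene = gene[1], group = group[1]),
                 by = c("protein_id", "peptide_id", "sample_id")]
  prot <- pep[, list(area = sum(pep_area), n_ions = sum(n_ions),
                     gene = gene[1], group = group[1]),
              by = c("protein_id", "sample_id")]
  data.table::setcolorder(prot, c("protein_id", "gene", "sample_id", "group",
                                  "area", "n_ions"))
  data.table::setattr(prot, "class",
                      c("protein_quant", class(prot)))
  prot[]
}

#' Protein-by-sample area matrix
#'
#' Widens a \code{protein_quant} long table into a numeric matrix (rows =
#' proteins, columns = samples) with NA for missing cells.
#'
#' @param quant output of \code{\link{rollup}}.
#' @return numeric matrix with protein ids as row names.
#' @export
protein_matrix <- function(quant) {
  wide <- data.table::dcast(data.table::as.data.table(quant),
                            protein_id ~ sample_id, value.var = "area")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$protein_id
  m
}

#' Run the full ion-level QC pipeline
#'
#' Applies, in order: AUC normalization, the per-ion lower-detection-limit
#' filter, the dataset-wide technical-replicate CV filter, then rollup of
#' injection medians to peptide and protein areas.
#'
#' @param table raw ion intensity table.
#' @param config a \code{\link{qc_config}}.
#' @return list with \code{quant} (a \code{protein_quant} table),
#'   \code{report} (normalization factors, exclusion log, stage counts) and
#'   the intermediate \code{table}.
#' @export
run_qc <- function(table, config = qc_config()) {
  n0 <- nrow(table)
  norm <- auc_normalize(table)
  lod <- detection_limit_filter(norm$table, config)
  cvf <- cv_filter(lod$table, config,
                   n_design_samples = length(unique(table$sample_id)))
  quant <- rollup(cvf$table)
  exclusions <- data.table::rbindlist(list(lod$exclusions, cvf$exclusions))
  counts <- data.table::data.table(
    stage = c("input", "after_detection_limit", "after_cv_filter"),
    n_measurements = c(n0, nrow(lod$table), nrow(cvf$table)))
  list(quant = quant,
       report = list(factors = norm$factors, exclusions = exclusions,
                     cv = cvf$cv, counts = counts),
       table = cvf$table)
}
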