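#' Pipeline configuration
#'
#' Bundles the stage configurations for an end-to-end run: either a
#' simulation design (\code{sim}) or the path of an ion table CSV
#' (\code{input}), the QC settings, the marker thresholds, annotation file
#' overrides, and an output directory for artifacts.
#'
#' @param sim a \code{\link{sim_config}}, or NULL to read \code{input}.
#' @param input path to a long-format ion table CSV (ignored when \code{sim}
#'   is given).
#' @param qc a \code{\link{qc_config}}.
#' @param thresholds a \code{\link{marker_thresholds}}.
#' @param secretome_file,aki_file annotation list overrides (NULL = packaged
#'   fixtures).
#' @param alpha significance level for the differential stage.
#' @param log_transform test on log areas.
#' @param out_dir directory for artifact files, or NULL to skip writing.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = NULL, input = NULL, qc = qc_config(),
                            thresholds = marker_thresholds(),
                            secretome_file = NULL, aki_file = NULL,
                            alpha = 0.05, log_transform = FALSE,
                            out_dir = NULL) {
  if (is.null(sim) && is.null(input))
    stop("either a simulation config or an input path is required")
  structure(list(sim = sim, input = input, qc = qc, thresholds = thresholds,
                 secretome_file = secretome_file, aki_file = aki_file,
                 alpha = alpha, log_transform = log_transform,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full quantification and discovery pipeline
#'
#' Executes, in order: simulation (or reading) of the ion table, AUC
#' normalization, detection-limit filter, CV filter, rollup, differential
#' testing, threshold qualification, categorization, secretome shortlisting
#' and prior-AKI flagging. When \code{out_dir} is set, every intermediate
#' artifact is written as CSV plus a key:value summary file.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with elements \code{ions}, \code{truth} (simulation only),
#'   \code{qc} (quant, report), \code{differential}, \code{qualified},
#'   \code{calls}, \code{markers} and \code{summary} (character lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$sim)) {
    study <- generate_study(config$sim)
    ions <- study$ions
    truth <- study$truth
  } else {
    ions <- read_ion_table(config$input)
  }
  qc <- run_qc(ions, config$qc)
  diffres <- run_differential(qc$quant, alpha = config$alpha,
                              log_transform = config$log_transform)
  ann <- load_annotation_sets(config$secretome_file, config$aki_file)
  qualified <- apply_thresholds(diffres, config$thresholds)
  calls <- categorize(qualified)
  markers <- prior_association_flag(secretome_filter(calls, ann), ann)

  artifacts <- list(ions = ions, truth = truth, qc = qc,
                    differential = diffres, qualified = qualified,
                    calls = calls, markers = markers)
  artifacts$summary <- summarize_pipeline(artifacts, config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_ion_table(ions, out("ion_table.csv"))
    if (!is.null(truth)) write_ground_truth(truth, out("ground_truth.csv"))
    data.table::fwrite(data.table::data.table(
      sample_id = names(qc$report$factors),
      factor = unname(qc$report$factors)), out("normalization_factors.csv"))
    data.table::fwrite(qc$report$exclusions, out("qc_exclusions.csv"))
    data.table::fwrite(qc$quant, out("protein_areas_long.csv"))
    wide <- data.table::dcast(qc$quant, protein_id ~ sample_id,
                              value.var = "area")
    data.table::fwrite(wide, out("protein_matrix.csv"))
    data.table::fwrite(diffres, out("differential_results.csv"))
    data.table::fwrite(markers, out("marker_calls.csv"))
    writeLines(artifacts$summary, out("summary.txt"))
  }
  artifacts
}

#' Human-readable pipeline summary
#'
#' Stage-by-stage counts (measurements in and excluded per reason, proteins
#' quantified, significant and qualified proteins per comparison, marker
#' categories, shortlist size) plus an echo of the thresholds, as
#' key: value lines.
#'
#' @param artifacts list as returned by \code{\link{run_pipeline}} (the
#'   \code{summary} element is ignored).
#' @param config the \code{\link{pipeline_config}} used (for the threshold
#'   echo); optional.
#' @return character vector of report lines.
#' @export
summarize_pipeline <- function(artifacts, config = NULL) {
  lines <- character()
  add <- function(k, v) {
    if (is.null(v) || length(v) == 0 || all(is.na(v))) v <- 0
    lines <<- c(lines, sprintf("%s: %s", k, v))
  }
  counts <- artifacts$qc$report$counts
  excl <- artifacts$qc$report$exclusions
  add("measurements_in", counts$n_measurements[counts$stage == "input"])
  add("measurements_after_detection_limit",
      counts$n_measurements[counts$stage == "after_detection_limit"])
  add("measurements_after_cv_filter",
      counts$n_measurements[counts$stage == "after_cv_filter"])
  for (r in c("below_LOD", "high_CV", "no_computable_cv"))
    add(paste0("excluded_", r), sum(excl$reason == r))
  q <- artifacts$qc$quant
  add("proteins_quantified", length(unique(q$protein_id)))
  d <- artifacts$differential
  for (cmp in comparisons()$label)
    add(paste0("significant_", cmp),
        sum(d$significant[d$comparison == cmp], na.rm = TRUE))
  if (!is.null(artifacts$qualified)) {
    qq <- artifacts$qualified
    for (cmp in comparisons()$label)
      add(paste0("qualified_", cmp),
          sum(qq$qualified[qq$comparison == cmp], na.rm = TRUE))
    add("qualified_proteins",
        length(unique(qq$protein_id[qq$qualified])))
  }
  if (!is.null(artifacts$calls))
    for (cat in c("injury", "recovery", "long_term"))
      add(paste0("category_", cat),
          sum(artifacts$calls$category == cat))
  if (!is.null(artifacts$markers)) {
    add("shortlisted", nrow(artifacts$markers))
    for (cat in c("injury", "recovery", "long_term"))
      add(paste0("shortlisted_", cat),
          sum(artifacts$markers$category == cat))
    add("prior_aki", sum(artifacts$markers$prior_aki))
    add("novel", sum(!artifacts$markers$prior_aki))
  }
  if (!is.null(config)) {
    add("alpha", config$alpha)
    add("fc_min", config$thresholds$fc_min)
    add("cv_threshold_pct", config$qc$cv_threshold_pct)
    add("cv_sample_fraction", config$qc$cv_sample_fraction)
    add("lod_iqr_multiplier", config$qc$lod_iqr_multiplier)
  }
  lines
}

#' Marker discovery from a published differential table
#'
#' Runs the discovery stages (threshold qualification, categorization,
#' secretome shortlist, prior-AKI flagging) directly on a differential-result
#' table such as the packaged published fixture, skipping quantification.
#'
#' @param results differential results; NULL loads the packaged fixture.
#' @param thresholds a \code{\link{marker_thresholds}}.
#' @param annotations list from \code{\link{load_annotation_sets}}.
#' @return list with \code{qualified}, \code{calls}, \code{markers} and
#'   \code{summary} lines.
#' @export
run_fixture_discovery <- function(results = NULL,
                                  thresholds = marker_thresholds(),
                                  annotations = load_annotation_sets()) {
  if (is.null(results)) results <- load_differential_fixture()
  qualified <- apply_thresholds(results, thresholds)
  calls <- categorize(qualified)
  markers <- prior_association_flag(secretome_filter(calls, annotations),
                                    annotations)
  lines <- character()
  add <- function(k, v) lines <<- c(lines, sprintf("%s: %s", k, v))
  for (cmp in comparisons()$label)
    add(paste0("qualified_", cmp),
        sum(qualified$qualified[qualified$comparison == cmp]))
  add("qualified_proteins", length(unique(qualified$protein_id[qualified$qualified])))
  add("shortlisted", nrow(markers))
  for (cat in c("injury", "recovery", "long_term"))
    add(paste0("shortlisted_", cat), sum(markers$category == cat))
  add("prior_aki", sum(markers$prior_aki))
  add("novel", sum(!markers$prior_aki))
  list(qualified = qualified, calls = calls, markers = markers,
       summary = lines)
}
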