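#' Marker qualification thresholds
#'
#' The two-stage reporting thresholds for candidate markers: an adjusted
#' p-value below \code{alpha} and a fold-change magnitude of at least
#' \code{fc_min} (defaults 0.05 and 1.2).
#'
#' @param fc_min minimum fold-change magnitude (>= 1).
#' @param alpha adjusted-p significance threshold, in (0, 1).
#' @return object of class \code{marker_thresholds}.
#' @export
marker_thresholds <- function(fc_min = 1.2, alpha = 0.05) {
  stopifnot(fc_min >= 1, alpha > 0, alpha < 1)
  structure(list(fc_min = fc_min, alpha = alpha),
            class = "marker_thresholds")
}

#' Threshold qualification of differential results
#'
#' A (protein, comparison) pair qualifies when its adjusted p-value is below
#' \code{alpha} and its fold magnitude is at least \code{fc_min}.
#'
#' Published result tables print adjusted p-values rounded to a fixed number
#' of decimals, so a strict comparison at the rounding boundary is
#' meaningless: a table whose inclusion criterion is p < 0.05 can print
#' "0.05". When the input carries a \code{printed_digits} attribute (set by
#' \code{\link{load_differential_fixture}}), values are compared at that
#' printed precision: a value within half an ulp of the threshold qualifies.
#' Exact (computed) p-values use the strict comparison.
#'
#' @param results differential results with columns protein_id, gene,
#'   comparison, fc_magnitude and p_adj (e.g. from
#'   \code{\link{run_differential}} or the packaged fixture).
#' @param thresholds a \code{\link{marker_thresholds}}.
#' @return the results with a logical \code{qualified} column.
#' @export
apply_thresholds <- function(results, thresholds = marker_thresholds()) {
  dt <- data.table::as.data.table(results)
  digits <- attr(results, "printed_digits")
  tol <- if (is.null(digits)) 0 else 0.5 * 10^(-digits)
  dt$qualified <- !is.na(dt$p_adj) & !is.na(dt$fc_magnitude) &
    dt$p_adj < thresholds$alpha + tol &
    dt$fc_magnitude >= thresholds$fc_min
  dt[]
}

#' Categorize qualified proteins by abundance pattern
#'
#' Assigns each protein with at least one qualifying comparison to one of
#' three marker categories from its pattern across the time course, with the
#' precedence long_term > recovery > injury:
#' \itemize{
#'   \item \code{long_term}: Baseline vs Recovery qualifies (long-term renal
#'     impairment);
#'   \item \code{recovery}: otherwise, both Baseline vs HeartFailure and
#'     HeartFailure vs Recovery qualify (abundance recovers with the heart);
#'   \item \code{injury}: otherwise, Baseline vs HeartFailure qualifies
#'     (altered in acute decompensation, not restored).
#' }
#' Proteins qualifying in no comparison (or only HeartFailure vs Recovery,
#' a pattern outside the scheme) receive no call and are dropped.
#'
#' @param results output of \code{\link{apply_thresholds}} covering all three
#'   comparisons.
#' @return data.table with one row per categorized protein: protein_id, gene,
#'   category, the qualifying comparisons, and their fold-changes.
#' @export
categorize <- function(results) {
  dt <- data.table::as.data.table(results)
  if (!"qualified" %in% names(dt))
    stop("results must carry a 'qualified' column; run apply_thresholds first")
  if (!"direction" %in% names(dt)) dt$direction <- NA_character_
  per <- dt[, list(
    gene = gene[1],
    q_B_HF = any(comparison == "B_HF" & qualified),
    q_HF_R = any(comparison == "HF_R" & qualified),
    q_B_R = any(comparison == "B_R" & qualified),
    qualifying = paste(sort(unique(comparison[qualified])), collapse = ";"),
    fold_changes = paste(sprintf("%s:%s%.2f", comparison[qualified],
                                 ifelse(!is.na(direction[qualified]) &
                                          direction[qualified] == "down",
                                        "-", "+"),
                                 fc_magnitude[qualified]), collapse = ";")
  ), by = "protein_id"]
  per$category <- ifelse(per$q_B_R, "long_term",
                  ifelse(per$q_B_HF & per$q_HF_R, "recovery",
                  ifelse(per$q_B_HF, "injury", NA_character_)))
  out <- per[!is.na(per$category),
             c("protein_id", "gene", "category", "qualifying",
               "fold_changes"), with = FALSE]
  out[]
}

#' Load annotation gene sets
#'
#' Reads the biofluid-detectability (secretome) and prior-AKI-association
#' gene lists, one symbol per line; symbols are uppercased and deduplicated.
#' The packaged defaults transcribe the published annotations for the study's
#' differential proteins (a secretome subset covering the proteins predicted
#' detectable in serum, plasma or urine, and the genes flagged as previously
#' AKI-associated); both files can be replaced by full-resource exports with
#' the same one-symbol-per-line format.
#'
#' @param secretome_file,aki_file paths; NULL uses the packaged fixtures.
#' @return list with character-vector sets \code{secretome} and
#'   \code{aki_genes}.
#' @export
load_annotation_sets <- function(secretome_file = NULL, aki_file = NULL) {
  if (is.null(secretome_file))
    secretome_file <- system.file("extdata", "secretome_biofluid_genes.txt",
                                  package = "swathmarkers", mustWork = TRUE)
  if (is.null(aki_file))
    aki_file <- system.file("extdata", "aki_associated_genes.txt",
                            package = "swathmarkers", mustWork = TRUE)
  read_set <- function(f) {
    x <- readLines(f)
    x <- toupper(trimws(x))
    unique(x[nzchar(x) & !startsWith(x, "#")])
  }
  list(secretome = read_set(secretome_file), aki_genes = read_set(aki_file))
}

#' Biofluid-detectability (secretome) shortlist
#'
#' Retains marker calls whose gene symbol appears in the secretome set
#' (case-insensitive exact match), i.e. proteins predicted detectable in
#' serum, plasma, or urine. Calls with a missing gene symbol are dropped by
#' default (they cannot be annotation-matched).
#'
#' @param calls marker calls from \code{\link{categorize}}.
#' @param annotations list from \code{\link{load_annotation_sets}}.
#' @param keep_missing_gene retain calls whose gene symbol is missing.
#' @return the shortlisted calls with \code{biofluid_detectable = TRUE}.
#' @export
secretome_filter <- function(calls, annotations, keep_missing_gene = FALSE) {
  dt <- data.table::as.data.table(calls)
  missing_gene <- is.na(dt$gene) | !nzchar(trimws(dt$gene))
  hit <- !missing_gene &
    toupper(trimws(dt$gene)) %in% toupper(annotations$secretome)
  keep <- hit | (missing_gene & keep_missing_gene)
  out <- dt[keep]
  out$biofluid_detectable <- TRUE
  out[]
}

#' Flag prior AKI associations
#'
#' Marks each call whose gene symbol appears in the prior-AKI gene set
#' (case-insensitive exact match); all others — including calls without a
#' gene symbol — are flagged novel.
#'
#' @param calls marker calls.
#' @param annotations list from \code{\link{load_annotation_sets}}.
#' @return the calls with a logical \code{prior_aki} column.
#' @export
prior_association_flag <- function(calls, annotations) {
  dt <- data.table::as.data.table(calls)
  g <- toupper(trimws(ifelse(is.na(dt$gene), "", dt$gene)))
  dt$prior_aki <- nzchar(g) & g %in% toupper(annotations$aki_genes)
  dt[]
}

#' End-to-end marker discovery
#'
#' Applies threshold qualification, pattern categorization, the secretome
#' shortlist and prior-AKI flagging in one step.
#'
#' @param results differential results covering the three comparisons.
#' @param thresholds a \code{\link{marker_thresholds}}.
#' @param annotations list from \code{\link{load_annotation_sets}}.
#' @return shortlisted marker calls with categories and flags.
#' @export
discover_markers <- function(results, thresholds = marker_thresholds(),
                             annotations = load_annotation_sets()) {
  qualified <- apply_thresholds(results, thresholds)
  calls <- categorize(qualified)
  shortlist <- secretome_filter(calls, annotations)
  prior_association_flag(shortlist, annotations)
}

#' Load the packaged differential-abundance fixture
#'
#' A transcription of the published table of proteins with fold-change >= 1.2
#' and adjusted p < 0.05 across the three comparisons (45 proteins, 48
#' protein-comparison rows). Fold magnitudes and adjusted p-values are as
#' printed (p rounded to two decimals except one three-decimal entry); the
#' returned table carries \code{printed_digits = 2} so
#' \code{\link{apply_thresholds}} compares at the printed precision.
#'
#' @param path alternative CSV with the same columns; NULL uses the packaged
#'   fixture.
#' @return data.table with columns protein_id, protein_name, gene,
#'   comparison, fc_magnitude, direction, p_adj.
#' @export
load_differential_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "differential_proteins_published.csv",
                        package = "swathmarkers", mustWork = TRUE)
  dt <- data.table::fread(path, colClasses = list(
    character = c("protein_id", "protein_name", "gene", "comparison",
                  "direction"),
    numeric = c("fc_magnitude", "p_adj")))
  data.table::setattr(dt, "printed_digits", 2)
  dt[]
}

#' Correlate marker areas with physiological variables
#'
#' Within one study group, correlates each protein's area across animals with
#' each physiological variable (Pearson by default, Spearman via
#' \code{method}), reporting the coefficient and two-sided p-value. Pairs
#' with fewer than 3 complete observations or a constant vector have an
#' undefined correlation and are reported as NA.
#'
#' @param quant \code{protein_quant} long table; sample ids must match the
#'   physiology table's animal ids.
#' @param physio data.frame with column animal_id plus numeric variables.
#' @param group study group to restrict to, or NULL for all animals.
#' @param proteins optional protein ids to restrict to.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return data.table: protein_id, gene, variable, n, estimate, p_value.
#' @export
correlate_with_physiology <- function(quant, physio, group = NULL,
                                      proteins = NULL,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  q <- data.table::as.data.table(quant)
  if (!is.null(group)) q <- q[q$group == group, ]
  if (!is.null(proteins)) q <- q[q$protein_id %in% proteins, ]
  vars <- setdiff(names(physio), c("animal_id", "group", "day"))
  rows <- list()
  for (p in unique(q$protein_id)) {
    qp <- q[q$protein_id == p, ]
    idx <- match(qp$sample_id, physio$animal_id)
    for (v in vars) {
      x <- qp$area
      y <- physio[[v]][idx]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      est <- pv <- NA_real_
      if (n >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
        ct <- suppressWarnings(
          stats::cor.test(x[ok], y[ok], method = method))
        est <- unname(ct$estimate); pv <- ct$p.value
      }
      rows[[length(rows) + 1L]] <- data.table::data.table(
        protein_id = p, gene = qp$gene[1], variable = v,
        n = n, estimate = est, p_value = pv)
    }
  }
  if (!length(rows))
    return(data.table::data.table(protein_id = character(),
                                  gene = character(), variable = character(),
                                  n = integer(), estimate = numeric(),
                                  p_value = numeric()))
  data.table::rbindlist(rows)
}
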