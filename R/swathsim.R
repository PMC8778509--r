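#' Simulation configuration for synthetic SWATH-MS studies
#'
#' Defines the design of a simulated ion-level SWATH-MS dataset: a three-group
#' study (Baseline, HeartFailure, Recovery) with technical injection
#' replicates, a hierarchical protein > peptide > transition-ion signal
#' structure, log-normal biological and technical variation, and optional
#' below-detection dropout.
#'
#' Protein base abundances are drawn log-uniformly over
#' \code{log10_abundance_range} (default four decades, matching the dynamic
#' range typical of tissue SWATH quantification). Each protein's total signal
#' is partitioned once into fixed peptide and ion shares, held constant across
#' samples so that rollup is comparable between groups. Between-sample
#' (biological) and between-injection (technical) variation are multiplicative
#' log-normal, parameterized by their coefficients of variation; a per-sample
#' loading factor (shared by all ions of a sample) emulates the sample-level
#' intensity differences that AUC normalization removes.
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range \code{c(min, max)} of peptides
#'   drawn per protein.
#' @param ions_per_peptide integer range \code{c(min, max)} of transition ions
#'   drawn per peptide.
#' @param group_sizes named integer vector of animals per group; names are the
#'   group labels. Defaults to the study design Baseline 5, HeartFailure 8,
#'   Recovery 7.
#' @param n_injections technical injections per sample (default 3).
#' @param log10_abundance_range interval of log10 protein base abundance.
#' @param technical_cv_pct between-injection coefficient of variation, percent.
#' @param biological_cv_pct between-animal coefficient of variation, percent.
#' @param sample_scale_cv_pct CV of the per-sample loading factor, percent.
#' @param n_differential number of proteins given true group effects.
#' @param fc_map data.frame with columns \code{protein_id}, \code{comparison}
#'   (one of \code{"B_HF"}, \code{"HF_R"}, \code{"B_R"}), \code{magnitude}
#'   (>= 1) and \code{direction} (\code{"up"} or \code{"down"}), or NULL to
#'   auto-assign: the first \code{n_differential} proteins receive a
#'   Baseline-to-HeartFailure effect of \code{fc_magnitude}/\code{fc_direction}.
#' @param fc_magnitude,fc_direction,fc_comparison defaults used when
#'   \code{fc_map} is NULL. \code{fc_direction = "balanced"} alternates up
#'   and down across the spiked proteins, keeping total ion mass roughly
#'   unchanged between groups — the regime total-intensity normalization
#'   presumes (and the regime of the study, whose differential proteins
#'   moved in both directions).
#' @param missingness_rate overall probability that an ion-sample measurement
#'   is below detection and absent from the table.
#' @param censor_quantile dropout is confined to ion-sample units whose
#'   noise-free expected intensity falls below this quantile of all units.
#' @param seed integer seed controlling all randomness.
#'
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_proteins = 100L,
                       peptides_per_protein = c(1L, 6L),
                       ions_per_peptide = c(1L, 6L),
                       group_sizes = c(Baseline = 5L, HeartFailure = 8L,
                                       Recovery = 7L),
                       n_injections = 3L,
                       log10_abundance_range = c(4, 8),
                       technical_cv_pct = 10,
                       biological_cv_pct = 30,
                       sample_scale_cv_pct = 25,
                       n_differential = 0L,
                       fc_map = NULL,
                       fc_magnitude = 2,
                       fc_direction = "balanced",
                       fc_comparison = "B_HF",
                       missingness_rate = 0,
                       censor_quantile = 0.25,
                       seed = 1L) {
  stopifnot(n_proteins >= 1, n_injections >= 1)
  if (length(group_sizes) < 2 || is.null(names(group_sizes)) ||
      any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector of at least two groups")
  if (any(group_sizes < 2))
    stop("every group needs at least 2 samples")
  if (length(peptides_per_protein) != 2 || peptides_per_protein[1] < 1 ||
      diff(peptides_per_protein) < 0)
    stop("peptides_per_protein must be an increasing range of positive integers")
  if (length(ions_per_peptide) != 2 || ions_per_peptide[1] < 1 ||
      diff(ions_per_peptide) < 0)
    stop("ions_per_peptide must be an increasing range of positive integers")
  if (diff(log10_abundance_range) < 0)
    stop("log10_abundance_range must be an interval")
  if (technical_cv_pct <= 0) stop("technical_cv_pct must be positive")
  if (biological_cv_pct < 0) stop("biological_cv_pct must be non-negative")
  if (missingness_rate < 0 || missingness_rate >= 1)
    stop("missingness_rate must lie in [0, 1)")
  if (censor_quantile <= 0 || censor_quantile > 1)
    stop("censor_quantile must lie in (0, 1]")
  if (n_differential < 0 || n_differential > n_proteins)
    stop("n_differential must lie in [0, n_proteins]")
  if (!fc_direction %in% c("up", "down", "balanced"))
    stop("fc_direction must be 'up', 'down' or 'balanced'")
  if (fc_magnitude < 1) stop("fc_magnitude must be >= 1")
  if (!is.null(fc_map)) {
    fc_map <- as.data.frame(fc_map)
    needed <- c("protein_id", "comparison", "magnitude", "direction")
    if (!all(needed %in% names(fc_map)))
      stop("fc_map needs columns ", paste(needed, collapse = ", "))
    if (any(fc_map$magnitude < 1)) stop("fc_map magnitudes must be >= 1")
    if (any(!fc_map$direction %in% c("up", "down")))
      stop("fc_map directions must be 'up' or 'down'")
    if (any(!fc_map$comparison %in% c("B_HF", "HF_R", "B_R")))
      stop("fc_map comparisons must be B_HF, HF_R or B_R")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    ions_per_peptide = as.integer(ions_per_peptide),
    group_sizes = group_sizes,
    n_injections = as.integer(n_injections),
    log10_abundance_range = log10_abundance_range,
    technical_cv_pct = technical_cv_pct,
    biological_cv_pct = biological_cv_pct,
    sample_scale_cv_pct = sample_scale_cv_pct,
    n_differential = as.integer(n_differential),
    fc_map = fc_map,
    fc_magnitude = fc_magnitude,
    fc_direction = fc_direction,
    fc_comparison = fc_comparison,
    missingness_rate = missingness_rate,
    censor_quantile = censor_quantile,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# log-normal sigma for a given CV (percent); E[exp(N(-s^2/2, s))] = 1
.lnorm_sigma <- function(cv_pct) sqrt(log(1 + (cv_pct / 100)^2))

# draw n values uniformly from an integer range; safe when the range is a point
.sample_range <- function(range, n) {
  vals <- range[1]:range[2]
  if (length(vals) == 1L) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# stable per-protein sub-seed: protein i keeps its stream when proteins are added
.protein_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483647L)
}

# resolve a protein's fc_map rows into per-group mean multipliers
# (Baseline = 1); the three pairwise contrasts are not independent, so
# HF_R is honoured only when B_R is absent, and checked for consistency
# when all three are supplied
.group_multipliers <- function(fc_rows, groups) {
  mult <- stats::setNames(rep(1, length(groups)), groups)
  if (nrow(fc_rows) == 0) return(mult)
  signed <- function(cmp) {
    r <- fc_rows[fc_rows$comparison == cmp, , drop = FALSE]
    if (nrow(r) == 0) return(NA_real_)
    if (nrow(r) > 1) stop("duplicate fc_map entry for comparison ", cmp)
    if (r$direction == "up") r$magnitude else 1 / r$magnitude
  }
  b_hf <- signed("B_HF"); hf_r <- signed("HF_R"); b_r <- signed("B_R")
  if (!is.na(b_hf)) mult["HeartFailure"] <- b_hf
  if (!is.na(b_r)) {
    mult["Recovery"] <- b_r
    if (!is.na(hf_r)) {
      implied <- mult["Recovery"] / mult["HeartFailure"]
      if (abs(log(implied) - log(hf_r)) > 1e-8)
        stop("fc_map over-determined: HF_R inconsistent with B_HF and B_R")
    }
  } else if (!is.na(hf_r)) {
    mult["Recovery"] <- mult["HeartFailure"] * hf_r
  }
  mult
}

.fc_from_multipliers <- function(mult) {
  ratio <- c(B_HF = unname(mult["HeartFailure"] / mult["Baseline"]),
             HF_R = unname(mult["Recovery"] / mult["HeartFailure"]),
             B_R  = unname(mult["Recovery"] / mult["Baseline"]))
  list(magnitude = pmax(ratio, 1 / ratio),
       direction = ifelse(ratio > 1, "up", ifelse(ratio < 1, "down", "none")))
}

#' Generate a synthetic SWATH-MS study with ground truth
#'
#' Draws an ion-level intensity table under the design in \code{config},
#' together with the simulator's record of true per-protein abundances and
#' group fold-changes for scoring downstream analyses.
#'
#' Expected (noise-free) protein-level intensity in a group equals the
#' protein's base abundance times its true fold-change for that group.
#' Randomness is organized as one study-level stream (per-sample loading
#' factors) plus per-protein sub-streams keyed on the protein index, so
#' enlarging \code{n_proteins} does not reshuffle existing proteins.
#' Below-detection dropout removes whole ion-sample units (all injections),
#' preferentially where the noise-free expected intensity falls in the lowest
#' \code{censor_quantile} of the study.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{ions} (a \code{data.table} with columns
#'   protein_id, gene, peptide_id, ion_id, sample_id, group, injection,
#'   intensity; missing measurements are absent rows) and \code{truth} (one
#'   row per protein: base abundance, differential flag, and
#'   magnitude/direction of the three pairwise fold-changes).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups <- names(config$group_sizes)
  samples <- data.table::data.table(
    sample_id = unlist(lapply(seq_along(groups), function(g)
      sprintf("%s_%02d", groups[g], seq_len(config$group_sizes[g])))),
    group = rep(groups, config$group_sizes)
  )
  n_samp <- nrow(samples)

  set.seed(config$seed)
  sample_scale <- exp(stats::rnorm(n_samp,
                                   -.lnorm_sigma(config$sample_scale_cv_pct)^2 / 2,
                                   .lnorm_sigma(config$sample_scale_cv_pct)))

  protein_ids <- sprintf("P%04d", seq_len(config$n_proteins))
  genes <- sprintf("GENE%04d", seq_len(config$n_proteins))

  fc_map <- config$fc_map
  if (is.null(fc_map) && config$n_differential > 0) {
    dirs <- if (identical(config$fc_direction, "balanced"))
      rep(c("up", "down"), length.out = config$n_differential)
    else rep(config$fc_direction, config$n_differential)
    fc_map <- data.frame(protein_id = protein_ids[seq_len(config$n_differential)],
                         comparison = config$fc_comparison,
                         magnitude = config$fc_magnitude,
                         direction = dirs)
  }
  if (is.null(fc_map))
    fc_map <- data.frame(protein_id = character(), comparison = character(),
                         magnitude = numeric(), direction = character())

  sig_b <- .lnorm_sigma(config$biological_cv_pct)
  sig_t <- .lnorm_sigma(config$technical_cv_pct)
  lo <- config$log10_abundance_range[1]
  hi <- config$log10_abundance_range[2]

  per_protein <- vector("list", config$n_proteins)
  truth_rows <- vector("list", config$n_proteins)
  for (i in seq_len(config$n_proteins)) {
    set.seed(.protein_seed(config$seed, i))
    n_pep <- .sample_range(config$peptides_per_protein, 1)
    n_ion <- .sample_range(config$ions_per_peptide, n_pep)
    base <- 10^stats::runif(1, lo, hi)
    pep_share <- stats::rgamma(n_pep, shape = 1)
    pep_share <- pep_share / sum(pep_share)
    ion_share <- unlist(lapply(seq_len(n_pep), function(p) {
      s <- stats::rgamma(n_ion[p], shape = 1)
      pep_share[p] * s / sum(s)
    }))
    pep_of_ion <- rep(seq_len(n_pep), n_ion)
    ion_idx <- unlist(lapply(n_ion, seq_len))
    n_ions_total <- length(ion_share)

    rows <- fc_map[fc_map$protein_id == protein_ids[i], , drop = FALSE]
    mult <- .group_multipliers(rows, groups)
    fc <- .fc_from_multipliers(mult)

    bio <- exp(stats::rnorm(n_samp, -sig_b^2 / 2, sig_b))
    # noise-free expected intensity of each ion in each sample
    expected <- outer(ion_share * base, mult[samples$group])
    u_drop <- matrix(stats::runif(n_ions_total * n_samp), n_ions_total, n_samp)
    tech <- array(exp(stats::rnorm(n_ions_total * n_samp * config$n_injections,
                                   -sig_t^2 / 2, sig_t)),
                  dim = c(n_ions_total, n_samp, config$n_injections))

    intensity <- expected *
      rep(bio * sample_scale, each = n_ions_total)
    dt <- data.table::data.table(
      protein_id = protein_ids[i],
      gene = genes[i],
      peptide_id = sprintf("%s_pep%02d", protein_ids[i],
                           rep(pep_of_ion, n_samp * config$n_injections)),
      ion_id = sprintf("%s_pep%02d_ion%02d", protein_ids[i],
                       rep(pep_of_ion, n_samp * config$n_injections),
                       rep(ion_idx, n_samp * config$n_injections)),
      sample_id = rep(rep(samples$sample_id, each = n_ions_total),
                      config$n_injections),
      group = rep(rep(samples$group, each = n_ions_total), config$n_injections),
      injection = rep(seq_len(config$n_injections),
                      each = n_ions_total * n_samp),
      intensity = as.vector(intensity) * as.vector(tech),
      .expected = as.vector(expected),
      .u_drop = as.vector(u_drop)
    )
    per_protein[[i]] <- dt
    truth_rows[[i]] <- data.table::data.table(
      protein_id = protein_ids[i], gene = genes[i],
      base_abundance = base,
      differential = nrow(rows) > 0,
      fc_B_HF = fc$magnitude[["B_HF"]], dir_B_HF = fc$direction[["B_HF"]],
      fc_HF_R = fc$magnitude[["HF_R"]], dir_HF_R = fc$direction[["HF_R"]],
      fc_B_R = fc$magnitude[["B_R"]], dir_B_R = fc$direction[["B_R"]]
    )
  }
  ions <- data.table::rbindlist(per_protein)
  truth <- data.table::rbindlist(truth_rows)

  if (config$missingness_rate > 0) {
    thr <- stats::quantile(ions$.expected, config$censor_quantile, type = 7)
    p_drop <- min(1, config$missingness_rate / config$censor_quantile)
    drop <- ions$.expected < thr & ions$.u_drop < p_drop
    ions <- ions[!drop]
  }
  ions[, c(".expected", ".u_drop") := NULL]
  data.table::setkey(ions, protein_id, peptide_id, ion_id, sample_id, injection)
  list(ions = ions[], truth = truth)
}

.ion_cols <- c("protein_id", "gene", "peptide_id", "ion_id", "sample_id",
               "group", "injection", "intensity")

#' Write / read a long-format ion intensity table
#'
#' The on-disk format is CSV with header
#' \code{protein_id,gene,peptide_id,ion_id,sample_id,group,injection,intensity};
#' below-detection measurements are absent rows, not zeros. Intensities are
#' serialized at full precision so a write/read round-trip is exact.
#'
#' @param table ion table as produced by \code{\link{generate_study}}.
#' @param path file path.
#' @return \code{read_ion_table} returns a keyed \code{data.table};
#'   \code{write_ion_table} returns \code{path} invisibly.
#' @export
write_ion_table <- function(table, path) {
  stopifnot(all(.ion_cols %in% names(table)))
  out <- data.table::as.data.table(table)[, .ion_cols, with = FALSE]
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_ion_table
#' @export
read_ion_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, .ion_cols))
    stop("malformed header: expected ", paste(.ion_cols, collapse = ","),
         " but found ", paste(header, collapse = ","))
  dt <- data.table::fread(path, colClasses = list(
    character = c("protein_id", "gene", "peptide_id", "ion_id", "sample_id",
                  "group"),
    integer = "injection", numeric = "intensity"))
  if (nrow(dt) == 0) {
    data.table::setkey(dt, protein_id, peptide_id, ion_id, sample_id, injection)
    return(dt[])
  }
  bad <- which(!is.finite(dt$intensity) | dt$intensity < 0)
  if (length(bad))
    stop("negative or non-finite intensity at row ", bad[1])
  dup <- which(duplicated(dt[, c("protein_id", "peptide_id", "ion_id",
                                 "sample_id", "injection")]))
  if (length(dup))
    stop("duplicated (protein, peptide, ion, sample, injection) key at row ",
         dup[1])
  data.table::setkey(dt, protein_id, peptide_id, ion_id, sample_id, injection)
  dt[]
}

#' Write / read simulator ground truth
#'
#' Companion CSV for \code{\link{generate_study}}'s truth table: one row per
#' protein with its base abundance and the magnitude and direction of the
#' three pairwise fold-changes.
#'
#' @param truth truth table from \code{\link{generate_study}}.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  data.table::fwrite(data.table::as.data.table(truth), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  data.table::fread(path)
}
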