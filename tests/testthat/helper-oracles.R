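# Independent oracles, deliberately written from first principles so they
# share no code path with the package implementation.

# Benjamini-Hochberg step-up: sort ascending, p_(i) * m / i, enforce
# monotonicity from the largest rank downward, cap at 1, restore order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Welch t, Welch-Satterthwaite df and two-sided p from the direct formulas.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(y) - mean(x)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Type-7 (linear interpolation between closest order statistics) quantile.
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

lod_oracle <- function(per_sample_values, k = 1.5) {
  q1 <- quantile7_oracle(per_sample_values, 0.25)
  q3 <- quantile7_oracle(per_sample_values, 0.75)
  q1 - k * (q3 - q1)
}

# Brute-force rollup: per ion-sample median over injections, summed per
# peptide then per protein, via explicit loops.
rollup_oracle <- function(df) {
  out <- list()
  for (p in unique(df$protein_id)) {
    dp <- df[df$protein_id == p, ]
    for (s in unique(dp$sample_id)) {
      dps <- dp[dp$sample_id == s, ]
      total <- 0
      for (pep in unique(dps$peptide_id)) {
        dpp <- dps[dps$peptide_id == pep, ]
        for (i in unique(dpp$ion_id))
          total <- total + median(dpp$intensity[dpp$ion_id == i])
      }
      out[[length(out) + 1]] <- data.frame(protein_id = p, sample_id = s,
                                           area = total)
    }
  }
  do.call(rbind, out)
}

# Build a long ion table from explicit per-injection intensities.
# spec: list of lists with protein, peptide, ion, sample, group, values.
make_ions <- function(spec) {
  rows <- lapply(spec, function(r) {
    data.frame(protein_id = r$protein, gene = toupper(r$protein),
               peptide_id = r$peptide, ion_id = r$ion,
               sample_id = r$sample,
               group = if (is.null(r$group)) "Baseline" else r$group,
               injection = seq_along(r$values), intensity = r$values,
               stringsAsFactors = FALSE)
  })
  data.table::as.data.table(do.call(rbind, rows))
}

# Random small ion table for property checks.
random_ion_table <- function(n_proteins = 3, n_samples = 4, n_inj = 3,
                             seed = 1) {
  set.seed(seed)
  spec <- list()
  for (p in seq_len(n_proteins)) {
    n_pep <- sample(1:3, 1)
    for (pe in seq_len(n_pep)) {
      n_ion <- sample(1:3, 1)
      for (io in seq_len(n_ion)) {
        for (s in seq_len(n_samples)) {
          spec[[length(spec) + 1]] <- list(
            protein = sprintf("prot%d", p),
            peptide = sprintf("prot%d_pep%d", p, pe),
            ion = sprintf("prot%d_pep%d_ion%d", p, pe, io),
            sample = sprintf("S%d", s),
            values = round(runif(n_inj, 10, 1000), 3))
        }
      }
    }
  }
  make_ions(spec)
}

# The published per-protein marker categories (the three abundance-pattern
# groups of the candidate-marker table), used to check categorization.
published_categories <- function() {
  list(
    injury = c("FLNA", "APOE", "TLN1", "FLNB", "ITGB1", "TPP1", "TCP1",
               "HSP90B1", "GM2A", "CCT8", "TXNDC17", "GC", "CCT3",
               "CRYZ", "APOA2", "UPP2", "PRDX1"),
    recovery = "APOA4",
    long_term = c("CCT6A", "PDXK"))
}
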