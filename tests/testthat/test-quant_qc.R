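two_sample_table <- function(totals = c(S1 = 100, S2 = 300)) {
  make_ions(lapply(names(totals), function(s)
    list(protein = "p1", peptide = "p1_pep1", ion = "p1_pep1_ion1",
         sample = s, values = totals[[s]])))
}

test_that("AUC normalization scales every sample to the grand mean total", {
  res <- auc_normalize(two_sample_table(c(S1 = 100, S2 = 300)))
  expect_equal(unname(res$factors[c("S1", "S2")]), c(2, 2 / 3))
  totals <- tapply(res$table$intensity, res$table$sample_id, sum)
  expect_equal(as.numeric(totals), c(200, 200))

  eq <- auc_normalize(two_sample_table(c(S1 = 50, S2 = 50)))
  expect_equal(unname(eq$factors), c(1, 1))
  expect_equal(eq$table$intensity, two_sample_table(c(S1 = 50, S2 = 50))$intensity)

  one <- auc_normalize(two_sample_table(c(S1 = 70)))
  expect_equal(unname(one$factors), 1)

  bad <- two_sample_table(c(S1 = 0, S2 = 10))
  expect_error(auc_normalize(bad), "S1")
})

test_that("normalization conserves the sum of sample totals", {
  for (seed in 1:5) {
    tab <- random_ion_table(seed = seed)
    res <- auc_normalize(tab)
    expect_equal(sum(res$table$intensity), sum(tab$intensity))
  }
})

test_that("quartiles match the order-statistics oracle", {
  q <- quartiles(1:8)
  expect_equal(q$q1, quantile7_oracle(1:8, 0.25))
  expect_equal(q$q3, quantile7_oracle(1:8, 0.75))
  expect_equal(q$q1, 2.75)
  expect_equal(q$q3, 6.25)
  expect_equal(q$iqr, 3.5)

  const <- quartiles(rep(4, 6))
  expect_equal(const$q1, 4); expect_equal(const$q3, 4)
  expect_equal(const$iqr, 0)

  single <- quartiles(5)
  expect_equal(single$q1, 5); expect_equal(single$q3, 5)

  expect_error(quartiles(numeric(0)), "finite value")

  for (seed in 1:20) {
    set.seed(seed)
    v <- runif(sample(2:30, 1), 0, 100)
    q <- quartiles(v)
    expect_equal(q$q1, quantile7_oracle(v, 0.25))
    expect_equal(q$q3, quantile7_oracle(v, 0.75))
    expect_lte(q$q1, q$q3)
  }
})

test_that("detection-limit filter removes only values strictly below the LOD", {
  # constant ion across four samples: LOD equals the value, nothing removed
  tab <- make_ions(lapply(1:4, function(s)
    list(protein = "p1", peptide = "p1_pep1", ion = "i1",
         sample = paste0("S", s), values = 10)))
  res <- detection_limit_filter(tab)
  expect_identical(nrow(res$exclusions), 0L)
  expect_identical(nrow(res$table), nrow(tab))

  # one extreme low outlier among tight values: removed iff below oracle LOD
  vals <- c(100, 101, 102, 103, 5)
  tab <- make_ions(lapply(seq_along(vals), function(s)
    list(protein = "p1", peptide = "p1_pep1", ion = "i1",
         sample = paste0("S", s), values = vals[s])))
  lod <- lod_oracle(vals)
  expect_true(5 < lod)
  res <- detection_limit_filter(tab)
  expect_identical(res$exclusions$sample_id, "S5")
  expect_identical(res$exclusions$reason, "below_LOD")
  expect_false("S5" %in% res$table$sample_id)

  # ion observed in a single sample: IQR 0, retained
  tab <- make_ions(list(list(protein = "p1", peptide = "p1_pep1", ion = "i1",
                             sample = "S1", values = c(3, 4, 5))))
  res <- detection_limit_filter(tab)
  expect_identical(nrow(res$exclusions), 0L)
  expect_identical(nrow(res$table), 3L)
})

test_that("the LOD operates on injection means and drops whole ion-sample units", {
  # S5's injections average 5 (below LOD) even though one injection is high
  spec <- lapply(1:4, function(s)
    list(protein = "p1", peptide = "p1_pep1", ion = "i1",
         sample = paste0("S", s), values = c(100, 100, 100)))
  spec[[5]] <- list(protein = "p1", peptide = "p1_pep1", ion = "i1",
                    sample = "S5", values = c(1, 1, 13))
  res <- detection_limit_filter(make_ions(spec))
  expect_identical(res$exclusions$sample_id, "S5")
  expect_identical(sum(res$table$sample_id == "S5"), 0L)
})

test_that("CV filter flags replicate CVs and excludes ions dataset-wide", {
  # injections {100,100,160}: CV ~ 28.9% > 25 => flagged for that sample
  spec <- lapply(1:10, function(s)
    list(protein = "p1", peptide = "p1_pep1", ion = "i1",
         sample = paste0("S", s),
         values = if (s == 1) c(100, 100, 160) else c(100, 101, 99)))
  res <- cv_filter(make_ions(spec))
  cv1 <- res$cv[res$cv$sample_id == "S1", ]
  expect_equal(cv1$cv_pct, 100 * sd(c(100, 100, 160)) / 120)
  expect_true(cv1$flagged)
  # flagged in 1 of 10 samples (10% < 20%): ion retained
  expect_identical(nrow(res$exclusions), 0L)

  # flagged in 2 of 10 samples (20% >= 20%): ion removed everywhere
  spec2 <- spec
  spec2[[2]]$values <- c(100, 100, 160)
  res2 <- cv_filter(make_ions(spec2))
  expect_identical(res2$exclusions$reason, "high_CV")
  expect_identical(nrow(res2$table), 0L)

  # identical triplets everywhere: CV 0, retained
  spec3 <- lapply(1:5, function(s)
    list(protein = "p1", peptide = "p1_pep1", ion = "i1",
         sample = paste0("S", s), values = c(7, 7, 7)))
  res3 <- cv_filter(make_ions(spec3))
  expect_identical(nrow(res3$exclusions), 0L)

  # single injections only: no computable CV anywhere => excluded with reason
  spec4 <- lapply(1:3, function(s)
    list(protein = "p1", peptide = "p1_pep1", ion = "i1",
         sample = paste0("S", s), values = 5))
  res4 <- cv_filter(make_ions(spec4))
  expect_identical(res4$exclusions$reason, "no_computable_cv")
  expect_identical(nrow(res4$table), 0L)
})

test_that("rollup selects injection medians and sums hierarchically", {
  tab <- make_ions(list(list(protein = "p1", peptide = "p1_pep1", ion = "i1",
                             sample = "S1", values = c(8, 10, 100))))
  q <- rollup(tab)
  expect_equal(q$area, 10)

  tab <- make_ions(list(
    list(protein = "p1", peptide = "P1", ion = "i1", sample = "S1", values = 5),
    list(protein = "p1", peptide = "P1", ion = "i2", sample = "S1", values = 7),
    list(protein = "p1", peptide = "P2", ion = "i3", sample = "S1", values = 10)))
  q <- rollup(tab)
  expect_equal(q$area, 22)
  expect_identical(q$n_ions, 3L)

  # protein absent in a sample: no row, not a zero
  tab <- make_ions(list(
    list(protein = "p1", peptide = "P1", ion = "i1", sample = "S1", values = 5),
    list(protein = "p2", peptide = "P2", ion = "i2", sample = "S2", values = 9)))
  q <- rollup(tab)
  expect_identical(nrow(q), 2L)
  expect_false(any(q$protein_id == "p1" & q$sample_id == "S2"))
  m <- protein_matrix(q)
  expect_true(is.na(m["p1", "S2"]))
})

test_that("rollup equals brute-force re-aggregation on random tables", {
  for (seed in 1:5) {
    tab <- random_ion_table(seed = seed)
    q <- rollup(tab)
    oracle <- rollup_oracle(as.data.frame(tab))
    merged <- merge(as.data.frame(q), oracle, by = c("protein_id", "sample_id"))
    expect_identical(nrow(merged), nrow(q))
    expect_equal(merged$area.x, merged$area.y)
  }
})

test_that("filters are monotone in their thresholds", {
  tab <- generate_study(sim_config(n_proteins = 15, seed = 13,
                                   technical_cv_pct = 25))$ions
  norm <- auc_normalize(tab)$table
  # lowering the CV threshold never increases the set of retained ions
  retained <- sapply(c(40, 25, 15, 8), function(thr) {
    res <- cv_filter(norm, qc_config(cv_threshold_pct = thr))
    length(unique(res$table$ion_id))
  })
  expect_true(all(diff(retained) <= 0))
  # raising the LOD multiplier never decreases retained measurements
  kept <- sapply(c(0.5, 1, 1.5, 3), function(k) {
    nrow(detection_limit_filter(norm, qc_config(lod_iqr_multiplier = k))$table)
  })
  expect_true(all(diff(kept) >= 0))
})

test_that("a clean, noise-free table passes the stage order unchanged", {
  # two proteins, identical sample totals, zero variance everywhere
  spec <- list()
  for (s in c("S1", "S2", "S3")) {
    spec[[length(spec) + 1]] <- list(protein = "p1", peptide = "P1",
                                     ion = "i1", sample = s,
                                     values = c(40, 40, 40))
    spec[[length(spec) + 1]] <- list(protein = "p1", peptide = "P2",
                                     ion = "i2", sample = s,
                                     values = c(10, 10, 10))
    spec[[length(spec) + 1]] <- list(protein = "p2", peptide = "P3",
                                     ion = "i3", sample = s,
                                     values = c(50, 50, 50))
  }
  res <- run_qc(make_ions(spec))
  expect_identical(nrow(res$report$exclusions), 0L)
  expect_true(all(res$report$factors == 1))
  q <- res$quant
  expect_equal(q$area[q$protein_id == "p1"], rep(50, 3))
  expect_equal(q$area[q$protein_id == "p2"], rep(50, 3))
})
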