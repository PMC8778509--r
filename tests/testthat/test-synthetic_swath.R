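test_that("configuration invariants are enforced", {
  expect_error(sim_config(group_sizes = c(A = 1, B = 5)), "at least 2")
  expect_error(sim_config(missingness_rate = 1), "missingness")
  expect_error(sim_config(technical_cv_pct = 0), "technical_cv_pct")
  expect_error(sim_config(fc_map = data.frame(
    protein_id = "P0001", comparison = "B_HF", magnitude = 0.5,
    direction = "up")), "magnitude")
  expect_error(sim_config(fc_magnitude = 0.8), "fc_magnitude")
})

test_that("record count equals the enumeration of the generated design", {
  cfg <- sim_config(n_proteins = 100, seed = 1)
  st <- generate_study(cfg)
  ions <- st$ions
  # brute-force enumeration: ions per protein x samples x injections
  keys <- unique(ions[, c("protein_id", "peptide_id", "ion_id")])
  n_samples <- sum(cfg$group_sizes)
  expect_identical(nrow(ions),
                   nrow(keys) * n_samples * cfg$n_injections)
  # every (ion, sample) unit carries the configured number of injections
  per_unit <- table(paste(ions$ion_id, ions$sample_id))
  expect_true(all(per_unit == cfg$n_injections))
  # peptide and ion counts respect the configured ranges
  pep_per_prot <- tapply(ions$peptide_id, ions$protein_id,
                         function(x) length(unique(x)))
  expect_true(all(pep_per_prot >= 1 & pep_per_prot <= 6))
})

test_that("same config and seed give byte-identical output", {
  cfg <- sim_config(n_proteins = 12, seed = 42, n_differential = 3,
                    missingness_rate = 0.1)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$ions, b$ions)
  expect_identical(a$truth, b$truth)
})

test_that("null design lists zero differential proteins with unit fold-changes", {
  st <- generate_study(sim_config(n_proteins = 10, seed = 3,
                                  n_differential = 0))
  expect_false(any(st$truth$differential))
  expect_true(all(st$truth$fc_B_HF == 1 & st$truth$fc_HF_R == 1 &
                    st$truth$fc_B_R == 1))
  expect_true(all(st$truth$dir_B_HF == "none"))
})

test_that("fc_map group effects imply consistent pairwise fold-changes", {
  fc <- data.frame(protein_id = c("P0001", "P0002"),
                   comparison = c("B_HF", "B_R"),
                   magnitude = c(2.6, 1.5),
                   direction = c("up", "down"))
  st <- generate_study(sim_config(n_proteins = 3, seed = 5, fc_map = fc))
  tr <- st$truth
  # P0001: HF up 2.6, Recovery unchanged => HF_R down 2.6, B_R none
  expect_equal(tr$fc_B_HF[1], 2.6)
  expect_equal(tr$fc_HF_R[1], 2.6)
  expect_identical(tr$dir_HF_R[1], "down")
  expect_equal(tr$fc_B_R[1], 1)
  # P0002: Recovery down 1.5, HF unchanged => HF_R down 1.5
  expect_equal(tr$fc_B_R[2], 1.5)
  expect_identical(tr$dir_B_R[2], "down")
  expect_equal(tr$fc_HF_R[2], 1.5)
  # P0003 untouched
  expect_false(tr$differential[3])
})

test_that("rolled-up grand mean recovers base abundance without dropout", {
  cfg <- sim_config(n_proteins = 4, seed = 8,
                    group_sizes = c(Baseline = 80, HeartFailure = 2,
                                    Recovery = 2),
                    technical_cv_pct = 10, biological_cv_pct = 20,
                    sample_scale_cv_pct = 10, missingness_rate = 0)
  st <- generate_study(cfg)
  q <- rollup(st$ions)   # raw rollup, no normalization
  base <- q[q$group == "Baseline", ]
  for (p in st$truth$protein_id) {
    grand <- mean(base$area[base$protein_id == p])
    expect_lt(abs(grand / st$truth$base_abundance[
      st$truth$protein_id == p] - 1), 0.15)
  }
})

test_that("injected technical CV is recovered from injection replicates", {
  cfg <- sim_config(n_proteins = 50, seed = 9, technical_cv_pct = 15,
                    missingness_rate = 0)
  st <- generate_study(cfg)
  dt <- data.table::as.data.table(st$ions)
  cv <- dt[, list(cv = stats::sd(intensity) / mean(intensity)),
           by = c("ion_id", "sample_id")]
  expect_gt(nrow(cv), 1000)
  pooled <- sqrt(mean(cv$cv^2)) * 100
  expect_lt(abs(pooled / 15 - 1), 0.20)
})

test_that("group-mean ratios converge to the true magnitude", {
  cfg <- sim_config(n_proteins = 3, seed = 10, n_differential = 2,
                    fc_magnitude = 2, fc_direction = "up",
                    group_sizes = c(Baseline = 40, HeartFailure = 40,
                                    Recovery = 2),
                    missingness_rate = 0)
  st <- generate_study(cfg)
  # raw rollup: with 2 of 3 proteins spiked, total-intensity normalization
  # would shift the totals and bias the ratio (a compositional property of
  # AUC normalization, not of the generator under test here)
  q <- rollup(st$ions)
  for (p in st$truth$protein_id[st$truth$differential]) {
    mb <- mean(q$area[q$protein_id == p & q$group == "Baseline"])
    mh <- mean(q$area[q$protein_id == p & q$group == "HeartFailure"])
    expect_lt(abs((mh / mb) / 2 - 1), 0.25)
  }
})

test_that("dropout hits low-intensity ions preferentially and thins the table", {
  cfg0 <- sim_config(n_proteins = 40, seed = 11, missingness_rate = 0)
  cfg1 <- sim_config(n_proteins = 40, seed = 11, missingness_rate = 0.10,
                     censor_quantile = 0.25)
  full <- generate_study(cfg0)$ions
  thin <- generate_study(cfg1)$ions
  expect_lt(nrow(thin), nrow(full))
  dropped_ions <- setdiff(paste(full$ion_id, full$sample_id),
                          paste(thin$ion_id, thin$sample_id))
  m <- tapply(full$intensity, paste(full$ion_id, full$sample_id), mean)
  expect_lt(median(m[dropped_ions]), median(m))
})

test_that("ion table round-trips through CSV exactly", {
  st <- generate_study(sim_config(n_proteins = 2, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_ion_table(st$ions, path)
  back <- read_ion_table(path)
  expect_equal(as.data.frame(back), as.data.frame(st$ions))

  tpath <- tempfile(fileext = ".csv")
  write_ground_truth(st$truth, tpath)
  expect_equal(as.data.frame(read_ground_truth(tpath)),
               as.data.frame(st$truth))
})

test_that("reader rejects malformed tables and accepts empty ones", {
  hdr <- "protein_id,gene,peptide_id,ion_id,sample_id,group,injection,intensity"
  row <- "P1,G1,P1_pep1,P1_pep1_ion1,S1,Baseline,1,10.5"

  f <- tempfile(); writeLines(c(hdr, row, row), f)
  expect_error(read_ion_table(f), "duplicated")

  f <- tempfile()
  writeLines(c(hdr, "P1,G1,P1_pep1,P1_pep1_ion1,S1,Baseline,1,-3"), f)
  expect_error(read_ion_table(f), "negative")

  f <- tempfile(); writeLines("a,b,c", f)
  expect_error(read_ion_table(f), "malformed header")

  f <- tempfile(); writeLines(hdr, f)
  empty <- read_ion_table(f)
  expect_identical(nrow(empty), 0L)
})
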