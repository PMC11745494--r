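small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_patients = 1, n_naive_clones = 150,
             umis_per_sample = 800, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_repertoires(small_cfg(42), emit_umi = TRUE)
  s2 <- simulate_repertoires(small_cfg(42), emit_umi = TRUE)
  expect_identical(s1$airr, s2$airr)
  expect_identical(s1$umi, s2$umi)
  expect_identical(s1$truth$clones, s2$truth$clones)
  s3 <- simulate_repertoires(small_cfg(43), emit_umi = FALSE)
  expect_false(identical(s1$airr, s3$airr))
})

test_that("simulated output honours the configured replicate design", {
  sim <- simulate_repertoires(small_cfg(7), emit_umi = FALSE)
  reps <- repertoires_from_airr(sim$airr)
  # 3 tum fragments + 1 LN + 1 PBMC, 2 replicates each
  expect_equal(length(reps), 10L)
  expect_true(all(vapply(reps, function(r) r$total_umi, numeric(1)) == 800))
  meta <- vapply(reps, function(r) r$metadata$tissue, character(1))
  expect_equal(sum(meta == "tum"), 6L)
  # within a repertoire keys are unique and frequencies sum to one
  for (r in reps) {
    expect_equal(sum(r$clonotypes$frequency), 1, tolerance = 1e-9)
    expect_false(anyDuplicated(tribcr:::clonotype_key(
      r$clonotypes$cdr3_nt, r$clonotypes$v_gene, r$clonotypes$j_gene)) > 0)
  }
})

test_that("junctions are in-frame, stop-free and germline-anchored", {
  sim <- simulate_repertoires(small_cfg(11), emit_umi = FALSE)
  expect_true(all(nchar(sim$airr$junction) %% 3 == 0))
  expect_false(any(grepl("\\*", sim$airr$junction_aa)))
  germ <- germline_reference()
  # every junction starts with its V allele's junction tail prefix
  row <- sim$airr[17, ]
  vrow <- germ[germ$gene == row$v_call, ]
  v_tail <- substr(vrow$sequence, nchar(vrow$sequence) - 11,
                   nchar(vrow$sequence))
  expect_equal(substr(row$junction, 1, 12), v_tail)
})

test_that("ground truth records lineages with plausible mutation loads", {
  cfg <- small_cfg(19, lineage_rate = 0.4, lineage_size_mean = 5,
                   shm_rate = 0.03, cdr3_len_range = c(45, 45))
  sim <- simulate_repertoires(cfg, emit_umi = FALSE)
  clones <- sim$truth$clones
  members <- clones[!is.na(clones$lineage_seed) &
                      clones$edge_mutations > 0, ]
  expect_gt(nrow(members), 30)
  # per-edge mutations ~ max(1, Pois(lambda)), lambda = shm_rate * len
  lambda <- 0.03 * 45
  want <- lambda + exp(-lambda)          # E[max(1, Pois(lambda))]
  se <- sd(members$edge_mutations) / sqrt(nrow(members))
  expect_lt(abs(mean(members$edge_mutations) - want), 3 * se + 0.1)
  # founders carry no mutations
  founders <- clones[clones$true_mutations == 0, ]
  expect_gt(nrow(founders), 100)
})

test_that("per-tissue isotype fractions converge to the configured mixture", {
  cfg <- sim_config(seed = 5, n_patients = 1, n_naive_clones = 2500,
                    umis_per_sample = 6000,
                    tissues = "PBMC", fragments = c(PBMC = 1), replicates = 1,
                    expansions = list(n = 0, fold = 1, tissue = "PBMC"),
                    expr_sigma = 0.3)
  sim <- simulate_repertoires(cfg, emit_umi = FALSE)
  reps <- repertoires_from_airr(sim$airr)
  fr <- isotype_fractions(reps[[1]], weight = "clonotype")
  want <- cfg$isotype_probs$PBMC
  for (iso in names(want)) {
    expect_lt(abs(fr[[iso]] - want[[iso]]), 0.05)
  }
})

test_that("zero contamination leaves nothing for decontamination to remove", {
  sim <- simulate_repertoires(small_cfg(3, contamination_rate = 0),
                              emit_umi = TRUE)
  res <- decontaminate(sim$umi)
  expect_equal(nrow(res$removals), 0L)
  expect_null(sim$truth$contamination)
})

test_that("planted contamination is logged and mostly recovered", {
  sim <- simulate_repertoires(small_cfg(13, contamination_rate = 0.01),
                              emit_umi = TRUE)
  planted <- sim$truth$contamination
  expect_gt(nrow(planted), 0)
  res <- decontaminate(sim$umi)
  removed_keys <- paste(res$removals$sample_id, res$removals$umi)
  planted_keys <- paste(planted$sample_id, planted$umi)
  # planted copies collide with their donors and must be removed
  expect_gt(mean(planted_keys %in% removed_keys), 0.9)
  # clean UMIs are almost never touched (random 12-mer tag collisions only)
  expect_lt(nrow(res$removals), nrow(planted) * 3)
})

test_that("tissue sharing drives overlap direction", {
  set.seed(NULL)
  wins <- 0
  for (seed in 1:10) {
    sim <- simulate_repertoires(small_cfg(seed), emit_umi = FALSE)
    reps <- repertoires_from_airr(sim$airr)
    tiss <- vapply(reps, function(r) r$metadata$tissue, character(1))
    pool <- function(t) pool_repertoires(reps[tiss == t], warn_context = FALSE)
    tum <- pool("tum"); ln <- pool("LN"); pbmc <- pool("PBMC")
    if (f2(tum, ln) > f2(tum, pbmc)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("worked fixtures reproduce the module example values", {
  fx <- worked_fixtures()
  expect_equal(f2(bcr_repertoire(fx$f2_a), bcr_repertoire(fx$f2_b)),
               sqrt(0.1), tolerance = 1e-9)
  tp <- triangle_points(fx$triangle, compartments = c("tum", "LN", "PBMC"))
  expect_equal(tp$chi2, 3.8, tolerance = 1e-12)
  dec <- decontaminate(fx$umi)
  expect_equal(dec$removals$sample_id, "s2")
  # writing and re-reading is lossless
  dir <- withr::local_tempdir()
  worked_fixtures(dir)
  back <- readr::read_tsv(file.path(dir, "triangle.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(fx$triangle))
})
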