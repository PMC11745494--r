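test_that("read_airr computes UMI frequencies and parses isotypes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    sequence_id = c("a", "b", "c"),
    junction = c("TGTGCGAAATGG", "TGTGCGCCCTGG", "TGTGCGGGGTGG"),
    v_call = "IGHV1-1*01", j_call = "IGHJ4*01",
    c_call = c("IGHM", "IGHG2", "IGHA1"),
    duplicate_count = c(6, 3, 1)), path)
  rep <- read_airr(path)
  expect_s3_class(rep, "bcr_repertoire")
  expect_equal(sort(rep$clonotypes$frequency, decreasing = TRUE),
               c(0.6, 0.3, 0.1))
  expect_setequal(rep$clonotypes$isotype, c("IgM", "IgG", "IgA"))
  expect_equal(rep$total_umi, 10L)
})

test_that("read_airr errors name the missing mandatory column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    junction = "TGTGCGAAATGG", j_call = "IGHJ4*01", duplicate_count = 2), path)
  expect_error(read_airr(path), "v_call")
})

test_that("records differing only in constant-region call merge into one clonotype", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    junction = "TGTGCGAAATGG", v_call = "IGHV1-1*01", j_call = "IGHJ4*01",
    c_call = c("IGHG1", "IGHG2"), duplicate_count = c(5, 2)), path)
  rep <- read_airr(path)
  expect_equal(nrow(rep$clonotypes), 1L)
  expect_equal(rep$clonotypes$umi_count, 7)
  expect_equal(rep$clonotypes$isotype, "IgG")
})

test_that("merged isotype is the dominant constituent, ties IgM > IgG > IgA", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    junction = rep("TGTGCGAAATGG", 3), v_call = "IGHV1-1*01",
    j_call = "IGHJ4*01", c_call = c("IGHM", "IGHG1", "IGHA2"),
    duplicate_count = c(2, 9, 2)), path)
  expect_equal(read_airr(path)$clonotypes$isotype, "IgG")
  readr::write_tsv(tibble::tibble(
    junction = "TGTGCGAAATGG", v_call = "IGHV1-1*01", j_call = "IGHJ4*01",
    c_call = c("IGHA1", "IGHM"), duplicate_count = c(4, 4)), path)
  expect_equal(read_airr(path)$clonotypes$isotype, "IgM")
})

test_that("write -> read round-trip preserves keys, counts and labels", {
  set.seed(11)
  rep <- make_rep(setNames(sample(2:40, 25), rand_nt(25, 36)),
                  isotype = sample(c("IgM", "IgG", "IgA"), 25, replace = TRUE),
                  sample_id = "p01_tum1_r1", patient_id = "p01",
                  tissue = "tum", fragment_id = "tum1", replicate_id = "r1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_airr(rep, path)
  back <- read_airr(path)
  ord <- function(cl) cl[order(cl$cdr3_nt), ]
  a <- ord(rep$clonotypes); b <- ord(back$clonotypes)
  expect_identical(a$cdr3_nt, b$cdr3_nt)
  expect_identical(a$v_gene, b$v_gene)
  expect_identical(a$isotype, b$isotype)
  expect_equal(a$umi_count, b$umi_count)
  expect_equal(a$frequency, b$frequency)
  expect_identical(back$metadata$sample_id, "p01_tum1_r1")
  expect_identical(back$metadata$tissue, "tum")
})

test_that("singleton filter and the 50-clonotype sample rule", {
  set.seed(4)
  counts <- c(rep(1, 15), sample(2:30, 45, replace = TRUE))
  rep <- make_rep(setNames(counts, rand_nt(60, 30)))
  filt <- apply_filters(rep)
  expect_equal(n_clonotypes(filt), 45L)
  expect_true(is_excluded(filt))      # 45 <= 50
  expect_equal(sum(filt$clonotypes$frequency), 1, tolerance = 1e-12)

  rep51 <- make_rep(setNames(sample(2:30, 51, replace = TRUE), rand_nt(51, 30)))
  expect_false(is_excluded(apply_filters(rep51)))   # "50 or less" excludes; 51 passes

  # min_umi_per_clonotype = 1 is the identity transform up to renormalization
  same <- apply_filters(rep, min_umi_per_clonotype = 1, min_clonotypes = 0)
  expect_equal(n_clonotypes(same), 60L)
  expect_equal(same$clonotypes$frequency, rep$clonotypes$frequency)

  # keep_singletons mode retains everything for lineage analyses
  lin <- apply_filters(rep, keep_singletons = TRUE, min_clonotypes = 0)
  expect_equal(n_clonotypes(lin), 60L)
})

test_that("pooling is the mean of per-file frequencies with implicit zeros", {
  a <- make_rep(c(AAA = 4, CCC = 6))               # freqs 0.4, 0.6
  b <- make_rep(c(AAA = 5))                        # freq 1
  pooled <- pool_repertoires(list(a, b))
  cl <- pooled$clonotypes[order(pooled$clonotypes$cdr3_nt), ]
  expect_equal(cl$frequency[cl$cdr3_nt == "AAA"], (0.4 + 1) / 2)
  expect_equal(cl$frequency[cl$cdr3_nt == "CCC"], 0.3)
  expect_equal(sum(cl$frequency), 1, tolerance = 1e-12)
  expect_equal(cl$umi_count[cl$cdr3_nt == "AAA"], 9)

  # clonotype at (0.1, 0.3) across two replicates pools to 0.2
  r1 <- make_rep(c(TTT = 1, GGG = 9))
  r2 <- make_rep(c(TTT = 3, GGG = 7))
  p2 <- pool_repertoires(list(r1, r2))
  expect_equal(p2$clonotypes$frequency[p2$clonotypes$cdr3_nt == "TTT"], 0.2)
})

test_that("pooling identical repertoires is idempotent and order-invariant", {
  set.seed(21)
  r <- make_rep(setNames(sample(1:50, 20), rand_nt(20, 33)))
  same <- pool_repertoires(list(r, r))
  ord <- order(same$clonotypes$cdr3_nt)
  ord0 <- order(r$clonotypes$cdr3_nt)
  expect_equal(same$clonotypes$frequency[ord], r$clonotypes$frequency[ord0])

  s <- make_rep(setNames(sample(1:50, 15), rand_nt(15, 33)))
  t <- make_rep(setNames(sample(1:50, 10), rand_nt(10, 33)))
  p_ab <- pool_repertoires(list(r, s, t))
  p_ba <- pool_repertoires(list(t, r, s))
  oa <- order(p_ab$clonotypes$cdr3_nt); ob <- order(p_ba$clonotypes$cdr3_nt)
  expect_equal(p_ab$clonotypes$frequency[oa], p_ba$clonotypes$frequency[ob])
  expect_identical(p_ab$clonotypes$cdr3_nt[oa], p_ba$clonotypes$cdr3_nt[ob])
})

test_that("degenerate inputs are rejected with typed errors", {
  expect_error(pool_repertoires(list()), "no repertoires")
  expect_error(bcr_repertoire(tibble::tibble(
    cdr3_nt = c("AAA", "AAA"), v_gene = "V", j_gene = "J",
    umi_count = c(1, 2))), "duplicate")
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    junction = "TGT", v_call = "V", j_call = "J", duplicate_count = 0), path)
  expect_error(read_airr(path), "empty repertoire")
})
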