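germ <- germline_reference()

# a lineage planted directly on germline fragments: junction = V tail (12 nt)
# + fixed middle + J head (12 nt)
plant_lineage <- function(n, n_mut_each = 2, middle = "GGGACTACTGCT",
                          v = "IGHV9-1*01", j = "IGHJ9-1*01", seed = 1) {
  set.seed(seed)
  vrow <- germ[germ$gene == v, ]; jrow <- germ[germ$gene == j, ]
  v_tail <- substr(vrow$sequence, nchar(vrow$sequence) - 11, nchar(vrow$sequence))
  j_head <- substr(jrow$sequence, 1, 12)
  naive <- paste0(v_tail, middle, j_head)
  seqs <- vapply(seq_len(n), function(i) {
    s <- strsplit(naive, "")[[1]]
    pos <- sample(length(s), n_mut_each)
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste(s, collapse = "")
  }, character(1))
  tibble::tibble(cdr3_nt = unique(c(naive, seqs)), v_gene = v, j_gene = j)
}

test_that("threshold detection finds the valley of a bimodal mixture", {
  set.seed(100)
  d <- c(rnorm(1000, 0.05, 0.02), rnorm(1000, 0.30, 0.05))
  thr <- detect_threshold(d)
  expect_false(attr(thr, "fallback"))
  # analytic minimum of the true mixture density between the modes
  mix <- function(x) 0.5 * dnorm(x, 0.05, 0.02) + 0.5 * dnorm(x, 0.30, 0.05)
  x_star <- optimize(mix, c(0.07, 0.28))$minimum
  expect_lt(abs(as.numeric(thr) - x_star), 0.03)
})

test_that("threshold detection is shift-consistent", {
  set.seed(101)
  d <- c(rnorm(800, 0.05, 0.02), rnorm(800, 0.30, 0.05))
  t0 <- as.numeric(detect_threshold(d))
  t1 <- as.numeric(detect_threshold(d + 0.05))
  expect_lt(abs((t1 - t0) - 0.05), 0.02)
})

test_that("degenerate distance samples fall back with a flag", {
  uni <- detect_threshold(rnorm(500, 0.3, 0.05))
  expect_true(attr(uni, "fallback"))
  expect_equal(as.numeric(uni), 0.15)
  expect_true(attr(detect_threshold(rep(0.2, 100)), "fallback"))
  expect_true(attr(detect_threshold(runif(5)), "fallback"))
})

test_that("single-linkage chains merge; distant junctions stay singletons", {
  # pairwise distances 0.10 / 0.10 / 0.20 at threshold 0.15: one lineage
  base <- strrep("A", 20)
  s2 <- paste0(strrep("A", 18), "CC")             # d(base, s2) = 0.10
  s3 <- paste0("CC", strrep("A", 16), "CC")       # d(base, s3) = 0.20, d(s2, s3) = 0.10
  cl <- tibble::tibble(cdr3_nt = c(base, s2, s3), v_gene = "V", j_gene = "J")
  lin <- build_lineages(cl, threshold = 0.15)
  expect_equal(length(unique(lin$lineage_id)), 1L)

  far <- tibble::tibble(
    cdr3_nt = c(strrep("A", 10), strrep("C", 10), strrep("G", 10)),
    v_gene = "V", j_gene = "J")
  lin2 <- build_lineages(far, threshold = 0.15)
  expect_equal(length(unique(lin2$lineage_id)), 3L)
})

test_that("lineage partitions equal the independent connected-components oracle", {
  set.seed(7)
  for (trial in 1:10) {
    # mixture of mutated families and unrelated junctions, one partition
    fams <- lapply(1:3, function(k)
      plant_lineage(6, n_mut_each = sample(1:3, 1),
                    middle = paste(sample(c("A", "C", "G", "T"), 12,
                                          replace = TRUE), collapse = ""),
                    seed = trial * 10 + k)$cdr3_nt)
    seqs <- unique(unlist(fams))
    cl <- tibble::tibble(cdr3_nt = seqs, v_gene = "V", j_gene = "J")
    thr <- 0.12
    lin <- build_lineages(cl, threshold = thr)
    got <- canonical_partition(lin$lineage_id)
    want <- canonical_partition(oracle_components(seqs, thr))
    # same partition up to label renaming
    expect_equal(got[order(seqs)], want[order(seqs)],
                 ignore_attr = TRUE,
                 label = sprintf("trial %d partition", trial))
  }
})

test_that("V/J/length partition separates lineages before clustering", {
  cl <- tibble::tibble(
    cdr3_nt = rep(strrep("A", 12), 2),
    v_gene = c("V1", "V2"), j_gene = "J")
  lin <- build_lineages(cl, threshold = 0.5)
  expect_equal(length(unique(lin$lineage_id)), 2L)
})

test_that("outgroup conjugate covers germline ends and masks the middle", {
  fam <- plant_lineage(8, n_mut_each = 1, seed = 3)
  og <- build_outgroup(fam$cdr3_nt, "IGHV9-1*01", "IGHJ9-1*01")
  expect_equal(nchar(og$sequence), nchar(fam$cdr3_nt[1]))
  expect_gt(og$n_masked, 0)
  vrow <- germ[germ$gene == "IGHV9-1*01", ]
  v_tail <- substr(vrow$sequence, nchar(vrow$sequence) - 11, nchar(vrow$sequence))
  expect_equal(substr(og$sequence, 1, 10), substr(v_tail, 1, 10))
  expect_error(build_outgroup(fam$cdr3_nt, "IGHV9-1*01", "missing"), "germline")
})

test_that("mutation counts against the outgroup recover planted substitutions", {
  fam <- plant_lineage(5, n_mut_each = 0, seed = 5)   # naive only
  lin <- build_lineages(fam, threshold = 0.15)
  mc <- mutation_counts(lin)
  expect_equal(mc$n_mutations, 0)

  # plant exactly 3 substitutions in germline-covered positions
  naive <- fam$cdr3_nt[1]
  s <- strsplit(naive, "")[[1]]
  for (p in c(2, 5, 8)) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  mut <- tibble::tibble(cdr3_nt = c(naive, paste(s, collapse = "")),
                        v_gene = "IGHV9-1*01", j_gene = "IGHJ9-1*01")
  mc2 <- mutation_counts(build_lineages(mut, threshold = 0.5))
  expect_setequal(mc2$n_mutations, c(0, 3))

  # a precomputed germline_mutations column is used verbatim
  mut$germline_mutations <- c(7, NA)
  mc3 <- mutation_counts(build_lineages(mut, threshold = 0.5))
  expect_equal(sort(mc3$n_mutations), c(3, 7))
})

test_that("two-member trees match the closed-form three-point solution", {
  fam <- plant_lineage(4, n_mut_each = 2, seed = 11)
  two <- fam[1:2, ]
  og <- build_outgroup(two$cdr3_nt, "IGHV9-1*01", "IGHJ9-1*01")
  tr <- lineage_tree(two, og)
  # closed form from the three pairwise distances
  seqs <- sort(two$cdr3_nt)
  d <- tribcr:::hamming_matrix(c(a = seqs[1], b = seqs[2], g = og$sequence))
  x <- (d["a", "g"] + d["b", "g"] - d["a", "b"]) / 2
  expect_equal(unname(tr$members$dist_to_root),
               unname(c(d["a", "g"] - x, d["b", "g"] - x)), tolerance = 1e-8)
})

test_that("star-like lineages give equal root distances; input order is irrelevant", {
  # members all at distance d from naive, mutated at member-specific positions
  fam <- plant_lineage(1, n_mut_each = 0, seed = 21)
  naive <- fam$cdr3_nt[1]
  mk <- function(pos) {
    s <- strsplit(naive, "")[[1]]
    for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
    paste(s, collapse = "")
  }
  # non-overlapping mutated positions inside the masked-free region
  members <- tibble::tibble(
    cdr3_nt = c(mk(c(2, 3)), mk(c(5, 6)), mk(c(8, 9)), mk(c(10, 11))),
    v_gene = "IGHV9-1*01", j_gene = "IGHJ9-1*01")
  og <- build_outgroup(c(naive, members$cdr3_nt), "IGHV9-1*01", "IGHJ9-1*01")
  tr <- lineage_tree(members, og)
  expect_lt(diff(range(tr$members$dist_to_root)), 1e-9)
  # all-equal distances tie out to the average rank (n + 1) / 2
  expect_equal(tr$members$rank, rep(2.5, 4))

  shuffled <- members[c(3, 1, 4, 2), ]
  tr2 <- lineage_tree(shuffled, og)
  m1 <- tr$members[order(tr$members$cdr3_nt), ]
  m2 <- tr2$members[order(tr2$members$cdr3_nt), ]
  expect_equal(m1$dist_to_root, m2$dist_to_root, tolerance = 1e-12)
})

test_that("duplicate member sequences do not perturb other root distances", {
  fam <- plant_lineage(6, n_mut_each = 2, seed = 31)
  og <- build_outgroup(fam$cdr3_nt, "IGHV9-1*01", "IGHJ9-1*01")
  tr <- lineage_tree(fam, og)
  dup <- dplyr::bind_rows(fam, fam[2, ])
  tr_dup <- lineage_tree(dup, og)
  a <- tr$members[order(tr$members$cdr3_nt), ]
  b <- tr_dup$members[order(tr_dup$members$cdr3_nt), ]
  expect_equal(a$dist_to_root, b$dist_to_root, tolerance = 1e-9)
})

test_that("root-distance ranks follow chain order and average over ties", {
  fam <- plant_lineage(1, n_mut_each = 0, seed = 41)
  naive <- fam$cdr3_nt[1]
  chain <- vapply(1:4, function(k) {
    s <- strsplit(naive, "")[[1]]
    for (p in seq_len(k) * 2) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
    paste(s, collapse = "")
  }, character(1))
  members <- tibble::tibble(cdr3_nt = chain, v_gene = "IGHV9-1*01",
                            j_gene = "IGHJ9-1*01")
  og <- build_outgroup(chain, "IGHV9-1*01", "IGHJ9-1*01")
  tr <- lineage_tree(members, og)
  m <- tr$members
  # rank order follows true mutation load along the chain
  true_load <- match(m$cdr3_nt, chain)
  expect_equal(m$rank, rank(true_load))
  # brute-force sort oracle
  expect_equal(m$rank, rank(m$dist_to_root))

  # clonotypes are keyed by amino-acid sequence: synonymous variants share a
  # row and average their ranks
  ranks <- rank_by_root_distance(list(tr))
  aa <- tribcr:::translate_nt(m$cdr3_nt)
  want <- tapply(m$rank, aa, mean)
  expect_equal(nrow(ranks), length(want))
  expect_equal(sort(ranks$avg_rank), sort(as.numeric(want)))
})

test_that("identical rank tables correlate perfectly; reversed anti-correlate", {
  ranks <- tibble::tibble(cdr3_aa = paste0("C", LETTERS[1:8], "W"),
                          v_gene = "V", j_gene = "J",
                          avg_rank = 1:8, avg_dist_to_root = (1:8) / 10,
                          n_lineages = 1L)
  same <- compare_tree_sets(ranks, ranks)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_equal(same$n_matched, 8L)
  rev_ranks <- ranks
  rev_ranks$avg_rank <- rev(rev_ranks$avg_rank)
  expect_equal(compare_tree_sets(ranks, rev_ranks)$r, -1, tolerance = 1e-12)
  # independent random ranks should not correlate strongly
  set.seed(50)
  hits <- 0
  for (i in 1:20) {
    shuf <- ranks
    shuf$avg_rank <- sample(100, 8)
    r <- compare_tree_sets(ranks, shuf)$r
    if (abs(r) < 0.75) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("Nei-Gojobori counting separates synonymous from nonsynonymous", {
  mrca <- "TGTGCGAGAGGG"                  # C A R G
  syn <- "TGCGCGAGAGGG"                   # TGT->TGC still Cys
  res <- dnds(syn, mrca)
  expect_true(res$defined)
  expect_equal(res$dnds, 0)
  expect_equal(res$Sd, 1)

  nonsyn <- "TGTGCGAAAGGG"                # AGA(R)->AAA(K)
  res2 <- dnds(nonsyn, mrca)
  expect_false(res2$defined)
  expect_true(is.na(res2$dnds))
  expect_equal(res2$Nd, 1)

  # masked codons are skipped entirely
  masked <- dnds("TGTGCGAGAGGG", "TGTNNNAGAGGG")
  expect_equal(masked$n_codons_used, 3)
})

test_that("neutral codon evolution yields dN/dS near one", {
  set.seed(77)
  codons <- names(tribcr:::GENETIC_CODE_TABLE)
  codons <- codons[tribcr:::GENETIC_CODE_TABLE != "*"]
  mrca <- paste(sample(codons, 120, replace = TRUE), collapse = "")
  bases <- c("A", "C", "G", "T")
  members <- vapply(1:30, function(i) {
    s <- strsplit(mrca, "")[[1]]
    for (k in 1:8) {
      repeat {
        p <- sample(length(s), 1)
        b <- sample(setdiff(bases, s[p]), 1)
        cand <- s; cand[p] <- b
        ci <- (p - 1) %/% 3
        codon <- paste(cand[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
        if (tribcr:::GENETIC_CODE_TABLE[[codon]] != "*") { s <- cand; break }
      }
    }
    paste(s, collapse = "")
  }, character(1))
  res <- dnds(members, mrca)
  expect_true(res$defined)
  expect_gt(res$Nd + res$Sd, 200)
  expect_gt(res$dnds, 0.7)
  expect_lt(res$dnds, 1.3)
})

test_that("build_trees returns trees only for sufficiently large lineages", {
  fam <- plant_lineage(7, n_mut_each = 2, seed = 61)
  lin <- build_lineages(fam, threshold = 0.2)
  trees <- build_trees(lin, min_size = 5)
  expect_gte(length(trees), 1L)
  tr <- trees[[1]]
  expect_s3_class(tr$tree, "phylo")
  expect_true(all(tr$members$dist_to_root >= 0))
  expect_true("germline" %in% tr$tree$tip.label)
  none <- build_trees(lin, min_size = 100)
  expect_equal(length(none), 0L)
})
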