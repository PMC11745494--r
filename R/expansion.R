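# Expanded-clonotype detection with cellular replicates.
#
# Raw per-sample UMI counts are distorted by sampling bias (e.g. tumor
# fragments of unequal size), so clonotype counts for testing are rebuilt
# from normalized frequencies: frequency in the normalized sample times the
# total number of unique UMIs across all sample groups. Replicate counts are
# compared between two groups with an exact conditional test; clonotypes
# with FDR < 0.05 and logFC > 0 are called expanded.

#' UMI-normalized pseudo-counts
#'
#' `count_k = round(f_k * total_umi_all_groups)` for each clonotype, where
#' `f_k` is the clonotype's frequency in the normalized sample and the
#' multiplier is the total number of unique UMIs in all groups of samples
#' under comparison. Rounding to integers is required by the exact test.
#'
#' @param rep A [bcr_repertoire].
#' @param total_umi_all_groups Total unique-UMI count across all samples in
#'   the comparison.
#' @return Tibble with the clonotype key columns and `count`.
#' @export
pseudo_counts <- function(rep, total_umi_all_groups) {
  stopifnot(total_umi_all_groups > 0)
  cl <- rep$clonotypes
  tibble::tibble(cdr3_nt = cl$cdr3_nt, v_gene = cl$v_gene, j_gene = cl$j_gene,
                 count = round(cl$frequency * total_umi_all_groups))
}

# two-sided exact test of x successes in n conditional trials against the
# library-size-proportional null; p-value sums all outcomes no more likely
# than the observed one. quasi_scale > 1 deflates counts to their effective
# Poisson scale first (quasi-likelihood handling of the variance inflation
# introduced by the pseudo-count transform); dispersion > 0 instead uses a
# beta-binomial with negative-binomial-style overdispersion.
exact_count_test <- function(x, n, p_null, dispersion = 0, quasi_scale = 1) {
  if (quasi_scale > 1) {
    x <- round(x / quasi_scale)
    n <- round(n / quasi_scale)
  }
  if (n == 0) return(NA_real_)
  x <- min(x, n)
  k <- 0:n
  if (dispersion <= 0) {
    pmf <- stats::dbinom(k, n, p_null)
  } else {
    rho <- dispersion / (1 + dispersion)
    a <- p_null * (1 - rho) / rho
    b <- (1 - p_null) * (1 - rho) / rho
    pmf <- exp(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
  }
  sum(pmf[pmf <= pmf[x + 1] * (1 + 1e-7)])
}

# pooled quasi-dispersion (variance over mean) across replicates; equals the
# count inflation factor when pseudo-counts are a scaled Poisson
estimate_quasi_dispersion <- function(count_matrix_list) {
  num <- 0; den <- 0
  for (m in count_matrix_list) {
    if (ncol(m) < 2) next
    mu <- rowMeans(m)
    s2 <- apply(m, 1, var)
    keep <- mu > 0
    num <- num + sum(s2[keep] - mu[keep])
    den <- den + sum(mu[keep])
  }
  if (den == 0) return(1)
  max(1, 1 + num / den)
}

# pooled method-of-moments overdispersion across replicates:
# Var = mu + phi * mu^2  =>  phi = sum(s2 - m) / sum(m^2)
estimate_dispersion <- function(count_matrix_list) {
  num <- 0; den <- 0
  for (m in count_matrix_list) {
    if (ncol(m) < 2) next
    mu <- rowMeans(m)
    s2 <- apply(m, 1, var)
    keep <- mu > 0
    num <- num + sum(s2[keep] - mu[keep])
    den <- den + sum(mu[keep]^2)
  }
  if (den == 0) return(0)
  max(0, num / den)
}

#' Detect expanded clonotypes between two sample groups
#'
#' Builds UMI-normalized pseudo-counts (see [pseudo_counts()]) for every
#' replicate, sums them per group, and tests each clonotype with a
#' two-sided exact test conditional on its total count across groups: under
#' the null the group-A count is binomial with probability proportional to
#' the group library sizes (a beta-binomial with the same mean when
#' `dispersion > 0`). Log fold change uses a prior count of
#' `prior_count` (default 0.5) to stabilize zeros; p-values are
#' Benjamini-Hochberg adjusted across clonotypes. A clonotype is called
#' expanded in group A when `fdr < alpha_fdr` and `logFC > 0`.
#'
#' @param reps_a,reps_b Lists of replicate [bcr_repertoire] objects (at
#'   least one each; a single replicate per group triggers a warning).
#' @param alpha_fdr FDR cutoff for the expansion call (default 0.05).
#' @param dispersion `0` (conditional binomial), a positive number
#'   (negative-binomial-style beta-binomial overdispersion), or `"auto"`
#'   (default): the replicate-estimated quasi-dispersion (variance/mean)
#'   deflates counts to their effective Poisson scale before the binomial
#'   test. The pseudo-count transform multiplies every count by roughly the
#'   number of samples, so replicate-based dispersion handling is required
#'   for a calibrated test -- the same role the original differential
#'   abundance machinery's dispersion estimation plays.
#' @param prior_count Prior count for the logFC (default 0.5).
#' @return Tibble with the clonotype key, per-group summed counts and
#'   replicate means, `logFC` (base 2, A over B), `p`, `fdr`, `expanded`.
#' @export
test_expansion <- function(reps_a, reps_b, alpha_fdr = 0.05,
                           dispersion = "auto", prior_count = 0.5) {
  if (inherits(reps_a, "bcr_repertoire")) reps_a <- list(reps_a)
  if (inherits(reps_b, "bcr_repertoire")) reps_b <- list(reps_b)
  if (length(reps_a) == 0 || length(reps_b) == 0)
    stop("both groups need at least one replicate", call. = FALSE)
  if (length(reps_a) < 2 || length(reps_b) < 2)
    warning("a single replicate per group cannot capture sampling noise",
            call. = FALSE)
  total_all <- sum(vapply(c(reps_a, reps_b), function(r) r$total_umi,
                          numeric(1)))
  count_tbl <- function(reps, tag) {
    lst <- lapply(seq_along(reps), function(i) {
      pc <- pseudo_counts(reps[[i]], total_all)
      pc$replicate <- paste0(tag, i)
      pc
    })
    dplyr::bind_rows(lst)
  }
  long <- dplyr::bind_rows(count_tbl(reps_a, "A"), count_tbl(reps_b, "B"))
  wide <- long |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "count",
                       values_fill = 0)
  a_cols <- grep("^A", setdiff(names(wide), c("cdr3_nt", "v_gene", "j_gene")),
                 value = TRUE)
  b_cols <- grep("^B", setdiff(names(wide), c("cdr3_nt", "v_gene", "j_gene")),
                 value = TRUE)
  ma <- as.matrix(wide[, a_cols, drop = FALSE])
  mb <- as.matrix(wide[, b_cols, drop = FALSE])
  keep <- rowSums(ma) + rowSums(mb) > 0
  wide <- wide[keep, , drop = FALSE]
  ma <- ma[keep, , drop = FALSE]; mb <- mb[keep, , drop = FALSE]
  quasi_scale <- 1
  if (identical(dispersion, "auto")) {
    quasi_scale <- estimate_quasi_dispersion(list(ma, mb))
    dispersion <- 0
  }
  sum_a <- rowSums(ma); sum_b <- rowSums(mb)
  lib_a <- sum(sum_a); lib_b <- sum(sum_b)
  p_null <- lib_a / (lib_a + lib_b)
  p <- vapply(seq_along(sum_a), function(i)
    exact_count_test(sum_a[i], sum_a[i] + sum_b[i], p_null, dispersion,
                     quasi_scale),
    numeric(1))
  mean_a <- rowMeans(ma); mean_b <- rowMeans(mb)
  # put the replicate means on a common library scale before the fold change
  scale_ab <- (lib_a / ncol(ma)) / (lib_b / ncol(mb))
  logFC <- log2((mean_a + prior_count) / (scale_ab * (mean_b + prior_count)))
  out <- tibble::tibble(
    cdr3_nt = wide$cdr3_nt, v_gene = wide$v_gene, j_gene = wide$j_gene,
    count_a = sum_a, count_b = sum_b, mean_a = mean_a, mean_b = mean_b,
    logFC = logFC, p = p)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$expanded <- out$fdr < alpha_fdr & out$logFC > 0
  attr(out, "dispersion") <- dispersion
  attr(out, "quasi_scale") <- quasi_scale
  out
}

#' Hypermutation contrast between expanded and non-expanded clonotypes
#'
#' Compares the mean mutation load of expanded versus non-expanded
#' clonotypes with a two-sided Mann-Whitney test.
#'
#' @param mutations Numeric vector of per-clonotype mutation counts.
#' @param expanded Logical vector marking expanded clonotypes.
#' @return List with `mean_expanded`, `mean_other`, `p`, `n_expanded`,
#'   `n_other`, `defined` (FALSE when either set is empty).
#' @export
mutation_contrast <- function(mutations, expanded) {
  stopifnot(length(mutations) == length(expanded))
  ok <- !is.na(mutations) & !is.na(expanded)
  x <- mutations[ok & expanded]
  y <- mutations[ok & !expanded]
  if (length(x) == 0 || length(y) == 0) {
    return(list(mean_expanded = NA_real_, mean_other = NA_real_, p = NA_real_,
                n_expanded = length(x), n_other = length(y), defined = FALSE))
  }
  wt <- wilcox.test(x, y, exact = FALSE)
  list(mean_expanded = mean(x), mean_other = mean(y), p = wt$p.value,
       n_expanded = length(x), n_other = length(y), defined = TRUE)
}
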