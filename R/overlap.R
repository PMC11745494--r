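# Pairwise repertoire-overlap statistics: F2, D and R, with per-isotype
# top-N normalization. Overlap metrics depend on overall repertoire richness,
# so comparisons are normalized by restricting each sample to the same number
# of top most frequent clonotypes (per isotype) before computing the metric.

#' Restrict a repertoire to its top-N clonotypes of one isotype
#'
#' Selects the `n` highest-frequency clonotypes (default `n = 109`), ties
#' broken by UMI count (descending) then CDR-H3 nucleotide sequence
#' (lexicographic), and renormalizes frequencies. When the repertoire holds
#' fewer than `n` qualifying clonotypes all are returned and the result
#' carries attribute `shortfall = TRUE`.
#'
#' @param rep A [bcr_repertoire].
#' @param n Number of clonotypes to keep (default 109).
#' @param isotype Restrict to one isotype (`"IgM"`, `"IgG"`, `"IgA"`) first;
#'   `NULL` uses the whole repertoire.
#' @return A [bcr_repertoire] with attribute `shortfall`.
#' @export
top_n_by_isotype <- function(rep, n = 109, isotype = NULL) {
  stopifnot(n >= 1)
  cl <- rep$clonotypes
  if (!is.null(isotype)) cl <- cl[cl$isotype == isotype, , drop = FALSE]
  ord <- order(-cl$frequency, -cl$umi_count, cl$cdr3_nt)
  cl <- cl[head(ord, n), , drop = FALSE]
  shortfall <- nrow(cl) < n
  out <- rep
  out$clonotypes <- cl
  out <- renormalize(out)
  attr(out, "shortfall") <- shortfall
  out
}

.overlap_frame <- function(rep_i, rep_j) {
  ci <- rep_i$clonotypes; cj <- rep_j$clonotypes
  ki <- clonotype_key(ci$cdr3_nt, ci$v_gene, ci$j_gene)
  kj <- clonotype_key(cj$cdr3_nt, cj$v_gene, cj$j_gene)
  shared <- intersect(ki, kj)
  list(fi = ci$frequency[match(shared, ki)],
       fj = cj$frequency[match(shared, kj)],
       d_i = nrow(ci), d_j = nrow(cj), n_shared = length(shared))
}

#' F2 repertoire overlap
#'
#' Clonotype-wise sum of geometric-mean frequencies of overlapping
#' clonotypes: `F2 = sum_k sqrt(f_ik * f_jk)` over clonotypes shared by the
#' two repertoires, after renormalizing each repertoire's frequencies to sum
#' to one. Symmetric; 0 for disjoint repertoires; 1 when the frequency
#' vectors coincide over identical clonotype sets.
#'
#' @param rep_i,rep_j [bcr_repertoire] objects (typically restricted with
#'   [top_n_by_isotype()] first).
#' @return Numeric in `[0, 1]`.
#' @examples
#' a <- bcr_repertoire(data.frame(cdr3_nt = c("A", "C"), v_gene = "V",
#'   j_gene = "J", umi_count = c(5, 5)))
#' b <- bcr_repertoire(data.frame(cdr3_nt = c("A", "G"), v_gene = "V",
#'   j_gene = "J", umi_count = c(2, 8)))
#' f2(a, b)  # sqrt(0.5 * 0.2) = 0.31623
#' @export
f2 <- function(rep_i, rep_j) {
  if (n_clonotypes(rep_i) == 0 || n_clonotypes(rep_j) == 0)
    stop("f2() requires non-empty repertoires", call. = FALSE)
  ov <- .overlap_frame(renormalize(rep_i), renormalize(rep_j))
  sum(sqrt(ov$fi * ov$fj))
}

#' D repertoire overlap
#'
#' Relative overlap diversity uninfluenced by clonotype frequency:
#' `D_ij = d_ij / (d_i * d_j)` where `d_ij` is the number of clonotypes
#' present in both samples and `d_i`, `d_j` are the two samples' diversities
#' (clonotype counts).
#'
#' @inheritParams f2
#' @return Numeric; 0 for disjoint repertoires.
#' @export
d_metric <- function(rep_i, rep_j) {
  ov <- .overlap_frame(rep_i, rep_j)
  if (ov$d_i == 0 || ov$d_j == 0)
    stop("d_metric() requires non-empty repertoires", call. = FALSE)
  ov$n_shared / (ov$d_i * ov$d_j)
}

#' R repertoire overlap (frequency correlation of shared clonotypes)
#'
#' Pearson correlation of log10 frequencies of the clonotypes shared by the
#' two repertoires. Requires at least three shared clonotypes; with fewer the
#' result is `NA` with attribute `defined = FALSE`.
#'
#' @inheritParams f2
#' @return Numeric in `[-1, 1]`, or flagged `NA`.
#' @export
r_metric <- function(rep_i, rep_j) {
  ov <- .overlap_frame(renormalize(rep_i), renormalize(rep_j))
  if (ov$n_shared < 3) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    attr(out, "n_shared") <- ov$n_shared
    return(out)
  }
  lf_i <- log10(ov$fi); lf_j <- log10(ov$fj)
  # correlation is undefined for zero variance (e.g. uniform frequencies)
  if (stats::sd(lf_i) == 0 || stats::sd(lf_j) == 0) {
    # identical constant vectors still mean perfect agreement
    out <- if (isTRUE(all.equal(lf_i, lf_j))) 1 else NA_real_
    attr(out, "defined") <- !is.na(out)
    attr(out, "n_shared") <- ov$n_shared
    return(out)
  }
  out <- cor(lf_i, lf_j)
  attr(out, "defined") <- TRUE
  attr(out, "n_shared") <- ov$n_shared
  out
}

#' All pairwise overlaps of a set of repertoires
#'
#' Long-format table of overlap statistics for every unordered pair of
#' repertoires, optionally split by isotype and restricted to top-N
#' clonotypes per isotype before metric computation.
#'
#' @param reps Named list of [bcr_repertoire] objects.
#' @param metrics Subset of `c("f2", "d", "r")`.
#' @param top_n Restrict each (isotype-split) repertoire to its `top_n` most
#'   frequent clonotypes first; `NULL` uses full repertoires.
#' @param by_isotype Compute each metric separately per isotype.
#' @param isotypes Isotypes used when `by_isotype = TRUE`.
#' @return Tibble with `sample_i`, `sample_j`, `isotype`, `metric`, `value`,
#'   `n_shared`, `n_top_used`, `shortfall`.
#' @export
pairwise_overlap <- function(reps, metrics = c("f2", "d", "r"), top_n = 109,
                             by_isotype = FALSE,
                             isotypes = c("IgM", "IgG", "IgA")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(names(reps)))
    names(reps) <- vapply(reps, function(r)
      r$metadata$sample_id %||% "?", character(1))
  ids <- names(reps)
  if (length(ids) < 2) stop("need at least two repertoires", call. = FALSE)
  iso_levels <- if (by_isotype) isotypes else "all"
  rows <- list()
  for (a in seq_len(length(ids) - 1)) for (b in (a + 1):length(ids)) {
    for (iso in iso_levels) {
      iso_arg <- if (identical(iso, "all")) NULL else iso
      ri <- reps[[a]]; rj <- reps[[b]]
      short_i <- short_j <- FALSE
      if (!is.null(top_n) || !is.null(iso_arg)) {
        n_use <- top_n %||% max(n_clonotypes(ri), n_clonotypes(rj))
        ri <- top_n_by_isotype(ri, n = n_use, isotype = iso_arg)
        rj <- top_n_by_isotype(rj, n = n_use, isotype = iso_arg)
        short_i <- isTRUE(attr(ri, "shortfall"))
        short_j <- isTRUE(attr(rj, "shortfall"))
      }
      if (n_clonotypes(ri) == 0 || n_clonotypes(rj) == 0) next
      ov <- .overlap_frame(ri, rj)
      for (m in metrics) {
        val <- switch(m, f2 = f2(ri, rj), d = d_metric(ri, rj),
                      r = as.numeric(r_metric(ri, rj)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_i = ids[a], sample_j = ids[b], isotype = iso, metric = m,
          value = val, n_shared = ov$n_shared,
          n_top_used = min(ov$d_i, ov$d_j),
          shortfall = short_i || short_j)
      }
    }
  }
  dplyr::bind_rows(rows)
}
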