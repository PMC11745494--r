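# Clonality and isotype-composition summaries.

shannon_index <- function(freqs) {
  f <- freqs[freqs > 0]
  f <- f / sum(f)
  -sum(f * log(f))
}

#' Repertoire clonality
#'
#' `1 - normalized Shannon-Wiener index`: with clonotype frequencies `f_k`,
#' `H = -sum f_k ln f_k` and clonality `= 1 - H / ln(richness)`. Zero for a
#' perfectly even repertoire, approaching one as a single clone dominates.
#' A single-clonotype repertoire is maximally clonal by convention
#' (clonality 1).
#'
#' @param rep A [bcr_repertoire] (or a bare numeric vector of frequencies).
#' @return Numeric in `[0, 1]`.
#' @examples
#' clonality(bcr_repertoire(data.frame(cdr3_nt = c("A", "C"), v_gene = "V",
#'   j_gene = "J", umi_count = c(9, 1))))  # 0.530985
#' @export
clonality <- function(rep) {
  freqs <- if (inherits(rep, "bcr_repertoire")) rep$clonotypes$frequency else rep
  freqs <- freqs[freqs > 0]
  if (length(freqs) == 0) stop("clonality of an empty repertoire", call. = FALSE)
  if (length(freqs) == 1) return(1)
  1 - shannon_index(freqs) / log(length(freqs))
}

#' Isotype composition of a repertoire
#'
#' Fraction of the repertoire attributed to each isotype, either by UMI
#' frequency mass (default, "percentage of repertoire") or by clonotype
#' count. Unknown isotypes (`"other"`) are excluded from the denominator
#' unless `include_other = TRUE`; fractions sum to one over the included
#' classes.
#'
#' @param rep A [bcr_repertoire].
#' @param weight `"umi"` (frequency mass) or `"clonotype"` (counts).
#' @param include_other Include the `"other"` class.
#' @return Named numeric vector of fractions.
#' @export
isotype_fractions <- function(rep, weight = c("umi", "clonotype"),
                              include_other = FALSE) {
  weight <- match.arg(weight)
  cl <- rep$clonotypes
  classes <- c("IgM", "IgG", "IgA", if (include_other) "other")
  cl <- cl[cl$isotype %in% classes, , drop = FALSE]
  w <- if (weight == "umi") cl$frequency else rep(1, nrow(cl))
  tot <- sum(w)
  out <- setNames(numeric(length(classes)), classes)
  if (tot > 0) {
    agg <- tapply(w, factor(cl$isotype, levels = classes), sum, default = 0)
    out[] <- agg / tot
  }
  out
}

#' Per-sample diversity summary
#'
#' @param rep A [bcr_repertoire].
#' @param weight Passed to [isotype_fractions()].
#' @return One-row tibble: `sample_id`, `richness`, `shannon`, `clonality`
#'   and isotype fraction columns.
#' @export
diversity_summary <- function(rep, weight = "umi") {
  fr <- isotype_fractions(rep, weight = weight)
  tibble::tibble(
    sample_id = rep$metadata$sample_id %||% NA_character_,
    richness = n_clonotypes(rep),
    shannon = shannon_index(rep$clonotypes$frequency),
    clonality = clonality(rep),
    frac_IgM = fr[["IgM"]], frac_IgG = fr[["IgG"]], frac_IgA = fr[["IgA"]])
}
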