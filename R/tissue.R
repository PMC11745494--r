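# Triangle (barycentric) analysis of clonal-group composition across three
# compartments (tissues, lymph-node fragments, or tumor fragments). Each
# clonal group becomes one point whose coordinates are the shares of its
# clonotypes attributed to each compartment; a chi-squared goodness-of-fit
# test against the uniform expectation asks whether the three compartments
# contributed equally.

#' Dominant isotype of a clonal group
#'
#' The isotype whose share of the group's clonotypes strictly exceeds
#' `cutoff` (default 0.6, i.e. ">60%"); `"mixed"` otherwise.
#'
#' @param isotypes Character vector of member isotypes.
#' @param cutoff Strict dominance cutoff (default 0.6).
#' @return A single label.
#' @export
dominant_isotype <- function(isotypes, cutoff = 0.6) {
  if (length(isotypes) == 0) return("mixed")
  shares <- table(isotypes) / length(isotypes)
  top <- which.max(shares)
  if (shares[top] > cutoff) names(shares)[top] else "mixed"
}

.chi2_uniform <- function(counts) {
  size <- sum(counts)
  if (size == 0) return(c(chi2 = NA_real_, p = NA_real_))
  expected <- size / length(counts)
  chi2 <- sum((counts - expected)^2 / expected)
  c(chi2 = chi2, p = pchisq(chi2, df = length(counts) - 1, lower.tail = FALSE))
}

#' Triangle points for clonal groups
#'
#' One row per clonal group: counts of member clonotypes attributed to each
#' of three compartments, barycentric coordinates (counts / size), dominant
#' isotype, and a per-group chi-squared goodness-of-fit test of the counts
#' against equal contribution of the three compartments (df = 2). A
#' clonotype observed in several compartments contributes one count to each
#' compartment of observation. Groups with fewer than 6 members are flagged
#' `low_count` (expected cell count below 2).
#'
#' @param membership Tibble with one row per clonotype occurrence: columns
#'   `lineage_id`, `compartment`, `isotype` (optional), and `frequency`
#'   (needed for isotype-usage normalization).
#' @param compartments Character vector of exactly three compartment labels
#'   (default: sorted unique values present).
#' @param normalize_isotypes Downsample each compartment to an equal number
#'   of top most frequent clonotypes per isotype before counting, removing
#'   quantitative isotype-usage bias between compartments.
#' @param top_n Per-isotype depth for `normalize_isotypes` (default: the
#'   minimum isotype count over compartments).
#' @return Tibble with `lineage_id`, count and coordinate columns (named
#'   after the compartments), `size`, `dominant_isotype`, `chi2`, `p`,
#'   `low_count`.
#' @export
triangle_points <- function(membership, compartments = NULL,
                            normalize_isotypes = FALSE, top_n = NULL) {
  membership <- tibble::as_tibble(membership)
  if (is.null(compartments))
    compartments <- sort(unique(membership$compartment))
  if (length(compartments) != 3)
    stop("triangle analysis requires exactly three compartments, got: ",
         paste(compartments, collapse = ", "), call. = FALSE)
  membership <- membership[membership$compartment %in% compartments, ,
                           drop = FALSE]
  if (normalize_isotypes) {
    if (!all(c("isotype", "frequency") %in% names(membership)))
      stop("isotype-usage normalization needs isotype and frequency columns",
           call. = FALSE)
    counts <- membership |>
      dplyr::count(.data$compartment, .data$isotype)
    if (is.null(top_n)) top_n <- min(counts$n)
    membership <- membership |>
      dplyr::group_by(.data$compartment, .data$isotype) |>
      dplyr::slice_max(.data$frequency, n = top_n, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  groups <- split(membership, membership$lineage_id)
  rows <- lapply(groups, function(g) {
    counts <- unname(vapply(compartments, function(cc)
      sum(g$compartment == cc), numeric(1)))
    size <- sum(counts)
    test <- .chi2_uniform(counts)
    row <- tibble::tibble(lineage_id = g$lineage_id[1], size = size,
                          dominant_isotype = if ("isotype" %in% names(g))
                            dominant_isotype(g$isotype) else NA_character_,
                          chi2 = test[["chi2"]], p = test[["p"]],
                          low_count = size < 6)
    for (i in seq_along(compartments)) {
      row[[paste0("n_", compartments[i])]] <- counts[i]
      row[[paste0("coord_", compartments[i])]] <- counts[i] / size
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  attr(out, "compartments") <- compartments
  out
}

#' Center of mass and pooled uniformity test for triangle points
#'
#' The center is the unweighted (by group size) mean of the barycentric
#' coordinates. The pooled chi-squared goodness-of-fit test is run on the
#' summed compartment counts over all groups (df = 2), asking whether the
#' three compartments contributed equally to clonal-group formation
#' overall.
#'
#' @param points Output of [triangle_points()].
#' @return List with `center` (named numeric, sums to 1), `chi2`, `df`, `p`
#'   and `n_groups`.
#' @export
center_and_test <- function(points) {
  compartments <- attr(points, "compartments")
  if (is.null(compartments))
    compartments <- sub("^coord_", "", grep("^coord_", names(points),
                                            value = TRUE))
  coords <- as.matrix(points[, paste0("coord_", compartments)])
  center <- colMeans(coords)
  names(center) <- compartments
  totals <- colSums(as.matrix(points[, paste0("n_", compartments)]))
  test <- .chi2_uniform(totals)
  list(center = center, chi2 = test[["chi2"]], df = 2L, p = test[["p"]],
       n_groups = nrow(points))
}

#' Barycentric-to-Cartesian projection for triangle plotting
#'
#' Maps 3-part coordinates onto the standard 2-simplex (equilateral
#' triangle with unit base) for plotting.
#'
#' @param coords Matrix or data frame of 3 columns summing to 1 per row.
#' @return Matrix with columns `x`, `y`.
#' @export
triangle_xy <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  x <- coords[, 2] + coords[, 3] / 2
  y <- coords[, 3] * sqrt(3) / 2
  cbind(x = x, y = y)
}
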