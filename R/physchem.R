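# CDR-H3 physicochemical profiling: length, net charge, Kyte-Doolittle
# hydropathy, predicted interaction strength and Kidera factors, computed on
# the five central amino acids of the top most frequent clonotypes.

.pkg_env <- new.env(parent = emptyenv())

#' Amino-acid property table
#'
#' Packaged, versioned table of per-residue descriptors for the 20 standard
#' amino acids: the ten Kidera factors (`kf1`-`kf10`; orthogonal, standardized
#' summaries of 188 physical properties), Kyte-Doolittle `hydropathy`,
#' pH-7 `charge` class (+1 for K/R, -1 for D/E, 0 otherwise; histidine
#' handling is a caller option) and the `strong` flag marking strongly
#' interacting residues (F, I, L, M, V, W, Y). Overridable by supplying a
#' TSV of the same shape.
#'
#' @param path Optional path to an alternative property TSV.
#' @return Tibble with 20 rows, one per amino acid.
#' @export
aa_properties <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_env$aa_props)) {
      path <- system.file("extdata", "aa_properties.tsv", package = "tribcr",
                          mustWork = TRUE)
      .pkg_env$aa_props <- readr::read_tsv(path, show_col_types = FALSE,
                                           progress = FALSE)
    }
    return(.pkg_env$aa_props)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# standardization guard: each Kidera factor has mean ~0, variance ~1
# (population variance over the 20 residues) per the published scale
kidera_standardization <- function(props = aa_properties()) {
  kf <- as.matrix(props[, paste0("kf", 1:10)])
  tibble::tibble(
    factor = colnames(kf),
    mean = colMeans(kf),
    variance = apply(kf, 2, function(x) mean((x - mean(x))^2)))
}

#' Central window of a CDR-H3 amino-acid sequence
#'
#' Substring of length `min(w, len)` centred on the sequence; for an even
#' overhang the start is `floor((len - w) / 2)` (0-based), i.e. centring is
#' left-biased. Sequences shorter than `w` are returned whole and flagged.
#'
#' @param cdr3_aa Character vector of amino-acid sequences.
#' @param w Window width (default 5).
#' @return Character vector of windows, with attribute `short` (logical
#'   vector marking sequences shorter than `w`).
#' @examples
#' central_window("CARDYW")  # "CARDY"
#' @export
central_window <- function(cdr3_aa, w = 5) {
  stopifnot(w >= 1)
  len <- nchar(cdr3_aa)
  start0 <- pmax(0L, (len - w) %/% 2L)      # 0-based, half-open
  out <- substr(cdr3_aa, start0 + 1L, start0 + pmin(w, len))
  attr(out, "short") <- len < w
  out
}

#' Per-sequence physicochemical descriptor
#'
#' * `charge`: count of K and R minus count of D and E (histidine excluded
#'   by default, the pH-7 net-charge convention);
#' * `hydropathy`: mean Kyte-Doolittle index;
#' * `strength`: predicted interaction strength, operationalized as the
#'   count of strongly interacting residues (F, I, L, M, V, W, Y);
#' * `kf1`..`kf10`: mean Kidera factor over residues.
#'
#' Non-standard residues raise an error naming the offending character --
#' there is no silent skipping.
#'
#' @param seqs Character vector of amino-acid sequences (non-empty).
#' @param name Descriptor name.
#' @param properties Property table from [aa_properties()].
#' @param include_histidine Count H as +1 in `charge`.
#' @return Numeric vector, one value per sequence.
#' @export
aa_descriptor <- function(seqs, name, properties = aa_properties(),
                          include_histidine = FALSE) {
  stopifnot(all(nchar(seqs) > 0))
  name <- match.arg(name, c("charge", "hydropathy", "strength",
                            paste0("kf", 1:10)))
  res <- strsplit(seqs, "")
  bad <- setdiff(unique(unlist(res)), properties$aa)
  if (length(bad))
    stop("non-standard residue(s) in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  col <- switch(name, charge = "charge", hydropathy = "hydropathy",
                strength = "strong", name)
  vals <- setNames(properties[[col]], properties$aa)
  if (name == "charge" && include_histidine) vals[["H"]] <- 1
  agg <- if (name %in% c("charge", "strength")) sum else mean
  vapply(res, function(r) agg(vals[r]), numeric(1))
}

#' CDR-H3 physicochemical profile of a repertoire
#'
#' Takes the `top_n` most frequent clonotypes (ties broken by UMI count then
#' sequence), extracts the `window` central amino acids of each CDR-H3, and
#' returns the unweighted mean of each descriptor across clonotypes, plus the
#' mean full CDR-H3 amino-acid length. Clonotypes without a translatable
#' CDR-H3 or containing non-standard residues are dropped and counted.
#'
#' @param rep A [bcr_repertoire].
#' @param top_n Number of most frequent clonotypes profiled (default 100).
#' @param window Central-window width (default 5).
#' @param properties Property table from [aa_properties()].
#' @param include_histidine Passed to [aa_descriptor()].
#' @return One-row tibble: `sample_id`, `n_used`, `n_dropped`,
#'   `mean_cdr3_len`, `charge`, `hydropathy`, `strength`, `kf1`..`kf10`.
#' @export
physchem_profile <- function(rep, top_n = 100, window = 5,
                             properties = aa_properties(),
                             include_histidine = FALSE) {
  cl <- rep$clonotypes
  ord <- order(-cl$frequency, -cl$umi_count, cl$cdr3_nt)
  cl <- cl[head(ord, top_n), , drop = FALSE]
  ok <- !is.na(cl$cdr3_aa) & nchar(cl$cdr3_aa) > 0 &
    !grepl(paste0("[^", paste(properties$aa, collapse = ""), "]"), cl$cdr3_aa)
  n_dropped <- sum(!ok)
  cl <- cl[ok, , drop = FALSE]
  descriptors <- c("charge", "hydropathy", "strength", paste0("kf", 1:10))
  out <- tibble::tibble(
    sample_id = rep$metadata$sample_id %||% NA_character_,
    n_used = nrow(cl), n_dropped = n_dropped,
    mean_cdr3_len = mean(nchar(cl$cdr3_aa)))
  win <- central_window(cl$cdr3_aa, w = window)
  for (d in descriptors) {
    out[[d]] <- mean(aa_descriptor(win, d, properties = properties,
                                   include_histidine = include_histidine))
  }
  out
}

#' Compare physicochemical profiles between two groups of samples
#'
#' One test per descriptor (two-sided t-test or Mann-Whitney) across the
#' per-sample profile values of two groups, with Bonferroni or
#' Bonferroni-Holm multiplicity correction.
#'
#' @param profiles Tibble of per-sample profiles (rows = samples) as from
#'   [physchem_profile()], plus a grouping column.
#' @param group Name of the grouping column (must hold exactly two levels).
#' @param test `"t"` or `"mannwhitney"`.
#' @param correction `"bonferroni"` or `"holm"`.
#' @param descriptors Columns to test (default: all profile descriptors).
#' @return Tibble with `descriptor`, `statistic`, `p`, `p_adj`,
#'   `mean_<group1>`, `mean_<group2>`.
#' @export
compare_physchem <- function(profiles, group = "group",
                             test = c("t", "mannwhitney"),
                             correction = c("bonferroni", "holm"),
                             descriptors = NULL) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  g <- factor(profiles[[group]])
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  if (is.null(descriptors)) {
    descriptors <- intersect(
      c("mean_cdr3_len", "charge", "hydropathy", "strength", paste0("kf", 1:10)),
      names(profiles))
  }
  lv <- levels(g)
  rows <- lapply(descriptors, function(d) {
    x <- profiles[[d]][g == lv[1]]
    y <- profiles[[d]][g == lv[2]]
    fit <- if (test == "t") t.test(x, y) else
      wilcox.test(x, y, exact = FALSE)
    tibble::tibble(descriptor = d, statistic = unname(fit$statistic),
                   p = fit$p.value, m1 = mean(x), m2 = mean(y))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- p.adjust(out$p, method = correction)
  names(out)[names(out) == "m1"] <- paste0("mean_", lv[1])
  names(out)[names(out) == "m2"] <- paste0("mean_", lv[2])
  out[, c("descriptor", "statistic", "p", "p_adj",
          paste0("mean_", lv[1]), paste0("mean_", lv[2]))]
}
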