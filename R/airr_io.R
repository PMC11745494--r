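# Reading/writing AIRR Rearrangement clonotype tables, filtering rules and
# replicate pooling.

.default_column_map <- c(
  cdr3_nt = "junction", cdr3_aa = "junction_aa",
  v_gene = "v_call", j_gene = "j_call", c_call = "c_call",
  umi_count = "duplicate_count",
  sample_id = "sample_id", patient_id = "patient_id", tissue = "tissue",
  fragment_id = "fragment_id", replicate_id = "replicate_id",
  v_region_nt = "v_region_nt", germline_mutations = "germline_mutations")

#' Parse isotype from a constant-region gene call
#'
#' `IGHM` maps to `IgM`, `IGHG*` to `IgG`, `IGHA*` to `IgA`; anything else
#' (including missing calls) maps to `"other"`.
#'
#' @param c_call Character vector of constant-region calls.
#' @return Character vector of `"IgM"`, `"IgG"`, `"IgA"` or `"other"`.
#' @export
parse_isotype <- function(c_call) {
  out <- rep("other", length(c_call))
  cc <- toupper(ifelse(is.na(c_call), "", c_call))
  out[startsWith(cc, "IGHM")] <- "IgM"
  out[startsWith(cc, "IGHG")] <- "IgG"
  out[startsWith(cc, "IGHA")] <- "IgA"
  out
}

.isotype_rank <- c(IgM = 1, IgG = 2, IgA = 3, other = 4)

# merge rows sharing one identity key: counts are summed; the isotype of the
# highest-UMI constituent wins, ties broken IgM > IgG > IgA
merge_clonotype_records <- function(cl) {
  cl$.key <- clonotype_key(cl$cdr3_nt, cl$v_gene, cl$j_gene)
  if (!anyDuplicated(cl$.key)) {
    cl$.key <- NULL
    return(cl)
  }
  merged <- cl |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(dplyr::desc(.data$umi_count),
                   .isotype_rank[.data$isotype], .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(setdiff(names(cl), c(".key", "umi_count"))),
                    dplyr::first),
      umi_count = sum(.data$umi_count), .groups = "drop") |>
    dplyr::select(-".key")
  merged
}

#' Read an AIRR Rearrangement TSV into a repertoire
#'
#' Reads a tab-separated clonotype table in the AIRR Rearrangement dialect
#' (columns `junction`, `v_call`, `j_call`, `c_call`, `duplicate_count` or
#' `umi_count`, plus optional sample labels), merges records that share the
#' clonotype identity key (CDR-H3 nucleotide sequence, V gene, J gene) and
#' computes UMI-based frequencies.
#'
#' @param path Path to a TSV file.
#' @param column_map Optional named character vector overriding the default
#'   mapping from internal field names to file column names (names are the
#'   internal fields, e.g. `c(umi_count = "umi_count")`).
#' @return A [bcr_repertoire].
#' @export
read_airr <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  map <- .default_column_map
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  # umi_count may live in either duplicate_count or umi_count
  if (!map[["umi_count"]] %in% names(tbl) && "umi_count" %in% names(tbl))
    map[["umi_count"]] <- "umi_count"
  mandatory <- c("cdr3_nt", "v_gene", "j_gene", "umi_count")
  for (field in mandatory) {
    if (!map[[field]] %in% names(tbl))
      stop("AIRR format error: missing mandatory column '", map[[field]], "'",
           call. = FALSE)
  }
  cl <- tibble::tibble(
    cdr3_nt = as.character(tbl[[map[["cdr3_nt"]]]]),
    v_gene = sub(",.*$", "", as.character(tbl[[map[["v_gene"]]]])),
    j_gene = sub(",.*$", "", as.character(tbl[[map[["j_gene"]]]])),
    umi_count = as.numeric(tbl[[map[["umi_count"]]]]))
  cl$isotype <- if (map[["c_call"]] %in% names(tbl))
    parse_isotype(tbl[[map[["c_call"]]]]) else "other"
  if (map[["cdr3_aa"]] %in% names(tbl)) cl$cdr3_aa <- tbl[[map[["cdr3_aa"]]]]
  for (lab in c("sample_id", "patient_id", "tissue", "fragment_id",
                "replicate_id", "v_region_nt", "germline_mutations")) {
    if (map[[lab]] %in% names(tbl)) cl[[lab]] <- tbl[[map[[lab]]]]
  }
  if (sum(cl$umi_count) <= 0)
    stop("empty repertoire: total UMI count is zero in ", path, call. = FALSE)
  bcr_repertoire(merge_clonotype_records(cl))
}

#' Write a repertoire as an AIRR Rearrangement TSV
#'
#' Inverse of [read_airr()]: identity keys, UMI counts and sample labels
#' round-trip exactly. Isotypes are written as constant-region calls
#' (`IgM` -> `IGHM`, `IgG` -> `IGHG`, `IgA` -> `IGHA`, `other` -> empty).
#'
#' @param rep A [bcr_repertoire].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  cl <- rep$clonotypes
  out <- tibble::tibble(
    sequence_id = sprintf("clonotype_%06d", seq_len(nrow(cl))),
    junction = cl$cdr3_nt,
    junction_aa = cl$cdr3_aa,
    v_call = cl$v_gene, j_call = cl$j_gene,
    c_call = c(IgM = "IGHM", IgG = "IGHG", IgA = "IGHA", other = "")[cl$isotype],
    duplicate_count = cl$umi_count)
  for (lab in c("sample_id", "patient_id", "tissue", "fragment_id",
                "replicate_id", "v_region_nt", "germline_mutations")) {
    val <- cl[[lab]] %||% rep$metadata[[lab]]
    if (!is.null(val)) out[[lab]] <- val
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Apply UMI- and sample-level filters to a repertoire
#'
#' Removes clonotypes supported by fewer than `min_umi_per_clonotype` UMIs
#' (default 2: singleton clonotypes are excluded from individual-clonotype
#' analyses) and renormalizes frequencies. A sample retaining
#' `min_clonotypes` or fewer clonotypes is flagged as excluded rather than
#' silently dropped. Singleton retention (`keep_singletons = TRUE`) is
#' intended for clonal-lineage analyses where sample size matters more than
#' per-clonotype confidence.
#'
#' @param rep A [bcr_repertoire].
#' @param min_umi_per_clonotype Minimum UMI count per clonotype (default 2).
#' @param min_clonotypes Samples with this many clonotypes or fewer after
#'   filtering are flagged excluded (default 50).
#' @param keep_singletons Retain single-UMI clonotypes (equivalent to
#'   `min_umi_per_clonotype = 1`).
#' @return The filtered [bcr_repertoire]; check [is_excluded()].
#' @export
apply_filters <- function(rep, min_umi_per_clonotype = 2, min_clonotypes = 50,
                          keep_singletons = FALSE) {
  stopifnot(min_umi_per_clonotype >= 0, min_clonotypes >= 0)
  if (keep_singletons) min_umi_per_clonotype <- min(min_umi_per_clonotype, 1)
  keep <- rep$clonotypes$umi_count >= min_umi_per_clonotype
  rep$clonotypes <- rep$clonotypes[keep, , drop = FALSE]
  rep$total_umi <- as.integer(round(sum(rep$clonotypes$umi_count)))
  if (nrow(rep$clonotypes)) {
    rep$clonotypes$frequency <- rep$clonotypes$umi_count / rep$total_umi
  }
  if (nrow(rep$clonotypes) <= min_clonotypes) {
    rep$excluded <- TRUE
    rep$exclusion_reason <- sprintf(
      "%d clonotypes after filtering (threshold: more than %d required)",
      nrow(rep$clonotypes), min_clonotypes)
  }
  rep
}

#' Pool repertoires by mean clonotype frequency
#'
#' Replicates (or fragments) of one sample context are pooled into a single
#' repertoire: for each clonotype the pooled frequency is the arithmetic
#' mean of its frequencies across the input files, a clonotype absent from a
#' file contributing frequency zero there. This equalizes the contribution
#' of every input set regardless of sequencing depth. UMI counts are summed.
#' Pooled frequencies are renormalized defensively (means over a common
#' clonotype universe already sum to one).
#'
#' @param reps List of [bcr_repertoire] objects (at least one).
#' @param warn_context Warn when patient labels differ across inputs.
#' @return A pooled [bcr_repertoire].
#' @examples
#' a <- bcr_repertoire(data.frame(cdr3_nt = c("AAA", "CCC"), v_gene = "V1",
#'   j_gene = "J1", umi_count = c(4, 6)))
#' b <- bcr_repertoire(data.frame(cdr3_nt = "AAA", v_gene = "V1",
#'   j_gene = "J1", umi_count = 5))
#' pool_repertoires(list(a, b))$clonotypes$frequency  # (0.4+1)/2, (0.6+0)/2
#' @export
pool_repertoires <- function(reps, warn_context = TRUE) {
  if (length(reps) == 0) stop("no repertoires to pool", call. = FALSE)
  if (warn_context) {
    pats <- unique(unlist(lapply(reps, function(r) r$metadata$patient_id)))
    if (length(pats) > 1)
      warning("pooling repertoires from different patients: ",
              paste(pats, collapse = ", "), call. = FALSE)
  }
  n <- length(reps)
  all_cl <- dplyr::bind_rows(lapply(reps, function(r) r$clonotypes))
  all_cl$.key <- clonotype_key(all_cl$cdr3_nt, all_cl$v_gene, all_cl$j_gene)
  pooled <- all_cl |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(dplyr::desc(.data$umi_count),
                   .isotype_rank[.data$isotype], .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(setdiff(
        names(all_cl), c(".key", "umi_count", "frequency"))), dplyr::first),
      umi_count = sum(.data$umi_count),
      frequency = sum(.data$frequency) / n,  # absent-in-file counts as 0
      .groups = "drop") |>
    dplyr::select(-".key")
  meta <- list(sample_id = paste(
    unlist(lapply(reps, function(r) r$metadata$sample_id %||% "?")),
    collapse = "+"))
  for (lab in c("patient_id", "tissue")) {
    u <- unique(unlist(lapply(reps, function(r) r$metadata[[lab]])))
    if (length(u) == 1L) meta[[lab]] <- u
  }
  # sample-level labels are no longer single-valued after pooling
  pooled$sample_id <- NULL
  pooled$fragment_id <- NULL
  pooled$replicate_id <- NULL
  out <- bcr_repertoire(pooled, metadata = meta, recompute_freq = FALSE)
  renormalize(out)
}
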