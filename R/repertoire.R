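#' Construct a BCR repertoire
#'
#' A repertoire is one sample's set of clonotypes. A clonotype is defined by
#' an identical CDR-H3 nucleotide sequence together with identical V- and
#' J-gene attribution; isotype is not part of the identity key, so records
#' that differ only in constant-region call belong to the same clonotype.
#' Frequencies are UMI-based: `umi_count / total_umi`.
#'
#' @param clonotypes Data frame with at least `cdr3_nt`, `v_gene`, `j_gene`
#'   and `umi_count`. Optional columns: `cdr3_aa` (filled by translation when
#'   the junction is in frame), `isotype` (one of `"IgM"`, `"IgG"`, `"IgA"`,
#'   `"other"`), sample labels (`sample_id`, `patient_id`, `tissue`,
#'   `fragment_id`, `replicate_id`), `v_region_nt`, `germline_mutations`, and
#'   `frequency` (recomputed unless `recompute_freq = FALSE`).
#' @param metadata Named list of sample-level labels; missing entries are
#'   taken from constant clonotype columns where possible.
#' @param recompute_freq Recompute `frequency` as `umi_count / total_umi`
#'   (default). When `FALSE`, an existing `frequency` column is kept (used by
#'   pooling, where frequencies are means, not UMI shares).
#' @return An object of class `bcr_repertoire`: a list with elements
#'   `clonotypes` (tibble), `metadata` (list), `total_umi`, `excluded`
#'   (logical) and `exclusion_reason`.
#' @examples
#' rep <- bcr_repertoire(data.frame(
#'   cdr3_nt = c("TGTGCGAGATGG", "TGTGCGAAATGG"),
#'   v_gene = "IGHV1-1", j_gene = "IGHJ4", umi_count = c(6, 4)))
#' rep$clonotypes$frequency
#' @export
bcr_repertoire <- function(clonotypes, metadata = list(), recompute_freq = TRUE) {
  cl <- tibble::as_tibble(clonotypes)
  required <- c("cdr3_nt", "v_gene", "j_gene", "umi_count")
  missing_cols <- setdiff(required, names(cl))
  if (length(missing_cols))
    stop("clonotype table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(cl$umi_count < 0)) stop("umi_count must be non-negative", call. = FALSE)
  key <- clonotype_key(cl$cdr3_nt, cl$v_gene, cl$j_gene)
  if (anyDuplicated(key))
    stop("duplicate clonotype identity keys; merge records first ",
         "(see read_airr)", call. = FALSE)
  if (!"isotype" %in% names(cl)) cl$isotype <- "other"
  if (!"cdr3_aa" %in% names(cl)) cl$cdr3_aa <- translate_nt(cl$cdr3_nt)
  total <- sum(cl$umi_count)
  if (nrow(cl) > 0 && total <= 0)
    stop("empty repertoire: total UMI count is zero", call. = FALSE)
  if (recompute_freq || !"frequency" %in% names(cl)) {
    cl$frequency <- if (nrow(cl)) cl$umi_count / total else numeric(0)
  }
  for (lab in c("sample_id", "patient_id", "tissue", "fragment_id", "replicate_id")) {
    if (is.null(metadata[[lab]]) && lab %in% names(cl)) {
      u <- unique(cl[[lab]])
      if (length(u) == 1L) metadata[[lab]] <- u
    }
  }
  structure(
    list(clonotypes = cl, metadata = metadata, total_umi = as.integer(round(total)),
         excluded = FALSE, exclusion_reason = NA_character_),
    class = "bcr_repertoire")
}

#' @export
print.bcr_repertoire <- function(x, ...) {
  cat("<bcr_repertoire> ", x$metadata$sample_id %||% "(unnamed)",
      ": ", nrow(x$clonotypes), " clonotypes, ", x$total_umi, " UMIs",
      if (isTRUE(x$excluded)) paste0(" [EXCLUDED: ", x$exclusion_reason, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of clonotypes in a repertoire
#' @param rep A `bcr_repertoire`.
#' @return Integer count.
#' @export
n_clonotypes <- function(rep) nrow(rep$clonotypes)

#' Was a sample flagged as excluded by filtering?
#' @param rep A `bcr_repertoire`.
#' @return Logical.
#' @export
is_excluded <- function(rep) isTRUE(rep$excluded)

# renormalize frequencies to sum to one (no-op on empty repertoires)
renormalize <- function(rep) {
  s <- sum(rep$clonotypes$frequency)
  if (nrow(rep$clonotypes) && s > 0) {
    rep$clonotypes$frequency <- rep$clonotypes$frequency / s
  }
  rep
}
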