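# Cross-sample UMI-collision decontamination.
#
# Molecules carrying the same UMI tag in different samples, with identical or
# near-identical consensus sequences, are treated as a contamination event
# (library cross-talk / index hopping). The read-count ratio decides the
# direction: a dominant sample keeps its molecule, the rest lose theirs; with
# no dominant sample the molecule is removed everywhere.

#' Read a UMI-level table
#'
#' @param path TSV with columns `sample_id`, `umi`, `sequence`, `reads`.
#' @return A tibble of UMI records.
#' @export
read_umi_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "umi", "sequence", "reads"), names(tbl))
  if (length(missing_cols))
    stop("UMI table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  tbl
}

#' Remove cross-sample UMI collisions
#'
#' For every UMI tag observed in two or more samples with identical or
#' near-identical consensus sequences (pairwise identity at least
#' `seq_similarity_min` on an equal-length trim): when the read count in one
#' sample exceeds every other involved sample's read count by strictly more
#' than `ratio` times, the UMI is eliminated from the lower-read sample(s)
#' only; otherwise (including a ratio of exactly `ratio`) it is eliminated
#' from all involved samples. UMIs shared between samples with dissimilar
#' sequences are genuine tag coincidences and are kept everywhere.
#'
#' @param records Tibble of UMI records (`sample_id`, `umi`, `sequence`,
#'   `reads`), e.g. from [read_umi_table()].
#' @param ratio Read-count dominance ratio (default 5; must exceed 1).
#' @param seq_similarity_min Minimum pairwise identity for two consensus
#'   sequences to count as the same molecule (default 0.9). The dominance
#'   rule is applied within connected components of this similarity relation.
#' @return A list with `kept` (surviving records) and `removals` (log with
#'   one row per removed record: `umi`, `sample_id`, `reads`,
#'   `group_max_reads`, `n_samples`, `decision`).
#' @examples
#' rec <- tibble::tibble(
#'   sample_id = c("s1", "s2"), umi = "ACGTACGT",
#'   sequence = "TGTGCGAGATGG", reads = c(12, 2))
#' decontaminate(rec)$removals  # 12/2 = 6 > 5: removed from s2 only
#' @export
decontaminate <- function(records, ratio = 5, seq_similarity_min = 0.9) {
  stopifnot(ratio > 1, seq_similarity_min >= 0, seq_similarity_min <= 1)
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(list(kept = records, removals = .empty_removal_log()))
  }
  if (any(records$reads < 1)) stop("reads must be >= 1", call. = FALSE)
  records$.row <- seq_len(nrow(records))
  shared_umis <- records |>
    dplyr::distinct(.data$umi, .data$sample_id) |>
    dplyr::count(.data$umi) |>
    dplyr::filter(.data$n >= 2) |>
    dplyr::pull(.data$umi)
  drop_rows <- integer(0)
  log_rows <- list()
  for (u in shared_umis) {
    grp <- records[records$umi == u, , drop = FALSE]
    k <- nrow(grp)
    adj <- matrix(FALSE, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      adj[i, j] <- adj[j, i] <-
        pair_identity(grp$sequence[i], grp$sequence[j]) >= seq_similarity_min
    }
    comp <- graph_components(adj | diag(TRUE, k))
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      sub <- grp[idx, , drop = FALSE]
      if (length(unique(sub$sample_id)) < 2) next
      rmax <- max(sub$reads)
      top <- which(sub$reads == rmax)
      dominant <- length(top) == 1L && all(rmax > ratio * sub$reads[-top])
      removed <- if (dominant) sub$.row[-top] else sub$.row
      decision <- if (dominant) "removed_minor" else "removed_all"
      drop_rows <- c(drop_rows, removed)
      keep_sub <- sub$.row %in% removed
      log_rows[[length(log_rows) + 1L]] <- tibble::tibble(
        umi = u, sample_id = sub$sample_id[keep_sub],
        sequence = sub$sequence[keep_sub],
        reads = sub$reads[keep_sub], group_max_reads = rmax,
        n_samples = length(unique(sub$sample_id)), decision = decision)
    }
  }
  removals <- if (length(log_rows)) dplyr::bind_rows(log_rows) else .empty_removal_log()
  kept <- records[!records$.row %in% drop_rows, , drop = FALSE]
  kept$.row <- NULL
  list(kept = kept, removals = removals)
}

.empty_removal_log <- function() {
  tibble::tibble(umi = character(), sample_id = character(),
                 sequence = character(), reads = numeric(),
                 group_max_reads = numeric(), n_samples = integer(),
                 decision = character())
}

#' Pairwise UMI collision rates
#'
#' Fraction of shared UMI tags per sample pair (Jaccard index of the two
#' samples' UMI sets), a quick QC summary of cross-talk pressure.
#'
#' @param records Tibble of UMI records.
#' @return Tibble with `sample_i`, `sample_j`, `n_shared`, `n_union`, `rate`
#'   (symmetric, in `[0, 1]`).
#' @export
collision_rate <- function(records) {
  records <- tibble::as_tibble(records)
  sets <- split(records$umi, records$sample_id)
  sets <- lapply(sets, unique)
  ids <- names(sets)
  if (length(ids) < 2) {
    return(tibble::tibble(sample_i = character(), sample_j = character(),
                          n_shared = integer(), n_union = integer(),
                          rate = numeric()))
  }
  pairs <- utils::combn(ids, 2)
  out <- apply(pairs, 2, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    sh <- length(intersect(a, b)); un <- length(union(a, b))
    tibble::tibble(sample_i = p[1], sample_j = p[2], n_shared = sh,
                   n_union = un, rate = if (un > 0) sh / un else 0)
  })
  dplyr::bind_rows(out)
}

#' Subtract decontamination removals from an AIRR clonotype table
#'
#' Decrements each clonotype's UMI count by the number of removed UMI records
#' matching its sample and junction sequence; clonotypes dropping to zero are
#' removed.
#'
#' @param airr Clonotype tibble (AIRR dialect columns as produced by
#'   [simulate_repertoires()], i.e. with `sample_id`, `junction`,
#'   `duplicate_count`).
#' @param removals Removal log from [decontaminate()] (carries the removed
#'   records' consensus sequences).
#' @return The adjusted clonotype tibble.
#' @export
apply_decontam_to_airr <- function(airr, removals) {
  if (nrow(removals) == 0) return(airr)
  if (!"sequence" %in% names(removals))
    stop("removals must carry the removed records' sequences", call. = FALSE)
  dec <- removals |>
    dplyr::count(.data$sample_id, .data$sequence, name = "n_removed")
  out <- airr |>
    dplyr::left_join(dec, by = c("sample_id", junction = "sequence")) |>
    dplyr::mutate(duplicate_count = .data$duplicate_count -
                    dplyr::coalesce(.data$n_removed, 0L)) |>
    dplyr::select(-"n_removed") |>
    dplyr::filter(.data$duplicate_count > 0)
  out
}
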