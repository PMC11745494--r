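# Clonal-lineage inference and hypermutation phylogeny.
#
# Clonotypes descending from one naive B cell share V gene, J gene and
# CDR-H3 length (the D segment is ignored: its germline annotation is too
# short and too mutated to be trusted), and their junctions are similar.
# Lineages are the single-linkage clusters of equal-length junctions at a
# nucleotide distance threshold detected automatically from the
# distance-to-nearest distribution. Trees are rooted on a germline V||J
# conjugate outgroup; junction positions without germline coverage (the
# D/N region) are masked out of every distance involving the outgroup.

#' Packaged pseudo-germline V/J reference
#'
#' Synthetic reference set of 10 V and 10 J alleles used by the repertoire
#' generator and by outgroup construction. Each row carries the germline
#' `sequence` fragment adjacent to the junction and `junction_offset`, the
#' number of its nucleotides lying inside the junction (from the conserved
#' Cys codon for V, up to the conserved Trp codon for J). This is a
#' synthetic stand-in for an IMGT germline database, sufficient for
#' junction-level outgroup construction.
#'
#' @param path Optional path to an alternative reference TSV
#'   (`gene`, `segment`, `sequence`, `junction_offset`).
#' @return Tibble of germline segments.
#' @export
germline_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "germline_vj.tsv", package = "tribcr",
                        mustWork = TRUE)
  }
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

.junction_partition <- function(clonotypes) {
  paste(clonotypes$v_gene, clonotypes$j_gene, nchar(clonotypes$cdr3_nt),
        sep = "|")
}

#' Distance-to-nearest distribution
#'
#' For every distinct junction sequence, the normalized Hamming distance to
#' its nearest non-identical neighbour within its V/J/CDR-H3-length
#' partition. Junctions alone in their partition yield `NA`.
#'
#' @param clonotypes Clonotype tibble (columns `cdr3_nt`, `v_gene`,
#'   `j_gene`), typically pooled patient-wise.
#' @return Numeric vector of distances (with `NA` for partition singletons).
#' @export
nn_distances <- function(clonotypes) {
  part <- .junction_partition(clonotypes)
  out <- lapply(split(clonotypes$cdr3_nt, part), function(seqs) {
    seqs <- unique(seqs)
    if (length(seqs) < 2) return(NA_real_)
    d <- hamming_matrix(seqs)
    diag(d) <- NA
    apply(d, 1, min, na.rm = TRUE)
  })
  unlist(out, use.names = FALSE)
}

#' Automatic identity-threshold detection
#'
#' Kernel-density estimate of the distance-to-nearest distribution; the
#' returned threshold is the distance at the deepest local minimum between
#' the two largest modes, searched within `search_range`. The typical
#' repertoire shows a bimodal distribution -- a low-distance mode of
#' hypermutation neighbours and a high-distance mode of unrelated junctions
#' -- whose valley (usually a 15-20% distance, i.e. 80-85% identity)
#' separates clonally related from unrelated sequences. With fewer than
#' `min_n` distances, a unimodal estimate, or no admissible minimum, the
#' conservative fallback threshold is returned and flagged.
#'
#' @param distances Numeric distance-to-nearest sample (`NA`s dropped).
#' @param fallback Fallback threshold (default 0.15).
#' @param search_range Interval searched for the minimum (default
#'   `c(0.05, 0.5)`).
#' @param min_n Minimum sample size for detection (default 20).
#' @return Threshold (numeric scalar) with attributes `fallback` (logical)
#'   and `bw` (bandwidth used, `NA` on fallback).
#' @export
detect_threshold <- function(distances, fallback = 0.15,
                             search_range = c(0.05, 0.5), min_n = 20) {
  d <- distances[!is.na(distances)]
  flag <- function(x, fb, bw = NA_real_) {
    attr(x, "fallback") <- fb
    attr(x, "bw") <- bw
    x
  }
  if (length(d) < min_n || length(unique(d)) < 2) return(flag(fallback, TRUE))
  dens <- stats::density(d, bw = "nrd0", n = 512)
  x <- dens$x; y <- dens$y; n <- length(y)
  is_max <- c(y[1] > y[2],
              diff(sign(diff(y))) == -2,
              y[n] > y[n - 1])
  maxima <- which(is_max)
  if (length(maxima) < 2) return(flag(fallback, TRUE, dens$bw))
  top2 <- sort(maxima[order(y[maxima], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  is_min <- c(FALSE, diff(sign(diff(y))) == 2, FALSE)
  cand <- intersect(which(is_min), between)
  cand <- cand[x[cand] > search_range[1] & x[cand] < search_range[2]]
  if (length(cand) == 0) return(flag(fallback, TRUE, dens$bw))
  flag(x[cand[which.min(y[cand])]], FALSE, dens$bw)
}

#' Assemble clonal lineages
#'
#' Partitions clonotypes by V gene, J gene and CDR-H3 length, then clusters
#' equal-length junctions by single linkage at the given normalized Hamming
#' distance threshold (two clonotypes belong to one lineage when connected
#' by a chain of neighbours within the threshold). Singletons are reported
#' as size-1 lineages.
#'
#' @param clonotypes Clonotype tibble or [bcr_repertoire]; rows beyond the
#'   identity key (tissue, isotype, sample labels) are preserved.
#' @param threshold Distance threshold, or `"auto"` to detect it with
#'   [detect_threshold()] from the pooled distance-to-nearest distribution.
#' @param min_size Drop lineages smaller than this from the output
#'   (default 1: keep all).
#' @return The input tibble plus `lineage_id`, with attributes
#'   `threshold_used` and `threshold_fallback`.
#' @export
build_lineages <- function(clonotypes, threshold = "auto", min_size = 1) {
  if (inherits(clonotypes, "bcr_repertoire")) clonotypes <- clonotypes$clonotypes
  clonotypes <- tibble::as_tibble(clonotypes)
  if (identical(threshold, "auto")) {
    threshold <- detect_threshold(nn_distances(clonotypes))
  }
  fallback <- isTRUE(attr(threshold, "fallback"))
  thr <- as.numeric(threshold)
  part <- .junction_partition(clonotypes)
  lineage_id <- character(nrow(clonotypes))
  for (p in unique(part)) {
    idx <- which(part == p)
    seqs <- unique(clonotypes$cdr3_nt[idx])
    if (length(seqs) == 1) {
      cl <- setNames(1L, seqs)
    } else {
      d <- hamming_matrix(seqs)
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      cl <- stats::cutree(hc, h = thr + 1e-9)
      names(cl) <- seqs
    }
    lineage_id[idx] <- paste(p, sprintf("L%03d", cl[clonotypes$cdr3_nt[idx]]),
                             sep = "|")
  }
  clonotypes$lineage_id <- lineage_id
  if (min_size > 1) {
    sizes <- table(lineage_id)
    clonotypes <- clonotypes[sizes[clonotypes$lineage_id] >= min_size, ,
                             drop = FALSE]
  }
  attr(clonotypes, "threshold_used") <- thr
  attr(clonotypes, "threshold_fallback") <- fallback
  clonotypes
}

#' Lineage size summary
#' @param lineages Output of [build_lineages()].
#' @return Tibble with `lineage_id`, `v_gene`, `j_gene`, `cdr3_len`, `size`
#'   (distinct junctions) and `n_records`.
#' @export
lineage_summary <- function(lineages) {
  lineages |>
    dplyr::group_by(.data$lineage_id) |>
    dplyr::summarise(v_gene = dplyr::first(.data$v_gene),
                     j_gene = dplyr::first(.data$j_gene),
                     cdr3_len = nchar(dplyr::first(.data$cdr3_nt)),
                     size = dplyr::n_distinct(.data$cdr3_nt),
                     n_records = dplyr::n(), .groups = "drop")
}

# majority-rule consensus of equal-length sequences (ties -> lexicographic)
.consensus <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(m, 2, function(col) names(sort(table(col), decreasing = TRUE))[1]),
        collapse = "")
}

# best ungapped overlap length of a germline fragment against one end of the
# consensus: maximizes matches - mismatches, ties towards longer coverage
.best_overlap <- function(germ, cons, end = c("left", "right"), min_overlap = 3) {
  end <- match.arg(end)
  len <- nchar(cons); glen <- nchar(germ)
  kmax <- min(len, glen)
  if (kmax < min_overlap) return(0L)
  best_k <- 0L; best_score <- -Inf
  for (k in min_overlap:kmax) {
    a <- if (end == "left") substr(germ, 1L, k) else
      substr(germ, glen - k + 1L, glen)
    b <- if (end == "left") substr(cons, 1L, k) else
      substr(cons, len - k + 1L, len)
    matches <- sum(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
    score <- 2L * matches - k
    if (score >= best_score) { best_score <- score; best_k <- k }
  }
  best_k
}

#' Construct the germline outgroup conjugate for a lineage
#'
#' The most recent common ancestor of a lineage is approximated by an
#' outgroup concatenating the germline V 3' end and the germline J 5' start
#' over the junction. The D/N region in between has no trustworthy germline
#' annotation and is masked with `N`; masked positions are excluded from all
#' distances involving the outgroup. Germline coverage at each end is the
#' best-scoring ungapped overlap against the lineage consensus.
#'
#' @param junctions Equal-length member junction sequences.
#' @param v_gene,j_gene Gene names looked up in `germline_db`.
#' @param germline_db Reference tibble from [germline_reference()].
#' @return List with `sequence` (the masked outgroup string) and `n_masked`.
#' @export
build_outgroup <- function(junctions, v_gene, j_gene,
                           germline_db = germline_reference()) {
  len <- unique(nchar(junctions))
  stopifnot(length(len) == 1)
  vrow <- germline_db[germline_db$gene == v_gene & germline_db$segment == "V", ]
  jrow <- germline_db[germline_db$gene == j_gene & germline_db$segment == "J", ]
  if (nrow(vrow) != 1 || nrow(jrow) != 1)
    stop("germline reference lacks gene ", v_gene, " or ", j_gene,
         call. = FALSE)
  # junction-covered germline fragments
  v_tail <- substr(vrow$sequence, nchar(vrow$sequence) - vrow$junction_offset + 1L,
                   nchar(vrow$sequence))
  j_head <- substr(jrow$sequence, 1L, jrow$junction_offset)
  cons <- .consensus(junctions)
  v_cover <- .best_overlap(v_tail, cons, end = "left")
  j_cover <- .best_overlap(j_head, cons, end = "right")
  j_cover <- min(j_cover, len - v_cover)
  mid <- len - v_cover - j_cover
  seq <- paste0(substr(v_tail, 1L, v_cover), strrep("N", mid),
                substr(j_head, nchar(j_head) - j_cover + 1L, nchar(j_head)))
  list(sequence = seq, n_masked = mid)
}

# exact 3-point root distances for two members + outgroup
.three_taxon_depths <- function(d_ao, d_bo, d_ab) {
  x <- (d_ao + d_bo - d_ab) / 2       # outgroup to internal node
  c(max(d_ao - x, 0), max(d_bo - x, 0))
}

#' Build a germline-rooted tree for one lineage
#'
#' Neighbour-joining on pairwise normalized Hamming distances over the
#' member junctions plus the masked germline outgroup, rooted on the
#' outgroup, with negative branch lengths clamped to zero. Members are
#' ordered lexicographically by sequence before tree construction, making
#' the result independent of input order. Duplicate junctions are collapsed
#' and share one tip. For exactly two distinct members the exact three-taxon
#' solution is used.
#'
#' @param members Tibble of lineage members (columns `cdr3_nt`, plus
#'   `cdr3_aa`, `v_gene`, `j_gene` if available).
#' @param outgroup Output of [build_outgroup()] (or a list with element
#'   `sequence`).
#' @return A `lineage_tree`: list with `tree` (an [ape::phylo] rooted on tip
#'   `"germline"`), `members` (tibble with `dist_to_root` and `rank`), and
#'   `outgroup` (the masked sequence).
#' @export
lineage_tree <- function(members, outgroup) {
  members <- tibble::as_tibble(members)
  seqs <- sort(unique(members$cdr3_nt))
  if (length(seqs) < 2)
    stop("lineage_tree() needs at least two distinct junctions", call. = FALSE)
  labels <- sprintf("m%03d", seq_along(seqs))
  all_seq <- c(setNames(seqs, labels), germline = outgroup$sequence)
  d <- hamming_matrix(all_seq)
  if (length(seqs) == 2) {
    depths <- .three_taxon_depths(d["m001", "germline"], d["m002", "germline"],
                                  d["m001", "m002"])
    x <- (d["m001", "germline"] + d["m002", "germline"] -
            d["m001", "m002"]) / 2
    tr <- ape::read.tree(text = sprintf(
      "(germline:%.10f,(m001:%.10f,m002:%.10f):0.0):0.0;",
      max(x, 0), depths[1], depths[2]))
    dist_root <- setNames(depths, c("m001", "m002"))
  } else {
    tr <- ape::nj(stats::as.dist(d))
    tr$edge.length <- pmax(tr$edge.length, 0)
    tr <- ape::root(tr, outgroup = "germline", resolve.root = TRUE)
    depth <- ape::node.depth.edgelength(tr)
    tips <- setdiff(tr$tip.label, "germline")
    dist_root <- setNames(depth[match(tips, tr$tip.label)], tips)
  }
  mem <- members[!duplicated(members$cdr3_nt), , drop = FALSE]
  mem <- mem[match(seqs, mem$cdr3_nt), , drop = FALSE]
  mem$tip <- labels
  # round away float dust so that genuinely equal depths tie in the ranks
  mem$dist_to_root <- round(unname(dist_root[labels]), 10)
  mem$rank <- rank(mem$dist_to_root, ties.method = "average")
  structure(list(tree = tr, members = mem, outgroup = outgroup$sequence),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> ", nrow(x$members), " members, outgroup-rooted\n",
      sep = "")
  invisible(x)
}

#' Build rooted trees for all sufficiently large lineages
#'
#' @param lineages Output of [build_lineages()].
#' @param germline_db Reference from [germline_reference()].
#' @param min_size Minimum lineage size (distinct junctions) for phylogeny
#'   (default 5).
#' @return Named list of `lineage_tree` objects (one per qualifying
#'   lineage); lineages whose genes are absent from the reference are
#'   skipped with a warning.
#' @export
build_trees <- function(lineages, germline_db = germline_reference(),
                        min_size = 5) {
  stopifnot(min_size >= 2)
  sizes <- lineage_summary(lineages)
  keep <- sizes$lineage_id[sizes$size >= min_size]
  out <- list()
  for (lid in keep) {
    mem <- lineages[lineages$lineage_id == lid, , drop = FALSE]
    og <- tryCatch(
      build_outgroup(mem$cdr3_nt, mem$v_gene[1], mem$j_gene[1], germline_db),
      error = function(e) NULL)
    if (is.null(og)) {
      warning("skipping lineage ", lid, ": genes absent from germline reference",
              call. = FALSE)
      next
    }
    out[[lid]] <- lineage_tree(mem, og)
  }
  out
}

#' Hypermutation counts relative to the germline outgroup
#'
#' Number of substitutions of each clonotype's junction relative to its
#' lineage's germline outgroup, counted over positions with germline
#' coverage (the masked D/N region is excluded). When the input already
#' carries a `germline_mutations` column (e.g. from upstream V-region
#' alignment), those values are used verbatim for non-missing entries.
#'
#' @param lineages Output of [build_lineages()].
#' @param germline_db Reference from [germline_reference()].
#' @return `lineages` plus an `n_mutations` column (`NA` where no outgroup
#'   could be built).
#' @export
mutation_counts <- function(lineages, germline_db = germline_reference()) {
  lineages$n_mutations <- NA_real_
  for (lid in unique(lineages$lineage_id)) {
    idx <- which(lineages$lineage_id == lid)
    og <- tryCatch(
      build_outgroup(lineages$cdr3_nt[idx], lineages$v_gene[idx[1]],
                     lineages$j_gene[idx[1]], germline_db),
      error = function(e) NULL)
    if (is.null(og)) next
    ref <- strsplit(og$sequence, "")[[1]]
    covered <- ref != "N"
    lineages$n_mutations[idx] <- vapply(lineages$cdr3_nt[idx], function(s) {
      sv <- strsplit(s, "")[[1]]
      sum(sv[covered] != ref[covered])
    }, numeric(1))
  }
  if ("germline_mutations" %in% names(lineages)) {
    use <- !is.na(lineages$germline_mutations)
    lineages$n_mutations[use] <- lineages$germline_mutations[use]
  }
  lineages
}

#' Average distance-to-root ranks per clonotype
#'
#' Within each lineage tree, members are ranked by distance to the root
#' (average rank for ties); a clonotype appearing in several lineages gets
#' the mean of its ranks. Clonotypes are keyed by CDR-H3 amino-acid
#' sequence, V gene and J gene so that rank tables from independently
#' sequenced libraries (e.g. short and long reads) can be matched.
#'
#' @param trees List of `lineage_tree` objects from [build_trees()].
#' @return Tibble with `cdr3_aa`, `v_gene`, `j_gene`, `avg_rank`,
#'   `avg_dist_to_root`, `n_lineages`.
#' @export
rank_by_root_distance <- function(trees) {
  rows <- dplyr::bind_rows(lapply(trees, function(tr) {
    m <- tr$members
    if (!"cdr3_aa" %in% names(m) || all(is.na(m$cdr3_aa)))
      m$cdr3_aa <- translate_nt(m$cdr3_nt)
    m[, intersect(c("cdr3_aa", "v_gene", "j_gene", "dist_to_root", "rank"),
                  names(m))]
  }))
  rows |>
    dplyr::group_by(.data$cdr3_aa, .data$v_gene, .data$j_gene) |>
    dplyr::summarise(avg_rank = mean(.data$rank),
                     avg_dist_to_root = mean(.data$dist_to_root),
                     n_lineages = dplyr::n(), .groups = "drop")
}

#' Compare rank tables from two tree sets
#'
#' Pearson correlation of average distance-to-root ranks over clonotypes
#' present in both tree sets (matched on CDR-H3 amino-acid sequence, V and
#' J gene).
#'
#' @param ranks_a,ranks_b Rank tables from [rank_by_root_distance()].
#' @return List with `r`, `p` and `n_matched`.
#' @export
compare_tree_sets <- function(ranks_a, ranks_b) {
  m <- dplyr::inner_join(ranks_a, ranks_b,
                         by = c("cdr3_aa", "v_gene", "j_gene"),
                         suffix = c("_a", "_b"))
  if (nrow(m) < 3) return(list(r = NA_real_, p = NA_real_, n_matched = nrow(m)))
  ct <- cor.test(m$avg_rank_a, m$avg_rank_b)
  list(r = unname(ct$estimate), p = ct$p.value, n_matched = nrow(m))
}

## ---- Nei-Gojobori dN/dS -------------------------------------------------

.codon_aa <- function(codon) GENETIC_CODE_TABLE[[codon]]

# fraction of the three possible changes at each codon position that are
# synonymous; stop codons act as a distinct residue state
.syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa0 <- .codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (.codon_aa(alt) == aa0) s <- s + 1 / 3
    }
  }
  s
}

# synonymous/nonsynonymous substitution counts between two codons, averaged
# over all orderings of the differing positions (Nei-Gojobori pathway rule)
.count_subs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1) list(pos) else {
    if (nd == 2) list(pos, rev(pos)) else {
      idx <- expand.grid(1:3, 1:3, 1:3)
      idx <- idx[apply(idx, 1, function(r) length(unique(r)) == 3), ]
      lapply(seq_len(nrow(idx)), function(i) pos[unlist(idx[i, ])])
    }
  }
  tot <- c(syn = 0, nonsyn = 0)
  for (path in perms) {
    cur <- c1
    for (p in path) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (.codon_aa(nxt) == .codon_aa(cur)) tot["syn"] <- tot["syn"] + 1
      else tot["nonsyn"] <- tot["nonsyn"] + 1
      cur <- nxt
    }
  }
  tot / length(perms)
}

#' Pooled Nei-Gojobori dN/dS of a lineage against its MRCA
#'
#' Counts synonymous and nonsynonymous sites in the MRCA (outgroup)
#' sequence and substitutions of every member against it, pooled over the
#' lineage: `dN/dS = (Nd/N) / (Sd/S)`. Codons containing masked (`N`)
#' positions on either side are skipped; incomplete trailing codons are
#' trimmed. No pseudocounts: with zero synonymous substitutions the ratio is
#' undefined and flagged.
#'
#' @param junctions Member junction sequences (equal length, in frame).
#' @param mrca MRCA/outgroup nucleotide sequence (may contain `N` masking).
#' @return List with `dnds`, `pn`, `ps`, `Nd`, `Sd`, `N`, `S`,
#'   `n_codons_used` and `defined`.
#' @export
dnds <- function(junctions, mrca) {
  ref_codons <- split_codons(mrca)
  usable <- which(!grepl("N", ref_codons, fixed = TRUE))
  Nd <- Sd <- Ns <- Ss <- 0
  n_used <- 0
  for (seq in junctions) {
    cod <- split_codons(seq)
    for (i in usable) {
      if (i > length(cod) || grepl("N", cod[i], fixed = TRUE)) next
      s_sites <- .syn_sites(ref_codons[i])
      Ss <- Ss + s_sites
      Ns <- Ns + (3 - s_sites)
      subs <- .count_subs(ref_codons[i], cod[i])
      Sd <- Sd + subs[["syn"]]
      Nd <- Nd + subs[["nonsyn"]]
      n_used <- n_used + 1
    }
  }
  pn <- if (Ns > 0) Nd / Ns else NA_real_
  ps <- if (Ss > 0) Sd / Ss else NA_real_
  defined <- !is.na(ps) && ps > 0 && !is.na(pn)
  list(dnds = if (defined) pn / ps else NA_real_,
       pn = pn, ps = ps, Nd = Nd, Sd = Sd, N = Ns, S = Ss,
       n_codons_used = n_used, defined = defined)
}

#' dN/dS for every sufficiently large lineage
#'
#' @param lineages Output of [build_lineages()].
#' @param germline_db Reference from [germline_reference()].
#' @param min_size Minimum lineage size (default 5).
#' @return Tibble with `lineage_id`, `size`, `dnds`, `Nd`, `Sd`, `defined`.
#' @export
lineage_dnds <- function(lineages, germline_db = germline_reference(),
                         min_size = 5) {
  sizes <- lineage_summary(lineages)
  keep <- sizes$lineage_id[sizes$size >= min_size]
  rows <- lapply(keep, function(lid) {
    mem <- lineages[lineages$lineage_id == lid, , drop = FALSE]
    og <- tryCatch(
      build_outgroup(mem$cdr3_nt, mem$v_gene[1], mem$j_gene[1], germline_db),
      error = function(e) NULL)
    if (is.null(og)) return(NULL)
    res <- dnds(unique(mem$cdr3_nt), og$sequence)
    tibble::tibble(lineage_id = lid,
                   size = length(unique(mem$cdr3_nt)),
                   dnds = res$dnds, Nd = res$Nd, Sd = res$Sd,
                   defined = res$defined)
  })
  dplyr::bind_rows(rows)
}
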