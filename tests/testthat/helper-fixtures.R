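# Shared fixture builders and independent brute-force oracles.

# quick repertoire: counts named by cdr3_nt (v/j constant unless given)
make_rep <- function(counts, v_gene = "IGHV9-1*01", j_gene = "IGHJ9-1*01",
                     isotype = "other", sample_id = "s1", ...) {
  bcr_repertoire(tibble::tibble(
    cdr3_nt = names(counts), v_gene = v_gene, j_gene = j_gene,
    isotype = isotype, umi_count = unname(counts), sample_id = sample_id, ...))
}

rand_nt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# independent brute-force F2: explicit double loop over clonotype keys
oracle_f2 <- function(rep_a, rep_b) {
  ca <- rep_a$clonotypes; cb <- rep_b$clonotypes
  fa <- ca$frequency / sum(ca$frequency)
  fb <- cb$frequency / sum(cb$frequency)
  ka <- paste(ca$cdr3_nt, ca$v_gene, ca$j_gene)
  kb <- paste(cb$cdr3_nt, cb$v_gene, cb$j_gene)
  total <- 0
  for (i in seq_along(ka)) for (j in seq_along(kb)) {
    if (ka[i] == kb[j]) total <- total + sqrt(fa[i] * fb[j])
  }
  total
}

# independent connected-components oracle: direct pairwise distances plus
# repeated merging of linked groups (no BFS, no hclust)
oracle_components <- function(seqs, threshold) {
  n <- length(seqs)
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    linked[i, j] <- linked[j, i] <- mean(chars[[i]] != chars[[j]]) <= threshold
  }
  groups <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (g1 in seq_along(groups)) {
      if (merged) break
      for (g2 in seq_along(groups)) {
        if (g2 <= g1) next
        if (any(linked[groups[[g1]], groups[[g2]]])) {
          groups[[g1]] <- c(groups[[g1]], groups[[g2]])
          groups[[g2]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  comp <- integer(n)
  for (g in seq_along(groups)) comp[groups[[g]]] <- g
  comp
}

# canonical form of a partition for comparison
canonical_partition <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

# pairwise decontamination oracle: a record dies if any pairwise comparison
# kills it (rule text applied verbatim to every sample pair)
oracle_decontam_kept <- function(reads_by_sample, ratio = 5) {
  ids <- names(reads_by_sample)
  dead <- setNames(rep(FALSE, length(ids)), ids)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    ri <- reads_by_sample[[i]]; rj <- reads_by_sample[[j]]
    if (ri > ratio * rj) {
      dead[j] <- TRUE
    } else if (rj > ratio * ri) {
      dead[i] <- TRUE
    } else {
      dead[i] <- TRUE; dead[j] <- TRUE
    }
  }
  ids[!dead]
}
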