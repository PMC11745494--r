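# Synthetic multi-patient, multi-tissue repertoire generator.
#
# Emulates the study design the analyses assume: per patient, tumor tissue
# in three fragments plus draining lymph node and PBMC compartments, each
# fragment homogenized and split into two cellular replicates. Clones carry
# lineage structure (mutation trees over junctions), tissue sharing,
# per-tissue isotype mixtures, log-normal expression overdispersion
# (emulating plasma-cell dominance), planted expansions and planted
# cross-sample UMI contamination, with a ground-truth ledger for every
# planted feature.

#' Simulation configuration
#'
#' Defaults follow the emulated sampling design (three tumor fragments plus
#' LN and PBMC compartments, two cellular replicates per fragment) at desk
#' scale.
#'
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @param n_patients Number of patients.
#' @param tissues Compartment labels.
#' @param fragments Named integer vector: fragments per tissue.
#' @param replicates Cellular replicates per fragment (default 2).
#' @param n_naive_clones Naive (founder) clones per patient.
#' @param umis_per_sample UMIs drawn per replicate sample.
#' @param lineage_rate Fraction of founder clones seeding a clonal lineage.
#' @param lineage_size_mean Mean extra members per lineage (Poisson).
#' @param shm_rate Per-site substitution rate per tree edge; edge mutation
#'   counts are Poisson(`shm_rate * junction_length`), minimum 1.
#' @param sharing Named vector of pairwise tissue-sharing probabilities
#'   (`"tum-LN"` etc.): probability that a clone resident in one tissue of
#'   the pair is also present in the other.
#' @param isotype_probs Named list per tissue of IgM/IgG/IgA probabilities.
#' @param expr_sigma Log-normal sigma of per-clone expression weights
#'   (plasma-cell overdispersion).
#' @param fragment_sigma Log-normal sigma of per-fragment weight jitter
#'   (spatial heterogeneity; shared by a fragment's replicates).
#' @param cdr3_len_range Junction length bounds in nt (rounded to codons).
#' @param expansions List `list(n=, fold=, tissue=)` of planted expansions.
#' @param contamination_rate Fraction of UMI records copied into another
#'   sample as planted contamination.
#' @param umi_read_mu,umi_read_size Negative-binomial read-count model per
#'   UMI (reads = 1 + NB(mu, size)).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_patients = 2,
                       tissues = c("tum", "LN", "PBMC"),
                       fragments = c(tum = 3, LN = 1, PBMC = 1),
                       replicates = 2,
                       n_naive_clones = 400,
                       umis_per_sample = 3000,
                       lineage_rate = 0.15,
                       lineage_size_mean = 4,
                       shm_rate = 0.02,
                       sharing = c("tum-LN" = 0.30, "tum-PBMC" = 0.05,
                                   "LN-PBMC" = 0.10),
                       isotype_probs = list(
                         tum = c(IgM = 0.20, IgG = 0.45, IgA = 0.35),
                         LN = c(IgM = 0.35, IgG = 0.35, IgA = 0.30),
                         PBMC = c(IgM = 0.25, IgG = 0.30, IgA = 0.45)),
                       expr_sigma = 1.5,
                       fragment_sigma = 1.0,
                       cdr3_len_range = c(30, 60),
                       expansions = list(n = 0, fold = 8, tissue = "tum"),
                       contamination_rate = 0,
                       umi_read_mu = 5, umi_read_size = 2) {
  stopifnot(replicates >= 1, n_naive_clones >= 1,
            all(sharing >= 0 & sharing <= 1),
            contamination_rate >= 0, contamination_rate < 1,
            all(tissues %in% names(fragments)),
            all(tissues %in% names(isotype_probs)))
  if (!is.null(expansions$n) && expansions$n > n_naive_clones)
    stop("more planted expansions than clones", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

.sharing_prob <- function(sharing, t1, t2) {
  keys <- c(paste(sort(c(t1, t2)), collapse = "-"),
            paste(t1, t2, sep = "-"), paste(t2, t1, sep = "-"))
  for (k in keys) {
    i <- match(k, names(sharing))
    if (!is.na(i)) return(unname(sharing[i]))
  }
  0
}

# stop-free random codons for junction middles
.nonstop_codons <- function() {
  names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
}

.random_middle <- function(n_codons) {
  if (n_codons <= 0) return("")
  paste(sample(.nonstop_codons(), n_codons, replace = TRUE), collapse = "")
}

# point-mutate a junction without creating stop codons
.mutate_junction <- function(seq, n_mut) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(seq, "")[[1]]
  for (k in seq_len(n_mut)) {
    repeat {
      pos <- sample(length(v), 1)
      new <- sample(setdiff(bases, v[pos]), 1)
      cand <- v
      cand[pos] <- new
      codon_i <- (pos - 1) %/% 3
      codon <- paste(cand[(codon_i * 3 + 1):(codon_i * 3 + 3)], collapse = "")
      if (GENETIC_CODE_TABLE[[codon]] != "*") {
        v <- cand
        break
      }
    }
  }
  paste(v, collapse = "")
}

#' Simulate multi-tissue BCR repertoires
#'
#' Generates, per patient, founder clones with junctions built as germline
#' V-end, random stop-free N-insertions and germline J-start; grows clonal
#' lineages as mutation trees (each new member mutates off a random
#' existing member with a Poisson number of substitutions); assigns tissue
#' presence from the pairwise sharing matrix, per-tissue isotypes, and
#' log-normal expression weights; plants expansions and UMI contamination;
#' and samples every replicate multinomially over the present clones'
#' weights.
#'
#' @param config A [sim_config()].
#' @param germline_db Germline reference from [germline_reference()].
#' @param emit_umi Also generate the UMI-level table (slower; needed for
#'   decontamination analyses).
#' @return List with `airr` (clonotype tibble over all samples, AIRR
#'   dialect), `umi` (UMI-level tibble or `NULL`), `truth` (ledger: clone
#'   table with lineage membership, true mutation counts, tissue presence
#'   and expansion status; contamination log), and `config`.
#' @export
simulate_repertoires <- function(config = sim_config(),
                                 germline_db = germline_reference(),
                                 emit_umi = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vg <- germline_db[germline_db$segment == "V", ]
  jg <- germline_db[germline_db$segment == "J", ]
  lens <- seq(config$cdr3_len_range[1], config$cdr3_len_range[2], by = 3)

  airr_rows <- list(); umi_rows <- list(); truth_rows <- list()
  contam_rows <- list()

  for (pat in seq_len(config$n_patients)) {
    patient_id <- sprintf("p%02d", pat)
    n0 <- config$n_naive_clones
    vi <- sample.int(nrow(vg), n0, replace = TRUE)
    ji <- sample.int(nrow(jg), n0, replace = TRUE)
    len <- lens[sample.int(length(lens), n0, replace = TRUE)]
    v_tail <- substr(vg$sequence[vi],
                     nchar(vg$sequence[vi]) - vg$junction_offset[vi] + 1L,
                     nchar(vg$sequence[vi]))
    j_head <- substr(jg$sequence[ji], 1L, jg$junction_offset[ji])
    junction <- vapply(seq_len(n0), function(i) {
      mid <- (len[i] - nchar(v_tail[i]) - nchar(j_head[i])) %/% 3L
      paste0(v_tail[i], .random_middle(mid), j_head[i])
    }, character(1))

    clones <- tibble::tibble(
      clone_id = sprintf("%s_c%05d", patient_id, seq_len(n0)),
      junction = junction, v_gene = vg$gene[vi], j_gene = jg$gene[ji],
      lineage_seed = NA_character_, true_mutations = 0L,
      edge_mutations = 0L)

    # grow lineages as mutation trees off a subset of founders
    seed_idx <- which(runif(n0) < config$lineage_rate)
    for (s in seed_idx) {
      n_extra <- rpois(1, config$lineage_size_mean)
      if (n_extra == 0) next
      fam <- clones[s, ]
      fam$lineage_seed <- fam$clone_id
      members <- fam
      for (k in seq_len(n_extra)) {
        parent <- members[sample(nrow(members), 1), ]
        n_mut <- max(1L, rpois(1, config$shm_rate * nchar(parent$junction)))
        child <- parent
        child$clone_id <- sprintf("%s_m%02d", fam$clone_id, k)
        child$junction <- .mutate_junction(parent$junction, n_mut)
        child$true_mutations <- parent$true_mutations + n_mut
        child$edge_mutations <- n_mut
        members <- dplyr::bind_rows(members, child)
      }
      clones$lineage_seed[s] <- fam$clone_id
      clones <- dplyr::bind_rows(clones, members[-1, ])
    }
    nc <- nrow(clones)

    # tissue presence: home tissue uniform, then pairwise sharing
    home <- sample(config$tissues, nc, replace = TRUE)
    presence <- matrix(FALSE, nc, length(config$tissues),
                       dimnames = list(NULL, config$tissues))
    presence[cbind(seq_len(nc), match(home, config$tissues))] <- TRUE
    for (tis in config$tissues) {
      other <- home != tis
      pr <- vapply(home[other], function(h)
        .sharing_prob(config$sharing, h, tis), numeric(1))
      presence[which(other)[runif(sum(other)) < pr], tis] <- TRUE
    }

    # per-tissue isotype; expression weights; planted expansions
    isotype <- matrix(NA_character_, nc, length(config$tissues),
                      dimnames = list(NULL, config$tissues))
    for (tis in config$tissues) {
      isotype[, tis] <- sample(names(config$isotype_probs[[tis]]), nc,
                               replace = TRUE,
                               prob = config$isotype_probs[[tis]])
    }
    weight <- rlnorm(nc, 0, config$expr_sigma)
    expanded <- rep(FALSE, nc)
    if (config$expansions$n > 0) {
      exp_target <- config$expansions$tissue
      candidates <- which(presence[, exp_target])
      picked <- sample(candidates, min(config$expansions$n, length(candidates)))
      expanded[picked] <- TRUE
    }

    truth_rows[[pat]] <- tibble::tibble(
      patient_id = patient_id, clone_id = clones$clone_id,
      junction = clones$junction, v_gene = clones$v_gene,
      j_gene = clones$j_gene, lineage_seed = clones$lineage_seed,
      true_mutations = clones$true_mutations,
      edge_mutations = clones$edge_mutations,
      tissues = apply(presence, 1, function(r)
        paste(config$tissues[r], collapse = ",")),
      weight = weight, expanded = expanded)

    # sample every replicate
    for (tis in config$tissues) {
      present <- which(presence[, tis])
      if (length(present) == 0) next
      for (fr in seq_len(config$fragments[[tis]])) {
        frag_jitter <- rlnorm(length(present), 0, config$fragment_sigma)
        w <- weight[present] * frag_jitter
        if (tis == config$expansions$tissue)
          w <- w * ifelse(expanded[present], config$expansions$fold, 1)
        for (rep_i in seq_len(config$replicates)) {
          sample_id <- sprintf("%s_%s%d_r%d", patient_id, tis, fr, rep_i)
          counts <- as.vector(rmultinom(1, config$umis_per_sample,
                                        w / sum(w)))
          hit <- which(counts > 0)
          idx <- present[hit]
          airr_rows[[length(airr_rows) + 1L]] <- tibble::tibble(
            sequence_id = clones$clone_id[idx],
            junction = clones$junction[idx],
            junction_aa = translate_nt(clones$junction[idx]),
            v_call = clones$v_gene[idx], j_call = clones$j_gene[idx],
            c_call = c(IgM = "IGHM", IgG = "IGHG1",
                       IgA = "IGHA1")[isotype[idx, tis]],
            duplicate_count = counts[hit],
            sample_id = sample_id, patient_id = patient_id, tissue = tis,
            fragment_id = paste0(tis, fr), replicate_id = paste0("r", rep_i))
          if (emit_umi) {
            n_umi <- sum(counts[hit])
            umi_rows[[length(umi_rows) + 1L]] <- tibble::tibble(
              sample_id = sample_id,
              umi = vapply(seq_len(n_umi), function(i) random_nt(12),
                           character(1)),
              sequence = base::rep(clones$junction[idx], counts[hit]),
              reads = 1 + rnbinom(n_umi, mu = config$umi_read_mu,
                                  size = config$umi_read_size))
          }
        }
      }
    }
  }

  airr <- dplyr::bind_rows(airr_rows)
  umi <- if (emit_umi) dplyr::bind_rows(umi_rows) else NULL

  # planted cross-sample contamination: copy UMI records into other samples
  if (emit_umi && config$contamination_rate > 0 && nrow(umi) > 0) {
    n_cont <- round(config$contamination_rate * nrow(umi))
    if (n_cont > 0) {
      donors <- sample.int(nrow(umi), n_cont)
      samples <- unique(umi$sample_id)
      recipients <- vapply(umi$sample_id[donors], function(s)
        sample(setdiff(samples, s), 1), character(1))
      donor_umi <- umi$umi[donors]
      donor_seq <- umi$sequence[donors]
      donor_reads <- umi$reads[donors]
      cont <- tibble::tibble(
        sample_id = recipients,
        umi = donor_umi,
        sequence = donor_seq,
        reads = pmax(1, round(donor_reads / runif(n_cont, 6, 15))))
      contam_rows[[1]] <- dplyr::bind_cols(
        cont, donor_sample = umi$sample_id[donors],
        donor_reads = donor_reads)
      umi <- dplyr::bind_rows(umi, cont)
    }
  }

  list(airr = airr, umi = umi,
       truth = list(
         clones = dplyr::bind_rows(truth_rows),
         contamination = if (length(contam_rows))
           contam_rows[[1]] else NULL),
       config = config)
}

#' Split a simulated AIRR table into per-sample repertoires
#'
#' @param airr AIRR-dialect clonotype tibble (e.g. `simulate_repertoires()$airr`).
#' @return Named list of [bcr_repertoire] objects, one per `sample_id`.
#' @export
repertoires_from_airr <- function(airr) {
  out <- lapply(split(airr, airr$sample_id), function(tbl) {
    cl <- tibble::tibble(
      cdr3_nt = tbl$junction, cdr3_aa = tbl$junction_aa,
      v_gene = tbl$v_call, j_gene = tbl$j_call,
      isotype = parse_isotype(tbl$c_call), umi_count = tbl$duplicate_count,
      sample_id = tbl$sample_id, patient_id = tbl$patient_id,
      tissue = tbl$tissue, fragment_id = tbl$fragment_id,
      replicate_id = tbl$replicate_id)
    bcr_repertoire(merge_clonotype_records(cl))
  })
  out
}

#' Hand-checkable worked fixtures
#'
#' The small toys used across module examples, built in code: the
#' two-clonotype F2 toy (shared clonotype at frequencies 0.5 and 0.2), the
#' (6, 3, 1) triangle group, and the 12-versus-2-read UMI collision.
#'
#' @param dir Optional directory; when given, each fixture is also written
#'   as a TSV there.
#' @return Named list of tibbles: `f2_a`, `f2_b`, `triangle`, `umi`.
#' @export
worked_fixtures <- function(dir = NULL) {
  f2_a <- tibble::tibble(
    cdr3_nt = c("TGTGCGAGATGG", "TGTAAAAGATGG"),
    v_gene = "IGHV9-1*01", j_gene = "IGHJ9-1*01", umi_count = c(5, 5))
  f2_b <- tibble::tibble(
    cdr3_nt = c("TGTGCGAGATGG", "TGTCCCAGATGG"),
    v_gene = "IGHV9-1*01", j_gene = "IGHJ9-1*01", umi_count = c(2, 8))
  triangle <- tibble::tibble(
    lineage_id = "G1",
    compartment = base::rep(c("tum", "LN", "PBMC"), c(6, 3, 1)),
    isotype = "IgG")
  umi <- tibble::tibble(
    sample_id = c("s1", "s2"), umi = "ACGTACGTACGT",
    sequence = "TGTGCGAGATGG", reads = c(12, 2))
  out <- list(f2_a = f2_a, f2_b = f2_b, triangle = triangle, umi = umi)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      readr::write_tsv(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       progress = FALSE)
    }
  }
  out
}
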