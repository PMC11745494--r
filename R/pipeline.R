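# End-to-end pipeline: decontamination -> filtering -> pooling ->
# overlap/diversity/physicochemistry -> lineages -> triangle -> expansion,
# from a single declarative configuration, with a run manifest.

.default_run_config <- function() {
  list(
    seed = 1,
    simulate = list(),          # sim_config() overrides; NULL to read inputs
    inputs = NULL,              # character vector of AIRR TSV paths
    umi_inputs = NULL,          # optional UMI-table TSV paths
    decontam = list(ratio = 5, seq_similarity_min = 0.9),
    filters = list(min_umi_per_clonotype = 2, min_clonotypes = 50),
    pool_by = c("patient_id", "tissue"),
    overlap = list(metrics = c("f2", "d", "r"), top_n = 109,
                   by_isotype = FALSE),
    physchem = list(top_n = 100, window = 5),
    lineage = list(threshold = "auto", min_tree_size = 5),
    triangle = list(compartments = c("tum", "LN", "PBMC"),
                    dominant_cutoff = 0.6, normalize_isotypes = FALSE),
    expansion = list(group_a = "tum", group_b = "LN", alpha_fdr = 0.05,
                     dispersion = "auto"),
    out_dir = "tribcr_run")
}

#' Load a pipeline run configuration
#'
#' @param config A named list of overrides, or a path to a YAML file with
#'   the same structure. Unset fields take package defaults; every
#'   analysis constant (top-N 109, top-100 profiling, 0.6 dominance
#'   cutoff, decontamination ratio 5, FDR 0.05) is a named parameter.
#' @return Validated configuration list.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  out <- utils::modifyList(.default_run_config(), config)
  if (!is.null(out$inputs)) {
    missing_in <- out$inputs[!file.exists(out$inputs)]
    if (length(missing_in))
      stop("input file(s) not found: ", paste(missing_in, collapse = ", "),
           call. = FALSE)
  }
  out
}

.write_stage <- function(tbl, out_dir, name, manifest) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  readr::write_tsv(tbl, path, progress = FALSE)
  manifest$outputs[[name]] <- list(path = path,
                                   md5 = unname(tools::md5sum(path)),
                                   rows = nrow(tbl))
  manifest
}

#' Run the full repertoire analysis pipeline
#'
#' Stages: (1) load or simulate per-sample repertoires; (2) cross-sample
#' UMI decontamination when UMI tables are available; (3) UMI/sample
#' filtering; (4) pooling of replicates and fragments by mean frequency;
#' (5) pairwise overlap metrics; (6) diversity and isotype summaries;
#' (7) CDR-H3 physicochemical profiles; (8) clonal lineages per patient
#' (singletons retained) with trees, mutation counts and dN/dS; (9)
#' triangle tissue-distribution statistics; (10) expanded-clonotype
#' detection between two tissue groups. Stage outputs are written as TSV
#' plus a JSON manifest recording parameters and output checksums; rerun
#' with the same configuration is byte-identical.
#'
#' @param config See [run_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest (named list), invisibly.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- run_config(config)
  say <- function(...) if (!quiet) message("[tribcr] ", ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("tribcr")),
                   parameters = cfg[setdiff(names(cfg), "out_dir")],
                   outputs = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- stage 1: inputs ------------------------------------------------------
  say("stage: inputs")
  sim <- NULL
  if (is.null(cfg$inputs)) {
    sim <- stage("simulate", {
      sc <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                  as.list(cfg$simulate)))
      simulate_repertoires(sc, emit_umi = TRUE)
    })
    airr <- sim$airr
    umi <- sim$umi
  } else {
    airr <- NULL
    reps <- stage("read", lapply(cfg$inputs, read_airr))
    names(reps) <- vapply(seq_along(reps), function(i)
      reps[[i]]$metadata$sample_id %||% basename(cfg$inputs[i]), character(1))
    umi <- if (!is.null(cfg$umi_inputs))
      dplyr::bind_rows(lapply(cfg$umi_inputs, read_umi_table)) else NULL
  }

  # -- stage 2: decontamination --------------------------------------------
  if (!is.null(umi)) {
    say("stage: decontamination")
    dec <- stage("decontam", decontaminate(
      umi, ratio = cfg$decontam$ratio,
      seq_similarity_min = cfg$decontam$seq_similarity_min))
    manifest <- .write_stage(dec$removals, cfg$out_dir, "decontam_removals",
                             manifest)
    if (!is.null(airr))
      airr <- stage("decontam_apply", apply_decontam_to_airr(airr, dec$removals))
  }
  if (!is.null(airr)) reps <- stage("split", repertoires_from_airr(airr))

  # -- stage 3: filtering ---------------------------------------------------
  say("stage: filtering")
  reps <- stage("filter", lapply(reps, apply_filters,
                                 min_umi_per_clonotype = cfg$filters$min_umi_per_clonotype,
                                 min_clonotypes = cfg$filters$min_clonotypes))
  excluded <- names(reps)[vapply(reps, is_excluded, logical(1))]
  if (length(excluded)) say("excluded samples: ", paste(excluded, collapse = ", "))
  reps_ok <- reps[!names(reps) %in% excluded]
  if (length(reps_ok) == 0) stop("pipeline stage 'filter' failed: no samples survive",
                                 call. = FALSE)

  # -- stage 4: pooling -----------------------------------------------------
  say("stage: pooling by ", paste(cfg$pool_by, collapse = " + "))
  pool_key <- vapply(reps_ok, function(r)
    paste(unlist(r$metadata[cfg$pool_by]), collapse = "_"), character(1))
  pooled <- stage("pool", lapply(split(reps_ok, pool_key), pool_repertoires))

  # -- stage 5: overlap -----------------------------------------------------
  say("stage: overlap")
  if (length(pooled) >= 2) {
    ov <- stage("overlap", pairwise_overlap(
      pooled, metrics = cfg$overlap$metrics, top_n = cfg$overlap$top_n,
      by_isotype = isTRUE(cfg$overlap$by_isotype)))
    manifest <- .write_stage(ov, cfg$out_dir, "overlap", manifest)
  }

  # -- stage 6: diversity ---------------------------------------------------
  say("stage: diversity")
  dv <- stage("diversity",
              dplyr::bind_rows(lapply(pooled, diversity_summary)))
  manifest <- .write_stage(dv, cfg$out_dir, "diversity", manifest)

  # -- stage 7: physicochemistry -------------------------------------------
  say("stage: physchem")
  pc <- stage("physchem", dplyr::bind_rows(lapply(
    pooled, physchem_profile, top_n = cfg$physchem$top_n,
    window = cfg$physchem$window)))
  pc$sample_id <- names(pooled)
  manifest <- .write_stage(pc, cfg$out_dir, "physchem", manifest)

  # -- stage 8: lineages (per patient, singletons kept) --------------------
  say("stage: lineages")
  reps_lin <- stage("filter_lineage", lapply(reps, apply_filters,
                                             keep_singletons = TRUE,
                                             min_clonotypes = 0))
  pat_key <- vapply(reps_lin, function(r)
    r$metadata$patient_id %||% "all", character(1))
  lineage_out <- list(); dnds_out <- list()
  for (pat in unique(pat_key)) {
    pat_pool <- stage("pool_lineage",
                      pool_repertoires(reps_lin[pat_key == pat]))
    cl <- pat_pool$clonotypes
    cl$patient_id <- pat
    lin <- stage("lineages", build_lineages(cl, threshold = cfg$lineage$threshold))
    lin <- stage("mutations", mutation_counts(lin))
    lineage_out[[pat]] <- lin
    dn <- stage("dnds", lineage_dnds(lin, min_size = cfg$lineage$min_tree_size))
    if (nrow(dn)) { dn$patient_id <- pat; dnds_out[[pat]] <- dn }
  }
  lineages <- dplyr::bind_rows(lineage_out)
  manifest <- .write_stage(lineages, cfg$out_dir, "lineages", manifest)
  if (length(dnds_out))
    manifest <- .write_stage(dplyr::bind_rows(dnds_out), cfg$out_dir, "dnds",
                             manifest)

  # -- stage 9: triangle ----------------------------------------------------
  say("stage: triangle")
  # occurrence-level membership: one row per clonotype per tissue of origin
  occ <- dplyr::bind_rows(lapply(reps_ok, function(r) {
    cl <- r$clonotypes
    tibble::tibble(cdr3_nt = cl$cdr3_nt, v_gene = cl$v_gene,
                   j_gene = cl$j_gene, isotype = cl$isotype,
                   frequency = cl$frequency,
                   patient_id = r$metadata$patient_id %||% "all",
                   compartment = r$metadata$tissue %||% NA_character_)
  }))
  occ <- dplyr::distinct(occ, .data$cdr3_nt, .data$v_gene, .data$j_gene,
                         .data$patient_id, .data$compartment,
                         .keep_all = TRUE)
  lin_key <- lineages[, c("cdr3_nt", "v_gene", "j_gene", "patient_id",
                          "lineage_id")]
  occ <- dplyr::inner_join(occ, lin_key,
                           by = c("cdr3_nt", "v_gene", "j_gene", "patient_id"))
  if (all(cfg$triangle$compartments %in% occ$compartment)) {
    tp <- stage("triangle", triangle_points(
      occ, compartments = cfg$triangle$compartments,
      normalize_isotypes = isTRUE(cfg$triangle$normalize_isotypes)))
    manifest <- .write_stage(tp, cfg$out_dir, "triangle", manifest)
    ct <- center_and_test(tp)
    manifest$triangle_center <- list(center = as.list(ct$center),
                                     chi2 = ct$chi2, p = ct$p)
  }

  # -- stage 10: expansion --------------------------------------------------
  say("stage: expansion")
  tiss <- vapply(reps_ok, function(r) r$metadata$tissue %||% NA_character_,
                 character(1))
  pats <- vapply(reps_ok, function(r) r$metadata$patient_id %||% "all",
                 character(1))
  exp_out <- list()
  for (pat in unique(pats)) {
    ga <- reps_ok[pats == pat & tiss == cfg$expansion$group_a]
    gb <- reps_ok[pats == pat & tiss == cfg$expansion$group_b]
    if (length(ga) == 0 || length(gb) == 0) next
    ex <- stage("expansion", test_expansion(
      ga, gb, alpha_fdr = cfg$expansion$alpha_fdr,
      dispersion = cfg$expansion$dispersion))
    ex$patient_id <- pat
    exp_out[[pat]] <- ex
  }
  if (length(exp_out)) {
    expansion <- dplyr::bind_rows(exp_out)
    manifest <- .write_stage(expansion, cfg$out_dir, "expansion", manifest)
    # hypermutation contrast of expanded vs non-expanded clonotypes
    mut <- dplyr::left_join(
      expansion,
      dplyr::distinct(lineages[, c("cdr3_nt", "v_gene", "j_gene",
                                   "patient_id", "n_mutations")]),
      by = c("cdr3_nt", "v_gene", "j_gene", "patient_id"))
    mc <- mutation_contrast(mut$n_mutations, mut$expanded)
    manifest$mutation_contrast <- mc
  }

  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("done: ", manifest_path)
  invisible(manifest)
}
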