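pipeline_defaults <- function() {
  list(
    paths = list(genotypes = NULL, phenotypes = NULL, panel = NULL,
                 replication_genotypes = NULL, out_dir = "."),
    simulate = list(enabled = TRUE, n_subjects = 441, n_snps_chd = 110,
                    n_snps_t2d = 83,
                    pattern_counts = c(61, 91, 97, 192),
                    maf_range = c(0.05, 0.45), missing_rate = 0.01,
                    # planted biclusters: disjoint blocks allocated left to right
                    # within each panel; shifts strong enough to survive the 5e-5
                    # per-SNP prescreen of a ~441-subject cohort
                    planted = list(
                      list(n_snps = 16, n_subjects = 45, dosage = 2,
                           shift = 2.5, target = "CHD"),
                      list(n_snps = 12, n_subjects = 40, dosage = 2,
                           shift = 2.5, target = "T2D"),
                      list(n_snps = 10, n_subjects = 35, dosage = 2,
                           shift = 2.5, target = "both"))),
    qc = list(snp_missing_max = 0.05, maf_min = 0.01, hwe_p_min = 1e-6,
              subject_missing_max = 0.05),
    # adjust_pcs: PCs computed from the analyzed panel itself proxy the planted
    # biclusters in a synthetic cohort (no true ancestry structure), so
    # adjusting for them absorbs the very signal under study; enable only when
    # the PCs come from genome-wide data
    gwas = list(p_thresh = 5e-5, n_pcs = 10, adjust_pcs = FALSE),
    nsnmf = list(theta = 0.5, k_min = 2, k_max = NULL, tau = 0.6,
                 mode = "factor_wise", max_iter = 2000, tol = 1e-6,
                 coding = "offset_dosage"),
    skat = list(weights = "flat", alpha = 0.05),
    architecture = list(jc_thresh = 0.8, alpha = 0.05),
    network = list(alpha = 0.05),
    replication = list(p_match = 1e-3),
    seed = 1L
  )
}

merge_config <- function(defaults, user, path = "") {
  errs <- character()
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(defaults)) { errs <- c(errs, paste0("unknown key: ", full)); next }
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      sub <- merge_config(defaults[[key]], as.list(user[[key]]), full)
      defaults[[key]] <- sub$config
      errs <- c(errs, sub$errors)
    } else defaults[[key]] <- user[[key]]
  }
  list(config = defaults, errors = errs)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (the reference thresholds: prescreen 5e-5, SNP missingness
#' 5%, MAF 1%, HWE 1e-6, extraction tau 0.6, redundancy 0.8, alpha 0.05),
#' checks ranges, and rejects unknown keys with an aggregated error message.
#'
#' @param config named list (e.g. parsed from a JSON file), possibly empty.
#' @return the normalized configuration, class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  mc <- merge_config(pipeline_defaults(), as.list(config))
  cfg <- mc$config
  errs <- mc$errors
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$nsnmf$k_min >= 2, "nsnmf$k_min must be >= 2")
  chk(is.null(cfg$nsnmf$k_max) || cfg$nsnmf$k_max >= cfg$nsnmf$k_min,
      "nsnmf$k_max must be >= k_min")
  chk(cfg$nsnmf$tau > 0 && cfg$nsnmf$tau <= 1, "nsnmf$tau must lie in (0, 1]")
  chk(cfg$nsnmf$theta >= 0 && cfg$nsnmf$theta <= 1, "nsnmf$theta must lie in [0, 1]")
  chk(cfg$qc$maf_min >= 0 && cfg$qc$maf_min < 0.5, "qc$maf_min out of range")
  chk(cfg$qc$snp_missing_max >= 0 && cfg$qc$snp_missing_max <= 1,
      "qc$snp_missing_max out of range")
  chk(cfg$gwas$p_thresh > 0 && cfg$gwas$p_thresh < 1, "gwas$p_thresh out of range")
  chk(cfg$architecture$jc_thresh >= 0 && cfg$architecture$jc_thresh <= 1,
      "architecture$jc_thresh out of range")
  for (a in c(cfg$skat$alpha, cfg$architecture$alpha, cfg$network$alpha))
    chk(a > 0 && a <= 1, "alpha values must lie in (0, 1]")
  chk(cfg$replication$p_match > 0 && cfg$replication$p_match < 1,
      "replication$p_match out of range")
  if (length(errs)) stop("invalid pipeline config:\n  ",
                         paste(errs, collapse = "\n  "))
  class(cfg) <- "pipeline_config"
  cfg
}

stage_path <- function(cfg, name) file.path(cfg$paths$out_dir, name)

write_stage_manifest <- function(cfg, stage, seed, outputs) {
  hashes <- tools::md5sum(outputs[file.exists(outputs)])
  obj <- list(stage = stage, seed = seed,
              config = unclass_deep(cfg),
              outputs = as.list(hashes),
              package_version = as.character(utils::packageVersion("snpsetarch")))
  jsonlite::write_json(obj, stage_path(cfg, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

need <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path, ": run stage '", stage, "' first")
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `qc`, `gwas`, `sweep`, `characterize`, `skat`,
#' `architecture`, `network`, `replicate`. Each stage reads the previous
#' stages' artifacts from the configured output directory, writes its own
#' TSV/JSON/GraphML outputs plus a manifest (config, seed, output hashes),
#' and logs in/out counts so the set accounting is readable from the log.
#' Per-stage seeds derive deterministically from the master seed
#' (simulate: seed; sweep: seed + 101; replicate sweep: seed + 202).
#'
#' @param name stage name.
#' @param config a validated [validate_config()] object (or a plain list,
#'   validated on the fly).
#' @return invisibly, a list of the stage's main in-memory outputs.
#' @export
run_stage <- function(name, config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(cfg$paths$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    name,
    simulate = stage_simulate(cfg),
    qc = stage_qc(cfg),
    gwas = stage_gwas(cfg),
    sweep = stage_sweep(cfg),
    characterize = stage_characterize(cfg),
    skat = stage_skat(cfg),
    architecture = stage_architecture(cfg),
    network = stage_network(cfg),
    replicate = stage_replicate(cfg),
    stop("unknown stage: ", name))
  invisible(out)
}

#' Run the full pipeline end to end
#'
#' `simulate` (when enabled) through `network`, plus `replicate` when a
#' replication genotype file is configured.
#'
#' @inheritParams run_stage
#' @return invisibly, the last stage's outputs.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  stages <- c(if (isTRUE(cfg$simulate$enabled)) "simulate",
              "qc", "gwas", "sweep", "characterize", "skat",
              "architecture", "network",
              if (!is.null(cfg$paths$replication_genotypes)) "replicate")
  out <- NULL
  for (s in stages) {
    message("== stage: ", s)
    out <- run_stage(s, cfg)
  }
  invisible(out)
}

plant_from_config <- function(sc) {
  # allocate disjoint index blocks: CHD-target sets from the CHD panel,
  # T2D/both from the T2D panel end onward; subjects sequential
  next_chd <- 1L; next_t2d <- sc$n_snps_chd + 1L; next_subj <- 1L
  total <- sc$n_snps_chd + sc$n_snps_t2d
  out <- list()
  for (p in sc$planted) {
    from_chd <- identical(p$target, "CHD")
    start <- if (from_chd) next_chd else next_t2d
    idx <- start:(start + p$n_snps - 1L)
    if (max(idx) > total) stop("planted sets exceed the SNP panel")
    if (from_chd) next_chd <- max(idx) + 1L else next_t2d <- max(idx) + 1L
    subj <- next_subj:(next_subj + p$n_subjects - 1L)
    if (max(subj) > sc$n_subjects) stop("planted sets exceed the cohort")
    next_subj <- max(subj) + 1L
    out[[length(out) + 1L]] <- planted_set(idx, subj, p$dosage, p$shift, p$target)
  }
  out
}

stage_simulate <- function(cfg) {
  sc <- cfg$simulate
  cc <- cohort_config(n_subjects = sc$n_subjects, n_snps_chd = sc$n_snps_chd,
                      n_snps_t2d = sc$n_snps_t2d,
                      pattern_counts = sc$pattern_counts,
                      planted_sets = plant_from_config(sc),
                      maf_range = sc$maf_range, missing_rate = sc$missing_rate,
                      seed = cfg$seed)
  sim <- simulate_cohort(cc)
  gp <- stage_path(cfg, "genotypes.tsv")
  pp <- stage_path(cfg, "phenotypes.tsv")
  pa <- stage_path(cfg, "panel.tsv")
  write_genotype_tsv(sim$genotypes, gp)
  write_phenotype_tsv(sim$phenotypes, pp)
  write_panel_tsv(sim$genotypes$snp_meta, pa)
  message("simulate: ", nrow(sim$genotypes$dosages), " SNPs x ",
          ncol(sim$genotypes$dosages), " subjects")
  write_stage_manifest(cfg, "simulate", cfg$seed, c(gp, pp, pa))
  sim
}

load_inputs <- function(cfg) {
  gp <- if (!is.null(cfg$paths$genotypes)) cfg$paths$genotypes
        else need(stage_path(cfg, "genotypes.tsv"), "simulate")
  pp <- if (!is.null(cfg$paths$phenotypes)) cfg$paths$phenotypes
        else need(stage_path(cfg, "phenotypes.tsv"), "simulate")
  pa <- if (!is.null(cfg$paths$panel)) cfg$paths$panel
        else need(stage_path(cfg, "panel.tsv"), "simulate")
  meta <- read_panel_tsv(pa)
  list(genotypes = read_genotypes(gp, "tsv", snp_meta = meta),
       phenotypes = read_phenotypes(pp))
}

stage_qc <- function(cfg) {
  inp <- load_inputs(cfg)
  g <- qc_filter(inp$genotypes, cfg$qc$snp_missing_max, cfg$qc$maf_min,
                 cfg$qc$hwe_p_min, cfg$qc$subject_missing_max)
  rep <- attr(g, "qc_report")
  message("qc: removed ", sum(rep$snps_removed), " SNPs, ",
          sum(rep$subjects_removed), " subjects; ", nrow(g$dosages), " SNPs remain")
  out1 <- stage_path(cfg, "qc_genotypes.tsv")
  out2 <- stage_path(cfg, "qc_report.tsv")
  write_genotype_tsv(g, out1)
  utils::write.table(rep, out2, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(cfg, "qc", cfg$seed, c(out1, out2))
  list(genotypes = g, report = rep)
}

stage_gwas <- function(cfg) {
  meta <- read_panel_tsv(need(stage_path(cfg, "panel.tsv"), "simulate"))
  g <- read_genotypes(need(stage_path(cfg, "qc_genotypes.tsv"), "qc"),
                      "tsv", snp_meta = meta)
  pheno <- read_phenotypes(need(stage_path(cfg, "phenotypes.tsv"), "simulate"))
  al <- align_subjects(g, pheno)
  g <- al$genotypes; pheno <- al$phenotypes
  if (cfg$gwas$n_pcs > 0) {
    pcs <- compute_pcs(g, cfg$gwas$n_pcs)
    pheno <- phenotype_table(cbind(as.data.frame(pheno), as.data.frame(pcs)))
  }
  covs <- skat_covariates(if (cfg$gwas$adjust_pcs) pheno else strip_pcs(pheno))
  res_chd <- logistic_gwas(g, pheno$chd, covs, "CHD")
  res_t2d <- logistic_gwas(g, pheno$t2d, covs, "T2D")
  pooled <- pool_panels(g, res_chd, res_t2d, cfg$gwas$p_thresh)
  message("gwas: ", sum(pooled$snp_meta$panel_label == "CHD"), " CHD + ",
          sum(pooled$snp_meta$panel_label == "T2D"), " T2D hits pooled (",
          nrow(pooled$dosages), " SNPs)")
  o <- c(gwas_chd = stage_path(cfg, "gwas_chd.tsv"),
         gwas_t2d = stage_path(cfg, "gwas_t2d.tsv"),
         pooled = stage_path(cfg, "pooled_genotypes.tsv"),
         panel = stage_path(cfg, "pooled_panel.tsv"),
         pheno = stage_path(cfg, "phenotypes_pcs.tsv"))
  utils::write.table(res_chd, o["gwas_chd"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res_t2d, o["gwas_t2d"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotype_tsv(pooled, o["pooled"])
  write_panel_tsv(pooled$snp_meta, o["panel"])
  write_phenotype_tsv(pheno, o["pheno"])
  write_stage_manifest(cfg, "gwas", cfg$seed, o)
  list(pooled = pooled, phenotypes = pheno)
}

load_pooled <- function(cfg) {
  meta <- read_panel_tsv(need(stage_path(cfg, "pooled_panel.tsv"), "gwas"))
  g <- read_genotypes(need(stage_path(cfg, "pooled_genotypes.tsv"), "gwas"),
                      "tsv", snp_meta = meta)
  pheno <- read_phenotypes(need(stage_path(cfg, "phenotypes_pcs.tsv"), "gwas"))
  list(genotypes = g, phenotypes = pheno, panel = meta)
}

stage_sweep <- function(cfg) {
  inp <- load_pooled(cfg)
  X <- encode_matrix(inp$genotypes, cfg$nsnmf$coding)
  k_max <- if (is.null(cfg$nsnmf$k_max)) floor(sqrt(nrow(X))) else cfg$nsnmf$k_max
  sets <- run_sweep(X, cfg$nsnmf$k_min, k_max, cfg$nsnmf$theta, cfg$nsnmf$tau,
                    cfg$nsnmf$mode, cfg$nsnmf$max_iter, cfg$nsnmf$tol,
                    seed = cfg$seed + 101L)
  message("sweep: k = ", cfg$nsnmf$k_min, "..", k_max, " -> ",
          length(sets), " SNP sets")
  o <- c(json = stage_path(cfg, "snp_sets.json"),
         tsv = stage_path(cfg, "snp_sets.tsv"))
  write_snp_sets(sets, o["json"], o["tsv"])
  write_stage_manifest(cfg, "sweep", cfg$seed + 101L, o)
  list(sets = sets)
}

read_snp_sets_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x) {
    ki <- as.integer(strsplit(x$label, "_")[[1]][2:3])
    snp_set(ki[1], ki[2], unlist(x$snp_ids), unlist(x$subject_ids))
  })
}

stage_characterize <- function(cfg) {
  inp <- load_pooled(cfg)
  sets <- read_snp_sets_json(need(stage_path(cfg, "snp_sets.json"), "sweep"))
  desc <- describe_sets(sets, inp$phenotypes, inp$panel)
  pur <- purity_summary(sets, inp$panel)
  message("characterize: panel-mix ", round(100 * pur$panel_mix_fraction, 1),
          "%, direction-mix ", round(100 * pur$direction_mix_fraction, 1), "%")
  o <- stage_path(cfg, "descriptors.tsv")
  write_descriptor_tsv(desc, o)
  write_stage_manifest(cfg, "characterize", cfg$seed, o)
  list(descriptors = desc, purity = pur)
}

strip_pcs <- function(pheno) {
  keep <- !grepl("^PC[0-9]+$", names(pheno))
  phenotype_table(as.data.frame(pheno)[, keep, drop = FALSE])
}

stage_skat <- function(cfg) {
  sets <- read_snp_sets_json(need(stage_path(cfg, "snp_sets.json"), "sweep"))
  inp <- load_pooled(cfg)
  if (!cfg$gwas$adjust_pcs) inp$phenotypes <- strip_pcs(inp$phenotypes)
  res <- test_all_sets(sets, inp$genotypes, inp$phenotypes,
                       weights = cfg$skat$weights, alpha = cfg$skat$alpha)
  message("skat: ", sum(res$significant), " of ", nrow(res),
          " sets significant at ", format(attr(res, "threshold")))
  o <- stage_path(cfg, "skat_results.tsv")
  utils::write.table(res, o, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(cfg, "skat", cfg$seed, o)
  list(results = res)
}

stage_architecture <- function(cfg) {
  inp <- load_pooled(cfg)
  sets <- read_snp_sets_json(need(stage_path(cfg, "snp_sets.json"), "sweep"))
  res <- utils::read.table(need(stage_path(cfg, "skat_results.tsv"), "skat"),
                           sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  sig <- sets[vapply(sets, function(s)
    res$significant[match(s$label, res$label)], logical(1))]
  pheno_sets <- define_phenotype_sets(inp$phenotypes)
  universe_n <- nrow(inp$phenotypes)
  rel_all <- relate_to_patterns(sig, pheno_sets, universe_n)
  retained <- redundancy_filter(sig, rel_all, cfg$architecture$jc_thresh)
  arch <- build_architecture(retained, pheno_sets, universe_n,
                             cfg$architecture$alpha, panel = inp$panel)
  message("architecture: ", length(sig), " significant -> ", length(retained),
          " non-redundant sets; ", nrow(arch), " significant relations")
  o <- c(rel = stage_path(cfg, "relations.tsv"),
         sets = stage_path(cfg, "retained_sets.json"))
  utils::write.table(attr(arch, "all_relations"), o["rel"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_snp_sets(retained, json_path = o["sets"])
  write_stage_manifest(cfg, "architecture", cfg$seed, o)
  list(retained = retained, relations = arch)
}

stage_network <- function(cfg) {
  retained <- read_snp_sets_json(need(stage_path(cfg, "retained_sets.json"),
                                      "architecture"))
  panel <- read_panel_tsv(need(stage_path(cfg, "pooled_panel.tsv"), "gwas"))
  net <- build_genotypic_network(retained, panel_size = nrow(panel),
                                 alpha = cfg$network$alpha)
  message("network: ", nrow(net$nodes), " nodes, ", nrow(net$edges),
          " edges, ", net$n_components, " components")
  o <- c(graphml = stage_path(cfg, "network.graphml"),
         tsv = stage_path(cfg, "network_edges.tsv"))
  export_graph(net, o["graphml"], "graphml")
  export_graph(net, o["tsv"], "edge_tsv")
  write_stage_manifest(cfg, "network", cfg$seed, o)
  list(network = net)
}

stage_replicate <- function(cfg) {
  if (is.null(cfg$paths$replication_genotypes))
    stop("paths$replication_genotypes is required for the replicate stage")
  panel <- read_panel_tsv(need(stage_path(cfg, "pooled_panel.tsv"), "gwas"))
  g_rep <- read_genotypes(cfg$paths$replication_genotypes, "tsv",
                          snp_meta = panel)
  disc <- read_snp_sets_json(need(stage_path(cfg, "snp_sets.json"), "sweep"))
  k_max <- if (is.null(cfg$nsnmf$k_max)) floor(sqrt(nrow(panel))) else cfg$nsnmf$k_max
  rep_sets <- replicate_sweep(g_rep, panel$snp_id, cfg$nsnmf$k_min, k_max,
                              cfg$nsnmf$theta, cfg$nsnmf$tau, cfg$nsnmf$mode,
                              cfg$nsnmf$max_iter, cfg$nsnmf$tol,
                              seed = cfg$seed + 202L, coding = cfg$nsnmf$coding)
  matches <- match_snp_sets(disc, rep_sets, nrow(panel), cfg$replication$p_match)
  message("replicate: ", sum(matches$replicated), " of ", nrow(matches),
          " discovery sets replicated")
  o <- stage_path(cfg, "replication_matches.tsv")
  utils::write.table(matches, o, sep = "\t", quote = FALSE, row.names = FALSE)
  write_stage_manifest(cfg, "replicate", cfg$seed + 202L, o)
  list(matches = matches, replication_sets = rep_sets)
}
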