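# End-to-end orchestration: a YAML/list config drives synthetic-data
# generation, assay processing, benchmark-dose modelling, the microarray
# pipeline and GSEA, with per-stage logs and a checksummed manifest.

.pipeline_defaults <- function() {
  list(
    stages = list(synth = TRUE, assay = TRUE, bmd = TRUE,
                  microarray = TRUE, gsea = TRUE),
    seed = 1,
    alpha = 0.001,          # DEG selection level
    bmr = 0.10,             # benchmark response
    ci = 0.90,              # BMD confidence level
    lrt_alpha = 0.05,
    n_perm = 1000,          # GSEA permutations
    n_genes = 2000,         # synthetic expression universe
    replicates = 3,
    noise_sd = 0.05,        # dose-response log-scale noise
    expression_sd = 0.25,
    dilution_factor = 20,
    inputs = list(),        # external input paths (optional)
    out_dir = "results/pipeline"
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, checks parameter ranges and verifies that any
#' referenced input paths exist; all problems are aggregated into a single
#' error report.
#'
#' @param config A named list, or a path to a YAML file.
#' @return The normalized config (class `pipeline_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.pipeline_defaults(), config)
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  chk(cfg$bmr > 0 && cfg$bmr < 1, "bmr must lie in (0, 1)")
  chk(cfg$ci > 0 && cfg$ci < 1, "ci must lie in (0, 1)")
  chk(cfg$lrt_alpha > 0 && cfg$lrt_alpha < 1, "lrt_alpha must lie in (0, 1)")
  chk(cfg$n_perm >= 100, "n_perm must be >= 100")
  chk(cfg$n_genes >= 200, "n_genes must be >= 200")
  chk(cfg$replicates >= 2, "replicates must be >= 2")
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed must be an integer")
  for (nm in names(cfg$inputs)) {
    chk(file.exists(cfg$inputs[[nm]]),
        sprintf("input path for '%s' does not exist: %s", nm, cfg$inputs[[nm]]))
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (synth -> assay -> bmd ->
#' microarray -> gsea); each stage reads only declared files or in-memory
#' outputs of the previous stage, writes its outputs under `out_dir`, and is
#' logged. A manifest (inputs, parameters, seeds, outputs, md5 checksums) is
#' written at the end; identical config and seed give identical checksums.
#'
#' @param config A [validate_config()] result (or raw list/path, validated
#'   here).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(...)), file = log_path,
        append = TRUE)
  }
  cat(sprintf("pipeline seed=%d\n", cfg$seed), file = log_path)
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) { logf(name, "disabled"); return() }
    logf(name, "start")
    tryCatch(fun(), error = function(e) {
      logf(name, "FAILED: %s", conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    logf(name, "done")
  }

  run_stage("synth", function() {
    rod <- dr_model("exponential", 3, a = 100, b = -0.002, d = 1.5)
    star <- dr_model("exponential", 1, a = 100)
    il1b_rod <- dr_model("exponential", 3, a = 20, b = 0.03, d = 1)
    state$dr <- list(
      viability_rod = gen_dose_response(rod, sd = cfg$noise_sd,
                                        seed = cfg$seed, endpoint = "viability"),
      viability_star = gen_dose_response(star, sd = cfg$noise_sd,
                                         seed = cfg$seed + 1,
                                         endpoint = "viability"),
      il1b_rod = gen_dose_response(il1b_rod, sd = cfg$noise_sd,
                                   seed = cfg$seed + 2, endpoint = "IL-1b"))
    for (nm in names(state$dr)) {
      p <- file.path(out, paste0("dr_", nm, ".csv"))
      write_dr_csv(state$dr[[nm]], p); emit(p)
      emit(sub("\\.csv$", "_truth.json", p))
    }
    true_curve <- list(lower = 0.05, upper = 3.2, c = 120, b = 1.1, g = 0.9)
    state$elisa <- gen_elisa_plate(
      true_curve, c(rod_33 = 45, star_29 = 12, sphere_25 = 18),
      sd = 0, seed = cfg$seed + 3)
    p <- file.path(out, "elisa_plate.csv")
    utils::write.table(state$elisa, p, sep = ",", quote = FALSE,
                       row.names = FALSE); emit(p)
    shifts <- default_set_shifts(cfg$n_genes)
    state$sets <- shifts$sets
    state$expr <- gen_expression(
      n_genes = cfg$n_genes, replicates = cfg$replicates,
      sd = cfg$expression_sd, spikes = default_spikes(cfg$n_genes),
      set_shifts = shifts, probes_per_gene = 2,
      flag_fail_rate = 0.02, control_fraction = 0.02,
      seed = cfg$seed + 4)
    p <- file.path(out, "gene_sets.gmt")
    write_gmt(state$sets, p); emit(p)
    logf("synth", "generated %d dose-response sets, 1 ELISA plate, %d-gene expression",
         length(state$dr), cfg$n_genes)
  })

  run_stage("assay", function() {
    if (is.null(state$elisa)) stop("assay stage needs the synth stage (or an input plate)")
    res <- elisa_plate_analysis(state$elisa,
                                dilution_factor = cfg$dilution_factor)
    p <- file.path(out, "elisa_calibration.json")
    jsonlite::write_json(unclass(res$curve)[c("lower", "upper", "c", "b", "g", "rss")],
                         p, auto_unbox = TRUE, digits = NA); emit(p)
    p <- file.path(out, "cytokine_concentrations.tsv")
    utils::write.table(res$samples, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
    endo <- data.frame(
      gnp = paste0("GNP-", 1:6),
      measured = c(0.030, 0.070, 1.667, 1.546, 0.436, 0.041),
      interference = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
    endo$outcome <- mapply(endotoxin_classify, endo$measured, 100,
                           MoreArgs = list(limit = 0.5),
                           interference = endo$interference)
    p <- file.path(out, "endotoxin_classification.tsv")
    utils::write.table(endo, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
  })

  run_stage("bmd", function() {
    if (is.null(state$dr)) stop("bmd stage needs dose-response data")
    summaries <- list()
    for (nm in names(state$dr)) {
      an <- bmd_analysis(state$dr[[nm]], bmr = cfg$bmr,
                         alpha = cfg$lrt_alpha, ci = cfg$ci)
      jp <- file.path(out, sprintf("bmd_%s.json", nm))
      tp <- file.path(out, sprintf("bmd_%s.tsv", nm))
      write_bmd_report(an, jp, tp); emit(jp)
      if (file.exists(tp)) emit(tp)
      summaries[[nm]] <- an
    }
    state$bmd <- summaries
  })

  run_stage("microarray", function() {
    if (is.null(state$expr)) stop("microarray stage needs expression data")
    em <- collapse_by_symbol(log2_quantile_normalize(filter_reliable(state$expr)))
    state$em <- em
    p <- file.path(out, "normalized_matrix.tsv")
    utils::write.table(round(em$values, 5), p, sep = "\t", quote = FALSE); emit(p)
    cmp_spec <- list(
      star_WT = list(group = list(cell_line = "WT", exposure = "GNP-1"),
                     control = list(cell_line = "WT", exposure = "control")),
      sphere_WT = list(group = list(cell_line = "WT", exposure = "GNP-4"),
                       control = list(cell_line = "WT", exposure = "control")),
      rod_WT = list(group = list(cell_line = "WT", exposure = "GNP-6"),
                    control = list(cell_line = "WT", exposure = "control")),
      rod_ASC = list(group = list(cell_line = "ASC-def", exposure = "GNP-6"),
                     control = list(cell_line = "ASC-def", exposure = "control")),
      rod_NLRP3 = list(group = list(cell_line = "NLRP3-def", exposure = "GNP-6"),
                       control = list(cell_line = "NLRP3-def", exposure = "control")),
      ASC_base = list(group = list(cell_line = "ASC-def", exposure = "control"),
                      control = list(cell_line = "WT", exposure = "control")),
      NLRP3_base = list(group = list(cell_line = "NLRP3-def", exposure = "control"),
                        control = list(cell_line = "WT", exposure = "control")))
    state$cmp_spec <- cmp_spec
    res <- lapply(names(cmp_spec), function(nm) {
      differential_expression(em, cmp_spec[[nm]]$group, cmp_spec[[nm]]$control,
                              label = nm)
    })
    names(res) <- names(cmp_spec)
    state$comparisons <- res
    for (nm in names(res)) {
      p <- file.path(out, sprintf("comparison_%s.tsv", nm))
      utils::write.table(res[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
    }
    degs <- select_degs(res, alpha = cfg$alpha)
    state$degs <- degs
    fdr <- estimate_fdr(degs, n_genes = nrow(em$values),
                        n_comparisons = length(res), alpha = cfg$alpha)
    p <- file.path(out, "deg_set.tsv")
    utils::write.table(
      data.frame(gene = degs$genes), p, sep = "\t", quote = FALSE,
      row.names = FALSE); emit(p)
    p <- file.path(out, "deg_summary.json")
    jsonlite::write_json(
      list(per_comparison = as.list(degs$per_comparison),
           union = length(degs$genes), total_calls = degs$total_calls,
           fdr = fdr), p, auto_unbox = TRUE, digits = NA); emit(p)
    if (length(degs$genes) >= 2) {
      pca <- pca_scores(em, degs$genes)
      p <- file.path(out, "pca_scores.tsv")
      utils::write.table(
        cbind(em$samples, round(pca$scores[, seq_len(min(4, ncol(pca$scores)))], 5)),
        p, sep = "\t", quote = FALSE, row.names = FALSE); emit(p)
      hm_cmp <- lapply(cmp_spec[1:5], function(x) x)
      hm <- log2fc_heatmap(em, hm_cmp, degs$genes)
      p <- file.path(out, "heatmap_log2fc.tsv")
      utils::write.table(round(hm$log2fc, 5), p, sep = "\t", quote = FALSE); emit(p)
      state$heatmap <- hm
    }
    logf("microarray", "union DEGs: %d; FDR estimate: %.3f",
         length(degs$genes), fdr)
  })

  run_stage("gsea", function() {
    if (is.null(state$comparisons)) stop("gsea stage needs the microarray stage")
    sets <- state$sets
    if (is.null(sets)) stop("gsea stage needs gene sets")
    enr <- lapply(names(state$comparisons), function(nm) {
      r <- rank_genes(state$comparisons[[nm]])
      permutation_significance(r, sets, n_perm = cfg$n_perm,
                               seed = cfg$seed + 10)
    })
    names(enr) <- names(state$comparisons)
    for (nm in names(enr)) {
      p <- file.path(out, sprintf("gsea_%s.tsv", nm))
      utils::write.table(enr[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
    }
    grid <- enrichment_summary_grid(enr, p_cut = 0.05, top_n = 20,
                                    min_times = 2)
    p <- file.path(out, "gsea_summary_grid.tsv")
    utils::write.table(grid, p, sep = "\t", quote = FALSE,
                       row.names = FALSE); emit(p)
    state$gsea <- enr
  })

  manifest <- list(
    parameters = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    seed = cfg$seed,
    outputs = lapply(sort(unique(outputs)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}
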