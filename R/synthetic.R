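# Synthetic-data generation with known ground truth, emulating the study's
# inputs: dose-response plates with multiplicative log-normal noise, ELISA
# plates driven by a true 5PL curve, and a feature-level expression matrix
# (8 conditions x 3 replicates) with fabricated quality flags, spiked DEGs
# and pathway-coherent shifts.

# Seeds are isolated: generators save/restore the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Default dose grid: two-fold series, six points plus a zero-dose control
#'
#' @param top Highest dose (default 100 ug/mL).
#' @param n_points Number of non-zero doses (default 6).
#' @return Numeric dose vector including 0.
#' @export
dose_grid_2fold <- function(top = 100, n_points = 6) {
  c(0, top / 2^((n_points - 1):0))
}

#' Generate a dose-response dataset from a known model
#'
#' Responses are the model mean times multiplicative log-normal noise:
#' `y = f(x) * exp(N(0, sd))`. Identical truth and seed give identical data.
#'
#' @param spec Generating [dr_model()].
#' @param doses Dose grid (default [dose_grid_2fold()]).
#' @param replicates Replicates per dose (default 3).
#' @param sd Log-scale noise standard deviation (default 0.05).
#' @param seed Integer seed.
#' @param endpoint,unit Labels recorded on the dataset.
#' @return A [dr_dataset()] with attribute `truth` (list: spec, sd, seed).
#' @export
gen_dose_response <- function(spec, doses = dose_grid_2fold(),
                              replicates = 3, sd = 0.05, seed = 1,
                              endpoint = "viability", unit = "ug/mL") {
  stopifnot(inherits(spec, "dr_model"), sd >= 0, replicates >= 1)
  x <- rep(doses, each = replicates)
  mu <- eval_model(spec, x)
  y <- .with_seed(seed, mu * exp(stats::rnorm(length(x), 0, sd)))
  d <- dr_dataset(x, y, replicate = rep(seq_len(replicates), length(doses)),
                  endpoint = endpoint, unit = unit)
  attr(d, "truth") <- list(spec = spec, sd = sd, seed = seed)
  d
}

#' Generate an ELISA plate from a known 5PL curve
#'
#' Produces an 8-point two-fold standard series plus blank wells and sample
#' wells whose true in-well concentrations are given; ODs are the true curve
#' value plus additive Gaussian noise.
#'
#' @param curve True curve: list with `lower`, `upper`, `c`, `b`, `g`.
#' @param sample_conc Named vector of true in-well sample concentrations
#'   (pg/mL).
#' @param top_standard Highest standard concentration (default 1000 pg/mL).
#' @param n_standards Number of standard points (default 8, two-fold).
#' @param wells_per_condition Replicate wells per sample condition
#'   (default 4).
#' @param sd OD noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return Data frame (well, role, condition, concentration, od) with
#'   attribute `truth`.
#' @export
gen_elisa_plate <- function(curve, sample_conc, top_standard = 1000,
                            n_standards = 8, wells_per_condition = 4,
                            sd = 0, seed = 1) {
  stopifnot(all(sample_conc >= 0))
  class(curve) <- "curve_5pl"
  std_conc <- top_standard / 2^(seq_len(n_standards) - 1)
  rows <- data.frame(
    role = c(rep("standard", 2 * n_standards), rep("blank", 2)),
    condition = "",
    concentration = c(rep(std_conc, each = 2), 0, 0),
    stringsAsFactors = FALSE)
  cond <- names(sample_conc) %||% paste0("sample", seq_along(sample_conc))
  smp <- data.frame(
    role = "sample",
    condition = rep(cond, each = wells_per_condition),
    concentration = rep(unname(sample_conc), each = wells_per_condition),
    stringsAsFactors = FALSE)
  plate <- rbind(rows, smp)
  mu <- eval_5pl(curve, plate$concentration)
  plate$od <- .with_seed(seed, mu + stats::rnorm(nrow(plate), 0, sd))
  plate$well <- sprintf("W%02d", seq_len(nrow(plate)))
  truth <- list(curve = curve, sample_conc = sample_conc, sd = sd, seed = seed)
  plate$concentration[plate$role == "sample"] <- NA  # unknowns on a real plate
  attr(plate, "truth") <- truth
  plate[, c("well", "role", "condition", "concentration", "od")]
}

#' Design of the expression experiment: 8 conditions x 3 replicates
#'
#' Wildtype cells exposed to control, nanostars (GNP-1), nanospheres (GNP-4)
#' and nanorods (GNP-6); ASC- and NLRP3-deficient cells exposed to control
#' and nanorods. 24 samples in total.
#'
#' @param replicates Replicates per condition (default 3).
#' @return Sample sheet data frame (sample, cell_line, exposure, replicate).
#' @export
expression_design <- function(replicates = 3) {
  cond <- rbind(
    data.frame(cell_line = "WT", exposure = c("control", "GNP-1", "GNP-4", "GNP-6")),
    data.frame(cell_line = "ASC-def", exposure = c("control", "GNP-6")),
    data.frame(cell_line = "NLRP3-def", exposure = c("control", "GNP-6")))
  sheet <- cond[rep(seq_len(nrow(cond)), each = replicates), ]
  sheet$replicate <- rep(seq_len(replicates), nrow(cond))
  sheet$sample <- sprintf("%s_%s_r%d", sheet$cell_line, sheet$exposure,
                          sheet$replicate)
  rownames(sheet) <- NULL
  sheet[, c("sample", "cell_line", "exposure", "replicate")]
}

#' Default spike table emulating shape-specific transcriptional responses
#'
#' Nanorod-specific downward shifts in cholesterol-synthesis-like and
#' oxidative-phosphorylation-like synthetic sets, plus condition-specific
#' spiked DEGs per exposed condition.
#'
#' @param n_genes Universe size.
#' @param n_per_condition Spiked genes per exposed condition (default 25).
#' @param log2fc Spike magnitude (default 2).
#' @return Data frame (gene, cell_line, exposure, log2fc).
#' @export
default_spikes <- function(n_genes, n_per_condition = 25, log2fc = 2) {
  conds <- expression_design(1)
  conds <- conds[conds$exposure != "control", c("cell_line", "exposure")]
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    idx <- ((i - 1) * n_per_condition + 1):(i * n_per_condition)
    sgn <- rep(c(1, -1), length.out = n_per_condition)
    rows[[i]] <- data.frame(gene = gene_ids[idx],
                            cell_line = conds$cell_line[i],
                            exposure = conds$exposure[i],
                            log2fc = sgn * log2fc,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default coherent gene-set shifts (pathway-level ground truth)
#'
#' @param n_genes Universe size.
#' @param set_size Genes per synthetic set (default 40).
#' @param shift Mean log2 shift (default -0.5 for the nanorod-downregulated
#'   sets, +0.5 for the cell-cycle-like set).
#' @return List with `sets` (named list of gene vectors) and `shifts`
#'   (data frame: set, cell_line, exposure, shift).
#' @export
default_set_shifts <- function(n_genes, set_size = 40, shift = 0.5) {
  gene_ids <- sprintf("GENE%05d", seq_len(n_genes))
  base <- n_genes - 3 * set_size
  if (base < 1) stop("n_genes too small for the default synthetic sets")
  sets <- list(
    cholesterol_synthesis_like = gene_ids[base:(base + set_size - 1)],
    oxidative_phosphorylation_like = gene_ids[(base + set_size):(base + 2 * set_size - 1)],
    cell_cycle_like = gene_ids[(base + 2 * set_size):(base + 3 * set_size - 1)])
  rod <- expand.grid(cell_line = c("WT", "ASC-def", "NLRP3-def"),
                     exposure = "GNP-6", stringsAsFactors = FALSE)
  shifts <- rbind(
    data.frame(set = "cholesterol_synthesis_like", rod, shift = -shift),
    data.frame(set = "oxidative_phosphorylation_like", rod, shift = -shift),
    data.frame(set = "cell_cycle_like", cell_line = "WT",
               exposure = c("GNP-1", "GNP-4"), shift = shift))
  list(sets = sets, shifts = shifts)
}

#' Generate a feature-level expression dataset with known ground truth
#'
#' Gene-level log2 expression is baseline + condition effects + N(0, sd)
#' noise; features (1-3 probes per gene) add a small probe offset; intensity
#' is 2^log2value. Quality flags are fabricated at the configured failure
#' rates; a fraction of features are control probes. Deterministic per seed.
#'
#' @param n_genes Number of genes (default 10246).
#' @param replicates Replicates per condition (default 3).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   means (defaults 8 and 2).
#' @param sd Within-group log2 noise sd (default 0.25).
#' @param spikes Spike table as in [default_spikes()] (NULL for none).
#' @param set_shifts Coherent shift spec as in [default_set_shifts()]
#'   (NULL for none).
#' @param probes_per_gene Max probes per gene, sampled 1..k (default 1).
#' @param flag_fail_rate Per-criterion failure probability of the four
#'   quality flags (default 0).
#' @param control_fraction Fraction of extra control features (default 0).
#' @param seed Integer seed.
#' @return A [feature_table()] with attribute `truth` (list: spikes,
#'   set_shifts, sd, seed, gene_means).
#' @export
gen_expression <- function(n_genes = 10246, replicates = 3,
                           baseline_mean = 8, baseline_sd = 2, sd = 0.25,
                           spikes = NULL, set_shifts = NULL,
                           probes_per_gene = 1, flag_fail_rate = 0,
                           control_fraction = 0, seed = 1) {
  sheet <- expression_design(replicates)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  .with_seed(seed, {
    mu <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    names(mu) <- genes
    # gene x sample matrix of true means
    m <- matrix(mu, n_genes, nrow(sheet),
                dimnames = list(genes, sheet$sample))
    add_effect <- function(gene, cell_line, exposure, delta) {
      cols <- sheet$cell_line == cell_line & sheet$exposure == exposure
      m[gene, cols] <<- m[gene, cols] + delta
    }
    if (!is.null(spikes)) {
      for (i in seq_len(nrow(spikes))) {
        add_effect(spikes$gene[i], spikes$cell_line[i], spikes$exposure[i],
                   spikes$log2fc[i])
      }
    }
    if (!is.null(set_shifts)) {
      sh <- set_shifts$shifts
      for (i in seq_len(nrow(sh))) {
        add_effect(set_shifts$sets[[sh$set[i]]], sh$cell_line[i],
                   sh$exposure[i], sh$shift[i])
      }
    }
    m <- m + matrix(stats::rnorm(length(m), 0, sd), nrow(m))
    # expand to probes
    k <- if (probes_per_gene > 1) {
      sample.int(probes_per_gene, n_genes, replace = TRUE)
    } else rep(1L, n_genes)
    gi <- rep(seq_len(n_genes), k)
    probe_offset <- stats::rnorm(length(gi), 0, 0.1) * (probes_per_gene > 1)
    vals <- m[gi, , drop = FALSE] + probe_offset
    feat <- data.frame(
      feature_id = sprintf("FEAT%06d", seq_along(gi)),
      symbol = genes[gi],
      above_noise = stats::runif(length(gi)) >= flag_fail_rate,
      below_saturation = stats::runif(length(gi)) >= flag_fail_rate,
      population_outlier = stats::runif(length(gi)) < flag_fail_rate,
      uniform_spot = stats::runif(length(gi)) >= flag_fail_rate,
      is_control = FALSE,
      stringsAsFactors = FALSE)
    if (control_fraction > 0) {
      n_ctrl <- ceiling(control_fraction * nrow(feat))
      ctrl <- data.frame(
        feature_id = sprintf("CTRL%06d", seq_len(n_ctrl)),
        symbol = "", above_noise = TRUE, below_saturation = TRUE,
        population_outlier = FALSE, uniform_spot = TRUE, is_control = TRUE,
        stringsAsFactors = FALSE)
      vals <- rbind(vals, matrix(baseline_mean, n_ctrl, ncol(vals)))
      feat <- rbind(feat, ctrl)
    }
    tab <- feature_table(feat, 2^vals, sheet)
    attr(tab, "truth") <- list(spikes = spikes, set_shifts = set_shifts,
                               sd = sd, seed = seed, gene_means = mu)
    tab
  })
}

#' Write a feature table to per-sample TSVs plus a sample sheet
#'
#' Ground truth is written alongside as JSON so downstream tests can assert
#' recovery without re-deriving it.
#'
#' @param tab A [feature_table()] (typically from [gen_expression()]).
#' @param dir Output directory (created if needed).
#' @return The sample sheet path, invisibly.
#' @export
write_feature_tables <- function(tab, dir) {
  stopifnot(inherits(tab, "feature_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- tab$samples
  sheet$file <- paste0(sheet$sample, ".tsv")
  for (j in seq_len(nrow(sheet))) {
    out <- cbind(tab$features[, c("feature_id", "symbol", FLAG_COLS)],
                 intensity = tab$intensity[, j])
    utils::write.table(out, file.path(dir, sheet$file[j]), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- attr(tab, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(spikes = truth$spikes,
           set_shifts = if (!is.null(truth$set_shifts))
             list(sets = truth$set_shifts$sets,
                  shifts = truth$set_shifts$shifts) else NULL,
           sd = truth$sd, seed = truth$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
      null = "null", pretty = TRUE)
  }
  invisible(sheet_path)
}

#' Write a dose-response dataset (and its truth) to CSV
#'
#' @param data A [dr_dataset()].
#' @param path CSV output path; truth JSON is written beside it.
#' @return `path`, invisibly.
#' @export
write_dr_csv <- function(data, path) {
  stopifnot(inherits(data, "dr_dataset"))
  out <- as.data.frame(data)
  out$endpoint <- attr(data, "endpoint")
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE)
  truth <- attr(data, "truth")
  if (!is.null(truth)) {
    spec <- truth$spec
    jsonlite::write_json(
      list(family = spec$family, level = spec$level,
           a = spec$a, b = spec$b, c = spec$c, d = spec$d,
           sd = truth$sd, seed = truth$seed),
      sub("\\.csv$", "_truth.json", path),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}
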