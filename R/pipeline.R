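# End-to-end orchestration: a YAML run configuration describes genotypes
# (either file manifests or synthetic generating parameters), the fixed
# experimental constants, and the stages to run. The pipeline produces
# per-genotype summaries shaped like the study's agonist-potency table
# (EC50, h, n) and desensitization/P_o table (D, k_d, k_r, P_o, n), with
# Dunnett significance marks versus the control genotype.

#' Read a pipeline run configuration
#'
#' The YAML layout:
#' ```yaml
#' seed: 1
#' control: WT
#' constants:            # all experimental constants, never hard-coded
#'   k_c: 200            # 1/s
#'   k_b: 25             # 1/(uM s)
#'   mk801: 1            # uM
#'   glutamate: 1000     # uM
#'   glycine: 30         # uM
#'   exchange_tau: 0.010 # s
#'   sampling_rate: 5000 # Hz
#'   filter_hz: 2000     # Hz
#' stages: {kinetics: true, dose_response: true, stats: true}
#' noise: {trace_sd: 0.02, dr_cv: 0.05}
#' genotypes:
#'   WT:    {k_d: 0.47, k_r: 0.59, P_o: 19.1, EC50: 5.0, h: 1.09, n_cells: 5}
#'   R846X: {k_d: 2.50, k_r: 1.37, P_o: 5.8, EC50: 5.7, h: 1.04, n_cells: 5}
#' ```
#' A genotype entry may instead carry file manifests: `control_trace`,
#' `mk_trace` (delimited traces with protocol sidecars, see
#' [write_trace()]) and/or `dr_table` (delimited dose-response table).
#'
#' @param path YAML file.
#' @return A `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a list with the same structure as the YAML file.
#' @export
run_config <- function(cfg) {
  defaults <- list(k_c = 200, k_b = 25, mk801 = 1, glutamate = 1000,
                   glycine = 30, exchange_tau = 0.010,
                   sampling_rate = 5000, filter_hz = 2000)
  cfg$constants <- utils::modifyList(defaults, cfg$constants %||% list())
  cfg$stages <- utils::modifyList(list(kinetics = TRUE,
                                       dose_response = TRUE, stats = TRUE),
                                  cfg$stages %||% list())
  cfg$noise <- utils::modifyList(list(trace_sd = 0.02, dr_cv = 0.05),
                                 cfg$noise %||% list())
  cfg$seed <- cfg$seed %||% 1
  if (is.null(cfg$genotypes) || length(cfg$genotypes) == 0L)
    stop("configuration lists no genotypes", call. = FALSE)
  if (is.null(cfg$control) || !cfg$control %in% names(cfg$genotypes))
    stop("control genotype missing from the genotype list", call. = FALSE)
  for (g in names(cfg$genotypes)) {
    for (f in c("control_trace", "mk_trace", "dr_table")) {
      p <- cfg$genotypes[[g]][[f]]
      if (!is.null(p) && !file.exists(p))
        stop("file for genotype ", g, " does not exist: ", p, call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-genotype kinetics stage: returns one row per cell
pipeline_kinetics_genotype <- function(name, spec, cst, noise, seed) {
  n_cells <- spec$n_cells %||% 1
  proto_ctl <- application_protocol(data.frame(
    t_start = c(0, 0.1), t_end = c(0.1, 5.1),
    glutamate = c(0, cst$glutamate), glycine = cst$glycine, mk801 = 0),
    exchange_tau = cst$exchange_tau)
  proto_mk <- application_protocol(data.frame(
    t_start = c(0, 0.1), t_end = c(0.1, 10.1),
    glutamate = c(0, cst$glutamate), glycine = cst$glycine,
    mk801 = c(0, cst$mk801)), exchange_tau = cst$exchange_tau)
  rows <- lapply(seq_len(n_cells), function(i) {
    if (!is.null(spec$control_trace)) {
      ctl <- read_trace(spec$control_trace)
      mk <- read_trace(spec$mk_trace)
    } else {
      k_o <- spec$k_o %||% ko_from_po(spec$P_o, cst$k_c)
      p <- kinetic_params(k_d = spec$k_d, k_r = spec$k_r, k_o = k_o,
                          k_c = cst$k_c, k_b = cst$k_b)
      cell_seed <- (seed * 1000L + i) %% .Machine$integer.max
      ctl <- gen_trace(p, proto_ctl, noise_sd = noise$trace_sd,
                       seed = cell_seed, filter_on = noise$trace_sd > 0,
                       sampling_rate = cst$sampling_rate,
                       genotype = name)$trace
      mk <- gen_trace(p, proto_mk, noise_sd = noise$trace_sd,
                      seed = cell_seed + 500L,
                      filter_on = noise$trace_sd > 0,
                      sampling_rate = cst$sampling_rate,
                      genotype = name)$trace
    }
    d <- fit_desensitization(ctl)
    po <- estimate_po_two_step(ctl, mk, k_c = cst$k_c, k_b = cst$k_b)
    data.frame(genotype = name, cell = i, D_percent = d$D_percent,
               k_d = d$k_d, k_r = d$k_r, tau_d = d$tau_d, P_o = po$P_o,
               k_o = po$k_o)
  })
  do.call(rbind, rows)
}

# per-genotype dose-response stage
pipeline_dr_genotype <- function(name, spec, noise, seed) {
  if (!is.null(spec$dr_table)) {
    tab <- utils::read.table(spec$dr_table, header = TRUE, sep = "\t")
    tab$genotype <- name
  } else {
    if (is.null(spec$EC50)) return(NULL)
    tab <- gen_dr_dataset(spec$EC50, spec$h %||% 1.2,
                          n_cells = spec$n_cells %||% 1,
                          noise_cv = noise$dr_cv,
                          seed = (seed * 2000L + 17L) %% .Machine$integer.max,
                          genotype = name)$table
  }
  fits <- fit_hill_per_cell(tab)
  do.call(rbind, lapply(fits, function(f) data.frame(
    genotype = name, cell_id = f$cell_id, EC50 = f$EC50, h = f$h,
    log10_EC50 = f$log10_EC50)))
}

sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_

dunnett_marks <- function(values, genotypes, control) {
  lev <- unique(genotypes)
  marks <- stats::setNames(rep("", length(lev)), lev)
  counts <- table(genotypes)
  if (length(lev) >= 2L && all(counts >= 2L)) {
    rep_ <- anova_dunnett(data.frame(genotype = genotypes, value = values),
                          control = control)
    cmp <- rep_$comparisons
    for (i in seq_len(nrow(cmp))) {
      g <- sub(" - .*$", "", cmp$comparison[i])
      if (cmp$significant[i]) marks[g] <- "*"
    }
  }
  marks
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (kinetics: desensitization +
#' two-step P_o per cell; dose-response: per-cell Hill fits; stats:
#' Dunnett marks versus the control genotype on P_o, desensitization and
#' log10 EC50) and assembles per-genotype summary tables.
#'
#' @param config a `run_config` (see [read_run_config()]).
#' @return Object of class `pipeline_report`: list with `config` echo,
#'   `per_cell` (kinetics and dose-response per-cell tables) and
#'   `tables` (`agonist_potency`, `desensitization_po`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  cst <- config$constants
  genos <- names(config$genotypes)
  # control first, then the spec order: stable, deterministic table order
  genos <- c(config$control, setdiff(genos, config$control))

  kin <- dr <- NULL
  if (isTRUE(config$stages$kinetics))
    kin <- do.call(rbind, lapply(genos, function(g)
      pipeline_kinetics_genotype(g, config$genotypes[[g]], cst,
                                 config$noise, config$seed)))
  if (isTRUE(config$stages$dose_response))
    dr <- do.call(rbind, lapply(genos, function(g)
      pipeline_dr_genotype(g, config$genotypes[[g]], config$noise,
                           config$seed)))

  tables <- list()
  if (!is.null(dr)) {
    pooled <- pool_fits(dr)
    pooled <- pooled[match(intersect(genos, pooled$genotype),
                           pooled$genotype), ]
    marks <- if (isTRUE(config$stages$stats))
      dunnett_marks(dr$log10_EC50, dr$genotype, config$control)
      else stats::setNames(rep("", nrow(pooled)), pooled$genotype)
    pooled$significant <- unname(marks[pooled$genotype])
    tables$agonist_potency <- pooled
  }
  if (!is.null(kin)) {
    agg <- do.call(rbind, lapply(split(kin, kin$genotype)[unique(kin$genotype)],
      function(g) data.frame(
        genotype = g$genotype[1], n = nrow(g),
        D_percent = mean(g$D_percent), D_sem = sem(g$D_percent),
        k_d = mean(g$k_d), k_d_sem = sem(g$k_d),
        k_r = mean(g$k_r), k_r_sem = sem(g$k_r),
        P_o = mean(g$P_o), P_o_sem = sem(g$P_o))))
    agg <- agg[match(intersect(genos, agg$genotype), agg$genotype), ]
    rownames(agg) <- NULL
    if (isTRUE(config$stages$stats) && length(unique(kin$genotype)) > 1L) {
      marks_po <- dunnett_marks(kin$P_o, kin$genotype, config$control)
      marks_d <- dunnett_marks(kin$D_percent, kin$genotype, config$control)
      agg$P_o_significant <- unname(marks_po[agg$genotype])
      agg$D_significant <- unname(marks_d[agg$genotype])
    }
    tables$desensitization_po <- agg
  }
  structure(list(config = unclass(config), per_cell = list(kinetics = kin,
                                                           dose_response = dr),
                 tables = tables),
            class = "pipeline_report")
}

#' Write / read a pipeline report
#'
#' Summary tables go to tab-delimited files (`agonist_potency.tsv`,
#' `desensitization_po.tsv`), per-cell tables to
#' `per_cell_<stage>.tsv`, and the configuration echo (seeds and all
#' fixed constants) to `report.yaml`. Numbers are serialized at full
#' precision so a read round-trips losslessly; column order is stable
#' across runs.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if needed).
#' @return `write_report`: the directory, invisibly; `read_report`: list
#'   of tables plus the configuration echo.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (cn in names(df)) if (is.numeric(df[[cn]]))
      df[[cn]] <- sprintf("%.17g", df[[cn]])
    df
  }
  for (nm in names(report$tables))
    utils::write.table(fmt(report$tables[[nm]]),
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$per_cell))
    if (!is.null(report$per_cell[[nm]]))
      utils::write.table(fmt(report$per_cell[[nm]]),
                         file.path(dir, paste0("per_cell_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(report$config[c("seed", "control", "constants",
                                   "stages", "noise")],
                   file.path(dir, "report.yaml"))
  invisible(dir)
}

#' @rdname write_report
#' @export
read_report <- function(dir) {
  tabs <- list()
  for (f in list.files(dir, pattern = "\\.tsv$")) {
    tabs[[sub("\\.tsv$", "", f)]] <-
      utils::read.table(file.path(dir, f), header = TRUE, sep = "\t",
                        colClasses = NA, stringsAsFactors = FALSE)
  }
  list(tables = tabs,
       config = yaml::read_yaml(file.path(dir, "report.yaml")))
}
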