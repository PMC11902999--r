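## Run orchestration: YAML run configuration, the two workflows (TSMR and
## mediation), artifact writing and the reproducibility manifest. All
## randomness flows from the single config seed through childSeed().

#' Read and validate a YAML run configuration
#'
#' Expected keys: `seed`, `output_dir`, `exposure`/`outcome` (and
#' `mediator` for mediation runs) each as `{path, label, type[, sep]}`,
#' optional `ld_matrix`, optional `confounders` (list of table entries),
#' and optional `instruments`, `estimators`, `sensitivity` override maps.
#' Referenced paths must exist at run start.
#'
#' @param path YAML file.
#' @param requireMediator demand a mediator table entry.
#' @return the validated configuration list.
#' @export
readRunConfig <- function(path, requireMediator = FALSE) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  req <- c("seed", "output_dir", "exposure", "outcome")
  if (requireMediator) req <- c(req, "mediator")
  miss <- setdiff(req, names(cfg))
  if (length(miss))
    stop("config validation: missing ", paste(miss, collapse = ", "))
  for (key in intersect(c("exposure", "outcome", "mediator"), names(cfg))) {
    entry <- cfg[[key]]
    if (is.null(entry$path) || !file.exists(entry$path))
      stop(sprintf("config validation: %s path missing or not found", key))
  }
  if (!is.null(cfg$ld_matrix) && !file.exists(cfg$ld_matrix))
    stop("config validation: ld_matrix not found")
  for (conf in cfg$confounders %||% list())
    if (is.null(conf$path) || !file.exists(conf$path))
      stop("config validation: confounder path missing or not found")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.loadTable <- function(entry, default_label) {
  readSumStats(entry$path, traitLabel = entry$label %||% default_label,
               traitType = entry$type %||% "binary",
               columnMap = if (length(entry$column_map))
                 unlist(entry$column_map) else NULL,
               sep = entry$sep %||% "\t")
}

.instrumentConfigFrom <- function(cfg) {
  over <- cfg$instruments %||% list()
  do.call(instrumentConfig, over)
}

.writeTSV <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], formatC, digits = 17, format = "g")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.FLAG_STAGE <- c(clump_dropped = "clump", flipped = "harmonize",
                 palindromic_dropped = "harmonize",
                 missing_outcome_dropped = "harmonize",
                 irreconcilable_dropped = "harmonize",
                 weak_dropped = "f_filter",
                 outcome_significant_dropped = "cross_trait",
                 confounder_dropped = "cross_trait")

# flag audit (snp_id, stage, flag, triggering value) for the TSV trail
.auditTable <- function(hi) {
  tab <- instrumentTable(hi)
  rows <- list()
  for (i in which(nzchar(tab$flags))) {
    for (fl in strsplit(tab$flags[i], ";", fixed = TRUE)[[1]]) {
      val <- switch(fl, weak_dropped = tab$f_stat[i],
                    outcome_significant_dropped = tab$pval_out[i],
                    palindromic_dropped = tab$eaf_exp[i], NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = tab$snp_id[i], stage = unname(.FLAG_STAGE[fl]), flag = fl,
        value = val, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(snp_id = character(0), stage = character(0),
                      flag = character(0), value = numeric(0)))
  do.call(rbind, rows)
}

.writeManifest <- function(cfg, outdir, extra = list()) {
  cfg_path <- file.path(outdir, "run_config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  manifest <- c(list(
    package = "mediateMR",
    version = as.character(utils::packageVersion("mediateMR")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    config = cfg), extra)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

.runOneLeg <- function(exposure, outcome, ld, confounders, icfg, cfg,
                       seed, outdir, runPresso = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hi <- selectInstruments(exposure, outcome, ld = ld,
                          confounderTables = confounders, config = icfg)
  if (nRetained(hi) == 0L)
    stop(sprintf("empty instrument set for %s -> %s", traitLabel(exposure),
                 traitLabel(outcome)))
  est <- cfg$estimators %||% list()
  battery <- mrAllMethods(hi, seed = seed, nBoot = est$n_boot %||% 1000,
                          bandwidthFactor = est$bandwidth_factor %||% 1,
                          level = est$level %||% 0.95)
  sens_cfg <- cfg$sensitivity %||% list()
  sens <- sensitivityBattery(hi, seed = childSeed(seed, 7L),
                             pressoNSim = sens_cfg$presso_n_sim %||% 1000,
                             outlierP = sens_cfg$outlier_p %||% 0.05,
                             runPresso = runPresso &&
                               (sens_cfg$run_presso %||% TRUE))
  .writeTSV(battery$table, file.path(outdir, "estimates.tsv"))
  .writeTSV(sens@looTable, file.path(outdir, "loo.tsv"))
  .writeTSV(.auditTable(hi), file.path(outdir, "audit.tsv"))
  .writeTSV(instrumentTable(hi), file.path(outdir, "harmonized.tsv"))
  writeSensitivityReport(sens, file.path(outdir, "sensitivity.json"))
  list(instruments = hi, battery = battery, sensitivity = sens)
}

#' Run the two-sample MR workflow
#'
#' Executes select, clump, harmonize, F-filter and cross-trait exclusion,
#' then the five-method estimator battery and the sensitivity battery,
#' writing `estimates.tsv` (five method rows with odds-ratio columns),
#' `sensitivity.json`, `loo.tsv`, `audit.tsv`, `harmonized.tsv` and a
#' reproducibility manifest to the output directory. Reruns with an
#' identical configuration are byte-identical. An empty surviving
#' instrument set aborts with a stage-named diagnostic.
#'
#' @param config path to a YAML run configuration, or an equivalent list.
#' @return invisibly, list(instruments, battery, sensitivity).
#' @export
runTSMR <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  if (is.null(cfg$seed)) stop("config validation: seed is required")
  exposure <- .loadTable(cfg$exposure, "exposure")
  outcome <- .loadTable(cfg$outcome, "outcome")
  ld <- if (!is.null(cfg$ld_matrix)) readLDMatrix(cfg$ld_matrix) else NULL
  confounders <- lapply(cfg$confounders %||% list(), .loadTable,
                        default_label = "confounder")
  icfg <- .instrumentConfigFrom(cfg)
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- .runOneLeg(exposure, outcome, ld, confounders, icfg, cfg,
                    seed = as.integer(cfg$seed), outdir = outdir)
  .writeManifest(cfg, outdir,
                 extra = list(thresholds = unclass(icfg),
                              n_retained = nRetained(res$instruments)))
  invisible(res)
}

#' Run the two-step mediation workflow
#'
#' Three TSMR legs (total effect, exposure to mediator, mediator to
#' outcome) plus the mediation combination, each leg written to its own
#' subdirectory, and a mediation report table whose columns mirror the
#' conventional layout: per-pathway total, direct A, direct B and combined
#' mediation odds ratios with confidence intervals, the integer-percent
#' mediated proportion, and the log-scale indirect effect with its
#' delta-method interval.
#'
#' @param config path to a YAML run configuration with exposure, mediator
#'   and outcome tables, or an equivalent list.
#' @return invisibly, list(mediation, legs, report).
#' @export
runMediation <- function(config) {
  cfg <- if (is.character(config)) readRunConfig(config, requireMediator = TRUE)
         else config
  if (is.null(cfg$seed)) stop("config validation: seed is required")
  if (is.null(cfg$mediator)) stop("config validation: missing mediator")
  exposure <- .loadTable(cfg$exposure, "exposure")
  mediator <- .loadTable(cfg$mediator, "mediator")
  outcome <- .loadTable(cfg$outcome, "outcome")
  ld <- if (!is.null(cfg$ld_matrix)) readLDMatrix(cfg$ld_matrix) else NULL
  confounders <- lapply(cfg$confounders %||% list(), .loadTable,
                        default_label = "confounder")
  icfg <- .instrumentConfigFrom(cfg)
  seed <- as.integer(cfg$seed)
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  legs <- list(
    total = .runOneLeg(exposure, outcome, ld, confounders, icfg, cfg,
                       childSeed(seed, 1L), file.path(outdir, "total")),
    stepA = .runOneLeg(exposure, mediator, ld, confounders, icfg, cfg,
                       childSeed(seed, 2L), file.path(outdir, "stepA")),
    stepB = .runOneLeg(mediator, outcome, ld,
                       c(confounders, list(exposure)), icfg, cfg,
                       childSeed(seed, 3L), file.path(outdir, "stepB")))
  est <- cfg$estimators %||% list()
  primary <- paste0("ivw_", est$ivw_variant %||% "mre")
  level <- est$level %||% 0.95
  med <- twoStepMediation(legs$total$battery$results[[primary]],
                          legs$stepA$battery$results[[primary]],
                          legs$stepB$battery$results[[primary]],
                          level = level)
  report <- mediationReport(med, mediator = traitLabel(mediator),
                            exposure = traitLabel(exposure))
  .writeTSV(report, file.path(outdir, "mediation_report.tsv"))
  .writeManifest(cfg, outdir,
                 extra = list(thresholds = unclass(icfg),
                              primary_ivw = primary))
  invisible(list(mediation = med, legs = legs, report = report))
}

#' Flatten a MediationResult into a one-row report table
#'
#' @param med a [MediationResult-class].
#' @param mediator,exposure labels for the report row.
#' @return one-row data.frame with odds-ratio columns for the total,
#'   direct A, direct B and combined mediation effects, the
#'   integer-percent mediated proportion, and the log-scale indirect
#'   effect with its delta-method interval.
#' @export
mediationReport <- function(med, mediator = "mediator",
                            exposure = "exposure") {
  stopifnot(is(med, "MediationResult"))
  eff <- med@effects
  g <- function(comp, col) eff[eff$component == comp, col]
  fmtOR <- function(comp)
    sprintf("%.3f (%.3f, %.3f)", g(comp, "or_"), g(comp, "or_low"),
            g(comp, "or_high"))
  data.frame(
    exposure = exposure, mediator = mediator,
    total_or = fmtOR("total"), direct_a_or = fmtOR("stepA"),
    direct_b_or = fmtOR("stepB"),
    mediation_or = sprintf("%.3f (%.3f, %.3f)", med@combinedOR$or_,
                           med@combinedOR$or_low, med@combinedOR$or_high),
    proportion_percent = med@proportion$percent_label %||% NA_character_,
    indirect_beta = g("indirect", "beta"),
    indirect_ci_low = g("indirect", "ci_low"),
    indirect_ci_high = g("indirect", "ci_high"),
    proportion = med@proportion$estimate,
    proportion_ci_low = med@proportion$ci_low,
    proportion_ci_high = med@proportion$ci_high,
    stringsAsFactors = FALSE)
}

#' Write a synthetic scenario to disk
#'
#' Generates the named preset at the given seed and writes the trait
#' tables, the truth ledger, the configuration and (when the scenario has
#' LD blocks) the LD matrix. All files pass the package's own validation
#' on re-reading, and identical invocations produce identical files.
#'
#' @param scenario preset name (see [mrScenario()]).
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
runSimulate <- function(scenario, seed, outdir) {
  config <- mrScenario(scenario, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- simParams(config)
  paths <- character(0)
  wr <- function(x, name) {
    path <- file.path(outdir, name)
    writeSumStats(x, path)
    path
  }
  if (scenario == "CHAIN") {
    sim <- simulateMediationChain(config)
    paths <- c(wr(sim$exposure, "exposure.tsv"),
               wr(sim$mediator, "mediator.tsv"),
               wr(sim$outcome, "outcome.tsv"))
  } else {
    sim <- simulatePair(config)
    paths <- c(wr(sim$exposure, "exposure.tsv"),
               wr(sim$outcome, "outcome.tsv"))
    if (!is.null(p$ld_block_spec)) {
      ld_path <- file.path(outdir, "ld.tsv")
      writeLDMatrix(simulateLDBlocks(config), ld_path)
      paths <- c(paths, ld_path)
    }
  }
  truth_path <- file.path(outdir, "truth.tsv")
  .writeTSV(sim$truth@perSnp, truth_path)
  cfg_path <- file.path(outdir, "sim_config.yaml")
  yaml::write_yaml(c(list(scenario = scenario),
                     p[!vapply(p, is.null, logical(1))]), cfg_path)
  invisible(c(paths, truth_path, cfg_path))
}
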