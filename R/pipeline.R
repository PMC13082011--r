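#' Run the full analysis pipeline from a single configuration
#'
#' Orchestrates simulate (or load) -> partition -> repertoire -> associate
#' -> mimicry -> signatures from one human-editable YAML or JSON
#' configuration, writing every intermediate table, a `run.log`, and a
#' machine-readable `run_report.json` with per-stage parameters, record
#' counts, warnings and elapsed times. Rerunning with an identical
#' configuration (including seeds) reproduces the result files
#' byte-identically; the run report additionally carries wall-clock timings
#' and is therefore not part of that contract.
#'
#' Each data stream (`serology`, `mimicry`, `expression`) is configured with
#' exactly one of a `spec` block (simulation parameters, passed to the
#' matching generator) or a `paths` block (input files). Unknown keys
#' anywhere in the configuration are rejected before any stage runs. A
#' stage failure aborts the downstream stages and is recorded in the
#' report.
#'
#' @param config path to a YAML/JSON configuration file, or an equivalent
#'   named list.
#' @param outdir output directory override (otherwise `config$outdir`).
#' @param seed global seed override applied to every stream's spec.
#' @return the run report, invisibly (a list; also written as JSON).
#' @examples
#' cfg <- demo_config()
#' cfg$outdir <- tempfile("mimiscan_demo_")
#' \donttest{report <- run_pipeline(cfg)}
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  cfg <- .load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  cfg <- .validate_config(cfg)
  if (is.null(cfg$outdir)) stop("config field 'outdir' is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(cfg$outdir, "inputs"), showWarnings = FALSE)

  log_path <- file.path(cfg$outdir, "run.log")
  cat("", file = log_path)
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    message(msg)
    cat(msg, "\n", file = log_path, append = TRUE)
  }

  p <- .pipeline_params(cfg$params)
  report <- list(config = cfg[setdiff(names(cfg), "outdir")],
                 stages = list(), status = "ok")
  env <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (report$status != "ok") {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    warns <- character(0)
    rec <- tryCatch({
      out <- withCallingHandlers(fun(), warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
      c(out, list(status = "ok"))
    }, error = function(e) {
      report$status <<- "failed"
      log_line("stage %s FAILED: %s", name, conditionMessage(e))
      list(status = "error", error = conditionMessage(e))
    })
    rec$warnings <- warns
    rec$elapsed_sec <- round(proc.time()[["elapsed"]] - t0, 3)
    report$stages[[name]] <<- rec
    log_line("stage %s: %s (%.2fs, %d warning(s))", name, rec$status,
             rec$elapsed_sec, length(warns))
  }

  run_stage("simulate", function() {
    counts <- list()
    if (!is.null(cfg$serology$spec)) {
      spec <- do.call(cohort_spec, .override_seed(cfg$serology$spec, cfg$seed))
      env$sero <- generate_serology_cohort(spec)
    } else {
      pth <- cfg$serology$paths
      env$sero <- list(catalog = read_tsv(pth$catalog),
                       annotations = read_tsv(pth$annotations),
                       ebs = read_ebs_matrix(pth$ebs),
                       meta = read_tsv(pth$meta))
    }
    write_tsv(env$sero$catalog, file.path(cfg$outdir, "inputs", "catalog.tsv"))
    write_tsv(env$sero$annotations,
              file.path(cfg$outdir, "inputs", "annotations.tsv"))
    write_ebs_matrix(env$sero$ebs, file.path(cfg$outdir, "inputs", "ebs.tsv"))
    write_tsv(env$sero$meta, file.path(cfg$outdir, "inputs", "meta.tsv"))
    if (!is.null(cfg$mimicry$spec)) {
      spec <- do.call(mimicry_spec, .override_seed(cfg$mimicry$spec, cfg$seed))
      env$ipms <- generate_ipms_tables(spec, query = p$query)
    } else {
      pth <- cfg$mimicry$paths
      env$ipms <- list(intensities = read_tsv(pth$intensities),
                       sequences = read_fasta(pth$fasta),
                       surface_list = read_surface_list(pth$surface))
    }
    write_tsv(env$ipms$intensities,
              file.path(cfg$outdir, "inputs", "intensities.tsv"))
    write_fasta(env$ipms$sequences,
                file.path(cfg$outdir, "inputs", "candidates.fasta"))
    write_surface_list(env$ipms$surface_list,
                       file.path(cfg$outdir, "inputs", "surface_list.txt"))
    if (!is.null(cfg$expression$spec)) {
      spec <- do.call(expression_spec,
                      .override_seed(cfg$expression$spec, cfg$seed))
      env$bundle <- generate_expression_cohort(spec)
    } else {
      pth <- cfg$expression$paths
      env$bundle <- list(expr = read_expression_matrix(pth$expr),
                         meta = read_tsv(pth$meta))
    }
    write_expression_matrix(env$bundle$expr,
                            file.path(cfg$outdir, "inputs", "expression.tsv"))
    write_tsv(env$bundle$meta,
              file.path(cfg$outdir, "inputs", "expression_meta.tsv"))
    jsonlite::write_json(
      list(seed = cfg$seed,
           serology = cfg$serology, mimicry = cfg$mimicry,
           expression = cfg$expression, params = p),
      file.path(cfg$outdir, "inputs", "spec.json"),
      auto_unbox = TRUE, pretty = TRUE, null = "null")
    list(counts = list(individuals = nrow(env$sero$ebs),
                       peptides = ncol(env$sero$ebs),
                       proteins = length(env$ipms$sequences),
                       tumors = ncol(env$bundle$expr)))
  })

  run_stage("partition", function() {
    env$assignment <- assign_groups(env$sero$catalog, env$sero$annotations,
                                    min_ce1_overlap = p$min_ce1_overlap)
    write_tsv(env$assignment, file.path(cfg$outdir, "assignments.tsv"))
    list(params = list(min_ce1_overlap = p$min_ce1_overlap),
         counts = as.list(table(env$assignment$group)))
  })

  run_stage("repertoire", function() {
    gsum <- group_ebs_summary(env$sero$ebs, env$assignment)
    env$arb <- compute_arb(env$sero$ebs, env$assignment, "CE1_VP1")
    cats <- arb_category(env$arb$arb)
    env$arb$category <- as.character(cats$category)
    env$arb$above_cutoff <- cats$above_cutoff
    ce1_ids <- env$assignment$peptide_id[env$assignment$group == "CE1_VP1"]
    env$sero_scores <- ce1_seroreactivity(
      env$sero$ebs, ce1_ids, k = p$k_panel,
      positivity_threshold = p$seropositivity_threshold, mode = "data_driven")
    write_tsv(gsum, file.path(cfg$outdir, "group_ebs_summary.tsv"))
    write_tsv(env$arb, file.path(cfg$outdir, "arb_ce1_vp1.tsv"))
    write_tsv(env$sero_scores, file.path(cfg$outdir, "ce1_seroreactivity.tsv"))
    env$gsum <- gsum
    list(params = list(k_panel = p$k_panel,
                       seropositivity_threshold = p$seropositivity_threshold),
         counts = list(individuals = nrow(env$sero$ebs),
                       arb_undefined = sum(!env$arb$defined)))
  })

  run_stage("associate", function() {
    meta <- env$sero$meta
    ce1_mean <- env$gsum$mean_ebs[env$gsum$group == "CE1_VP1"]
    fit <- fit_diagnosis_logistic(ce1_mean, meta$diagnosis)
    tt <- compare_group_means(
      c(env$gsum$mean_ebs[env$gsum$group == "CE1_VP1"],
        env$gsum$mean_ebs[env$gsum$group == "NON_CE1_VP1"]),
      rep(c("CE1_VP1", "NON_CE1_VP1"), each = nrow(meta)))
    tab <- table(meta$diagnosis, env$arb$category)
    chisq <- arb_category_chisq(tab)
    hcc <- meta$diagnosis == "HCC" & env$arb$defined
    surv <- km_logrank(meta$survival_time[hcc], meta$event[hcc],
                       ifelse(env$arb$above_cutoff[hcc], "ARB>0.5", "ARB<=0.5"))
    res <- list(logistic = list(odds_ratio = fit$odds_ratio,
                                odds_ratio_per_sd = fit$odds_ratio_per_sd,
                                p_value = fit$p_value, n = fit$n_used),
                t_test_ce1_vs_nonce1 = as.list(tt),
                arb_chisq = list(statistic = chisq$statistic, df = chisq$df,
                                 p_value = chisq$p_value),
                logrank_arb = list(statistic = surv$statistic,
                                   p_value = surv$p_value, n = surv$n_used))
    jsonlite::write_json(res, file.path(cfg$outdir, "association.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_tsv(surv$curves, file.path(cfg$outdir, "km_curves_arb.tsv"))
    list(counts = list(logistic_n = fit$n_used, survival_n = surv$n_used),
         results = res)
  })

  run_stage("mimicry", function() {
    env$funnel <- mimicry_funnel(
      env$ipms$intensities, env$ipms$surface_list, env$ipms$sequences,
      query = p$query, pseudocount = p$pseudocount, cutoff = p$fc_cutoff,
      cell_line_mode = p$cell_line_mode, antibody_mode = p$antibody_mode)
    write_tsv(env$funnel$ranking$table,
              file.path(cfg$outdir, "mimicry_ranking.tsv"))
    aln_path <- file.path(cfg$outdir, "mimicry_alignments.txt")
    sink(aln_path)
    for (r in env$funnel$ranking$alignments) print(r)
    sink()
    list(params = list(fc_cutoff = p$fc_cutoff, pseudocount = p$pseudocount,
                       antibody_mode = p$antibody_mode,
                       cell_line_mode = p$cell_line_mode, query = p$query),
         counts = as.list(env$funnel$counts))
  })

  run_stage("signatures", function() {
    bundle <- env$bundle
    norm <- zscore_within_dataset(bundle$expr, bundle$meta$dataset)
    score <- adcc_score(norm)
    nk <- nk_stratify(bundle$meta$nk_score, cutoff = p$nk_cutoff)
    seropos <- bundle$meta$ce1_score > p$seropositivity_threshold
    chisq <- serostatus_nk_chisq(nk, seropos)
    spearman <- stratified_asph_adcc(norm["ASPH", ], score, seropos)
    surv <- asph_sero_survival(norm["ASPH", ], bundle$meta$survival_time,
                               bundle$meta$event, seropos)
    out <- data.frame(sample_id = bundle$meta$sample_id,
                      adcc_score = score, nk_stratum = as.character(nk),
                      seropositive = seropos,
                      asph_normalized = norm["ASPH", ])
    write_tsv(out, file.path(cfg$outdir, "signature_scores.tsv"))
    res <- list(nk_serostatus_chisq = list(statistic = chisq$statistic,
                                           p_value = chisq$p_value),
                asph_adcc_spearman = spearman,
                asph_survival = list(
                  high = if (!is.null(surv$asph_high))
                    list(statistic = surv$asph_high$statistic,
                         p_value = surv$asph_high$p_value),
                  low = if (!is.null(surv$asph_low))
                    list(statistic = surv$asph_low$statistic,
                         p_value = surv$asph_low$p_value)))
    jsonlite::write_json(res, file.path(cfg$outdir, "signatures.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(params = list(nk_cutoff = p$nk_cutoff),
         counts = list(tumors = ncol(bundle$expr),
                       seropositive = sum(seropos)),
         results = res)
  })

  report$n_stages <- length(report$stages)
  jsonlite::write_json(report, file.path(cfg$outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  log_line("pipeline %s (%d stages)", report$status, report$n_stages)
  if (report$status != "ok") {
    warning("pipeline finished with status '", report$status, "'")
  }
  invisible(report)
}

#' Bundled demonstration configuration
#'
#' A pure-simulation configuration at reduced cohort size, suitable for a
#' quick end-to-end run; the packaged copy lives at
#' `system.file("extdata", "demo_config.yaml", package = "mimiscan")`.
#'
#' @return named list configuration (set `outdir` before running).
#' @export
demo_config <- function() {
  .load_config(system.file("extdata", "demo_config.yaml",
                           package = "mimiscan"))
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    cfg <- if (grepl("^\\s*\\{", txt)) jsonlite::fromJSON(txt,
                                                          simplifyVector = TRUE)
           else yaml::yaml.load(txt)
  } else if (is.list(config)) {
    cfg <- config
  } else {
    stop("config must be a file path or a named list")
  }
  cfg
}

.override_seed <- function(spec_args, seed) {
  if (is.null(spec_args)) spec_args <- list()
  if (!is.null(seed) && is.null(spec_args$seed)) spec_args$seed <- seed
  spec_args
}

.pipeline_params <- function(params) {
  defaults <- list(min_ce1_overlap = 1L, pseudocount = 1, fc_cutoff = 100,
                   antibody_mode = "any", cell_line_mode = "all",
                   k_panel = 40L, seropositivity_threshold = 0,
                   nk_cutoff = 0.01, query = ce1_query(),
                   strip_leading_cys = FALSE)
  if (is.null(params)) params <- list()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown params key(s): ", paste(unknown, collapse = ", "))
  }
  out <- utils::modifyList(defaults, params)
  if (out$strip_leading_cys && out$query == ce1_query()) {
    out$query <- ce1_query(strip_leading_cys = TRUE)
  }
  out
}

.validate_config <- function(cfg) {
  allowed <- c("seed", "outdir", "serology", "mimicry", "expression", "params")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (stream in c("serology", "mimicry", "expression")) {
    blk <- cfg[[stream]]
    if (is.null(blk)) blk <- list(spec = list()) # default: pure simulation
    unknown <- setdiff(names(blk), c("spec", "paths"))
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in '%s': %s", stream,
                   paste(unknown, collapse = ", ")))
    }
    has_spec <- !is.null(blk$spec)
    has_paths <- !is.null(blk$paths)
    if (has_spec && has_paths) {
      stop(sprintf("stream '%s' must have exactly one of 'spec' or 'paths'",
                   stream))
    }
    if (!has_spec && !has_paths) blk$spec <- list()
    cfg[[stream]] <- blk
  }
  cfg
}
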