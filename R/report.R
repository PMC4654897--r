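#' Concordance and tetrachoric correlation summary table
#'
#' One row per zygosity/sex stratum (MZM, DZM, MZF, DZF, OSDZ) of complete
#' pairs: concordant-affected, discordant and concordant-unaffected counts
#' with row percentages, the total, and the ML tetrachoric correlation.
#'
#' @param cohort A `twin_cohort`.
#' @param horizon_age Affection horizon (default end of follow-up).
#' @param complete_pairs_only Restrict to pairs with both members alive at
#'   follow-up end (default `TRUE`).
#' @return A data.frame, one row per stratum.
#' @export
report_table2 <- function(cohort, horizon_age = Inf, complete_pairs_only = TRUE) {
  strata <- list(MZM = list(z = "MZ", s = "male"),
                 DZM = list(z = "DZSS", s = "male"),
                 MZF = list(z = "MZ", s = "female"),
                 DZF = list(z = "DZSS", s = "female"),
                 OSDZ = list(z = "DZOS", s = "pooled"))
  rows <- lapply(names(strata), function(nm) {
    st <- strata[[nm]]
    tab <- pair_contingency(cohort, zygosity = st$z, sex = st$s,
                            horizon_age = horizon_age,
                            complete_pairs_only = complete_pairs_only)
    te <- if (tab$n_cc + tab$n_cd > 0 && tab$n_cd + tab$n_dd > 0)
      tetrachoric(tab) else NULL
    tot <- tab$total
    pct <- function(x) if (tot > 0) 100 * x / tot else NA_real_
    data.frame(stratum = nm,
               concordant_affected = tab$n_cc, concordant_affected_pct = pct(tab$n_cc),
               discordant = tab$n_cd, discordant_pct = pct(tab$n_cd),
               concordant_unaffected = tab$n_dd, concordant_unaffected_pct = pct(tab$n_dd),
               total_pairs = tot,
               rho = if (is.null(te) || isTRUE(te$boundary)) NA_real_ else te$rho,
               rho_lo = if (is.null(te) || isTRUE(te$boundary)) NA_real_ else te$ci95[1],
               rho_hi = if (is.null(te) || isTRUE(te$boundary)) NA_real_ else te$ci95[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Biometric model summary table
#'
#' Fits the saturated model and the requested submodels for each sex block
#' and assembles one row per model: zygosity prevalences, MZ/DZ
#' correlations, model-based case-wise concordance rates, broad-sense
#' heritability, variance components with CIs, log likelihood, AIC and the
#' likelihood-ratio test against the saturated model. `sex = "both"` is the
#' sex-adjusted block (sex-specific thresholds, shared components,
#' opposite-sex pairs included); `"male"`/`"female"` are the sex-stratified
#' blocks (same-sex pairs only).
#'
#' @param cohort A `twin_cohort`.
#' @param weights Optional [censoring_weights()] frame; `NULL` fits
#'   unweighted outcomes by `horizon_age`.
#' @param horizon_age Horizon for the unweighted path.
#' @param sexes Blocks to fit.
#' @param models Submodels to fit in addition to the saturated model.
#' @param pool_dz Pool DZ correlations in the saturated model.
#' @return A data.frame, one row per (block, model); non-converged rows are
#'   marked in column `converged`.
#' @export
report_table3 <- function(cohort, weights = NULL, horizon_age = Inf,
                          sexes = c("male", "female", "both"),
                          models = c("ACE", "ADE", "AE", "CE"),
                          pool_dz = FALSE) {
  pairs <- twin_pairs(cohort, horizon_age = horizon_age, weights = weights)
  rows <- list()
  for (sx in sexes) {
    block <- if (sx == "both") "sex-adjusted" else sx
    sat <- fit_saturated(pairs, sex = sx, pool_dz = pool_dz)
    dzn <- setdiff(names(sat$correlations), "MZ")
    npairs_dz <- vapply(dzn, function(cl) sum(restrict_sex(pairs, sx)$zyg == cl), 0)
    rmz <- sat$correlations[["MZ"]]
    rdz <- sum(sat$correlations[dzn] * npairs_dz) / sum(npairs_dz)
    h_sat <- heritability(sat, dz_weights = npairs_dz)
    qbar <- mean(sat$prevalences)
    rows[[length(rows) + 1]] <- data.frame(
      block = block, model = "saturated",
      mz_prevalence = qbar, dz_prevalence = qbar,
      mz_rho = rmz, dz_rho = rdz,
      mz_casewise = safe_casewise(rmz, qbar),
      dz_casewise = safe_casewise(rdz, qbar),
      heritability = h_sat$h2, heritability_lo = h_sat$ci95[1], heritability_hi = h_sat$ci95[2],
      a2 = NA_real_, d2 = NA_real_, c2 = NA_real_, e2 = NA_real_,
      loglik = sat$loglik, aic = sat$aic, n_free = sat$n_free,
      chi2 = NA_real_, df = NA_integer_, p = NA_real_,
      converged = sat$converged, stringsAsFactors = FALSE)
    for (mt in models) {
      fit <- fit_components(pairs, mt, sex = sx)
      lrt <- compare_models(fit, sat)
      h <- heritability(fit)
      qmz <- weighted_prevalence(pairs, sx, "MZ")
      qdz <- weighted_prevalence(pairs, sx, c("DZSS", "DZOS"))
      rows[[length(rows) + 1]] <- data.frame(
        block = block, model = mt,
        mz_prevalence = qmz, dz_prevalence = qdz,
        mz_rho = fit$correlations[["rMZ"]], dz_rho = fit$correlations[["rDZ"]],
        mz_casewise = safe_casewise(fit$correlations[["rMZ"]], qmz),
        dz_casewise = safe_casewise(fit$correlations[["rDZ"]], qdz),
        heritability = h$h2, heritability_lo = h$ci95[1], heritability_hi = h$ci95[2],
        a2 = fit$components[["a2"]], d2 = fit$components[["d2"]],
        c2 = fit$components[["c2"]], e2 = fit$components[["e2"]],
        loglik = fit$loglik, aic = fit$aic, n_free = fit$n_free,
        chi2 = lrt$chi2, df = lrt$df, p = lrt$p,
        converged = fit$converged, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

safe_casewise <- function(rho, q) {
  if (!is.finite(rho) || !is.finite(q) || q <= 0 || q >= 1 || abs(rho) >= 1)
    return(NA_real_)
  model_casewise(rho, q)
}

weighted_prevalence <- function(pairs, sx, classes) {
  pr <- restrict_sex(pairs, if (sx == "both") "both" else sx)
  pr <- pr[pr$zyg %in% classes, , drop = FALSE]
  if (nrow(pr) == 0) return(NA_real_)
  sum(pr$w * (pr$y1 + pr$y2)) / (2 * sum(pr$w))
}

#' Run the full analysis pipeline
#'
#' Drives every stage end to end: simulate (or load and link registry
#' files), tabulate concordance, construct IPCW outcomes, fit the biometric
#' models, estimate the competing-risk cumulative incidence, and produce
#' the age-resolved curves. All tables are written as TSV into `out_dir`
#' together with a machine-readable run log (key = value lines holding the
#' seed, config hash, package version, exclusion ledger and convergence
#' flags). Outputs are deterministic given config and seed.
#'
#' @param config A named list or path to a YAML file. Recognised entries:
#'   `seed`, `n_pairs`, `twins_file`/`events_file` (load instead of
#'   simulate), `horizon` (IPCW horizon age, default 60), `grid` (age grid
#'   for curves, default `seq(40, 90, 5)`), `models`, `sexes`, `bootstrap`
#'   (B for concordance curves, default 0), `out_dir`.
#' @return Invisibly, a list with the cohort, tables, curves and file paths.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(seed = 1, n_pairs = 45000, horizon = 60,
                                grid = seq(40, 90, 5), bootstrap = 0,
                                models = c("ACE", "ADE", "AE", "CE"),
                                sexes = c("male", "female", "both"),
                                twins_file = NULL, events_file = NULL,
                                out_dir = "twinliab-run"),
                           config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  log_lines <- c(sprintf("seed=%s", cfg$seed),
                 sprintf("package_version=%s", as.character(utils::packageVersion("twinliab"))),
                 sprintf("config_hash=%s", config_hash(cfg)))
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    header <- sprintf("# seed=%s config_hash=%s", cfg$seed, config_hash(cfg))
    writeLines(header, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                        quote = FALSE, append = TRUE))
    path
  }
  out <- list(paths = character())
  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("failed_stage=%s", name),
                   sprintf("error=%s", conditionMessage(e))),
                 file.path(cfg$out_dir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cohort <- run_stage("cohort", {
    if (!is.null(cfg$twins_file)) {
      tw <- load_twin_register(cfg$twins_file)
      ev <- load_event_register(cfg$events_file)
      build_analysis_cohort(tw, ev)
    } else {
      simulate_cohort(sim_params(n_pairs = cfg$n_pairs, seed = cfg$seed))
    }
  })
  ledger <- exclusion_ledger(cohort)
  if (!is.null(ledger))
    log_lines <- c(log_lines, sprintf("excluded_%s=%d", names(ledger), ledger))
  out$table2 <- run_stage("concordance", report_table2(cohort))
  out$paths <- c(out$paths, emit(out$table2, "table2"))
  wts <- run_stage("weights", censoring_weights(cohort, cfg$horizon))
  out$table3 <- run_stage("models",
                          report_table3(cohort, weights = wts, sexes = cfg$sexes,
                                        models = cfg$models))
  out$paths <- c(out$paths, emit(out$table3, "table3"))
  log_lines <- c(log_lines,
                 sprintf("model_converged_%s_%s=%s", out$table3$block,
                         out$table3$model, out$table3$converged))
  out$cif <- run_stage("cif", as.data.frame(estimate_cif(cohort, by_sex = TRUE)))
  out$paths <- c(out$paths, emit(out$cif, "cif"))
  out$concordance_age <- run_stage("age_concordance",
                                   as.data.frame(concordance_by_age(cohort, cfg$grid,
                                                                    B = cfg$bootstrap)))
  out$paths <- c(out$paths, emit(out$concordance_age, "concordance_by_age"))
  out$components_age <- run_stage("age_components",
                                  as.data.frame(components_by_age(cohort, cfg$grid)))
  out$paths <- c(out$paths, emit(out$components_age, "components_by_age"))
  writeLines(c(log_lines, "status=complete"), file.path(cfg$out_dir, "run_log.txt"))
  out$cohort <- cohort
  invisible(out)
}

config_hash <- function(cfg) {
  cfg$out_dir <- NULL          # hash the analysis content, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(cfg[order(names(cfg))])), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}
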