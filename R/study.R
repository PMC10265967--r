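## Cohort runner and the statistical comparison layer.

#' Run the shock-field pipeline over a cohort
#'
#' For every model x configuration pair: builds the electrode set, attaches
#' it to the model's lattice mesh (electrode-surface snapping), solves the
#' 10 V shock field, and derives DFT voltage/energy, impedance, mean
#' E-field and coverage.  Per model, the mesh, fibre field, stiffness
#' matrix and multigrid hierarchy are assembled once and reused across
#' configurations (electrode snapping enters as a local sparse stiffness
#' correction).  Results are cached on disk keyed by a content hash of all
#' inputs, making interrupted runs resumable.  Individual solve failures
#' are recorded and the run continues.
#'
#' @param cohort A cohort from [build_cohort()].
#' @param configurations Named list of [icd_configuration()] objects
#'   (default: the ten study configurations).
#' @param h Lattice spacing in mm (default 2.5).
#' @param sigma A [conductivity_map()].
#' @param criterion A [dft_criterion()].
#' @param tol Solver relative-residual tolerance.
#' @param cache_dir Cache directory; `NULL` disables caching.  Defaults to
#'   the user cache directory for this package.
#' @param current_method Electrode-current rule (see
#'   [electrode_currents()]).
#' @param verbose Print per-solve progress.
#' @return A data.frame with one row per model x configuration: metrics,
#'   solver diagnostics, and an `error` column for failed solves (metrics
#'   `NA`); failures are also attached as attribute `"failures"`.
#' @export
run_cohort <- function(cohort,
                       configurations = enumerate_study_configurations(),
                       h = 2.5, sigma = conductivity_map(),
                       criterion = dft_criterion(), tol = 1e-8,
                       cache_dir = tools::R_user_dir("torsodft", "cache"),
                       current_method = "reaction",
                       verbose = interactive()) {
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(configurations)))
    names(configurations) <- vapply(configurations, configuration_name,
                                    character(1))
  rows <- list()
  failures <- list()
  for (model in cohort) {
    mesh0 <- NULL; sys0 <- NULL; mg0 <- NULL; prev_ve <- NULL
    for (cfg_name in names(configurations)) {
      cfg <- configurations[[cfg_name]]
      key <- cache_key(model, cfg_name, h, sigma, criterion, tol,
                       current_method)
      cached <- cache_get(cache_dir, key)
      if (!is.null(cached)) {
        rows[[length(rows) + 1L]] <- cached
        next
      }
      t0 <- proc.time()[3]
      row <- tryCatch({
        if (is.null(mesh0)) {
          mesh0 <- tetrahedralize(model$phantom, NULL, h)
          mesh0 <- assign_fibers(mesh0, model$phantom)
          sys0 <- assemble_system(mesh0, sigma)
          mg0 <- mg_hierarchy(sys0$K, mesh0)
        }
        eset <- build_configuration(cfg, model$phantom)
        mesh_c <- attach_electrodes(mesh0, eset)
        dK <- delta_stiffness(sys0, mesh0, mesh_c)
        sys_c <- sys0
        sys_c$dK <- dK
        sol <- solve_shock(mesh_c, sigma, v_applied = criterion$v_applied,
                           system = sys_c, mg = mg0, method = "mg",
                           tol = tol, x0 = prev_ve)
        prev_ve <- sol$ve
        met <- shock_metrics(sol, mesh_c, sigma, criterion, system = sys_c,
                             current_method = current_method)
        cbind(data.frame(model_id = model$model_id, anatomy = model$anatomy,
                         variant = model$variant, configuration = cfg_name,
                         stringsAsFactors = FALSE),
              met,
              data.frame(solver_iters = sol$iters, solver_relres = sol$relres,
                         solve_seconds = unname(proc.time()[3] - t0),
                         error = NA_character_, stringsAsFactors = FALSE))
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- list(
          model_id = model$model_id, configuration = cfg_name,
          message = conditionMessage(e))
        warning("solve failed for ", model$model_id, " / ", cfg_name, ": ",
                conditionMessage(e), call. = FALSE)
        data.frame(model_id = model$model_id, anatomy = model$anatomy,
                   variant = model$variant, configuration = cfg_name,
                   dft_voltage_V = NA_real_, dft_energy_J = NA_real_,
                   impedance_ohm = NA_real_, mean_e_field_V_per_mm = NA_real_,
                   coverage = NA_real_, charge_imbalance = NA_real_,
                   solver_iters = NA_integer_, solver_relres = NA_real_,
                   solve_seconds = unname(proc.time()[3] - t0),
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      if (is.na(row$error)) cache_put(cache_dir, key, row)
      if (isTRUE(verbose))
        message(sprintf("%s / %-22s DFT %6.0f V  R %5.1f Ohm  [%.1fs]",
                        model$model_id, cfg_name, row$dft_voltage_V,
                        row$impedance_ohm, row$solve_seconds))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

cache_key <- function(model, cfg_name, h, sigma, criterion, tol,
                      current_method) {
  ## key on geometric content: the cohort seed only chooses scar
  ## territories, which are keyed explicitly below
  params <- unclass(model$phantom$params)
  params$seed <- NULL
  payload <- list(params = params,
                  variant = model$variant,
                  scar_territory = model$phantom$scar_territory,
                  scar_radius = model$phantom$scar_radius,
                  cfg = cfg_name, h = h, sigma = unclass(sigma),
                  criterion = unclass(criterion), tol = tol,
                  current_method = current_method, cache_version = 1L)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(payload, tf, version = 2)
  unname(tools::md5sum(tf))
}

cache_get <- function(cache_dir, key) {
  if (is.null(cache_dir)) return(NULL)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (!file.exists(f)) return(NULL)
  tryCatch(readRDS(f), error = function(e) NULL)
}

cache_put <- function(cache_dir, key, row) {
  if (is.null(cache_dir)) return(invisible(NULL))
  f <- file.path(cache_dir, paste0(key, ".rds"))
  tryCatch(saveRDS(row, f), error = function(e) NULL)
  invisible(f)
}

#' Summarize cohort results per configuration
#'
#' Median and inter-quartile bounds of the shock metrics, optionally also
#' split by heart variant.
#'
#' @param results Data.frame from [run_cohort()].
#' @param by Grouping columns (default `"configuration"`).
#' @param metrics Metric columns to summarize.
#' @return A long data.frame with `metric`, grouping columns, `n`,
#'   `median`, `q1`, `q3`.
#' @export
summarize_study <- function(results, by = "configuration",
                            metrics = c("dft_energy_J", "impedance_ohm",
                                        "mean_e_field_V_per_mm")) {
  ok <- results[is.na(results$error), , drop = FALSE]
  out <- list()
  groups <- split(ok, ok[by], drop = TRUE)
  for (gname in names(groups)) {
    g <- groups[[gname]]
    for (met in metrics) {
      qs <- stats::quantile(g[[met]], c(0.25, 0.5, 0.75), na.rm = TRUE,
                            names = FALSE)
      rec <- g[1, by, drop = FALSE]
      rec$metric <- met
      rec$n <- sum(!is.na(g[[met]]))
      rec$median <- qs[2]; rec$q1 <- qs[1]; rec$q3 <- qs[3]
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$metric), , drop = FALSE]
}

#' Paired comparison of two configurations
#'
#' Pairs the cohort models of two configurations and runs the Wilcoxon
#' signed-rank test on one metric, reporting medians and IQRs.
#'
#' @param results Data.frame from [run_cohort()].
#' @param config_a,config_b Configuration names to compare.
#' @param metric Metric column (default `"dft_energy_J"`).
#' @return One-row data.frame with medians, IQR bounds, the signed-rank
#'   statistic and the two-sided p-value.
#' @export
compare_configurations <- function(results, config_a, config_b,
                                   metric = "dft_energy_J") {
  ok <- results[is.na(results$error), , drop = FALSE]
  a <- ok[ok$configuration == config_a, c("model_id", metric)]
  b <- ok[ok$configuration == config_b, c("model_id", metric)]
  merged <- merge(a, b, by = "model_id", suffixes = c("_a", "_b"))
  xa <- merged[[paste0(metric, "_a")]]
  xb <- merged[[paste0(metric, "_b")]]
  wt <- paired_wilcoxon(xa, xb)
  qa <- stats::quantile(xa, c(0.25, 0.5, 0.75), names = FALSE)
  qb <- stats::quantile(xb, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(config_a = config_a, config_b = config_b, metric = metric,
             n = nrow(merged),
             median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
             median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
             statistic = wt$statistic, p_value = wt$p.value,
             stringsAsFactors = FALSE)
}

#' Tukey-style boxplot of a cohort metric per configuration
#'
#' @param results Data.frame from [run_cohort()].
#' @param metric Metric column to plot.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_study <- function(results, metric = "dft_energy_J") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_study() requires the ggplot2 package")
  ok <- results[is.na(results$error), , drop = FALSE]
  ggplot2::ggplot(ok, ggplot2::aes(x = .data$configuration,
                                   y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = metric)
}
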