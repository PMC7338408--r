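#' Compare measurement groups the way figure panels do
#'
#' Two groups: two-tailed unpaired Student's t test (equal variances).
#' More than two: one-way ANOVA followed by Bonferroni-adjusted pairwise
#' comparisons (pooled-SD t tests over all pairs). Group summaries are
#' reported as mean +/- s.e.m.
#'
#' @param values named list of numeric vectors, one per group (>= 2 groups,
#'   >= 2 values each).
#' @param measurement label for the quantity being compared.
#' @return object of class \code{group_comparison}: \code{test} used,
#'   \code{summary} (per-group n, mean, sd, sem), \code{statistic} (t or F),
#'   \code{p_value} (t test or ANOVA), and for multigroup designs
#'   \code{pairwise} (data.frame with raw and Bonferroni-adjusted p values).
#' @export
compare_groups <- function(values, measurement = "measurement") {
  if (!is.list(values) || length(values) < 2L)
    stop("`values` must be a named list of >= 2 groups")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("group labels must be non-empty")
  ns <- vapply(values, length, integer(1))
  if (any(ns < 2L))
    stop("every group needs >= 2 values (got ",
         paste(ns, collapse = ", "), ")")
  summ <- data.frame(
    group = names(values), n = ns,
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, stats::sd, numeric(1)))
  summ$sem <- summ$sd / sqrt(summ$n)
  long <- data.frame(
    value = unlist(values, use.names = FALSE),
    group = factor(rep(names(values), times = ns), levels = names(values)))
  if (length(values) == 2L) {
    tt <- stats::t.test(values[[1L]], values[[2L]], var.equal = TRUE,
                        alternative = "two.sided")
    out <- list(measurement = measurement, test = "two-tailed unpaired t test",
                summary = summ, statistic = unname(tt$statistic),
                p_value = tt$p.value, pairwise = NULL)
  } else {
    av <- stats::aov(value ~ group, data = long)
    ans <- summary(av)[[1L]]
    ptab <- stats::pairwise.t.test(long$value, long$group, pool.sd = TRUE,
                                   p.adjust.method = "none")$p.value
    pairs <- which(!is.na(ptab), arr.ind = TRUE)
    raw <- ptab[pairs]
    pw <- data.frame(
      group1 = rownames(ptab)[pairs[, 1L]],
      group2 = colnames(ptab)[pairs[, 2L]],
      p_raw = raw,
      p_adjusted = stats::p.adjust(raw, method = "bonferroni"))
    out <- list(measurement = measurement,
                test = "one-way ANOVA + Bonferroni pairwise",
                summary = summ,
                statistic = ans[["F value"]][1L],
                p_value = ans[["Pr(>F)"]][1L],
                pairwise = pw)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: %s\n", x$measurement, x$test))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s n=%-3d %.4g +/- %.4g (s.e.m.)\n",
                x$summary$group[i], x$summary$n[i], x$summary$mean[i],
                x$summary$sem[i]))
  cat(sprintf("  statistic = %.4g, p = %.4g\n", x$statistic, x$p_value))
  if (!is.null(x$pairwise))
    for (i in seq_len(nrow(x$pairwise)))
      cat(sprintf("  %s vs %s: adj. p = %.4g\n", x$pairwise$group1[i],
                  x$pairwise$group2[i], x$pairwise$p_adjusted[i]))
  invisible(x)
}

#' Read and validate an analysis configuration
#'
#' @param config path to a YAML/JSON config, or an equivalent list. Required
#'   fields: \code{seed}, \code{modules} (named list of module parameter
#'   blocks). Optional: \code{output_dir}, \code{files} (named paths that
#'   must exist).
#' @return validated config list (class \code{analysis_config}).
#' @export
read_analysis_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) jsonlite::fromJSON(config)
              else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$seed)) stop("config is missing `seed`")
  if (is.null(config$modules) || !length(config$modules))
    stop("config is missing `modules`")
  if (!is.null(config$files)) {
    missing <- !vapply(unlist(config$files), file.exists, logical(1))
    if (any(missing))
      stop("config references missing file(s): ",
           paste(unlist(config$files)[missing], collapse = ", "))
  }
  known <- c("permeability", "morphometry", "secretome", "mechanics",
             "transport", "stats")
  unknown <- setdiff(names(config$modules), known)
  if (length(unknown))
    stop("unknown module(s) in config: ", paste(unknown, collapse = ", "))
  structure(config, class = c("analysis_config", "list"))
}

#' Run the full quantification pipeline from a config
#'
#' Executes the requested module blocks over synthetic or supplied inputs,
#' writing tidy CSVs, JSON summaries and a structured log to
#' \code{output_dir}. Every stochastic step is seeded from the config seed,
#' so re-running an identical config is bit-identical. Per-module failures
#' are logged and reported without aborting the rest of the batch.
#'
#' Module blocks and their parameters (all optional with defaults):
#' \itemize{
#'   \item \code{permeability}: \code{true_PD}, \code{noise_sd} — generate a
#'     time-lapse and estimate P_D.
#'   \item \code{morphometry}: \code{n_cells}, \code{ki67_fraction},
#'     \code{golgi_angles}, \code{junctional_fraction}, \code{noise_sd} —
#'     render and quantify all morphometric statistics.
#'   \item \code{secretome}: \code{fold_changes} (named list),
#'     \code{noise_sd} — render duplicate membranes, quantify, normalize.
#'   \item \code{mechanics}: \code{E}, \code{n_curves}, \code{noise_sd} —
#'     generate indentation curves, fit, summarize.
#'   \item \code{transport}: \code{P_D}, \code{duration} — radial efflux
#'     with mass bookkeeping; and the 1D device gradient's time-to-half.
#'   \item \code{stats}: \code{groups} (named list of numeric vectors) —
#'     group comparison.
#' }
#'
#' @param config path or list (see \code{\link{read_analysis_config}}).
#' @param output_dir overrides the config's output directory.
#' @return result bundle (named list per module, with \code{$status}),
#'   invisibly; \code{attr(, "failed")} names any failed modules.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- read_analysis_config(config)
  out <- if (!is.null(output_dir)) output_dir
         else if (!is.null(cfg$output_dir)) cfg$output_dir
         else stop("no output directory given")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  log_lines <- character()
  logit <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  logit("ductflux %s | seed %d | modules: %s",
        as.character(utils::packageVersion("ductflux")), seed,
        paste(names(cfg$modules), collapse = ", "))
  results <- list()
  for (mod in names(cfg$modules)) {
    pars <- cfg$modules[[mod]]
    if (!is.list(pars)) pars <- list()
    res <- tryCatch({
      r <- switch(mod,
        permeability = pipe_permeability(pars, seed, out),
        morphometry = pipe_morphometry(pars, seed, out),
        secretome = pipe_secretome(pars, seed, out),
        mechanics = pipe_mechanics(pars, seed, out),
        transport = pipe_transport(pars, seed, out),
        stats = pipe_stats(pars, out))
      r$status <- "ok"
      logit("module %s: ok (%s)", mod,
            paste(names(pars), unlist(lapply(pars, function(p)
              paste(format(unlist(p)), collapse = "/"))),
              sep = "=", collapse = " "))
      r
    }, error = function(e) {
      logit("module %s: FAILED: %s", mod, conditionMessage(e))
      list(status = "failed", error = conditionMessage(e))
    })
    results[[mod]] <- res
  }
  summary <- lapply(results, function(r)
    r[setdiff(names(r), c("stack", "fit", "series"))])
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       force = TRUE)
  writeLines(log_lines, file.path(out, "pipeline.log"))
  failed <- names(results)[vapply(results, function(r)
    identical(r$status, "failed"), logical(1))]
  attr(results, "failed") <- failed
  if (length(failed))
    warning("module(s) failed: ", paste(failed, collapse = ", "))
  invisible(results)
}

pipe_permeability <- function(pars, seed, out) {
  spec <- synthetic_vessel_spec(
    true_PD = pars$true_PD %||% 1e-6,
    noise_sd = pars$noise_sd %||% 0, seed = seed)
  g <- generate_vessel_timelapse(spec)
  fit <- estimate_permeability(g$stack)
  utils::write.csv(fit$traces, file.path(out, "permeability_traces.csv"),
                   row.names = FALSE)
  write_permeability_json(fit, file.path(out, "permeability_fit.json"))
  plot_permeability_fit(fit, file.path(out, "permeability_qc.pdf"))
  list(true_PD = spec$true_PD, P_D = fit$P_D, r_squared = fit$r_squared,
       diameter_um = fit$geometry$diameter_um, fit = fit)
}

pipe_morphometry <- function(pars, seed, out) {
  spec <- synthetic_morphology_spec(
    n_cells = pars$n_cells %||% 25,
    ki67_fraction = pars$ki67_fraction %||% 0.2,
    golgi_angles = unlist(pars$golgi_angles %||% 30),
    junctional_fraction = pars$junctional_fraction %||% 0.5,
    noise_sd = pars$noise_sd %||% 0, seed = seed)
  g <- generate_morphology_image(spec)
  cells <- g$truth$params$cells
  kf <- ki67_fraction(g$stack)
  scores <- vapply(seq_len(nrow(cells)), function(i) {
    pr <- extract_line_profile(
      g$stack,
      list(c(cells$profile_x1[i], cells$profile_y1[i]),
           c(cells$profile_x2[i], cells$profile_y2[i])),
      channel = "actin", id = as.character(cells$cell[i]))
    junctional_actin_score(pr)
  }, numeric(1))
  angles <- vapply(seq_len(nrow(cells)), function(i)
    golgi_polarity_angle(c(cells$x[i], cells$y[i]),
                         c(cells$gm130_x[i], cells$gm130_y[i]),
                         c(cells$apical_x[i], cells$apical_y[i]))$angle,
    numeric(1))
  tidy <- data.frame(cell = cells$cell, junctional_score = scores,
                     golgi_angle = angles,
                     ki67_positive_truth = cells$ki67_positive)
  utils::write.csv(tidy, file.path(out, "morphometry_cells.csv"),
                   row.names = FALSE)
  list(ki67_fraction = kf$fraction, ki67_truth = g$truth$params$true_ki67_fraction,
       mean_junctional_score = mean(scores),
       expected_junctional_score = g$truth$params$expected_junctional_score,
       mean_golgi_angle = mean(angles))
}

pipe_secretome <- function(pars, seed, out) {
  layout <- cytokine_array_layout()
  folds <- unlist(pars$fold_changes %||% list(CK1 = 3))
  g <- generate_cytokine_array(layout, fold_changes = folds, seed = seed,
                               noise_sd = pars$noise_sd %||% 0)
  ev <- quantify_array(g$stack, layout, channel = "ev")
  mut <- quantify_array(g$stack, layout, channel = "mutant")
  df <- write_array_csv(mut, ev, file.path(out, "secretome.csv"))
  list(relative_secretion = as.list(stats::setNames(
    df$relative_secretion, df$cytokine)),
    expected = g$truth$params$expected_normalized)
}

pipe_mechanics <- function(pars, seed, out) {
  E <- pars$E %||% 130
  n <- pars$n_curves %||% 6
  fits <- vapply(seq_len(n), function(i) {
    g <- generate_indentation_curve(E, noise_sd = pars$noise_sd %||% 2e-9,
                                    seed = seed + i)
    fit_hertz(g$curve)$E
  }, numeric(1))
  s <- summarize_stiffness(fits)
  utils::write.csv(data.frame(curve = seq_len(n), E_pa = fits),
                   file.path(out, "stiffness_fits.csv"), row.names = FALSE)
  list(E_true = E, E_mean = s$mean, E_sd = s$sd, n = s$n)
}

pipe_transport <- function(pars, seed, out) {
  dom <- transport_domain(grid_spacing = 2, extent = 600,
                          vascular = list(center = c(0, 0), diameter = 160),
                          duct = list(center = c(500, 0), diameter = 160))
  es <- simulate_radial_efflux(dom, P_D = pars$P_D %||% 1e-6,
                               duration = pars$duration %||% 300)
  gd <- simulate_device_gradient(
    transport_domain(grid_spacing = 5, extent = 500, D = 1e-6),
    source_conc = 1, duration = 4000, dimension = "1d")
  utils::write.csv(es$bookkeeping[seq(1, nrow(es$bookkeeping),
                                      length.out = 301), ],
                   file.path(out, "efflux_bookkeeping.csv"),
                   row.names = FALSE)
  list(mass_conservation_error = mass_conservation_error(es),
       gradient_time_to_half_s = gd$time_to_half,
       midpoint_steady = stats::approx(steady_profile(gd)$position,
                                       steady_profile(gd)$conc, 250)$y)
}

pipe_stats <- function(pars, out) {
  groups <- lapply(pars$groups %||% list(a = c(1, 2, 3), b = c(2, 3, 4)),
                   unlist)
  gc <- compare_groups(groups, measurement = pars$measurement %||% "demo")
  utils::write.csv(gc$summary, file.path(out, "group_summary.csv"),
                   row.names = FALSE)
  list(test = gc$test, statistic = gc$statistic, p_value = gc$p_value,
       pairwise = gc$pairwise)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
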