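#' Read a concentration CSV
#'
#' Reads the schema written by [write_concentration_csv()]: a `site_id`
#' column followed by numeric metal columns. Metal names are matched
#' case-insensitively against the reference-dose table and normalized to its
#' spelling. Missing cells, negative values and metals without a reference
#' dose are errors.
#'
#' @param path CSV file path
#' @param rfd reference-dose table used for metal-name validation
#' @return site x metal numeric matrix with canonical metal column names
#' @export
read_concentration_csv <- function(path, rfd = rfd_table()) {
  if (!file.exists(path)) stop_dustrisk("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"site_id" %in% names(df)) stop_dustrisk("missing 'site_id' column in %s", path)
  metals_in <- setdiff(names(df), "site_id")
  if (length(metals_in) == 0) stop_dustrisk("no metal columns in %s", path)
  for (m in metals_in) {
    col <- df[[m]]
    if (is.character(col)) col <- suppressWarnings(as.numeric(ifelse(col == "", NA, col)))
    bad <- which(is.na(col))
    if (length(bad))
      stop_dustrisk("missing or non-numeric value at row %d, column '%s'", bad[1], m)
    if (any(col < 0)) stop_dustrisk("negative concentration at row %d, column '%s'",
                                    which(col < 0)[1], m)
    df[[m]] <- col
  }
  idx <- match(tolower(metals_in), tolower(rfd$metal))
  if (anyNA(idx))
    stop_dustrisk("unknown metal(s): %s (known: %s)",
                  paste(metals_in[is.na(idx)], collapse = ", "),
                  paste(rfd$metal, collapse = ", "))
  conc <- as.matrix(df[metals_in])
  colnames(conc) <- rfd$metal[idx]
  rownames(conc) <- as.character(df$site_id)
  conc
}

#' Cluster-versus-risk concordance report
#'
#' Summarizes the hazard index within each embedding cluster (mean, min,
#' max, members), ranks clusters by mean HI, and cross-tabulates cluster
#' membership against empirical HI terciles (tercile boundaries assigned to
#' the lower band).
#'
#' @param hi named numeric vector of per-site hazard indices, or the
#'   data.frame from [hazard_index()]
#' @param labels a `cluster_assignment` or an integer vector of labels named
#'   (or ordered) like `hi`
#' @return An object of class `concordance_report`: `per_cluster`
#'   (data.frame), `ranking` (cluster ids by decreasing mean HI),
#'   `degenerate` (all-tied flag), `tercile_table`.
#' @export
concordance_report <- function(hi, labels) {
  if (is.data.frame(hi)) hi <- stats::setNames(hi$HI, hi$site_id)
  lab <- if (inherits(labels, "cluster_assignment")) labels$labels else as.vector(labels)
  if (length(lab) != length(hi))
    stop_dustrisk("site sets differ: %d HI values vs %d labels", length(hi), length(lab))
  cl <- sort(unique(lab))
  per <- do.call(rbind, lapply(cl, function(g) {
    v <- hi[lab == g]
    data.frame(cluster = g, n = length(v), mean_HI = mean(v),
               min_HI = min(v), max_HI = max(v),
               members = paste(names(v), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  ranking <- per$cluster[order(per$mean_HI, decreasing = TRUE)]
  degenerate <- max(hi) - min(hi) < 1e-12
  q <- stats::quantile(hi, c(1 / 3, 2 / 3), type = 7)
  brks <- unique(c(-Inf, q, Inf))   # heavy ties can collapse a tercile band
  terc <- cut(hi, breaks = brks,
              labels = c("low", "mid", "high")[seq_len(length(brks) - 1)],
              right = TRUE)
  structure(list(per_cluster = per, ranking = ranking, degenerate = degenerate,
                 tercile_table = table(cluster = lab, tercile = terc)),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Cluster vs hazard-index concordance\n")
  print(x$per_cluster[, c("cluster", "n", "mean_HI", "min_HI", "max_HI")])
  cat("  ranking by mean HI:", paste(x$ranking, collapse = " > "),
      if (x$degenerate) "(degenerate: all HI equal)" else "", "\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the package's standard settings. `input` may be a CSV path or `NULL`, in
#' which case `synthetic` (a [synthetic_config()]) supplies the data.
#'
#' @param input path to a concentration CSV, or `NULL`
#' @param synthetic a [synthetic_config()] used when `input` is `NULL`
#' @param exposure an [exposure_factors()] object
#' @param rfd reference-dose table
#' @param cumvar_threshold PCA cumulative-variance threshold
#' @param fa_m factor count, or `"auto"` for the BIC rule
#' @param tsne a [tsne_params()] object
#' @param opt_objectives character subset of kl / silhouette / sammon
#' @param opt_budget evaluation budget per objective
#' @param cluster_k cluster count or `"auto"`
#' @param stages character vector of stages to run, from
#'   `c("risk", "pca", "fa", "tsne", "opt", "cluster")`
#' @param outdir output directory
#' @param seed master seed; stage seeds derive from it deterministically
#' @param advisory_hi advisory HI band boundary reported in the concordance
#'   output (screening threshold stays the strict HI > 1)
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = synthetic_config(),
                            exposure = exposure_factors(), rfd = rfd_table(),
                            cumvar_threshold = 0.8, fa_m = "auto",
                            tsne = tsne_params(),
                            opt_objectives = "kl", opt_budget = 30,
                            cluster_k = "auto",
                            stages = c("risk", "pca", "fa", "tsne", "opt", "cluster"),
                            outdir = tempfile("dustrisk_run_"), seed = 1,
                            advisory_hi = 0.5) {
  stages <- match.arg(stages, c("risk", "pca", "fa", "tsne", "opt", "cluster"),
                      several.ok = TRUE)
  structure(list(input = input, synthetic = synthetic, exposure = exposure,
                 rfd = rfd, cumvar_threshold = cumvar_threshold, fa_m = fa_m,
                 tsne = tsne, opt_objectives = opt_objectives,
                 opt_budget = opt_budget, cluster_k = cluster_k,
                 stages = stages, outdir = outdir, seed = as.integer(seed),
                 advisory_hi = advisory_hi),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `exposure.*`
#' keys override individual exposure factors and `rfd.<metal>.<path>` keys
#' override individual reference doses.
#'
#' @param path YAML or JSON file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  exp_over <- raw$exposure %||% list()
  f <- do.call(exposure_factors, exp_over)
  rfd <- rfd_table()
  for (m in names(raw$rfd %||% list())) {
    i <- match(tolower(m), tolower(rfd$metal))
    if (is.na(i)) stop_dustrisk("rfd override for unknown metal '%s'", m)
    for (pth in names(raw$rfd[[m]])) rfd[i, pth] <- raw$rfd[[m]][[pth]]
  }
  args <- list(exposure = f, rfd = rfd)
  for (key in c("input", "cumvar_threshold", "fa_m", "opt_objectives",
                "opt_budget", "cluster_k", "stages", "outdir", "seed",
                "advisory_hi"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  if (!is.null(raw$tsne)) args$tsne <- do.call(tsne_params, raw$tsne)
  if (!is.null(raw$synthetic)) args$synthetic <- do.call(synthetic_config, raw$synthetic)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the selected stages in order — risk (ADD/HQ/HI), PCA with
#' component selection, factor analysis with retention battery, t-SNE,
#' hyperparameter optimization, clustering with quality metrics and the
#' cluster-versus-risk concordance report — writing each stage's tables to
#' `config$outdir` along with `run_manifest.json` (configuration echo, seed,
#' per-stage wall time and status). A failed stage is recorded and the
#' stages depending on it are skipped.
#'
#' Stage seeds are derived from the master seed by a fixed counter scheme
#' (`derive(master, stage_index)`), so runs are reproducible end to end
#' while stages stay independent.
#'
#' @param config a [pipeline_config()]
#' @return (invisibly) list with `outdir`, `success`, `results` (per-stage
#'   objects), `manifest`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list(),
                   r_version = as.character(getRversion()),
                   package_version = as.character(utils::packageVersion("dustrisk")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  results <- list()
  failed <- character(0)

  run_stage <- function(name, deps, fun) {
    if (!name %in% c(config$stages, "input", "concordance")) {
      manifest$stages[[name]] <<- list(status = "not requested"); return(invisible(NULL))
    }
    if (length(intersect(deps, failed))) {
      failed <<- c(failed, name)
      manifest$stages[[name]] <<- list(status = "skipped",
                                       reason = sprintf("dependency failed: %s",
                                                        paste(intersect(deps, failed), collapse = ",")))
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(out, "error")) {
      failed <<- c(failed, name)
      manifest$stages[[name]] <<- list(status = "failed", message = conditionMessage(out),
                                       seconds = round(dt, 3))
      message(sprintf("[dustrisk] stage %s FAILED: %s", name, conditionMessage(out)))
    } else {
      results[[name]] <<- out
      manifest$stages[[name]] <<- list(status = "ok", seconds = round(dt, 3))
      message(sprintf("[dustrisk] stage %-6s ok (%.2fs, seed %d)", name, dt, config$seed))
    }
    invisible(NULL)
  }

  # -- input ----------------------------------------------------------------
  run_stage("input", character(0), function() {
    if (!is.null(config$input)) read_concentration_csv(config$input, config$rfd)
    else {
      ds <- generate_dataset(config$synthetic)
      write_concentration_csv(ds, file.path(outdir, "concentrations.csv"))
      ds$concentrations
    }
  })
  conc <- results$input

  # -- risk -----------------------------------------------------------------
  run_stage("risk", "input", function() {
    hz <- hazard_quotients(conc, config$exposure, config$rfd)
    add_long <- as.data.frame.table(hz$ADD, responseName = "value")
    names(add_long) <- c("site_id", "metal", "path", "value")
    utils::write.csv(add_long, file.path(outdir, "hazard_add.csv"), row.names = FALSE)
    hq_long <- as.data.frame.table(hz$HQ_path, responseName = "value")
    names(hq_long) <- c("site_id", "metal", "path", "value")
    utils::write.csv(hq_long, file.path(outdir, "hazard_hq.csv"), row.names = FALSE)
    utils::write.csv(hazard_index(hz), file.path(outdir, "hazard_hi.csv"), row.names = FALSE)
    utils::write.csv(summarize_add(hz), file.path(outdir, "add_summary.csv"), row.names = FALSE)
    hz
  })

  z <- NULL
  if (any(c("pca", "fa", "tsne", "opt", "cluster") %in% config$stages) &&
      !"input" %in% failed)
    z <- tryCatch(standardize(conc), error = function(e) { failed <<- c(failed, "input"); NULL })

  # -- pca ------------------------------------------------------------------
  run_stage("pca", "input", function() {
    model <- pca_fit(z)
    sel <- select_components(model, cumvar_threshold = config$cumvar_threshold)
    utils::write.csv(scree_table(model), file.path(outdir, "pca_eigen.csv"), row.names = FALSE)
    utils::write.csv(data.frame(site_id = rownames(model$scores), model$scores),
                     file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(metal = rownames(model$cos2_variables), model$cos2_variables),
                     file.path(outdir, "pca_cos2.csv"), row.names = FALSE)
    utils::write.csv(data.frame(metal = rownames(model$contributions), model$contributions),
                     file.path(outdir, "pca_contrib.csv"), row.names = FALSE)
    write_json_file(list(kaiser_k = sel$kaiser_k, cumvar_k = sel$cumvar_k,
                         cumvar_threshold = sel$cumvar_threshold,
                         aic_k = sel$aic_k, bic_k = sel$bic_k,
                         aic_threshold = sel$aic_threshold,
                         bic_threshold = sel$bic_threshold,
                         aic_threshold_k = sel$aic_threshold_k,
                         bic_threshold_k = sel$bic_threshold_k,
                         aic_curve = unname(sel$aic_curve),
                         bic_curve = unname(sel$bic_curve)),
                    file.path(outdir, "pca_selection.json"))
    list(model = model, selection = sel)
  })

  # -- fa -------------------------------------------------------------------
  run_stage("fa", "input", function() {
    n <- nrow(z)
    sel <- select_m(data = z, n = n, seed = derive_seed(config$seed, 2))
    m <- if (identical(config$fa_m, "auto")) sel$default_m else config$fa_m
    fit <- suppressWarnings(fa_fit(stats::cor(z), m, n))
    tab <- data.frame(metal = rownames(fit$loadings), round(fit$loadings, 4),
                      h2 = fit$h2, u2 = fit$u2, com = fit$com)
    utils::write.csv(tab, file.path(outdir, "fa_loadings.csv"), row.names = FALSE)
    write_json_file(list(m = m, chi_square = fit$fit$chi_square, df = fit$fit$df,
                         p_value = fit$fit$p_value, RMSR = fit$fit$RMSR,
                         TLI = fit$fit$TLI, BIC = fit$fit$BIC, AIC = fit$fit$AIC,
                         bic_ln_n = fit$fit$bic_ln_n,
                         heywood = fit$heywood,
                         factor_corr = fit$factor_corr,
                         score_adequacy = fit$score_adequacy),
                    file.path(outdir, "fa_fit.json"))
    write_json_file(list(selected = sel$selected_m, default_m = sel$default_m,
                         aic_curve = sel$aic_curve, bic_curve = sel$bic_curve,
                         vss_c1 = unname(sel$vss_curve["c1", ]),
                         vss_c2 = unname(sel$vss_curve["c2", ]),
                         pa_retained = sel$parallel$pa_retained,
                         random_eigen_means = sel$parallel$random_eigen_means),
                    file.path(outdir, "fa_selection.json"))
    list(fit = fit, selection = sel)
  })

  # -- tsne -----------------------------------------------------------------
  run_stage("tsne", "input", function() {
    params <- config$tsne
    params$seed <- derive_seed(config$seed, 3)
    emb <- tsne_run(z, params)
    utils::write.csv(data.frame(site_id = rownames(emb$Y), emb$Y),
                     file.path(outdir, "tsne_embedding.csv"), row.names = FALSE)
    utils::write.csv(data.frame(iteration = seq_along(emb$kl_trace), kl = emb$kl_trace),
                     file.path(outdir, "tsne_trace.csv"), row.names = FALSE)
    emb
  })

  # -- opt ------------------------------------------------------------------
  run_stage("opt", "input", function() {
    opts <- list()
    for (obj in config$opt_objectives) {
      res <- optimize_tsne(z, objective = obj, budget = config$opt_budget,
                           seed = derive_seed(config$seed, 4),
                           max_iter = config$tsne$max_iter,
                           defaults = config$tsne)
      tr <- res$trace
      tr$objective_name <- obj
      utils::write.csv(tr, file.path(outdir, sprintf("bayesopt_trace_%s.csv", obj)),
                       row.names = FALSE)
      opts[[obj]] <- res
    }
    opts
  })

  # -- cluster + concordance ------------------------------------------------
  run_stage("cluster", "input", function() {
    emb <- if (!is.null(results$opt)) {
      best <- results$opt[[config$opt_objectives[1]]]
      tsne_run(z, best$best_params)
    } else if (!is.null(results$tsne)) results$tsne
    else {
      params <- config$tsne
      params$seed <- derive_seed(config$seed, 3)
      tsne_run(z, params)
    }
    cl <- assign_clusters(emb$Y, k = config$cluster_k, seed = derive_seed(config$seed, 5))
    utils::write.csv(data.frame(site_id = rownames(emb$Y), cluster = cl$labels),
                     file.path(outdir, "cluster_labels.csv"), row.names = FALSE)
    qr <- quality_report(z, emb$Y, cl$labels)
    write_json_file(list(k = cl$k, intra_per_cluster = as.list(qr$intra_per_cluster),
                         inter_mean = qr$inter_mean,
                         silhouette_mean = qr$silhouette_mean,
                         sammon_error = qr$sammon_error),
                    file.path(outdir, "cluster_quality.json"))
    conc_rep <- NULL
    if (!is.null(results$risk)) {
      conc_rep <- concordance_report(hazard_index(results$risk), cl)
      write_json_file(list(per_cluster = conc_rep$per_cluster,
                           ranking = conc_rep$ranking,
                           degenerate = conc_rep$degenerate,
                           advisory_hi = config$advisory_hi,
                           sites_above_advisory = sum(results$risk$HI > config$advisory_hi),
                           tercile_table = as.data.frame(conc_rep$tercile_table)),
                      file.path(outdir, "concordance.json"))
    }
    list(assignment = cl, quality = qr, concordance = conc_rep, embedding = emb)
  })

  manifest$config <- list(
    input = config$input %||% "synthetic", seed = config$seed,
    stages = config$stages, cumvar_threshold = config$cumvar_threshold,
    fa_m = config$fa_m, opt_objectives = config$opt_objectives,
    opt_budget = config$opt_budget, cluster_k = config$cluster_k,
    tsne = unclass(config$tsne), exposure = unclass(config$exposure))
  manifest$failed <- failed
  manifest$success <- length(failed) == 0
  write_json_file(manifest, file.path(outdir, "run_manifest.json"))
  invisible(list(outdir = outdir, success = length(failed) == 0,
                 results = results, manifest = manifest))
}
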