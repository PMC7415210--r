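#' Configuration for an end-to-end pipeline run
#'
#' @param mode `"synthetic"` (generate a cohort first) or `"directory"`
#'   (consume an existing cohort directory with one TSV per participant and a
#'   `manifest.csv`).
#' @param generator a [generator_config()] (synthetic mode).
#' @param input_dir cohort directory (directory mode).
#' @param out_dir output directory for all artifacts.
#' @param window a [window_params()].
#' @param k_min,k_max scanned cluster-number range.
#' @param replicates k-means restarts per k.
#' @param threshold_sd exemplar selection threshold in SD units.
#' @param k optional fixed number of states; when given, the model-selection
#'   scan is skipped and exemplar centroids for this k seed the final
#'   clustering.
#' @param alpha significance level for scalar tests.
#' @param q FDR level.
#' @param covariates covariate column names in the manifest.
#' @param seed master seed; every random draw in the run flows from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "directory"),
                       generator = generator_config(),
                       input_dir = NULL,
                       out_dir,
                       window = window_params(),
                       k_min = 2, k_max = 9, replicates = 100,
                       threshold_sd = 1.5,
                       k = NULL,
                       alpha = 0.05, q = 0.05,
                       covariates = c("age", "sex"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "directory") {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop("directory mode requires an existing input_dir")
    }
    if (!file.exists(file.path(input_dir, "manifest.csv"))) {
      stop("manifest.csv not found in ", input_dir)
    }
  }
  structure(list(mode = mode, generator = generator, input_dir = input_dir,
                 out_dir = out_dir, window = window, k_min = k_min,
                 k_max = k_max, replicates = replicates,
                 threshold_sd = threshold_sd, k = k, alpha = alpha, q = q,
                 covariates = covariates, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full dynamic-FC pipeline
#'
#' Synthesize or load a cohort, build sliding-window FC, detect states
#' (exemplar subsampling, optional cluster-number scan, final L1 k-means),
#' compute per-state FC and temporal properties, nodal temporal variability,
#' and the group-statistics layer; write all artifacts plus a run manifest
#' into `config$out_dir`. Identical config and seed give identical numeric
#' outputs. Any stage error aborts with the stage name; artifacts already
#' written are retained.
#'
#' @param config a [run_config()].
#' @return (invisibly) the output directory path.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "log.txt")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    logmsg("stage: ", name)
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  warnings_seen <- character(0)
  note_warning <- function(w) {
    warnings_seen <<- c(warnings_seen, conditionMessage(w))
    cat("warning: ", conditionMessage(w), "\n", file = log_path,
        append = TRUE, sep = "")
    invokeRestart("muffleWarning")
  }

  set.seed(config$seed)
  seeds <- setNames(as.list(draw_subseeds(4)),
                    c("generator", "model_selection", "reserved1",
                      "reserved2"))

  # --- input ----------------------------------------------------------------
  if (config$mode == "synthetic") {
    gen <- config$generator
    gen$seed <- seeds$generator
    cohort_dir <- file.path(out, "cohort")
    stage("simulate", generate_cohort(gen, cohort_dir))
  } else {
    cohort_dir <- config$input_dir
  }
  manifest <- read.csv(file.path(cohort_dir, "manifest.csv"),
                       stringsAsFactors = FALSE)

  # --- windows --------------------------------------------------------------
  wfc_list <- stage("windows", withCallingHandlers(
    cohort_windows(cohort_dir, manifest, config$window),
    warning = note_warning))
  n_win <- vapply(wfc_list, n_windows, integer(1))
  logmsg("windows: ", length(wfc_list), " participants x ", n_win[1],
         " windows (", sum(n_win), " matrices)")

  # --- state detection ------------------------------------------------------
  exemplars <- stage("exemplars", withCallingHandlers(
    select_exemplars(wfc_list, config$threshold_sd),
    warning = note_warning))
  logmsg("exemplars: ", nrow(exemplars$vectors), " windows selected")

  if (is.null(config$k)) {
    ms <- stage("model_selection", withCallingHandlers(
      evaluate_k_range(exemplars, config$k_min, config$k_max,
                       config$replicates, seed = seeds$model_selection),
      warning = note_warning))
    k <- as.integer(ms$chosen_k)
    init <- ms$best[[match(k, ms$curves$k)]]$centroids
    jsonlite::write_json(
      list(curves = ms$curves, chosen_k = k,
           silhouette_elbow_k = ms$silhouette_elbow_k,
           criteria_agree = ms$agree, replicates = ms$replicates,
           seed = ms$seed),
      file.path(out, "model_selection.json"), auto_unbox = TRUE,
      digits = NA, dataframe = "columns")
  } else {
    k <- as.integer(config$k)
    set.seed(seeds$model_selection)
    fit_best <- NULL
    for (r in seq_len(max(10, config$replicates %/% 10))) {
      fit <- kmedians_l1(exemplars$vectors, k)
      if (is.null(fit_best) || fit$cost < fit_best$cost) fit_best <- fit
    }
    init <- fit_best$centroids
    jsonlite::write_json(list(fixed_k = k, seed = seeds$model_selection),
                         file.path(out, "model_selection.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  model <- stage("final_clustering", final_clustering(wfc_list, init))
  if (model$reseeds > 0) logmsg("empty-cluster reseeds: ", model$reseeds)

  labels_df <- data.frame(
    participant = model$participant,
    window_index = unlist(lapply(n_win, seq_len)),
    state = model$labels_flat)
  write.csv(labels_df, file.path(out, "labels.csv"), row.names = FALSE,
            quote = FALSE)
  p <- wfc_list[[1]]$n_regions
  for (s in seq_len(k)) {
    write_matrix_tsv(file.path(out, sprintf("centroid_state%d.tsv", s)),
                     devectorize_upper(model$centroids[s, ], p),
                     wfc_list[[1]]$region_labels)
  }

  # --- state metrics --------------------------------------------------------
  sfc_list <- stage("state_fc", lapply(seq_along(wfc_list), function(i) {
    participant_state_fc(wfc_list[[i]], model$labels[[i]], k)
  }))
  props <- stage("temporal_properties", lapply(seq_along(wfc_list), function(i) {
    temporal_properties(model$labels[[i]], k, id = wfc_list[[i]]$id)
  }))
  groups <- manifest$group[match(vapply(props, `[[`, "", "id"), manifest$id)]
  grp_summary <- group_temporal_summary(props, groups)

  freq_names <- outer(seq_len(k), seq_len(k),
                      function(a, b) sprintf("freq_%d_to_%d", a, b))
  props_df <- do.call(rbind, lapply(seq_along(props), function(i) {
    pr <- props[[i]]
    row <- data.frame(id = pr$id, group = groups[i], t(pr$dwell),
                      transitions = pr$transitions)
    fr <- as.data.frame(t(as.numeric(pr$frequencies)))
    names(fr) <- as.character(freq_names)
    cbind(row, fr)
  }))
  names(props_df)[3:(2 + k)] <- paste0("dwell_", seq_len(k))
  write_tsv(props_df, file.path(out, "temporal_properties.csv"), sep = ",")

  # --- temporal variability -------------------------------------------------
  profiles <- stage("variability", lapply(wfc_list, temporal_variability))
  var_df <- data.frame(id = vapply(profiles, `[[`, "", "id"),
                       group = groups,
                       do.call(rbind, lapply(profiles, `[[`, "v")))
  write_tsv(var_df, file.path(out, "variability.csv"), sep = ",")
  jsonlite::write_json(lapply(profiles, function(pf)
    list(id = pf$id, valid = as.logical(pf$valid))),
    file.path(out, "variability_validity.json"), auto_unbox = TRUE)

  # --- statistics -----------------------------------------------------------
  demo <- stage("demographics", demographics_table(manifest))
  write_tsv(demo, file.path(out, "demographics.tsv"))

  edge_results <- stage("edgewise_glm", withCallingHandlers(
    lapply(seq_len(k), function(s) {
      edgewise_glm(sfc_list, manifest, s, q = config$q,
                   covariates = config$covariates)
    }), warning = note_warning))
  for (s in seq_len(k)) {
    if (!is.null(edge_results[[s]])) {
      write_tsv(edge_results[[s]],
                file.path(out, sprintf("edges_state%d.tsv", s)))
    }
  }

  # temporal-property tests: one FDR family over k dwell times, the
  # transition count, and the k(k-1) off-diagonal transition frequencies
  prop_tests <- stage("temporal_stats", {
    tests <- list()
    for (s in seq_len(k)) {
      rt <- adjusted_rank_test(props_df[[paste0("dwell_", s)]],
                               props_df$group,
                               manifest[match(props_df$id, manifest$id),
                                        config$covariates, drop = FALSE])
      tests[[paste0("dwell_", s)]] <- rt
    }
    tests$transitions <- adjusted_rank_test(
      props_df$transitions, props_df$group,
      manifest[match(props_df$id, manifest$id), config$covariates,
               drop = FALSE])
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b) next
      colname <- sprintf("freq_%d_to_%d", a, b)
      v <- props_df[[colname]]
      tests[[colname]] <- if (sd(v) == 0) list(U = NA, p = 1) else
        adjusted_rank_test(v, props_df$group,
                           manifest[match(props_df$id, manifest$id),
                                    config$covariates, drop = FALSE])
    }
    ps <- vapply(tests, `[[`, numeric(1), "p")
    fdr <- bh_fdr(ps, config$q)
    for (i in seq_along(tests)) {
      tests[[i]]$p_fdr <- fdr$adjusted[i]
      tests[[i]]$significant <- fdr$reject[i]
    }
    tests
  })
  jsonlite::write_json(prop_tests, file.path(out, "temporal_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  var_stats <- stage("variability_stats",
                     variability_glm(profiles, manifest, q = config$q,
                                     covariates = config$covariates))
  write_tsv(var_stats, file.path(out, "variability_stats.tsv"))

  # ROC on the median strength of significant edges, per state x direction.
  # Selection and classification reuse the same sample, as in the source
  # analysis; interpret AUCs as descriptive, not out-of-sample.
  roc <- stage("roc", {
    res <- list()
    for (s in seq_len(k)) {
      er <- edge_results[[s]]
      if (is.null(er)) next
      for (dir in c("patient>control", "patient<control")) {
        sig <- er[er$significant & er$direction == dir, , drop = FALSE]
        if (nrow(sig) == 0) next
        scores <- median_significant_strength(sfc_list, sig, s)
        grp <- manifest$group[match(names(scores), manifest$id)]
        auc <- roc_auc(scores, grp)
        res[[sprintf("state%d_%s", s,
                     ifelse(dir == "patient>control", "increased",
                            "decreased"))]] <-
          list(auc = as.numeric(auc),
               orientation = attr(auc, "orientation"),
               n_edges = nrow(sig), n_participants = length(scores))
      }
    }
    res
  })
  jsonlite::write_json(roc, file.path(out, "roc.json"), auto_unbox = TRUE,
                       digits = NA)

  pcor <- stage("partial_correlations",
                partial_correlation_table(sfc_list, edge_results, props_df,
                                          profiles, var_stats, manifest,
                                          config$covariates, k))
  write_tsv(pcor, file.path(out, "partialcorr.tsv"))

  # --- summary --------------------------------------------------------------
  n_sig_edges <- vapply(seq_len(k), function(s) {
    er <- edge_results[[s]]
    if (is.null(er)) NA_integer_ else sum(er$significant)
  }, integer(1))
  skipped_states <- which(is.na(n_sig_edges))
  summary <- list(
    n_participants = nrow(manifest),
    n_regions = p,
    n_windows_per_participant = n_win[1],
    n_windows_total = sum(n_win),
    window_length_tr = config$window$window_length,
    window_step_tr = config$window$step,
    chosen_k = k,
    state_strength = model$strength,
    group_mean_dwell = lapply(grp_summary, `[[`, "mean_dwell"),
    group_mean_transitions = lapply(grp_summary, `[[`, "mean_transitions"),
    n_significant_edges = as.list(setNames(n_sig_edges,
                                           paste0("state", seq_len(k)))),
    skipped_states = skipped_states,
    n_significant_variability_regions = sum(var_stats$significant),
    roc = roc,
    warnings = warnings_seen,
    seed = config$seed)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run_config_echo(config),
                       file.path(out, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  logmsg("done")
  invisible(out)
}

partial_correlation_table <- function(sfc_list, edge_results, props_df,
                                      profiles, var_stats, manifest,
                                      covariates, k) {
  pat <- manifest[manifest$group == "patient", , drop = FALSE]
  rows <- list()
  add <- function(indicator, values_by_id, score_name) {
    ids <- intersect(names(values_by_id), pat$id)
    if (length(ids) < length(covariates) + 3) return()
    x <- values_by_id[ids]
    y <- pat[[score_name]][match(ids, pat$id)]
    cov <- pat[match(ids, pat$id), covariates, drop = FALSE]
    pc <- tryCatch(partial_correlation(x, y, cov), error = function(e) NULL)
    if (is.null(pc)) return()
    rows[[length(rows) + 1]] <<- data.frame(
      indicator = indicator, score = score_name, r = pc$r, p = pc$p,
      n = pc$n, stringsAsFactors = FALSE)
  }
  scores <- intersect(c("MMSE", "NPI"), names(manifest))

  for (s in seq_len(k)) {
    er <- edge_results[[s]]
    if (is.null(er)) next
    for (dir in c("patient>control", "patient<control")) {
      sig <- er[er$significant & er$direction == dir, , drop = FALSE]
      if (nrow(sig) == 0) next
      vals <- median_significant_strength(sfc_list, sig, s)
      lab <- sprintf("median_FC_state%d_%s", s,
                     ifelse(dir == "patient>control", "increased",
                            "decreased"))
      for (sc in scores) add(lab, vals, sc)
    }
  }
  for (s in seq_len(k)) {
    vals <- setNames(props_df[[paste0("dwell_", s)]], props_df$id)
    for (sc in scores) add(sprintf("dwell_state%d", s), vals, sc)
  }
  vals <- setNames(props_df$transitions, props_df$id)
  for (sc in scores) add("transitions", vals, sc)

  sig_regions <- var_stats$region[var_stats$significant]
  ids <- vapply(profiles, `[[`, "", "id")
  for (reg in sig_regions) {
    vals <- setNames(vapply(profiles, function(pf) pf$v[[reg]], numeric(1)),
                     ids)
    for (sc in scores) add(sprintf("variability_%s", reg), vals, sc)
  }
  if (length(rows) == 0) {
    return(data.frame(indicator = character(0), score = character(0),
                      r = numeric(0), p = numeric(0), n = integer(0)))
  }
  do.call(rbind, rows)
}

run_config_echo <- function(cfg) {
  out <- unclass(cfg)
  out$generator <- config_echo(cfg$generator)
  out$window <- unclass(cfg$window)
  out
}

#' Summarize a completed pipeline run
#'
#' @param dir run directory produced by [run_pipeline()].
#' @return the parsed `summary.json` as a list; errors listing missing
#'   artifacts when the run is incomplete.
#' @export
summarize_run <- function(dir) {
  expected <- c("summary.json", "labels.csv", "model_selection.json",
                "temporal_properties.csv", "variability.csv",
                "variability_stats.tsv", "temporal_stats.json", "roc.json",
                "partialcorr.tsv", "demographics.tsv", "run_config.json",
                "log.txt")
  missing <- expected[!file.exists(file.path(dir, expected))]
  if (length(missing) > 0) {
    stop("incomplete run; missing artifacts: ", paste(missing, collapse = ", "))
  }
  jsonlite::read_json(file.path(dir, "summary.json"), simplifyVector = TRUE)
}

# deterministic writers: fixed number formatting so identical runs produce
# byte-identical files
write_tsv <- function(df, path, sep = "\t") {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (nm in names(df)[num]) out[[nm]] <- fmt_num(df[[nm]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = sep), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(unname(as.list(out)), list(sep = sep))), con)
  }
}

write_matrix_tsv <- function(path, m, labels = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(labels)) writeLines(paste(labels, collapse = "\t"), con)
  writeLines(apply(m, 1, function(row) paste(fmt_num(row), collapse = "\t")),
             con)
}
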