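#' Read cell event tables from disk
#'
#' Loads per-(donor, condition) event CSVs into one event table. Input is
#' either a directory of files named `<donor>__<condition>.csv` or a
#' manifest CSV with columns `file`, `donor`, `condition`. Each event file
#' must have a `cell_type` column plus one raw-intensity column per
#' protein; extra columns are ignored with a message.
#'
#' @param path directory of event CSVs, or a manifest CSV path.
#' @param proteins optional protein column names to enforce.
#' @return a `data.table` with columns `donor`, `condition`, `cell_type`
#'   and the protein columns (the format [compute_sample_medians()] takes).
#' @export
read_event_tables <- function(path, proteins = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    files <- files[!basename(files) %in% c("manifest.csv", "metadata.csv")]
    if (!length(files)) stop("no event CSVs found in ", path, call. = FALSE)
    parts <- strsplit(sub("\\.csv$", "", basename(files)), "__", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
      stop("file name(s) not of the form <donor>__<condition>.csv: ",
           paste(basename(files)[bad], collapse = ", "), call. = FALSE)
    manifest <- data.frame(file = files,
                           donor = vapply(parts, `[`, "", 1L),
                           condition = vapply(parts, `[`, "", 2L))
  } else if (file.exists(path)) {
    manifest <- as.data.frame(data.table::fread(path))
    need <- c("file", "donor", "condition")
    miss <- setdiff(need, names(manifest))
    if (length(miss))
      stop("manifest is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    manifest$file <- ifelse(file.exists(manifest$file), manifest$file,
                            file.path(dirname(path), manifest$file))
  } else stop("path does not exist: ", path, call. = FALSE)

  gone <- !file.exists(manifest$file)
  if (any(gone))
    stop("manifest refers to missing file(s): ",
         paste(manifest$file[gone], collapse = ", "), call. = FALSE)

  tabs <- lapply(seq_len(nrow(manifest)), function(i) {
    dt <- data.table::fread(manifest$file[i])
    if (!"cell_type" %in% names(dt))
      stop("file ", manifest$file[i], " is missing column 'cell_type'",
           call. = FALSE)
    if (!is.null(proteins)) {
      miss <- setdiff(proteins, names(dt))
      if (length(miss))
        stop("file ", manifest$file[i], " is missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      extra <- setdiff(names(dt), c("cell_type", proteins))
      if (length(extra)) {
        message("ignoring extra column(s) in ", basename(manifest$file[i]),
                ": ", paste(extra, collapse = ", "))
        dt <- dt[, c("cell_type", proteins), with = FALSE]
      }
    }
    dt[, `:=`(donor = manifest$donor[i], condition = manifest$condition[i])]
    dt
  })
  out <- data.table::rbindlist(tabs, use.names = TRUE)
  data.table::setcolorder(out, c("donor", "condition", "cell_type"))
  out
}

#' Write cohort event tables to disk
#'
#' One CSV per (donor, condition) plus a manifest, donor metadata CSV, and
#' a JSON ground-truth sidecar. Round-trips through
#' [read_event_tables()].
#'
#' @param cohort a `stimmod_cohort`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_event_tables <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "stimmod_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ev <- cohort$events
  keys <- unique(ev[, c("donor", "condition")])
  files <- file.path(out_dir, paste0(keys$donor, "__", keys$condition, ".csv"))
  donor <- condition <- NULL
  for (i in seq_len(nrow(keys))) {
    sub <- ev[donor == keys$donor[i] & condition == keys$condition[i],
              !c("donor", "condition")]
    data.table::fwrite(sub, files[i])
  }
  manifest <- data.frame(file = basename(files), donor = keys$donor,
                         condition = keys$condition)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  data.table::fwrite(cohort$metadata, file.path(out_dir, "metadata.csv"))
  jsonlite::write_json(
    list(module_of_feature = as.list(cohort$truth$module_of_feature),
         sex_effect_features = cohort$truth$sex_effect_features),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Default pipeline configuration
#'
#' Nested configuration for [run_pipeline()]. Unknown keys anywhere in
#' `overrides` are rejected, so typos fail before any computation.
#'
#' @param overrides named list of blocks to override (partial: unnamed
#'   blocks keep defaults).
#' @return validated nested list of class `stimmod_pipeline_config`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    sim = list(n_donors = 86, cells_per_sample = 1000, seed = 1L),
    features = list(cofactor = 5, min_mean = 0.2, min_events = 20),
    modules = list(cutoff = 0.5, linkage = "average", min_size = 4,
                   min_density = 0.5),
    stats = list(n_perm = 1000, fdr = 0.01, alpha = 0.05),
    models = list(enabled = TRUE,
                  penalties = c("ridge", "lasso", "grouplasso", "sgl"),
                  n_train = 50, k = 10, repeats = 3, n_lambda = 20),
    seed = 1L
  )
  for (blk in names(overrides)) {
    if (!blk %in% names(cfg))
      stop("unknown configuration block: ", blk, call. = FALSE)
    if (blk == "seed") { cfg$seed <- overrides$seed; next }
    for (key in names(overrides[[blk]])) {
      if (!key %in% names(cfg[[blk]]))
        stop("unknown key '", key, "' in block '", blk, "'", call. = FALSE)
      cfg[[blk]][[key]] <- overrides[[blk]][[key]]
    }
  }
  if (cfg$modules$cutoff <= 0 || cfg$modules$cutoff >= 1)
    stop("modules$cutoff must lie in (0, 1)", call. = FALSE)
  if (cfg$features$min_events < 1)
    stop("features$min_events must be at least 1", call. = FALSE)
  structure(cfg, class = "stimmod_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> medians -> features -> threshold -> correlation
#' -> clustering -> adjacency -> modules -> scores -> sex-stratified
#' statistics -> SAM -> penalized classifiers, on either a simulated cohort
#' or externally supplied events + metadata.
#'
#' @param config a [pipeline_config()] (or overrides list).
#' @param events optional pre-loaded event table (skips simulation).
#' @param metadata donor metadata (required with `events`).
#' @param quiet suppress stage log lines.
#' @return a results bundle (list) with elements `features`, `responsive`,
#'   `corr`, `hclust`, `adjacency`, `modules`, `module_summary`,
#'   `within_module`, `scores`, `stratified`, `correlation_tests`,
#'   `score_tests`, `sam`, `sam_report`, `models`, `config`, `timings`, and
#'   `truth`/`recovery_ari` for simulated runs.
#' @export
run_pipeline <- function(config = pipeline_config(), events = NULL,
                         metadata = NULL, quiet = FALSE) {
  if (!inherits(config, "stimmod_pipeline_config"))
    config <- pipeline_config(config)
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  timings <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    log_stage("stage %-12s %.2fs", name, timings[[name]])
    out
  }

  truth <- NULL
  if (is.null(events)) {
    cohort <- tick("simulate", {
      sc <- sim_config(n_donors = config$sim$n_donors,
                       cells_per_sample = config$sim$cells_per_sample)
      simulate_cohort(sc, seed = config$sim$seed)
    })
    events <- cohort$events
    metadata <- cohort$metadata
    truth <- cohort$truth
  }
  if (is.null(metadata)) stop("metadata is required with external events",
                              call. = FALSE)

  med <- tick("medians", compute_sample_medians(
    events, cofactor = config$features$cofactor,
    min_events = config$features$min_events))
  fm <- tick("features", derive_features(med))
  resp <- tick("threshold", threshold_features(fm, config$features$min_mean))
  corr <- tick("correlate", correlation_matrix(resp))
  hc <- tick("cluster", cluster_features(corr, config$modules$linkage))
  adj <- tick("adjacency", bin_adjacency(corr, config$modules$cutoff))
  mods <- tick("modules", extract_modules(hc, adj, config$modules$min_size,
                                          config$modules$min_density))
  summ <- if (length(mods$modules)) module_summary(mods, resp$meta) else NULL
  wmc <- if (length(mods$modules)) within_module_correlation(corr, mods) else NULL
  z <- tick("normalize", normalize_features(resp))
  scores <- tick("scores", compute_module_scores(z, mods))
  strat <- tick("stratify", stratified_correlations(
    resp, metadata, full_order = hc$labels[hc$order]))
  ct <- tick("corr_tests", compare_correlation_distributions(strat, mods))
  st <- tick("score_tests", compare_module_scores(scores, metadata))
  sam <- tick("sam", sam_permutation_fdr(resp$values, metadata$sex,
                                         n_perm = config$stats$n_perm,
                                         fdr = config$stats$fdr,
                                         seed = config$seed))
  sam_rep <- significant_features(sam, resp$meta)

  models <- NULL
  if (isTRUE(config$models$enabled)) {
    models <- tick("models", {
      split <- split_train_test(metadata, n_train = config$models$n_train,
                                seed = config$seed)
      groups <- module_groups(mods, colnames(resp$values))
      fit_all_classifiers(resp, metadata, split, groups,
                          penalties = config$models$penalties,
                          k = config$models$k,
                          repeats = config$models$repeats,
                          n_lambda = config$models$n_lambda,
                          seed = config$seed)
    })
  }

  out <- list(features = fm, responsive = resp, corr = corr, hclust = hc,
              adjacency = adj, modules = mods, module_summary = summ,
              within_module = wmc, scores = scores, stratified = strat,
              correlation_tests = ct, score_tests = st, sam = sam,
              sam_report = sam_rep, models = models, config = config,
              metadata = metadata, timings = timings)
  if (!is.null(truth)) {
    out$truth <- truth
    tr <- truth$module_of_feature[colnames(resp$values)]
    out$recovery_ari <- adjusted_rand_index(tr, mods$module_of[colnames(resp$values)])
  }
  out
}

#' Group-id vector for grouped penalties from a module assignment
#'
#' Features outside every module enter as singleton groups by default, or
#' as one shared `"unassigned"` group.
#'
#' @param assignment a `stimmod_modules` object.
#' @param features feature ids in model-column order.
#' @param unassigned `"singleton"` or `"pooled"`.
#' @return character group-id vector aligned with `features`.
#' @export
module_groups <- function(assignment, features,
                          unassigned = c("singleton", "pooled")) {
  unassigned <- match.arg(unassigned)
  g <- assignment$module_of[features]
  una <- is.na(g) | g == "unassigned"
  if (unassigned == "singleton") {
    g[una] <- paste0("single_", which(una))
  } else g[una] <- "unassigned"
  unname(g)
}

#' Fit and evaluate the four penalized classifiers
#'
#' Ridge and lasso (module-blind) plus group lasso and sparse group lasso
#' (module-aware) logistic models of donor class, each tuned by
#' cross-validation on the training donors and evaluated on the held-out
#' donors.
#'
#' @param fm post-threshold `stimmod_features`.
#' @param metadata donor metadata.
#' @param split a [split_train_test()] result.
#' @param groups group-id vector from [module_groups()].
#' @param penalties which of the four families to fit.
#' @param class_col class column.
#' @param seed,k,repeats,n_lambda CV settings.
#' @return named list per penalty: `cv`, `fit`, `evaluation`.
#' @export
fit_all_classifiers <- function(fm, metadata, split, groups,
                                penalties = c("ridge", "lasso", "grouplasso", "sgl"),
                                class_col = "sex", seed = 1L, k = 10,
                                repeats = 3, n_lambda = 20) {
  Xtr <- fm$values[fm$donors %in% split$train, , drop = FALSE]
  Xte <- fm$values[fm$donors %in% split$test, , drop = FALSE]
  Xtr[is.na(Xtr)] <- 0; Xte[is.na(Xte)] <- 0
  ytr <- factor(metadata[[class_col]][match(rownames(Xtr), metadata$donor_id)])
  yte <- factor(metadata[[class_col]][match(rownames(Xte), metadata$donor_id)])
  out <- lapply(penalties, function(pen) {
    cv <- cross_validate_lambda(Xtr, ytr, penalty = pen,
                                groups = if (pen %in% c("grouplasso", "sgl"))
                                  groups else NULL,
                                k = k, repeats = repeats, n_lambda = n_lambda,
                                seed = seed)
    ev <- evaluate_model(cv$fit, Xte, yte)
    list(cv = cv, fit = cv$fit, evaluation = ev)
  })
  names(out) <- penalties
  out
}

#' Write a results bundle to disk
#'
#' Persists the pipeline artifacts as plain CSV/JSON: feature matrix,
#' correlation and adjacency matrices, module assignment, module scores,
#' test tables, SAM results, model performance, and a run manifest with
#' the seed and package version.
#'
#' @param bundle a [run_pipeline()] result.
#' @param out_dir output directory.
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, mode = 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  files <- c()
  put_csv <- function(x, name, rn = TRUE) {
    f <- file.path(out_dir, name)
    utils::write.csv(x, f, row.names = rn)
    files <<- c(files, f)
  }
  put_json <- function(x, name) {
    f <- file.path(out_dir, name)
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, f)
  }
  put_csv(bundle$responsive$values, "features.csv")
  put_csv(bundle$responsive$meta, "feature_meta.csv", rn = FALSE)
  put_csv(bundle$corr$R, "correlation.csv")
  put_csv(bundle$adjacency$A, "adjacency.csv")
  put_json(as.list(bundle$modules$module_of), "modules.json")
  put_csv(bundle$scores$scores, "module_scores.csv")
  if (!is.null(bundle$module_summary))
    put_csv(bundle$module_summary, "module_summary.csv", rn = FALSE)
  put_csv(bundle$correlation_tests$per_module, "correlation_tests.csv", rn = FALSE)
  put_csv(bundle$score_tests, "score_tests.csv", rn = FALSE)
  put_json(list(d = as.list(bundle$sam$d), q_value = as.list(bundle$sam$q_value),
                s0 = bundle$sam$s0,
                significant_up = bundle$sam$significant_up,
                significant_down = bundle$sam$significant_down),
           "sam.json")
  if (!is.null(bundle$models)) {
    perf <- do.call(rbind, lapply(names(bundle$models), function(m) {
      ev <- bundle$models[[m]]$evaluation
      data.frame(model = m, accuracy = ev$accuracy, auc = ev$auc,
                 lambda = bundle$models[[m]]$cv$best_lambda,
                 alpha = bundle$models[[m]]$cv$best_alpha)
    }))
    put_csv(perf, "model_performance.csv", rn = FALSE)
  }
  put_json(list(seed = bundle$config$seed,
                package_version = as.character(utils::packageVersion("stimmod")),
                config = unclass(bundle$config),
                timings = as.list(bundle$timings)),
           "run_manifest.json")
  invisible(files)
}
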