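# configurable pipeline runner: simulate/load -> normalize -> train ->
# predict -> average -> evaluate / filter / markers / concordance /
# associate / project, with deterministic outputs and a run manifest

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop(sprintf("config file not found: '%s'", config), call. = FALSE)
    }
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path",
                             call. = FALSE)
  config
}

pipeline_known_stages <- c("simulate", "load", "normalize", "train", "predict",
                           "average", "evaluate", "filter", "markers",
                           "concordance", "associate", "project")

#' Run the prediction pipeline from a configuration
#'
#' Executes the requested stages in order.  `simulate` (or `load`) provides
#' the per-platform expression and the drug response table; `normalize`
#' applies the per-platform recipe; `train` builds the per-platform
#' signatures on the training split; `predict` scores the test samples;
#' `average` combines the platform predictions; `evaluate` reports
#' concordance indices; `filter` sweeps significance cutoffs
#' (restricted-feature runs); `markers` exports the recurrently significant
#' features; `concordance` compares platform predictions by Spearman
#' correlation; `associate` correlates scores with a per-sample covariate;
#' `project` scores a tumor cohort after robust z-scoring.
#'
#' Every run writes its outputs as TSV into `out`, alongside a
#' `manifest.json` provenance sidecar (config hash, seed, package and R
#' versions, stage list, files written).  Rerunning an identical config
#' reproduces the deterministic outputs bit for bit.
#'
#' @param config a named list, or the path to a YAML/JSON file.  Top-level
#'   keys: `stages` (character vector), `seed`, `out`, plus one optional
#'   block per stage (see the pipeline vignette for the keys of each).
#' @param out output directory (overrides `config$out`); created if absent.
#' @param seed overrides `config$seed`.
#' @return Invisibly, a list with the in-memory state (`signatures`,
#'   `predictions`, `evaluation`, ...) and the `manifest`.
#' @export
run_pipeline <- function(config, out = NULL, seed = NULL) {
  config <- read_pipeline_config(config)
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0) {
    stop("config$stages is empty", call. = FALSE)
  }
  unknown <- setdiff(stages, pipeline_known_stages)
  if (length(unknown) > 0) {
    stop(sprintf("unknown stage(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(pipeline_known_stages, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1
  if (!is.null(out)) config$out <- out
  if (is.null(config$out)) stop("no output directory given", call. = FALSE)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  state <- new.env(parent = emptyenv())
  state$files <- character(0)
  emit <- function(obj, name, writer = write_matrix) {
    path <- file.path(config$out, name)
    writer(obj, path)
    state$files <- c(state$files, name)
    path
  }
  emit_tibble <- function(df, name) {
    path <- file.path(config$out, name)
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$files <- c(state$files, name)
    path
  }

  for (stage in stages) {
    message(sprintf("[corsens] stage: %s", stage))
    ok <- try(pipeline_stage(stage, config, state, emit, emit_tibble),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      stop(sprintf("stage '%s' failed: %s", stage,
                   conditionMessage(attr(ok, "condition"))), call. = FALSE)
    }
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed,
    stages = stages,
    package_version = as.character(utils::packageVersion("corsens")),
    r_version = as.character(getRversion()),
    files = state$files
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    signatures = state$signatures, predictions = state$predictions,
    averaged = state$averaged, evaluation = state$evaluation,
    dataset = state$dataset, manifest = manifest
  ))
}

pipeline_stage <- function(stage, config, state, emit, emit_tibble) {
  switch(stage,
    simulate = {
      sc <- config$simulate
      sc$train_fraction <- NULL
      sim_cfg <- do.call(simulation_config,
                         c(sc[intersect(names(sc), names(formals(simulation_config)))],
                           list(seed = config$seed)))
      state$dataset <- simulate_dataset(sim_cfg)
      tf <- config$simulate$train_fraction
      if (is.null(tf)) tf <- sim_cfg$n_train / (sim_cfg$n_train + sim_cfg$n_test)
      split <- split_train_test(state$dataset, tf,
                                seed = derive_seed(config$seed, 1))
      state$split <- split
      state$expr_train <- lapply(state$dataset$expression, subset_samples,
                                 samples = split$train)
      state$expr_test <- lapply(state$dataset$expression, subset_samples,
                                samples = split$test)
      state$resp_train <- subset_samples(state$dataset$response, split$train)
      state$resp_test <- subset_samples(state$dataset$response, split$test)
      state$tumors <- state$dataset$tumors
      for (pl in names(state$dataset$expression)) {
        emit(state$dataset$expression[[pl]],
             sprintf("simulated_expression_%s.tsv", pl))
      }
      emit(state$dataset$response, "simulated_response.tsv")
    },
    load = {
      inp <- config$inputs
      if (is.null(inp)) stop("stage 'load' needs config$inputs", call. = FALSE)
      exprs <- lapply(inp$expression, function(e) {
        do.call(read_expression_matrix,
                e[intersect(names(e), names(formals(read_expression_matrix)))])
      })
      names(exprs) <- vapply(exprs, function(e) e$platform, character(1))
      resp <- do.call(read_response_table,
                      inp$response[intersect(names(inp$response),
                                             names(formals(read_response_table)))])
      train_ids <- inp$train_samples
      test_ids <- inp$test_samples
      if (is.null(train_ids)) {
        stop("stage 'load' needs inputs$train_samples (and test_samples)",
             call. = FALSE)
      }
      state$expr_train <- lapply(exprs, subset_samples, samples = train_ids)
      state$expr_test <- if (is.null(test_ids)) exprs else
        lapply(exprs, subset_samples, samples = test_ids)
      state$resp_train <- subset_samples(resp, train_ids)
      state$resp_test <- if (is.null(test_ids)) resp else
        subset_samples(resp, test_ids)
    },
    normalize = {
      if (is.null(state$expr_train)) {
        stop("no data loaded; run 'simulate' or 'load' first", call. = FALSE)
      }
      nc <- config$normalize
      recipe <- nc$recipe
      if (is.null(recipe)) recipe <- "median_center"
      apply_recipe <- function(e) {
        for (step in recipe) {
          e <- switch(step,
            log = log_transform(e, base = nc$log_base %||% 2,
                                offset = nc$log_offset %||% 0),
            median_center = median_center(e),
            robust_z = robust_zscore(e),
            stop(sprintf("unknown normalize step '%s'", step), call. = FALSE))
        }
        e
      }
      state$expr_train <- lapply(state$expr_train, apply_recipe)
      state$expr_test <- lapply(state$expr_test, apply_recipe)
      if (state$resp_train$transform_state == "raw_concentration") {
        base <- nc$response_log_base %||% 10
        state$resp_train <- neglog_response(state$resp_train, base = base)
        state$resp_test <- neglog_response(state$resp_test, base = base)
      }
    },
    train = {
      if (is.null(state$expr_train)) {
        stop("no training data; run 'simulate' or 'load' first", call. = FALSE)
      }
      alpha <- config$train$alpha
      state$signatures <- lapply(state$expr_train, function(e) {
        s <- build_signature(e, state$resp_train)
        if (!is.null(alpha)) s <- filter_by_alpha(s, alpha)
        s
      })
      for (pl in names(state$signatures)) {
        emit(state$signatures[[pl]], sprintf("signature_%s.tsv", pl))
      }
    },
    predict = {
      if (is.null(state$signatures)) {
        stop("no signatures; run 'train' first", call. = FALSE)
      }
      drop_zeroed <- isTRUE(config$predict$drop_zeroed)
      state$predictions <- mapply(function(sig, e) {
        score_samples(sig, e, drop_zeroed = drop_zeroed)
      }, state$signatures, state$expr_test[names(state$signatures)],
      SIMPLIFY = FALSE)
      for (pl in names(state$predictions)) {
        emit(state$predictions[[pl]], sprintf("predictions_%s.tsv", pl))
      }
    },
    average = {
      state$averaged <- average_predictions(unname(state$predictions))
      emit(state$averaged, "predictions_averaged.tsv")
    },
    evaluate = {
      if (is.null(state$averaged) && is.null(state$predictions)) {
        stop("no predictions; run 'predict' first", call. = FALSE)
      }
      pred <- state$averaged %||% state$predictions[[1]]
      state$evaluation <- evaluate_predictions(
        pred, state$resp_test,
        null_iter = config$evaluate$null_iter %||% 0,
        seed = derive_seed(config$seed, 2))
      emit(state$evaluation, "evaluation.tsv", writer = write_evaluation)
    },
    filter = {
      alphas <- config$filter$alphas %||% c(1, 0.05, 0.01, 0.001)
      exclude <- config$filter$exclude %||% character(0)
      rows <- lapply(alphas, function(a) {
        per_platform <- mapply(function(sig, e) {
          s <- if (a < 1) filter_by_alpha(sig, a) else sig
          pred <- score_samples(s, e, drop_zeroed = a < 1)
          list(pred = pred,
               retained = attr(retained_features(s, exclude = exclude),
                               "average_retained"))
        }, state$signatures, state$expr_test[names(state$signatures)],
        SIMPLIFY = FALSE)
        pred <- average_predictions(lapply(per_platform, `[[`, "pred"))
        ev <- evaluate_predictions(pred, state$resp_test)
        tibble::tibble(
          alpha = a,
          avg_features_per_drug = mean(vapply(per_platform, `[[`, numeric(1),
                                              "retained")),
          aggregate_c = ev$aggregate_c)
      })
      emit_tibble(dplyr::bind_rows(rows), "cutoff_sweep.tsv")
    },
    markers = {
      alpha <- config$markers$alpha %||% 0.01
      min_drugs <- config$markers$min_drugs %||% 2
      for (pl in names(state$signatures)) {
        sig <- state$signatures[[pl]]
        keep <- recurrent_features(sig, alpha = alpha, min_drugs = min_drugs)
        m <- sig$r[keep, , drop = FALSE]
        emit(m, sprintf("markers_%s.tsv", pl))
      }
    },
    concordance = {
      pls <- names(state$predictions)
      rows <- list()
      for (i in seq_along(pls)) for (j in seq_along(pls)) if (i < j) {
        tab <- platform_concordance(state$predictions[[pls[i]]],
                                    state$predictions[[pls[j]]])
        tab$platform_a <- pls[i]
        tab$platform_b <- pls[j]
        rows[[length(rows) + 1]] <- tab
      }
      emit_tibble(dplyr::bind_rows(rows), "platform_concordance.tsv")
    },
    associate = {
      cov <- config$associate$covariate %||% "group"
      pred <- state$averaged %||% state$predictions[[1]]
      samples <- colnames(pred$score)
      covariate <- if (identical(cov, "group")) {
        g <- state$dataset$truth$groups
        if (is.null(g)) stop("no group labels available for 'associate'",
                             call. = FALSE)
        as.numeric(g[samples] == max(g))
      } else {
        v <- utils::read.delim(cov, sep = "\t")
        setNames(v[[2]], v[[1]])[samples]
      }
      rows <- lapply(rownames(pred$score), function(d) {
        res <- covariate_association(setNames(pred$score[d, ], samples),
                                     setNames(covariate, samples))
        dplyr::mutate(res, drug = d, .before = 1)
      })
      emit_tibble(dplyr::bind_rows(rows), "covariate_association.tsv")
    },
    project = {
      tumors <- state$tumors
      if (is.null(tumors) || length(tumors) == 0) {
        stop("no tumor cohort available for 'project'", call. = FALSE)
      }
      for (pl in intersect(names(state$signatures), names(tumors))) {
        tz <- robust_zscore(tumors[[pl]])
        matched <- match_features(state$signatures[[pl]], tz)
        pred <- score_samples(matched$signature, matched$expression)
        emit(pred, sprintf("tumor_projection_%s.tsv", pl))
      }
    },
    stop(sprintf("unknown stage '%s'", stage), call. = FALSE)
  )
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
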