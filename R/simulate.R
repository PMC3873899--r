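# latent-factor generator for multi-platform pharmacogenomic data with
# planted drug-sensitivity signature structure

#' Simulation configuration
#'
#' Parameters of the latent-factor generative model used for testing and
#' calibration.  Every sample carries one latent activity per drug (plus a
#' group-level shift when `n_groups > 1`, giving an ER+/ER--like block
#' structure); each drug plants a driver-feature module that loads on its
#' latent; non-driver features are pure platform noise; drug response is
#' `-logGI50 = beta * latent + noise`.  Missingness is applied completely
#' at random.
#'
#' Defaults mirror the scale of a multi-platform breast cancer cell line
#' panel: 35 training and 18 test lines (53 in all), 31 drugs, three
#' platforms (two transcript-level with 2000 features each at desk scale,
#' and a 131-feature protein panel), 100-feature driver modules, unit
#' loading and effect size, platform noise SD 1, response noise SD 0.25,
#' 5% missing cells, and two sample groups.
#'
#' @param n_train,n_test,n_tumors sample counts (tumors form a separate
#'   cohort generated from the same latent model).
#' @param n_features named integer vector: features per platform.
#' @param n_drugs number of drugs.
#' @param driver_module_size driver features planted per drug (recycled to
#'   `n_drugs`); modules are drawn independently per drug and may overlap.
#' @param beta per-drug latent effect on response (recycled).
#' @param loading loading of driver features on their drug latent.
#' @param platform_noise_sd named per-platform feature noise SD (recycled).
#' @param response_noise_sd SD of the response noise.
#' @param missing_rate probability in `[0, 1)` that any expression or
#'   response cell is missing.
#' @param n_groups number of sample groups; `group_sd` scales the group
#'   shift added to every latent.
#' @param group_sd SD of the per-(group, drug) latent shift.
#' @param seed master seed; all randomness derives from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_train = 35, n_test = 18, n_tumors = 0,
                              n_features = c(gene_array = 2000, rnaseq = 2000,
                                             rppa = 131),
                              n_drugs = 31, driver_module_size = 100,
                              beta = 1, loading = 1,
                              platform_noise_sd = 1, response_noise_sd = 0.25,
                              missing_rate = 0.05, n_groups = 2, group_sd = 1,
                              seed = 1) {
  n_features <- unlist(n_features)  # accept YAML/JSON-style named lists
  platform_noise_sd <- unlist(platform_noise_sd)
  if (is.null(names(n_features))) {
    names(n_features) <- paste0("platform", seq_along(n_features))
  }
  if (length(platform_noise_sd) == 1) {
    platform_noise_sd <- setNames(rep(platform_noise_sd, length(n_features)),
                                  names(n_features))
  }
  cfg <- list(
    n_train = n_train, n_test = n_test, n_tumors = n_tumors,
    n_features = n_features, n_drugs = n_drugs,
    driver_module_size = rep_len(driver_module_size, n_drugs),
    beta = rep_len(beta, n_drugs), loading = loading,
    platform_noise_sd = platform_noise_sd[names(n_features)],
    response_noise_sd = response_noise_sd, missing_rate = missing_rate,
    n_groups = n_groups, group_sd = group_sd, seed = seed
  )
  with(cfg, {
    stopifnot(n_train >= 1, n_test >= 1, n_tumors >= 0, n_drugs >= 1,
              all(n_features >= 1), all(driver_module_size >= 1),
              all(platform_noise_sd >= 0), response_noise_sd >= 0,
              missing_rate >= 0, missing_rate < 1, n_groups >= 1)
  })
  if (any(cfg$driver_module_size > min(cfg$n_features))) {
    stop(sprintf("driver_module_size (max %d) exceeds the smallest platform's feature count (%d)",
                 max(cfg$driver_module_size), min(cfg$n_features)), call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a multi-platform cell line dataset with planted signatures
#'
#' Generates, under one master seed, the expression matrices (one per
#' platform, already on the log scale, `norm_state = "logged"`), the
#' negative-log drug response table, an optional tumor cohort, and the
#' ground truth (latents, driver sets, effect sizes, group labels) for
#' parameter-recovery checks.  The same seed yields bit-identical output.
#'
#' Feature identifiers are shared across platforms up to each platform's
#' feature count (platform `k` measures the first `n_features[k]` features
#' of the common universe), so cross-platform feature matching is exercised
#' naturally.
#'
#' @param config a [simulation_config()].
#' @return A list:
#'   `expression` (named list of [expression_matrix()], training+test
#'   samples), `response` ([drug_response_table()], `neglog`),
#'   `tumors` (named list of [expression_matrix()], or empty), and
#'   `truth` (list: `latent` samples x drugs, `tumor_latent`, `drivers`
#'   per-drug feature-id lists, `beta`, `groups`, `tumor_groups`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_train + config$n_test
  feat_universe <- sprintf("G%05d", seq_len(max(config$n_features)))
  sample_ids <- sprintf("S%03d", seq_len(n))
  tumor_ids <- if (config$n_tumors > 0) sprintf("T%03d", seq_len(config$n_tumors)) else character(0)
  drug_ids <- sprintf("Drug%02d", seq_len(config$n_drugs))

  groups <- setNames(rep_len(seq_len(config$n_groups), n), sample_ids)
  tumor_groups <- setNames(rep_len(seq_len(config$n_groups), config$n_tumors),
                           tumor_ids)
  # per-(group, drug) latent shift shared by cell lines and tumors
  group_shift <- matrix(rnorm(config$n_groups * config$n_drugs,
                              sd = if (config$n_groups > 1) config$group_sd else 0),
                        config$n_groups, config$n_drugs)

  latent <- matrix(rnorm(n * config$n_drugs), n, config$n_drugs,
                   dimnames = list(sample_ids, drug_ids)) +
    group_shift[groups, , drop = FALSE]
  tumor_latent <- NULL
  if (config$n_tumors > 0) {
    tumor_latent <- matrix(rnorm(config$n_tumors * config$n_drugs),
                           config$n_tumors, config$n_drugs,
                           dimnames = list(tumor_ids, drug_ids)) +
      group_shift[tumor_groups, , drop = FALSE]
  }

  drivers <- lapply(seq_len(config$n_drugs), function(d) {
    sort(sample.int(max(config$n_features), config$driver_module_size[d]))
  })
  names(drivers) <- drug_ids

  # signal carried by each feature: sum of loadings over drugs it drives
  make_platform <- function(platform, n_feat, noise_sd, lat, ids) {
    m <- matrix(rnorm(n_feat * length(ids), sd = noise_sd), n_feat, length(ids),
                dimnames = list(feat_universe[seq_len(n_feat)], ids))
    for (d in seq_len(config$n_drugs)) {
      idx <- drivers[[d]][drivers[[d]] <= n_feat]
      if (length(idx) > 0) {
        m[idx, ] <- m[idx, ] + config$loading * matrix(lat[, d], length(idx),
                                                       length(ids), byrow = TRUE)
      }
    }
    if (config$missing_rate > 0) {
      m[runif(length(m)) < config$missing_rate] <- NA_real_
    }
    expression_matrix(m, platform = platform, norm_state = "logged")
  }

  expression <- lapply(names(config$n_features), function(pl) {
    make_platform(pl, config$n_features[[pl]], config$platform_noise_sd[[pl]],
                  latent, sample_ids)
  })
  names(expression) <- names(config$n_features)

  tumors <- list()
  if (config$n_tumors > 0) {
    tumors <- lapply(names(config$n_features), function(pl) {
      make_platform(pl, config$n_features[[pl]], config$platform_noise_sd[[pl]],
                    tumor_latent, tumor_ids)
    })
    names(tumors) <- names(config$n_features)
  }

  resp <- t(latent) * config$beta +
    matrix(rnorm(config$n_drugs * n, sd = config$response_noise_sd),
           config$n_drugs, n)
  dimnames(resp) <- list(drug_ids, sample_ids)
  if (config$missing_rate > 0) {
    resp[runif(length(resp)) < config$missing_rate] <- NA_real_
  }

  list(
    expression = expression,
    response = drug_response_table(resp, transform_state = "neglog"),
    tumors = tumors,
    truth = list(latent = latent, tumor_latent = tumor_latent,
                 drivers = lapply(drivers, function(i) feat_universe[i]),
                 beta = setNames(config$beta, drug_ids),
                 groups = groups, tumor_groups = tumor_groups),
    config = config
  )
}

#' Reproducible (optionally stratified) train/test split
#'
#' Partitions the dataset's cell line identifiers into disjoint, exhaustive
#' train and test sets.  When the dataset carries group labels the split is
#' stratified: each group contributes its share of training samples
#' (rounded), so group proportions are preserved to within one sample.
#'
#' @param dataset output of [simulate_dataset()], or any list with a
#'   `response` table (and optional `truth$groups`).
#' @param train_fraction fraction of samples assigned to training, in
#'   `(0, 1)`.
#' @param seed integer seed.
#' @return A list with character vectors `train` and `test`.
#' @export
split_train_test <- function(dataset, train_fraction, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  ids <- colnames(dataset$response$values)
  groups <- dataset$truth$groups
  if (is.null(groups)) groups <- setNames(rep(1L, length(ids)), ids)
  set.seed(seed)
  train <- unlist(lapply(unique(groups[ids]), function(g) {
    members <- ids[groups[ids] == g]
    k <- round(train_fraction * length(members))
    k <- max(min(k, length(members)), 0L)
    sample(members, k)
  }), use.names = FALSE)
  # keep input order for determinism of downstream matrix construction
  train <- ids[ids %in% train]
  test <- setdiff(ids, train)
  if (length(train) == 0 || length(test) == 0) {
    stop("train_fraction leaves one side of the split empty", call. = FALSE)
  }
  list(train = train, test = test)
}
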