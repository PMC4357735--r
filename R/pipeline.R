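#' Default run configuration
#'
#' Flat key-value list of the tunable pipeline parameters with their
#' defaults: 30-bp windows, ten flanks per side, minimum five reads per
#' training window, scan threshold at 70% of the maximum PWM score, 500
#' trees.
#'
#' @param ... overrides for any default.
#' @return named list.
#' @export
default_run_config <- function(...) {
  cfg <- list(window_size = 30, n_flank = 10, min_reads = 5,
              threshold = 0.7, threshold_type = "fraction",
              target_sites = NULL, contexts = "CG", n_trees = 500,
              tree_grid = c(100, 200, 500, 1000), stability_tol = 0.005,
              balanced = FALSE, seed = 1, tf_name = "TF")
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read a run configuration file
#'
#' YAML (or JSON) key-value document; unknown keys are rejected so typos
#' fail loudly. Values not present fall back to [default_run_config()].
#'
#' @param path configuration file.
#' @return named list as from [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  path_keys <- c("genome", "pfm", "cpg_cg", "cpg_ch", "cpg_hmc", "peaks",
                 "conservation", "tss", "tes", "exon", "intron",
                 "cpg_island", "repeat", "out_dir", "model")
  unknown <- setdiff(names(cfg), c(names(defaults), path_keys))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- defaults
  out[names(cfg)] <- cfg
  out
}

#' Load pipeline inputs from files into a bundle
#'
#' Reads the files named in a configuration list (keys `genome`, `pfm`,
#' `cpg_cg`/`cpg_ch`/`cpg_hmc`, `peaks`, `conservation`, plus one BED per
#' annotation class) into the same in-memory bundle shape that
#' [simulate_dataset()] produces.
#'
#' @param config named list of file paths (see [read_run_config()]).
#' @return list usable as `bundle` by [run_train()] / [run_predict()].
#' @export
read_pipeline_inputs <- function(config) {
  need <- function(key) {
    if (is.null(config[[key]]))
      stop("configuration lacks required input '", key, "'", call. = FALSE)
    if (!file.exists(config[[key]]))
      stop("input file for '", key, "' not found: ", config[[key]],
           call. = FALSE)
    config[[key]]
  }
  cpg <- list(CG = read_cpg_table(need("cpg_cg"), context_filter = "CG"))
  if (!is.null(config$cpg_ch))
    cpg$CH <- read_cpg_table(need("cpg_ch"), context_filter = "CH")
  if (!is.null(config$cpg_hmc))
    cpg$hmC <- read_cpg_table(need("cpg_hmc"), context_filter = "hmC")
  annotations <- lapply(stats::setNames(ANNOTATION_KEYS, ANNOTATION_KEYS),
                        function(k) read_bed(need(k)))
  list(genome = read_fasta(need("genome")),
       pfm = read_pfm(need("pfm")),
       cpg = cpg,
       peaks = if (is.null(config$peaks)) NULL else read_bed(need("peaks")),
       annotations = annotations,
       track = read_wig(need("conservation")))
}

genome_base_freqs <- function(genome) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(genome))[, c("A", "C", "G", "T"), drop = FALSE])
  counts / sum(counts)
}

scan_and_label <- function(bundle, config) {
  pwm <- pfm_to_pwm(bundle$pfm, background = genome_base_freqs(bundle$genome))
  if (!is.null(config$target_sites)) {
    thr <- choose_threshold(bundle$genome, pwm, config$target_sites)
    candidates <- scan_genome(bundle$genome, pwm, thr$threshold, "absolute")
  } else {
    candidates <- scan_genome(bundle$genome, pwm, config$threshold,
                              config$threshold_type)
  }
  if (!is.null(bundle$peaks))
    candidates <- label_candidates(candidates, bundle$peaks)
  candidates
}

window_counts_for <- function(sites, bundle, config, context) {
  chrom_lengths <- vapply(bundle$genome, nchar, 0L)
  layout <- build_windows_all(sites, config$window_size, config$n_flank,
                              chrom_lengths)
  aggregate_counts(layout, bundle$cpg[[context]])
}

#' Train a binding model end-to-end on a bundle
#'
#' Stages: PWM scan (candidate selection), labelling against the
#' gold-standard peaks, random half split, training-set QC (minimum-read
#' masking, CpG-island exclusion), per-context methylation model fitting,
#' feature assembly and random-forest training. Any stage error is
#' re-raised with the stage name.
#'
#' @param bundle pipeline inputs ([simulate_dataset()] or
#'   [read_pipeline_inputs()]), with `peaks` present.
#' @param seed seed controlling the split and the forest.
#' @param ... overrides merged into [default_run_config()].
#' @return list with `model` (a `tf_model`), `train_sites`, `test_sites`
#'   (labelled candidate tables) and `report` (stage-by-stage counts, OOB
#'   error, normalised importances).
#' @export
run_train <- function(bundle, seed = 1, ...) {
  config <- default_run_config(...)
  config$seed <- seed
  if (is.null(bundle$peaks))
    stop("[label] training requires gold-standard peaks", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  candidates <- stage("scan", scan_and_label(bundle, config))
  if (nrow(candidates) < 4L)
    stop("[scan] only ", nrow(candidates),
         " candidate sites found; cannot train", call. = FALSE)
  split <- stage("split", split_train_test(candidates, seed))
  train_sites <- split$train

  contexts <- intersect(config$contexts, names(bundle$cpg))
  if (!length(contexts))
    stop("[counts] none of the requested contexts present in the bundle",
         call. = FALSE)
  meth_models <- list()
  train_scores <- list()
  qc_stats <- NULL
  for (ctx in contexts) {
    wc <- stage("counts", window_counts_for(train_sites, bundle, config, ctx))
    qc <- stage("qc", qc_filter_training(train_sites, wc,
                                         bundle$annotations$cpg_island,
                                         config$min_reads))
    if (is.null(qc_stats)) {
      qc_stats <- list(n_dropped_island = qc$n_dropped_island,
                       n_masked_windows = qc$n_masked_windows)
      train_sites_qc <- qc$sites
    }
    bound_ids <- qc$sites$site_id[qc$sites$label == "bound"]
    model <- stage("meth_model", fit_methylation_model(
      qc$window_counts[qc$window_counts$site_id %in% bound_ids, ],
      qc$window_counts[!(qc$window_counts$site_id %in% bound_ids), ],
      config$window_size, config$n_flank, ctx))
    meth_models[[ctx]] <- model
    # scores for the RF are computed on unmasked counts; the min-read mask
    # applies to parameter fitting only
    train_scores[[ctx]] <- methylation_score_all(
      wc[wc$site_id %in% qc$sites$site_id, ], model)
  }
  names(train_scores) <- contexts

  features <- stage("features", assemble_feature_table(
    train_sites_qc, train_scores, bundle$track, bundle$annotations))
  labels <- train_sites_qc$label[match(features$site_id,
                                       train_sites_qc$site_id)]
  forest <- stage("train_rf", train_rf(
    features, labels, n_trees = config$n_trees, seed = seed,
    balanced = config$balanced, meth_models = meth_models,
    tf_name = config$tf_name))

  report <- list(
    n_candidates = nrow(candidates),
    n_train = nrow(train_sites), n_test = nrow(split$test),
    n_train_after_qc = nrow(train_sites_qc),
    qc = qc_stats,
    class_counts = table(train_sites_qc$label),
    oob_error = forest$oob_error,
    gini_importance = gini_importance(forest),
    config = config)
  list(model = forest, train_sites = train_sites_qc,
       test_sites = split$test, report = report)
}

#' Predict binding probabilities on a bundle
#'
#' Computes per-context methylation scores with the model's stored
#' beta-binomial parameters, assembles features under the model's schema
#' and returns vote-fraction probabilities. Candidates (not peaks) are
#' the unit of prediction; pass `sites` to score a fixed candidate set
#' (e.g. a held-out split), otherwise the bundle's genome is scanned
#' afresh.
#'
#' @param model a trained `tf_model` with methylation models attached.
#' @param bundle pipeline inputs (peaks not required).
#' @param sites optional candidate table; scanned from the genome when
#'   omitted.
#' @param ... configuration overrides (must match the training geometry).
#' @return data.frame: candidate coordinates, motif score, per-context
#'   methylation scores and `prob_bound`.
#' @export
run_predict <- function(model, bundle, sites = NULL, ...) {
  config <- default_run_config(...)
  if (!length(model$meth_models))
    stop("model carries no methylation models; cannot score a bundle",
         call. = FALSE)
  geom <- model$meth_models[[1]]
  config$window_size <- geom$window_size
  config$n_flank <- geom$n_flank
  if (is.null(sites)) sites <- scan_and_label(bundle, config)
  if (nrow(sites) == 0L) {
    warning("empty candidate set; nothing to predict")
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), site_id = character(),
                      motif_score = numeric(), strand = character(),
                      prob_bound = numeric(), stringsAsFactors = FALSE))
  }
  contexts <- names(model$meth_models)
  missing_ctx <- setdiff(contexts, names(bundle$cpg))
  if (length(missing_ctx))
    stop("bundle lacks methylation context(s) required by the model: ",
         paste(missing_ctx, collapse = ", "), call. = FALSE)
  scores <- lapply(contexts, function(ctx)
    methylation_score_all(window_counts_for(sites, bundle, config, ctx),
                          model$meth_models[[ctx]]))
  names(scores) <- contexts
  features <- assemble_feature_table(sites, scores, bundle$track,
                                     bundle$annotations)
  prob <- predict_proba(model, features)
  out <- sites[match(features$site_id, sites$site_id),
               c("chrom", "start", "end", "site_id", "motif_score",
                 "strand"), drop = FALSE]
  for (ctx in contexts)
    out[[paste0("meth_score_", tolower(sub("hmC", "hmc", ctx)))]] <-
      as.numeric(scores[[ctx]][features$site_id])
  out$prob_bound <- as.numeric(prob)
  rownames(out) <- NULL
  out
}
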