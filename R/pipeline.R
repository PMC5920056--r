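# End-to-end pipeline: simulate (or load) data, compute distances, generate
# partitions, evaluate, and write result files plus a reproducibility
# manifest.

stage_msg <- function(fmt, ...) {
  message(sprintf("[distinctcv %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full distinctness-aware CV pipeline
#'
#' Orchestrates the stages configured in `config` and writes all outputs to
#' `out_dir`: the (synthetic or loaded) expression and target TSVs, the
#' partition JSON, the per-condition distinctness table, the evaluation
#' results TSV and a `manifest.json` recording every parameter and seed —
#' sufficient to reproduce any output exactly.
#'
#' @param config named list with fields:
#'   * `seed` — root seed (all stage seeds derive from it);
#'   * either `synthetic` (arguments for [synthetic_config()]) or
#'     `expression`/`targets` (TSV paths, plus optional `transpose`);
#'   * `partition` — list with `kind` (`"rcv"`, `"ccv"` or `"sacv"`) and its
#'     parameters (`k`, or `test_size` plus any [sa_config()] fields);
#'   * `method` — regression method for [regression_spec()], or `NULL` to
#'     skip evaluation;
#'   * `distance_zscore` — z-score features before distances (default
#'     `FALSE`).
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with the in-memory stage results and the paths
#'   of all written files.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  t0 <- proc.time()[["elapsed"]]

  # --- data stage -----------------------------------------------------
  if (!is.null(config$synthetic)) {
    stage_msg("simulating synthetic data")
    syn_args <- config$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- seed
    scfg <- do.call(synthetic_config, syn_args)
    ds <- generate_dataset(scfg)
    x <- ds$conditions
    y <- ds$targets
    paths$expression <- write_expression(x, file.path(out_dir, "expression.tsv"))
    paths$targets <- write_expression(y, file.path(out_dir, "targets.tsv"))
    lab <- data.frame(condition_id = rownames(x), cluster = ds$cluster_labels)
    paths$labels <- file.path(out_dir, "labels.tsv")
    utils::write.table(lab, paths$labels, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (is.null(config$expression)) {
      stop("config needs either `synthetic` or `expression`", call. = FALSE)
    }
    stage_msg("reading expression from %s", config$expression)
    x <- read_expression(config$expression,
                         transpose = isTRUE(config$transpose))
    y <- NULL
    if (!is.null(config$targets)) {
      y <- read_expression(config$targets)
      y <- as_target_matrix(y, x)
    }
    ds <- NULL
  }

  # --- distances ------------------------------------------------------
  stage_msg("computing pairwise distances (%d conditions)", nrow(x))
  distances <- compute_pairwise_distances(
    x, zscore = isTRUE(config$distance_zscore))

  # --- partitions -----------------------------------------------------
  pcfg <- config$partition
  if (is.null(pcfg)) pcfg <- list(kind = "rcv", k = 6L)
  stage_msg("generating %s partitions", pcfg$kind)
  pseed <- derive_seed(seed, 10L)
  collection <- switch(
    pcfg$kind,
    rcv = random_kfold(nrow(x), pcfg$k %||% 6L, pseed),
    ccv = clustered_kfold(x, pcfg$k %||% 6L, pseed),
    sacv = {
      sa_args <- pcfg[setdiff(names(pcfg), c("kind", "k"))]
      sa_args$seed <- pseed
      sacv_generate(distances = distances,
                    config = do.call(sa_config, sa_args))$collection
    },
    stop("unknown partition kind: ", pcfg$kind, call. = FALSE)
  )
  paths$partitions <- write_partitions(
    collection, file.path(out_dir, "partitions.json"), rownames(x),
    seed = pseed, meta = pcfg)
  paths$distinctness <- write_distinctness(
    collection, distances, file.path(out_dir, "distinctness.tsv"))

  # --- evaluation -----------------------------------------------------
  result <- NULL
  if (!is.null(config$method) && !is.null(y)) {
    stage_msg("evaluating %s over %d partitions x %d genes", config$method,
              length(collection$partitions), ncol(y))
    spec <- regression_spec(config$method, seed = derive_seed(seed, 20L))
    result <- evaluate_collection(x, y, collection, spec, distances)
    paths$results <- write_results(result,
                                   file.path(out_dir, "results.tsv"))
  }

  # --- manifest -------------------------------------------------------
  manifest <- list(
    package = "distinctcv",
    version = as.character(utils::packageVersion("distinctcv")),
    seed = seed,
    config = config,
    n_conditions = nrow(x),
    n_features = ncol(x),
    n_genes = if (!is.null(y)) ncol(y) else 0L,
    outputs = lapply(paths, basename),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 2)
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  stage_msg("done in %.1fs; outputs in %s", manifest$elapsed_seconds, out_dir)
  invisible(list(conditions = x, targets = y, dataset = ds,
                 distances = distances, collection = collection,
                 result = result, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
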