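#' Configure an end-to-end run
#'
#' Bundles the world configuration with the mapping, inference and RSA
#' parameters. Every stochastic component derives its own seed
#' deterministically from the global seed and a component label, so a rerun
#' with the same configuration reproduces every number bit-identically.
#'
#' @param world a [world_config()]; its `seed` is overridden by a seed
#'   derived from `seed`.
#' @param n_folds outer cross-validation folds (default 5).
#' @param grid a [penalty_grid()].
#' @param n_perm permutation count for the permutation test.
#' @param ks component counts for reduced RSA.
#' @param bin_size dimensions per quantile bin.
#' @param rsa_networks network indices to run RSA on (default all).
#' @param out_dir output directory, or NULL to keep everything in memory.
#' @param seed global integer seed.
#' @return a `run_config`.
#' @export
run_config <- function(world = world_config(), n_folds = 5L,
                       grid = penalty_grid(), n_perm = 199L,
                       ks = c(10L, 5L), bin_size = 100L,
                       rsa_networks = NULL, out_dir = NULL, seed = 1L) {
  stopifnot(inherits(world, "world_config"))
  world$seed <- component_seed(seed, "world")
  structure(list(world = world, n_folds = as.integer(n_folds), grid = grid,
                 n_perm = as.integer(n_perm), ks = as.integer(ks),
                 bin_size = as.integer(bin_size),
                 rsa_networks = rsa_networks, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file may carry a `world` block with any [world_config()] fields and
#' top-level `n_folds`, `n_perm`, `ks`, `bin_size`, `out_dir`, `seed`.
#'
#' @param path path to a .yaml/.yml or .json file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  wc <- do.call(world_config, raw$world %||% list())
  args <- raw[setdiff(names(raw), "world")]
  args$world <- wc
  do.call(run_config, args)
}

# write a numeric matrix as headerless CSV (row order = stimulus order)
write_matrix_csv <- function(M, path) {
  utils::write.table(M, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
}

#' Export a study's activation and brain matrices as plain-text containers
#'
#' One directory per network with one CSV per layer (row order = stimulus
#' order, fit rows first), one CSV per subject, and a JSON sidecar holding
#' the world configuration, the seed, and the split labels.
#'
#' @param study a `unidim_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_study <- function(study, dir) {
  stopifnot(inherits(study, "unidim_study"))
  config <- study$config
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(config$n_networks)) {
    nd <- file.path(dir, sprintf("network%02d", i))
    dir.create(nd, showWarnings = FALSE)
    aset <- pool_activation_set(make_network(study$world, i, "all"))
    for (l in seq_along(aset$layers)) {
      write_matrix_csv(aset$layers[[l]],
                       file.path(nd, sprintf("layer%02d.csv", l)))
    }
  }
  bd <- file.path(dir, "brains")
  dir.create(bd, showWarnings = FALSE)
  for (s in seq_along(study$brains)) {
    write_matrix_csv(study$brains[[s]],
                     file.path(bd, sprintf("subject%02d.csv", s)))
  }
  sidecar <- unclass(config)
  sidecar$split <- list(fit = seq_len(config$n_stim_fit),
                        eval = config$n_stim_fit + seq_len(config$n_stim_eval))
  jsonlite::write_json(sidecar, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full analysis end to end
#'
#' simulate -> pool/PCA -> score -> infer -> RSA -> report. When `out_dir`
#' is set, the score table (CSV), the inference and RSA results, and a
#' machine-readable summary (JSON) are persisted with a config sidecar; an
#' existing `scores.csv` from a previous run with the same config is reused
#' rather than recomputed, so deleting only the report does not redo the
#' mappings.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return list with `table`, `inference`, `rsa` (per network),
#'   `quantiles`, and `summary` (the reported numbers).
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(lbl) say("[%6.1fs] %s", proc.time()[["elapsed"]] - t0, lbl)

  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  stage("simulating world")
  world <- make_latents(config$world)
  study <- build_study(world)
  plan <- fold_plan(config$world$n_stim_eval, config$n_folds,
                    seed = component_seed(config$seed, "folds"))
  engines <- study_engines(study, plan)

  scores_path <- if (!is.null(out_dir)) file.path(out_dir, "scores.csv")
  if (!is.null(out_dir) && file.exists(scores_path)) {
    stage("reusing persisted score table")
    tbl <- utils::read.csv(scores_path)
    class(tbl) <- c("score_table", "data.frame")
  } else {
    stage("scoring dimensions")
    tbl <- score_dimensions(study, plan, config$grid, engines = engines)
    if (!is.null(out_dir)) {
      utils::write.csv(as.data.frame(tbl), scores_path, row.names = FALSE)
    }
  }

  stage("inference (permutation test)")
  inf <- run_inference(study, tbl, plan, config$grid, n_perm = config$n_perm,
                       seed = component_seed(config$seed, "perm_stream"),
                       engines = engines)
  qb <- quantile_bin_means(tbl, config$bin_size)

  stage("representational similarity analysis")
  split <- split_train_test(config$world$n_stim_eval,
                            seed = component_seed(config$seed, "rsa"))
  nets <- config$rsa_networks %||% seq_len(config$world$n_networks)
  rsa <- lapply(nets, function(i) run_rsa(study, i, tbl, split,
                                          ks = config$ks))
  names(rsa) <- paste0("network", nets)

  summary <- list(
    n_dimensions = nrow(tbl),
    rho = inf$rho,
    rho_partial = inf$rho_partial,
    p_value = inf$p_value,
    n_permutations = inf$n_permutations,
    null_association = abs(inf$rho) < 0.1,
    universality_range = range(tbl$universality),
    quantile_bins = qb,
    rsa_full = vapply(rsa, function(r) r$test_similarity_full, numeric(1)),
    rsa_reduced = lapply(rsa, function(r) as.list(r$test_similarity_reduced)),
    seed = config$seed
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    sidecar <- unclass(config$world)
    sidecar$global_seed <- config$seed
    sidecar$n_perm <- config$n_perm
    jsonlite::write_json(sidecar, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  stage("done")
  list(table = tbl, inference = inf, rsa = rsa, quantiles = qb,
       summary = summary)
}
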