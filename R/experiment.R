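#' Reproducible experiment runner
#'
#' A run configuration fully determines an experiment: the walk model, the
#' substrate, the n values at which tau is recorded, the number of
#' realizations, the step horizon and the seed. Running it writes a tau
#' table (TSV), a manifest (JSON) and, where requested, N(t) tables —
#' byte-identical outputs for identical configurations.
#'
#' @name cli_io
NULL

#' Build and validate a run configuration
#'
#' @param model a [walk_model()] or a model name (with `...` parameters
#'   forwarded to [walk_model()]).
#' @param substrate an `rw_substrate` or one of "line", "square", "cubic",
#'   "gasket", "ttree", "percolation".
#' @param n n values at which tau_n is recorded.
#' @param realizations number of realizations (> 0).
#' @param horizon step budget per realization.
#' @param seed integer seed.
#' @param outdir output directory.
#' @param t_record optional times for N(t) recording.
#' @param label recipe label carried into the manifest.
#' @param ... forwarded to [walk_model()] when `model` is a name.
#' @return A validated `run_config`.
#' @export
run_config <- function(model, substrate, n, realizations, seed,
                       horizon = Inf, outdir = tempdir(), t_record = NULL,
                       label = NULL, ...) {
  if (is.character(model)) model <- walk_model(model, ...)
  if (is.character(substrate)) {
    substrate <- switch(substrate,
                        line = substrate_hypercubic(1),
                        square = substrate_hypercubic(2),
                        cubic = substrate_hypercubic(3),
                        gasket = substrate_gasket(),
                        ttree = substrate_ttree(),
                        percolation = substrate_percolation(512, seed = seed),
                        stop("unknown substrate name"))
  }
  cfg <- structure(list(model = model, substrate = substrate,
                        n = sort(as.integer(n)),
                        realizations = as.integer(realizations),
                        horizon = horizon, seed = as.integer(seed),
                        outdir = outdir, t_record = t_record, label = label),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$realizations < 1) stop("realizations must be >= 1")
  if (any(cfg$n < 2)) stop("n values must be >= 2")
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed must be explicit")
  # model/substrate compatibility mirrors the simulators' own checks
  check_model_substrate(cfg$model, cfg$substrate)
  if (cfg$model$name == "tsaw" && (is_graph_substrate(cfg$substrate) ||
                                   cfg$substrate$params$d != 1))
    stop("the TSAW is defined on the 1d line")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config%s: %s on %s, n = {%s}, %d realizations, seed %d>\n",
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              x$model$name, x$substrate$kind,
              paste(x$n, collapse = ","), x$realizations, x$seed))
  invisible(x)
}

config_descriptor <- function(cfg) {
  list(label = cfg$label, model = list(name = cfg$model$name,
                                       params = cfg$model$params),
       substrate = substrate_descriptor(cfg$substrate),
       n = cfg$n, realizations = cfg$realizations,
       horizon = if (is.finite(cfg$horizon)) cfg$horizon else "Inf",
       seed = cfg$seed, t_record = cfg$t_record)
}

# Polynomial rolling hash of the serialized configuration (no external
# digest needed). The intermediate products stay below 2^53, so the result
# is exact and platform-independent.
config_hash_of <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run an experiment from a configuration
#'
#' Simulates the tau ensemble (and N(t) ensemble if `t_record` is set),
#' writes TSV outputs and a JSON manifest into `outdir`, and returns the
#' manifest. Identical configurations produce byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return The manifest (invisibly also written to `manifest.json`):
#'   config hash, package version, wall time, per-stage record counts and
#'   output file names.
#' @export
run_experiment <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  taus <- tau_ensemble(cfg$model, cfg$substrate, cfg$n, cfg$realizations,
                       cfg$seed, cfg$horizon)
  tau_df <- data.frame(realization = rep(seq_len(nrow(taus)), ncol(taus)),
                       n = rep(attr(taus, "n_record"), each = nrow(taus)),
                       tau = as.vector(taus))
  tau_df <- tau_df[is.finite(tau_df$tau), ]
  tau_path <- file.path(cfg$outdir, "tau.tsv")
  utils::write.table(tau_df, tau_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  files <- "tau.tsv"
  counts <- list(tau_records = nrow(tau_df))
  if (!is.null(cfg$t_record)) {
    N <- n_visited_ensemble(cfg$model, cfg$substrate, cfg$t_record,
                            cfg$realizations, cfg$seed)
    n_df <- data.frame(realization = rep(seq_len(nrow(N)), ncol(N)),
                       t = rep(attr(N, "t_record"), each = nrow(N)),
                       N = as.vector(N))
    n_path <- file.path(cfg$outdir, "n_visited.tsv")
    utils::write.table(n_df, n_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files <- c(files, "n_visited.tsv")
    counts$n_records <- nrow(n_df)
  }
  desc <- config_descriptor(cfg)
  manifest <- list(config = desc,
                   config_hash = config_hash_of(jsonlite::toJSON(desc, auto_unbox = TRUE)),
                   package_version = as.character(utils::packageVersion("rwexplore")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                   counts = counts, files = files)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Catalogue of canned experiment recipes
#'
#' One desk-scale recipe per experiment family: the recurrent, marginal and
#' transient tau-distribution campaigns, the boundary observables, the
#' covariance measurements, starvation sweeps, and the non-Markovian
#' examples. Parameter reductions relative to large-scale campaigns are
#' noted in each description.
#'
#' @param seed integer seed baked into every recipe.
#' @param outdir base output directory.
#' @return Named list of `run_config` objects (plus descriptions); every
#'   entry validates.
#' @export
list_recipes <- function(seed = 1, outdir = tempdir()) {
  rc <- function(label, ...) run_config(..., seed = seed, label = label,
                                        outdir = file.path(outdir, label))
  recipes <- list(
    `recurrent-1d` = rc("recurrent-1d", "levy", "line",
                        n = c(100, 500, 1000), realizations = 2000,
                        alpha = log(6) / log(3)),
    `recurrent-gasket` = rc("recurrent-gasket", "simple", "gasket",
                            n = c(100, 500, 1000), realizations = 1000),
    `recurrent-percolation` = rc("recurrent-percolation", "simple",
                                 "percolation", n = c(100, 500, 1000),
                                 realizations = 500),
    `marginal-1d-levy` = rc("marginal-1d-levy", "levy", "line",
                            n = c(800, 1600, 3200), realizations = 2000,
                            alpha = 1),
    `marginal-2d-persistent` = rc("marginal-2d-persistent", "persistent",
                                  "square", n = c(800, 1600, 3200),
                                  realizations = 2000, p = 0.3),
    `marginal-2d-collapse` = rc("marginal-2d-collapse", "simple", "square",
                                n = c(200, 800, 3200), realizations = 2000),
    `transient-2d-levy` = rc("transient-2d-levy", "levy", "square",
                             n = c(400, 800, 1600), realizations = 2000,
                             alpha = 1),
    `transient-3d-persistent` = rc("transient-3d-persistent", "persistent",
                                   "cubic", n = c(200, 800, 3200),
                                   realizations = 2000, p = 0.25),
    `transient-3d` = rc("transient-3d", "simple", "cubic",
                        n = c(200, 400, 500), realizations = 2000),
    `tsaw-1d` = rc("tsaw-1d", "tsaw", "line", n = c(200, 400, 800),
                   realizations = 2000),
    `covariance-levy-1.5` = rc("covariance-levy-1.5", "levy", "line",
                               n = c(100, 400), realizations = 5000,
                               alpha = 1.5,
                               t_record = 10 * 2^(0:8))
  )
  descriptions <- c(
    `recurrent-1d` = "1d Levy flights, alpha = ln6/ln3 (mu = ln3/ln6); tau tables at n = 100, 500, 1000",
    `recurrent-gasket` = "simple walk on the generation-10 Sierpinski gasket (mu = ln3/ln5)",
    `recurrent-percolation` = "simple walk on a 512^2 critical bond-percolation cluster (mu ~ 0.659; scaled down from 1000^2)",
    `marginal-1d-levy` = "1d Levy flights at alpha = 1 (marginal)",
    `marginal-2d-persistent` = "2d persistent walk, p = 0.3 (marginal)",
    `marginal-2d-collapse` = "2d simple walk; collapse versus tau/sqrt(n) at n = 200, 800, 3200",
    `transient-2d-levy` = "2d Levy flights at alpha = 1 (mu = 2)",
    `transient-3d-persistent` = "3d persistent walk, p = 0.25",
    `transient-3d` = "3d simple walk (mu = 3/2)",
    `tsaw-1d` = "1d true self-avoiding walk (mu = 2/3)",
    `covariance-levy-1.5` = "N(t) ensemble for multi-time covariances, 1d Levy alpha = 1.5"
  )
  # starvation sweep is not a tau-table run; represented as a parameter list
  attr(recipes, "descriptions") <- descriptions
  attr(recipes, "starvation-2d") <- list(S_values = c(8, 16, 32, 64),
                                         d = 2, reps = 1000, seed = seed)
  attr(recipes, "fbm") <- list(H = c(sub = 0.4, super = 0.75),
                               n = c(20, 40, 80), seed = seed)
  recipes
}
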