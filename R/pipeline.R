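# End-to-end command wrappers: read inputs, run an analysis stage, write
# plain-text results plus a manifest sufficient to reproduce the run.
# Progress is logged via message() (standard error); results go to files.

.manifest <- function(dir, command, inputs = character(0), config = list()) {
  man <- list(
    command = command,
    package = as.character(utils::packageVersion("divshift")),
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)), basename(inputs)))
    else list(),
    config = config)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

.ensure_dir <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  dir
}

#' Run the diversification-rate shift analysis on files
#'
#' Reads a chronogram and a richness table, runs [run_search], and writes
#' `search_steps.tsv`, `search_report.json`, and `manifest.json` to the
#' output directory. Each forward/backward step is logged to standard
#' error.
#'
#' @param tree Path to a Newick chronogram.
#' @param richness Path to a richness TSV, or `NULL` for a fully resolved
#'   tree.
#' @param cutoff AIC cutoff (default 4).
#' @param out Output directory.
#' @param quiet Suppress progress messages?
#' @return The `search_report`, invisibly.
#' @export
cmd_shift <- function(tree, richness = NULL, cutoff = 4, out, quiet = FALSE) {
  .ensure_dir(out)
  tr <- read_newick(tree)
  rich <- if (!is.null(richness)) read_richness(richness) else NULL
  match_richness(tr, rich)  # fail early with file context
  if (!quiet)
    message(sprintf("shift search: %d tips, cutoff %.3g (constant-rate model: k = 2)",
                    length(tr$tip.label), cutoff))
  rep <- run_search(tr, rich, cutoff = cutoff)
  if (!quiet) {
    for (i in seq_len(nrow(rep$steps))) {
      s <- rep$steps[i, ]
      message(sprintf("  step %d [%s%s]: lnL = %.4f, k = %d, AIC = %.4f",
                      s$step, s$action,
                      if (is.na(s$node)) "" else paste0(" ", s$node),
                      s$lnL, s$k, s$AIC))
    }
    message(sprintf("final: %d shift(s), delta AIC = %.4f",
                    length(rep$final_model$shifts), rep$delta_aic))
  }
  write_search_report(rep, out)
  .manifest(out, "shift",
            inputs = c(tree, if (!is.null(richness)) richness),
            config = list(cutoff = cutoff))
  invisible(rep)
}

#' Run the richness-envelope analysis on files
#'
#' Builds a confidence envelope for expected clade richness through time
#' and classifies the clades of a clade table against it. The envelope
#' rate can come from a named preset, an explicit `(r, eps)` pair, or be
#' estimated from a richness/age pair via [estimate_r]
#' (`estimate_from = c(n, t)`), in which case the estimate is logged.
#'
#' @param clades Path to a clade table TSV (see [read_clade_table]), or
#'   `NULL` to export the envelope only.
#' @param preset One of `"low"`, `"high"`, `"background"`
#'   (see [envelope_presets]); ignored when `r` is given.
#' @param r,eps Explicit envelope parameters.
#' @param estimate_from Optional `c(n, t)`: estimate `r` from richness `n`
#'   and age `t` at the given `eps` and `mode` before building the
#'   envelope.
#' @param mode `"crown"` or `"stem"` (estimator and envelope law).
#' @param level Confidence level (default 0.95).
#' @param t_max,step Envelope grid (Ma).
#' @param out Output directory.
#' @param quiet Suppress progress messages?
#' @return List with the envelope table and (when clades were given) the
#'   assessments, invisibly.
#' @export
cmd_envelope <- function(clades = NULL, preset = NULL, r = NULL, eps = NULL,
                         estimate_from = NULL, mode = "crown", level = 0.95,
                         t_max = 100, step = 1, out, quiet = FALSE) {
  .ensure_dir(out)
  if (!is.null(estimate_from)) {
    if (is.null(eps)) eps <- 0
    r <- estimate_r(estimate_from[1L], estimate_from[2L], eps, mode)
    if (!quiet)
      message(sprintf("estimated r = %.4g per Myr (n = %d, t = %g Ma, eps = %g, %s)",
                      r, as.integer(estimate_from[1L]), estimate_from[2L],
                      eps, mode))
  } else if (is.null(r)) {
    if (is.null(preset)) stop("give a preset, an explicit r, or estimate_from")
    ps <- envelope_presets()[[match.arg(preset, c("low", "high", "background"))]]
    r <- ps$r
    eps <- ps$eps
  }
  if (is.null(eps)) eps <- 0
  env <- envelope_table(r, eps, mode, level, t_max, step)
  utils::write.csv(env, file.path(out, "envelope.csv"), row.names = FALSE)
  assessed <- NULL
  if (!is.null(clades)) {
    tab <- read_clade_table(clades)
    tab <- tab[!is.na(tab$richness), , drop = FALSE]
    if (nrow(tab)) {
      assessed <- assess_clades(tab, r, eps, level)
      utils::write.table(assessed, file.path(out, "assessments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (!quiet) message("clade table has no richness entries; envelope only")
  }
  .manifest(out, "envelope", inputs = c(if (!is.null(clades)) clades),
            config = list(r = r, eps = eps, mode = mode, level = level,
                          t_max = t_max, step = step))
  invisible(list(envelope = env, assessments = assessed))
}

#' Simulate a dataset to files
#'
#' Runs [simulate_tree] (optionally followed by [collapse_to_backbone])
#' and writes `tree.nwk`, `richness.tsv`, and a manifest carrying the full
#' configuration and seed, so the run can be reproduced exactly.
#'
#' @param config A [sim_config], or a path to a JSON file of its fields.
#' @param cut_age Optional collapse age passed to [collapse_to_backbone].
#' @param out Output directory.
#' @return Invisibly, the list of generated objects.
#' @export
cmd_simulate <- function(config, cut_age = NULL, out) {
  .ensure_dir(out)
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- sim_config(b = cfg$b, d = if (is.null(cfg$d)) 0 else cfg$d,
                         duration = cfg$duration, n_tips = cfg$n_tips,
                         seed = cfg$seed,
                         start = if (is.null(cfg$start)) "crown" else cfg$start,
                         shift = if (!is.null(cfg$shift)) as.list(cfg$shift))
    if (is.null(cut_age) && !is.null(cfg$cut_age)) cut_age <- cfg$cut_age
  }
  tree <- simulate_tree(config)
  if (!is.null(cut_age)) {
    bb <- collapse_to_backbone(tree, cut_age)
    tree <- bb$tree
    richness <- bb$richness
  } else {
    richness <- data.frame(tip = tree$tip.label,
                           n_species = 1L, stringsAsFactors = FALSE)
  }
  write_newick(tree, file.path(out, "tree.nwk"))
  utils::write.table(richness, file.path(out, "richness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .manifest(out, "simulate",
            config = c(unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                       list(cut_age = cut_age)))
  invisible(list(tree = tree, richness = richness, config = config))
}

#' Write the bundled cichlid dataset to files
#'
#' Emits the [cichlid_fixture] tables as `clades.tsv` and `richness.tsv`
#' plus the envelope presets as `presets.json`, with a manifest.
#'
#' @param out Output directory.
#' @param mode Passed to [cichlid_fixture].
#' @return Invisibly, the fixture list.
#' @export
cmd_fixture <- function(out, mode = "crown") {
  .ensure_dir(out)
  fx <- suppressWarnings(cichlid_fixture(mode))
  utils::write.table(fx$clades, file.path(out, "clades.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(fx$richness, file.path(out, "richness.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fx$presets, file.path(out, "presets.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .manifest(out, "fixture", config = list(mode = mode))
  invisible(fx)
}
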