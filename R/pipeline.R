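# Pipeline orchestration: each analysis stage behind one entry point with a
# structured configuration, deterministic outputs and a run manifest.

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or YAML file) with an integer `seed`,
#' an `out_dir`, and stage-specific entries. Every referenced input path must
#' exist at validation time, and a seed is mandatory because every stochastic
#' stage is seeded.
#'
#' @param config named list or path to a YAML file.
#' @param base_dir directory against which relative paths are resolved.
#' @return the validated configuration (paths resolved), invisibly classed
#'   `run_config`.
#' @export
read_run_config <- function(config, base_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    base_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path", call. = FALSE)
  if (is.null(config$seed) || !is.numeric(config$seed))
    stop("config must declare an integer 'seed'", call. = FALSE)
  if (is.null(config$out_dir)) stop("config must declare 'out_dir'", call. = FALSE)
  paths <- config$paths
  if (!is.null(paths)) {
    for (nm in names(paths)) {
      p <- paths[[nm]]
      if (!file.exists(p)) {
        p2 <- file.path(base_dir, p)
        if (!file.exists(p2))
          stop(sprintf("input path '%s' does not exist: %s", nm, p), call. = FALSE)
        paths[[nm]] <- p2
      }
    }
    config$paths <- paths
  }
  structure(config, class = c("run_config", "list"))
}

.stage_names <- c("simulate", "molrate", "predict-macro", "drift",
                  "fit-traits", "mk", "depth")

#' Run one pipeline stage
#'
#' Subcommand-style orchestration of the full analysis: `"simulate"` writes
#' the synthetic study fixture; `"molrate"` estimates micro- and
#' macroevolutionary molecular rates and compares their confidence
#' intervals; `"predict-macro"` runs the haplotype-pruning prediction;
#' `"drift"` runs the trait drift simulation, model fit, prediction
#' probability and Ne-specificity test; `"fit-traits"` fits BM/OU with AICc
#' selection and the parametric-bootstrap power analysis; `"mk"` runs the
#' McDonald-Kreitman test; `"depth"` the genotype-depth association. Every
#' run writes its results plus a `manifest.json` (configuration echo, seed,
#' package version) under the configured output directory; inputs are never
#' modified, and a rerun with the same configuration reproduces the output
#' files byte for byte.
#'
#' @param stage one of `"simulate"`, `"molrate"`, `"predict-macro"`,
#'   `"drift"`, `"fit-traits"`, `"mk"`, `"depth"`.
#' @param config configuration list or YAML path; see [read_run_config()].
#' @param quiet suppress progress messages.
#' @return list of stage results, invisibly; files are written to
#'   `config$out_dir/<stage>/`.
#' @export
run_pipeline <- function(stage, config, quiet = FALSE) {
  stage <- match.arg(stage, .stage_names)
  cfg <- read_run_config(config)
  out <- file.path(cfg$out_dir, stage)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  say("stage '%s' (seed %d) -> %s", stage, cfg$seed, out)

  res <- switch(stage,
    "simulate" = .stage_simulate(cfg, out),
    "molrate" = .stage_molrate(cfg, out),
    "predict-macro" = .stage_predict_macro(cfg, out),
    "drift" = .stage_drift(cfg, out),
    "fit-traits" = .stage_fit_traits(cfg, out),
    "mk" = .stage_mk(cfg, out),
    "depth" = .stage_depth(cfg, out)
  )
  manifest <- list(stage = stage, seed = cfg$seed,
                   package = "evoscales",
                   version = as.character(utils::packageVersion("evoscales")),
                   config = unclass(cfg))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.rate_record <- function(est) {
  list(label = est$label, median = est$median, ci_low = est$ci_low,
       ci_high = est$ci_high, n = est$n)
}

.cfg_model <- function(cfg, aln) {
  mc <- cfg$model
  if (is.null(mc) || identical(mc$name, "HKY") && is.null(mc$kappa)) return(NULL)
  if (identical(mc$name, "JC")) return(subst_model("JC"))
  pi <- if (is.null(mc$pi)) empirical_frequencies(aln) else unlist(mc$pi)
  subst_model("HKY", kappa = mc$kappa, pi = pi)
}

.stage_simulate <- function(cfg, out) {
  fx <- make_study_fixture(cfg$fixture %||% list(), master_seed = cfg$seed)
  write_fixture(fx, file.path(out, "fixture"))
  fx
}

.read_dist <- function(path, units = "Myr") {
  read_tree_distribution(path, format = "multi-newick", units = units)
}

.stage_molrate <- function(cfg, out) {
  p <- cfg$paths
  micro_dist <- .read_dist(p$micro_trees)
  macro_dist <- .read_dist(p$macro_trees)
  micro_aln <- read_fasta(p$micro_alignment)
  macro_aln <- read_fasta(p$macro_alignment)
  micro <- rate_over_distribution(micro_dist, micro_aln,
                                  .cfg_model(cfg, micro_aln), label = "micro")
  macro <- rate_over_distribution(macro_dist, macro_aln,
                                  .cfg_model(cfg, macro_aln), label = "macro")
  cmp <- rate_ci_compare(micro, macro)
  .write_json(list(micro = .rate_record(micro), macro = .rate_record(macro),
                   comparison = cmp), file.path(out, "rates.json"))
  write.table(rbind(as.data.frame(micro), as.data.frame(macro)),
              file.path(out, "per_tree_rates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(micro = micro, macro = macro, comparison = cmp)
}

.stage_predict_macro <- function(cfg, out) {
  p <- cfg$paths
  combined <- .read_dist(p$combined_trees)
  aln <- read_fasta(p$alignment)
  clade <- readLines(p$clade_tips)
  clade <- clade[nzchar(clade)]
  inds <- if (is.null(cfg$n_individuals)) clade else clade[seq_len(min(cfg$n_individuals, length(clade)))]
  pred <- predict_macro_rate_by_pruning(combined, aln, .cfg_model(cfg, aln),
                                        clade_tips = clade, individuals = inds)
  .write_json(list(macro_predicted = .rate_record(pred)),
              file.path(out, "predicted_rate.json"))
  write.table(as.data.frame(pred), file.path(out, "per_tree_rates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pred
}

.cfg_drift <- function(cfg) {
  d <- cfg$drift
  if (is.null(d)) stop("config must declare 'drift' (s2, Ne, tau)", call. = FALSE)
  drift_params(d$s2, d$Ne, d$tau)
}

.stage_drift <- function(cfg, out) {
  p <- cfg$paths
  tree <- read_newick(readLines(p$tree)[1], units = "Myr")
  traits <- read_trait_table(p$traits)
  dp <- .cfg_drift(cfg)
  n_sim <- cfg$n_sim %||% 100L
  mode <- cfg$drift_mode %||% "exact"
  pred <- drift_prediction_test(tree, traits, dp, n_sim = n_sim,
                                seed = cfg$seed, mode = mode)
  scales <- unlist(cfg$specificity_scales %||% c(0.01, 1, 100))
  spec <- specificity_test(tree, traits, dp, scales = scales, n_sim = n_sim,
                           seed = cfg$seed, mode = mode)
  .write_json(list(
    predicted_bm_rate = predicted_bm_rate(dp),
    empirical_model = pred$empirical_fit$model,
    empirical_sigma2 = pred$empirical_fit$sigma2,
    prediction_probability = pred$p,
    significant = pred$significant
  ), file.path(out, "drift_prediction.json"))
  write.table(spec, file.path(out, "specificity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = c(rep("empirical", length(pred$emp_rates)),
                                    rep("simulated", length(pred$sim_rates))),
                         sigma2 = c(pred$emp_rates, pred$sim_rates)),
              file.path(out, "sigma2_samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  list(prediction = pred, specificity = spec)
}

.stage_fit_traits <- function(cfg, out) {
  p <- cfg$paths
  tree <- read_newick(readLines(p$tree)[1], units = "Myr")
  traits <- read_trait_table(p$traits)
  x <- .trait_vector(traits, tree$tip.label)
  fb <- fit_bm(tree, x)
  fo <- fit_ou(tree, x)
  best <- aicc_select(list(fb, fo), n = length(x))
  B <- cfg$pmc_B %||% 200L
  pmc <- pmc_power(tree, x, B = B, seed = cfg$seed)
  rec <- function(f) list(model = f$model, sigma2 = f$sigma2,
                          alpha = if (is.na(f$alpha)) NULL else f$alpha,
                          theta = f$theta, loglik = f$loglik, aicc = f$aicc)
  .write_json(list(bm = rec(fb), ou = rec(fo), selected = best$model,
                   pmc = list(B = B, delta_obs = pmc$delta_obs,
                              p_value = pmc$p_value, power = pmc$power)),
              file.path(out, "trait_fits.json"))
  list(bm = fb, ou = fo, selected = best, pmc = pmc)
}

.stage_mk <- function(cfg, out) {
  p <- cfg$paths
  aln <- read_fasta(p$alignment)
  og_id <- cfg$outgroup
  if (is.null(og_id)) stop("config must declare 'outgroup' (sequence id)", call. = FALSE)
  if (!og_id %in% rownames(aln)) stop("outgroup not in alignment: ", og_id, call. = FALSE)
  ingroup_ids <- setdiff(rownames(aln), og_id)
  if (!is.null(cfg$ingroup_prefix))
    ingroup_ids <- grep(cfg$ingroup_prefix, ingroup_ids, value = TRUE)
  tab <- mk_test(mk_counts(aln[ingroup_ids, , drop = FALSE],
                           aln[og_id, , drop = FALSE]))
  .write_json(list(Pn = tab$Pn, Ps = tab$Ps, Dn = tab$Dn, Ds = tab$Ds,
                   NI = if (is.na(tab$NI)) NULL else tab$NI,
                   alpha = if (is.na(tab$alpha)) NULL else tab$alpha,
                   p = tab$p, outgroup = og_id),
              file.path(out, "mk_test.json"))
  tab
}

.stage_depth <- function(cfg, out) {
  p <- cfg$paths
  dat <- read.table(p$depth_data, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  res <- depth_association(dat)
  .write_json(list(statistic = res$statistic, p = res$p, n = res$n,
                   states = res$states, method = res$method, note = res$note),
              file.path(out, "depth_association.json"))
  res
}
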