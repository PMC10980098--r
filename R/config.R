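#' Optimization run configuration
#'
#' Flat key/value configuration for the design loop. Every tunable named by
#' the scoring and optimization modules is surfaced here; unknown keys are
#' rejected so that config-file typos cannot silently change a run.
#'
#' Keys and defaults:
#' \describe{
#'   \item{protein_chain, peptide_chain}{chain ids used when parsing PDB
#'     input ("A", "B").}
#'   \item{objectives}{exactly two of `"interface_sasa"`, `"energy"`,
#'     `"binding_ratio"` (default buried interface area + contact energy, the
#'     pair tracked round-by-round in the optimization summaries).}
#'   \item{directions}{per-objective `"maximize"`/`"minimize"`. Defaults:
#'     interface_sasa maximize, energy minimize, binding_ratio maximize.}
#'   \item{cutoff}{residue-contact cutoff, Angstrom (5).}
#'   \item{probe_radius, n_points}{surface-area parameters (1.4 A, 960).}
#'   \item{well_depth, contact_distance, clash_distance, clash_penalty}{
#'     contact-potential parameters (1, 5 A, 2.5 A, 10).}
#'   \item{binding_side}{chain whose binding ratio is the scalar objective
#'     ("protein"; "peptide" and "mean" also accepted).}
#'   \item{n_rounds, batch_size}{optimization budget (64 rounds of 16).}
#'   \item{n_seeds, mutations_per_seed}{seed pool (16 mutants at Hamming 2).}
#'   \item{seed_fasta}{optional FASTA of user-supplied seed peptides (e.g.
#'     natural sequence variants) used instead of random mutants.}
#'   \item{include_native}{score the native sequence with the seeds (FALSE).}
#'   \item{mutations_per_proposal}{substitutions per proposed mutant (1).}
#'   \item{n_candidates}{mutants generated per round before acquisition
#'     ranking (256).}
#'   \item{n_mc}{Monte-Carlo draws for the acquisition (128).}
#'   \item{ref_margin}{reference-point margin below the observed minimum, as
#'     a fraction of the observed range (0.1).}
#'   \item{max_len}{embedding padding length; NULL = native peptide length.}
#'   \item{proposer}{`"nehvi"` or `"random"` (uniform-random selection at the
#'     same candidate-generation budget, the baseline arm).}
#'   \item{seed}{base RNG seed for the whole run (1).}
#' }
#'
#' @param ... overrides of the defaults above.
#' @return object of class `bo_config`.
#' @export
bo_config <- function(...) {
  defaults <- list(
    protein_chain = "A", peptide_chain = "B",
    objectives = c("interface_sasa", "energy"),
    directions = NULL,
    cutoff = 5.0, probe_radius = 1.4, n_points = 960,
    well_depth = 1.0, contact_distance = 5.0,
    clash_distance = 2.5, clash_penalty = 10.0,
    binding_side = "protein",
    n_rounds = 64L, batch_size = 16L,
    n_seeds = 16L, mutations_per_seed = 2L, include_native = FALSE,
    seed_fasta = NULL,
    mutations_per_proposal = 1L, n_candidates = 256L,
    n_mc = 128L, ref_margin = 0.1, max_len = NULL,
    proposer = "nehvi", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_pf("unknown configuration key(s): %s",
            paste(unknown, collapse = ", "), class = "pepforge_bad_config")
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  valid_obj <- c("interface_sasa", "energy", "binding_ratio")
  if (length(cfg$objectives) != 2 || !all(cfg$objectives %in% valid_obj))
    stop_pf("objectives must be exactly two of: %s",
            paste(valid_obj, collapse = ", "), class = "pepforge_bad_config")
  default_dir <- c(interface_sasa = "maximize", energy = "minimize",
                   binding_ratio = "maximize")
  if (is.null(cfg$directions))
    cfg$directions <- unname(default_dir[cfg$objectives])
  if (length(cfg$directions) != 2 ||
      !all(cfg$directions %in% c("maximize", "minimize")))
    stop_pf("directions must be two of 'maximize'/'minimize'",
            class = "pepforge_bad_config")
  if (cfg$n_rounds < 1 || cfg$batch_size < 1)
    stop_pf("n_rounds and batch_size must be >= 1",
            class = "pepforge_bad_config")
  if (!cfg$proposer %in% c("nehvi", "random"))
    stop_pf("proposer must be 'nehvi' or 'random'",
            class = "pepforge_bad_config")
  if (!cfg$binding_side %in% c("protein", "peptide", "mean"))
    stop_pf("binding_side must be 'protein', 'peptide' or 'mean'",
            class = "pepforge_bad_config")
  structure(cfg, class = "bo_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat key/value YAML with exactly the keys documented in [bo_config()];
#' unknown keys are an error.
#'
#' @param path YAML file path.
#' @return a `bo_config`.
#' @export
read_bo_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_pf("the 'yaml' package is required to read configuration files",
            class = "pepforge_bad_config")
  vals <- yaml::read_yaml(path)
  if (!is.list(vals))
    stop_pf("configuration file must be a key/value mapping",
            class = "pepforge_bad_config")
  vals$objectives <- if (!is.null(vals$objectives)) unlist(vals$objectives)
  vals$directions <- if (!is.null(vals$directions)) unlist(vals$directions)
  do.call(bo_config, vals)
}

#' @export
print.bo_config <- function(x, ...) {
  cat("<bo_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-22s %s\n", k,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

# The two configured structural objectives as a single scoring closure.
objective_scorer <- function(config) {
  pot <- contact_potential(config$well_depth, config$contact_distance,
                           config$clash_distance, config$clash_penalty)
  force(config)
  function(complex) {
    vapply(config$objectives, function(obj) {
      switch(obj,
        interface_sasa = as.numeric(interface_buried_sasa(
          complex, config$probe_radius, config$n_points)),
        energy = contact_energy(complex, pot),
        binding_ratio = {
          if (config$binding_side == "mean")
            mean(c(binding_ratio(complex, "protein", config$cutoff),
                   binding_ratio(complex, "peptide", config$cutoff)))
          else binding_ratio(complex, config$binding_side, config$cutoff)
        })
    }, numeric(1))
  }
}
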