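# Reproducible pipeline runs: one subcommand per pipeline stage, a config
# file (YAML or JSON) with dotted-key overrides, and a JSON run manifest
# (config hash, seed, input digests, timings, outputs) per run.

.config_error <- function(msg)
  stop(structure(class = c("evoscape_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))

.input_error <- function(msg)
  stop(structure(class = c("evoscape_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))

.read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) .config_error(paste("config file not found:", config))
  out <- tryCatch({
    if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }, error = function(e) .config_error(paste("malformed config:", conditionMessage(e))))
  if (!is.list(out)) .config_error("malformed config: not a mapping")
  out
}

# apply "a.b=value" overrides to a nested list
.apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) .config_error(paste("bad override:", ov))
    path <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    cfg[[path]] <- val
  }
  cfg
}

.cfg_get <- function(cfg, key, default = NULL, required = FALSE) {
  v <- cfg[[key]]
  if (is.null(v)) {
    if (required) .config_error(paste("missing config key:", key))
    return(default)
  }
  v
}

.load_dataset <- function(dir) {
  if (!dir.exists(dir)) .input_error(paste("data directory not found:", dir))
  wt_path <- file.path(dir, "wildtype.fasta")
  if (!file.exists(wt_path)) .input_error("wildtype.fasta not found")
  files <- sort(list.files(dir, pattern = "^round_\\d+\\.fasta$",
                           full.names = TRUE))
  if (length(files) == 0L) .input_error("no round_*.fasta files found")
  rounds <- as.integer(sub("^round_0*(\\d+)\\.fasta$", "\\1", basename(files)))
  samples <- Map(read_round_fasta, files, rounds)
  trajectory_dataset(read_wildtype_fasta(wt_path), unname(samples))
}

#' Run one pipeline stage with config, seed and manifest
#'
#' Subcommands: `synth` (generate a planted landscape and trajectory),
#' `simulate` (trajectory over a given model), `moments` (per-round
#' frequency tables and population statistics), `infer` (full landscape
#' fit), `score` (score sequences under a model), `epistasis` (double
#' mutant classification), `walk` (adaptive walk), `survey` (convergence
#' survey), `evaluate` (contact PPV of a model against a contact map).
#' Every run writes its outputs plus `manifest.json` into `outdir`.
#'
#' @param subcommand one of the stage names above.
#' @param config path to a YAML/JSON config file, or a named list.
#' @param outdir output directory (created; default `"evoscape_run"`).
#' @param seed integer seed for all stochastic stages.
#' @param overrides character vector of `key.subkey=value` config
#'   overrides.
#' @param verbose print progress.
#' @return invisibly, the manifest (also written as JSON).
#' @export
evoscape_run <- function(subcommand, config = list(), outdir = "evoscape_run",
                         seed = 1L, overrides = character(0),
                         verbose = FALSE) {
  known <- c("synth", "simulate", "moments", "infer", "score", "epistasis",
             "walk", "survey", "evaluate")
  if (!subcommand %in% known)
    stop(structure(class = c("evoscape_usage_error", "error", "condition"),
                   list(message = paste("unknown subcommand:", subcommand),
                        call = NULL)))
  cfg <- .apply_overrides(.read_config(config), overrides)
  seed <- as.integer(seed)
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name) { outputs <<- c(outputs, name); file.path(outdir, name) }

  model_from_cfg <- function() {
    path <- .cfg_get(cfg, "model", required = TRUE)
    if (!file.exists(path)) .input_error(paste("model file not found:", path))
    read_potts(path)
  }

  if (subcommand == "synth") {
    truth <- generate_landscape(
      L = .cfg_get(cfg, "L", 30L), n_coupled_pairs = .cfg_get(cfg, "n_coupled_pairs", 5L),
      field_scale = .cfg_get(cfg, "field_scale", 1.0),
      coupling_scale = .cfg_get(cfg, "coupling_scale", 1.5),
      n_perturb = .cfg_get(cfg, "n_perturb", 3L), seed = seed)
    synth <- generate_trajectory_dataset(
      truth, rounds = .cfg_get(cfg, "rounds", 8L),
      pop_size = .cfg_get(cfg, "pop_size", 5000L),
      brood = .cfg_get(cfg, "brood", 100L),
      sample_sizes = .cfg_get(cfg, "sample_sizes", 2000L),
      target_load = .cfg_get(cfg, "target_load", 4), seed = seed)
    write_synthetic_trajectory(synth, outdir)
    outputs <- c(outputs, list.files(outdir))
  } else if (subcommand == "simulate") {
    landscape <- model_from_cfg()
    wt <- read_wildtype_fasta(.cfg_get(cfg, "wildtype", required = TRUE))
    mm <- build_mutation_model(read_bias_tsv(.cfg_get(
      cfg, "bias", system.file("extdata", "epcr_bias_synthetic.tsv",
                               package = "evoscape"))),
      .cfg_get(cfg, "target_load", 4), length(wt))
    ds <- simulate_trajectory(wt, mm, landscape,
                              rounds = .cfg_get(cfg, "rounds", 8L),
                              pop_size = .cfg_get(cfg, "pop_size", 5000L),
                              brood = .cfg_get(cfg, "brood", 100L),
                              sample_sizes = .cfg_get(cfg, "sample_sizes", 2000L),
                              seed = seed)
    for (s in ds$rounds)
      write_round_fasta(s, emit(sprintf("round_%02d.fasta", s$round)))
    utils::write.table(population_stats(ds), emit("population_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "moments") {
    ds <- .load_dataset(.cfg_get(cfg, "data_dir", required = TRUE))
    utils::write.table(population_stats(ds), emit("population_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (s in ds$rounds) {
      f <- empirical_frequencies(s, second = FALSE)
      write_first_order_tsv(f, emit(sprintf("freq_round_%02d.tsv", s$round)))
    }
  } else if (subcommand == "infer") {
    ds <- .load_dataset(.cfg_get(cfg, "data_dir", required = TRUE))
    mm <- build_mutation_model(read_bias_tsv(.cfg_get(
      cfg, "bias", system.file("extdata", "epcr_bias_synthetic.tsv",
                               package = "evoscape"))),
      .cfg_get(cfg, "target_load", 4), length(ds$wildtype))
    icfg <- inference_config(
      lambda_main = .cfg_get(cfg, "lambda_main", 1e-3),
      lambda_int = .cfg_get(cfg, "lambda_int", 1e-2),
      rho = .cfg_get(cfg, "rho", 1e5),
      lambda_reg = .cfg_get(cfg, "lambda_reg", 50),
      learning_rate = .cfg_get(cfg, "learning_rate", 0.03),
      max_steps = .cfg_get(cfg, "max_steps", 700L),
      seed = seed)
    fit <- fit_landscape(ds, mm, config = icfg, verbose = verbose)
    write_potts(fit$model, emit("model.json"))
    utils::write.table(
      data.frame(step = seq_along(fit$mean_fit$loss_trace) - 1L,
                 loss = fit$mean_fit$loss_trace),
      emit("loss_trace.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    mem <- mutation_effect_map(fit$model, fit$wildtype_aa)
    utils::write.table(cbind(position = seq_len(nrow(mem)), as.data.frame(mem)),
                       emit("mutation_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (subcommand == "score") {
    landscape <- model_from_cfg()
    path <- .cfg_get(cfg, "sequences", required = TRUE)
    if (!file.exists(path)) .input_error(paste("sequence file not found:", path))
    s <- read_round_fasta(path, 0L)
    ab <- codon_alphabet()
    sc <- score_sequences(landscape,
                          matrix(ab$ac_map[s$seqs], nrow = nrow(s$seqs)))
    utils::write.table(data.frame(record = seq_along(sc), score = sc),
                       emit("scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (subcommand == "epistasis") {
    landscape <- model_from_cfg()
    wt <- read_wildtype_fasta(.cfg_get(cfg, "wildtype", required = TRUE))
    ep <- classify_epistasis(landscape, translate_codons(wt),
                             tol = .cfg_get(cfg, "tol", 1e-9))
    jsonlite::write_json(list(counts = as.list(ep$counts),
                              reciprocal = ep$reciprocal),
                         emit("epistasis.json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (subcommand == "walk") {
    landscape <- model_from_cfg()
    start <- .cfg_get(cfg, "start", required = TRUE)
    w <- adaptive_walk(landscape, start,
                       moves = .cfg_get(cfg, "moves", "single"),
                       max_steps = .cfg_get(cfg, "max_steps", 10000L))
    write_walk(w, emit("walk.fasta"), emit("walk_scores.tsv"))
  } else if (subcommand == "survey") {
    landscape <- model_from_cfg()
    sv <- convergence_survey(landscape, .cfg_get(cfg, "n_starts", 100L),
                             seed = seed,
                             reference = .cfg_get(cfg, "reference"))
    utils::write.table(sv, emit("survey.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (subcommand == "evaluate") {
    landscape <- model_from_cfg()
    cpath <- .cfg_get(cfg, "contacts", required = TRUE)
    if (!file.exists(cpath)) .input_error(paste("contact map not found:", cpath))
    contacts <- read_contact_map(cpath)
    sc <- interaction_scores(landscape,
                             min_separation = .cfg_get(cfg, "min_separation", 5))
    ppv <- contact_ppv(sc, contacts,
                       thresholds = .cfg_get(cfg, "thresholds", c(5, 8)),
                       top_k = .cfg_get(cfg, "top_k"))
    utils::write.table(ppv, emit("ppv.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(utils::head(top_interactions(sc), 20),
                       emit("top_interactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  cfg_file <- file.path(outdir, "config_used.json")
  jsonlite::write_json(cfg, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  input_files <- unlist(cfg[vapply(cfg, function(v)
    is.character(v) && length(v) == 1L && file.exists(v) && !dir.exists(v),
    logical(1))], use.names = TRUE)
  manifest <- list(
    tool = "evoscape", version = as.character(utils::packageVersion("evoscape")),
    subcommand = subcommand, seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    input_digests = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = unique(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
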