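# Named end-to-end workflows tying the modules together, with a provenance
# manifest for every run.

#' Run configuration
#'
#' @param seed Master seed; every stochastic step derives its own stream
#'   from it.
#' @param out Output directory.
#' @param ... Workflow-specific settings (see [run_workflow()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, out = tempfile("reprecon_"), ...) {
  structure(c(list(seed = seed, out = out), list(...)), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with at least `seed` and `out` entries.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

workflow_names <- c("simulate", "fit-map", "reconstruct", "synthesize", "evaluate")

#' Execute a named analysis workflow
#'
#' Available workflows:
#' \describe{
#'   \item{simulate}{Build a synthetic world and feature model, simulate `t`
#'     trials, and write `features.csv`, `trials.csv`, `embedding.txt` and
#'     `world.json`. Settings: `t` (default 500), plus any
#'     [synthetic_world()] argument.}
#'   \item{fit-map}{Read `features.csv`, `trials.csv`, `embedding.txt` from
#'     `config$inputs`, clean responses, embed trials, fit the
#'     visual-semantic map, and serialize it to `map/`.}
#'   \item{reconstruct}{Read a serialized map and an embedding, recover the
#'     feature vector of `config$concept`, and (with a toy extractor of
#'     matching channel count) write a caricature reconstruction PNG plus a
#'     JSON results bundle. Settings: `concept`, `inputs`, `size` (default
#'     32), `iterations` (default 300).}
#'   \item{synthesize}{Sample `n` target feature vectors from a feature model
#'     fitted on simulated activations and synthesize matching stimuli with a
#'     toy extractor; writes PNGs and `features.csv`. Settings: `n`,
#'     `channels`, `size`, `iterations`.}
#'   \item{evaluate}{Given a serialized map plus `features.csv`/`trials.csv`,
#'     compute held-out semantic-content predictions and write
#'     `evaluation.json`.}
#' }
#' Every workflow writes a `manifest.json` recording inputs, seeds, package
#' version, configuration hash and produced files.
#'
#' @param name One of `"simulate"`, `"fit-map"`, `"reconstruct"`,
#'   `"synthesize"`, `"evaluate"`.
#' @param config A [run_config()].
#' @return The manifest (invisibly), with workflow outputs on disk.
#' @export
run_workflow <- function(name, config) {
  if (!name %in% workflow_names) {
    abort(sprintf("Unknown workflow '%s'. Valid names: %s",
                  name, paste(workflow_names, collapse = ", ")))
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  outputs <- switch(
    name,
    "simulate" = wf_simulate(config),
    "fit-map" = wf_fit_map(config),
    "reconstruct" = wf_reconstruct(config),
    "synthesize" = wf_synthesize(config),
    "evaluate" = wf_evaluate(config)
  )
  manifest <- list(
    workflow = name,
    package_version = as.character(utils::packageVersion("reprecon")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    inputs = config$inputs %||% list(),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_embedding_txt <- function(embedding, path) {
  lines <- vapply(seq_along(embedding$vocab), function(i) {
    paste(embedding$vocab[i],
          paste(format(embedding$vectors[i, ], digits = 17, trim = TRUE,
                       scientific = TRUE), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

write_features_csv <- function(features, path) {
  out <- dplyr::bind_cols(tibble(trial_id = rownames(features)),
                          as_tibble(features))
  readr::write_csv(out, path)
  invisible(path)
}

read_features_csv <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  m
}

wf_simulate <- function(config) {
  t_n <- config$t %||% 500
  world <- synthetic_world(
    m = config$m %||% 40, d = config$d %||% 32, v = config$v %||% 64,
    noise_sd = config$noise_sd %||% 0.5, seed = child_seed(config$seed, 1)
  )
  fm <- world_feature_model(world, seed = child_seed(config$seed, 2))
  sim <- simulate_experiment(world, fm, t_n, seed = child_seed(config$seed, 3))
  paths <- c(
    features = file.path(config$out, "features.csv"),
    trials = file.path(config$out, "trials.csv"),
    embedding = file.path(config$out, "embedding.txt"),
    world = file.path(config$out, "world.json")
  )
  write_features_csv(sim$features, paths["features"])
  write_trials(sim$responses, paths["trials"])
  write_embedding_txt(world$embedding, paths["embedding"])
  jsonlite::write_json(
    list(m = world$m, d = world$d, v = world$v, noise_sd = world$noise_sd,
         lexicon = world$lexicon, seed = world$seed),
    paths["world"], auto_unbox = TRUE, digits = NA
  )
  as.list(paths)
}

wf_inputs <- function(config) {
  inp <- config$inputs
  if (is.null(inp)) abort("This workflow requires `inputs` in the config.")
  inp
}

wf_fit_map <- function(config) {
  inp <- wf_inputs(config)
  features <- read_features_csv(inp$features)
  trials <- load_trials(inp$trials)
  emb <- load_embedding(inp$embedding)
  cleaned <- clean_responses(trials, emb)
  sems <- embed_trials(cleaned$responses, emb)
  usable <- intersect(rownames(features), sems$trial_id)
  map <- fit_concept_map(
    features[usable, , drop = FALSE],
    semantic_matrix(sems)[usable, , drop = FALSE],
    variance_threshold = config$variance_threshold %||% 0.9,
    provenance = list(seed = config$seed, trials = length(usable))
  )
  map_dir <- file.path(config$out, "map")
  write_concept_map(map, map_dir)
  list(map = map_dir, trials_used = length(usable))
}

wf_reconstruct <- function(config) {
  inp <- wf_inputs(config)
  map <- read_concept_map(inp$map)
  emb <- load_embedding(inp$embedding)
  concept <- config$concept %||% abort("`concept` missing from config.")
  rep <- concept_to_features(concept, emb, map)
  size <- config$size %||% 32
  extractor <- make_toy_extractor(length(rep$features), size,
                                  seed = child_seed(config$seed, 1))
  res <- reconstruct_image(
    rep$features, extractor,
    reconstruction_config(iterations = config$iterations %||% 300,
                          seed = child_seed(config$seed, 2))
  )
  png_path <- file.path(config$out, paste0(concept, ".png"))
  ok_png <- requireNamespace("png", quietly = TRUE)
  if (ok_png) write_image_png(res$image, png_path)
  bundle <- file.path(config$out, paste0(concept, "_result.json"))
  jsonlite::write_json(
    list(concept = concept, achieved = unname(res$achieved),
         target = unname(rep$features), r_squared = res$r_squared,
         trace = res$trace),
    bundle, auto_unbox = TRUE, digits = NA
  )
  c(list(result = bundle), if (ok_png) list(image = png_path))
}

wf_synthesize <- function(config) {
  n <- config$n %||% 2
  channels <- config$channels %||% 8
  size <- config$size %||% 32
  extractor <- make_toy_extractor(channels, size,
                                  seed = child_seed(config$seed, 1))
  corpus <- with_seed(child_seed(config$seed, 2), {
    imgs <- lapply(seq_len(100), function(i) {
      array(runif(size * size * 3), dim = c(size, size, 3))
    })
    t(vapply(imgs, extract_channel_features, numeric(channels),
             extractor = extractor, layers = names(extractor$layers)[1]))
  })
  fm <- fit_feature_space(corpus)
  targets <- sample_target_features(fm, n, seed = child_seed(config$seed, 3))
  ok_png <- requireNamespace("png", quietly = TRUE)
  achieved <- matrix(0, n, channels)
  files <- character(0)
  for (i in seq_len(n)) {
    res <- synthesize_stimulus(
      targets[i, ], extractor,
      synthesis_config(iterations = config$iterations %||% 200,
                       seed = child_seed(config$seed, 10 + i))
    )
    achieved[i, ] <- res$achieved
    if (ok_png) {
      f <- file.path(config$out, sprintf("stimulus_%03d.png", i))
      write_image_png(res$image, f)
      files <- c(files, f)
    }
  }
  rownames(achieved) <- sprintf("t%05d", seq_len(n))
  fpath <- file.path(config$out, "features.csv")
  write_features_csv(achieved, fpath)
  c(list(features = fpath), if (length(files)) list(images = files))
}

wf_evaluate <- function(config) {
  inp <- wf_inputs(config)
  map <- read_concept_map(inp$map)
  emb <- load_embedding(inp$embedding)
  features <- read_features_csv(inp$features)
  trials <- load_trials(inp$trials)
  cleaned <- clean_responses(trials, emb)
  usable <- intersect(rownames(features), unique(cleaned$responses$trial_id))
  pred <- predict_semantic_content(
    features[usable, , drop = FALSE],
    cleaned$responses[cleaned$responses$trial_id %in% usable, ],
    emb, map, n_null = config$n_null %||% 200,
    seed = child_seed(config$seed, 1)
  )
  out <- file.path(config$out, "evaluation.json")
  jsonlite::write_json(
    list(mean_cosine = pred$mean, z = pred$z, p = pred$p,
         per_image = pred$per_image),
    out, auto_unbox = TRUE, digits = NA
  )
  list(evaluation = out)
}
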