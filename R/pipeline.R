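# End-to-end pipeline commands.  Each command is a plain function over the
# package's building blocks; the bundled CLI script (inst/cli/sleepdep.R) is
# a thin flag-parsing wrapper around them.  Every command writes an
# effective-config snapshot next to its outputs for provenance.

snapshot_config <- function(out_dir, what, cfg) {
  jsonlite::write_json(cfg, file.path(out_dir, paste0(what, "_config.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Synthesize a dataset directory
#'
#' Generates a synthetic world and writes `sleep.csv`, `posts.csv`,
#' `truth.csv` and `corpus.txt` (plus an effective-config snapshot) to
#' `out_dir`.
#'
#' @param out_dir output directory.
#' @param config a [world_config()].
#' @param quiet suppress the summary message.
#' @return the world, invisibly.
#' @export
cmd_synthesize <- function(out_dir, config = world_config(), quiet = FALSE) {
  world <- generate_world(config)
  world_to_files(world, out_dir)
  snapshot_config(out_dir, "synthesize", unclass(config))
  if (!quiet) {
    message("wrote synthetic dataset to ", out_dir)
    print(world)
  }
  invisible(world)
}

#' Label a posts file against sleep data
#'
#' Runs ingest, the tiredness model and labeling: reads the sleep CSV and
#' posts file, builds one trajectory per subject, labels every post, and
#' writes `labeled.csv` and `trajectory.csv` to `out_dir`.  Per-label and
#' per-drop-reason counts are printed unless `quiet`.
#'
#' @param sleep_path sleep episodes CSV.
#' @param posts_path posts CSV or JSON-lines.
#' @param out_dir output directory.
#' @param params a [tiredness_params()] object.
#' @param quiet suppress count messages.
#' @return the labeled data frame, invisibly.
#' @export
cmd_label <- function(sleep_path, posts_path, out_dir,
                      params = tiredness_params(), quiet = FALSE) {
  for (p in c(sleep_path, posts_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  schedules <- read_sleep_csv(sleep_path)
  posts <- read_posts(posts_path)
  trajs <- lapply(schedules, build_trajectory, params = params)
  labeled <- label_posts(posts, trajs, params, quiet = quiet)
  write_labeled_posts(labeled, file.path(out_dir, "labeled.csv"))
  write_trajectory_csv(trajs, file.path(out_dir, "trajectory.csv"))
  snapshot_config(out_dir, "label", unclass(params))
  invisible(labeled)
}

#' Train and evaluate the classifier on a labeled dataset
#'
#' Reads the labeled CSV (joining post text back in from the posts file),
#' trains CBOW embeddings on the corpus, builds the feature tensor, runs one
#' seeded split/train/evaluate cycle per seed, and writes `metrics.json`
#' plus a model checkpoint (`model.rds`, last seed's model) to `out_dir`.
#'
#' @param labeled_path labeled CSV from [cmd_label()].
#' @param posts_path the posts file (source of the post text).
#' @param corpus_path plain-text corpus, one sentence per line.
#' @param out_dir output directory.
#' @param emb_config an [embedding_config()].
#' @param config a [train_config()].
#' @param seeds integer seeds for [repeated_evaluation()].
#' @param quiet suppress progress messages.
#' @return the `eval_result`, invisibly.
#' @export
cmd_train_eval <- function(labeled_path, posts_path, corpus_path, out_dir,
                           emb_config = embedding_config(),
                           config = train_config(), seeds = 1:5,
                           quiet = FALSE) {
  for (p in c(labeled_path, posts_path, corpus_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  labeled <- read_labeled_posts(labeled_path)
  posts <- read_posts(posts_path)
  labeled$text <- posts$text[match(labeled$post_id, posts$post_id)]
  rows <- labeled[labeled$drop_reason == "none", , drop = FALSE]
  if (length(unique(rows$label)) < 2L)
    stop("labeled data contains a single class; cannot train")
  corpus <- strsplit(readLines(corpus_path, warn = FALSE), " ", fixed = TRUE)
  emb <- train_embeddings(corpus, emb_config)
  tensor <- build_tensor(rows, emb)
  if (!quiet)
    message("vocabulary ", length(emb$vocab), ", kappa ", tensor$kappa,
            ", delta ", length(tensor$labels))
  res <- repeated_evaluation(tensor, config, seeds, quiet = quiet)
  metrics <- list(per_seed_aucs = res$per_seed_aucs, mean_auc = res$mean_auc,
                  sd_auc = res$sd_auc, n_train = res$n_train,
                  n_val = res$n_val, n_test = res$n_test,
                  seeds = res$seeds, config = unclass(config))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg <- config; cfg$seed <- as.integer(seeds[length(seeds)])
  parts <- split_dataset(tensor, cfg)
  model <- train_model(parts$train, parts$val, cfg, quiet = TRUE)
  saveRDS(model, file.path(out_dir, "model.rds"))
  snapshot_config(out_dir, "train_eval",
                  list(embedding = unclass(emb_config),
                       train = unclass(config), seeds = seeds))
  if (!quiet) print(res)
  invisible(res)
}

#' Run the whole pipeline on a synthetic world
#'
#' synthesize -> label -> train/evaluate, all under `out_dir`.
#' @param out_dir output directory.
#' @param world a [world_config()].
#' @param emb_config an [embedding_config()].
#' @param config a [train_config()].
#' @param seeds seeds for [repeated_evaluation()].
#' @param quiet suppress progress messages.
#' @return the `eval_result`, invisibly.
#' @export
cmd_run_all <- function(out_dir, world = world_config(),
                        emb_config = embedding_config(),
                        config = train_config(), seeds = 1:5, quiet = FALSE) {
  data_dir <- file.path(out_dir, "data")
  cmd_synthesize(data_dir, world, quiet = quiet)
  cmd_label(file.path(data_dir, "sleep.csv"), file.path(data_dir, "posts.csv"),
            out_dir, quiet = quiet)
  cmd_train_eval(file.path(out_dir, "labeled.csv"),
                 file.path(data_dir, "posts.csv"),
                 file.path(data_dir, "corpus.txt"), out_dir,
                 emb_config, config, seeds, quiet = quiet)
}
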