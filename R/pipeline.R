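# End-to-end orchestration. Every run_* function is a thin, deterministic
# wrapper over the package's core functions: it resolves a configuration,
# executes one stage, writes its artifacts (plus the resolved configuration)
# under `out_dir`, and returns the main result invisibly. The CLI script in
# inst/cli/allodyn dispatches straight to these.

write_resolved_config <- function(config_list, out_dir, name) {
  path <- file.path(out_dir, paste0(name, "_config.json"))
  jsonlite::write_json(config_list, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Simulate a synthetic dataset to disk
#'
#' Generates the seeded synthetic dataset and writes the manifest,
#' per-sample matrices and per-complex fingerprints (see
#' [write_samples()]), plus the resolved generator configuration.
#'
#' @param config an [synthetic_config()].
#' @param out_dir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(config = synthetic_config(), out_dir) {
  ensure_dir(out_dir)
  ds <- simulate_dataset(config)
  write_samples(ds, out_dir)
  write_resolved_config(unclass(config), out_dir, "simulate")
  invisible(out_dir)
}

#' Featurize trajectories to descriptor matrices on disk
#'
#' Maps the reference residues onto each trajectory, assembles the 16-row
#' descriptor matrix for both atom sets, and writes matrices plus a
#' manifest.
#'
#' @param trajectories list of records, each a list with `complex_id`,
#'   `replica`, `traj` (an `allodyn_traj`) and optionally `label` and
#'   `smiles`.
#' @param reference an `allodyn_traj` reference structure.
#' @param reference_residues six residue ids in the reference.
#' @param out_dir output directory.
#' @param frame_interval ns per frame.
#' @return the manifest tibble, invisibly.
#' @export
run_featurize <- function(trajectories, reference, reference_residues,
                          out_dir, frame_interval = 0.05) {
  ensure_dir(file.path(out_dir, "matrices"))
  rows <- list()
  for (rec in trajectories) {
    for (atom_set in c("all_atoms", "backbone")) {
      sel <- map_reference_residues(rec$traj, reference, reference_residues,
                                    atom_set = atom_set)
      m <- assemble_descriptor_matrix(rec$traj, sel,
                                      frame_interval = frame_interval)
      rel <- file.path("matrices",
                       paste0(sample_key(rec$complex_id, rec$replica,
                                         atom_set), ".tsv"))
      write_matrix_tsv(m, file.path(out_dir, rel))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        complex_id = rec$complex_id, replica = rec$replica,
        atom_set = atom_set,
        label = rec$label %||% NA_integer_,
        smiles = rec$smiles %||% NA_character_,
        matrix_path = rel)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}

#' Train the classifier from a dataset directory
#'
#' Reads the dataset, performs the complex-level 80:10:10 split, trains
#' the classifier, and writes the split TSV, the per-epoch training log
#' TSV (epoch, gamma, lambda, train FL, train H, train L, val L), the
#' checkpoint, and the resolved configuration.
#'
#' @param data_dir dataset directory (from [run_simulate()] or
#'   [write_samples()]).
#' @param out_dir output directory.
#' @param model_cfg,loss_cfg,train_cfg configuration objects.
#' @param ratio split ratio.
#' @param seed overrides `train_cfg$seed` and the split seed when given.
#' @return the `allodyn_fit`, invisibly.
#' @export
run_train <- function(data_dir, out_dir, model_cfg = model_config(),
                      loss_cfg = loss_config(), train_cfg = train_config(),
                      ratio = c(0.8, 0.1, 0.1), seed = NULL) {
  ensure_dir(out_dir)
  if (!is.null(seed)) train_cfg$seed <- assert_count(seed, "seed", 0L)
  samples <- read_samples(data_dir)
  model_cfg$n_frames <- ncol(samples[[1]]$matrix)
  model_cfg$fp_length <- length(samples[[1]]$fingerprint)
  split <- grouped_split(samples, ratio = ratio, seed = train_cfg$seed)
  fit <- train_classifier(samples, split, model_cfg, loss_cfg, train_cfg)
  write_split(split, file.path(out_dir, "split.tsv"))
  readr::write_tsv(fit$log, file.path(out_dir, "training_log.tsv"),
                   progress = FALSE)
  save_checkpoint(fit$model, file.path(out_dir, "checkpoint.rds"),
                  seed = train_cfg$seed)
  write_resolved_config(list(model = unclass(model_cfg),
                             loss = unclass(loss_cfg),
                             train = unclass(train_cfg), ratio = ratio),
                        out_dir, "train")
  fit$data_dir <- data_dir
  invisible(fit)
}

#' Train the imputer against a trained checkpoint
#'
#' @param data_dir dataset directory.
#' @param train_dir directory produced by [run_train()] (checkpoint +
#'   split).
#' @param out_dir output directory (defaults to `train_dir`; the
#'   checkpoint is rewritten with the imputer attached).
#' @param imputer_cfg,imp_train_cfg configuration objects.
#' @param seed overrides `imp_train_cfg$seed` when given.
#' @return the `allodyn_imputer_fit`, invisibly.
#' @export
run_impute <- function(data_dir, train_dir, out_dir = train_dir,
                       imputer_cfg = imputer_config(),
                       imp_train_cfg = imputer_train_config(), seed = NULL) {
  ensure_dir(out_dir)
  if (!is.null(seed)) imp_train_cfg$seed <- assert_count(seed, "seed", 0L)
  samples <- read_samples(data_dir)
  ck <- load_checkpoint(file.path(train_dir, "checkpoint.rds"))
  split <- read_split(file.path(train_dir, "split.tsv"))
  ifit <- train_imputer(samples, ck$model, split = split,
                        imputer_cfg = imputer_cfg,
                        imp_train_cfg = imp_train_cfg)
  readr::write_tsv(ifit$log, file.path(out_dir, "imputer_log.tsv"),
                   progress = FALSE)
  save_checkpoint(ck$model, file.path(out_dir, "checkpoint.rds"),
                  imputer = ifit$imputer, seed = ck$seed)
  write_resolved_config(list(imputer = unclass(imputer_cfg),
                             imputer_train = unclass(imp_train_cfg)),
                        out_dir, "impute")
  invisible(ifit)
}

#' Evaluate a checkpoint across confidence thresholds
#'
#' Writes one metrics report (JSON) and one confusion matrix (TSV) per
#' threshold, plus a summary TSV of the sweep.
#'
#' @param data_dir dataset directory.
#' @param train_dir directory holding `checkpoint.rds` and `split.tsv`.
#' @param out_dir output directory.
#' @param subset which split subset to evaluate.
#' @param thresholds confidence thresholds.
#' @param use_matrix use descriptor matrices (`TRUE`) or the imputed
#'   route (`FALSE`; requires an imputer in the checkpoint).
#' @return the sweep tibble, invisibly.
#' @export
run_evaluate <- function(data_dir, train_dir, out_dir,
                         subset = c("test", "val", "train"),
                         thresholds = c(0.5, 0.8, 0.95), use_matrix = TRUE) {
  subset <- match.arg(subset)
  ensure_dir(out_dir)
  samples <- read_samples(data_dir)
  ck <- load_checkpoint(file.path(train_dir, "checkpoint.rds"))
  split <- read_split(file.path(train_dir, "split.tsv"))
  eval_samples <- split_samples(samples, split, subset)
  preds <- predict_samples(ck$model, eval_samples, imputer = ck$imputer,
                           use_matrix = use_matrix)
  sweep <- threshold_sweep(preds, thresholds = thresholds)
  for (i in seq_len(nrow(sweep))) {
    tau <- sweep$threshold[i]
    m <- sweep$metrics[[i]]
    tag <- sprintf("%s_tau%s", subset, gsub("\\.", "p", format(tau)))
    jsonlite::write_json(
      list(subset = subset, threshold = tau, accuracy = m$accuracy,
           f1 = m$f1, f1_average = m$f1_average, kappa = m$kappa,
           coverage = m$coverage, n = m$n,
           origin = preds$origin[1]),
      file.path(out_dir, paste0("metrics_", tag, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    conf <- tibble::as_tibble(m$confusion, rownames = "true_class")
    readr::write_tsv(conf, file.path(out_dir, paste0("confusion_", tag, ".tsv")),
                     progress = FALSE)
  }
  readr::write_tsv(dplyr::select(sweep, -"metrics"),
                   file.path(out_dir, paste0("sweep_", subset, ".tsv")),
                   progress = FALSE)
  invisible(sweep)
}

#' Integrated-gradients attribution report for a subset
#'
#' @param data_dir dataset directory.
#' @param train_dir directory holding the checkpoint and split.
#' @param out_dir output directory.
#' @param subset split subset to attribute.
#' @param n_steps path resolution.
#' @return the `allodyn_attribution` tibble, invisibly.
#' @export
run_attribute <- function(data_dir, train_dir, out_dir, subset = "test",
                          n_steps = 64L) {
  ensure_dir(out_dir)
  samples <- read_samples(data_dir)
  ck <- load_checkpoint(file.path(train_dir, "checkpoint.rds"))
  split <- read_split(file.path(train_dir, "split.tsv"))
  eval_samples <- split_samples(samples, split, subset)
  attrs <- lapply(eval_samples, function(s)
    integrated_gradients_joint(ck$model, s$matrix, s$fingerprint,
                               n_steps = n_steps))
  labels <- vapply(eval_samples, `[[`, integer(1), "label")
  report <- summarize_attributions(attrs, labels)
  jsonlite::write_json(
    list(n_steps = attr(report, "n_steps"),
         baseline_spec = attr(report, "baseline_spec"),
         rows = as.data.frame(report)),
    file.path(out_dir, sprintf("attribution_%s.json", subset)),
    auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Predict a manifest of complexes, with or without dynamics
#'
#' Reads the dataset directory; when `use_matrix = FALSE` (or a sample has
#' no stored matrix) the imputed route is used and flagged in the output.
#'
#' @param data_dir dataset directory.
#' @param train_dir directory holding the checkpoint.
#' @param out_dir output directory.
#' @param threshold confidence threshold.
#' @param use_matrix use stored descriptor matrices.
#' @return the prediction tibble, invisibly.
#' @export
run_predict <- function(data_dir, train_dir, out_dir, threshold = 0.5,
                        use_matrix = TRUE) {
  ensure_dir(out_dir)
  samples <- read_samples(data_dir)
  ck <- load_checkpoint(file.path(train_dir, "checkpoint.rds"))
  preds <- predict_samples(ck$model, samples, imputer = ck$imputer,
                           threshold = threshold, use_matrix = use_matrix)
  readr::write_tsv(preds, file.path(out_dir, "predictions.tsv"),
                   progress = FALSE)
  invisible(preds)
}
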