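#' Write / read a descriptor matrix as full-precision TSV
#'
#' Values are written with 17 significant digits (`%.17g`), which round-trips
#' IEEE doubles exactly, so serialization is lossless.
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv()` returns the matrix; `write_matrix_tsv()`
#'   returns `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, "\t", fixed = TRUE), as.numeric))
}

#' Read / write a sample manifest
#'
#' The manifest is a TSV with one row per sample and columns `complex_id`,
#' `replica`, `atom_set`, `label`, `matrix_path` and either `smiles` or
#' `fingerprint_path`.
#'
#' @param path TSV file path.
#' @return a tibble.
#' @export
read_manifest <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_manifest
#' @param manifest a data frame of sample metadata.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Bind descriptor matrices, fingerprints and labels into samples
#'
#' Validates every manifest row against the stored matrices and
#' fingerprints (16 descriptor rows, z-scored; binary fingerprints of the
#' expected length) and assembles the flat sample list the trainer
#' consumes. All row-level problems are aggregated into one error report.
#'
#' @param manifest data frame with columns `complex_id`, `replica`,
#'   `atom_set`, `label`, and `matrix_path` (or a `matrices` list).
#' @param matrices optional named list of matrices keyed
#'   `complexid_replica_atomset`; when absent, `matrix_path` is read from
#'   disk relative to `base_dir`.
#' @param fingerprints named list mapping `complex_id` to 0/1 vectors
#'   (e.g. from [load_fingerprints()]).
#' @param fp_length expected fingerprint length.
#' @param base_dir base directory for relative paths.
#' @return flat list of `allodyn_sample` records.
#' @export
build_dataset <- function(manifest, matrices = NULL, fingerprints,
                          fp_length = 2048L, base_dir = ".") {
  manifest <- tibble::as_tibble(manifest)
  if (nrow(manifest) == 0L) {
    warn("empty manifest: returning an empty sample list")
    return(list())
  }
  required <- c("complex_id", "replica", "atom_set", "label")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    abort(paste("manifest is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  errors <- character()
  samples <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    key <- sample_key(row$complex_id, row$replica, row$atom_set)
    err <- NULL
    m <- NULL
    if (!is.null(matrices)) {
      m <- matrices[[key]]
      if (is.null(m)) err <- sprintf("no matrix for key '%s'", key)
    } else if (!is.null(row$matrix_path) && !is.na(row$matrix_path)) {
      p <- if (file.exists(row$matrix_path)) row$matrix_path else
        file.path(base_dir, row$matrix_path)
      if (!file.exists(p)) err <- sprintf("matrix file not found: %s",
                                          row$matrix_path)
      else m <- read_matrix_tsv(p)
    } else {
      err <- "no matrix source (matrices list or matrix_path)"
    }
    if (is.null(err) && nrow(m) != 16L) {
      err <- sprintf("matrix has %d rows, expected 16", nrow(m))
    }
    fp <- fingerprints[[row$complex_id]]
    if (is.null(err) && is.null(fp)) {
      err <- sprintf("no fingerprint for complex '%s'", row$complex_id)
    }
    if (is.null(err)) err <- validate_fingerprint(fp, fp_length)
    if (!is.null(err)) {
      errors <- c(errors, sprintf("row %d (%s): %s", i, key, err))
    } else {
      samples[[i]] <- new_sample(row$complex_id, row$replica, row$atom_set,
                                 m, fp, label_to_int(row$label))
    }
  }
  if (length(errors)) {
    abort(paste0("dataset assembly failed:\n",
                 paste("  -", errors, collapse = "\n")))
  }
  samples
}

sample_key <- function(complex_id, replica, atom_set) {
  sprintf("%s_r%d_%s", complex_id, as.integer(replica), atom_set)
}

# largest-remainder apportionment of n units over ratio
largest_remainder <- function(n, ratio) {
  q <- n * ratio
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(q - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Complex-level train/validation/test split
#'
#' Partitions complexes (never samples) into train/val/test so that all
#' samples of a complex land in one subset, eliminating replica-level
#' leakage. Complexes are shuffled within each class label (stratified),
#' interleaved across classes, then cut into contiguous blocks sized by
#' largest-remainder rounding of the ratio.
#'
#' @param samples flat sample list or `allodyn_dataset`.
#' @param ratio length-3 ratio summing to 1 (default 80:10:10).
#' @param seed shuffle seed.
#' @return object of class `allodyn_split`: list with character vectors
#'   `train`, `val`, `test`, plus the ratio and seed.
#' @export
grouped_split <- function(samples, ratio = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ratio) != 3L || abs(sum(ratio) - 1) > 1e-8 || any(ratio < 0)) {
    abort("`ratio` must be three non-negative numbers summing to 1")
  }
  info <- samples_info(samples)
  complexes <- dplyr::distinct(info, .data$complex_id, .data$label)
  if (nrow(complexes) < 3L) abort("need at least three complexes to split")
  set.seed(seed)
  # stratified shuffle, then interleave classes to balance each subset
  by_class <- split(complexes$complex_id, complexes$label)
  by_class <- lapply(by_class, function(ids) ids[sample.int(length(ids))])
  n_max <- max(lengths(by_class))
  ordered <- unlist(lapply(seq_len(n_max), function(i)
    unlist(lapply(by_class, function(ids)
      if (i <= length(ids)) ids[i] else NULL))), use.names = FALSE)
  counts <- largest_remainder(length(ordered), ratio)
  cuts <- cumsum(counts)
  structure(
    list(train = ordered[seq_len(cuts[1])],
         val = if (counts[2]) ordered[(cuts[1] + 1):cuts[2]] else character(),
         test = if (counts[3]) ordered[(cuts[2] + 1):cuts[3]] else character(),
         ratio = ratio, seed = seed),
    class = "allodyn_split")
}

#' Select the samples belonging to one split subset
#'
#' @param samples flat sample list or dataset.
#' @param split an [grouped_split()] result.
#' @param subset `"train"`, `"val"` or `"test"`.
#' @return flat list of samples.
#' @export
split_samples <- function(samples, split, subset = c("train", "val", "test")) {
  subset <- match.arg(subset)
  samples <- dataset_samples(samples)
  ids <- split[[subset]]
  samples[purrr::map_chr(samples, "complex_id") %in% ids]
}

#' Write / read a dataset to a directory
#'
#' Lays out `manifest.tsv`, one full-precision matrix TSV per sample under
#' `matrices/`, and one fingerprint text file per complex under
#' `fingerprints/`. The round trip is lossless.
#'
#' @param samples flat sample list or dataset.
#' @param dir output directory (created if missing).
#' @return `write_samples()` returns `dir` invisibly; `read_samples()`
#'   returns the flat sample list.
#' @export
write_samples <- function(samples, dir) {
  samples <- dataset_samples(samples)
  dir.create(file.path(dir, "matrices"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "fingerprints"), showWarnings = FALSE)
  info <- samples_info(samples)
  info$matrix_path <- vapply(samples, function(s)
    file.path("matrices", paste0(sample_key(s$complex_id, s$replica,
                                            s$atom_set), ".tsv")),
    character(1))
  info$fingerprint_path <- file.path("fingerprints",
                                     paste0(info$complex_id, ".txt"))
  for (i in seq_along(samples)) {
    write_matrix_tsv(samples[[i]]$matrix, file.path(dir, info$matrix_path[i]))
  }
  for (id in unique(info$complex_id)) {
    s <- samples[[match(id, info$complex_id)]]
    write_fingerprint_file(s$fingerprint,
                           file.path(dir, "fingerprints", paste0(id, ".txt")))
  }
  write_manifest(info, file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' @rdname write_samples
#' @export
read_samples <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  fps <- list()
  for (id in unique(manifest$complex_id)) {
    fp <- read_fingerprint_file(
      file.path(dir, manifest$fingerprint_path[match(id, manifest$complex_id)]))
    attr(fp, "source") <- "provided"
    fps[[id]] <- fp
  }
  fp_length <- length(fps[[1]])
  build_dataset(manifest, fingerprints = fps, fp_length = fp_length,
                base_dir = dir)
}

#' Write / read a split assignment as TSV
#'
#' @param split an `allodyn_split`.
#' @param path TSV path (columns `complex_id`, `subset`).
#' @export
write_split <- function(split, path) {
  df <- tibble::tibble(
    complex_id = c(split$train, split$val, split$test),
    subset = rep(c("train", "val", "test"),
                 c(length(split$train), length(split$val), length(split$test))))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(list(train = df$complex_id[df$subset == "train"],
                 val = df$complex_id[df$subset == "val"],
                 test = df$complex_id[df$subset == "test"],
                 ratio = NULL, seed = NULL),
            class = "allodyn_split")
}
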