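#' Configuration for the synthetic complex generator
#'
#' Defines the study conditions for a seeded, class-structured synthetic
#' dataset that emulates the real input of the classifier: per-complex
#' descriptor matrices of 16 time series (1 RMSD + 15 pairwise residue
#' distances) over `n_frames` frames, expanded into `n_replicas` x 2
#' atom-set variants (eight samples per complex under the defaults), plus a
#' binary ligand fingerprint per complex.
#'
#' Descriptor rows follow stationary Ornstein-Uhlenbeck (OU) dynamics with
#' mean-reversion rate `ou_theta` (per frame) and diffusion scale `ou_sigma`
#' (angstrom / sqrt(frame)), so the stationary variance is
#' `ou_sigma^2 / (2 * ou_theta)`. For allosteric complexes the long-run mean
#' of the rows in `shift_rows` is offset by `class_shift` angstrom; the
#' series start at the unshifted baseline and relax towards the shifted mean
#' at rate `ou_theta`, emulating a ligand-induced conformational transition
#' at the start of the production run. The relaxation transient is what
#' survives per-row z-scoring and carries the temporal class signal.
#'
#' Fingerprints place a class-determined pattern on the first
#' `fp_informative_bits` bits (allosteric = 1, orthosteric = 0), flip each
#' informative bit independently with probability `fp_flip_prob`, and fill
#' the remaining bits with sparse Bernoulli(`fp_noise_density`) noise.
#'
#' @param n_complexes number of protein-ligand complexes.
#' @param class_balance fraction of complexes labelled allosteric.
#' @param n_frames frames per descriptor series (columns).
#' @param n_replicas independent MD replicas per complex; each contributes
#'   an all-atom and a backbone sample.
#' @param ou_theta OU mean-reversion rate per frame (> 0).
#' @param ou_sigma OU diffusion scale (>= 0).
#' @param class_shift long-run mean offset (angstrom) applied to
#'   `shift_rows` for allosteric complexes.
#' @param shift_rows integer indices (1 = RMSD row, 2..16 = distance rows)
#'   receiving the class shift.
#' @param variant_cor correlation between the all-atom and backbone noise
#'   realizations of the same replica.
#' @param fp_length fingerprint length in bits.
#' @param fp_informative_bits number of leading class-informative bits.
#' @param fp_flip_prob flip probability for informative bits.
#' @param fp_noise_density density of the uninformative background bits.
#' @param seed integer RNG seed.
#' @return An object of class `allodyn_synth_config` (a named list).
#' @export
#' @examples
#' cfg <- synthetic_config(n_complexes = 4, n_frames = 200, seed = 1)
#' ds <- simulate_dataset(cfg)
#' length(ds)
synthetic_config <- function(n_complexes = 40,
                             class_balance = 0.5,
                             n_frames = 2000,
                             n_replicas = 4,
                             ou_theta = 0.05,
                             ou_sigma = 0.3,
                             class_shift = 1.0,
                             shift_rows = 2:9,
                             variant_cor = 0.8,
                             fp_length = 2048,
                             fp_informative_bits = 64,
                             fp_flip_prob = 0.1,
                             fp_noise_density = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_complexes = assert_count(n_complexes, "n_complexes"),
    class_balance = assert_prob(class_balance, "class_balance"),
    n_frames = assert_count(n_frames, "n_frames"),
    n_replicas = assert_count(n_replicas, "n_replicas"),
    ou_theta = assert_number(ou_theta, "ou_theta", min = 1e-12),
    ou_sigma = assert_number(ou_sigma, "ou_sigma", min = 0),
    class_shift = assert_number(class_shift, "class_shift"),
    shift_rows = vapply(shift_rows, assert_count, integer(1),
                        name = "shift_rows"),
    variant_cor = assert_number(variant_cor, "variant_cor", -1, 1),
    fp_length = assert_count(fp_length, "fp_length"),
    fp_informative_bits = assert_count(fp_informative_bits,
                                       "fp_informative_bits", min = 0L),
    fp_flip_prob = assert_prob(fp_flip_prob, "fp_flip_prob"),
    fp_noise_density = assert_prob(fp_noise_density, "fp_noise_density"),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (any(cfg$shift_rows < 1L | cfg$shift_rows > 16L)) {
    abort("`shift_rows` must index the 16 descriptor rows")
  }
  if (cfg$fp_informative_bits > cfg$fp_length) {
    abort("`fp_informative_bits` cannot exceed `fp_length`")
  }
  structure(cfg, class = "allodyn_synth_config")
}

# zero-mean stationary OU noise, exact one-frame discretization
ou_noise <- function(n, theta, sigma) {
  if (sigma == 0) return(numeric(n))
  sd_stat <- sigma / sqrt(2 * theta)
  a <- exp(-theta)
  sd_step <- sd_stat * sqrt(1 - a^2)
  eps <- rnorm(n)
  # x_1 stationary, then x_t = a x_{t-1} + sd_step eps_t via recursive filter
  z <- c(sd_stat * eps[1], sd_step * eps[-1])
  as.numeric(stats::filter(z, a, method = "recursive"))
}

descriptor_row_labels <- function() {
  pairs <- utils::combn(6, 2)
  c("RMSD", sprintf("d_%d_%d", pairs[1, ], pairs[2, ]))
}

# random per-complex baselines: RMSD around 1-2.5 A, binding-site residue
# pair distances 8-25 A
draw_baseline <- function() {
  c(runif(1, 1, 2.5), runif(15, 8, 25))
}

#' Simulate one raw descriptor matrix
#'
#' Draws a 16 x `n_frames` matrix of OU-autocorrelated descriptor series
#' for a complex of the given class, using the current RNG stream. For
#' allosteric complexes the rows in `config$shift_rows` relax from the
#' baseline towards `baseline + class_shift`. The output is raw (not
#' z-scored); see [zscore_rows()].
#'
#' @param config an [synthetic_config()] object.
#' @param label class label (`"orthosteric"`/`"allosteric"` or 0/1).
#' @param baseline optional length-16 vector of row baselines; drawn from
#'   the RNG stream when `NULL`.
#' @return a 16 x `n_frames` numeric matrix with descriptor row names.
#' @export
simulate_descriptor_series <- function(config, label, baseline = NULL) {
  stopifnot(inherits(config, "allodyn_synth_config"))
  y <- label_to_int(label)
  if (is.null(baseline)) baseline <- draw_baseline()
  stopifnot(length(baseline) == 16L, all(is.finite(baseline)))
  n <- config$n_frames
  shift <- numeric(16)
  if (y == 1L) shift[config$shift_rows] <- config$class_shift
  relax <- exp(-config$ou_theta * (seq_len(n) - 1L))
  m <- matrix(0, 16L, n, dimnames = list(descriptor_row_labels(), NULL))
  for (r in seq_len(16L)) {
    mu_path <- baseline[r] + shift[r] * (1 - relax)
    m[r, ] <- mu_path + ou_noise(n, config$ou_theta, config$ou_sigma)
  }
  m
}

#' Simulate one ligand fingerprint
#'
#' Binary vector of length `fp_length`: the first `fp_informative_bits`
#' bits equal the class pattern (1 for allosteric) flipped independently
#' with `fp_flip_prob`; the remaining bits are Bernoulli background noise.
#' Uses the current RNG stream.
#'
#' @inheritParams simulate_descriptor_series
#' @return integer vector of 0/1 of length `config$fp_length`.
#' @export
simulate_fingerprint <- function(config, label) {
  stopifnot(inherits(config, "allodyn_synth_config"))
  y <- label_to_int(label)
  k <- config$fp_informative_bits
  fp <- integer(config$fp_length)
  if (k > 0L) {
    pattern <- rep.int(y, k)
    flips <- runif(k) < config$fp_flip_prob
    fp[seq_len(k)] <- as.integer(xor(pattern == 1L, flips))
  }
  n_noise <- config$fp_length - k
  if (n_noise > 0L) {
    fp[(k + 1L):config$fp_length] <-
      as.integer(runif(n_noise) < config$fp_noise_density)
  }
  fp
}

#' Simulate a full synthetic dataset
#'
#' Generates `n_complexes` complexes; each carries one fingerprint and
#' `n_replicas` x 2 samples (all-atom and backbone variants of each
#' replica). The two variants of a replica are correlated noise
#' realizations (`variant_cor`) of the same latent OU process around the
#' same mean path. Descriptor matrices are per-row z-scored unless
#' `normalize = FALSE`. Fully deterministic given `config$seed`.
#'
#' @param config an [synthetic_config()] object.
#' @param normalize z-score each sample's rows (the form the classifier
#'   consumes). Default `TRUE`.
#' @return a list of complexes (class `allodyn_dataset`); each complex is a
#'   list with `complex_id`, `label` and `samples`.
#' @export
simulate_dataset <- function(config, normalize = TRUE) {
  stopifnot(inherits(config, "allodyn_synth_config"))
  set.seed(config$seed)
  n <- config$n_complexes
  n_allo <- round(n * config$class_balance)
  labels <- c(rep(1L, n_allo), rep(0L, n - n_allo))
  labels <- labels[sample.int(n)]
  rho <- config$variant_cor
  complexes <- vector("list", n)
  for (i in seq_len(n) ) {
    id <- sprintf("cpx%03d", i)
    y <- labels[i]
    baseline <- draw_baseline()
    fp <- simulate_fingerprint(config, y)
    samples <- list()
    for (rep_i in seq_len(config$n_replicas)) {
      # shared latent + variant-specific OU noise around the same mean path
      mean_path <- simulate_descriptor_series(
        zero_noise(config), y, baseline = baseline)
      latent <- descriptor_noise(config)
      for (atom_set in c("all_atoms", "backbone")) {
        own <- descriptor_noise(config)
        mat <- mean_path + rho * latent + sqrt(1 - rho^2) * own
        if (normalize) mat <- zscore_rows(mat)
        samples[[length(samples) + 1L]] <- new_sample(
          complex_id = id, replica = rep_i, atom_set = atom_set,
          matrix = mat, fingerprint = fp, label = y)
      }
    }
    complexes[[i]] <- structure(
      list(complex_id = id, label = y, samples = samples),
      class = "allodyn_complex")
  }
  structure(complexes, class = "allodyn_dataset", config = config)
}

zero_noise <- function(config) {
  config$ou_sigma <- 0
  config
}

descriptor_noise <- function(config) {
  n <- config$n_frames
  m <- matrix(0, 16L, n)
  for (r in seq_len(16L)) m[r, ] <- ou_noise(n, config$ou_theta, config$ou_sigma)
  m
}

new_sample <- function(complex_id, replica, atom_set, matrix, fingerprint,
                       label = NA_integer_) {
  structure(
    list(complex_id = complex_id, replica = as.integer(replica),
         atom_set = atom_set, matrix = matrix,
         fingerprint = as.integer(fingerprint), label = label),
    class = "allodyn_sample")
}

#' Flatten a dataset into its samples
#'
#' @param dataset an `allodyn_dataset` (list of complexes) or an already
#'   flat list of samples.
#' @return a flat list of `allodyn_sample` records.
#' @export
dataset_samples <- function(dataset) {
  if (length(dataset) && inherits(dataset[[1]], "allodyn_sample")) {
    return(dataset)
  }
  purrr::flatten(purrr::map(dataset, "samples"))
}

#' Tabulate sample metadata
#'
#' @param samples flat list of samples (see [dataset_samples()]).
#' @return a tibble with one row per sample: `complex_id`, `replica`,
#'   `atom_set`, `label`.
#' @export
samples_info <- function(samples) {
  samples <- dataset_samples(samples)
  tibble::tibble(
    complex_id = purrr::map_chr(samples, "complex_id"),
    replica = purrr::map_int(samples, "replica"),
    atom_set = purrr::map_chr(samples, "atom_set"),
    label = purrr::map_int(samples, "label")
  )
}
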