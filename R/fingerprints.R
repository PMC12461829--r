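#' Encode a SMILES string as a circular binary fingerprint
#'
#' Hashed circular (Morgan/ECFP-style) fingerprint of radius 2, folded to
#' `length` bits. The hashing is delegated to the OpenBabel toolkit
#' (ChemmineOB, fingerprint type ECFP4 = radius 2); OpenBabel emits 4096
#' bits which are OR-folded down to the requested length. Bit positions
#' are toolkit-defined: encodings are deterministic for a given toolkit
#' version but are not bit-identical across chemistry toolkits.
#'
#' @param smiles a single SMILES string.
#' @param radius circular neighborhood radius (only 2 is supported by the
#'   ECFP4 backend; other values error).
#' @param length fingerprint length in bits (must divide the toolkit's
#'   native 4096).
#' @return integer 0/1 vector of length `length`, with attribute
#'   `source = "computed"`.
#' @export
encode_fingerprint <- function(smiles, radius = 2, length = 2048) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    abort("encode_fingerprint() requires the ChemmineOB package")
  }
  if (length(smiles) != 1L || !is.character(smiles) || !nzchar(smiles)) {
    abort("`smiles` must be a single non-empty string")
  }
  if (radius != 2) abort("only radius = 2 (ECFP4) is supported")
  native <- 4096L
  if (native %% length != 0L) abort("`length` must divide 4096")
  bits <- tryCatch(
    as.numeric(unlist(ChemmineOB::forEachMol("SMILES", smiles, function(m)
      ChemmineOB::fingerprint_OB(list(m), "ECFP4")))),
    error = function(e) NULL)
  if (is.null(bits) || length(bits) != native) {
    abort(sprintf("unparseable SMILES: '%s'", smiles))
  }
  folds <- matrix(as.integer(bits), nrow = length)
  fp <- as.integer(rowSums(folds) > 0)
  attr(fp, "source") <- "computed"
  fp
}

validate_fingerprint <- function(fp, fp_length = 2048L) {
  if (length(fp) != fp_length) {
    return(sprintf("fingerprint length %d, expected %d", length(fp), fp_length))
  }
  if (!all(fp %in% c(0L, 1L))) return("fingerprint contains non-binary values")
  NULL
}

#' Load fingerprints for a set of complexes
#'
#' Resolves one fingerprint per complex from a manifest-style table. Rows
#' with a `smiles` value are encoded with [encode_fingerprint()]; rows
#' with a `fingerprint_path` are read from a one-line text file of 0/1
#' characters. Every fingerprint is validated for length and binarity;
#' all failures are aggregated into a single error report.
#'
#' @param table data frame with column `complex_id` and at least one of
#'   `smiles`, `fingerprint_path` (missing entries may be `NA`).
#' @param fp_length expected fingerprint length.
#' @param base_dir directory that relative `fingerprint_path` entries are
#'   resolved against.
#' @return named list mapping `complex_id` to integer 0/1 vectors.
#' @export
load_fingerprints <- function(table, fp_length = 2048L, base_dir = ".") {
  if (!"complex_id" %in% names(table)) {
    abort("fingerprint table must have a `complex_id` column")
  }
  has_smiles <- "smiles" %in% names(table)
  has_path <- "fingerprint_path" %in% names(table)
  if (!has_smiles && !has_path) {
    abort("fingerprint table needs a `smiles` or `fingerprint_path` column")
  }
  table <- dplyr::distinct(
    dplyr::select(tibble::as_tibble(table),
                  dplyr::any_of(c("complex_id", "smiles", "fingerprint_path"))))
  errors <- character()
  out <- list()
  for (i in seq_len(nrow(table))) {
    id <- table$complex_id[i]
    fp <- NULL
    smi <- if (has_smiles) table$smiles[i] else NA_character_
    pth <- if (has_path) table$fingerprint_path[i] else NA_character_
    res <- tryCatch({
      if (!is.na(smi) && nzchar(smi)) {
        fp <- encode_fingerprint(smi, length = fp_length)
      } else if (!is.na(pth) && nzchar(pth)) {
        full <- if (file.exists(pth)) pth else file.path(base_dir, pth)
        fp <- read_fingerprint_file(full)
        attr(fp, "source") <- "provided"
      } else {
        stop("neither smiles nor fingerprint_path given")
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (is.null(res)) res <- validate_fingerprint(fp, fp_length)
    if (!is.null(res)) {
      errors <- c(errors, sprintf("row %d (%s): %s", i, id, res))
    } else {
      if (!is.null(out[[id]]) && !identical(as.integer(out[[id]]),
                                            as.integer(fp))) {
        errors <- c(errors,
                    sprintf("row %d (%s): conflicting fingerprints", i, id))
      }
      out[[id]] <- fp
    }
  }
  if (length(errors)) {
    abort(paste0("fingerprint loading failed:\n",
                 paste("  -", errors, collapse = "\n")))
  }
  out
}

read_fingerprint_file <- function(path) {
  line <- trimws(readLines(path, n = 1L, warn = FALSE))
  as.integer(strsplit(line, "")[[1]])
}

write_fingerprint_file <- function(fp, path) {
  writeLines(paste(fp, collapse = ""), path)
}
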