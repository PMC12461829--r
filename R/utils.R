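#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif sd setNames predict
#' @importFrom utils head modifyList
NULL

# scalar validators used by the config constructors ---------------------------

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s",
                  name, min, paste(format(x), collapse = ", ")))
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(min), format(max)))
  }
  as.numeric(x)
}

assert_prob <- function(x, name) assert_number(x, name, 0, 1)

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

# Class labels: the positive class (index 1 in 0-based label coding) is
# "allosteric" throughout the package; "orthosteric" is 0.
ALLODYN_CLASSES <- c("orthosteric", "allosteric")

label_to_int <- function(label) {
  if (all(is.na(label))) return(rep(NA_integer_, length(label)))
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1) | is.na(label))) {
      abort("numeric labels must be 0 or 1")
    }
    return(as.integer(label))
  }
  m <- match(label, ALLODYN_CLASSES)
  if (any(is.na(m) & !is.na(label))) {
    abort("labels must be 'orthosteric' or 'allosteric' (or 0/1)")
  }
  m - 1L
}

int_to_label <- function(x) ALLODYN_CLASSES[x + 1L]

# deterministic seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483647)
}
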