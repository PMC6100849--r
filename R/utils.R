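stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

#' Derive a stage-specific sub-seed from a master seed
#'
#' Stable integer hash of (seed, stage name), so that adding or reordering
#' pipeline stages never shifts another stage's random stream. The result is
#' always a valid 32-bit seed.
#'
#' @param seed master seed (integer).
#' @param stage character stage name.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed %% 2147483647)
  for (code in utf8ToInt(stage)) {
    # 31-based polynomial rolling hash, kept under 2^53 so doubles stay exact
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# delimiter from file extension: .csv -> comma, anything else -> tab
infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# format labels like L00017; used for synthetic locality identifiers
pad_id <- function(prefix, i, width = 5L) {
  sprintf("%s%0*d", prefix, width, i)
}
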