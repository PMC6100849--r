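# Shared fixture builders (all generated in code, no files).

make_specimen_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(species = r[[1]], family = "FamA",
               life_form_group = if (length(r) >= 4) r[[4]] else "herb_subshrub",
               year = r[[3]], locality = r[[2]], n_relatives = 0,
               stringsAsFactors = FALSE)))
}

# profiles data frame lying exactly on a chosen log-log line + offsets
make_profiles_on_line <- function(art, intercept, slope, offset = 0,
                                  life_form = "herb_subshrub",
                                  n_relatives = NULL) {
  loc <- 10^(intercept + slope * log10(art) + offset)
  out <- data.frame(species = sprintf("sp%03d", seq_along(art)),
                    life_form_group = life_form, art = art,
                    n_localities = loc, stringsAsFactors = FALSE)
  if (!is.null(n_relatives)) out$n_relatives <- n_relatives
  out
}

# hand-rolled spread classification for association-test fixtures
make_classification <- function(label, n_relatives, residual, n_localities,
                                lag = 54) {
  out <- data.frame(species = sprintf("sp%03d", seq_along(label)),
                    art = lag + 10, n_localities = n_localities,
                    residual = residual, label = label,
                    n_relatives = n_relatives, stringsAsFactors = FALSE)
  attr(out, "lag_threshold_used") <- lag
  class(out) <- c("spread_classification", "data.frame")
  out
}

random_binary_matrix <- function(n, k, p = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n * k, 1, p), n, k,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("a%02d", seq_len(k))))
  m
}
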