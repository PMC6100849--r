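#' Configuration for the synthetic herbarium-data generator
#'
#' Bundles and validates every knob of the generator. The defaults emulate
#' the study system the package targets: a national weed-specimen database
#' with 305 nonnative species (herb/subshrub-dominated), records spanning
#' the colonial era to a 2003 reference year, collection effort growing
#' steeply through the 20th century, a saturating per-year detection
#' process, locality counts log-log linear in true residence time with
#' lognormal noise around the reported regression line, planted widespread
#' (ML) and limited-spread (FL) outliers, zero-inflated congener counts,
#' and a 50-attribute binary matrix with planted group syndromes.
#'
#' @param n_species number of species (>= 10).
#' @param herb_fraction fraction assigned to the herb/subshrub life form.
#' @param era `c(start, end)` calendar years of possible true arrivals;
#'   must precede `ref_year`.
#' @param ref_year last year of records.
#' @param effort_max specimens per year at `ref_year` (effort ramps up
#'   exponentially from ~5 at the era start).
#' @param effort_shape `"exponential"` (historical ramp, the default) or
#'   `"constant"` (flat effort at `effort_max`, useful for isolating the
#'   detection process).
#' @param effort_noise lognormal sd of per-year effort noise (0 = smooth
#'   monotone template).
#' @param detection_scale effort at which the yearly detection probability
#'   of a present species reaches one half: `p = ef / (ef + scale)`.
#' @param beta0,beta1 intercept/slope of the true
#'   `log10(localities) ~ log10(residence time)` relation.
#' @param sigma lognormal noise sd in log10 units. When
#'   `sigma = 0` and `outlier_fraction = 0` locality counts are left
#'   unrounded so the configuration is an exact diagnostic line; otherwise
#'   counts are rounded to integers (and floored at 1), which censors
#'   species whose expected count falls below ~1.
#' @param outlier_fraction fraction of species displaced off the line
#'   (exactly `round(n * fraction)` species, alternating above/below).
#' @param outlier_shift displacement in log10 units.
#' @param congener_zero_prob,congener_mean zero-inflated Poisson parameters
#'   for native-congener counts.
#' @param n_attributes number of binary attributes.
#' @param base_attr_prob incidence probability outside syndromes.
#' @param syndrome_spec named list: per planted group, `list(attributes =
#'   <indices or names>, prob = <elevated incidence>)`. Default: four
#'   groups, five exclusive attributes each at probability 0.9.
#' @param lag_threshold years used only for the era-adequacy warning flag.
#' @param seed integer seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 305,
                             herb_fraction = 278 / 305,
                             era = c(1700, 1995),
                             ref_year = 2003,
                             effort_max = 2000,
                             effort_shape = c("exponential", "constant"),
                             effort_noise = 0.1,
                             detection_scale = 500,
                             beta0 = -2.549,
                             beta1 = 1.8213,
                             sigma = 0.3,
                             outlier_fraction = 0.2,
                             outlier_shift = 1.0,
                             congener_zero_prob = 0.45,
                             congener_mean = 2,
                             n_attributes = 50,
                             base_attr_prob = 0.2,
                             syndrome_spec = NULL,
                             lag_threshold = 54,
                             seed = 1) {
  stopifnot(is_count(n_species, 10), length(era) == 2L, era[1] < era[2])
  if (era[2] >= ref_year) stopf("synthetic_config: era must precede ref_year")
  if (!is_prob(c(herb_fraction, outlier_fraction, congener_zero_prob,
                 base_attr_prob)))
    stopf("synthetic_config: probabilities must lie in [0, 1]")
  stopifnot(sigma >= 0, outlier_shift >= 0, detection_scale > 0,
            effort_max > 0, congener_mean >= 0, is_count(n_attributes))
  effort_shape <- match.arg(effort_shape)
  if (is.null(syndrome_spec)) {
    n_grp <- 4L
    per <- 5L
    if (n_attributes < n_grp * per)
      stopf("synthetic_config: need >= %d attributes for the default syndromes",
            n_grp * per)
    syndrome_spec <- stats::setNames(lapply(seq_len(n_grp), function(g)
      list(attributes = ((g - 1L) * per + 1L):(g * per), prob = 0.9)),
      paste0("G", seq_len(n_grp)))
  }
  for (s in syndrome_spec) {
    if (!is_prob(s$prob)) stopf("synthetic_config: syndrome prob must lie in [0, 1]")
    if (is.numeric(s$attributes) && any(s$attributes > n_attributes))
      stopf("synthetic_config: syndrome attribute index out of range")
  }
  cfg <- list(n_species = as.integer(n_species), herb_fraction = herb_fraction,
              era = as.integer(era), ref_year = as.integer(ref_year),
              effort_max = effort_max, effort_shape = effort_shape,
              effort_noise = effort_noise,
              detection_scale = detection_scale, beta0 = beta0, beta1 = beta1,
              sigma = sigma, outlier_fraction = outlier_fraction,
              outlier_shift = outlier_shift,
              congener_zero_prob = congener_zero_prob,
              congener_mean = congener_mean,
              n_attributes = as.integer(n_attributes),
              base_attr_prob = base_attr_prob,
              syndrome_spec = syndrome_spec,
              lag_threshold = lag_threshold,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Binary attribute matrix with planted group syndromes
#'
#' Draws each entry Bernoulli(`base_prob`), except that species of a
#' planted group carry that group's syndrome attributes at the elevated
#' probability from `syndrome_spec`.
#'
#' @param groups named character vector of group labels (names = species).
#' @param n_attributes number of attributes (columns `attr01`, ...).
#' @param syndrome_spec as in [synthetic_config()].
#' @param base_prob baseline incidence probability.
#' @param seed integer seed.
#' @return an `attribute_matrix`.
#' @export
plant_attributes <- function(groups, n_attributes, syndrome_spec,
                             base_prob = 0.2, seed = 1) {
  stopifnot(!is.null(names(groups)))
  set.seed(seed)
  n <- length(groups)
  p <- base::matrix(base_prob, n, n_attributes)
  attr_names <- pad_id("attr", seq_len(n_attributes), width = 2L)
  for (g in names(syndrome_spec)) {
    spec <- syndrome_spec[[g]]
    cols <- if (is.character(spec$attributes))
      match(spec$attributes, attr_names) else spec$attributes
    p[groups == g, cols] <- spec$prob
  }
  m <- base::matrix(as.integer(stats::runif(n * n_attributes) < p), n,
                    n_attributes, dimnames = list(names(groups), attr_names))
  as_attribute_matrix(m)
}

#' Generate a synthetic herbarium dataset with known ground truth
#'
#' Simulates, per species: a true arrival year uniform over the era; a
#' yearly saturating detection process (probability `ef / (ef +
#' detection_scale)` each post-arrival year) whose first success is the
#' first-record year; a locality count `round(10^(beta0 + beta1 *
#' log10(rt_true) + N(0, sigma) + shift))` floored at 1, where `rt_true`
#' is the true residence time and `shift` is the planted outlier
#' displacement; zero-inflated-Poisson congener counts; and a binary
#' attribute matrix with planted syndromes. Specimen records comprise one
#' row per occupied locality, dated from the first-record year onward with
#' years drawn proportional to effort. Species never detected by
#' `ref_year` appear in the truth table only.
#'
#' @param config a `synthetic_config`.
#' @return object of class `synthetic_dataset`: `specimens` (a
#'   `specimen_table`), `attributes` (an `attribute_matrix` over all
#'   species), `truth` (per-species ground truth), `effort_template`
#'   (year, ef actually used to drive detection), `config`, and
#'   `warn_no_post_lag` (`TRUE` when the era leaves no species past the
#'   lag threshold).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_species
  species <- pad_id("sp", seq_len(n), width = 4L)
  years <- seq(cfg$era[1], cfg$ref_year)
  ny <- length(years)

  # monotone exponential effort ramp (~5 specimens/yr at era start) + noise,
  # or flat effort when isolating the detection process
  ef <- if (cfg$effort_shape == "constant") rep(cfg$effort_max, ny) else {
    g <- log(cfg$effort_max / 5) / (ny - 1)
    cfg$effort_max * exp(g * (seq_len(ny) - ny))
  }
  if (cfg$effort_noise > 0)
    ef <- ef * exp(stats::rnorm(ny, 0, cfg$effort_noise))
  ef <- pmax(1, round(ef))
  p_detect <- ef / (ef + cfg$detection_scale)

  arrival <- cfg$era[1] + floor(stats::runif(n) * (cfg$era[2] - cfg$era[1] + 1))
  rt_true <- cfg$ref_year - arrival

  # first detection: per species, first post-arrival year whose Bernoulli
  # draw under that year's effort succeeds
  U <- base::matrix(stats::runif(ny * n), ny, n)
  det <- U < p_detect
  first_detect <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    from <- arrival[i] - cfg$era[1] + 1L
    hit <- which(det[from:ny, i])
    if (length(hit)) first_detect[i] <- years[from + hit[1L] - 1L]
  }

  life_form <- ifelse(seq_len(n) <= round(n * cfg$herb_fraction),
                      "herb_subshrub", "tree_shrub")
  family <- sample(pad_id("Fam", 1:8, width = 2L), n, replace = TRUE)

  # planted spread outliers: exactly round(n * fraction), alternating ML/FL
  n_out <- round(n * cfg$outlier_fraction)
  out_idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
  shift <- numeric(n)
  true_class <- rep("EXPECTED", n)
  if (n_out > 0) {
    up <- out_idx[seq_len(n_out) %% 2L == 1L]
    down <- setdiff(out_idx, up)
    shift[up] <- cfg$outlier_shift
    shift[down] <- -cfg$outlier_shift
    true_class[up] <- "ML"
    true_class[down] <- "FL"
  }

  log_loc <- cfg$beta0 + cfg$beta1 * log10(pmax(rt_true, 1)) +
    stats::rnorm(n, 0, cfg$sigma) + shift
  n_loc <- if (cfg$sigma == 0 && cfg$outlier_fraction == 0)
    pmax(10^log_loc, 1) else pmax(1, round(10^log_loc))

  zero <- stats::runif(n) < cfg$congener_zero_prob
  n_rel <- ifelse(zero, 0L, stats::rpois(n, cfg$congener_mean))

  detected <- !is.na(first_detect)
  recs <- vector("list", n)
  loc_counter <- 0L
  for (i in which(detected)) {
    k <- if (n_loc[i] == round(n_loc[i])) as.integer(n_loc[i]) else
      max(1L, floor(n_loc[i]))
    span <- which(years >= first_detect[i])
    yrs <- if (k > 1L)
      c(first_detect[i], sort(sample(years[span], k - 1L, replace = TRUE,
                                     prob = ef[span])))
    else first_detect[i]
    recs[[i]] <- data.frame(species = species[i], family = family[i],
                            life_form_group = life_form[i], year = yrs,
                            locality = pad_id("L", loc_counter + seq_len(k)),
                            n_relatives = n_rel[i], stringsAsFactors = FALSE)
    loc_counter <- loc_counter + k
  }
  specimens <- as_specimen_table(do.call(rbind, recs[detected]),
                                 ref_year = cfg$ref_year)

  group <- stats::setNames(sample(names(cfg$syndrome_spec), n, replace = TRUE),
                           species)
  attributes <- plant_attributes(group, cfg$n_attributes, cfg$syndrome_spec,
                                 base_prob = cfg$base_attr_prob,
                                 seed = sub_seed(cfg$seed, "attributes"))

  truth <- data.frame(species = species, life_form_group = life_form,
                      family = family, arrival = arrival, rt_true = rt_true,
                      first_detect = first_detect, detected = detected,
                      n_localities_true = n_loc, true_class = true_class,
                      planted_outlier = shift != 0,
                      group = unname(group), n_relatives = n_rel,
                      stringsAsFactors = FALSE)

  out <- list(specimens = specimens, attributes = attributes, truth = truth,
              effort_template = data.frame(year = years, ef = ef),
              config = cfg,
              warn_no_post_lag = !any(rt_true > cfg$lag_threshold))
  class(out) <- "synthetic_dataset"
  out
}

#' Ground-truth table of a synthetic dataset
#'
#' @param dataset a `synthetic_dataset`.
#' @return the per-species truth data frame (one row per species).
#' @export
truth_table <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dataset$truth
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic herbarium dataset: %d species (%d detected), %d specimens\n",
              nrow(x$truth), sum(x$truth$detected), nrow(x$specimens)))
  cat(sprintf("  era %d-%d, ref year %d, %d attributes\n",
              x$config$era[1], x$config$era[2], x$config$ref_year,
              x$config$n_attributes))
  if (x$warn_no_post_lag)
    cat("  WARNING: no species passes the lag threshold under this era\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' `specimens.csv` and `attributes.csv` match the ingestion schemas of
#' [read_specimens()] and [read_attribute_matrix()]; `truth.csv` holds the
#' ground truth and `config.json` the generator settings.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$specimens, file.path(dir, "specimens.csv"),
                   row.names = FALSE)
  am <- data.frame(species = rownames(dataset$attributes),
                   as.data.frame(unclass(dataset$attributes)),
                   check.names = FALSE)
  utils::write.csv(am, file.path(dir, "attributes.csv"), row.names = FALSE)
  utils::write.csv(dataset$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  cfg <- dataset$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
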