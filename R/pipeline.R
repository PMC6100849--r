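#' Configuration for the full analysis pipeline
#'
#' @param specimens path to a specimen CSV/TSV, or `NULL` when `synthetic`
#'   is given.
#' @param attributes path to an attribute-matrix CSV/TSV, or `NULL`.
#' @param synthetic a `synthetic_config`; when supplied the pipeline
#'   generates its own inputs.
#' @param ref_year reference year for residence times.
#' @param ref_effort effort at which the saturation model's `n_max` is read.
#' @param lag_thresholds named vector of lag-phase durations in years per
#'   life-form group.
#' @param level confidence level of the spread band.
#' @param nmds_dims,nmds_restarts NMDS settings.
#' @param n_perm_vector permutations for ordination vector fits.
#' @param n_rand_cosa randomizations for the COSA importance null.
#' @param cosa_lambda,cosa_k_nn,cosa_epsilon COSA settings.
#' @param prune_epsilon tolerance of the attribute screen.
#' @param prune_min_retain minimum attributes the screen must keep for the
#'   downstream ordination/COSA stages (default 30). The leave-one-out
#'   screen prunes aggressively on noisy data (redundant attributes are
#'   individually dispensable), and ordinations over very few binary
#'   attributes degenerate through tied distances; the floor keeps the
#'   retained set at a size a practitioner's screen would leave.
#' @param k_groups ordination group count; `NULL` selects by silhouette.
#' @param seed master seed; every stochastic stage consumes a stage-specific
#'   [sub_seed()] of it.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(specimens = NULL, attributes = NULL,
                            synthetic = NULL, ref_year = 2003,
                            ref_effort = 1800,
                            lag_thresholds = c(herb_subshrub = 54,
                                               tree_shrub = 300),
                            level = 0.95, nmds_dims = 2, nmds_restarts = 10,
                            n_perm_vector = 999, n_rand_cosa = 1000,
                            cosa_lambda = 0.2, cosa_k_nn = NULL,
                            cosa_epsilon = 0.01, prune_epsilon = 0.005,
                            prune_min_retain = 30,
                            k_groups = NULL, seed = 1, out_dir = NULL) {
  if (is.null(synthetic) && is.null(specimens))
    stopf("pipeline_config: either input paths or a synthetic config required")
  stopifnot(level > 0, level < 1, is_count(n_perm_vector),
            is_count(n_rand_cosa), is_count(nmds_dims), ref_effort > 0,
            all(lag_thresholds > 0))
  cfg <- list(specimens = specimens, attributes = attributes,
              synthetic = synthetic, ref_year = as.integer(ref_year),
              ref_effort = ref_effort, lag_thresholds = lag_thresholds,
              level = level, nmds_dims = as.integer(nmds_dims),
              nmds_restarts = as.integer(nmds_restarts),
              n_perm_vector = as.integer(n_perm_vector),
              n_rand_cosa = as.integer(n_rand_cosa),
              cosa_lambda = cosa_lambda, cosa_k_nn = cosa_k_nn,
              cosa_epsilon = cosa_epsilon, prune_epsilon = prune_epsilon,
              prune_min_retain = prune_min_retain,
              k_groups = k_groups, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file.path(dir, name))
}

#' Run the full analysis pipeline
#'
#' Sequences every stage: ingest (or synthesize) specimen records,
#' deduplicate, build the yearly effort series, fit the saturating
#' detection model and correct residence times, fit the log-log spread
#' regression per life-form group and classify species against its
#' confidence band, run the kinship association tests, screen the
#' attribute matrix, ordinate the species (NMDS + K-means + vector fits),
#' and compute COSA attribute importances for the four a-priori
#' spread-by-kinship groups with their randomization null. Stage failures
#' abort the remaining stages but return the bundle accumulated so far
#' (with an `error` field). When `config$out_dir` is set, every table is
#' written as TSV and a `manifest.tsv` of MD5 content hashes is produced.
#'
#' @param config a `pipeline_config`.
#' @return object of class `report_bundle` with elements `effort`,
#'   `saturation`, `profiles`, `spread` (per life-form fits and
#'   classifications), `dnh`, `screen`, `ordination`, `cosa`, `log`,
#'   `manifest` (when written), and `error` (`NULL` on success).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = cfg, log = character(), error = NULL)
  class(bundle) <- "report_bundle"
  note <- function(...) bundle$log <<- c(bundle$log, sprintf(...))

  run <- function(expr) tryCatch(expr, error = function(e) {
    bundle$error <<- conditionMessage(e)
    NULL
  })

  # ingest ----------------------------------------------------------------
  stage <- run({
    if (!is.null(cfg$synthetic)) {
      ds <- generate_dataset(cfg$synthetic)
      note("synthetic dataset: %d species, %d specimens",
           nrow(ds$truth), nrow(ds$specimens))
      list(specimens = ds$specimens, attributes = ds$attributes, dataset = ds)
    } else {
      sp <- read_specimens(cfg$specimens, ref_year = cfg$ref_year)
      am <- if (!is.null(cfg$attributes)) read_attribute_matrix(cfg$attributes)
      note("read %d specimen records", nrow(sp))
      list(specimens = sp, attributes = am, dataset = NULL)
    }
  })
  if (is.null(stage)) return(bundle)
  specimens <- deduplicate_specimens(stage$specimens)
  note("specimens after deduplication: %d", nrow(specimens))
  bundle$dataset <- stage$dataset

  # effort + detection correction ------------------------------------------
  ok <- run({
    bundle$effort <- effort_series(specimens)
    bundle$saturation <- fit_saturation(bundle$effort$ef,
                                        bundle$effort$n_species,
                                        ref_effort = cfg$ref_effort)
    bundle$profiles <- species_profiles(specimens, bundle$saturation,
                                        effort = bundle$effort)
    note("saturation model: a=%.5g b=%.5g n_max=%d r2=%.3f",
         bundle$saturation$a, bundle$saturation$b, bundle$saturation$n_max,
         bundle$saturation$r2)
    write_tsv(bundle$effort, cfg$out_dir, "effort.tsv")
    write_tsv(bundle$profiles, cfg$out_dir, "profiles.tsv")
    TRUE
  })
  if (is.null(ok)) return(bundle)

  # spread regression + classification per life form -----------------------
  ok <- run({
    bundle$spread <- list()
    for (lf in names(cfg$lag_thresholds)) {
      pr <- bundle$profiles[bundle$profiles$life_form_group == lf, ,
                            drop = FALSE]
      if (nrow(pr) < 3L) {
        note("life form %s: only %d species, regression skipped", lf, nrow(pr))
        next
      }
      fit <- fit_spread(pr, life_form = lf)
      cls <- classify_spread(pr, fit,
                             lag_threshold = cfg$lag_thresholds[[lf]],
                             level = cfg$level)
      note("life form %s: n=%d slope=%.4f r2=%.4f | post-lag=%d ML=%d FL=%d",
           lf, fit$n, fit$slope, fit$r2,
           sum(cls$label != "PRE_LAG"), sum(cls$label == "ML"),
           sum(cls$label == "FL"))
      bundle$spread[[lf]] <- list(fit = fit, classification = cls)
      write_tsv(cls, cfg$out_dir, sprintf("classification_%s.tsv", lf))
    }
    TRUE
  })
  if (is.null(ok) || length(bundle$spread) == 0L) return(bundle)

  herb <- bundle$spread[["herb_subshrub"]]
  if (is.null(herb)) herb <- bundle$spread[[1L]]

  # kinship association tests ----------------------------------------------
  ok <- run({
    bundle$dnh <- dnh_tests(herb$classification)
    write_tsv(bundle$dnh, cfg$out_dir, "dnh_tests.tsv")
    TRUE
  })
  if (is.null(ok)) return(bundle)

  if (is.null(stage$attributes)) {
    note("no attribute matrix: screening, ordination and COSA skipped")
    bundle <- finalize_bundle(bundle, cfg)
    return(bundle)
  }

  # attribute screen --------------------------------------------------------
  ok <- run({
    herb_species <- intersect(rownames(stage$attributes),
                              herb$classification$species)
    m <- stage$attributes[herb_species, , drop = FALSE]
    bundle$screen <- prune_attributes(m, epsilon = cfg$prune_epsilon,
                                      min_retain = cfg$prune_min_retain)
    note("attribute screen: %d of %d attributes retained",
         length(bundle$screen$retained), ncol(m))
    bundle$matrix <- as_attribute_matrix(
      m[, bundle$screen$retained, drop = FALSE])
    write_tsv(bundle$screen$report, cfg$out_dir, "prune_report.tsv")
    TRUE
  })
  if (is.null(ok)) return(bundle)

  # ordination ---------------------------------------------------------------
  ok <- run({
    d <- jaccard_dist(bundle$matrix)
    ord <- nmds(d, dims = cfg$nmds_dims, restarts = cfg$nmds_restarts,
                seed = sub_seed(cfg$seed, "nmds"))
    k <- cfg$k_groups
    if (is.null(k))
      k <- choose_k(ord$points, 2:min(8, nrow(ord$points) - 1L),
                    seed = sub_seed(cfg$seed, "choose_k"))$k
    grp <- kmeans_groups(ord$points, k, seed = sub_seed(cfg$seed, "kmeans"))
    cls <- herb$classification
    idx <- match(rownames(ord$points), cls$species)
    covs <- data.frame(n_relatives = cls$n_relatives[idx],
                       n_localities = cls$n_localities[idx],
                       art = cls$art[idx],
                       residual = cls$residual[idx])
    vf <- fit_vectors(ord$points, covs, n_perm = cfg$n_perm_vector,
                      seed = sub_seed(cfg$seed, "envfit"))
    bundle$ordination <- list(nmds = ord, k = k, groups = grp$labels,
                              vectors = vf)
    note("NMDS stress=%.4f r2=%.4f; k=%d groups", ord$stress, ord$r2, k)
    bundle$dnh_groups <- dnh_tests(herb$classification,
                                   groups = grp$labels)
    write_tsv(data.frame(species = rownames(ord$points), ord$points,
                         group = grp$labels), cfg$out_dir, "ordination.tsv")
    write_tsv(vf, cfg$out_dir, "vector_fits.tsv")
    write_tsv(bundle$dnh_groups, cfg$out_dir, "dnh_tests_groups.tsv")
    TRUE
  })
  if (is.null(ok)) return(bundle)

  # COSA ---------------------------------------------------------------------
  ok <- run({
    bundle$cosa <- dnh_syndrome_report(herb$classification, bundle$matrix,
                                       n_rand = cfg$n_rand_cosa,
                                       seed = sub_seed(cfg$seed, "cosa"),
                                       epsilon = cfg$cosa_epsilon,
                                       lambda = cfg$cosa_lambda,
                                       k_nn = cfg$cosa_k_nn)
    note("COSA: %d usable group(s)%s",
         length(unique(bundle$cosa$groups)) -
           length(bundle$cosa$not_computable),
         if (length(bundle$cosa$not_computable))
           paste0(", not computable: ",
                  paste(bundle$cosa$not_computable, collapse = ", ")) else "")
    write_tsv(bundle$cosa$importance, cfg$out_dir, "cosa_importance.tsv")
    TRUE
  })
  if (is.null(ok)) return(bundle)

  finalize_bundle(bundle, cfg)
}

finalize_bundle <- function(bundle, cfg) {
  if (!is.null(cfg$out_dir)) {
    writeLines(bundle$log, file.path(cfg$out_dir, "run.log"))
    files <- sort(setdiff(list.files(cfg$out_dir), "manifest.tsv"))
    manifest <- data.frame(file = files,
                           md5 = unname(tools::md5sum(
                             file.path(cfg$out_dir, files))),
                           stringsAsFactors = FALSE)
    utils::write.table(manifest, file.path(cfg$out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bundle$manifest <- manifest
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis pipeline report\n")
  for (line in x$log) cat(" -", line, "\n")
  if (!is.null(x$error)) cat(" ERROR:", x$error, "\n")
  invisible(x)
}
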