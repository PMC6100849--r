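#' Read and validate a specimen-record table
#'
#' Parses a CSV (comma) or TSV (tab, any other extension) file of herbarium
#' specimen records. The header must contain the six columns `species`,
#' `family`, `life_form_group`, `year`, `locality`, `n_relatives`.
#' Unparseable or out-of-range years abort with the offending row numbers;
#' rows with a missing year are dropped and counted (attribute
#' `n_dropped_missing_year`), since a record without a collection year cannot
#' enter the residence-time analysis.
#'
#' @param path path to the file.
#' @param ref_year last year of records; years must lie in `[1500, ref_year]`.
#' @return a `specimen_table`: data frame of validated records with
#'   attributes `ref_year` and `n_dropped_missing_year`.
#' @export
read_specimens <- function(path, ref_year = 2003) {
  if (!file.exists(path)) stopf("read_specimens: no such file: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                           colClasses = "character", quote = "\"",
                           fileEncoding = "UTF-8", check.names = FALSE,
                           stringsAsFactors = FALSE)
  as_specimen_table(raw, ref_year = ref_year)
}

#' @rdname read_specimens
#' @param x a data frame with the six required columns (`year` and
#'   `n_relatives` may be character or numeric).
#' @export
as_specimen_table <- function(x, ref_year = 2003) {
  required <- c("species", "family", "life_form_group", "year", "locality",
                "n_relatives")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stopf("specimen table: missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  x <- x[required]

  year_chr <- trimws(as.character(x$year))
  blank <- is.na(year_chr) | year_chr == "" | toupper(year_chr) == "NA"
  year <- suppressWarnings(as.numeric(year_chr))
  bad <- which(!blank & (is.na(year) | year != floor(year)))
  if (length(bad))
    stopf("specimen table: unparseable year in row(s): %s",
          paste(bad, collapse = ", "))
  out_of_range <- which(!blank & !is.na(year) & (year < 1500 | year > ref_year))
  if (length(out_of_range))
    stopf("specimen table: year outside [1500, %d] in row(s): %s",
          ref_year, paste(out_of_range, collapse = ", "))

  lf <- trimws(as.character(x$life_form_group))
  bad_lf <- which(!lf %in% c("herb_subshrub", "tree_shrub"))
  if (length(bad_lf))
    stopf("specimen table: life_form_group must be herb_subshrub or tree_shrub (row(s) %s)",
          paste(bad_lf, collapse = ", "))

  nr <- suppressWarnings(as.numeric(as.character(x$n_relatives)))
  bad_nr <- which(is.na(nr) | nr < 0 | nr != floor(nr))
  if (length(bad_nr))
    stopf("specimen table: n_relatives must be a nonnegative integer (row(s) %s)",
          paste(bad_nr, collapse = ", "))

  keep <- !blank
  out <- data.frame(species = as.character(x$species)[keep],
                    family = as.character(x$family)[keep],
                    life_form_group = lf[keep],
                    year = as.integer(year[keep]),
                    locality = as.character(x$locality)[keep],
                    n_relatives = as.integer(nr[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "ref_year") <- as.integer(ref_year)
  attr(out, "n_dropped_missing_year") <- sum(blank)
  class(out) <- c("specimen_table", "data.frame")
  out
}

ref_year_of <- function(table) {
  ry <- attr(table, "ref_year")
  if (is.null(ry)) stopf("not a specimen_table: missing ref_year attribute")
  ry
}

#' Remove repeated specimens of a species from the same locality
#'
#' One record is kept per (species, locality) pair, the one with the earliest
#' collection year. Idempotent.
#'
#' @param table a `specimen_table`.
#' @return a deduplicated `specimen_table`.
#' @export
deduplicate_specimens <- function(table) {
  stopifnot(inherits(table, "specimen_table"))
  if (nrow(table) == 0L) return(table)
  ord <- order(table$species, table$locality, table$year)
  t2 <- table[ord, , drop = FALSE]
  first <- !duplicated(t2[c("species", "locality")])
  out <- t2[first, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ref_year") <- attr(table, "ref_year")
  attr(out, "n_dropped_missing_year") <- attr(table, "n_dropped_missing_year")
  class(out) <- class(table)
  out
}

#' Yearly collection effort and detection counts
#'
#' For every calendar year in the observed span: `ef`, the number of
#' specimens collected (rows of the table); `n_species`, the number of
#' distinct species collected that year; and `n_new`, the number of species
#' whose first record falls in that year. Years inside the span with no
#' records are reported with zeros.
#'
#' @param table a deduplicated `specimen_table`.
#' @return data frame with columns `year`, `ef`, `n_species`, `n_new`.
#' @export
effort_series <- function(table) {
  stopifnot(inherits(table, "specimen_table"))
  if (nrow(table) == 0L)
    return(data.frame(year = integer(), ef = integer(),
                      n_species = integer(), n_new = integer()))
  years <- seq(min(table$year), max(table$year))
  ef <- as.integer(table(factor(table$year, levels = years)))
  sp_year <- unique(table[c("species", "year")])
  n_species <- as.integer(table(factor(sp_year$year, levels = years)))
  first <- tapply(table$year, table$species, min)
  n_new <- as.integer(table(factor(first, levels = years)))
  data.frame(year = years, ef = ef, n_species = n_species, n_new = n_new)
}

#' Per-species profiles: first record, residence time, localities
#'
#' Summarizes a deduplicated specimen table into one row per species with
#' its first-record year, residence time `rt = ref_year - first_year`, the
#' probability `pu` of having gone undetected in the first-record year, the
#' adjusted residence time `art = rt + scale * pu`, the number of distinct
#' localities, the native-congener count and the life-form group.
#'
#' @param table a deduplicated `specimen_table`.
#' @param pu_lookup either a named numeric vector of `pu` keyed by year, a
#'   function `year -> pu`, or a `saturation_fit` together with `effort`.
#' @param effort effort series (needed only when `pu_lookup` is a
#'   `saturation_fit`).
#' @param correction_scale years added per unit undetection probability.
#' @return data frame of class `species_profiles`.
#' @export
species_profiles <- function(table, pu_lookup, effort = NULL,
                             correction_scale = 100) {
  stopifnot(inherits(table, "specimen_table"))
  ref_year <- ref_year_of(table)
  if (nrow(table) == 0L)
    stopf("species_profiles: empty specimen table")

  sp <- sort(unique(table$species))
  idx <- split(seq_len(nrow(table)), table$species)[sp]
  first_year <- vapply(idx, function(i) min(table$year[i]), integer(1))
  n_loc <- vapply(idx, function(i) length(unique(table$locality[i])), integer(1))
  n_rel <- vapply(idx, function(i) table$n_relatives[i][1L], integer(1))
  lf <- vapply(idx, function(i) table$life_form_group[i][1L], character(1))
  fam <- vapply(idx, function(i) table$family[i][1L], character(1))

  if (inherits(pu_lookup, "saturation_fit")) {
    if (is.null(effort)) stopf("species_profiles: effort series required with a saturation_fit")
    pu_lookup <- pu_by_year(pu_lookup, effort)
  }
  pu <- if (is.function(pu_lookup)) {
    vapply(first_year, pu_lookup, numeric(1))
  } else {
    missing_years <- setdiff(as.character(first_year), names(pu_lookup))
    if (length(missing_years))
      stopf("species_profiles: pu_lookup missing year(s): %s",
            paste(sort(unique(missing_years)), collapse = ", "))
    unname(pu_lookup[as.character(first_year)])
  }
  if (!is_prob(pu)) stopf("species_profiles: pu values must lie in [0, 1]")

  rt <- ref_year - first_year
  out <- data.frame(species = sp,
                    family = fam,
                    life_form_group = lf,
                    first_year = first_year,
                    rt = rt,
                    pu = pu,
                    art = adjust_residence_time(rt, pu, correction_scale),
                    n_localities = n_loc,
                    n_relatives = n_rel,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ref_year") <- ref_year
  class(out) <- c("species_profiles", "data.frame")
  out
}
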