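#' @keywords internal
pft_levels <- function() {
  c("coccolithophore", "cyanobacterium", "diatom", "dinoflagellate")
}

canonical_growth_columns <- function() {
  c(strain_id = "strain_id", pft = "pft", temperature = "temperature_C",
    growth_rate = "growth_rate_d", light = "light_umol",
    day_length = "day_length_h", is_diazotroph = "is_diazotroph",
    fluctuating_nutrients = "fluctuating_nutrients",
    isolation_lat = "isolation_lat", isolation_lon = "isolation_lon",
    source = "source")
}

#' Construct a validated growth dataset
#'
#' A growth dataset is a data frame of strain-level growth measurements
#' (one row per measurement) carrying a provenance attribute that records
#' every filter applied to it with before/after counts.  Validation
#' enforces: temperatures finite and within [-5, 60] degrees C; growth
#' rates finite; functional type one of coccolithophore, cyanobacterium,
#' diatom, dinoflagellate; isolation coordinates, when present, within
#' [-90, 90] and [-180, 180); and a single functional type per strain.
#'
#' @param df data frame with at least \code{strain_id}, \code{pft},
#'   \code{temperature}, \code{growth_rate}; optional \code{light},
#'   \code{day_length}, \code{is_diazotroph},
#'   \code{fluctuating_nutrients}, \code{isolation_lat},
#'   \code{isolation_lon}, \code{source}.
#' @param provenance a provenance data frame (rule, n_before, n_removed,
#'   n_after), usually left at its empty default.
#' @return object of class \code{growth_dataset} (a data frame).
#' @export
growth_dataset <- function(df, provenance = empty_provenance()) {
  required <- c("strain_id", "pft", "temperature", "growth_rate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  optional <- c("light", "day_length", "is_diazotroph",
                "fluctuating_nutrients", "isolation_lat", "isolation_lon",
                "source")
  for (col in optional) if (is.null(df[[col]])) df[[col]] <- NA
  df <- df[c(required, optional)]
  df$strain_id <- as.character(df$strain_id)
  df$pft <- as.character(df$pft)
  df$source <- as.character(df$source)
  for (col in c("temperature", "growth_rate", "light", "day_length",
                "isolation_lat", "isolation_lon")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("is_diazotroph", "fluctuating_nutrients")) {
    df[[col]] <- as.logical(df[[col]])
  }

  bad <- which(!is.finite(df$temperature) | df$temperature < -5 |
                 df$temperature > 60)
  if (length(bad)) {
    stop(sprintf("row %d: temperature must be finite and within [-5, 60] degC",
                 bad[1]))
  }
  bad <- which(!is.finite(df$growth_rate))
  if (length(bad)) {
    stop(sprintf("row %d: growth_rate must be finite", bad[1]))
  }
  bad <- which(!df$pft %in% pft_levels())
  if (length(bad)) {
    stop(sprintf("row %d: pft '%s' is not one of: %s", bad[1],
                 df$pft[bad[1]], paste(pft_levels(), collapse = ", ")))
  }
  bad <- which(!is.na(df$isolation_lat) &
                 (df$isolation_lat < -90 | df$isolation_lat > 90))
  if (length(bad)) {
    stop(sprintf("row %d: isolation_lat %g outside [-90, 90]",
                 bad[1], df$isolation_lat[bad[1]]))
  }
  bad <- which(!is.na(df$isolation_lon) &
                 (df$isolation_lon < -180 | df$isolation_lon >= 180))
  if (length(bad)) {
    stop(sprintf("row %d: isolation_lon %g outside [-180, 180)",
                 bad[1], df$isolation_lon[bad[1]]))
  }
  multi <- tapply(df$pft, df$strain_id, function(x) length(unique(x)))
  if (any(multi > 1)) {
    stop(sprintf("strain '%s' is assigned to more than one functional type",
                 names(multi)[which(multi > 1)[1]]))
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("growth_dataset", "data.frame"))
}

empty_provenance <- function() {
  data.frame(rule = character(), n_before = integer(),
             n_removed = integer(), n_after = integer())
}

#' Provenance (filter log) of a growth dataset
#' @param ds a \code{growth_dataset}.
#' @return data frame with one row per applied filter rule.
#' @export
provenance <- function(ds) {
  attr(ds, "provenance") %||% empty_provenance()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf("Growth dataset: %d measurements, %d strains, %d functional types\n",
              nrow(x), length(unique(x$strain_id)),
              length(unique(x$pft))))
  prov <- provenance(x)
  if (nrow(prov)) {
    cat("Filters applied:\n")
    for (i in seq_len(nrow(prov))) {
      cat(sprintf("  %-40s removed %d (%d -> %d)\n", prov$rule[i],
                  prov$n_removed[i], prov$n_before[i], prov$n_after[i]))
    }
  }
  invisible(x)
}

#' Read a strain growth-rate table from delimited text
#'
#' Reads a CSV or TSV file with a header into a validated
#' [growth_dataset()].  The delimiter is auto-detected from the header line
#' (comma vs tab) unless given.  Column names are resolved through a
#' dialect mapping whose default is the canonical schema
#' \code{strain_id, pft, temperature_C, growth_rate_d, light_umol,
#' day_length_h, is_diazotroph, fluctuating_nutrients, isolation_lat,
#' isolation_lon, source}; supply \code{dialect} entries of the form
#' \code{c(temperature = "temp.c")} to read other layouts.  Optional
#' columns absent from the file are marked missing.
#'
#' @param path file path.
#' @param dialect named character vector mapping internal field names to
#'   file column names; merged over the canonical defaults.
#' @param sep field delimiter; \code{NULL} (default) auto-detects.
#' @return a \code{growth_dataset}.
#' @export
read_growth_table <- function(path, dialect = NULL, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cols <- canonical_growth_columns()
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", fileEncoding = "UTF-8",
                           check.names = FALSE)
  required <- c("strain_id", "pft", "temperature", "growth_rate")
  for (field in required) {
    if (!cols[[field]] %in% names(raw)) {
      stop(sprintf("schema error: required column '%s' (field %s) not found",
                   cols[[field]], field))
    }
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(cols)) {
    df[[field]] <- if (cols[[field]] %in% names(raw)) raw[[cols[[field]]]] else NA
  }
  for (field in c("temperature", "growth_rate", "light", "day_length",
                  "isolation_lat", "isolation_lon")) {
    x <- df[[field]]
    if (is.character(x)) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(parsed))
      if (length(bad)) {
        stop(sprintf("row %d: cannot parse '%s' as numeric for column %s",
                     bad[1], x[bad[1]], cols[[field]]))
      }
      df[[field]] <- parsed
    }
  }
  growth_dataset(df)
}

#' Write a growth dataset back to delimited text
#'
#' Round-trips the canonical column layout written by
#' [read_growth_table()].
#'
#' @param ds a \code{growth_dataset}.
#' @param path output file path.
#' @param sep delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
write_growth_table <- function(ds, path, sep = ",") {
  out <- as.data.frame(ds)
  names(out) <- canonical_growth_columns()[names(out)]
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Compilation selection filters
#'
#' Configuration for the three quality-control rules used when compiling
#' thermal growth data across laboratory studies:
#' \itemize{
#'   \item \code{light}: drop measurements taken under continuous light
#'     (\code{day_length == 24} h) at or below \code{light_min}
#'     (default 80 umol photons m^-2 s^-1).  Records lacking light or
#'     day-length metadata are retained: the rule only fires on measured
#'     values, since silent exclusion of sparsely annotated studies would
#'     bias the compilation.
#'   \item \code{diazotrophs}: drop nitrogen-fixing cyanobacteria, whose
#'     physiology differs fundamentally from the rest of the group.
#'   \item \code{fluctuating_nutrients}: drop studies that exposed strains
#'     to fluctuating nutrient concentrations, which yield reaction norms
#'     that are not comparable to nutrient-replete assays.
#' }
#' Each rule is independently toggleable.
#'
#' @param drop_low_light,drop_diazotrophs,drop_fluctuating_nutrients
#'   logical toggles (all default \code{TRUE}).
#' @param light_min light threshold (umol photons m^-2 s^-1) applied when
#'   day length is 24 h.
#' @return list of class \code{filter_config}.
#' @export
filter_config <- function(drop_low_light = TRUE,
                          drop_diazotrophs = TRUE,
                          drop_fluctuating_nutrients = TRUE,
                          light_min = 80) {
  structure(list(drop_low_light = drop_low_light,
                 drop_diazotrophs = drop_diazotrophs,
                 drop_fluctuating_nutrients = drop_fluctuating_nutrients,
                 light_min = light_min),
            class = "filter_config")
}

#' Apply compilation selection filters
#'
#' Applies the enabled [filter_config()] rules per measurement and appends
#' one provenance row per rule with before/after counts.  Filtering is
#' idempotent and the rules commute: the surviving record set does not
#' depend on the order in which the rules run.
#'
#' @param ds a \code{growth_dataset}.
#' @param rules a [filter_config()].
#' @return the filtered \code{growth_dataset}.
#' @export
apply_selection_filters <- function(ds, rules = filter_config()) {
  stopifnot(inherits(ds, "growth_dataset"), inherits(rules, "filter_config"))
  prov <- provenance(ds)
  drop_rule <- function(df, drop, label) {
    drop[is.na(drop)] <- FALSE
    prov <<- rbind(prov, data.frame(
      rule = label, n_before = nrow(df),
      n_removed = sum(drop), n_after = nrow(df) - sum(drop)))
    df[!drop, , drop = FALSE]
  }
  df <- as.data.frame(ds)
  if (rules$drop_low_light) {
    df <- drop_rule(
      df, df$day_length == 24 & df$light <= rules$light_min,
      sprintf("continuous light <= %g umol photons/m2/s", rules$light_min))
  }
  if (rules$drop_diazotrophs) {
    df <- drop_rule(df, df$is_diazotroph, "diazotrophic strains")
  }
  if (rules$drop_fluctuating_nutrients) {
    df <- drop_rule(df, df$fluctuating_nutrients,
                    "fluctuating-nutrient studies")
  }
  growth_dataset(df, provenance = prov)
}

#' Per-group compilation summary
#'
#' Counts strains (n) and discrete growth measurements (N) per functional
#' type, with an "All" row whose counts are the column sums of the group
#' rows.
#'
#' @param ds a \code{growth_dataset}.
#' @return data frame with columns \code{pft}, \code{n_strains},
#'   \code{n_measurements}.
#' @export
dataset_summary <- function(ds) {
  stopifnot(inherits(ds, "growth_dataset"))
  groups <- pft_levels()
  n_strains <- vapply(groups, function(g) {
    length(unique(ds$strain_id[ds$pft == g]))
  }, integer(1))
  n_meas <- vapply(groups, function(g) sum(ds$pft == g), integer(1))
  data.frame(pft = c(groups, "All"),
             n_strains = c(n_strains, sum(n_strains)),
             n_measurements = c(n_meas, sum(n_meas)),
             row.names = NULL)
}

#' Fit reaction norms to every strain in a dataset
#'
#' Runs [fit_reaction_norm()] per strain and assembles a traits table:
#' fitted parameters, derived traits, performance breadth, limb slopes and
#' the upper-limit QC flag, alongside isolation coordinates.  Strains with
#' too few distinct temperatures or no positive growth are reported with
#' \code{converged = FALSE} and missing traits rather than aborting the
#' compilation.
#'
#' @param ds a \code{growth_dataset}.
#' @param control a [norberg_control()].
#' @param fraction performance-breadth threshold (default 0.2).
#' @return data frame, one row per strain.
#' @export
strain_traits <- function(ds, control = norberg_control(), fraction = 0.2) {
  stopifnot(inherits(ds, "growth_dataset"))
  strains <- unique(ds$strain_id)
  rows <- lapply(strains, function(sid) {
    sub <- ds[ds$strain_id == sid, ]
    base <- data.frame(
      strain_id = sid, pft = sub$pft[1],
      isolation_lat = sub$isolation_lat[1],
      isolation_lon = sub$isolation_lon[1],
      n_points = nrow(sub),
      a = NA_real_, b = NA_real_, z = NA_real_, w = NA_real_,
      sigma = NA_real_, converged = FALSE,
      T_opt = NA_real_, mu_max = NA_real_, T_min = NA_real_,
      T_max = NA_real_, niche_width = NA_real_,
      T_lo = NA_real_, T_hi = NA_real_,
      slope_up = NA_real_, slope_down = NA_real_,
      tmax_qc_pass = FALSE)
    fit <- tryCatch(
      fit_reaction_norm(sub$temperature, sub$growth_rate, control),
      error = function(e) NULL)
    if (is.null(fit)) return(base)
    tr <- derive_traits(fit)
    br <- performance_breadth(fit, fraction)
    base[c("a", "b", "z", "w")] <- as.list(fit$params)
    base$sigma <- fit$sigma
    base$converged <- fit$converged
    base[c("T_opt", "mu_max", "T_min", "T_max", "niche_width")] <-
      tr[c("T_opt", "mu_max", "T_min", "T_max", "niche_width")]
    base[c("T_lo", "T_hi", "slope_up", "slope_down")] <-
      br[c("T_lo", "T_hi", "slope_up", "slope_down")]
    base$tmax_qc_pass <- qc_tmax(fit)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
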