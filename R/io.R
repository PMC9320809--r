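#' @importFrom stats median setNames aggregate complete.cases
#' @importFrom utils head modifyList
NULL

.find_column <- function(df, aliases, required = TRUE, what = aliases[1]) {
  hit <- intersect(aliases, names(df))
  if (length(hit) == 0L) {
    if (required) {
      stop(sprintf("format error: missing required column '%s' (accepted names: %s)",
                   what, paste(aliases, collapse = ", ")), call. = FALSE)
    }
    return(NULL)
  }
  hit[1]
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

#' Read an event-logged courtship observation file
#'
#' Reads a delimited table of scored behavioral observations (one row per
#' scored timepoint or per state-onset event, as exported by manual
#' video-scoring software) and converts each trial to a fixed-interval state
#' series. Two dialects are supported and auto-detected: `"grid"` (one row per
#' observation, times exact multiples of `interval_s` -- the scoring mode in
#' which the video is paused every 10 s) and `"events"` (state onsets at
#' arbitrary times). In both cases the state at grid point `t` is the last
#' recorded state with time `<= t`, so an onset logged between grid points
#' never snaps backward; each grid point represents the half-open interval
#' `[t, t + interval_s)`. Snapping is idempotent: re-reading an
#' already-gridded log changes nothing.
#'
#' If the final recorded state of a trial is `copulating`, the grid is
#' extended to the first grid point at or after its onset so that copulation
#' is retained; scoring ends at copulation.
#'
#' @param path Path to a CSV or TSV file with at least columns for trial id
#'   (`trial_id`/`trial`), time in seconds (`time_s`/`time`) and behavior
#'   label (`behavior`/`state`/`label`). Optional metadata columns
#'   `male_strain`, `female_strain`, `block_id` are carried through.
#' @param interval_s Grid interval in seconds (default 10).
#' @param dialect `"auto"` (default), `"grid"` or `"events"`.
#' @param max_span_s Maximum recording span in seconds (default 1800).
#' @return An `ethogram_set`: a list of [ethogram_trial()] objects.
#' @export
read_event_log <- function(path, interval_s = 10,
                           dialect = c("auto", "grid", "events"),
                           max_span_s = 1800) {
  dialect <- match.arg(dialect)
  df <- .read_delim_auto(path)
  id_col <- .find_column(df, c("trial_id", "trial"), what = "trial_id")
  t_col <- .find_column(df, c("time_s", "time"), what = "time_s")
  b_col <- .find_column(df, c("behavior", "state", "label"), what = "behavior")
  m_col <- .find_column(df, "male_strain", required = FALSE)
  f_col <- .find_column(df, "female_strain", required = FALSE)
  blk_col <- .find_column(df, "block_id", required = FALSE)

  if (any(is.na(df[[t_col]])) || any(df[[t_col]] < 0)) {
    stop("validation error: times must be non-negative and non-missing", call. = FALSE)
  }
  .check_state_labels(as.character(df[[b_col]]), where = basename(path))

  trials <- lapply(split(df, as.character(df[[id_col]])), function(d) {
    d <- d[order(d[[t_col]]), , drop = FALSE]
    times <- as.numeric(d[[t_col]])
    labs <- as.character(d[[b_col]])
    cop <- which(labs == "copulating")
    if (length(cop) > 0L && (length(cop) > 1L || cop != length(labs))) {
      stop(sprintf(
        "validation error: trial '%s' has recorded states after 'copulating'",
        d[[id_col]][1]
      ), call. = FALSE)
    }
    on_grid <- all(abs(times / interval_s - round(times / interval_s)) < 1e-9)
    use_dialect <- if (dialect == "auto") {
      if (on_grid) "grid" else "events"
    } else {
      dialect
    }
    if (use_dialect == "grid" && !on_grid) {
      stop(sprintf("format error: trial '%s' has times off the %g-s grid under dialect 'grid'",
                   d[[id_col]][1], interval_s), call. = FALSE)
    }
    grid_end <- floor(max(times) / interval_s) * interval_s
    if (length(cop) == 1L) {
      grid_end <- max(grid_end, ceiling(times[cop] / interval_s) * interval_s)
    }
    grid <- seq(0, grid_end, by = interval_s)
    # last recorded state with time <= t; error if the log starts after t = 0
    idx <- findInterval(grid + 1e-9, times)
    if (any(idx == 0L)) {
      stop(sprintf("validation error: trial '%s' has no state recorded at or before t = 0",
                   d[[id_col]][1]), call. = FALSE)
    }
    states <- labs[idx]
    first_cop <- which(states == "copulating")
    if (length(first_cop) > 0L) states <- states[seq_len(first_cop[1])]
    ethogram_trial(
      trial_id = as.character(d[[id_col]][1]),
      states = states,
      male_strain = if (is.null(m_col)) NA_character_ else as.character(d[[m_col]][1]),
      female_strain = if (is.null(f_col)) NA_character_ else as.character(d[[f_col]][1]),
      interval_s = interval_s,
      block_id = if (is.null(blk_col)) NULL else as.character(d[[blk_col]][1]),
      max_span_s = max_span_s
    )
  })
  as_ethogram_set(unname(trials))
}

#' Write an ethogram set back to a gridded event log
#'
#' Inverse of [read_event_log()] for the `"grid"` dialect: one row per scored
#' timepoint. `read_event_log(write_event_log(x))` reproduces the state
#' sequences exactly.
#'
#' @param trials An `ethogram_set` or list of [ethogram_trial()] objects.
#' @param path Output file path (`.tsv` writes tab-separated, otherwise CSV).
#' @return The path, invisibly.
#' @export
write_event_log <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    data.frame(
      trial_id = tr$trial_id,
      male_strain = tr$male_strain,
      female_strain = tr$female_strain,
      block_id = tr$block_id,
      time_s = (seq_along(tr$states) - 1L) * tr$interval_s,
      behavior = tr$states,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

# Canonical compound names (Table-2 style) and common synonyms, matched
# case-insensitively after stripping spaces/hyphens.
.chc_synonyms <- c(
  "7tricosene" = "7-C23", "7c23" = "7-C23",
  "7pentacosene" = "7-C25", "7c25" = "7-C25",
  "5pentacosene" = "5-C25", "5c25" = "5-C25",
  "9pentacosene" = "9-C25", "9c25" = "9-C25",
  "2methylhexacosane" = "2-Me-C26", "2mec26" = "2-Me-C26",
  "2methyltriacontane" = "2-Me-C30", "2mec30" = "2-Me-C30",
  "cisvaccenylacetate" = "cVA", "cva" = "cVA",
  "nheneicosane" = "n-C21", "nc21" = "n-C21", "c21" = "n-C21",
  "ndocosane" = "n-C22", "nc22" = "n-C22", "c22" = "n-C22",
  "ntetracosane" = "n-C24", "nc24" = "n-C24", "c24" = "n-C24",
  "hexacosane" = "n-C26", "nc26" = "n-C26", "c26" = "n-C26"
)

#' Canonicalize a cuticular-hydrocarbon compound name
#'
#' Maps common naming styles (e.g. `"7-tricosene"`, `"7C23"`) onto the
#' canonical short labels (`"7-C23"`, `"cVA"`, ...). Unrecognized names are
#' returned unchanged (compounds are free-form).
#'
#' @param x Character vector of compound names.
#' @return Character vector of canonical names.
#' @export
canonical_compound <- function(x) {
  key <- tolower(gsub("[ _‐-]", "", x))
  hit <- .chc_synonyms[key]
  unname(ifelse(is.na(hit), x, hit))
}

#' Normalize cuticular hydrocarbon peak areas against an internal standard
#'
#' Converts raw GC peak areas to dimensionless abundances by dividing each
#' compound's area by the hexacosane (n-C26) internal-standard area of the
#' same individual. The internal standard is removed from the output. The
#' result is scale-invariant: multiplying all areas of one individual by a
#' constant leaves its profile unchanged.
#'
#' @param peak_table Data frame with columns `individual` (or
#'   `individual_id`), `strain`, `sex`, `treatment`, `compound`, `area`.
#' @param internal_standard Compound name of the internal standard
#'   (default `"n-C26"`, hexacosane); matched after canonicalization.
#' @return Data frame of CHC profiles in long form: `individual_id`,
#'   `strain`, `sex`, `treatment`, `compound` (canonical name), `amount`.
#' @export
normalize_chc <- function(peak_table, internal_standard = "n-C26") {
  id_col <- .find_column(peak_table, c("individual_id", "individual"),
                         what = "individual_id")
  for (col in c("strain", "sex", "treatment", "compound", "area")) {
    .find_column(peak_table, col)
  }
  df <- data.frame(
    individual_id = as.character(peak_table[[id_col]]),
    strain = as.character(peak_table$strain),
    sex = as.character(peak_table$sex),
    treatment = as.character(peak_table$treatment),
    compound = canonical_compound(as.character(peak_table$compound)),
    area = as.numeric(peak_table$area),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$area)) || any(df$area < 0)) {
    stop("validation error: peak areas must be non-negative and non-missing",
         call. = FALSE)
  }
  is_name <- canonical_compound(internal_standard)
  out <- lapply(split(df, df$individual_id), function(d) {
    is_rows <- d$compound == is_name
    if (!any(is_rows) || sum(d$area[is_rows]) <= 0) {
      stop(sprintf(
        "validation error: individual '%s' has zero or missing internal-standard (%s) area",
        d$individual_id[1], is_name
      ), call. = FALSE)
    }
    ref <- sum(d$area[is_rows])
    d <- d[!is_rows, , drop = FALSE]
    d$amount <- d$area / ref
    d$area <- NULL
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Reshape long CHC profiles to an individuals-by-compounds matrix
#'
#' @param profiles Long-form output of [normalize_chc()].
#' @return Data frame with one row per individual (`individual_id`, `strain`,
#'   `sex`, `treatment`) and one numeric column per compound. Compounds not
#'   measured for an individual are 0.
#' @export
chc_wide <- function(profiles) {
  ids <- unique(profiles[c("individual_id", "strain", "sex", "treatment")])
  compounds <- sort(unique(profiles$compound))
  mat <- matrix(0, nrow(ids), length(compounds),
                dimnames = list(ids$individual_id, compounds))
  for (i in seq_len(nrow(profiles))) {
    mat[profiles$individual_id[i], profiles$compound[i]] <- profiles$amount[i]
  }
  cbind(ids, as.data.frame(mat, check.names = FALSE), row.names = NULL)
}

#' Write a result table to TSV or JSON
#'
#' Values round-trip at full stored precision: TSV output uses shortest
#' round-trippable decimal representations, JSON output is written with
#' unrestricted digits.
#'
#' @param results Non-empty data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @seealso [read_results()]
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (nrow(results) == 0L || ncol(results) == 0L) {
    stop("validation error: refusing to write an empty result table", call. = FALSE)
  }
  if (format == "tsv") {
    # format doubles at 17 significant digits so values survive the round trip
    out <- results
    for (col in names(out)) {
      if (is.double(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                             sprintf("%.17g", out[[col]]))
      }
    }
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "columns", digits = I(17),
                         na = "null", auto_unbox = FALSE)
  }
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return A data frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path))
  }
}
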