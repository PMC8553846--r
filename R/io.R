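# Readers and writers for peak lists, relaxation series tables, shift
# tables, structure-attribute files and the YAML run configuration.
#
# Unit policy: all conversions happen here.  Internally delays and T_relax
# are seconds, rates and nu_CPMG are s^-1, shifts are ppm.  Residue numbers
# are taken verbatim from the input files; no renumbering is ever applied.

#' Read a 2D peak list
#'
#' Parses either a Sparky-style `.list` file (whitespace-aligned columns
#' `Assignment w1 w2 Height`, labels such as `G67N-H` or `V64CG1-HG1`) or a
#' headered TSV with columns `residue`, `atom`, `shift_w1`, `shift_w2`,
#' `height` and optionally `height_error`.  The fractional error floor is
#' applied wherever an explicit error is absent or smaller
#' (see [apply_error_floor()]).
#'
#' @param path file to read.
#' @param dialect `"sparky"` or `"tsv"`.
#' @param condition_label free-text label for the sample condition
#'   (e.g. `"K+"`).
#' @param field_1H spectrometer 1H frequency in MHz (optional metadata).
#' @param error_floor fractional error floor, default 0.02.
#' @return a `peak_table`: data.frame with columns `residue_id`,
#'   `atom_label`, `shift_w1`, `shift_w2`, `height`, `height_error`, plus
#'   attributes `condition_label` and `field_1H`.
#' @export
read_peak_list <- function(path, dialect = c("tsv", "sparky"),
                           condition_label = NA_character_,
                           field_1H = NA_real_, error_floor = 0.02) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  pk <- if (dialect == "sparky") parse_sparky_lines(lines, path)
        else parse_peak_tsv_lines(lines, path)
  if (nrow(pk)) {
    pk$height_error <- apply_error_floor(pk$height, pk$height_error,
                                         floor = error_floor)
    key <- paste(pk$residue_id, pk$atom_label)
    if (anyDuplicated(key))
      stop("duplicate (residue, atom) entries in ", path, ": ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  structure(pk, condition_label = condition_label, field_1H = field_1H,
            class = c("peak_table", "data.frame"))
}

parse_sparky_lines <- function(lines, path) {
  lines <- sub("#.*", "", lines)
  keep <- which(nzchar(trimws(lines)))
  out <- list()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (identical(tolower(f[1]), "assignment")) next  # header line
    if (length(f) < 4)
      stop("malformed Sparky line ", i, " in ", path, ": ", lines[i])
    m <- regmatches(f[1], regexec("^([A-Za-z])(\\d+)([A-Za-z0-9']*)-", f[1]))[[1]]
    if (length(m) == 0)
      stop("cannot parse assignment on line ", i, " in ", path, ": ", f[1])
    vals <- suppressWarnings(as.numeric(f[2:4]))
    if (anyNA(vals))
      stop("non-numeric field on line ", i, " in ", path, ": ", lines[i])
    atom <- if (nzchar(m[4])) m[4] else "N"
    err <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
    out[[length(out) + 1]] <- data.frame(
      residue_id = as.integer(m[3]), atom_label = atom,
      shift_w1 = vals[1], shift_w2 = vals[2], height = vals[3],
      height_error = err, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_peak_df())
  do.call(rbind, out)
}

parse_peak_tsv_lines <- function(lines, path) {
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1) return(empty_peak_df())
  df <- read.table(text = lines, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("residue", "atom", "shift_w1", "shift_w2", "height")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("peak TSV ", path, " lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$height))))
  if (length(bad))
    stop("malformed height on data line ", bad[1], " of ", path)
  data.frame(
    residue_id = as.integer(df$residue), atom_label = as.character(df$atom),
    shift_w1 = as.numeric(df$shift_w1), shift_w2 = as.numeric(df$shift_w2),
    height = as.numeric(df$height),
    height_error = if ("height_error" %in% names(df))
      as.numeric(df$height_error) else NA_real_,
    stringsAsFactors = FALSE)
}

empty_peak_df <- function() {
  data.frame(residue_id = integer(), atom_label = character(),
             shift_w1 = numeric(), shift_w2 = numeric(),
             height = numeric(), height_error = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a peak table as a headered TSV
#'
#' Inverse of [read_peak_list()] with `dialect = "tsv"`.
#'
#' @param peaks a `peak_table` or compatible data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  df <- data.frame(residue = peaks$residue_id, atom = peaks$atom_label,
                   shift_w1 = peaks$shift_w1, shift_w2 = peaks$shift_w2,
                   height = peaks$height, height_error = peaks$height_error)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relaxation series table
#'
#' The table has one `residue` column followed by one column per relaxation
#' delay, the delay in seconds encoded in the column name (e.g. `0`, `0.4`,
#' `1.4`; a trailing suffix such as `0.4_rep` marks replicate delays, which
#' are retained as separate points).  Missing cells (`NA` or empty) are
#' recorded as absent, distinguished from zero intensity.
#'
#' @param path TSV/CSV file; separator inferred from the extension
#'   (`.csv` means comma, anything else tab).
#' @param experiment experiment label attached to each series
#'   (`"R1"` or `"R1rho"`).
#' @param noise_fraction fractional intensity error assigned to each point
#'   (subject to the 2\% floor), used when the table carries no errors.
#' @return list of `relax_series` objects (one per residue), each a list
#'   with `residue_id`, `experiment`, `delays`, `intensities`,
#'   `intensity_errors`, `fittable`.
#' @export
read_series_table <- function(path, experiment = "R1", noise_fraction = 0.02) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"residue" %in% names(df))
    stop("series table ", path, " lacks a 'residue' column")
  delay_cols <- setdiff(names(df), "residue")
  delays <- suppressWarnings(as.numeric(sub("_.*$", "", delay_cols)))
  if (anyNA(delays))
    stop("cannot parse delay (seconds) from column name(s): ",
         paste(delay_cols[is.na(delays)], collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    y <- suppressWarnings(as.numeric(df[i, delay_cols]))
    ok <- is.finite(y)
    relax_series(residue_id = as.integer(df$residue[i]),
                 experiment = experiment,
                 delays = delays[ok], intensities = y[ok],
                 intensity_errors = apply_error_floor(
                   y[ok], noise_fraction * max(abs(y[ok]), 0)),
                 n_missing = sum(!ok))
  })
}

#' Construct a relaxation series
#'
#' @param residue_id integer residue number.
#' @param experiment `"R1"` or `"R1rho"`.
#' @param delays relaxation delays in seconds.
#' @param intensities measured peak heights.
#' @param intensity_errors per-point errors (all positive).
#' @param n_missing number of cells absent in the source table.
#' @return object of class `relax_series`; `$fittable` is `FALSE` when
#'   fewer than two distinct-delay points are available.
#' @export
relax_series <- function(residue_id, experiment, delays, intensities,
                         intensity_errors, n_missing = 0) {
  stopifnot(length(delays) == length(intensities),
            length(delays) == length(intensity_errors))
  if (length(intensity_errors) && any(intensity_errors <= 0))
    stop("intensity errors must all be positive")
  structure(list(residue_id = residue_id, experiment = experiment,
                 delays = as.numeric(delays),
                 intensities = as.numeric(intensities),
                 intensity_errors = as.numeric(intensity_errors),
                 n_missing = n_missing,
                 fittable = length(unique(delays)) >= 2),
            class = "relax_series")
}

#' Write a residue-to-value series table
#'
#' Inverse of [read_series_table()]: one row per residue, one column per
#' delay (replicate delays get `_rep<k>` suffixes so column names stay
#' unique).
#'
#' @param series list of `relax_series` sharing one delay grid.
#' @param path output path (TSV, or CSV if the extension is `.csv`).
#' @return `path`, invisibly.
#' @export
write_series_table <- function(series, path) {
  delays <- series[[1]]$delays
  nm <- as.character(delays)
  dup <- ave(seq_along(nm), nm, FUN = seq_along)
  nm[dup > 1] <- paste0(nm[dup > 1], "_rep", dup[dup > 1] - 1)
  m <- t(vapply(series, function(s) {
    stopifnot(isTRUE(all.equal(s$delays, delays)))
    s$intensities
  }, numeric(length(delays))))
  df <- data.frame(residue = vapply(series, `[[`, integer(1), "residue_id"), m,
                   check.names = FALSE)
  names(df) <- c("residue", nm)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-condition chemical shift table
#'
#' One row per residue/atom with columns `residue`, `atom`, `shift_H`,
#' `shift_X` (the heteronucleus shift, 15N or 13C).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_shift_table <- function(path) {
  stopifnot(file.exists(path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("residue", "atom", "shift_H", "shift_X")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("shift table ", path, " lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Write a per-residue attribute file for structure coloring
#'
#' Emits a Chimera-style attribute file (`attribute: name`, then one
#' `\\t:<residue>\\t<value>` line per residue, ordered by residue number).
#' Residues absent from `values` get no line: in structure renderings their
#' absence encodes "data unavailable".
#'
#' @param values named numeric vector or list, names = residue numbers.
#' @param path output path.
#' @param attribute_name attribute identifier (no spaces).
#' @return `path`, invisibly.
#' @export
write_residue_attributes <- function(values, path, attribute_name) {
  values <- unlist(values)
  stopifnot(length(values) > 0, !is.null(names(values)))
  res <- as.integer(names(values))
  o <- order(res)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("attribute: ", attribute_name),
               "match mode: 1-to-1", "recipient: residues"), con)
  writeLines(sprintf("\t:%d\t%.10g", res[o], as.numeric(values)[o]), con)
  invisible(path)
}

#' Read a per-residue attribute file
#'
#' Inverse of [write_residue_attributes()].
#'
#' @param path attribute file.
#' @return named numeric vector (names = residue numbers).
#' @export
read_residue_attributes <- function(path) {
  lines <- grep("^\t:", readLines(path, warn = FALSE), value = TRUE)
  parts <- strsplit(sub("^\t:", "", lines), "\t")
  setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
           vapply(parts, `[[`, character(1), 1))
}

#' Write a 2D intensity grid as CSV
#'
#' First column holds the direct-dimension (x) ppm values, the header row
#' the indirect-dimension (y) ppm values; cells are intensities.
#'
#' @param grid list with `x`, `y`, `z` (matrix `length(x)` by
#'   `length(y)`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(is.matrix(grid$z), nrow(grid$z) == length(grid$x),
            ncol(grid$z) == length(grid$y))
  df <- data.frame(x = grid$x, grid$z, check.names = FALSE)
  names(df) <- c("x", as.character(grid$y))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 2D intensity grid from CSV
#'
#' Inverse of [write_grid_csv()].
#'
#' @param path CSV file.
#' @return list with `x`, `y`, `z`.
#' @export
read_grid_csv <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",", check.names = FALSE)
  list(x = df$x, y = as.numeric(names(df)[-1]),
       z = unname(as.matrix(df[, -1, drop = FALSE])))
}

#' Read and validate a pipeline configuration
#'
#' YAML file holding the analysis defaults (Monte Carlo replicates, error
#' floor, CSP weights, threshold rule, seed) and per-stage experiment
#' metadata.  Unknown keys are preserved; known keys are validated.
#'
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipeline_config(cfg)
}

#' Build a pipeline configuration from a list
#'
#' @param x named list of overrides; see Details for defaults.
#' @details Defaults: `mc_replicates = 500`, `error_floor = 0.02`,
#'   `threshold_sigma_factor = 1.5`, `trim_fraction = 0.1`,
#'   `weights = csp_weights()`, `seed = 1`.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  cfg <- modifyList(list(
    mc_replicates = 500L, error_floor = 0.02,
    threshold_sigma_factor = 1.5, trim_fraction = 0.1,
    weights = list(W_N = 0.101, W_C = 0.251), seed = 1L), x)
  stopifnot(cfg$mc_replicates >= 2,
            cfg$trim_fraction >= 0, cfg$trim_fraction < 0.5,
            cfg$error_floor >= 0)
  cfg$weights <- csp_weights(cfg$weights$W_N, cfg$weights$W_C)
  class(cfg) <- "pipeline_config"
  cfg
}
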