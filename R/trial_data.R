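#' Construct and validate a multi-environment trial table
#'
#' A trial table holds one yield record per line-by-environment combination
#' of a multi-environment trial, together with the environment descriptors
#' (year, location, soil texture class).  It is the phenotypic input of
#' [reaction_norm()].
#'
#' @param df data frame with columns `line`, `env`, `year`, `location`,
#'   `soil`, `yield` (extra columns are kept but ignored downstream).
#' @param duplicates policy for repeated (line, env) rows: `"error"` rejects
#'   them, `"mean"` collapses them to their arithmetic mean yield (the usual
#'   entry-mean reduction of replicated field plots).
#'
#' @return A `data.frame` of class `trial_table`, validated so that each
#'   (line, env) pair occurs once, every environment maps to a single
#'   (year, location, soil) triple, and all yields are finite.
#' @export
trial_table <- function(df, duplicates = c("error", "mean")) {
  duplicates <- match.arg(duplicates)
  required <- c("line", "env", "year", "location", "soil", "yield")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$line <- as.character(df$line)
  df$env <- as.character(df$env)
  df$soil <- as.character(df$soil)
  df$location <- as.character(df$location)
  df$year <- as.integer(df$year)
  if (!is.numeric(df$yield)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$yield)))))
    stop("non-numeric yield value(s) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  df$yield <- as.numeric(df$yield)
  if (nrow(df) == 0L) stop("trial table has no records", call. = FALSE)
  if (any(!is.finite(df$yield))) {
    stop("non-finite yield value(s) at row(s): ",
         paste(utils::head(which(!is.finite(df$yield)), 5L), collapse = ", "),
         call. = FALSE)
  }

  key <- paste(df$line, df$env, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    if (duplicates == "error") {
      pair <- strsplit(dup[1L], "\r", fixed = TRUE)[[1L]]
      stop("duplicate record(s) for (line, environment) pair(s), e.g. (",
           pair[1L], ", ", pair[2L], "); use duplicates = \"mean\" to average",
           call. = FALSE)
    }
    agg <- tapply(df$yield, key, mean)
    first <- df[!duplicated(key), , drop = FALSE]
    first$yield <- as.numeric(agg[paste(first$line, first$env, sep = "\r")])
    df <- first
  }

  env_info <- unique(df[, c("env", "year", "location", "soil")])
  if (anyDuplicated(env_info$env)) {
    bad <- env_info$env[duplicated(env_info$env)][1L]
    stop("environment '", bad,
         "' maps to more than one (year, location, soil) combination",
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read a phenotype table from delimited text
#'
#' @param path path to a delimited text file with a header row.
#' @param column_map named character vector mapping the canonical roles
#'   `line`, `env`, `year`, `location`, `soil`, `yield` to column names in
#'   the file; defaults to identity.
#' @param sep field delimiter.
#' @param duplicates see [trial_table()].
#' @return a `trial_table`.
#' @export
read_trial_table <- function(path,
                             column_map = NULL,
                             sep = ",",
                             duplicates = c("error", "mean")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  roles <- c("line", "env", "year", "location", "soil", "yield")
  map <- stats::setNames(roles, roles)
  if (!is.null(column_map)) map[names(column_map)] <- unlist(column_map)
  absent <- map[!(map %in% names(raw))]
  if (length(absent) > 0L) {
    stop("mapped column(s) not present in file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- raw[, unname(map)]
  names(df) <- roles
  trial_table(df, duplicates = match.arg(duplicates))
}

#' Write a trial table as CSV
#' @param table a `trial_table`.
#' @param path output path.
#' @export
write_trial_table <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("line", "env", "year",
                                            "location", "soil", "yield")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct and validate a biallelic marker matrix
#'
#' @param codes numeric matrix (lines x markers) of allele-dosage codes in
#'   \{0, 1, 2\} with `NA` allowed; rownames are line identifiers.
#' @param max_missing maximum tolerated per-marker missing fraction
#'   (default 1 = no filter); markers above it are dropped.
#' @return matrix of class `marker_matrix`.
#' @export
marker_matrix <- function(codes, max_missing = 1) {
  codes <- as.matrix(codes)
  if (is.null(rownames(codes)) || anyDuplicated(rownames(codes))) {
    stop("marker matrix needs unique line identifiers as rownames",
         call. = FALSE)
  }
  if (ncol(codes) < 1L) stop("marker matrix has no markers", call. = FALSE)
  storage.mode(codes) <- "double"
  ok <- is.na(codes) | codes == 0 | codes == 1 | codes == 2
  if (!all(ok)) {
    idx <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("invalid marker code ", codes[idx[1L], idx[2L]], " at line '",
         rownames(codes)[idx[1L]], "', marker '",
         colnames(codes)[idx[2L]], "' (codes must be 0/1/2 or missing)",
         call. = FALSE)
  }
  if (max_missing < 1) {
    frac <- colMeans(is.na(codes))
    codes <- codes[, frac <= max_missing, drop = FALSE]
    if (ncol(codes) == 0L) {
      stop("no markers left after missing-fraction filter", call. = FALSE)
    }
  }
  class(codes) <- c("marker_matrix", class(codes))
  codes
}

#' Read a marker matrix from delimited text
#'
#' Expects a header row; the first column (`line`) carries line identifiers
#' and the remaining columns carry 0/1/2 codes with empty or `NA` cells for
#' missing calls.
#'
#' @inheritParams read_trial_table
#' @param max_missing see [marker_matrix()].
#' @return a `marker_matrix`.
#' @export
read_marker_matrix <- function(path, sep = ",", max_missing = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("marker file needs a line column plus markers",
                           call. = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated line identifier(s) in marker file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  codes <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(codes) <- "double"
  rownames(codes) <- ids
  marker_matrix(codes, max_missing = max_missing)
}

#' Write a marker matrix as CSV
#' @param markers a `marker_matrix`.
#' @param path output path.
#' @export
write_marker_matrix <- function(markers, path) {
  df <- data.frame(line = rownames(markers),
                   unclass(markers)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Incidence matrix connecting records to factor levels
#'
#' Builds the binary matrix Z that connects phenotype records to the levels
#' of a classification factor (line, environment, or soil class), i.e. the
#' Z_L, Z_E, Z_S matrices of the reaction-norm models.
#'
#' @param table a `trial_table`.
#' @param factor one of `"line"`, `"environment"`, `"soil"`.
#' @return binary matrix, rows in record order, one column per observed
#'   level (column names are the level labels); each row sums to 1.
#' @export
incidence <- function(table, factor = c("line", "environment", "soil")) {
  factor <- match.arg(factor)
  col <- switch(factor, line = "line", environment = "env", soil = "soil")
  values <- table[[col]]
  levels <- unique(values)
  Z <- matrix(0, nrow = length(values), ncol = length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(values), match(values, levels))] <- 1
  Z
}

#' Restrict a trial table and marker matrix to their common lines
#'
#' @param table a `trial_table`.
#' @param markers a `marker_matrix`.
#' @return list with components `table`, `markers` (both restricted to the
#'   line-ID intersection) and `report` (dropped lines and record counts).
#' @export
align_trial <- function(table, markers) {
  common <- intersect(unique(table$line), rownames(markers))
  if (length(common) == 0L) {
    stop("no line identifiers are shared between the trial table and the ",
         "marker matrix", call. = FALSE)
  }
  dropped_pheno <- setdiff(unique(table$line), common)
  dropped_geno <- setdiff(rownames(markers), common)
  keep <- table$line %in% common
  out_table <- table[keep, , drop = FALSE]
  rownames(out_table) <- NULL
  class(out_table) <- c("trial_table", "data.frame")
  out_markers <- markers[common, , drop = FALSE]
  class(out_markers) <- c("marker_matrix", "matrix", "array")
  list(table = out_table,
       markers = out_markers,
       report = list(n_lines = length(common),
                     n_records = nrow(out_table),
                     dropped_phenotyped_lines = dropped_pheno,
                     dropped_genotyped_lines = dropped_geno,
                     dropped_records = sum(!keep)))
}
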