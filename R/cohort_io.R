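#' Metabolite measurement matrix
#'
#' The central metabolome container: a samples x features numeric matrix in
#' which `NA` marks a value below the platform's detection limit (the
#' missingness mask), together with a scale tag recording where the matrix
#' sits in the preprocessing chain.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   row and column names. `NA` entries are missing (non-detected).
#' @param scale_tag one of `"raw"` (area counts, strictly positive where
#'   observed), `"log10"`, or `"standardized"`.
#' @return A `metab_matrix` object.
#' @export
metab_matrix <- function(values, scale_tag = c("raw", "log10", "standardized")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_vagmet("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_vagmet("`values` must carry sample (row) and feature (column) names")
  }
  check_unique(rownames(values), "sample identifiers")
  check_unique(colnames(values), "feature identifiers")
  if (scale_tag == "raw" && any(values <= 0, na.rm = TRUE)) {
    abort_vagmet("raw metabolite values must be strictly positive where observed")
  }
  structure(
    list(values = values, scale_tag = scale_tag),
    class = "metab_matrix"
  )
}

#' @export
print.metab_matrix <- function(x, ...) {
  cat(sprintf(
    "<metab_matrix> %d samples x %d features [%s], %.1f%% missing\n",
    nrow(x$values), ncol(x$values), x$scale_tag,
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.metab_matrix <- function(x) dim(x$values)

#' @rdname metab_matrix
#' @param x a `metab_matrix`.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.metab_matrix <- function(x) rownames(x$values)

#' @export
sample_ids.taxa_table <- function(x) rownames(x$rel_abundance)

#' @rdname metab_matrix
#' @export
feature_ids <- function(x) colnames(x$values)

#' @rdname metab_matrix
#' @export
missing_mask <- function(x) is.na(x$values)

# Missing-value tokens accepted in delimited files (vendor exports vary).
.missing_tokens <- c("", "na", "nan")

#' Read a metabolite matrix (and optional annotations) from delimited text
#'
#' Blank, `NA` and `NaN` cells (case-insensitive) parse as missing. Columns
#' named `display_name`, `named_flag`, `super_pathway`, `sub_pathway`,
#' `kegg_ids` or `platform_tag` in a features-in-rows file are split off as
#' feature annotations.
#'
#' @param path delimited text file; first column holds row identifiers.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`
#'   (common vendor layout).
#' @param sep field separator (tab default).
#' @return A list with elements `matrix` (a [metab_matrix()], `scale_tag =
#'   "raw"`) and `annotations` (a tibble, possibly empty).
#' @export
read_metabolite_matrix <- function(path,
                                   orientation = c("samples_in_rows", "features_in_rows"),
                                   sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort_vagmet(sprintf("file not found: %s", path))
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = character(0))
  if (ncol(raw) < 2L) abort_vagmet("expected at least one identifier and one data column")
  ids <- raw[[1L]]
  check_unique(ids, "row identifiers")
  body <- raw[, -1L, drop = FALSE]
  check_unique(colnames(body), "column identifiers")

  ann_names <- c("display_name", "named_flag", "super_pathway", "sub_pathway",
                 "kegg_ids", "platform_tag")
  ann_cols <- intersect(colnames(body), ann_names)
  annotations <- tibble(feature_id = character())
  if (orientation == "features_in_rows" && length(ann_cols) > 0L) {
    annotations <- as_tibble(body[, ann_cols, drop = FALSE])
    annotations$feature_id <- ids
    annotations <- annotations[, c("feature_id", ann_cols)]
    if ("named_flag" %in% ann_cols) {
      annotations$named_flag <- tolower(annotations$named_flag) %in% c("true", "t", "1", "yes")
    }
    body <- body[, setdiff(colnames(body), ann_cols), drop = FALSE]
  }

  vals <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                 dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- trimws(body[[j]])
    miss <- is.na(cell) | tolower(cell) %in% .missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !miss & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      abort_vagmet(sprintf(
        "non-numeric value '%s' at row %s, column %s", cell[i], ids[i], colnames(body)[j]
      ))
    }
    if (any(num < 0, na.rm = TRUE)) {
      i <- which(num < 0)[1L]
      abort_vagmet(sprintf(
        "negative raw value at row %s, column %s", ids[i], colnames(body)[j]
      ))
    }
    vals[, j] <- ifelse(miss, NA_real_, num)
  }
  if (orientation == "features_in_rows") vals <- t(vals)
  list(matrix = metab_matrix(vals, scale_tag = "raw"), annotations = annotations)
}

#' Write a metabolite matrix as delimited text
#'
#' @param mat a [metab_matrix()].
#' @param path output file.
#' @param digits significant digits for values.
#' @export
write_metabolite_matrix <- function(mat, path, digits = 10L) {
  stopifnot(inherits(mat, "metab_matrix"))
  v <- mat$values
  out <- data.frame(sample_id = rownames(v), check.names = FALSE)
  for (j in seq_len(ncol(v))) {
    out[[colnames(v)[j]]] <- ifelse(is.na(v[, j]), "", formatC(v[, j], digits = digits, format = "g"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Taxa relative-abundance table with optional 16S total load
#'
#' @param rel_abundance numeric samples x taxa matrix with names; rows are
#'   renormalized to sum to one.
#' @param total_load optional named per-sample positive vector of total 16S
#'   copy numbers (qPCR); samples without a value get `NA`.
#' @return A `taxa_table` object.
#' @export
taxa_table <- function(rel_abundance, total_load = NULL) {
  if (!is.matrix(rel_abundance) || !is.numeric(rel_abundance)) {
    abort_vagmet("`rel_abundance` must be a numeric matrix")
  }
  if (is.null(rownames(rel_abundance)) || is.null(colnames(rel_abundance))) {
    abort_vagmet("`rel_abundance` must carry sample and taxon names")
  }
  check_unique(rownames(rel_abundance), "sample identifiers")
  check_unique(colnames(rel_abundance), "taxon identifiers")
  if (any(rel_abundance < 0, na.rm = TRUE)) abort_vagmet("abundances must be non-negative")
  rs <- rowSums(rel_abundance, na.rm = TRUE)
  if (any(rs == 0)) {
    abort_vagmet(sprintf(
      "sample(s) with all-zero abundances: %s",
      paste(head(rownames(rel_abundance)[rs == 0], 5L), collapse = ", ")
    ))
  }
  rel <- sweep(rel_abundance, 1L, rs, "/")
  load <- rep(NA_real_, nrow(rel))
  names(load) <- rownames(rel)
  if (!is.null(total_load)) {
    if (is.null(names(total_load))) abort_vagmet("`total_load` must be named by sample_id")
    if (any(total_load <= 0, na.rm = TRUE)) abort_vagmet("total_load must be positive where present")
    hit <- intersect(names(total_load), rownames(rel))
    miss <- setdiff(names(total_load), rownames(rel))
    if (length(miss) > 0L) {
      warning(sprintf("total_load sample(s) not in table: %s",
                      paste(head(miss, 5L), collapse = ", ")))
    }
    load[hit] <- total_load[hit]
  }
  structure(list(rel_abundance = rel, total_load = load), class = "taxa_table")
}

#' @export
print.taxa_table <- function(x, ...) {
  cat(sprintf(
    "<taxa_table> %d samples x %d taxa, total load for %d samples\n",
    nrow(x$rel_abundance), ncol(x$rel_abundance), sum(!is.na(x$total_load))
  ))
  invisible(x)
}

#' Read a taxa table (and optional qPCR load file) from delimited text
#'
#' @param path samples x taxa abundance table, first column sample ids.
#' @param load_path optional two-column file (sample_id, total_load).
#' @param sep field separator.
#' @return A [taxa_table()]. Rows are renormalized; samples absent from the
#'   load file keep `NA` load.
#' @export
read_taxa_table <- function(path, load_path = NULL, sep = "\t") {
  if (!file.exists(path)) abort_vagmet(sprintf("file not found: %s", path))
  raw <- read.delim(path, sep = sep, check.names = FALSE)
  ids <- as.character(raw[[1L]])
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  load <- NULL
  if (!is.null(load_path)) {
    lf <- read.delim(load_path, sep = sep, check.names = FALSE)
    load <- as.numeric(lf[[2L]])
    names(load) <- as.character(lf[[1L]])
  }
  taxa_table(m, total_load = load)
}

#' Write a taxa table (and its load vector) as delimited text
#'
#' @param taxa a [taxa_table()].
#' @param path abundance output file.
#' @param load_path optional load output file.
#' @export
write_taxa_table <- function(taxa, path, load_path = NULL) {
  stopifnot(inherits(taxa, "taxa_table"))
  out <- data.frame(sample_id = rownames(taxa$rel_abundance), check.names = FALSE)
  out <- cbind(out, as.data.frame(taxa$rel_abundance, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(load_path)) {
    keep <- !is.na(taxa$total_load)
    write.table(
      data.frame(sample_id = names(taxa$total_load)[keep],
                 total_load = taxa$total_load[keep]),
      load_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}

#' Validate per-sample cohort metadata
#'
#' Checks the contract every analysis relies on: unique sample ids, outcome
#' consistent with gestational age at birth (sPTB before 37 weeks, term at
#' or after), and known factor levels.
#'
#' @param df data frame with columns `sample_id`, `outcome` (`"sPTB"` /
#'   `"TB"`), `gab_weeks`, `race` (`"Black"`, `"White"`, `"Other"`), and
#'   optionally `age_years`, `bmi`, `nulliparous`, `ptb_history`,
#'   `progesterone`, `batch`, `cst`.
#' @return The validated metadata as a tibble.
#' @export
cohort_metadata <- function(df) {
  need <- c("sample_id", "outcome", "gab_weeks", "race")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    abort_vagmet(sprintf("metadata lacks column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(df)
  check_unique(df$sample_id, "sample identifiers")
  if (!all(df$outcome %in% c("sPTB", "TB"))) abort_vagmet("outcome must be 'sPTB' or 'TB'")
  if (!all(df$race %in% c("Black", "White", "Other"))) {
    abort_vagmet("race must be one of 'Black', 'White', 'Other'")
  }
  bad <- (df$outcome == "sPTB" & df$gab_weeks >= 37) |
    (df$outcome == "TB" & df$gab_weeks < 37)
  if (any(bad)) {
    abort_vagmet(sprintf(
      "outcome/gab_weeks mismatch for sample(s): %s",
      paste(head(df$sample_id[bad], 5L), collapse = ", ")
    ))
  }
  df
}

#' Write a result collection to TSV or JSON
#'
#' Columns are written in their existing (deterministic) order; numeric
#' fields are rendered at fixed precision so that rereading reproduces the
#' table within that precision.
#'
#' @param x a data frame of results, or a list for JSON.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @param digits significant digits for numeric fields.
#' @export
write_report <- function(x, path, format = c("tsv", "json"), digits = 10L) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort_vagmet(sprintf("unknown report format: %s", format[1L]))
  })
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(path))
  }
  if (!is.data.frame(x)) abort_vagmet("TSV reports require a data frame")
  out <- as.data.frame(x)
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         formatC(out[[j]], digits = digits, format = "g"))
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#'
#' @param path file written with `format = "tsv"`.
#' @return A tibble.
#' @export
read_report <- function(path) {
  as_tibble(read.delim(path, sep = "\t", check.names = FALSE))
}
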