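#' Construct a feature table
#'
#' A feature table is the universal currency of the pipeline: a numeric
#' sample-by-variable matrix (samples in rows) with unique, case-sensitive
#' sample and variable identifiers and an optional per-variable class label
#' (e.g. "HMO", "SCFA", or a phylum for OTU tables).
#'
#' @param values numeric matrix, samples in rows.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(values)`.
#' @param variable_ids character vector of unique variable identifiers;
#'   defaults to `colnames(values)`.
#' @param variable_class optional character vector, one label per variable.
#' @return an object of class `feature_table`: the numeric matrix with
#'   dimnames set and, if given, a `variable_class` attribute.
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          variable_ids = colnames(values),
                          variable_class = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("feature table values must be numeric")
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(variable_ids))
    variable_ids <- sprintf("V%d", seq_len(ncol(values)))
  sample_ids <- trimws(as.character(sample_ids))
  variable_ids <- trimws(as.character(variable_ids))
  if (length(sample_ids) != nrow(values))
    stop("length of sample_ids does not match number of rows")
  if (length(variable_ids) != ncol(values))
    stop("length of variable_ids does not match number of columns")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id: ", dup[1])
  dup <- variable_ids[duplicated(variable_ids)]
  if (length(dup)) stop("duplicate variable id: ", dup[1])
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("missing value at (%s, %s)",
                 sample_ids[bad[1, 1]], variable_ids[bad[1, 2]]))
  }
  dimnames(values) <- list(sample_ids, variable_ids)
  if (!is.null(variable_class)) {
    if (length(variable_class) != ncol(values))
      stop("variable_class must have one entry per variable")
    variable_class <- as.character(variable_class)
    names(variable_class) <- variable_ids
    attr(values, "variable_class") <- variable_class
  }
  class(values) <- c("feature_table", class(values))
  values
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d variables\n", nrow(x), ncol(x)))
  cls <- attr(x, "variable_class")
  if (!is.null(cls)) {
    tab <- table(cls)
    cat("variable classes:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname feature_table
#' @param x object to test or coerce.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

ft_values <- function(x) {
  y <- unclass(x)
  attr(y, "variable_class") <- NULL
  y
}

#' Read a feature table from delimited text
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the extension;
#' `.tsv`/`.txt` are tab-separated, anything else comma-separated) into a
#' validated [feature_table]. QIIME-style OTU exports whose header line
#' starts with `#OTU ID` are accepted: the leading `#` is stripped.
#'
#' @param path path to the delimited file.
#' @param orientation `"samples-in-rows"` (default: first column holds sample
#'   ids, header holds variable ids) or `"samples-in-columns"` (transposed on
#'   read).
#' @return a [feature_table].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples-in-rows",
                                               "samples-in-columns")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  # QIIME/BIOM TSV exports prefix the header with '#OTU ID'
  if (startsWith(lines[1], "#")) lines[1] <- sub("^#\\s*", "", lines[1])
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          row.names = NULL, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  row_ids <- trimws(df[[1]])
  col_ids <- trimws(colnames(df)[-1])
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(!is.finite(num) | is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("missing value at (%s, %s)",
                 row_ids[bad[1, 1]], col_ids[bad[1, 2]]))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "samples-in-columns") num <- t(num)
  feature_table(num)
}

#' Write a feature table to delimited text
#'
#' Values are written at full double precision (15 significant digits), so a
#' write/read round trip is lossless to at least 12 significant digits.
#'
#' @param table a [feature_table].
#' @param path output path; `.tsv`/`.txt` write tab-separated, else CSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is_feature_table(table))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  m <- ft_values(table)
  df <- data.frame(sample_id = rownames(m),
                   format(m, digits = 15, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(m))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample metadata for the dyad design
#'
#' Builds and validates the per-sample metadata table: day after birth, the
#' consecutive-day block label, and the diet period. The diet period is a
#' deterministic function of the day block: blocks 103-108 and 145-147 are
#' exclusive breastfeeding (BM), 165-175 is breastfeeding plus fruit snack
#' (FBM), and 219-228 and 262-268 are weaning (W).
#'
#' @param sample_id character vector of sample ids.
#' @param day_after_birth integer days after birth.
#' @param day_block character block labels, e.g. `"103-108"`.
#' @return a `data.frame` of class `sample_metadata` with columns
#'   `sample_id`, `day_after_birth`, `day_block`, `diet_period`.
#' @export
sample_metadata <- function(sample_id, day_after_birth, day_block) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in metadata")
  day_block <- as.character(day_block)
  period <- diet_period_for_block(day_block)
  df <- data.frame(sample_id = sample_id,
                   day_after_birth = as.integer(day_after_birth),
                   day_block = day_block,
                   diet_period = period,
                   stringsAsFactors = FALSE)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Map day blocks to diet periods
#'
#' @param day_block character vector of block labels.
#' @return character vector of periods in `{"BM","FBM","W"}`.
#' @export
diet_period_for_block <- function(day_block) {
  map <- c("103-108" = "BM", "145-147" = "BM", "165-175" = "FBM",
           "219-228" = "W", "262-268" = "W")
  unknown <- setdiff(unique(day_block), names(map))
  if (length(unknown))
    stop("unknown day block: ", paste(unknown, collapse = ", "))
  unname(map[day_block])
}

#' Look up metadata rows for a feature table
#'
#' Every sample id in the table must resolve to exactly one metadata row.
#'
#' @param table a [feature_table].
#' @param metadata a [sample_metadata] data frame.
#' @return the metadata rows reordered to match the table's samples.
#' @export
match_metadata <- function(table, metadata) {
  idx <- match(rownames(table), metadata$sample_id)
  if (anyNA(idx)) {
    stop("no metadata for sample: ",
         rownames(table)[which(is.na(idx))[1]])
  }
  metadata[idx, , drop = FALSE]
}

#' Align feature tables on their common samples
#'
#' Restricts two or more tables to the intersection of their sample ids, in
#' the first table's sample order, so all blocks share an identical row
#' order. This is the required step before any multi-block fit: here the
#' metabolome covers all 32 stool samples while 16S metagenomics covers only
#' 25 of them.
#'
#' @param tables list of [feature_table] objects (at least two).
#' @return an object of class `block_set`: a list with elements `blocks`
#'   (the aligned tables), `common_samples`, and `dropped` (per-block list of
#'   sample ids removed).
#' @export
align_blocks <- function(tables) {
  if (!is.list(tables) || length(tables) < 2)
    stop("align_blocks needs a list of at least two feature tables")
  stopifnot(all(vapply(tables, is_feature_table, logical(1))))
  common <- Reduce(intersect, lapply(tables, rownames))
  if (!length(common)) stop("no samples common to all blocks")
  common <- rownames(tables[[1]])[rownames(tables[[1]]) %in% common]
  dropped <- lapply(tables, function(t) setdiff(rownames(t), common))
  blocks <- lapply(tables, function(t) {
    out <- t[common, , drop = FALSE]
    feature_table(out, variable_class = attr(t, "variable_class"))
  })
  if (is.null(names(blocks)))
    names(blocks) <- paste0("block", seq_along(blocks))
  structure(list(blocks = blocks, common_samples = common,
                 dropped = dropped),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("block_set: %d blocks on %d common samples\n",
              length(x$blocks), length(x$common_samples)))
  for (i in seq_along(x$blocks)) {
    cat(sprintf("  %s: %d variables, %d samples dropped\n",
                names(x$blocks)[i], ncol(x$blocks[[i]]),
                length(x$dropped[[i]])))
  }
  invisible(x)
}

#' Write an analysis result bundle to disk
#'
#' Serializes any of the pipeline's result objects to a directory of flat
#' CSV files plus a `manifest.json` recording parameters, seed and package
#' version. A generic with methods for DCV, permutation, ComDim, PCA and
#' network results; unknown objects fall back to writing any matrix or
#' data-frame elements they contain.
#'
#' @param results a result object from a pipeline stage.
#' @param dir output directory, created if missing.
#' @param extra named list merged into the manifest (e.g. the seed used).
#' @return character vector of files written (the manifest last), invisibly.
#' @export
write_result_bundle <- function(results, dir, extra = list()) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || !dir.exists(dir)) stop("cannot create directory: ", dir)
  files <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    if (is.matrix(obj)) {
      df <- data.frame(id = rownames(obj) %||% seq_len(nrow(obj)),
                       format(obj, digits = 15, trim = TRUE),
                       check.names = FALSE)
      colnames(df) <- c("id", colnames(obj) %||%
                          paste0("V", seq_len(ncol(obj))))
      utils::write.table(df, p, sep = ",", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.csv(obj, p, row.names = FALSE, quote = FALSE)
    }
    files <<- c(files, p)
  }
  tabs <- result_tables(results)
  for (nm in names(tabs)) wr(tabs[[nm]], paste0(nm, ".csv"))
  manifest <- c(list(class = class(results)[1],
                     package = "dyadomics",
                     version = as.character(utils::packageVersion("dyadomics")),
                     written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     files = basename(files),
                     parameters = result_parameters(results)),
                extra)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(files, mp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flat tables to serialize for each result class; internal dispatch.
result_tables <- function(x) UseMethod("result_tables")

#' @export
result_tables.default <- function(x) {
  if (is.matrix(x)) return(list(values = x))
  if (is.data.frame(x)) return(list(values = x))
  if (is.list(x)) {
    keep <- Filter(function(e) is.matrix(e) || is.data.frame(e), x)
    return(keep)
  }
  list(values = data.frame(value = unlist(x)))
}

result_parameters <- function(x) UseMethod("result_parameters")

#' @export
result_parameters.default <- function(x) {
  p <- attr(x, "parameters")
  if (is.null(p) && is.list(x) && !is.null(x$config)) p <- x$config
  p %||% list()
}
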