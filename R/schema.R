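#' Clinical feature schemas
#'
#' A schema describes the coded clinical features of an ACS dataset: each
#' feature has an integer label, a name, a measurement scale
#' (\code{"nominal"}, \code{"ordinal"} or \code{"ratio"}) and, for the
#' categorical scales, the ordered set of allowed integer codes. Ratio
#' features carry a target range (default \code{[-1, 1]}) into which they are
#' mapped by min-max normalization. The bundled default schema holds the 40
#' working features of the ACS study (sex, age, history items, chronic
#' medication, presenting symptom, vital signs, cardiac markers, ECG
#' annotations, ...) together with the four outcome classes STEMI, NSTEMI,
#' UA and Other.
#'
#' @param features list of feature specifications; each element is a list with
#'   entries \code{label} (unique integer), \code{name}, \code{scale}, and
#'   \code{codes} (categorical scales) or \code{range} (ratio scale,
#'   default \code{c(-1, 1)}).
#' @param n_classes number of outcome classes.
#' @param class_names character vector of length \code{n_classes}.
#' @return An object of class \code{"acs_schema"}.
#' @seealso [read_schema()], [default_schema()], [read_acs()]
#' @export
acs_schema <- function(features, n_classes = 4L,
                       class_names = c("STEMI", "NSTEMI", "UA", "Other")) {
  if (!is.list(features) || length(features) == 0L)
    stop("schema error: feature list is empty")
  n_classes <- as.integer(n_classes)
  if (length(class_names) != n_classes)
    stop("schema error: 'class_names' must have length 'n_classes'")
  feats <- lapply(features, normalize_feature_spec)
  labels <- vapply(feats, function(f) f$label, integer(1))
  if (anyDuplicated(labels)) {
    dup <- labels[duplicated(labels)][1L]
    stop(sprintf("schema error: duplicate feature label %d", dup))
  }
  structure(list(features = feats, n_classes = n_classes,
                 class_names = as.character(class_names)),
            class = "acs_schema")
}

normalize_feature_spec <- function(f) {
  if (is.null(f$label) || is.null(f$name) || is.null(f$scale))
    stop("schema error: each feature needs 'label', 'name' and 'scale'")
  scale <- as.character(f$scale)
  if (!scale %in% c("nominal", "ordinal", "ratio"))
    stop(sprintf("schema error: unknown scale '%s' for feature '%s'",
                 scale, f$name))
  spec <- list(label = as.integer(f$label), name = as.character(f$name),
               scale = scale)
  if (scale %in% c("nominal", "ordinal")) {
    if (is.null(f$codes) || length(f$codes) == 0L)
      stop(sprintf("schema error: categorical feature '%s' declares no codes",
                   f$name))
    spec$codes <- as.integer(unlist(f$codes))
    spec$range <- NULL
  } else {
    spec$codes <- NULL
    spec$range <- if (is.null(f$range)) c(-1, 1) else as.numeric(unlist(f$range))
    if (length(spec$range) != 2L || spec$range[1] >= spec$range[2])
      stop(sprintf("schema error: invalid target range for feature '%s'",
                   f$name))
  }
  spec
}

#' Read a feature schema from a YAML config
#'
#' @param path path to a YAML file with top-level entries \code{n_classes},
#'   \code{class_names} and \code{features} (see the bundled
#'   \code{acs_schema.yaml} for the format).
#' @param text YAML given as a string instead of a file.
#' @return An \code{"acs_schema"} object.
#' @export
read_schema <- function(path = NULL, text = NULL) {
  cfg <- if (!is.null(text)) yaml::yaml.load(text) else yaml::read_yaml(path)
  if (is.null(cfg$features)) stop("schema error: config has no 'features' entry")
  acs_schema(cfg$features,
             n_classes = if (is.null(cfg$n_classes)) 4L else cfg$n_classes,
             class_names = if (is.null(cfg$class_names))
               c("STEMI", "NSTEMI", "UA", "Other") else cfg$class_names)
}

#' The bundled 40-feature ACS schema
#'
#' @return The default \code{"acs_schema"} shipped with the package: 40 coded
#'   clinical features and the four classes STEMI, NSTEMI, UA, Other.
#' @export
default_schema <- function() {
  read_schema(system.file("extdata", "acs_schema.yaml", package = "acsclass",
                          mustWork = TRUE))
}

#' @export
print.acs_schema <- function(x, ...) {
  cat(sprintf("ACS feature schema: %d features, %d classes (%s)\n",
              length(x$features), x$n_classes,
              paste(x$class_names, collapse = ", ")))
  tab <- table(vapply(x$features, function(f) f$scale, character(1)))
  cat("  scales:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

schema_labels <- function(schema)
  vapply(schema$features, function(f) f$label, integer(1))

schema_names <- function(schema)
  vapply(schema$features, function(f) f$name, character(1))

schema_scales <- function(schema)
  vapply(schema$features, function(f) f$scale, character(1))

#' Labels of the ratio-scaled features of a schema
#' @param schema an \code{"acs_schema"}.
#' @return integer vector of feature labels.
#' @export
ratio_features <- function(schema)
  schema_labels(schema)[schema_scales(schema) == "ratio"]

feature_by_label <- function(schema, label) {
  i <- match(label, schema_labels(schema))
  if (is.na(i)) stop(sprintf("schema error: no feature with label %d", label))
  schema$features[[i]]
}

#' Labeled ACS datasets
#'
#' An \code{acs_dataset} couples an n-by-p numeric matrix of coded feature
#' values (columns in schema order) with an integer class label per row and
#' the schema that gives the columns their meaning. Categorical values must
#' be members of the feature's code set; labels must lie in
#' \code{1..n_classes}.
#'
#' @param values numeric matrix (rows = patients, columns = schema features).
#' @param labels integer vector of class labels in \code{1..n_classes}.
#' @param schema an \code{"acs_schema"}.
#' @param check validate the categorical codes and labels (default TRUE).
#' @return An object of class \code{"acs_dataset"}.
#' @export
acs_dataset <- function(values, labels, schema, check = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.integer(labels)
  if (nrow(values) == 0L) stop("dataset error: no rows")
  if (nrow(values) != length(labels))
    stop("dataset error: number of rows and labels differ")
  if (ncol(values) != length(schema$features))
    stop("dataset error: column count does not match schema")
  colnames(values) <- schema_names(schema)
  if (check) {
    if (anyNA(values) || anyNA(labels))
      stop("dataset error: missing values are not allowed")
    bad <- which(labels < 1L | labels > schema$n_classes)
    if (length(bad))
      stop(sprintf("dataset error: row %d has class label %d outside 1..%d",
                   bad[1L], labels[bad[1L]], schema$n_classes))
    for (j in seq_along(schema$features)) {
      f <- schema$features[[j]]
      if (f$scale == "ratio") next
      bad <- which(!(values[, j] %in% f$codes))
      if (length(bad))
        stop(sprintf(
          "dataset error: row %d, feature '%s': value %g is not an allowed code",
          bad[1L], f$name, values[bad[1L], j]))
    }
  }
  structure(list(values = values, labels = labels, schema = schema),
            class = "acs_dataset")
}

#' @export
print.acs_dataset <- function(x, ...) {
  cat(sprintf("ACS dataset: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  counts <- tabulate(x$labels, x$schema$n_classes)
  cat("  classes:",
      paste(sprintf("%s=%d", x$schema$class_names, counts), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.acs_dataset <- function(x) dim(x$values)

#' Subset rows and/or features of a dataset
#'
#' @param data an \code{"acs_dataset"}.
#' @param rows row indices (default all).
#' @param features feature labels to keep (default all). The schema of the
#'   result is restricted accordingly.
#' @return An \code{"acs_dataset"}.
#' @export
subset_acs <- function(data, rows = NULL, features = NULL) {
  vals <- data$values
  labs <- data$labels
  schema <- data$schema
  if (!is.null(rows)) {
    vals <- vals[rows, , drop = FALSE]
    labs <- labs[rows]
  }
  if (!is.null(features)) {
    idx <- match(features, schema_labels(schema))
    if (anyNA(features) || anyNA(idx))
      stop("dataset error: unknown feature label in subset")
    vals <- vals[, idx, drop = FALSE]
    schema <- acs_schema(schema$features[idx], schema$n_classes,
                         schema$class_names)
  }
  acs_dataset(vals, labs, schema, check = FALSE)
}

#' Read / write ACS datasets as delimited text
#'
#' The on-disk format is one header row with the schema feature names plus a
#' final \code{class} column, followed by one row per patient. Comma and tab
#' separators are supported. Values are validated against the schema; any
#' out-of-code categorical value, missing cell or out-of-range label raises a
#' row-indexed error.
#'
#' @param path file path; for \code{read_acs}, alternatively use \code{text}.
#' @param text dataset given as a string.
#' @param schema an \code{"acs_schema"}.
#' @param sep field separator; \code{NULL} (default) auto-detects comma vs tab
#'   from the header line.
#' @return \code{read_acs}: an \code{"acs_dataset"}. \code{write_acs}:
#'   invisibly, the path.
#' @export
read_acs <- function(path = NULL, schema, text = NULL, sep = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("dataset error: no data rows")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  want <- c(schema_names(schema), "class")
  if (!setequal(names(df), want) || length(names(df)) != length(want))
    stop("dataset error: header does not match schema feature names + 'class'")
  df <- df[, want]
  vals <- as.matrix(df[, seq_len(ncol(df) - 1L), drop = FALSE])
  if (!is.numeric(vals)) stop("dataset error: non-numeric cell in table")
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L]
    stop(sprintf("dataset error: row %d has a missing value", bad))
  }
  acs_dataset(vals, df$class, schema)
}

#' @rdname read_acs
#' @param data an \code{"acs_dataset"}.
#' @export
write_acs <- function(data, path, sep = ",") {
  df <- as.data.frame(data$values, check.names = FALSE)
  df$class <- data$labels
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalization of ratio features
#'
#' \code{fit_normalizer} records the observed minimum and maximum of each
#' requested ratio feature; \code{apply_normalizer} maps every covered value
#' affinely so that the fitted minimum lands on the lower end of the
#' feature's target range and the fitted maximum on the upper end (by default
#' \code{[-1, 1]}). Values outside the fitted range map outside the target
#' range: the transform is affine, never clipped, so it preserves the order
#' and relative spacing of the raw measurements. A constant feature is
#' flagged degenerate and maps to the range midpoint (0 for \code{[-1, 1]})
#' with a warning at fit time.
#'
#' @param data an \code{"acs_dataset"}.
#' @param features labels of the features to cover; default all ratio
#'   features of the schema.
#' @return \code{fit_normalizer}: an \code{"acs_normalizer"} (data frame of
#'   label, min, max, degenerate flag). \code{apply_normalizer}: the dataset
#'   with covered columns transformed.
#' @export
fit_normalizer <- function(data, features = ratio_features(data$schema)) {
  features <- as.integer(features)
  if (length(features) == 0L) {
    st <- data.frame(label = integer(0), min = numeric(0), max = numeric(0),
                     degenerate = logical(0))
    return(structure(st, class = c("acs_normalizer", "data.frame")))
  }
  scales <- schema_scales(data$schema)
  idx <- match(features, schema_labels(data$schema))
  if (anyNA(idx)) stop("normalizer error: feature label not in schema")
  if (any(scales[idx] != "ratio"))
    stop("normalizer error: only ratio features can be normalized")
  mins <- apply(data$values[, idx, drop = FALSE], 2, min)
  maxs <- apply(data$values[, idx, drop = FALSE], 2, max)
  degen <- maxs <= mins
  if (any(degen))
    warning(sprintf("constant ratio feature(s) %s: normalized to range midpoint",
                    paste(features[degen], collapse = ", ")))
  st <- data.frame(label = features, min = mins, max = maxs,
                   degenerate = degen, row.names = NULL)
  structure(st, class = c("acs_normalizer", "data.frame"))
}

#' @rdname fit_normalizer
#' @param stats an \code{"acs_normalizer"} from [fit_normalizer()].
#' @export
apply_normalizer <- function(data, stats) {
  if (nrow(stats) == 0L) return(data)
  idx <- match(stats$label, schema_labels(data$schema))
  if (anyNA(idx)) stop("normalizer error: stats cover a feature not in data")
  vals <- data$values
  for (r in seq_len(nrow(stats))) {
    j <- idx[r]
    f <- data$schema$features[[j]]
    rng <- if (is.null(f$range)) c(-1, 1) else f$range
    if (stats$degenerate[r]) {
      vals[, j] <- mean(rng)
    } else {
      span <- stats$max[r] - stats$min[r]
      vals[, j] <- rng[1] + (vals[, j] - stats$min[r]) / span * (rng[2] - rng[1])
    }
  }
  acs_dataset(vals, data$labels, data$schema, check = FALSE)
}

#' @export
print.acs_normalizer <- function(x, ...) {
  cat(sprintf("min-max normalizer for %d ratio feature(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}
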