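#' Construct a labelled samples-by-features matrix
#'
#' The basic container used throughout the package: a numeric matrix with one
#' row per sample and one column per feature, plus a class label per sample.
#' All downstream stages (normalization, partitioning, feature selection, the
#' ensemble) operate on this object.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param labels Vector of class labels, one per row; coerced to factor.
#' @param feature_names Unique feature names; defaults to existing column
#'   names or `f1..fd`.
#' @param sample_ids Unique sample identifiers; defaults to existing row
#'   names or `s1..sn`.
#' @return An object of class `data_matrix` with elements `values`,
#'   `labels`, `feature_names`, `sample_ids`.
#' @export
data_matrix <- function(values, labels, feature_names = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("values must be finite with no missing entries")
  }
  if (length(labels) != nrow(values)) {
    stop("labels length (", length(labels), ") != number of rows (", nrow(values), ")")
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(values)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (anyDuplicated(feature_names)) stop("duplicate feature names")
  if (length(feature_names) != ncol(values)) stop("feature_names length mismatch")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, labels = factor(labels),
         feature_names = feature_names, sample_ids = sample_ids),
    class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat("data_matrix: ", nrow(x$values), " samples x ", ncol(x$values),
      " features, ", nlevels(x$labels), " classes (",
      paste(levels(x$labels), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.data_matrix <- function(x) dim(x$values)

#' Subset a data_matrix by samples and/or features
#'
#' @param x A `data_matrix`.
#' @param i Row (sample) indices.
#' @param j Column (feature) indices.
#' @param ... Unused.
#' @return A `data_matrix` restricted to the requested rows/columns.
#' @export
`[.data_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  data_matrix(x$values[i, j, drop = FALSE], x$labels[i],
              feature_names = x$feature_names[j], sample_ids = x$sample_ids[i])
}

#' Read a delimited expression matrix with a label column
#'
#' Expects one header row of feature names plus a designated label column.
#' Every non-label cell must parse as a finite number; missing values are
#' rejected by default or replaced by the per-feature median when
#' `impute = "median"`.
#'
#' @param path Path to a CSV/TSV file (gzip accepted via standard R
#'   connections).
#' @param label_column Name of the label column.
#' @param delimiter Field delimiter, default ",".
#' @param impute `"reject"` (default) errors on any missing/non-numeric cell;
#'   `"median"` replaces missing cells by the feature median.
#' @return A [data_matrix].
#' @export
read_matrix <- function(path, label_column = "class", delimiter = ",",
                        impute = c("reject", "median")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "")
  if (!label_column %in% names(df)) {
    stop("configuration error: label column '", label_column, "' not present")
  }
  labels <- df[[label_column]]
  feats <- df[setdiff(names(df), label_column)]
  if (anyDuplicated(names(feats))) {
    stop("parse error: duplicate feature names: ",
         paste(unique(names(feats)[duplicated(names(feats))]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow(df), length(feats))
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop("parse error: non-numeric value '", col[bad[1]], "' at row ",
           bad[1], ", column '", names(feats)[j], "'")
    }
    vals[, j] <- num
  }
  if (anyNA(vals)) {
    if (impute == "reject") {
      idx <- which(is.na(vals), arr.ind = TRUE)[1, ]
      stop("parse error: missing value at row ", idx[1], ", column '",
           names(feats)[idx[2]], "'")
    }
    for (j in seq_len(ncol(vals))) {
      nas <- is.na(vals[, j])
      if (any(nas)) vals[nas, j] <- stats::median(vals[!nas, j])
    }
  }
  rid <- if (!is.null(rownames(df)) && !identical(rownames(df), as.character(seq_len(nrow(df)))))
    rownames(df) else paste0("s", seq_len(nrow(df)))
  message("read ", nrow(vals), " samples x ", ncol(vals), " features from ", path)
  data_matrix(vals, labels, feature_names = names(feats), sample_ids = rid)
}

#' Write a data_matrix back to delimited text
#'
#' @param x A [data_matrix].
#' @param path Output path.
#' @param label_column Name for the label column.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, label_column = "class", delimiter = ",") {
  df <- as.data.frame(x$values, check.names = FALSE)
  df[[label_column]] <- as.character(x$labels)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Fit per-feature min-max normalization parameters
#'
#' Records the column minima and maxima of the supplied (training) matrix so
#' the same affine map can later be applied to held-out data without leaking
#' test-set information.
#'
#' @param train A [data_matrix] or numeric matrix.
#' @return Object of class `minmax_params` with `min` and `max` vectors.
#' @export
fit_minmax <- function(train) {
  X <- if (inherits(train, "data_matrix")) train$values else as.matrix(train)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("empty matrix")
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "minmax_params")
}

#' Apply fitted min-max normalization
#'
#' Maps each cell to (x - min) / (max - min) using the fitted training
#' extrema. Constant features map to 0; values outside the training range
#' (possible on held-out data) are clipped to [0, 1].
#'
#' @param params A `minmax_params` object from [fit_minmax()].
#' @param X A [data_matrix] or numeric matrix with matching feature count.
#' @return Same type as `X`, normalized.
#' @export
apply_minmax <- function(params, X) {
  is_dm <- inherits(X, "data_matrix")
  V <- if (is_dm) X$values else as.matrix(X)
  if (ncol(V) != length(params$min)) {
    stop("dimension mismatch: ", ncol(V), " columns vs ",
         length(params$min), " fitted features")
  }
  rng <- params$max - params$min
  out <- sweep(V, 2, params$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (is_dm) {
    data_matrix(out, X$labels, feature_names = X$feature_names,
                sample_ids = X$sample_ids)
  } else {
    dimnames(out) <- dimnames(V)
    out
  }
}

#' Save / load normalization parameters as JSON
#'
#' @param params A `minmax_params` object.
#' @param path File path.
#' @return `path` (save) or the restored `minmax_params` (load).
#' @export
save_minmax <- function(params, path) {
  jsonlite::write_json(list(min = unname(params$min), max = unname(params$max)),
                       path, digits = NA)
  invisible(path)
}

#' @rdname save_minmax
#' @export
load_minmax <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(min = obj$min, max = obj$max), class = "minmax_params")
}

#' Stratified train/test split
#'
#' Splits sample indices so that each class contributes approximately
#' `ratio` of its members to the training side (rounded to nearest, with at
#' least one sample per class on each side). Deterministic given `seed`.
#'
#' @param X A [data_matrix] (or a factor of labels).
#' @param ratio Training fraction, in (0, 1).
#' @param seed Integer seed.
#' @return Object of class `split_spec` with integer vectors `train` and
#'   `test`, plus `ratio` and `seed`.
#' @export
stratified_split <- function(X, ratio = 0.8, seed = 1L) {
  labels <- if (inherits(X, "data_matrix")) X$labels else factor(X)
  if (ratio <= 0 || ratio >= 1) stop("ratio must be strictly between 0 and 1")
  counts <- table(labels)
  if (any(counts < 2)) {
    stop("class(es) with a single sample: ",
         paste(names(counts)[counts < 2], collapse = ", "),
         "; merge or remove them before splitting")
  }
  rng <- local_rng(seed)
  train <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    n_tr <- round(ratio * length(idx))
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train <- c(train, rng$sample(idx, n_tr))
  }
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_along(labels), train),
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_spec")
}

# Seeded RNG scoped to a closure so package functions never disturb the
# caller's .Random.seed stream ordering guarantees beyond base semantics.
local_rng <- function(seed) {
  env <- new.env()
  run <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed) %% .Machine$integer.max)
    if (!is.null(env$state)) assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    sample = function(x, size = length(x), replace = FALSE)
      run(sample(x, size, replace = replace)),
    runif = function(n, min = 0, max = 1) run(stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) run(stats::rnorm(n, mean, sd)),
    with = function(code) run(force(code))
  )
}

# Derive a child seed from a master seed and a stage tag; stays below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}
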