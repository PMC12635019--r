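# Readers/writers for clock coefficient tables, beta matrices and sample
# metadata, plus clock application.
#
# Conventions: beta matrices are stored internally as samples x CpGs; clock
# tables are two-column delimited files (cpg, coefficient) with an optional
# "(Intercept)" row; metadata files carry sample_id, age, status.

#' Construct a clock model
#'
#' A clock model is a named sparse linear predictor: an intercept plus a
#' CpG -> coefficient map. Predictions are `intercept + sum_j w_j * beta_ij`.
#'
#' @param name Model label (non-empty string).
#' @param intercept Intercept in response units (e.g. years).
#' @param coefficients Named numeric vector, names are CpG ids. Zero entries
#'   are dropped.
#' @param response_proxy Free-text description of the response variable the
#'   model was trained on (default "chronological age (years)").
#' @return An object of class `clock_model` with fields `name`, `intercept`,
#'   `coefficients`, `response_proxy`, `n_features`.
#' @examples
#' clock_model("toy", 30, c(cg1 = 0.5, cg2 = -0.2))
#' @export
clock_model <- function(name, intercept, coefficients,
                        response_proxy = "chronological age (years)") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("clock model name must be a non-empty string")
  }
  if (!is_scalar_num(intercept)) stop_input("intercept must be a finite number")
  if (!is.numeric(coefficients) || is.null(names(coefficients)) ||
      any(!nzchar(names(coefficients)))) {
    stop_input("coefficients must be a named numeric vector")
  }
  dup <- names(coefficients)[duplicated(names(coefficients))]
  if (length(dup)) stop_input("duplicate CpG id in coefficients: %s", dup[1L])
  if (any(!is.finite(coefficients))) stop_input("non-finite coefficient")
  coefficients <- coefficients[coefficients != 0]
  structure(
    list(name = name, intercept = intercept,
         coefficients = coefficients, response_proxy = response_proxy,
         n_features = length(coefficients)),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %s: %d features, intercept %.4g, response: %s\n",
              x$name, x$n_features, x$intercept, x$response_proxy))
  invisible(x)
}

#' Construct a beta-value matrix
#'
#' Wraps a samples x CpGs numeric matrix of methylation beta values
#' (methylated fraction per CpG, in \[0,1\]) with validated identifiers.
#'
#' @param values Numeric matrix, samples in rows, CpGs in columns.
#' @param sample_ids,cpg_ids Optional identifiers; taken from `dimnames` when
#'   absent.
#' @param strict When `TRUE` (default) values outside \[0,1\] are an error;
#'   otherwise they are clipped with a warning. `NA` values are allowed.
#' @return A numeric matrix of class `beta_matrix`.
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        cpg_ids = colnames(values), strict = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  if (is.null(cpg_ids)) cpg_ids <- paste0("cg", seq_len(ncol(values)))
  if (anyDuplicated(sample_ids)) stop_input("duplicate sample ids")
  if (anyDuplicated(cpg_ids)) stop_input("duplicate CpG ids")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    if (strict) {
      stop_input("beta value out of [0,1] at sample '%s', CpG '%s' (%.4g)",
                 sample_ids[bad[1L, 1L]], cpg_ids[bad[1L, 2L]],
                 values[bad[1L, , drop = FALSE]])
    }
    warning(sprintf("%d beta value(s) outside [0,1] clipped", nrow(bad)))
    values <- clip01(values)
  }
  rownames(values) <- sample_ids
  if (ncol(values) > 0L) colnames(values) <- cpg_ids
  class(values) <- c("beta_matrix", "matrix", "array")
  values
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d samples x %d CpGs\n", nrow(x), ncol(x)))
  invisible(x)
}

# Sniff the delimiter of a header line: tab wins if present, else comma.
sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a clock coefficient table
#'
#' Expects a delimited file (tab or comma, auto-sniffed) with a CpG-id column
#' and a coefficient column; an optional row keyed `(Intercept)` provides the
#' intercept. Zero-coefficient rows are dropped with a message.
#'
#' @param path File path.
#' @param name Model name; defaults to the file base name.
#' @param sep Field separator; `NULL` (default) auto-sniffs from the header.
#' @param response_proxy Passed to [clock_model()].
#' @return A [clock_model()].
#' @export
read_clock_table <- function(path, name = NULL, sep = NULL,
                             response_proxy = "chronological age (years)") {
  if (!file.exists(path)) stop_input("clock table not found: %s", path)
  sep <- sep %||% sniff_sep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "", strip.white = TRUE)
  if (ncol(tab) < 2L) stop_input("clock table %s needs >= 2 columns", path)
  ids <- tab[[1L]]
  coef_chr <- tab[[2L]]
  coefs <- suppressWarnings(as.numeric(coef_chr))
  bad <- which(is.na(coefs) & !is.na(coef_chr))
  if (length(bad)) {
    stop_input("non-numeric coefficient '%s' at data row %d of %s",
               coef_chr[bad[1L]], bad[1L], path)
  }
  is_int <- ids %in% c("(Intercept)", "Intercept", "intercept")
  if (sum(is_int) > 1L) stop_input("multiple intercept rows in %s", path)
  dup <- ids[!is_int][duplicated(ids[!is_int])]
  if (length(dup)) stop_input("duplicate CpG id '%s' in %s", dup[1L], path)
  intercept <- if (any(is_int)) coefs[is_int] else {
    warning(sprintf("no intercept row in %s; intercept set to 0", path))
    0
  }
  ids <- ids[!is_int]; coefs <- coefs[!is_int]
  n_zero <- sum(coefs == 0)
  if (n_zero) message(sprintf("dropped %d zero-coefficient row(s)", n_zero))
  clock_model(name %||% sub("\\.[^.]*$", "", basename(path)),
              intercept, stats::setNames(coefs, ids),
              response_proxy = response_proxy)
}

#' Write a clock coefficient table
#'
#' @param model A [clock_model()].
#' @param path Output path; tab-separated with an `(Intercept)` row.
#' @return `path`, invisibly.
#' @export
write_clock_table <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  df <- data.frame(
    cpg = c(names(model$coefficients), "(Intercept)"),
    coefficient = fmt_num(c(unname(model$coefficients), model$intercept)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a beta-value matrix from delimited text
#'
#' GEO series-matrix bodies store CpGs in rows and samples in columns; other
#' exports use the transpose. The orientation is declared, or auto-detected
#' from row ids matching the Illumina probe-name pattern (`cg\\d+`/`ch.\\d+`).
#'
#' @param path File path; tab or comma separated, first column ids, first row
#'   header of ids.
#' @param orientation One of `"cpgs-in-rows"`, `"samples-in-rows"`, `"auto"`.
#' @param strict Reject out-of-range values (default `TRUE`); otherwise clip
#'   with a warning.
#' @return A [beta_matrix()] in samples x CpGs orientation.
#' @export
read_beta_matrix <- function(path,
                             orientation = c("cpgs-in-rows", "samples-in-rows", "auto"),
                             strict = TRUE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_input("beta matrix not found: %s", path)
  sep <- sniff_sep(path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop_input("beta matrix %s has no data rows", path)
  nfield <- lengths(strsplit(lines, sep, fixed = TRUE))
  if (length(unique(nfield[-1L])) > 1L) {
    stop_input("ragged row at line %d of %s",
               1L + which(nfield[-1L] != nfield[2L])[1L], path)
  }
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           row.names = 1L, check.names = FALSE,
                           comment.char = "", quote = "\"")
  m <- as.matrix(tab)
  storage.mode(m) <- "double"
  if (orientation == "auto") {
    probe_like <- function(x) mean(grepl("^(cg[0-9]+|ch\\.[0-9]+)", x)) > 0.5
    orientation <- if (probe_like(rownames(m))) "cpgs-in-rows"
      else if (probe_like(colnames(m))) "samples-in-rows"
      else stop_input("cannot auto-detect orientation of %s", path)
  }
  if (orientation == "cpgs-in-rows") m <- t(m)
  # drop all-missing CpG columns
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropped %d all-missing CpG column(s)", sum(all_na)))
    m <- m[, !all_na, drop = FALSE]
  }
  beta_matrix(m, strict = strict)
}

#' Write a beta-value matrix as delimited text
#'
#' @param beta A [beta_matrix()].
#' @param path Output path.
#' @param orientation Layout on disk; default CpGs in rows (GEO convention).
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, orientation = "cpgs-in-rows") {
  stopifnot(inherits(beta, "beta_matrix"))
  m <- unclass(beta)
  if (orientation == "cpgs-in-rows") m <- t(m)
  out <- cbind(id = rownames(m),
               as.data.frame(apply(m, 2L, fmt_num), stringsAsFactors = FALSE,
                             check.names = FALSE))
  names(out)[1L] <- if (orientation == "cpgs-in-rows") "cpg_id" else "sample_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `age` (years), `status` (healthy/disease/unknown),
#' optional `disease_name`.
#'
#' @param path Delimited file path (tab or comma, auto-sniffed).
#' @return A `data.frame` with validated columns.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop_input("metadata not found: %s", path)
  sep <- sniff_sep(path)
  md <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "age", "status")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop_input("metadata missing column(s): %s",
                               paste(miss, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) stop_input("duplicate sample_id in metadata")
  md$age <- as.numeric(md$age)
  if (any(!is.finite(md$age)) || any(md$age < 0)) {
    stop_input("ages must be finite and >= 0")
  }
  bad <- setdiff(unique(md$status), c("healthy", "disease", "unknown"))
  if (length(bad)) stop_input("unknown status value(s): %s",
                              paste(bad, collapse = ", "))
  md
}

#' Write sample metadata
#'
#' @param metadata A metadata `data.frame` (see [read_sample_metadata()]).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  md <- metadata
  md$age <- fmt_num(md$age)
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply a clock model to a beta matrix
#'
#' Computes per-sample predictions `intercept + sum_j w_j beta_ij` over the
#' model CpGs present in the matrix, with a coverage report for those absent.
#'
#' @param model A [clock_model()].
#' @param beta A [beta_matrix()] (samples x CpGs).
#' @param missing_policy What to do with model CpGs absent from the matrix
#'   (or `NA` in a sample): `"zero"` (default; contribute 0, warn),
#'   `"error"`, or `"mean-impute"` (column mean of observed values; for fully
#'   absent CpGs the mean beta 0.5 is used).
#' @return A list with `predictions` (named numeric, response units),
#'   `used_cpgs`, `missing_cpgs` and `coverage` (fraction of model features
#'   found).
#' @export
apply_clock <- function(model, beta,
                        missing_policy = c("zero", "error", "mean-impute")) {
  stopifnot(inherits(model, "clock_model"), inherits(beta, "beta_matrix"))
  missing_policy <- match.arg(missing_policy)
  w <- model$coefficients
  present <- names(w) %in% colnames(beta)
  if (!any(present)) stop_input("no overlap between model '%s' CpGs and beta matrix",
                                model$name)
  missing_cpgs <- names(w)[!present]
  if (length(missing_cpgs)) {
    if (missing_policy == "error") {
      stop_input("model '%s': %d CpG(s) missing from matrix (first: %s)",
                 model$name, length(missing_cpgs), missing_cpgs[1L])
    }
    warning(sprintf("model '%s': %d of %d CpGs missing from matrix",
                    model$name, length(missing_cpgs), model$n_features))
  }
  used <- names(w)[present]
  sub <- unclass(beta)[, used, drop = FALSE]
  if (anyNA(sub)) {
    if (missing_policy == "error") stop_input("NA beta values under strict policy")
    fill <- if (missing_policy == "mean-impute") {
      colMeans(sub, na.rm = TRUE)
    } else rep(0, ncol(sub))
    fill[!is.finite(fill)] <- 0.5
    for (j in seq_len(ncol(sub))) sub[is.na(sub[, j]), j] <- fill[j]
  }
  base <- model$intercept
  if (length(missing_cpgs) && missing_policy == "mean-impute") {
    base <- base + sum(w[missing_cpgs] * 0.5)
  }
  pred <- drop(sub %*% w[used]) + base
  list(predictions = stats::setNames(as.numeric(pred), rownames(beta)),
       used_cpgs = used, missing_cpgs = missing_cpgs,
       coverage = length(used) / model$n_features)
}
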