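#' Declare a nominal (categorical) attribute
#'
#' Nominal attributes take values in a finite, unordered set of labels.
#'
#' @param name Attribute name (unique within a schema).
#' @param values Character vector of admissible values (non-empty, unique).
#' @return An object of class `attribute_schema`.
#' @export
#' @examples
#' attr_nominal("INSS", c("1", "2", "3", "4", "4s"))
attr_nominal <- function(name, values) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  values <- as.character(values)
  if (length(values) == 0L) stop("nominal attribute '", name, "' needs a non-empty domain")
  if (anyDuplicated(values)) stop("duplicated values in domain of '", name, "'")
  structure(list(name = name, kind = "nominal", values = values),
            class = "attribute_schema")
}

#' Declare an ordered (numeric) attribute
#'
#' Ordered attributes vary within a closed interval of the real axis; rule
#' conditions on them are threshold conditions with half-open intervals
#' (lambda, mu].
#'
#' @param name Attribute name.
#' @param bounds Length-2 numeric: finite lower and upper bound, low < high.
#' @return An object of class `attribute_schema`.
#' @export
#' @examples
#' attr_ordered("x1", c(0, 100))
attr_ordered <- function(name, bounds) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  bounds <- as.numeric(bounds)
  if (length(bounds) != 2L || !all(is.finite(bounds)) || bounds[1L] >= bounds[2L])
    stop("bounds of ordered attribute '", name, "' must be finite with low < high")
  structure(list(name = name, kind = "ordered", bounds = bounds),
            class = "attribute_schema")
}

#' Assemble attribute declarations into a schema
#'
#' @param ... `attribute_schema` objects (or a single list of them).
#' @return An object of class `cohort_schema`: a named list of attributes.
#' @export
#' @examples
#' cohort_schema(attr_ordered("x1", c(1, 100)),
#'               attr_nominal("x2", c("red", "green", "blue")))
cohort_schema <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && !inherits(attrs[[1L]], "attribute_schema"))
    attrs <- attrs[[1L]]
  if (!length(attrs) || !all(vapply(attrs, inherits, logical(1L), "attribute_schema")))
    stop("cohort_schema() takes attribute_schema objects")
  nms <- vapply(attrs, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("attribute names must be unique within a schema")
  names(attrs) <- nms
  structure(attrs, class = "cohort_schema")
}

#' @export
print.cohort_schema <- function(x, ...) {
  cat("cohort schema with", length(x), "attributes:\n")
  for (a in x) {
    dom <- if (a$kind == "nominal") paste0("{", paste(a$values, collapse = ", "), "}")
           else sprintf("[%g, %g]", a$bounds[1L], a$bounds[2L])
    cat(sprintf("  %s: %s %s\n", a$name, a$kind, dom))
  }
  invisible(x)
}

schema_names <- function(schema) vapply(schema, `[[`, character(1L), "name")

check_value <- function(attr, v) {
  if (attr$kind == "nominal") {
    v <- as.character(v)
    ok <- v %in% attr$values
  } else {
    v <- suppressWarnings(as.numeric(v))
    ok <- is.finite(v) & v >= attr$bounds[1L] & v <= attr$bounds[2L]
  }
  ok
}

#' Construct a typed cohort dataset
#'
#' Binds a table of attribute values to a schema and an outcome column,
#' validating every cell against the declared attribute domains.
#'
#' @param data A data.frame holding one column per schema attribute (extra
#'   columns beyond `outcome` and `id` are rejected).
#' @param schema A [cohort_schema()].
#' @param outcome Name of the outcome column in `data`.
#' @param id Optional name of an instance-id column; defaults to row numbers.
#' @return An object of class `cohort_dataset` with elements `data`
#'   (attribute columns, typed), `outcome` (character vector), `ids`
#'   (character vector, unique), `schema` and `classes`.
#' @export
#' @examples
#' sch <- cohort_schema(attr_nominal("A", c("a", "b")))
#' cohort_dataset(data.frame(A = c("a", "b", "a"), y = c("G", "P", "G")),
#'                sch, outcome = "y")
cohort_dataset <- function(data, schema, outcome, id = NULL) {
  stopifnot(is.data.frame(data), inherits(schema, "cohort_schema"))
  if (!outcome %in% names(data)) stop("outcome column '", outcome, "' not found")
  nms <- schema_names(schema)
  missing_cols <- setdiff(nms, names(data))
  if (length(missing_cols))
    stop("data lacks attribute column(s): ", paste(missing_cols, collapse = ", "))
  n <- nrow(data)
  if (n < 1L) stop("dataset must contain at least one instance")

  ids <- if (is.null(id)) as.character(seq_len(n)) else as.character(data[[id]])
  if (anyDuplicated(ids)) stop("instance ids must be unique")

  out <- as.character(data[[outcome]])
  if (anyNA(out) || any(!nzchar(out))) stop("missing outcome label(s)")
  if (any(out == "NC")) stop("'NC' is reserved and cannot be an outcome label")

  cols <- list()
  for (a in schema) {
    v <- data[[a$name]]
    na_at <- which(is.na(v))
    if (length(na_at))
      stop(sprintf("missing value at row %d, column '%s'", na_at[1L], a$name))
    ok <- check_value(a, v)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop(sprintf("value '%s' at row %d is outside the domain of '%s'",
                   as.character(v[bad]), bad, a$name))
    }
    cols[[a$name]] <- if (a$kind == "nominal") as.character(v) else as.numeric(v)
  }
  structure(list(
    data = as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE),
    outcome = out,
    ids = ids,
    schema = schema,
    classes = unique(out)
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort dataset: %d instances, %d attributes, classes {%s}\n",
              nrow(x$data), length(x$schema), paste(x$classes, collapse = ", ")))
  invisible(x)
}

n_instances <- function(dataset) nrow(dataset$data)

#' Subset a cohort dataset by instance position or id
#'
#' @param dataset A [cohort_dataset()].
#' @param idx Integer positions, logical mask, or character instance ids.
#' @return A `cohort_dataset` restricted to the selected instances.
#' @export
subset_instances <- function(dataset, idx) {
  if (is.character(idx)) idx <- match(idx, dataset$ids)
  if (is.logical(idx)) idx <- which(idx)
  if (anyNA(idx)) stop("unknown instance id in subset")
  out <- dataset
  out$data <- dataset$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$outcome <- dataset$outcome[idx]
  out$ids <- dataset$ids[idx]
  out$classes <- dataset$classes[dataset$classes %in% unique(out$outcome)]
  out
}

# One canonical string per full attribute profile; used for duplicate-profile
# diagnosis and matched purging of test sets.
profile_keys <- function(dataset) {
  cols <- lapply(dataset$schema, function(a) {
    v <- dataset$data[[a$name]]
    if (a$kind == "ordered") formatC(v, digits = 15, format = "g") else v
  })
  do.call(paste, c(cols, sep = "\r"))
}
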