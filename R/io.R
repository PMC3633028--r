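#' Read a schema configuration from YAML
#'
#' The file maps each attribute column to its kind and domain and names the
#' outcome column:
#' \preformatted{
#' outcome: Outcome
#' attributes:
#'   INSS: {kind: nominal, values: ["1", "2", "3", "4", "4s"]}
#'   Age:  {kind: ordered, bounds: [0, 20]}
#' }
#' Unknown keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return List with `schema` (a [cohort_schema()]) and `outcome` (column
#'   name).
#' @export
read_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  extra <- setdiff(names(cfg), c("outcome", "attributes", "id"))
  if (length(extra))
    stop("unknown schema config key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$outcome) || is.null(cfg$attributes))
    stop("schema config needs 'outcome' and 'attributes'")
  attrs <- lapply(names(cfg$attributes), function(a) {
    sp <- cfg$attributes[[a]]
    extra <- setdiff(names(sp), c("kind", "values", "bounds"))
    if (length(extra))
      stop("attribute '", a, "': unknown key(s) ", paste(extra, collapse = ", "))
    if (identical(sp$kind, "nominal")) attr_nominal(a, as.character(sp$values))
    else if (identical(sp$kind, "ordered")) attr_ordered(a, as.numeric(sp$bounds))
    else stop("attribute '", a, "': kind must be 'nominal' or 'ordered'")
  })
  list(schema = cohort_schema(attrs), outcome = cfg$outcome,
       id = cfg$id)
}

#' Read a delimited dataset against a schema configuration
#'
#' Accepts CSV or TSV (by file extension, or explicitly via `sep`); every
#' cell is validated against the declared attribute domains, with row and
#' column coordinates in error messages.
#'
#' @param path Path to the data file (header required).
#' @param schema Either the path to a YAML schema config (see
#'   [read_schema()]) or the list it returns.
#' @param sep Field separator; default chosen from the file extension
#'   (`.tsv`/`.txt` = tab, else comma).
#' @return A [cohort_dataset()].
#' @export
read_dataset <- function(path, schema, sep = NULL) {
  if (is.character(schema)) schema <- read_schema(schema)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cohort_dataset(df, schema$schema, outcome = schema$outcome, id = schema$id)
}

#' Write a cohort dataset to a delimited file
#'
#' Round-trips with [read_dataset()].
#'
#' @param dataset A [cohort_dataset()].
#' @param path Output path; extension selects the separator as in
#'   [read_dataset()].
#' @param outcome Name for the outcome column (default `"Outcome"`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, outcome = "Outcome") {
  df <- dataset$data
  df[[outcome]] <- dataset$outcome
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read rules from a text file
#'
#' Accepts either the plain rule grammar (one rule per line, `#` comments and
#' blank lines ignored) or the structured JSON written by [write_rules()].
#'
#' @param path Path to the rule file.
#' @param schema A [cohort_schema()].
#' @return A [rule_classifier()] (uncalibrated).
#' @export
read_rules <- function(path, schema) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("^\\s*\\[", first)) {
    objs <- jsonlite::read_json(path, simplifyVector = FALSE)
    rules <- lapply(objs, function(o)
      parse_rule(o$text, schema, id = o$id))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    rules <- lapply(seq_along(lines), function(i)
      parse_rule(lines[i], schema, id = sprintf("r%d", i)))
  }
  rule_classifier(rules, schema)
}

#' Write rules to a text file
#'
#' `format = "grammar"` writes one rule per line in the textual grammar;
#' `format = "json"` writes one structured object per rule (id, conditions,
#' consequence, stats). Both round-trip through [read_rules()].
#'
#' @param classifier A [rule_classifier()] (or list of [rule()]s).
#' @param path Output path.
#' @param format `"grammar"` or `"json"`.
#' @param outcome Consequence-side name used by the grammar (default
#'   `"Outcome"`).
#' @return `path`, invisibly.
#' @export
write_rules <- function(classifier, path, format = c("grammar", "json"),
                        outcome = "Outcome") {
  format <- match.arg(format)
  rules <- if (inherits(classifier, "rule_classifier")) classifier$rules
           else classifier
  if (format == "grammar") {
    writeLines(vapply(rules, format_rule, character(1L), outcome = outcome),
               path)
  } else {
    objs <- lapply(rules, function(r) {
      o <- list(id = r$id, consequence = r$consequence,
                conditions = lapply(unname(r$premise), unclass),
                text = format_rule(r, outcome = outcome))
      if (!is.null(r$stats)) o$stats <- r$stats[c("C", "E", "P")]
      o
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
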