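## Reading and writing tabular multi-label data: delimited text (CSV-style,
## configurable dialect) and Weka ARFF.

#' Read a dataset schema from a YAML or JSON document
#'
#' The schema names every column of a delimited file and assigns each a kind
#' (`numeric`/`nominal`/`ordinal`) and role (`input`/`identifier`/`excluded`/
#' `target`). Target columns list their `classes` (and optionally the
#' `positive` class for binary labels); nominal/ordinal inputs list their
#' `categories`. Omitted category/class inventories are inferred from the data
#' in order of first appearance.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` schema document.
#' @return A schema list consumable by [read_mld_csv()].
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop_fmll("schema file not found: %s", path)
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (is.null(doc$columns)) stop_fmll("schema document lacks a 'columns' list")
  doc
}

infer_levels <- function(v) unique(v[!is.na(v)])

#' Read a delimited text file as a multi-label dataset
#'
#' @param path Path to the file.
#' @param schema Schema list (see [read_schema()]): `name` plus `columns`,
#'   each column a list with `name`, and optionally `kind`, `role`,
#'   `categories`/`classes`, `positive`.
#' @param delimiter Field separator. The default `";"` matches the common
#'   semicolon-delimited distribution of ecological survey tables.
#' @param header Number of header rows to skip (default 1; the first header
#'   row is only used to check column count).
#' @param missing String marking a missing feature cell (default: empty
#'   field). Missingness is only legal in input features, never in labels.
#' @return A [multilabel_dataset()].
#' @export
read_mld_csv <- function(path, schema, delimiter = ";", header = 1L,
                         missing = "") {
  if (!file.exists(path)) stop_fmll("dataset file not found: %s", path)
  raw <- utils::read.table(path, sep = delimiter, header = FALSE,
                           skip = header, colClasses = "character",
                           quote = "\"", comment.char = "", fill = FALSE,
                           na.strings = NULL, check.names = FALSE,
                           stringsAsFactors = FALSE)
  cols <- schema$columns
  if (ncol(raw) != length(cols))
    stop_fmll("file has %d columns but schema declares %d", ncol(raw), length(cols))
  names(raw) <- vapply(cols, `[[`, "", "name")
  for (nm in names(raw)) raw[[nm]][raw[[nm]] == missing] <- NA
  build_mld_from_schema(raw, cols, schema$name %||% basename(path))
}

build_mld_from_schema <- function(df, cols, name) {
  features <- list(); labels <- list()
  for (col in cols) {
    role <- col$role %||% "input"
    if (role == "target") {
      classes <- as.character(col$classes %||% infer_levels(df[[col$name]]))
      labels[[length(labels) + 1L]] <-
        label_spec(col$name, classes, positive = col$positive)
    } else {
      kind <- col$kind %||% "numeric"
      cats <- if (kind == "numeric") character()
              else as.character(col$categories %||% infer_levels(df[[col$name]]))
      features[[length(features) + 1L]] <-
        feature_spec(col$name, kind = kind, categories = cats, role = role)
    }
  }
  multilabel_dataset(df, features, labels, name = name)
}

## -- ARFF ------------------------------------------------------------------

## foreign::read.arff drops declared-but-unused nominal levels; scan the
## header ourselves to recover the full declared category domains.
parse_arff_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  attrs <- list()
  for (ln in lines) {
    lt <- trimws(ln)
    if (grepl("^@data", lt, ignore.case = TRUE)) break
    if (!grepl("^@attribute", lt, ignore.case = TRUE)) next
    body <- trimws(sub("^@attribute[[:space:]]+", "", lt, ignore.case = TRUE))
    if (grepl("^'", body)) {
      nm <- sub("^'((?:[^'\\\\]|\\\\.)*)'.*$", "\\1", body)
      rest <- trimws(sub("^'(?:[^'\\\\]|\\\\.)*'", "", body))
    } else {
      nm <- sub("^([^[:space:]]+).*$", "\\1", body)
      rest <- trimws(sub("^[^[:space:]]+", "", body))
    }
    if (grepl("^\\{", rest)) {
      inner <- sub("^\\{(.*)\\}.*$", "\\1", rest)
      vals <- strsplit(inner, ",")[[1]]
      vals <- vapply(vals, function(v) {
        v <- trimws(v)
        sub("^'(.*)'$", "\\1", sub('^"(.*)"$', "\\1", v))
      }, "")
      attrs[[nm]] <- list(type = "nominal", levels = vals)
    } else {
      attrs[[nm]] <- list(type = tolower(rest), levels = NULL)
    }
  }
  attrs
}

#' Read an ARFF file as a multi-label dataset
#'
#' Nominal ARFF attributes become nominal features (or labels) with their
#' declared category order; numeric attributes become numeric features; `?`
#' cells become missing values.
#'
#' @param path Path to an ARFF file.
#' @param label_names Attribute names to treat as labels; each must be a
#'   nominal attribute.
#' @param positive Named character vector giving the positive class of binary
#'   labels (default: second declared class).
#' @param ordinal Names of nominal attributes to re-mark as ordinal (ARFF has
#'   no ordinal type; declared value order is taken as the rank order).
#' @param roles Named character vector overriding roles of non-label columns
#'   (e.g. `c(ID = "identifier")`).
#' @param name Dataset name (default: file name).
#' @return A [multilabel_dataset()].
#' @export
read_mld_arff <- function(path, label_names, positive = NULL,
                          ordinal = character(), roles = character(),
                          name = NULL) {
  if (!file.exists(path)) stop_fmll("ARFF file not found: %s", path)
  df <- foreign::read.arff(path)
  attrs <- parse_arff_header(path)
  missing_lab <- setdiff(label_names, names(df))
  if (length(missing_lab))
    stop_fmll("label attribute(s) absent from ARFF: %s",
              paste(missing_lab, collapse = ", "))
  features <- list(); labels <- list()
  for (nm in names(df)) {
    att <- attrs[[nm]]
    is_nominal <- !is.null(att) && att$type == "nominal"
    if (nm %in% label_names) {
      if (!is_nominal)
        stop_fmll("label attribute '%s' is not nominal", nm)
      labels[[length(labels) + 1L]] <-
        label_spec(nm, att$levels,
                   positive = if (!is.null(positive)) unname(positive[nm]) else NULL)
      df[[nm]] <- as.character(df[[nm]])
    } else {
      role <- if (nm %in% names(roles)) unname(roles[nm]) else "input"
      if (is_nominal) {
        kind <- if (nm %in% ordinal) "ordinal" else "nominal"
        features[[length(features) + 1L]] <-
          feature_spec(nm, kind = kind, categories = att$levels, role = role)
        df[[nm]] <- as.character(df[[nm]])
      } else {
        features[[length(features) + 1L]] <- feature_spec(nm, role = role)
      }
    }
  }
  multilabel_dataset(df, features, labels,
                     name = name %||% sub("\\.arff$", "", basename(path)))
}

arff_quote <- function(x) {
  needs <- (grepl("[ ,{}'\"%]", x) | x == "") & !is.na(x)
  x[needs] <- paste0("'", gsub("'", "\\\\'", x[needs]), "'")
  x
}

#' Write a multi-label dataset as ARFF
#'
#' Numeric features are written at full double precision (17 significant
#' digits) so a write-then-read round trip reproduces values exactly;
#' missing feature cells are written as `?`. Ordinal features are written as
#' nominal attributes (declared value order preserved).
#'
#' @param dataset A [multilabel_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mld_arff <- function(dataset, path) {
  stopifnot(inherits(dataset, "multilabel_dataset"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("@relation %s", arff_quote(dataset$name)), con)
  cols <- character(0)
  for (f in dataset$features) {
    decl <- if (f$kind == "numeric") "numeric"
            else paste0("{", paste(arff_quote(f$categories), collapse = ","), "}")
    writeLines(sprintf("@attribute %s %s", arff_quote(f$name), decl), con)
    cols <- c(cols, f$name)
  }
  for (l in dataset$labels) {
    writeLines(sprintf("@attribute %s {%s}", arff_quote(l$name),
                       paste(arff_quote(l$classes), collapse = ",")), con)
    cols <- c(cols, l$name)
  }
  writeLines("@data", con)
  out <- vapply(cols, function(nm) {
    v <- dataset$data[[nm]]
    s <- if (is.numeric(v)) formatC(v, digits = 17, format = "g")
         else arff_quote(as.character(v))
    s[is.na(v)] <- "?"
    s
  }, character(nrow(dataset$data)))
  if (nrow(dataset$data) == 1L) out <- matrix(out, nrow = 1L)
  writeLines(apply(out, 1L, paste, collapse = ","), con)
  invisible(path)
}
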