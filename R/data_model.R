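#' Construct and validate a nominal response table
#'
#' A response table is the single input format for model fitting and the
#' output format of the simulator: one row per (case, rater) pair, carrying
#' the case's ground-truth class and the rater's response class.  This is
#' the layout of multi-reader observer studies, e.g. 150 chest-CT cases
#' read by 6 radiologists into 3 diagnostic classes gives 900 rows.
#'
#' Classes are coded as 0-based integers `0 .. C-1`.  Case and rater
#' identifiers may be arbitrary integers or strings; they are recoded to
#' dense 0-based indices and the original labels kept as attributes.
#'
#' @param data data.frame with columns `case`, `rater`, `truth`, `response`.
#' @param n_classes optional override for the number of classes C; must be
#'   at least `1 + max(observed class code)`.  Useful when a small sample
#'   does not realize every legal class.
#' @param class_labels optional character vector of length C mapping class
#'   codes to names (e.g. `c("normal", "non-COVID pneumonia", "COVID-19")`).
#' @return An object of class `response_table`: a data.frame with integer
#'   columns `case`, `rater`, `truth`, `response` (all 0-based) and
#'   attributes `n_cases`, `n_raters`, `n_classes`, `case_labels`,
#'   `rater_labels`, `class_labels`.
#' @examples
#' df <- data.frame(case = c(0, 0, 1, 1), rater = c(0, 1, 0, 1),
#'                  truth = c(2, 2, 0, 0), response = c(2, 1, 0, 0))
#' tbl <- response_table(df)
#' n_classes(tbl)
#' @export
response_table <- function(data, n_classes = NULL, class_labels = NULL) {
  need <- c("case", "rater", "truth", "response")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0) stop("response table has no rows", call. = FALSE)

  case_labels <- sort(unique(data$case))
  rater_labels <- sort(unique(data$rater))
  case <- match(data$case, case_labels) - 1L
  rater <- match(data$rater, rater_labels) - 1L

  truth <- check_class_codes(data$truth, "truth")
  response <- check_class_codes(data$response, "response")

  cmax <- max(truth, response)
  C <- if (is.null(n_classes)) cmax + 1L else as.integer(n_classes)
  if (C < cmax + 1L)
    stop("n_classes = ", C, " but class code ", cmax, " observed", call. = FALSE)
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  if (!is.null(class_labels) && length(class_labels) != C)
    stop("class_labels must have length ", C, call. = FALSE)

  key <- paste(case, rater)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (case, rater) pair: ", d, call. = FALSE)
  }
  # ground truth must be constant within a case
  gt_per_case <- tapply(truth, case, function(x) length(unique(x)))
  bad <- names(gt_per_case)[gt_per_case > 1L]
  if (length(bad) > 0)
    stop("inconsistent ground truth for case(s) ",
         paste(case_labels[as.integer(bad) + 1L], collapse = ", "), call. = FALSE)

  out <- data.frame(case = case, rater = rater, truth = truth, response = response)
  structure(out,
            n_cases = length(case_labels),
            n_raters = length(rater_labels),
            n_classes = C,
            case_labels = case_labels,
            rater_labels = rater_labels,
            class_labels = class_labels,
            class = c("response_table", "data.frame"))
}

check_class_codes <- function(x, what) {
  xi <- suppressWarnings(as.integer(as.character(x)))
  if (anyNA(xi))
    stop(what, " contains values that are not integer class codes", call. = FALSE)
  if (any(xi < 0L))
    stop(what, " contains negative class codes", call. = FALSE)
  xi
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("Nominal response table: %d rows (%d cases x %d raters, %d classes)\n",
              nrow(x), n_cases(x), n_raters(x), n_classes(x)))
  NextMethod()
}

#' Dimensions of a response table
#'
#' @param table a [response_table()].
#' @return integer scalar.
#' @export
n_cases <- function(table) attr(table, "n_cases")

#' @rdname n_cases
#' @export
n_raters <- function(table) attr(table, "n_raters")

#' @rdname n_cases
#' @export
n_classes <- function(table) attr(table, "n_classes")

#' Read a nominal response table from CSV
#'
#' Reads a long-format observer-study file (UTF-8, header row) and
#' validates it into a [response_table()].  Column names differ between
#' sources, so a `column_map` translates the file's names onto the
#' canonical `case`, `rater`, `truth`, `response`.
#'
#' @param path path to a CSV file.
#' @param column_map named character vector with entries `case`, `rater`,
#'   `truth`, `response` giving the corresponding column names in the file.
#' @inheritParams response_table
#' @return a [response_table()].
#' @seealso [write_responses()] for the inverse operation.
#' @export
read_responses <- function(path,
                           column_map = c(case = "case", rater = "rater",
                                          truth = "truth", response = "response"),
                           n_classes = NULL, class_labels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  need <- c("case", "rater", "truth", "response")
  if (!all(need %in% names(column_map)))
    stop("column_map must name ", paste(need, collapse = ", "), call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  missing_cols <- setdiff(unname(column_map[need]), names(raw))
  if (length(missing_cols) > 0)
    stop("column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- data.frame(case = raw[[column_map[["case"]]]],
                   rater = raw[[column_map[["rater"]]]],
                   truth = raw[[column_map[["truth"]]]],
                   response = raw[[column_map[["response"]]]])
  response_table(df, n_classes = n_classes, class_labels = class_labels)
}

#' Write a response table to CSV
#'
#' Emits the same dialect [read_responses()] reads with its default
#' `column_map`, so simulator output is directly consumable by the fitting
#' pipeline (read-write round trips are the identity on the coded table).
#'
#' @param table a [response_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(table, path) {
  stopifnot(inherits(table, "response_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Confusion matrix of one rater
#'
#' Tabulates a single rater's responses against the ground truth: entry
#' (s, t) counts the cases with true class s that the rater called class t.
#' Row sums therefore give the class distribution of the cases the rater
#' read, and the trace counts correct classifications.
#'
#' @param table a [response_table()].
#' @param rater 0-based rater index.
#' @return a C x C integer matrix, rows = ground truth, columns = response.
#' @export
confusion_matrix <- function(table, rater) {
  stopifnot(inherits(table, "response_table"))
  J <- n_raters(table)
  if (length(rater) != 1L || is.na(rater) || rater < 0L || rater >= J)
    stop("rater must be a single index in [0, ", J, ")", call. = FALSE)
  C <- n_classes(table)
  sub <- table[table$rater == rater, , drop = FALSE]
  m <- table(factor(sub$truth, levels = 0:(C - 1L)),
             factor(sub$response, levels = 0:(C - 1L)))
  m <- matrix(as.integer(m), nrow = C, ncol = C)
  labs <- attr(table, "class_labels") %||% as.character(0:(C - 1L))
  dimnames(m) <- list(truth = labs, response = labs)
  m
}
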