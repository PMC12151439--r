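#' Read and validate a unit-interval regression table
#'
#' Reads a CSV/TSV file with a header, validates that the response lies in
#' (0, 1] — rejecting exact zeros with the offending row numbers, clamping
#' exact ones to `1 - 1e-10` with a warning — drops rows with missing values
#' in the used columns (reporting how many), and checks that the requested
#' columns are numeric.
#'
#' @param path path to a delimited text file with a header row.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names; `NULL`
#'   means every other numeric column.
#' @param sep field separator; by default inferred from the file extension
#'   (`.tsv`/`.txt` use tab, otherwise comma).
#' @return A list with `data` (the cleaned data frame), `formula` (response
#'   on covariates), `response`, `covariates`, `n_clamped` and
#'   `dropped_rows` (row indices removed for missingness).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(y = c(0.2, 0.5, 0.9), x = 1:3), f, row.names = FALSE)
#' read_unit_data(f, "y", "x")
#' @export
read_unit_data <- function(path, response, covariates = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  if (!response %in% names(df))
    stop("response column '", response, "' not found", call. = FALSE)
  if (is.null(covariates))
    covariates <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          response)
  missing_cols <- setdiff(covariates, names(df))
  if (length(missing_cols))
    stop("covariate column(s) not found: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  used <- df[, c(response, covariates), drop = FALSE]
  not_num <- names(used)[!vapply(used, is.numeric, logical(1))]
  if (length(not_num))
    stop("non-numeric column(s): ", paste(not_num, collapse = ", "),
         call. = FALSE)
  keep <- complete.cases(used)
  dropped <- which(!keep)
  if (length(dropped))
    message("dropped ", length(dropped), " row(s) with missing values")
  used <- used[keep, , drop = FALSE]
  if (nrow(used) == 0L) stop("no complete rows left", call. = FALSE)
  y <- used[[response]]
  zero <- which(y <= 0)
  if (length(zero))
    stop("response values must be in (0,1]; found values <= 0 in row(s) ",
         paste(utils::head(zero, 10L), collapse = ", "), call. = FALSE)
  if (any(y > 1))
    stop("response values must be in (0,1]; found values > 1", call. = FALSE)
  ones <- y == 1
  if (any(ones)) {
    warning(sum(ones), " response value(s) equal to 1 clamped to 1 - 1e-10",
            call. = FALSE)
    y[ones] <- 1 - 1e-10
    used[[response]] <- y
  }
  fml <- stats::as.formula(paste(response, "~",
                                 if (length(covariates))
                                   paste(covariates, collapse = " + ")
                                 else "1"))
  list(data = used, formula = fml, response = response,
       covariates = covariates, n_clamped = sum(ones),
       dropped_rows = dropped)
}
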