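# Tabular and JSON interfaces: expression tables, model round-trip,
# report export.

MODEL_SCHEMA <- "regspline-model/1"

#' Read a log-expression table
#'
#' Reads a tab-separated table with a \code{gene_id} column, one numeric
#' column per tissue, and optionally a logical \code{differential} column
#' flagging differentially expressed genes. \code{NaN} cells and duplicate
#' gene ids are rejected; missing (\code{NA}) cells are allowed and make a
#' gene ineligible for differential analyses involving that tissue.
#'
#' @param path Path to the TSV file.
#' @return Data frame with \code{gene_id}, tissue columns and optionally
#'   \code{differential}.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stopf("expression table missing gene_id column")
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup)) stopf("duplicate gene_id in expression table: %s", paste(unique(dup), collapse = ", "))
  tissue_cols <- setdiff(names(tab), c("gene_id", "differential"))
  if (!length(tissue_cols)) stopf("expression table has no tissue columns")
  for (cc in tissue_cols) {
    if (!is.numeric(tab[[cc]])) stopf("non-numeric expression column '%s'", cc)
    if (any(is.nan(tab[[cc]])) || any(is.infinite(tab[[cc]])))
      stopf("non-finite expression value in column '%s'", cc)
  }
  if ("differential" %in% names(tab)) tab$differential <- as.logical(tab$differential)
  tab
}

#' Write a log-expression table
#' @param expression Expression data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  utils::write.table(expression, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted influence model to JSON
#'
#' Writes knots, coefficients, sigma, variant and (if present) regulator
#' weights under a versioned schema so that [read_model()] restores a
#' field-equal model.
#'
#' @param model An \code{influence_fit}.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "influence_fit")) stopf("write_model expects an influence_fit")
  obj <- list(schema_version = MODEL_SCHEMA,
              variant = model$variant,
              sigma = model$sigma,
              penalty_order = model$penalty_order,
              coefficients = as.numeric(model$coefficients))
  if (!is.null(model$basis)) {
    obj$basis <- list(knots = model$basis$knots, degree = model$basis$degree,
                      n_basis = model$basis$n_basis, domain = model$basis$domain)
  }
  if (!is.null(model$regulator_weights)) {
    obj$regulator_weights <- as.list(model$regulator_weights)
    obj$weight_combine <- model$weight_combine %||% "mean"
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a fitted influence model from JSON
#'
#' @param path Path written by [write_model()].
#' @return An \code{influence_fit} (without training data: fitted values,
#'   residuals and MSE are not serialized).
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema_version, MODEL_SCHEMA))
    stopf("model schema mismatch: expected '%s', found '%s'",
          MODEL_SCHEMA, obj$schema_version %||% "<none>")
  basis <- NULL
  if (!is.null(obj$basis)) {
    basis <- structure(list(knots = as.numeric(obj$basis$knots),
                            degree = as.integer(obj$basis$degree),
                            n_basis = as.integer(obj$basis$n_basis),
                            domain = as.numeric(obj$basis$domain)),
                       class = "spline_basis")
  }
  w <- NULL
  if (!is.null(obj$regulator_weights)) w <- unlist(obj$regulator_weights)
  structure(list(coefficients = as.numeric(obj$coefficients), basis = basis,
                 sigma = obj$sigma, penalty_order = obj$penalty_order,
                 variant = obj$variant, regulator_weights = w,
                 weight_combine = obj$weight_combine,
                 fitted.values = NULL, residuals = NULL, y = NULL,
                 mse = NULL, n = NULL, call = NULL),
            class = "influence_fit")
}

#' Export an influence curve as TSV
#'
#' @param model An \code{influence_fit}.
#' @param path Output path.
#' @param grid Evaluation grid (default 1 kb steps over the basis domain).
#' @return `path`, invisibly.
#' @export
write_influence_curve <- function(model, path,
                                  grid = seq(model$basis$domain[1], model$basis$domain[2],
                                             length.out = 201)) {
  utils::write.table(influence_curve(model, grid), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
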