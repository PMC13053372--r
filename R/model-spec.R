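#' Declare a composite (emergent variable) block
#'
#' A composite is an exact weighted linear combination of at least two observed
#' components, with no construct-level error term. The order of the components
#' is fixed and determines the banded loading pattern used in the
#' Henseler-Ogasawara specification (see [build_ho_pattern()]).
#'
#' @param name construct label.
#' @param components character vector (length >= 2) of distinct column names.
#' @return An object of class `"cms_block"` with `kind = "composite"`.
#' @seealso [latent()], [cms_model()]
#' @export
#' @examples
#' composite("M", c("m1", "m2", "m3"))
composite <- function(name, components) {
  components <- as.character(components)
  if (length(components) < 2L)
    stop("a composite needs at least two components", call. = FALSE)
  if (anyDuplicated(components))
    stop("component labels must be distinct", call. = FALSE)
  structure(list(kind = "composite", name = as.character(name),
                 vars = components), class = "cms_block")
}

#' Declare a reflective latent variable block
#'
#' A latent variable measured by at least two observed indicators, each with
#' its own measurement error.
#'
#' @param name construct label.
#' @param indicators character vector (length >= 2) of distinct column names.
#' @return An object of class `"cms_block"` with `kind = "latent"`.
#' @seealso [composite()], [cms_model()]
#' @export
latent <- function(name, indicators) {
  indicators <- as.character(indicators)
  if (length(indicators) < 2L)
    stop("a latent block needs at least two indicators", call. = FALSE)
  if (anyDuplicated(indicators))
    stop("indicator labels must be distinct", call. = FALSE)
  structure(list(kind = "latent", name = as.character(name),
                 vars = indicators), class = "cms_block")
}

#' Describe a moderated mediation model with a composite mediator
#'
#' Bundles the measurement blocks and the structural roles for the three-step
#' composite moderated structural equations (CMS) estimator: a latent predictor
#' `X`, a composite mediator `M` and a latent outcome `Y`, with the `X:M`
#' interaction entering the outcome equation.
#'
#' @param predictor a [latent()] block for the exogenous predictor.
#' @param mediator a [composite()] block for the mediator.
#' @param outcome a [latent()] block for the outcome.
#' @return An object of class `"cms_model"`.
#' @export
#' @examples
#' cms_model(
#'   predictor = latent("X", c("x1", "x2", "x3")),
#'   mediator  = composite("M", c("m1", "m2", "m3")),
#'   outcome   = latent("Y", c("y1", "y2", "y3"))
#' )
cms_model <- function(predictor, mediator, outcome) {
  stopifnot(inherits(predictor, "cms_block"), predictor$kind == "latent",
            inherits(mediator, "cms_block"), mediator$kind == "composite",
            inherits(outcome, "cms_block"), outcome$kind == "latent")
  all_vars <- c(predictor$vars, mediator$vars, outcome$vars)
  if (anyDuplicated(all_vars))
    stop("a variable may appear in only one block", call. = FALSE)
  structure(list(predictor = predictor, mediator = mediator,
                 outcome = outcome, vars = all_vars),
            class = "cms_model")
}

#' @export
print.cms_model <- function(x, ...) {
  cat("CMS model description\n")
  cat("  predictor (latent):   ", x$predictor$name, "=~",
      paste(x$predictor$vars, collapse = " + "), "\n")
  cat("  mediator (composite): ", x$mediator$name, "<~",
      paste(x$mediator$vars, collapse = " + "), "\n")
  cat("  outcome (latent):     ", x$outcome$name, "=~",
      paste(x$outcome$vars, collapse = " + "), "\n")
  cat("  structural:           ", x$mediator$name, "~", x$predictor$name, ";",
      x$outcome$name, "~", x$predictor$name, "+", x$mediator$name, "+",
      paste0(x$predictor$name, ":", x$mediator$name), "\n")
  invisible(x)
}

#' Read a model description from a structured text config
#'
#' The config is line based. Block headers are `composite: <name>` and
#' `latent: <name>`, each followed by an indented `components:` or
#' `indicators:` line listing space- or comma-separated column names. A
#' `structural:` block with `predictor:`, `mediator:` and `outcome:` lines
#' assigns the roles. Lines starting with `#` are comments.
#'
#' @param path path to the config file.
#' @return A [cms_model()] object.
#' @export
read_cms_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  blocks <- list()
  roles <- list()
  current <- NULL
  split_names <- function(x) {
    out <- strsplit(trimws(x), "[,[:space:]]+")[[1]]
    out[nzchar(out)]
  }
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (key %in% c("composite", "latent")) {
      current <- val
      blocks[[current]] <- list(kind = key, vars = character())
    } else if (key %in% c("components", "indicators")) {
      if (is.null(current))
        stop("'", key, "' line outside a block in ", path, call. = FALSE)
      blocks[[current]]$vars <- split_names(val)
    } else if (key == "structural") {
      current <- NULL
    } else if (key %in% c("predictor", "mediator", "outcome")) {
      roles[[key]] <- val
    } else if (key == "interaction") {
      # informational; the CMS topology always includes predictor:mediator
    } else {
      stop("unrecognized config line: '", ln, "'", call. = FALSE)
    }
  }
  for (r in c("predictor", "mediator", "outcome"))
    if (is.null(roles[[r]]))
      stop("config is missing a '", r, ":' role line", call. = FALSE)
  get_block <- function(role, kind, ctor) {
    nm <- roles[[role]]
    b <- blocks[[nm]]
    if (is.null(b)) stop("role '", role, "' refers to undeclared block '",
                         nm, "'", call. = FALSE)
    if (b$kind != kind)
      stop("role '", role, "' must be a ", kind, " block", call. = FALSE)
    ctor(nm, b$vars)
  }
  cms_model(predictor = get_block("predictor", "latent", latent),
            mediator = get_block("mediator", "composite", composite),
            outcome = get_block("outcome", "latent", latent))
}

#' Read a rectangular numeric data table
#'
#' Delimited text with a header row of variable names; no missing values are
#' accepted. Used by the command-line interface and convenient for scripts.
#'
#' @param path path to the file.
#' @param sep field separator (default comma).
#' @return A numeric data frame.
#' @export
read_cms_data <- function(path, sep = ",") {
  dat <- read.csv(path, sep = sep, check.names = FALSE)
  if (anyNA(dat)) stop("data contain missing values", call. = FALSE)
  if (!all(vapply(dat, is.numeric, logical(1))))
    stop("all data columns must be numeric", call. = FALSE)
  dat
}

# Validate that data provide every model-referenced column exactly once and
# return the numeric matrix in model order.
model_matrix <- function(data, model) {
  data <- as.data.frame(data)
  missing <- setdiff(model$vars, names(data))
  if (length(missing))
    stop("data are missing model column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyNA(data[model$vars])) stop("data contain missing values", call. = FALSE)
  mat <- as.matrix(data[model$vars])
  storage.mode(mat) <- "double"
  if (nrow(mat) <= ncol(mat))
    stop("need more observations than observed variables", call. = FALSE)
  mat
}
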