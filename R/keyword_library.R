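#' Read a keyword library from JSON
#'
#' The library maps diagnosis-text categories (`primary`, `other`) to ordered
#' modules, each carrying a keyword list and an optional module weight in
#' `[0, 5]`. The default library bundles the seven-module vocabularies for the
#' main-diagnosis and other-diagnosis fields together with their reference
#' weights.
#'
#' @param path Path to a JSON file of the form
#'   `{"primary": [{"module": ..., "keywords": [...], "weight": ...}, ...],
#'     "other": [...]}`. Defaults to the bundled library.
#' @return An object of class `keyword_library`: a named list of categories,
#'   each a list of modules with `module`, `keywords`, `weight`.
#' @export
read_keyword_library <- function(path = default_library_path()) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lib <- lapply(raw, function(cat) {
    lapply(cat, function(m) {
      list(module = as.character(m$module),
           keywords = vapply(m$keywords, as.character, character(1)),
           weight = if (is.null(m$weight)) NA_real_ else as.numeric(m$weight))
    })
  })
  structure(lib, class = "keyword_library")
}

#' @rdname read_keyword_library
#' @export
default_keyword_library <- function() read_keyword_library()

default_library_path <- function() {
  system.file("extdata", "keyword_library.json", package = "traumaprog",
              mustWork = TRUE)
}

#' Validate a keyword library
#'
#' Checks module-name uniqueness, non-empty keyword lists and weight bounds.
#'
#' @param library A `keyword_library`.
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_keyword_library <- function(library) {
  stopifnot(inherits(library, "keyword_library") || is.list(library))
  for (cat_name in names(library)) {
    cat <- library[[cat_name]]
    mods <- vapply(cat, `[[`, character(1), "module")
    if (anyDuplicated(mods))
      stop("duplicate module names in category '", cat_name, "'")
    for (m in cat) {
      if (!length(m$keywords) || any(!nzchar(m$keywords)))
        stop("module '", m$module, "' has an empty keyword list")
      if (!is.na(m$weight) && (m$weight < 0 || m$weight > 5))
        stop("module '", m$module, "' weight outside [0, 5]")
    }
  }
  invisible(TRUE)
}

#' Module names of a library category
#' @param library A `keyword_library`.
#' @param category `"primary"` or `"other"`.
#' @return Character vector of module names, in library order.
#' @export
library_modules <- function(library, category = "primary") {
  vapply(library[[match.arg(category, names(library))]], `[[`,
         character(1), "module")
}

#' Module weights of a library category
#' @inheritParams library_modules
#' @return Named numeric vector of weights (NA where unset).
#' @export
library_weights <- function(library, category = "primary") {
  cat <- library[[match.arg(category, names(library))]]
  stats::setNames(vapply(cat, `[[`, numeric(1), "weight"),
                  vapply(cat, `[[`, character(1), "module"))
}

#' Replace the weights of a library category
#' @inheritParams library_modules
#' @param weights Numeric vector, one per module, in `[0, 5]`.
#' @return The modified library.
#' @export
set_library_weights <- function(library, weights, category = "primary") {
  category <- match.arg(category, names(library))
  stopifnot(length(weights) == length(library[[category]]),
            all(weights >= 0 & weights <= 5))
  for (j in seq_along(weights)) library[[category]][[j]]$weight <- weights[j]
  library
}

#' @export
print.keyword_library <- function(x, ...) {
  for (cat_name in names(x)) {
    cat(cat_name, "diagnosis library (", length(x[[cat_name]]), "modules )\n")
    for (m in x[[cat_name]]) {
      cat(sprintf("  %-22s w=%-3s %s\n", m$module,
                  ifelse(is.na(m$weight), "?", format(m$weight)),
                  paste(m$keywords, collapse = ", ")))
    }
  }
  invisible(x)
}
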