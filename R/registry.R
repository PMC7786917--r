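# The FI-30 item registry: 30 deficit items, each with an ordered coding
# scheme mapping response labels to deficit weights in [0, 1].

# grades admitted by the instrument convention: binary 0/1 plus the ordinal
# intermediate values used for graded deficits
LEGAL_WEIGHTS <- c(0, 0.25, 0.33, 0.5, 0.66, 0.75, 1)
N_ITEMS <- 30L

#' Construct a coding scheme
#'
#' A coding scheme is an ordered set of (label, weight) pairs mapping a
#' categorical survey response to a deficit weight. Weights must be strictly
#' increasing, start at 0, end at 1, and belong to the admitted grade set
#' \{0, 0.25, 0.33, 0.5, 0.66, 0.75, 1\}.
#'
#' @param labels character vector of response labels, least to most severe.
#' @param weights numeric vector of deficit weights, same length.
#' @return An object of class `fi30_scheme`.
#' @examples
#' coding_scheme(c("Good", "Average", "Poor Health"), c(0, 0.5, 1))
#' @export
coding_scheme <- function(labels, weights) {
  labels <- as.character(labels)
  weights <- as.numeric(weights)
  if (length(labels) != length(weights) || length(labels) < 2) {
    fi30_stop("fi30_scheme_error",
              "a coding scheme needs >= 2 (label, weight) pairs of equal length")
  }
  if (anyDuplicated(tolower(trimws(labels)))) {
    fi30_stop("fi30_scheme_error", "scheme labels must be unique (case-insensitively)")
  }
  bad <- weights[!weights %in% LEGAL_WEIGHTS]
  if (length(bad)) {
    fi30_stop("fi30_scheme_error",
              sprintf("illegal scheme weight(s) %s; admitted grades are %s",
                      paste(bad, collapse = ", "),
                      paste(LEGAL_WEIGHTS, collapse = ", ")))
  }
  if (any(diff(weights) <= 0)) {
    fi30_stop("fi30_scheme_error", "scheme weights must be strictly increasing")
  }
  if (weights[1] != 0 || weights[length(weights)] != 1) {
    fi30_stop("fi30_scheme_error",
              "scheme weights must start at 0 and end at 1")
  }
  structure(list(labels = labels, weights = weights), class = "fi30_scheme")
}

#' @export
print.fi30_scheme <- function(x, ...) {
  cat(paste(sprintf("%s = %g", x$labels, x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a deficit item
#'
#' @param item_id integer identifier in 1..30.
#' @param name item name (instrument wording).
#' @param scheme an [coding_scheme()] object.
#' @param source one of `"self-report"`, `"biomarker"`, `"performance"`.
#' @return An object of class `fi30_item`.
#' @export
deficit_item <- function(item_id, name, scheme,
                         source = c("self-report", "biomarker", "performance")) {
  source <- match.arg(source)
  item_id <- as.integer(item_id)
  if (is.na(item_id) || item_id < 1L || item_id > N_ITEMS) {
    fi30_stop("fi30_registry_error", "item_id must be an integer in 1..30")
  }
  if (!inherits(scheme, "fi30_scheme")) {
    fi30_stop("fi30_registry_error", "scheme must be a coding_scheme()")
  }
  structure(list(item_id = item_id, name = as.character(name),
                 scheme = scheme, source = source),
            class = "fi30_item")
}

parse_levels <- function(spec) {
  # "Good=0|Average=0.5|Poor Health=1" -> scheme
  parts <- strsplit(spec, "|", fixed = TRUE)[[1]]
  kv <- regmatches(parts, regexec("^(.*)=([0-9.]+)$", parts))
  if (any(lengths(kv) != 3)) {
    fi30_stop("fi30_registry_error",
              sprintf("cannot parse level specification: %s", spec))
  }
  coding_scheme(trimws(vapply(kv, `[`, "", 2)),
                as.numeric(vapply(kv, `[`, "", 3)))
}

#' Read an item registry from a CSV file
#'
#' The file must have columns `item_id`, `name`, `source` and `levels`, the
#' latter holding `label=weight` pairs separated by `|`
#' (e.g. `"Good=0|Average=0.5|Poor Health=1"`). The parsed registry is
#' validated against the instrument invariants (exactly 30 items with ids
#' 1..30, legal schemes).
#'
#' @param path path to the registry CSV.
#' @return A list of 30 [deficit_item()] objects, class `fi30_registry`,
#'   ordered and named by `item_id`.
#' @seealso [fi30_registry()] for the shipped default, [validate_registry()].
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) {
    fi30_stop("fi30_registry_error", sprintf("registry file not found: %s", path))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "name", "source", "levels")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    fi30_stop("fi30_registry_error",
              sprintf("registry is missing column(s): %s",
                      paste(missing_cols, collapse = ", ")))
  }
  items <- lapply(seq_len(nrow(df)), function(i) {
    deficit_item(df$item_id[i], df$name[i], parse_levels(df$levels[i]),
                 df$source[i])
  })
  reg <- structure(items, class = "fi30_registry",
                   names = as.character(df$item_id))
  diag <- validate_registry(reg)
  if (length(diag)) {
    fi30_stop("fi30_registry_error",
              paste(c("invalid registry:", diag), collapse = "\n  "))
  }
  reg[order(vapply(reg, function(it) it$item_id, 1L))]
}

#' The shipped FI-30 item registry
#'
#' Returns the default 30-item instrument: item 1 self-rated health
#' (Good/Average/Poor Health = 0/0.5/1), graded biomarker items for BMI
#' (item 10), random blood sugar (item 17), GDS-15 depression (item 20) and
#' high blood pressure (item 22, grades 0/0.33/0.66/1), and 25 binary
#' (No = 0 / Yes = 1) deficit items covering sensory problems, chronic
#' disease history, activities of daily living and performance tests.
#'
#' @return A `fi30_registry` (list of 30 `fi30_item` objects).
#' @examples
#' reg <- fi30_registry()
#' length(reg)
#' reg[["1"]]$scheme
#' @export
fi30_registry <- function() {
  path <- system.file("extdata", "fi30_items.csv", package = "fi30")
  read_registry(path)
}

#' Validate an item registry
#'
#' Checks the registry invariants: 30 items, ids exactly 1..30 without
#' duplicates, every scheme with strictly increasing legal weights from 0
#' to 1, a known source tag, and non-empty names.
#'
#' @param registry a `fi30_registry`, or a path to a registry CSV (in which
#'   case parse errors are reported as findings rather than thrown).
#' @return Character vector of violations; `character(0)` if the registry
#'   is valid.
#' @examples
#' validate_registry(fi30_registry())  # character(0)
#' @export
validate_registry <- function(registry) {
  if (is.character(registry) && length(registry) == 1) {
    reg <- tryCatch(read_registry(registry), fi30_error = function(e) e)
    if (inherits(reg, "fi30_error")) return(conditionMessage(reg))
    return(character(0))  # read_registry already validated
  }
  findings <- character(0)
  note <- function(fmt, ...) findings <<- c(findings, sprintf(fmt, ...))

  if (!is.list(registry)) return("registry is not a list of items")
  ids <- vapply(registry, function(it) as.integer(it$item_id %||% NA), 1L)
  if (length(registry) != N_ITEMS) {
    note("expected %d items, found %d", N_ITEMS, length(registry))
  }
  if (anyDuplicated(ids)) {
    note("duplicate item_id(s): %s",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!setequal(ids[!is.na(ids)], seq_len(N_ITEMS))) {
    note("item_ids are not exactly 1..%d", N_ITEMS)
  }
  for (it in registry) {
    id <- it$item_id %||% "?"
    if (!inherits(it$scheme, "fi30_scheme")) {
      note("item %s: missing or invalid coding scheme", id)
      next
    }
    w <- it$scheme$weights
    if (any(!w %in% LEGAL_WEIGHTS)) {
      note("item %s: illegal weight(s) %s", id,
           paste(setdiff(w, LEGAL_WEIGHTS), collapse = ", "))
    }
    if (any(diff(w) <= 0) || w[1] != 0 || w[length(w)] != 1) {
      note("item %s: weights must increase strictly from 0 to 1", id)
    }
    if (!isTRUE(it$source %in% c("self-report", "biomarker", "performance"))) {
      note("item %s: unknown source '%s'", id, it$source %||% "")
    }
    if (!nzchar(it$name %||% "")) note("item %s: empty name", id)
  }
  findings
}

#' Code a raw survey response into a deficit weight
#'
#' Maps a response label to its deficit weight under the item's coding
#' scheme. Matching is case-insensitive after trimming whitespace. A numeric
#' response is accepted if it is already a legal weight of the scheme
#' (pre-graded input). Missing responses (`NA`, `""`) pass through as `NA`.
#'
#' @param item a `fi30_item` (one element of a registry).
#' @param response character label, or a numeric weight of the scheme;
#'   vectorized.
#' @return Numeric vector of deficit weights (`NA` for missing input).
#' @examples
#' reg <- fi30_registry()
#' code_item(reg[["1"]], "Average")  # 0.5
#' code_item(reg[["22"]], "Mild")    # 0.33
#' code_item(reg[["15"]], "No")      # 0
#' @export
code_item <- function(item, response) {
  if (!inherits(item, "fi30_item")) {
    fi30_stop("fi30_coding_error", "item must be a fi30_item")
  }
  sch <- item$scheme
  if (is.numeric(response)) {
    ok <- is.na(response) | response %in% sch$weights
    if (!all(ok)) {
      fi30_stop("fi30_coding_error",
                sprintf("item %d (%s): numeric value(s) %s are not weights of the scheme",
                        item$item_id, item$name,
                        paste(unique(response[!ok]), collapse = ", ")))
    }
    return(as.numeric(response))
  }
  resp <- trimws(as.character(response))
  resp[!nzchar(resp)] <- NA_character_
  idx <- match(tolower(resp), tolower(trimws(sch$labels)))
  unknown <- !is.na(resp) & is.na(idx)
  if (any(unknown)) {
    fi30_stop("fi30_coding_error",
              sprintf("item %d (%s): unknown response label(s): %s",
                      item$item_id, item$name,
                      paste(unique(resp[unknown]), collapse = ", ")))
  }
  sch$weights[idx]
}
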