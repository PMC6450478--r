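#' Build a medication catalog
#'
#' The catalog is the universal item set: one entry per canonical medication
#' name with a per-dose-unit utility value `P(i)`, a diluent/carrier flag, a
#' free-text drug class, and raw-name synonyms. It also carries the
#' route-merge map used during cleaning (e.g. `"IV drip" -> "IV"`).
#'
#' The utility value `P(i)` weights a dose quantity `q` into a medication
#' utility `U(i, q) = P(i) * q`; medications absent from the catalog default
#' to `P = 1` so that utility degrades gracefully to dose mass.
#'
#' @param medications A data frame with columns `name` (unique), `utility`
#'   (non-negative, default 1), `is_diluent` (logical, default `FALSE`) and
#'   `class` (character, default `""`).
#' @param synonyms Named character vector mapping raw names to canonical
#'   names; every synonym must map to exactly one catalog entry.
#' @param route_merge Named character vector mapping raw route labels to
#'   merged labels.
#' @return An object of class `med_catalog`.
#' @seealso [read_med_catalog()], [canonicalize_medication()], [merge_route()]
#' @export
med_catalog <- function(medications = tibble(name = character()),
                        synonyms = character(),
                        route_merge = character()) {
  medications <- as_tibble(medications)
  if (!"name" %in% names(medications)) abort("catalog needs a `name` column")
  if (anyDuplicated(medications$name)) abort("catalog names must be unique")
  if (!"utility" %in% names(medications)) medications$utility <- 1
  if (!"is_diluent" %in% names(medications)) medications$is_diluent <- FALSE
  if (!"class" %in% names(medications)) medications$class <- ""
  if (any(medications$utility < 0)) abort("utility values P(i) must be >= 0")
  synonyms <- unlist(synonyms)
  if (length(synonyms)) {
    if (is.null(names(synonyms)) || any(names(synonyms) == "")) {
      abort("synonyms must be a named vector (raw name -> canonical name)")
    }
    if (anyDuplicated(names(synonyms))) {
      abort("each synonym must map to exactly one canonical name")
    }
    missing <- setdiff(unique(synonyms), medications$name)
    if (length(missing)) {
      abort(paste0(
        "synonyms point at medications absent from the catalog: ",
        paste(missing, collapse = ", ")
      ))
    }
  }
  route_merge <- unlist(route_merge)
  core <- c("name", "utility", "is_diluent", "class")
  structure(
    list(
      medications = medications[c(core, setdiff(names(medications), core))],
      synonyms = synonyms,
      route_merge = route_merge
    ),
    class = "med_catalog"
  )
}

#' @export
print.med_catalog <- function(x, ...) {
  cat(
    "<med_catalog> ", nrow(x$medications), " medications (",
    sum(x$medications$is_diluent), " diluents), ",
    length(x$synonyms), " synonyms, ",
    length(x$route_merge), " route merges\n",
    sep = ""
  )
  invisible(x)
}

#' Read / write a medication catalog as JSON
#'
#' The JSON layout is
#' `{"medications": {name: {"P": num, "is_diluent": bool, "class": str,
#' "synonyms": [..]}}, "route_merge": {raw: merged}}`.
#'
#' @param path File path.
#' @return `read_med_catalog()` returns a [med_catalog()];
#'   `write_med_catalog()` returns `path` invisibly.
#' @export
read_med_catalog <- function(path) {
  doc <- jsonlite::read_json(path)
  meds <- doc$medications %||% list()
  medications <- tibble(
    name = names(meds),
    utility = unname(purrr::map_dbl(meds, ~ .x$P %||% 1)),
    is_diluent = unname(purrr::map_lgl(meds, ~ isTRUE(.x$is_diluent))),
    class = unname(purrr::map_chr(meds, ~ .x$class %||% ""))
  )
  synonyms <- purrr::imap(meds, function(m, nm) {
    syn <- unlist(m$synonyms)
    if (length(syn)) setNames(rep(nm, length(syn)), syn) else character()
  })
  synonyms <- unlist(unname(synonyms)) %||% character()
  route_merge <- unlist(doc$route_merge) %||% character()
  med_catalog(medications, synonyms, route_merge)
}

#' @rdname read_med_catalog
#' @param catalog A [med_catalog()].
#' @export
write_med_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "med_catalog"))
  syn_by_canon <- split(names(catalog$synonyms), unname(catalog$synonyms))
  meds <- purrr::pmap(catalog$medications, function(name, utility, is_diluent,
                                                    class, ...) {
    c(
      list(
        P = utility, is_diluent = is_diluent, class = class,
        synonyms = as.list(syn_by_canon[[name]] %||% character())
      ),
      list(...) # extra annotation columns (e.g. a generator's route)
    )
  })
  names(meds) <- catalog$medications$name
  doc <- list(medications = meds, route_merge = as.list(catalog$route_merge))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Canonicalize medication names
#'
#' Maps raw medication names through the catalog's synonym table; names
#' without a synonym entry pass through unchanged.
#'
#' @param x Character vector of raw names.
#' @param catalog A [med_catalog()].
#' @return Character vector of canonical names.
#' @export
canonicalize_medication <- function(x, catalog) {
  hit <- match(x, names(catalog$synonyms))
  out <- x
  out[!is.na(hit)] <- unname(catalog$synonyms[hit[!is.na(hit)]])
  out
}

#' Merge route labels
#'
#' Applies the catalog's route-merge map; unmapped labels pass through.
#'
#' @inheritParams canonicalize_medication
#' @return Character vector of merged route labels.
#' @export
merge_route <- function(x, catalog) {
  hit <- match(x, names(catalog$route_merge))
  out <- x
  out[!is.na(hit)] <- unname(catalog$route_merge[hit[!is.na(hit)]])
  out
}

# P(i) lookup with default 1 for uncatalogued medications.
utility_value <- function(x, catalog, default = 1) {
  hit <- match(x, catalog$medications$name)
  out <- rep_len(as.numeric(default), length(x))
  out[!is.na(hit)] <- catalog$medications$utility[hit[!is.na(hit)]]
  out
}

is_diluent <- function(x, catalog) {
  hit <- match(x, catalog$medications$name)
  out <- rep_len(FALSE, length(x))
  out[!is.na(hit)] <- catalog$medications$is_diluent[hit[!is.na(hit)]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
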