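#' Names of the supported disgust-sensitivity instruments
#'
#' `child_22`: the 22-item child self-report (responses 0-3);
#' `dsr`: the 27-item revised Disgust Scale for adults (0-4);
#' `dsr_parent_ext`: its 13-item parenting-scenario extension (0-4);
#' `tdds`: the 21-item Three-Domain Disgust Scale (0-6, seven items per
#' pathogen/sexual/moral subdomain).
#'
#' @return character vector of instrument names
#' @export
instrument_names <- function() c("child_22", "dsr", "dsr_parent_ext", "tdds")

#' Load an instrument's scoring specification
#'
#' Specifications are editable JSON files (item count, response range,
#' reverse-keyed items, item-to-subscale map). The TDDS map follows the
#' instrument's published interleaved 7/7/7 subdomain structure. The
#' `child_22` and `dsr` subscale maps and the `dsr` reverse keying are
#' SYNTHETIC defaults — the true keys live in the instruments' source
#' publications and must be supplied (via `path`) before substantive use;
#' each file's `provenance` field says so.
#'
#' @param name one of [instrument_names()]
#' @param path optional path to a custom JSON specification
#' @return an object of class `instrument_spec`
#' @export
instrument_spec <- function(name = instrument_names(), path = NULL) {
  if (is.null(path)) {
    name <- match.arg(name)
    path <- system.file("extdata", "instruments", paste0(name, ".json"),
                        package = "gastrogaze", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- list(name = raw$name, n_items = as.integer(raw$n_items),
               response_range = as.integer(raw$response_range),
               reverse_items = as.integer(raw$reverse_items %||% integer(0)),
               subscales = lapply(raw$subscales %||% list(), as.integer),
               provenance = raw$provenance %||% "")
  items <- unlist(spec$subscales, use.names = FALSE)
  if (anyDuplicated(items))
    abort_input("instrument spec maps an item to more than one subscale")
  if (length(items) && (min(items) < 1 || max(items) > spec$n_items))
    abort_input("subscale map references items outside 1..n_items")
  structure(spec, class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> %s: %d items, responses %d-%d\n",
              x$name, x$n_items, x$response_range[1], x$response_range[2]))
  if (length(x$subscales))
    cat("subscales:", paste(names(x$subscales), vapply(x$subscales, length, 1L),
                            collapse = ", "), "\n")
  if (length(x$reverse_items))
    cat("reverse-keyed:", paste(x$reverse_items, collapse = ", "), "\n")
  invisible(x)
}

#' Score questionnaire responses
#'
#' Totals are sums over (reverse-keyed where specified) item responses;
#' subscale scores are sums over the mapped items. A missing item makes the
#' total — and the subscale it maps to — missing for that participant; no
#' imputation, consistent with a pairwise-complete downstream analysis.
#'
#' @param responses data.frame with `participant_id` and columns
#'   `item_1..item_k`; integer responses within the instrument's range, or
#'   `NA`
#' @param spec an [instrument_spec()]
#' @return data.frame with `participant_id`, `total`, one column per
#'   subscale, and `n_missing`
#' @export
score_questionnaire <- function(responses, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  cols <- paste0("item_", seq_len(spec$n_items))
  missing_cols <- setdiff(cols, names(responses))
  if (length(missing_cols))
    abort_input("responses lack item columns: ",
                paste(missing_cols, collapse = ", "))
  M <- as.matrix(responses[, cols])
  rng <- spec$response_range
  bad <- which(!is.na(M) & (M < rng[1] | M > rng[2] | M != round(M)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort_input("out-of-range response for participant ",
                responses$participant_id[bad[1, 1]], ", item_", bad[1, 2],
                ": ", M[bad[1, , drop = FALSE]],
                " (allowed ", rng[1], "-", rng[2], ")")
  if (length(spec$reverse_items))
    M[, spec$reverse_items] <- rng[1] + rng[2] - M[, spec$reverse_items]
  out <- data.frame(participant_id = responses$participant_id,
                    total = rowSums(M))
  for (sc in names(spec$subscales))
    out[[sc]] <- rowSums(M[, spec$subscales[[sc]], drop = FALSE])
  out$n_missing <- rowSums(is.na(M))
  out
}
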