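#' Construct an elemental composition
#'
#' An `elemental_composition` holds one sample's per-element atomic-percent
#' table as measured by energy-dispersive X-ray spectroscopy (EDX). EDX is
#' blind to hydrogen, so H never appears among the entries; the rescaling
#' step imputes it later.
#'
#' @param sample_id character label for the sample (e.g. `"Ba-alg"`).
#' @param entries named numeric vector, element symbol -> atomic percent.
#'   All values must be strictly positive and the total must lie in
#'   \[95, 105\] (tolerating discarded traces and rounding).
#' @param metadata optional named list (instrument, washing protocol, ionic
#'   radius `r_ion_nm`, ...).
#' @return object of class `elemental_composition`.
#' @export
#' @examples
#' elemental_composition("Ba-alg",
#'   c(C = 51.16, O = 45.81, Ba = 2.74, Na = 0.14, Cl = 0.05, Al = 0.06, Si = 0.04))
elemental_composition <- function(sample_id, entries, metadata = list()) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  if (is.null(names(entries)) || any(names(entries) == "")) {
    stop("entries must be a named numeric vector (element -> atomic percent)")
  }
  bad_sym <- setdiff(names(entries), .element_symbols)
  if (length(bad_sym)) {
    stop(sprintf("sample '%s': invalid element symbol(s): %s",
                 sample_id, paste(bad_sym, collapse = ", ")))
  }
  if (anyDuplicated(names(entries))) {
    stop(sprintf("sample '%s': duplicate element entries: %s", sample_id,
                 paste(unique(names(entries)[duplicated(names(entries))]),
                       collapse = ", ")))
  }
  if (any(!is.finite(entries)) || any(entries <= 0)) {
    off <- names(entries)[!is.finite(entries) | entries <= 0]
    stop(sprintf("sample '%s': atomic percent must be > 0 (element %s)",
                 sample_id, paste(off, collapse = ", ")))
  }
  tot <- sum(entries)
  if (tot < 95 || tot > 105) {
    stop(sprintf("sample '%s': atomic percents sum to %.2f, outside [95, 105]",
                 sample_id, tot))
  }
  structure(
    list(sample_id = sample_id,
         entries = entries[order(match(names(entries), .element_symbols))],
         metadata = metadata),
    class = "elemental_composition"
  )
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat(sprintf("<elemental_composition> %s  (%d elements, total %.2f at%%)\n",
              x$sample_id, length(x$entries), sum(x$entries)))
  print(round(x$entries, 3))
  invisible(x)
}

#' Read a table of elemental compositions
#'
#' Reads EDX atomic-percent tables from CSV. The canonical dialect is long
#' format with columns `sample_id`, `element`, `atomic_percent`; a wide
#' dialect (one row per sample, one column per element, empty cells for
#' absent elements) is accepted on read only.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param dialect `"long"` (default) or `"wide"`.
#' @return list of [elemental_composition()] objects, one per sample, in
#'   file order. An empty file yields an empty list with a warning.
#' @export
read_composition_table <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("no rows in ", path)
    return(list())
  }
  if (dialect == "long") {
    need <- c("sample_id", "element", "atomic_percent")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("format error: missing column(s) ", paste(miss, collapse = ", "))
    }
    df$atomic_percent <- as.numeric(df$atomic_percent)
    bad <- which(!is.finite(df$atomic_percent))
    if (length(bad)) {
      stop("unparseable atomic_percent at data line(s) ",
           paste(bad, collapse = ", "))
    }
    ids <- unique(df$sample_id)
    lapply(ids, function(id) {
      sub <- df[df$sample_id == id, , drop = FALSE]
      elemental_composition(id, stats::setNames(sub$atomic_percent, sub$element))
    })
  } else {
    if (!"sample_id" %in% names(df)) {
      stop("format error: missing column sample_id")
    }
    elems <- setdiff(names(df), "sample_id")
    lapply(seq_len(nrow(df)), function(i) {
      v <- suppressWarnings(as.numeric(df[i, elems]))
      names(v) <- elems
      v <- v[is.finite(v) & v > 0]
      elemental_composition(df$sample_id[i], v)
    })
  }
}

#' Write compositions back to long-format CSV
#'
#' @param comps list of [elemental_composition()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(comps, path) {
  rows <- do.call(rbind, lapply(comps, function(cm) {
    data.frame(sample_id = cm$sample_id, element = names(cm$entries),
               atomic_percent = unname(cm$entries))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a composition to JSON
#'
#' @param comp an [elemental_composition()].
#' @return a JSON string carrying sample_id, entries and metadata.
#' @export
composition_to_json <- function(comp) {
  jsonlite::toJSON(
    list(sample_id = comp$sample_id, entries = as.list(comp$entries),
         metadata = comp$metadata),
    auto_unbox = TRUE, digits = NA)
}

#' Drop trace elements from a composition
#'
#' Elements below `cutoff` atomic percent (sputtering artefacts such as Al,
#' Si, and for Ba-alginate the residual Cl left by washing) are removed.
#' Retained values are not renormalized: the subsequent C12 rescaling uses
#' only ratios, so renormalization is irrelevant. The removed set is
#' recorded in `metadata$discarded`.
#'
#' @param comp an [elemental_composition()].
#' @param cutoff atomic-percent threshold, default 0.10 (the smallest cutoff
#'   consistent with the retained/discarded split of the reference data).
#' @return the filtered composition; idempotent at fixed cutoff.
#' @export
discard_traces <- function(comp, cutoff = 0.10) {
  stopifnot(inherits(comp, "elemental_composition"), cutoff >= 0)
  drop <- comp$entries < cutoff
  if (!"C" %in% names(comp$entries) || isTRUE(drop[["C"]])) {
    stop(sprintf("sample '%s': no carbon retained; carbon is the scaling anchor",
                 comp$sample_id))
  }
  out <- comp
  out$entries <- comp$entries[!drop]
  discarded <- comp$entries[drop]
  if (length(discarded)) {
    prev <- comp$metadata$discarded %||% stats::setNames(numeric(0), character(0))
    out$metadata$discarded <- c(prev, discarded)
  }
  out
}
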