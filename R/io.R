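# Result serialization: CSV/TSV with a provenance header block, JSON
# alternative, and lossless round-trip for scan tables.

#' Write result tables with a provenance header
#'
#' Writes each named table to `out_dir` as CSV/TSV (with `#`-prefixed
#' metadata lines: model, seed, tolerances, package version) or JSON.
#' Numeric columns are written at full precision so tables round-trip
#' losslessly through [read_results_table()].
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @param format `csv`, `tsv` or `json`.
#' @param meta named list of provenance fields (model, seed, ...).
#' @return character vector of file paths, invisibly.
#' @export
write_results <- function(tables, out_dir, format = c("csv", "tsv", "json"),
                          meta = list()) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- c(meta, list(package = "glycoMCA",
                       version = as.character(utils::packageVersion("glycoMCA"))))
  paths <- character(0)
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ".", format))
    if (format == "json") {
      jsonlite::write_json(list(meta = meta, data = tables[[nm]]), path,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      sep <- if (format == "csv") "," else "\t"
      con <- file(path, "w")
      writeLines(sprintf("# %s: %s", names(meta),
                         vapply(meta, function(x) paste(format(x), collapse = " "),
                                character(1))), con)
      df <- tables[[nm]]
      num <- vapply(df, is.numeric, logical(1))
      df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
      utils::write.table(df, con, sep = sep, row.names = FALSE,
                         quote = FALSE)
      close(con)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read back a results table written by [write_results()]
#'
#' @param path file path (csv or tsv).
#' @return data.frame; the provenance header is attached as attribute
#'   `meta` (character lines).
#' @export
read_results_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = sep,
                          header = TRUE, stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Control coefficients shaped like a published comparison table
#'
#' Arranges concentration control coefficients of several conditions into
#' one enzyme x (condition, metabolite) table, rounded to 2 significant
#' figures in the `printed` columns.
#'
#' @param cc_list named list of `glyco_control` objects (names = condition
#'   labels).
#' @return data.frame with an `enzyme` column and one column per
#'   condition/metabolite pair.
#' @export
control_summary_table <- function(cc_list) {
  enzymes <- unique(unlist(lapply(cc_list, function(cc) rownames(cc$CS))))
  out <- data.frame(enzyme = enzymes, stringsAsFactors = FALSE)
  for (cond in names(cc_list)) {
    cs <- cc_list[[cond]]$CS
    for (met in colnames(cs)) {
      col <- paste(cond, met, sep = "_")
      out[[col]] <- signif(cs[match(enzymes, rownames(cs)), met], 2)
    }
  }
  out
}
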