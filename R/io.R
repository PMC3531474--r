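#' Write an SI table to TSV
#' @param si An `si_table`.
#' @param path Output path.
#' @export
write_si_table <- function(si, path) {
  utils::write.table(as.data.frame(si), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an SI table from TSV
#'
#' Expects at least `bait`, `prey`, `background`, `SI`; `n_reps` and
#' `class` are filled with defaults when absent.
#'
#' @param path Path to a tab-separated file.
#' @return An `si_table`.
#' @export
read_si_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("bait", "prey", "background", "SI")
  if (!all(need %in% names(d)))
    stop("SI table must have columns: ", paste(need, collapse = ", "))
  if (is.null(d$n_reps)) d$n_reps <- NA_integer_
  if (is.null(d$class)) d$class <- NA_character_
  if (is.null(d$cross_id))
    d$cross_id <- paste(d$bait, d$prey, d$background)
  if (is.null(d$bait_species)) d$bait_species <- NA_character_
  if (is.null(d$prey_species)) d$prey_species <- NA_character_
  d <- d[, c("cross_id", "bait", "prey", "bait_species", "prey_species",
             "background", "SI", "n_reps", "class")]
  class(d) <- c("si_table", "data.frame")
  d
}

#' Import SI tables from a spreadsheet
#'
#' Reads one sheet of an XLSX workbook of per-cross SI values (such as
#' the raw and corrected screen datasets distributed with published
#' DHFR-PCA screens) and maps its columns onto the `si_table` layout.
#'
#' @param path XLSX file path.
#' @param sheet Sheet name or index.
#' @param columns Named character vector mapping `si_table` fields
#'   (`bait`, `prey`, `background`, `SI`, optionally `class`) to the
#'   sheet's column names.
#' @return An `si_table`.
#' @export
import_si_xlsx <- function(path, sheet = 1L,
                           columns = c(bait = "bait", prey = "prey",
                                       background = "background", SI = "SI")) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("importing XLSX requires the readxl package")
  d <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  miss <- setdiff(unname(columns), names(d))
  if (length(miss) > 0L)
    stop("sheet lacks columns: ", paste(miss, collapse = ", "))
  out <- data.frame(bait = as.character(d[[columns[["bait"]]]]),
                    prey = as.character(d[[columns[["prey"]]]]),
                    background = as.character(d[[columns[["background"]]]]),
                    SI = as.numeric(d[[columns[["SI"]]]]),
                    stringsAsFactors = FALSE)
  out$class <- if ("class" %in% names(columns))
    as.character(d[[columns[["class"]]]]) else NA_character_
  out$cross_id <- paste(out$bait, out$prey, out$background)
  out$n_reps <- NA_integer_
  out$bait_species <- NA_character_
  out$prey_species <- NA_character_
  out <- out[, c("cross_id", "bait", "prey", "bait_species", "prey_species",
                 "background", "SI", "n_reps", "class")]
  class(out) <- c("si_table", "data.frame")
  out
}

#' Label SI crosses as within- or among-complex
#'
#' @param si An `si_table`.
#' @param complexes Named character vector protein -> complex.
#' @return The table with `class` set to `"SW"` / `"SA"`.
#' @export
assign_si_classes <- function(si, complexes) {
  stopifnot(inherits(si, "si_table"))
  unknown <- setdiff(unique(c(si$bait, si$prey)), names(complexes))
  if (length(unknown) > 0L)
    stop("proteins without complex assignment: ",
         paste(unknown, collapse = ", "))
  si$class <- ifelse(complexes[si$bait] == complexes[si$prey], "SW", "SA")
  si
}
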