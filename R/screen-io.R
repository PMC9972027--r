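## Reading and writing the pipeline's tabular artifacts, with strict
## validation. Long (tidy) CSV is the input dialect; stage outputs are
## TSV with a deterministic column order, row sort and float precision so
## that files are diffable across runs.

.plateColumns <- c("plate_id", "well", "compound_id", "cell_line",
    "dose", "role", "od")
.plateRoles <- c("sample", "negative_control", "positive_control", "blank")

## Validate a long-format plate table; `where` names the source for error
## messages. Returns the table with canonical column types.
validatePlateTable <- function(plates, cellLines = NULL,
                               where = "plate table") {
    if (!is.data.frame(plates))
        stop(where, ": expected a data.frame")
    missing <- setdiff(.plateColumns, names(plates))
    if (length(missing))
        stop(where, ": missing columns: ", paste(missing, collapse = ", "))
    plates$compound_id <- as.character(plates$compound_id)
    plates$compound_id[!nzchar(trimws(ifelse(is.na(plates$compound_id), "",
        plates$compound_id)))] <- NA_character_
    plates$od <- as.numeric(plates$od)
    plates$dose <- as.numeric(plates$dose)
    bad <- which(!plates$role %in% .plateRoles)
    if (length(bad))
        stop(where, ": unknown role '", plates$role[bad[1]],
             "' at row ", bad[1])
    bad <- which(is.na(plates$od) | plates$od < 0)
    if (length(bad))
        stop(where, ": missing or negative od at row ", bad[1])
    bad <- which(!grepl("^[A-H](1[0-2]|[1-9])$", plates$well))
    if (length(bad))
        stop(where, ": malformed well label '", plates$well[bad[1]],
             "' at row ", bad[1], " (expected A1-H12)")
    key <- paste(plates$plate_id, plates$well, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup))
        stop(where, ": duplicate (plate_id, well) = (",
             plates$plate_id[dup[1]], ", ", plates$well[dup[1]],
             ") at row ", dup[1])
    isSample <- plates$role == "sample"
    bad <- which(isSample & (is.na(plates$compound_id) | is.na(plates$dose)))
    if (length(bad))
        stop(where, ": sample well without compound_id/dose at row ", bad[1])
    bad <- which(plates$role == "blank" & !is.na(plates$compound_id))
    if (length(bad))
        stop(where, ": blank well carries a compound_id at row ", bad[1])
    if (!is.null(cellLines)) {
        bad <- which(!plates$cell_line %in% cellLines)
        if (length(bad))
            stop(where, ": unknown cell line '", plates$cell_line[bad[1]],
                 "' at row ", bad[1])
    }
    plates
}

#' Read a long-format plate-reader table
#'
#' Reads a CSV with columns `plate_id, well, compound_id, cell_line, dose,
#' role, od` and validates every row: roles must be one of sample /
#' negative_control / positive_control / blank; optical densities must be
#' present and non-negative (missing readings are rejected, never
#' imputed); `(plate_id, well)` pairs must be unique; sample wells need a
#' compound id and dose; blanks must not carry one. Errors name the first
#' offending row.
#'
#' @param path CSV file path.
#' @param cellLines optional vector of admissible cell-line names.
#' @return A validated data.frame of plate measurements.
#' @export
readPlateTable <- function(path, cellLines = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    raw <- read.csv(path, stringsAsFactors = FALSE,
        colClasses = c(plate_id = "character", well = "character"))
    validatePlateTable(raw, cellLines, where = basename(path))
}

#' Read a compound annotation table
#'
#' CSV with columns `compound_id, name, category, flags`; ids must be
#' unique and the `flags` field holds zero or more semicolon-separated
#' triage tags (e.g. `topoisomerase_class;cardiac_glycoside_class`).
#'
#' @param path CSV file path.
#' @return data.frame of annotations (`flags` kept as the raw string;
#'   see [annotationFlags()] for the parsed list).
#' @export
readCompoundAnnotations <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ann <- read.csv(path, stringsAsFactors = FALSE,
        colClasses = "character")
    need <- c("compound_id", "name", "category", "flags")
    missing <- setdiff(need, names(ann))
    if (length(missing))
        stop(basename(path), ": missing columns: ",
             paste(missing, collapse = ", "))
    dup <- which(duplicated(ann$compound_id))
    if (length(dup))
        stop(basename(path), ": duplicated compound_id '",
             ann$compound_id[dup[1]], "' at row ", dup[1])
    ann$flags[is.na(ann$flags)] <- ""
    ann
}

#' Parse annotation flags into a named list
#'
#' @param annotations an annotation data.frame.
#' @return Named list (by compound id) of character vectors of flags; an
#'   empty flags field yields `character(0)`.
#' @export
annotationFlags <- function(annotations) {
    fl <- strsplit(annotations$flags, ";", fixed = TRUE)
    fl <- lapply(fl, function(x) x[nzchar(trimws(x))])
    names(fl) <- annotations$compound_id
    fl
}

#' Write a stage-result table deterministically
#'
#' Serializes a result table as TSV preceded by a `# stage:` comment line.
#' Rows are sorted by `compound_id` then `cell_line` (when present) and
#' floating-point columns are written at fixed 6-decimal precision, so the
#' same logical table always produces a byte-identical file.
#'
#' @param table a data.frame (or S4Vectors DataFrame) of results.
#' @param path output file path.
#' @param stageName short stage label recorded in the header comment.
#' @return `path`, invisibly.
#' @seealso [readResults()]
#' @export
writeResults <- function(table, path, stageName) {
    df <- as.data.frame(table, stringsAsFactors = FALSE)
    keys <- intersect(c("compound_id", "cell_line"), names(df))
    if (length(keys) && nrow(df)) {
        ord <- do.call(order, unname(df[keys]))
        df <- df[ord, , drop = FALSE]
    }
    isDouble <- vapply(df, is.double, logical(1))
    df[isDouble] <- lapply(df[isDouble], function(x)
        ifelse(is.na(x), "NA", sprintf("%.6f", x)))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste0("# stage: ", stageName), con)
    write.table(df, con, sep = "\t", quote = FALSE,
        row.names = FALSE, eol = "\n")
    invisible(path)
}

#' Read back a stage-result table written by [writeResults()]
#'
#' @param path TSV file path.
#' @return data.frame (header comment lines are skipped).
#' @export
readResults <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
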