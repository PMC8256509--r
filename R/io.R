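#' Read a schema-checked TSV table
#'
#' Reads a tab-separated table with header and validates it against a
#' declared schema: required columns must be present and coercible to the
#' declared class. Mismatches raise an error listing expected vs found;
#' a malformed numeric cell is reported with its row and column.
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   one of `"character"`, `"numeric"`, `"integer"`. `NULL` skips
#'   validation.
#' @return data.frame.
#' @export
readTableChecked <- function(path, schema = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(schema)) {
        miss <- setdiff(names(schema), names(df))
        if (length(miss))
            stop(sprintf("schema mismatch in %s: expected column(s) [%s], found [%s]",
                         path, paste(names(schema), collapse = ", "),
                         paste(names(df), collapse = ", ")))
        for (col in names(schema)) {
            if (schema[[col]] %in% c("numeric", "integer")) {
                v <- suppressWarnings(as.numeric(df[[col]]))
                bad <- which(is.na(v) & !is.na(df[[col]]))
                if (length(bad))
                    stop(sprintf("malformed numeric cell in %s: row %d, column '%s'",
                                 path, bad[1], col))
                df[[col]] <- if (schema[[col]] == "integer") as.integer(v) else v
            } else df[[col]] <- as.character(df[[col]])
        }
    }
    df
}

#' Write a TSV table
#'
#' Tab-separated, header row, no quoting, no row names; the counterpart
#' of [readTableChecked()] (write then read is the identity on the table
#' content).
#'
#' @param df data.frame.
#' @param path file path.
#' @return invisibly, `path`.
#' @export
writeTableChecked <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

# Read an expression TSV (first column "gene") into a numeric matrix.
readExpressionTSV <- function(path) {
    df <- readTableChecked(path, schema = c(gene = "character"))
    x <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
    storage.mode(x) <- "double"
    rownames(x) <- df$gene
    x
}
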