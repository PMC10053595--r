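#' Derive a reproducible sub-seed from a master seed and a purpose string
#'
#' Each synthetic-data artifact draws from its own pseudo-random stream keyed
#' by `(seed, purpose)`, so adding a new generator never perturbs the draws of
#' an existing one. The sub-seed is a simple polynomial hash folded into the
#' 32-bit positive-integer range.
#'
#' @param seed integer master seed
#' @param purpose character tag naming the stream
#' @return an integer usable with [set.seed()]
#' @keywords internal
derive_seed <- function(seed, purpose) {
  codes <- utf8ToInt(purpose)
  h <- as.double(seed %% 2147483647L)
  for (k in codes) h <- (h * 131 + k) %% 2147483629
  as.integer(h %% 2147483647) + 1L
}

#' Evaluate an expression under a named random stream
#'
#' Seeds the RNG with [derive_seed()] for the duration of `expr` and restores
#' the previous RNG state afterwards.
#'
#' @param seed integer master seed
#' @param purpose character stream tag
#' @param expr expression to evaluate
#' @keywords internal
with_stream <- function(seed, purpose, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, purpose))
  expr
}

# shared missing-value token for all result tables
.NA_TOKEN <- "."

#' Write a result table as TSV
#'
#' One row per record, header line, tab separation, `.` for missing values —
#' the common dialect of every table the pipeline emits.
#'
#' @param df data.frame to write
#' @param path output path
#' @return `path`, invisibly
#' @export
write_result_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.numeric(col)) col <- ifelse(is.na(col), .NA_TOKEN, format(col, digits = 15, trim = TRUE, scientific = FALSE))
    else col <- ifelse(is.na(col), .NA_TOKEN, as.character(col))
    out[[j]] <- col
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a result table written by [write_result_tsv()]
#' @param path TSV path
#' @return data.frame with `.` restored to NA
#' @export
read_result_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = .NA_TOKEN,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
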