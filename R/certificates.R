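#' @title Death-certificate records
#' @description
#' A death certificate is represented as one row of a data frame with the
#' free-text fields a certifier completes: the immediate cause of death
#' (`cause_a`, "line a"), up to three sequential "due to (or as a consequence
#' of)" lines (`cause_b`, `cause_c`, `cause_d`), the "other significant
#' conditions contributing" section (`scc`), and the description of injury
#' (`injury_desc`). An optional `ucod` column carries the ICD-10 underlying
#' cause-of-death code assigned by NCHS, from which the gold overdose label
#' is derived; `label` is a logical (TRUE = drug overdose death).
#'
#' Missing text is always represented as the empty string, never `NA`:
#' blank "due to" lines are the norm on real certificates.
#' @name certificates
NULL

CERT_TEXT_FIELDS <- c("cause_a", "cause_b", "cause_c", "cause_d",
                      "scc", "injury_desc")
CERT_FIELDS <- c("id", CERT_TEXT_FIELDS, "ucod")

#' Read death certificates from a delimited file
#'
#' Reads a CSV or TSV file (header required) into the standard certificate
#' data frame. Columns may be renamed through `column_map`; columns absent
#' from both the file and the map yield empty text. When a `ucod` column is
#' present, gold labels are derived with [label_from_ucod()].
#'
#' @param path Path to a CSV (default) or TSV file with a header row.
#' @param column_map Named character vector mapping standard field names
#'   (`id`, `cause_a` ... `cause_d`, `scc`, `injury_desc`, `ucod`) to the
#'   column names used in the file, e.g. `c(cause_a = "COD_LINE_A")`.
#'   Unmapped standard names are looked up under their own name.
#' @param sep Field separator; inferred from the file extension when `NULL`
#'   (`.tsv`/`.tab` => tab, otherwise comma).
#' @return A data frame with columns `id`, `cause_a` ... `cause_d`, `scc`,
#'   `injury_desc`, `ucod`, `label`; one row per input row, order preserved.
#' @export
read_certificates <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) {
    stop("cannot read certificate file: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, comment.char = "",
                           stringsAsFactors = FALSE)
  map <- stats::setNames(CERT_FIELDS, CERT_FIELDS)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), CERT_FIELDS)
    if (length(bad)) {
      stop("column_map names unknown field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(column_map)] <- column_map
    missing_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_cols)) {
      stop("column_map refers to column(s) not present in the file: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(raw)
  out <- data.frame(id = character(n), stringsAsFactors = FALSE)
  for (f in CERT_FIELDS) {
    col <- map[[f]]
    out[[f]] <- if (col %in% names(raw)) {
      v <- raw[[col]]
      v[is.na(v)] <- ""
      trimws(v)
    } else {
      character(n)
    }
  }
  if (!nrow(out) || all(out$id == "")) out$id <- as.character(seq_len(n))
  out$label <- rep(NA, n)
  has_code <- !is.na(out$ucod) & nzchar(out$ucod)
  if (any(has_code)) out$label[has_code] <- label_from_ucod(out$ucod[has_code])
  out
}

#' Label a death as drug overdose from its ICD-10 underlying cause code
#'
#' Applies the consensus surveillance definition: a death is a drug overdose
#' iff the underlying cause-of-death (UCOD) code falls in X40-X44
#' (unintentional), X60-X64 (suicide), X85 (homicide) or Y10-Y14
#' (undetermined intent). Matching is on the uppercased 3-character prefix;
#' a fourth digit or dot suffix is ignored, so `"X429"` and `"X42.9"` both
#' label TRUE.
#'
#' @param code Character vector of non-empty ICD-10 codes (letter followed
#'   by digits).
#' @return Logical vector, TRUE for overdose codes.
#' @examples
#' label_from_ucod(c("X42", "I25", "Y149"))
#' @export
label_from_ucod <- function(code) {
  if (!length(code)) return(logical(0))
  code <- as.character(code)
  ok <- !is.na(code) & grepl("^[A-Za-z][0-9]{2}", code)
  if (!all(ok)) {
    stop("malformed ICD-10 code(s): ",
         paste(unique(code[!ok]), collapse = ", "),
         " (expected a letter followed by digits)", call. = FALSE)
  }
  toupper(substr(code, 1, 3)) %in% overdose_ucod_codes()
}

#' The 3-character ICD-10 UCOD codes defining a drug overdose death
#' @return Character vector of 16 codes.
#' @export
overdose_ucod_codes <- function() {
  c(sprintf("X4%d", 0:4), sprintf("X6%d", 0:4), "X85", sprintf("Y1%d", 0:4))
}

#' Normalize certifier free text
#'
#' Uppercases, replaces every punctuation character with a single space (so
#' "FENTANYL/HEROIN" yields two tokens rather than one merged one), collapses
#' runs of whitespace, and trims. Output contains only `[A-Z0-9 ]`.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(x) {
  x[is.na(x)] <- ""
  x <- toupper(x)
  x <- gsub("[^A-Z0-9 ]", " ", x)
  x <- gsub(" +", " ", x)
  trimws(x)
}

#' Combine certificate fields into one normalized free-text string
#'
#' The selected fields are concatenated in certificate reading order
#' (`cause_a`, `cause_b`, `cause_c`, `cause_d`, \[`scc`,\] `injury_desc`)
#' and normalized with [normalize_text()]. Two field combinations are
#' supported: `"all_sections"` uses every free-text section, `"no_scc"`
#' drops the significant-conditions-contributing section, which on real
#' certificates may describe a previous, non-fatal overdose and so can
#' confound the classifier.
#'
#' @param dc Certificate data frame (see [read_certificates()]).
#' @param field_set `"all_sections"` or `"no_scc"`.
#' @return Character vector of normalized combined text, one per row.
#' @export
combine_fields <- function(dc, field_set = c("all_sections", "no_scc")) {
  field_set <- match.arg(field_set)
  fields <- if (field_set == "all_sections") {
    c("cause_a", "cause_b", "cause_c", "cause_d", "scc", "injury_desc")
  } else {
    c("cause_a", "cause_b", "cause_c", "cause_d", "injury_desc")
  }
  present <- intersect(fields, names(dc))
  if (!length(present)) return(character(nrow(dc)))
  parts <- lapply(present, function(f) {
    v <- as.character(dc[[f]])
    v[is.na(v)] <- ""
    v
  })
  normalize_text(do.call(paste, parts))
}

#' Write certificates (optionally with predictions) to a delimited file
#'
#' @param dc Certificate data frame, possibly with appended prediction
#'   columns.
#' @param path Output path; extension `.tsv`/`.tab` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_certificates <- function(dc, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(dc, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
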