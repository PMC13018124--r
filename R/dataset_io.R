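## NONMEM-style long-format observation dataset: CSV serialization and
## schema validation.

.dataset_columns <- c("ID", "TIME", "EVID", "AMT", "DVID", "DV", "CENS",
                      "LLOQ", "EGFR", "OCT2", "OCTN1", "AGE", "WT", "SEX")

#' Validate an observation dataset
#'
#' Schema: mandatory columns ID, TIME (h, >= 0), EVID (1 dose / 0
#' observation), AMT (mg on dose records), DVID (1 plasma ug/mL, 2 VAS), DV,
#' CENS (0/1 left-censored), LLOQ (ug/mL), EGFR, OCT2, OCTN1, AGE, WT, SEX.
#' Dose records must carry AMT > 0 and no DV; observation records must carry
#' a DV (or be censored); pain records (DVID = 2) are never censored.
#' Violations are reported with the offending row numbers.
#'
#' @param dataset data.frame to check
#' @return the dataset, invisibly, when valid; otherwise an error
#' @export
validate_dataset <- function(dataset) {
  missing_cols <- setdiff(.dataset_columns, names(dataset))
  if (length(missing_cols))
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad, na.rm = TRUE))
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(which(bad), collapse = ", "), ")"))
  }
  flag(is.na(dataset$TIME) | dataset$TIME < 0, "TIME must be >= 0")
  flag(!dataset$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  dose <- dataset$EVID == 1L
  flag(dose & (is.na(dataset$AMT) | dataset$AMT <= 0),
       "dose records must have AMT > 0")
  flag(dose & !is.na(dataset$DV), "dose records must have empty DV")
  obs <- dataset$EVID == 0L
  flag(obs & !dataset$DVID %in% c(1L, 2L),
       "observation records must have DVID 1 (plasma) or 2 (VAS)")
  flag(obs & is.na(dataset$DV) & dataset$CENS != 1L,
       "observation records must have DV present or CENS = 1")
  flag(!dataset$CENS %in% c(0L, 1L), "CENS must be 0 or 1")
  flag(obs & dataset$DVID == 2L & dataset$CENS == 1L,
       "pain records (DVID = 2) must not be censored")
  if (length(problems))
    stop("invalid observation dataset:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(dataset)
}

#' Read / write observation datasets
#'
#' Plain CSV with header, comma separator, dot decimal; missing values
#' serialized as empty fields. `read_dataset()` validates the schema and
#' reports violations with row numbers; write-then-read is an identity on
#' the mandatory columns.
#'
#' @param path file path
#' @return `read_dataset()`: validated data.frame
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  dataset <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("EVID", "DVID", "CENS", "ID"), names(dataset)))
    dataset[[nm]] <- as.integer(dataset[[nm]])
  validate_dataset(dataset)
  dataset
}

#' @rdname read_dataset
#' @param dataset a valid observation data.frame
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, na = "")
  invisible(path)
}
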