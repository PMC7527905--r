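## Readers/writers for instance tables and evaluation reports. Strict CSV
## dialect: comma separator, dot decimal, UTF-8, header required.

#' Read an instance table from CSV
#'
#' Expects columns `subject_id,limb_id,mean,max,osc` plus optional
#' `nihss,mrc,age,sex,diagnosis`. Numeric columns are parsed strictly: a
#' non-numeric cell (e.g. a locale-style decimal comma) is an error naming
#' the first offending row.
#'
#' @param path CSV file.
#' @return an [instance_table()].
#' @export
read_instance_table <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("subject_id", "limb_id", "mean", "max", "osc")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    stop_dg("instance CSV missing column(s): %s",
            paste(missing_cols, collapse = ", "), class = "dg_schema_error")
  num_cols <- intersect(c("mean", "max", "osc", "nihss", "mrc", "age"),
                        names(d))
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% c("", "NA")))
    if (length(bad))
      stop_dg("non-numeric value '%s' in column '%s', row %d",
              d[[col]][bad[1L]], col, bad[1L], class = "dg_parse_error")
    d[[col]] <- v
  }
  for (col in c("nihss", "mrc"))
    if (col %in% names(d)) d[[col]] <- as.integer(d[[col]])
  lv <- limb_level(d$limb_id)  # validates known limb ids
  if (any(is.na(lv) & !is.na(d$limb_id) & d$limb_id != ""))
    stop_dg("unknown limb_id value(s): %s",
            paste(unique(d$limb_id[is.na(lv)]), collapse = ", "),
            class = "dg_parse_error")
  instance_table(d)
}

#' @rdname read_instance_table
#' @param table an [instance_table()] to write.
#' @export
write_instance_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an evaluation or reproduction report as JSON
#'
#' Confusion matrices are emitted as labeled count arrays; ROC curves as
#' FPR/TPR point lists.
#'
#' @param report an `evaluation_report` or the list from
#'   [run_reproduction()].
#' @param path output JSON file.
#' @export
write_report <- function(report, path) {
  to_plain <- function(x) {
    if (inherits(x, "confusion_matrix"))
      return(list(classes = rownames(x),
                  counts = unclass(unname(as.matrix(x)))))
    if (inherits(x, "roc_curve"))
      return(list(fpr = x$fpr, tpr = x$tpr, auc = x$auc))
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(x, to_plain))
    x
  }
  jsonlite::write_json(to_plain(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
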