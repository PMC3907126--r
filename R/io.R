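#' Read response records from CSV
#'
#' Expects a header `subject_id,group,item_1..item_k` (extra columns such as
#' `sex` and `age` are carried through). Cells may use either the canonical
#' category labels (any case, surplus whitespace ignored) or the numeric
#' 0..3 code dialect; an empty cell is a missing answer. Rows containing an
#' unknown category are rejected with their line number and returned via the
#' `rejected` attribute; well-formed rows load normally.
#'
#' @param path CSV file path.
#' @param instrument A `likert_instrument` (determines k and the labels).
#' @return Data.frame of records with canonical labels; attribute
#'   `rejected` is a data.frame of `line` and `message` for dropped rows.
#' @export
read_responses <- function(path, instrument) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  k <- nrow(instrument$items)
  cols <- paste0("item_", seq_len(k))
  missing_cols <- setdiff(c("subject_id", "group", cols), names(raw))
  if (length(missing_cols)) {
    stop("response file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- logical(nrow(raw))
  msg <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    res <- tryCatch({
      for (cn in cols) {
        raw[i, cn] <- normalize_category(raw[i, cn], instrument)
      }
      NA_character_
    }, error = function(e) conditionMessage(e))
    ok[i] <- is.na(res)
    msg[i] <- if (is.na(res)) "" else res
  }
  rejected <- data.frame(line = which(!ok) + 1L, # header is line 1
                         message = msg[!ok], stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    warning(sprintf("%d malformed row(s) rejected (lines %s)",
                    nrow(rejected), paste(rejected$line, collapse = ", ")))
  }
  out <- raw[ok, , drop = FALSE]
  for (cn in cols) out[[cn]][is.na(out[[cn]])] <- ""
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write scored records to CSV
#'
#' @param scores The `scores` data.frame from [batch_score()] (or the
#'   `score_batch` itself).
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  if (inherits(scores, "score_batch")) scores <- scores$scores
  utils::write.csv(scores, path, row.names = FALSE, na = "")
}

#' Write an instrument definition to a YAML config
#' @param instrument A `likert_instrument`.
#' @param path Output path.
#' @export
write_instrument <- function(instrument, path) {
  doc <- list(
    name = instrument$name,
    categories = as.list(instrument$categories),
    forward_scores = as.list(instrument$forward_scores),
    screen_cutoff = instrument$screen_cutoff,
    short_form_cutoff = instrument$short_form_cutoff,
    max_missing = instrument$max_missing,
    items = lapply(seq_len(nrow(instrument$items)), function(i) {
      it <- instrument$items[i, ]
      list(item_id = it$item_id, text = it$text, reversed = it$reversed,
           domain = it$domain, subscale = it$subscale,
           short_form = it$short_form)
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read an instrument definition from a YAML config
#' @param path YAML file path.
#' @return A `likert_instrument`.
#' @export
read_instrument <- function(path) {
  doc <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(doc$items, function(it) {
    data.frame(item_id = it$item_id, text = it$text, reversed = it$reversed,
               domain = it$domain %||% NA_character_,
               subscale = it$subscale %||% NA_character_,
               short_form = it$short_form %||% FALSE,
               stringsAsFactors = FALSE)
  }))
  likert_instrument(
    name = doc$name,
    items = items,
    categories = unlist(doc$categories),
    forward_scores = unlist(doc$forward_scores),
    screen_cutoff = doc$screen_cutoff %||% NA_integer_,
    short_form_cutoff = doc$short_form_cutoff %||% NA_integer_,
    max_missing = doc$max_missing %||% 4L
  )
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
fmt2 <- function(x) formatC(x, format = "f", digits = 2)

#' Render a validation report as text
#'
#' Deterministic plain-text rendering of an [evaluate_final()] report:
#' per-group summary (median and range included), the comparison table
#' (U, z, r), operating points at the cut-offs, the reliability table and
#' the factor table. Rates, AUC and r are shown with 2 decimals, means and
#' SDs with 1; full precision lives in the JSON serialisation
#' ([report_to_json()]).
#'
#' @param report An `evaluation_report`.
#' @return Character vector of lines.
#' @export
render_report <- function(report) {
  out <- c(
    paste0("== Validation report: ", report$instrument, " =="),
    paste0("case group: ", report$case_group,
           "; cut-offs: total >= ", report$cutoffs$total,
           if (!is.na(report$cutoffs$short_form))
             paste0(", short form >= ", report$cutoffs$short_form) else ""),
    "",
    "-- Group summary (valid records) --",
    sprintf("%-12s %5s %12s %16s", "group", "n", "mean +/- SD", "median (range)")
  )
  gs <- report$group_summary
  for (i in seq_len(nrow(gs))) {
    out <- c(out, sprintf("%-12s %5d %12s %16s",
                          gs$group[i], gs$n[i],
                          paste0(fmt1(gs$mean[i]), " +/- ", fmt1(gs$sd[i])),
                          sprintf("%s (%d-%d)", fmt1(gs$median[i]),
                                  gs$min[i], gs$max[i])))
  }
  out <- c(out, sprintf("invalid records excluded: %d", report$n_invalid), "")
  if (!is.null(report$comparisons)) {
    out <- c(out, paste0("-- ", report$case_group, " vs control groups --"),
             sprintf("%-12s %8s %8s %6s %8s", "control", "U", "z", "r", "AUC"))
    cm <- report$comparisons
    for (i in seq_len(nrow(cm))) {
      g <- cm$control_group[i]
      out <- c(out, sprintf("%-12s %8s %8s %6s %8s", g,
                            fmt1(cm$u[i]), fmt1(cm$z[i]), fmt2(cm$r[i]),
                            fmt2(report$roc[[g]]$auc)))
    }
    out <- c(out, "")
  }
  if (!is.null(report$operating_points)) {
    out <- c(out, "-- Operating points --",
             sprintf("%-12s %-11s %6s %12s %12s", "control", "scale",
                     "cutoff", "sensitivity", "specificity"))
    opt <- report$operating_points
    for (i in seq_len(nrow(opt))) {
      out <- c(out, sprintf("%-12s %-11s %6d %12s %12s",
                            opt$control_group[i], opt$scale[i], opt$cutoff[i],
                            fmt2(opt$sensitivity[i]), fmt2(opt$specificity[i])))
    }
    out <- c(out, "")
  }
  out <- c(out, "-- Reliability (Cronbach's alpha) --",
           sprintf("%-12s %-22s %6s", "group", "scale", "alpha"))
  rl <- report$reliability
  for (i in seq_len(nrow(rl))) {
    out <- c(out, sprintf("%-12s %-22s %6s", rl$group[i], rl$scale[i],
                          fmt2(rl$alpha[i])))
  }
  out <- c(out, "")
  if (!is.null(report$factors)) {
    f <- report$factors
    out <- c(out,
             sprintf("-- Factor solution (excluding %s): %d factors --",
                     report$case_group, f$n_factors),
             paste0("variance explained: ",
                    paste(sprintf("%.1f%%", 100 * f$variance_explained),
                          collapse = ", ")))
    L <- if (!is.null(f$rotated)) f$rotated else f$loadings
    hdr <- sprintf("%-10s %s", "item", paste(sprintf("%6s", colnames(f$loadings)),
                                             collapse = " "))
    out <- c(out, "rotated loadings:", hdr)
    for (i in seq_len(nrow(L))) {
      out <- c(out, sprintf("%-10s %s", rownames(L)[i],
                            paste(sprintf("%6s", fmt2(L[i, ])), collapse = " ")))
    }
  }
  out
}

#' Serialise a validation report to JSON
#' @param report An `evaluation_report`.
#' @param path Optional path; when given, the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
report_to_json <- function(report, path = NULL) {
  ser <- unclass(report)
  ser$roc <- lapply(ser$roc, unclass)
  if (!is.null(ser$factors)) {
    ser$factors <- unclass(ser$factors)
    ser$factors$item_names <- rownames(ser$factors$loadings)
  }
  js <- jsonlite::toJSON(ser, digits = NA, na = "null", auto_unbox = TRUE,
                         matrix = "rowmajor")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a validation report back from JSON
#' @param path JSON file path (or a JSON string).
#' @return An `evaluation_report` whose rendering is byte-identical to the
#'   original's.
#' @export
report_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  x$cutoffs <- list(total = x$cutoffs$total,
                    short_form = x$cutoffs$short_form %||% NA_integer_)
  x$roc <- lapply(x$roc, function(r) structure(r, class = "roc_result"))
  if (!is.null(x$factors)) {
    f <- x$factors
    fix_mat <- function(mm) {
      mm <- as.matrix(mm)
      dimnames(mm) <- list(f$item_names, paste0("F", seq_len(ncol(mm))))
      mm
    }
    f$loadings <- fix_mat(f$loadings)
    if (!is.null(f$rotated)) f$rotated <- fix_mat(f$rotated)
    f$communalities <- stats::setNames(unlist(f$communalities), f$item_names)
    f$item_names <- NULL
    x$factors <- structure(f, class = "factor_solution")
  }
  structure(x, class = "evaluation_report")
}
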