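#' Likert instrument definitions
#'
#' A `likert_instrument` bundles everything needed to score a fixed-order
#' Likert questionnaire: the item table (text, reverse flags, domain and
#' subscale assignments, short-form membership), the response categories and
#' their forward scores, and the screening cut-offs and record-validity
#' parameters.
#'
#' @param name Instrument name (single string).
#' @param items A data.frame with columns `item_id` (1..k, contiguous),
#'   `text`, `reversed` (logical), `domain` (original domain label),
#'   `subscale` (subscale label or NA), `short_form` (logical).
#' @param categories Character vector of the ordered response labels,
#'   lowest-scoring first.
#' @param forward_scores Named integer vector mapping each category label to
#'   its forward score; must be a bijection onto `0:(length(categories)-1)`.
#' @param screen_cutoff Total score at or above which a record screens
#'   positive.
#' @param short_form_cutoff Short-form score at or above which a record
#'   screens positive on the short form (NA if the instrument has none).
#' @param max_missing Maximum number of missing items tolerated before a
#'   record is invalid.
#'
#' @return An object of class `likert_instrument`.
#' @export
likert_instrument <- function(name, items, categories, forward_scores,
                              screen_cutoff, short_form_cutoff = NA_integer_,
                              max_missing = 4L) {
  stopifnot(is.character(name), length(name) == 1L)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  required <- c("item_id", "text", "reversed", "domain", "subscale", "short_form")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols)) {
    stop("items is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  items$item_id <- as.integer(items$item_id)
  if (!identical(items$item_id, seq_len(nrow(items)))) {
    stop("item ids must be unique and contiguous from 1, in order")
  }
  if (!is.logical(items$reversed) || anyNA(items$reversed)) {
    stop("items$reversed must be logical without NA")
  }
  forward_scores <- vapply(forward_scores, as.integer, integer(1))
  if (!setequal(names(forward_scores), categories) ||
      !setequal(unname(forward_scores), seq_along(categories) - 1L)) {
    stop("forward_scores must be a bijection from the categories onto 0..",
         length(categories) - 1L)
  }
  obj <- structure(
    list(
      name = name,
      items = items,
      categories = categories,
      forward_scores = forward_scores[categories],
      screen_cutoff = as.integer(screen_cutoff),
      short_form_cutoff = as.integer(short_form_cutoff),
      max_missing = as.integer(max_missing)
    ),
    class = "likert_instrument"
  )
  obj
}

#' @export
print.likert_instrument <- function(x, ...) {
  cat("<likert_instrument> ", x$name, "\n", sep = "")
  cat("  items:        ", nrow(x$items),
      " (", sum(x$items$reversed), " reversed)\n", sep = "")
  cat("  categories:   ", paste(x$categories, collapse = " | "), "\n", sep = "")
  cat("  max total:    ", max_total(x), "\n", sep = "")
  cat("  screen >=     ", x$screen_cutoff, sep = "")
  if (!is.na(x$short_form_cutoff)) {
    cat("; short form >= ", x$short_form_cutoff, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Maximum attainable total score
#' @param instrument A `likert_instrument`.
#' @return Integer, `(number of categories - 1) * number of items`.
#' @export
max_total <- function(instrument) {
  (length(instrument$categories) - 1L) * nrow(instrument$items)
}

#' Item ids belonging to the short form
#' @param instrument A `likert_instrument`.
#' @export
short_form_items <- function(instrument) {
  instrument$items$item_id[instrument$items$short_form]
}

# Canonical RAADS-14 response categories, lowest score first.
raads_categories <- c(
  "never true",
  "true only when I was younger than 16",
  "true only now",
  "true now and when I was young"
)

raads14_item_table <- function() {
  text <- c(
    "It is difficult for me to understand how other people are feeling when we are talking",
    "Some ordinary textures that do not bother others feel very offensive when they touch my skin",
    "It is very difficult for me to work and function in groups",
    "It is difficult to figure out what other people expect of me",
    "I often don't know how to act in social situations",
    "I can chat and make small talk with people",
    "When I feel overwhelmed by my senses, I have to isolate myself to shut them down",
    "How to make friends and socialize is a mystery to me",
    "When talking to someone, I have a hard time telling when it is my turn to talk or to listen",
    "Sometimes I have to cover my ears to block out painful noises (like vacuum cleaners or people talking too much or too loudly)",
    "It can be very hard to read someone's face, hand, and body movements when we are talking",
    "I focus on details rather than the overall idea",
    "I take things too literally, so I often miss what people are trying to say",
    "I get extremely upset when the way I like to do things is suddenly changed"
  )
  domain <- c(
    "social_relatedness",   # 1
    "sensory_motor",        # 2
    "social_relatedness",   # 3
    "social_relatedness",   # 4
    "social_relatedness",   # 5
    "language",             # 6
    "sensory_motor",        # 7
    "social_relatedness",   # 8
    "social_relatedness",   # 9
    "sensory_motor",        # 10
    "social_relatedness",   # 11
    "circumscribed_interests", # 12
    "language",             # 13
    "circumscribed_interests"  # 14
  )
  subscale <- c(
    "mentalizing_deficits", # 1
    "sensory_reactivity",   # 2
    "social_anxiety",       # 3
    "mentalizing_deficits", # 4
    "social_anxiety",       # 5
    "social_anxiety",       # 6
    "sensory_reactivity",   # 7
    "social_anxiety",       # 8
    "mentalizing_deficits", # 9
    "sensory_reactivity",   # 10
    "mentalizing_deficits", # 11
    "mentalizing_deficits", # 12
    "mentalizing_deficits", # 13
    "mentalizing_deficits"  # 14
  )
  data.frame(
    item_id = 1:14,
    text = text,
    reversed = seq_len(14) == 6L,
    domain = domain,
    subscale = subscale,
    short_form = seq_len(14) <= 5L,
    stringsAsFactors = FALSE
  )
}

#' The bundled RAADS-14 Screen instrument
#'
#' The RAADS-14 Screen is a 14-item self-report questionnaire for screening
#' adults for autism spectrum disorder in psychiatric settings, abridged from
#' the 80-item RAADS-R. Each item is answered on a four-point duration scale
#' scored 0-3 ("never true" up to "true now and when I was young"); item 6
#' ("I can chat and make small talk with people") is reverse-scored. Items
#' partition into three subscales: mentalizing deficits (7 items: 1, 4, 9,
#' 11, 12, 13, 14), social anxiety (4 items: 3, 5, 6, 8) and sensory
#' reactivity (3 items: 2, 7, 10). The total score ranges 0-42 with a screen
#' cut-off of 14; items 1-5 form a rapid short form scored 0-15 with a
#' cut-off of 4. Records with more than 4 missing items, or with every item
#' checked identically (which ignores the reversed item), are invalid.
#'
#' @return A `likert_instrument` for the RAADS-14 Screen.
#' @examples
#' inst <- raads14_instrument()
#' max_total(inst) # 42
#' @export
raads14_instrument <- function() {
  likert_instrument(
    name = "RAADS-14 Screen",
    items = raads14_item_table(),
    categories = raads_categories,
    forward_scores = stats::setNames(0:3, raads_categories),
    screen_cutoff = 14L,
    short_form_cutoff = 4L,
    max_missing = 4L
  )
}

# Normalize a raw answer to a canonical category label.
# Matching is case-insensitive after whitespace collapsing; the numeric
# dialect "0".."k-1" is accepted and mapped through forward scores.
# Returns NA_character_ for missing, raises a format error for unknown labels.
normalize_category <- function(x, instrument) {
  squeeze <- function(s) tolower(gsub("\\s+", " ", trimws(s)))
  canon <- instrument$categories
  lookup <- stats::setNames(canon, squeeze(canon))
  scores <- instrument$forward_scores
  by_code <- stats::setNames(names(scores), as.character(unname(scores)))
  out <- rep(NA_character_, length(x))
  x <- as.character(x)
  ok_na <- is.na(x) | trimws(x) == ""
  key <- squeeze(x[!ok_na])
  hit <- lookup[key]
  code_hit <- by_code[key]
  hit[is.na(hit)] <- code_hit[is.na(hit)]
  if (anyNA(hit)) {
    bad <- unique(x[!ok_na][is.na(hit)])
    stop("unknown response category label(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  out[!ok_na] <- hit
  out
}

#' Score a single item response
#'
#' Forward items take the category's forward score; reversed items take the
#' complement `max_score - forward`, so that on the RAADS-14 answering
#' "never true" to the reversed item scores 3. Missing answers score NA here;
#' record-level scoring decides how missingness enters the total.
#'
#' @param category Response label (canonical, any-case, or numeric-code
#'   dialect), or NA/"" for missing.
#' @param reversed Is the item reverse-formulated?
#' @param instrument A `likert_instrument` supplying categories and scores.
#' @return Integer score in `0:(n_categories-1)`, or NA for missing.
#' @examples
#' inst <- raads14_instrument()
#' score_item("true now and when I was young", FALSE, inst) # 3
#' score_item("never true", TRUE, inst)                     # 3
#' @export
score_item <- function(category, reversed, instrument) {
  canon <- normalize_category(category, instrument)
  fwd <- unname(instrument$forward_scores[canon])
  top <- length(instrument$categories) - 1L
  if (isTRUE(reversed)) fwd <- top - fwd
  as.integer(fwd)
}

# Internal: cohort data.frame -> integer score matrix (subjects x items),
# NA for missing. Cohort columns item_1..item_k hold raw categories.
response_score_matrix <- function(cohort, instrument) {
  k <- nrow(instrument$items)
  cols <- paste0("item_", seq_len(k))
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols)) {
    stop("response data lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  top <- length(instrument$categories) - 1L
  m <- matrix(NA_integer_, nrow(cohort), k)
  for (j in seq_len(k)) {
    canon <- normalize_category(cohort[[cols[j]]], instrument)
    fwd <- unname(instrument$forward_scores[canon])
    if (instrument$items$reversed[j]) fwd <- top - fwd
    m[, j] <- as.integer(fwd)
  }
  colnames(m) <- cols
  m
}

#' Check a record's validity
#'
#' Applies the instrument's record-exclusion rules: more than `max_missing`
#' missing items invalidates a record (`too_many_missing`); answering every
#' item with the same category invalidates it (`straight_line`) provided the
#' instrument contains at least one reversed item (otherwise an extreme but
#' attentive responder could legitimately produce the pattern) and at least
#' two items were answered. Missing answers are ignored when checking for
#' straight-lining. When both rules fire, `too_many_missing` is reported.
#'
#' @param record A one-row data.frame or named list with `item_1..item_k`
#'   entries (raw categories, NA/"" for missing).
#' @param instrument A `likert_instrument`.
#' @return A list with `valid` (logical), `reason` (NA, "too_many_missing" or
#'   "straight_line") and `n_missing`.
#' @export
validate_record <- function(record, instrument) {
  cohort <- as.data.frame(record, stringsAsFactors = FALSE)
  k <- nrow(instrument$items)
  cols <- paste0("item_", seq_len(k))
  raw <- vapply(cols, function(cn) as.character(cohort[[cn]][1]), character(1))
  canon <- normalize_category(raw, instrument)
  n_missing <- sum(is.na(canon))
  answered <- canon[!is.na(canon)]
  if (n_missing > instrument$max_missing) {
    return(list(valid = FALSE, reason = "too_many_missing", n_missing = n_missing))
  }
  has_reversed <- any(instrument$items$reversed)
  if (has_reversed && length(answered) >= 2L &&
      length(unique(answered)) == 1L) {
    return(list(valid = FALSE, reason = "straight_line", n_missing = n_missing))
  }
  list(valid = TRUE, reason = NA_character_, n_missing = n_missing)
}

#' Score one response record
#'
#' Sums item scores into the total, subscale and short-form scores and
#' applies the screening cut-offs. Missing items (up to the validity limit)
#' score zero by default, a conservative choice reported via `n_missing`;
#' `missing = "prorate"` instead scales each sum by
#' `n_items / n_answered` within the scale and rounds to the nearest integer.
#'
#' @param record One-row data.frame or named list with `item_1..item_k`.
#' @param instrument A `likert_instrument`.
#' @param missing Either "zero" (default) or "prorate".
#' @return A list: `subject_id`, `group`, `total`, per-subscale scores,
#'   `short_form`, `screen_positive`, `short_form_positive`, `n_missing`,
#'   `valid`, `invalid_reason`.
#' @examples
#' inst <- raads14_instrument()
#' rec <- c(list(subject_id = "s1", group = "ASD"),
#'          stats::setNames(as.list(rep("true now and when I was young", 14)),
#'                          paste0("item_", 1:14)))
#' score_record(rec, inst)$total # 39: item 6 is reversed
#' @export
score_record <- function(record, instrument, missing = c("zero", "prorate")) {
  missing <- match.arg(missing)
  cohort <- as.data.frame(record, stringsAsFactors = FALSE)
  scores <- batch_score(cohort, instrument, missing = missing)
  as.list(scores$scores[1, ])
}

# Sum a score vector over given item ids under the missing rule.
sum_scale <- function(score_row, ids, missing) {
  s <- score_row[ids]
  if (!anyNA(s)) return(sum(s))
  if (all(is.na(s))) return(0L)
  raw <- sum(s, na.rm = TRUE)
  if (missing == "zero") {
    as.integer(raw)
  } else {
    as.integer(round(raw * length(ids) / sum(!is.na(s))))
  }
}

#' Score a cohort of response records
#'
#' Scores every record, applies the validity rules, and summarises valid
#' records per group (n, mean, SD, median, range of the total score).
#'
#' @param cohort Data.frame with columns `subject_id`, `group`,
#'   `item_1..item_k` (raw categories; NA or "" for missing).
#' @param instrument A `likert_instrument`.
#' @param missing Missing-item rule passed to scoring ("zero" or "prorate").
#' @return A list of class `score_batch` with elements `scores` (one row per
#'   record, screen flags and validity included), `summary` (per-group
#'   statistics over valid records) and `invalid` (subject ids with reasons).
#' @export
batch_score <- function(cohort, instrument, missing = c("zero", "prorate")) {
  missing <- match.arg(missing)
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  if (is.null(cohort$subject_id)) cohort$subject_id <- as.character(seq_len(nrow(cohort)))
  if (is.null(cohort$group)) cohort$group <- NA_character_
  m <- response_score_matrix(cohort, instrument)
  items <- instrument$items
  sub_levels <- unique(items$subscale[!is.na(items$subscale)])
  sf_ids <- short_form_items(instrument)

  n <- nrow(cohort)
  n_missing <- rowSums(is.na(m))
  total <- integer(n)
  sub_scores <- matrix(0L, n, length(sub_levels),
                       dimnames = list(NULL, sub_levels))
  short_form <- integer(n)
  valid <- logical(n)
  reason <- rep(NA_character_, n)
  top <- length(instrument$categories) - 1L

  for (i in seq_len(n)) {
    row <- m[i, ]
    for (s in sub_levels) {
      ids <- items$item_id[!is.na(items$subscale) & items$subscale == s]
      sub_scores[i, s] <- sum_scale(row, ids, missing)
    }
    total[i] <- as.integer(sum(sub_scores[i, ]))
    extra <- setdiff(items$item_id, items$item_id[!is.na(items$subscale)])
    if (length(extra)) total[i] <- total[i] + sum_scale(row, extra, missing)
    short_form[i] <- if (length(sf_ids)) sum_scale(row, sf_ids, missing) else NA_integer_
    v <- validate_record(cohort[i, , drop = FALSE], instrument)
    valid[i] <- v$valid
    reason[i] <- v$reason
  }

  scores <- data.frame(
    subject_id = as.character(cohort$subject_id),
    group = as.character(cohort$group),
    total = total,
    stringsAsFactors = FALSE
  )
  for (s in sub_levels) scores[[s]] <- sub_scores[, s]
  scores$short_form <- short_form
  scores$screen_positive <- total >= instrument$screen_cutoff
  scores$short_form_positive <- if (!is.na(instrument$short_form_cutoff)) {
    short_form >= instrument$short_form_cutoff
  } else NA
  scores$n_missing <- n_missing
  scores$valid <- valid
  scores$invalid_reason <- reason

  ok <- scores[scores$valid, , drop = FALSE]
  if (nrow(ok)) {
    summary <- do.call(rbind, lapply(split(ok, ok$group), function(g) {
      data.frame(
        group = g$group[1],
        n = nrow(g),
        mean = mean(g$total),
        sd = stats::sd(g$total),
        median = stats::median(g$total),
        min = min(g$total),
        max = max(g$total),
        stringsAsFactors = FALSE
      )
    }))
    rownames(summary) <- NULL
  } else {
    summary <- data.frame(group = character(), n = integer(), mean = numeric(),
                          sd = numeric(), median = numeric(), min = numeric(),
                          max = numeric(), stringsAsFactors = FALSE)
  }
  invalid <- scores[!scores$valid, c("subject_id", "group", "invalid_reason")]
  rownames(invalid) <- NULL
  structure(list(scores = scores, summary = summary, invalid = invalid),
            class = "score_batch")
}

#' @export
print.score_batch <- function(x, ...) {
  cat("<score_batch> ", nrow(x$scores), " records (",
      nrow(x$invalid), " invalid)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
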