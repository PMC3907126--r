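# Shared fixture builders. Everything is generated in code at test time.

raads_cats <- c("never true",
                "true only when I was younger than 16",
                "true only now",
                "true now and when I was young")

# A record answering every item with the category scoring `code` forward.
uniform_record <- function(code, instrument = raads14_instrument(),
                           group = "ASD") {
  k <- nrow(instrument$items)
  rec <- c(list(subject_id = "s1", group = group),
           stats::setNames(as.list(rep(raads_cats[code + 1], k)),
                           paste0("item_", seq_len(k))))
  rec
}

# A record from a vector of forward scores (NA = missing). Reversed items
# get the complementary category so the scored value equals the given score.
record_from_scores <- function(scores, instrument = raads14_instrument(),
                               group = "ASD", id = "s1") {
  k <- nrow(instrument$items)
  stopifnot(length(scores) == k)
  lab <- character(k)
  for (j in seq_len(k)) {
    if (is.na(scores[j])) { lab[j] <- ""; next }
    code <- if (instrument$items$reversed[j]) 3 - scores[j] else scores[j]
    lab[j] <- instrument$categories[code + 1]
  }
  c(list(subject_id = id, group = group),
    stats::setNames(as.list(lab), paste0("item_", seq_len(k))))
}

cohort_from_score_matrix <- function(m, groups,
                                     instrument = raads14_instrument()) {
  rows <- lapply(seq_len(nrow(m)), function(i) {
    as.data.frame(record_from_scores(m[i, ], instrument,
                                     group = groups[i],
                                     id = sprintf("s%04d", i)),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Generic item bank instrument: n items over the given domain labels,
# subscales assigned cyclically, no reversed items.
bank_instrument <- function(domains, subscales = NULL, name = "bank") {
  n <- length(domains)
  if (is.null(subscales)) {
    subscales <- rep(c("mentalizing_deficits", "social_anxiety",
                       "sensory_reactivity"), length.out = n)
  }
  items <- data.frame(
    item_id = seq_len(n),
    text = sprintf("bank item %d", seq_len(n)),
    reversed = FALSE,
    domain = domains,
    subscale = subscales,
    short_form = FALSE,
    stringsAsFactors = FALSE
  )
  likert_instrument(name, items, raads_cats,
                    stats::setNames(0:3, raads_cats),
                    screen_cutoff = NA_integer_)
}

# Simulation item models for a bank: informative items follow the standard
# graded-response model, null items (signal 0) are pure noise.
bank_sim_items <- function(instrument, null_ids = integer(0),
                           discrimination = 1.7) {
  n <- nrow(instrument$items)
  base <- seq(-0.3, 1.3, length.out = n)
  sim_items(
    item_id = seq_len(n),
    discrimination = discrimination,
    t1 = base, t2 = base + 0.3, t3 = base + 0.6,
    subscale = instrument$items$subscale,
    loading = 0.2,
    reversed = instrument$items$reversed,
    signal = ifelse(seq_len(n) %in% null_ids, 0, 1)
  )
}

# Data from an exact linear factor model: x = F L' + e, standardised scale.
factor_model_data <- function(n, loading_blocks, loading = 0.7) {
  k <- sum(loading_blocks)
  nf <- length(loading_blocks)
  f <- matrix(stats::rnorm(n * nf), n, nf)
  L <- matrix(0, k, nf)
  start <- 1
  for (j in seq_len(nf)) {
    L[start:(start + loading_blocks[j] - 1), j] <- loading
    start <- start + loading_blocks[j]
  }
  x <- f %*% t(L) + matrix(stats::rnorm(n * k), n, k) %*%
    diag(sqrt(1 - loading^2), k)
  list(x = x, L = L)
}

# Exhaustive cut-off search: the reference oracle for select_cutoff.
brute_force_cutoff <- function(scores, is_case, min_sens, rule = "highest") {
  cases <- scores[is_case]
  cand <- seq(floor(min(scores)), ceiling(max(scores)) + 1)
  qual <- cand[vapply(cand, function(t) mean(cases >= t), numeric(1)) >= min_sens]
  as.integer(if (rule == "highest") max(qual) else min(qual))
}
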