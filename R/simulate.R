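#' Item models for the graded-response generator
#'
#' Each simulated item follows a cumulative-logit graded-response model:
#' given a subject's item-level latent trait theta, the probability of
#' scoring at least k is `plogis(discrimination * (theta - threshold_k))`
#' for the three ordered thresholds. The subject's latent input to item j is
#' `signal * (G + gamma * F_s(j))` where G is the general trait (group mean
#' and SD from the group profile), `F_s(j)` the item's subscale factor
#' (standardised, correlated `subscale_cor` across subscales) and
#' `gamma = trait_sd * sqrt(loading / (1 - loading))`, so `loading` is the
#' share of within-group latent variance contributed by the subscale factor.
#' Items with `signal = 0` replace the structural part with unit white noise
#' and so carry no group or factor information (planted null items).
#'
#' @param item_id Integer ids.
#' @param discrimination Positive slopes.
#' @param t1,t2,t3 Strictly increasing category thresholds.
#' @param subscale Subscale label per item (factor assignment).
#' @param loading Subscale-factor variance share in `[0, 1)`.
#' @param reversed Reverse-formulated flag: the emitted category is the one
#'   whose forward score is the complement of the model-drawn score.
#' @param signal Structural-signal weight in `[0, 1]` (1 = standard model).
#' @return A data.frame of item models.
#' @export
sim_items <- function(item_id, discrimination, t1, t2, t3, subscale,
                      loading = 0.3, reversed = FALSE, signal = 1) {
  df <- data.frame(item_id = as.integer(item_id),
                   discrimination = discrimination,
                   t1 = t1, t2 = t2, t3 = t3,
                   subscale = subscale,
                   loading = loading, reversed = reversed, signal = signal,
                   stringsAsFactors = FALSE)
  if (any(df$discrimination <= 0)) stop("discrimination must be positive")
  if (any(!(df$t1 < df$t2 & df$t2 < df$t3))) {
    stop("thresholds must be strictly increasing per item")
  }
  if (any(df$loading < 0 | df$loading >= 1)) stop("loading must be in [0, 1)")
  df
}

# Default RAADS-14 item models. Threshold locations are spread across the
# latent range (a fixed permutation decorrelates difficulty from subscale);
# the two intermediate duration categories occupy narrow bands (gaps 0.3)
# so extreme categories dominate, as in short duration-scale data.
raads14_sim_items <- function() {
  base_order <- c(7, 1, 10, 4, 13, 2, 8, 12, 5, 14, 3, 11, 6, 9)
  base <- seq(-0.4, 1.6, length.out = 14)[order(base_order)]
  items <- raads14_item_table()
  sim_items(
    item_id = items$item_id,
    discrimination = rep(c(1.6, 1.9, 1.4, 1.7), length.out = 14),
    t1 = base, t2 = base + 0.3, t3 = base + 0.6,
    subscale = items$subscale,
    loading = 0.3,
    reversed = items$reversed
  )
}

#' Calibrated group trait profiles for the RAADS-14 generator
#'
#' Latent-trait means and SDs for the four diagnostic groups, frozen from
#' [calibrate_profiles()] run against the published phase-III total-score
#' moments (ASD 30.8 +/- 8.6, ADHD 15.4 +/- 9.3, other psychiatric
#' disorders 12.6 +/- 9.3, non-psychiatric 3.9 +/- 4.6). The default group
#' sizes are the phase-III study sizes (the non-psychiatric sample is the
#' phase-II one, the only phase in which it was collected).
#'
#' @return Data.frame with `group`, `trait_mean`, `trait_sd`, `n`,
#'   `target_mean`, `target_sd`.
#' @export
default_group_profiles <- function() {
  data.frame(
    group = c("ASD", "ADHD", "OPD", "NONPSYCH"),
    trait_mean = c(1.83, 0.38, 0.07, -1.05),
    trait_sd = c(0.73, 0.69, 0.79, 0.65),
    n = c(77L, 301L, 69L, 590L),
    target_mean = c(30.8, 15.4, 12.6, 3.9),
    target_sd = c(8.6, 9.3, 9.3, 4.6),
    stringsAsFactors = FALSE
  )
}

#' Build a simulation configuration
#'
#' @param profiles Data.frame of group profiles (`group`, `trait_mean`,
#'   `trait_sd`, `n`).
#' @param items Item-model data.frame from [sim_items()].
#' @param subscale_cor Correlation between subscale factors (default 0.5).
#' @param straight_line_rate Fraction of records overwritten with a single
#'   repeated category (inattentive responders).
#' @param missing_rate Per-item probability of a missing answer.
#' @param categories Ordered response labels, lowest score first.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(profiles, items, subscale_cor = 0.5,
                       straight_line_rate = 0.025, missing_rate = 0.003,
                       categories = raads_categories) {
  stopifnot(all(c("group", "trait_mean", "trait_sd", "n") %in% names(profiles)))
  if (any(profiles$trait_sd <= 0)) stop("trait_sd must be positive")
  if (any(profiles$n < 1)) stop("group sizes must be >= 1")
  rates <- c(straight_line_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("contamination rates must be in [0, 1]")
  if (abs(subscale_cor) > 1) stop("subscale_cor must be in [-1, 1]")
  structure(
    list(profiles = profiles, items = items, subscale_cor = subscale_cor,
         straight_line_rate = straight_line_rate,
         missing_rate = missing_rate, categories = categories),
    class = "sim_config"
  )
}

#' Default calibrated RAADS-14 simulation configuration
#'
#' @param n_per_group Optional named vector overriding group sizes, e.g.
#'   `c(ASD = 500)`.
#' @param straight_line_rate,missing_rate Contamination rates (defaults
#'   0.025 and 0.003, of the order of the exclusion counts observed in
#'   clinical questionnaire collections).
#' @return A `sim_config`.
#' @export
raads14_sim_config <- function(n_per_group = NULL,
                               straight_line_rate = 0.025,
                               missing_rate = 0.003) {
  profiles <- default_group_profiles()
  if (!is.null(n_per_group)) {
    idx <- match(names(n_per_group), profiles$group)
    if (anyNA(idx)) stop("unknown group(s): ",
                         paste(names(n_per_group)[is.na(idx)], collapse = ", "))
    profiles$n[idx] <- as.integer(n_per_group)
  }
  sim_config(profiles, raads14_sim_items(),
             straight_line_rate = straight_line_rate,
             missing_rate = missing_rate)
}

# Draw the subjects x items integer score matrix for one group under the
# graded-response model. latent draws are taken from the current RNG stream.
draw_group_scores <- function(n, trait_mean, trait_sd, items, subscale_cor) {
  k <- nrow(items)
  subs <- unique(items$subscale)
  ns <- length(subs)
  G <- trait_mean + trait_sd * stats::rnorm(n)
  if (ns > 1) {
    Sigma <- matrix(subscale_cor, ns, ns); diag(Sigma) <- 1
    Fm <- matrix(stats::rnorm(n * ns), n, ns) %*% chol(Sigma)
  } else {
    Fm <- matrix(stats::rnorm(n), n, 1)
  }
  colnames(Fm) <- subs
  eps <- matrix(stats::rnorm(n * k), n, k)
  u <- matrix(stats::runif(n * k), n, k)
  scores <- matrix(0L, n, k)
  for (j in seq_len(k)) {
    it <- items[j, ]
    gamma <- trait_sd * sqrt(it$loading / (1 - it$loading))
    theta <- it$signal * (G + gamma * Fm[, it$subscale]) +
      sqrt(max(0, 1 - it$signal^2)) * eps[, j]
    p1 <- stats::plogis(it$discrimination * (theta - it$t1))
    p2 <- stats::plogis(it$discrimination * (theta - it$t2))
    p3 <- stats::plogis(it$discrimination * (theta - it$t3))
    scores[, j] <- (u[, j] <= p1) + (u[, j] <= p2) + (u[, j] <= p3)
  }
  scores
}

#' Generate a synthetic diagnostic cohort
#'
#' Draws item-level Likert responses for every group in the configuration
#' under the graded-response model, emits category labels (reversed items
#' emit the complementary category so that instrument scoring recovers the
#' model-drawn score), then applies contamination: straight-lining records
#' (all items set to one repeated category) and per-item missingness.
#' Fully reproducible from `seed`.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @return Data.frame with `subject_id`, `group`, `item_1..item_k` holding
#'   category labels ("" for missing).
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  items <- config$items
  k <- nrow(items)
  cats <- config$categories
  top <- length(cats) - 1L
  out <- vector("list", nrow(config$profiles))
  for (g in seq_len(nrow(config$profiles))) {
    pr <- config$profiles[g, ]
    sc <- draw_group_scores(pr$n, pr$trait_mean, pr$trait_sd, items,
                            config$subscale_cor)
    # contamination: straight-liners pick one category for every item
    sl <- stats::runif(pr$n) < config$straight_line_rate
    sl_cat <- sample.int(top + 1L, pr$n, replace = TRUE) - 1L
    miss <- matrix(stats::runif(pr$n * k) < config$missing_rate, pr$n, k)
    lab <- matrix("", pr$n, k)
    for (j in seq_len(k)) {
      code <- sc[, j]
      if (isTRUE(items$reversed[j])) code <- top - code
      code[sl] <- sl_cat[sl] # straight-liners: raw category, no reversal logic
      lab[, j] <- cats[code + 1L]
      lab[miss[, j], j] <- ""
    }
    df <- data.frame(
      subject_id = sprintf("%s_%04d", pr$group, seq_len(pr$n)),
      group = pr$group,
      stringsAsFactors = FALSE
    )
    for (j in seq_len(k)) df[[paste0("item_", j)]] <- lab[, j]
    out[[g]] <- df
  }
  do.call(rbind, out)
}

#' Calibrate group trait profiles against target score moments
#'
#' Deterministic moment-matching of the generator: for each group, a coarse
#' grid over (trait mean, trait SD) followed by a local refinement minimises
#' the squared distance between simulated total-score mean/SD and the
#' targets. Common random numbers (a fixed internal stream per evaluation
#' size) make the search deterministic and the objective smooth.
#'
#' @param targets Data.frame with `group`, `target_mean`, `target_sd`.
#' @param items Item models (default the RAADS-14 set).
#' @param subscale_cor Subscale factor correlation.
#' @param n Monte Carlo subjects per objective evaluation.
#' @param seed Seed for the common-random-number stream.
#' @return Data.frame `group`, `trait_mean`, `trait_sd` plus the achieved
#'   `mean` and `sd`.
#' @export
calibrate_profiles <- function(targets, items = raads14_sim_items(),
                               subscale_cor = 0.5, n = 4000L,
                               seed = 104729L) {
  stopifnot(all(c("group", "target_mean", "target_sd") %in% names(targets)))
  evaluate <- function(mu, sdv) {
    set.seed(as.integer(seed))
    sc <- draw_group_scores(n, mu, sdv, items, subscale_cor)
    tot <- rowSums(sc)
    c(mean = mean(tot), sd = stats::sd(tot))
  }
  fit_one <- function(tm, ts) {
    best <- NULL
    search <- function(mus, sds) {
      for (mu in mus) for (sdv in sds) {
        mo <- evaluate(mu, sdv)
        obj <- (mo["mean"] - tm)^2 + (mo["sd"] - ts)^2
        if (is.null(best) || obj < best$obj) {
          best <<- list(mu = mu, sd = sdv, obj = obj, mo = mo)
        }
      }
    }
    search(seq(-3, 3, by = 0.25), seq(0.4, 1.6, by = 0.2))
    search(seq(best$mu - 0.25, best$mu + 0.25, by = 0.05),
           seq(max(0.1, best$sd - 0.2), best$sd + 0.2, by = 0.04))
    search(seq(best$mu - 0.05, best$mu + 0.05, by = 0.01),
           seq(max(0.05, best$sd - 0.04), best$sd + 0.04, by = 0.01))
    best
  }
  res <- lapply(seq_len(nrow(targets)), function(i) {
    b <- fit_one(targets$target_mean[i], targets$target_sd[i])
    mu <- round(b$mu, 2); sdv <- round(b$sd, 2)
    mo <- evaluate(mu, sdv)
    data.frame(group = targets$group[i],
               trait_mean = mu, trait_sd = sdv,
               mean = unname(mo["mean"]), sd = unname(mo["sd"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Sample skewness (bias-uncorrected moment estimator).
sample_skewness <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  mean((x - m)^3) / s^3
}
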