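#' Phase 1: quota-constrained discrimination-index item selection
#'
#' Abridges an item bank by keeping, within each original domain, the items
#' with the highest discrimination index (point-biserial case/control effect
#' size times corrected item-total correlation within the domain), in
#' numbers fixed by per-domain quotas so the short form keeps the bank's
#' domain proportions. Ties resolve to the lower item id.
#'
#' @param cohort Response data.frame (`subject_id`, `group`, `item_*`).
#' @param bank A `likert_instrument` describing the full item bank (the
#'   `domain` column drives the quotas).
#' @param quotas Named integer vector, domain -> number of items to keep.
#' @param case_group,control_group Group labels contrasted by the index.
#' @return A list: `selected` (item ids, ascending), `table` (per-item
#'   `domain`, `r_pb`, `r_it`, `index`, `rank_in_domain`, `selected`).
#' @export
phase1_select <- function(cohort, bank, quotas,
                          case_group = "ASD", control_group = "NONPSYCH") {
  items <- bank$items
  if (anyNA(items$domain)) stop("every bank item needs a domain label")
  for (d in names(quotas)) {
    size <- sum(items$domain == d)
    if (quotas[[d]] > size) {
      stop(sprintf("quota for domain '%s' (%d) exceeds its size (%d)",
                   d, quotas[[d]], size), call. = FALSE)
    }
  }
  keep <- cohort$group %in% c(case_group, control_group)
  cohort <- cohort[keep, , drop = FALSE]
  if (!any(cohort$group == case_group) || !any(cohort$group == control_group)) {
    stop("both case and control groups must be present", call. = FALSE)
  }
  m <- response_score_matrix(cohort, bank)
  m[is.na(m)] <- 0L
  is_case <- cohort$group == case_group

  tab <- items[, c("item_id", "domain")]
  tab$r_pb <- NA_real_; tab$r_it <- NA_real_; tab$index <- NA_real_
  for (d in unique(items$domain)) {
    ids <- items$item_id[items$domain == d]
    dm <- m[, ids, drop = FALSE]
    for (pos in seq_along(ids)) {
      ds <- discrimination_index(dm[, pos], is_case, dm, pos)
      row <- tab$item_id == ids[pos]
      tab$r_pb[row] <- ds$r_pb
      tab$r_it[row] <- ds$r_it
      tab$index[row] <- ds$index
    }
  }
  tab$rank_in_domain <- NA_integer_
  for (d in unique(tab$domain)) {
    i <- which(tab$domain == d)
    o <- order(-tab$index[i], tab$item_id[i], na.last = TRUE)
    tab$rank_in_domain[i[o]] <- seq_along(i)
  }
  tab$selected <- FALSE
  for (d in names(quotas)) {
    in_d <- tab$domain == d
    tab$selected[in_d] <- tab$rank_in_domain[in_d] <= quotas[[d]]
  }
  list(selected = sort(tab$item_id[tab$selected]), table = tab)
}

# Per-item ROC AUC of case discrimination.
per_item_auc <- function(m, is_case) {
  vapply(seq_len(ncol(m)), function(j) {
    if (length(unique(m[, j])) < 2L) return(0.5) # constant item: chance level
    empirical_roc(m[, j], is_case)$auc
  }, numeric(1))
}

#' Phase 2: per-item ROC pruning and re-ordering
#'
#' Tests each pilot item's power to discriminate cases within a psychiatric
#' cohort by its individual ROC AUC (case vs all other records), removes the
#' `n_drop` items with the lowest AUC (ties resolve to the lower item id
#' being dropped first), and re-orders the survivors with
#' [reorder_items()]: best discriminators first to enable a short form.
#'
#' @param cohort Psychiatric response data.frame (cases and non-case
#'   psychiatric records).
#' @param pilot A `likert_instrument` for the pilot item set.
#' @param n_drop Number of items to remove (default 4).
#' @param case_group Case label (default "ASD").
#' @return A list of class `reduction_report`: `selected` (surviving item
#'   ids in the new order), `dropped` (ids with AUC), `per_item` (full AUC
#'   table), `audit` (stage-by-stage ranking tables).
#' @export
phase2_prune <- function(cohort, pilot, n_drop = 4L, case_group = "ASD") {
  items <- pilot$items
  k <- nrow(items)
  if (n_drop >= k) stop("n_drop must be smaller than the item count", call. = FALSE)
  if (!any(cohort$group == case_group) || all(cohort$group == case_group)) {
    stop("cohort must contain case and non-case records", call. = FALSE)
  }
  m <- response_score_matrix(cohort, pilot)
  m[is.na(m)] <- 0L
  is_case <- cohort$group == case_group
  auc <- per_item_auc(m, is_case)
  per_item <- data.frame(item_id = items$item_id, subscale = items$subscale,
                         auc = auc, stringsAsFactors = FALSE)
  drop_order <- order(per_item$auc, per_item$item_id)
  dropped_ids <- per_item$item_id[drop_order[seq_len(n_drop)]]
  kept <- per_item[!per_item$item_id %in% dropped_ids, , drop = FALSE]
  ordered <- reorder_items(kept$item_id, kept$auc, kept$subscale)
  structure(
    list(selected = ordered,
         dropped = per_item[per_item$item_id %in% dropped_ids, , drop = FALSE],
         per_item = per_item,
         audit = list(
           stage = "phase2_prune",
           case_group = case_group,
           n_records = nrow(cohort),
           auc_ranking = per_item[order(per_item$auc, per_item$item_id), ],
           dropped = dropped_ids,
           final_order = ordered
         )),
    class = "reduction_report"
  )
}

#' @export
print.reduction_report <- function(x, ...) {
  cat("<reduction_report> kept", length(x$selected), "items, dropped",
      nrow(x$dropped), "\n")
  cat("  order:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Re-order items by discriminability
#'
#' Puts the five items with the highest per-item AUC first (descending AUC,
#' ties by ascending id) so they can serve as a rapid short form; the
#' remaining items are interleaved across subscales by a deterministic
#' greedy rule (pick from the subscale with most items left that differs
#' from the previous pick; ties by subscale first appearance; within a
#' subscale, ascending id), which avoids adjacent same-subscale items
#' whenever feasible.
#'
#' @param item_ids Item ids.
#' @param auc Per-item AUC aligned with `item_ids`.
#' @param subscale Subscale labels aligned with `item_ids`.
#' @param n_top Number of top discriminators placed first (default 5).
#' @return Item ids in the new order.
#' @export
reorder_items <- function(item_ids, auc, subscale, n_top = 5L) {
  stopifnot(length(item_ids) == length(auc), length(auc) == length(subscale))
  n_top <- min(n_top, length(item_ids))
  ord <- order(-auc, item_ids)
  top <- item_ids[ord[seq_len(n_top)]]
  rest_idx <- ord[-seq_len(n_top)]
  pool <- data.frame(item_id = item_ids[rest_idx],
                     subscale = subscale[rest_idx],
                     stringsAsFactors = FALSE)
  pool <- pool[order(pool$item_id), , drop = FALSE]
  sub_order <- unique(subscale[order(match(subscale, subscale))])
  prev <- subscale[item_ids == top[n_top]][1]
  out <- integer(0)
  while (nrow(pool)) {
    counts <- table(factor(pool$subscale, levels = sub_order))
    counts <- counts[counts > 0]
    eligible <- names(counts)[names(counts) != prev]
    pick_sub <- if (length(eligible)) {
      eligible[which.max(counts[eligible])]
    } else {
      names(counts)[1]
    }
    cand <- pool$item_id[pool$subscale == pick_sub][1]
    out <- c(out, cand)
    pool <- pool[pool$item_id != cand, , drop = FALSE]
    prev <- pick_sub
  }
  c(top, out)
}

#' Derive a scoring instrument from a reduction result
#'
#' Renumbers the surviving items in their new order, marks the first
#' `short_form_n` as the short form, and attaches cut-offs, yielding a
#' `likert_instrument` directly usable for scoring.
#'
#' @param bank The source `likert_instrument`.
#' @param ordered_ids Surviving item ids in final order.
#' @param name Name for the derived instrument.
#' @param screen_cutoff,short_form_cutoff,max_missing Scoring parameters.
#' @param short_form_n Number of leading items forming the short form.
#' @return A `likert_instrument`.
#' @export
derive_instrument <- function(bank, ordered_ids, name = "derived",
                              screen_cutoff = NA_integer_,
                              short_form_cutoff = NA_integer_,
                              max_missing = 4L, short_form_n = 5L) {
  src <- bank$items[match(ordered_ids, bank$items$item_id), , drop = FALSE]
  items <- data.frame(
    item_id = seq_along(ordered_ids),
    text = src$text,
    reversed = src$reversed,
    domain = src$domain,
    subscale = src$subscale,
    short_form = seq_along(ordered_ids) <= short_form_n,
    stringsAsFactors = FALSE
  )
  likert_instrument(name, items, bank$categories, bank$forward_scores,
                    screen_cutoff = screen_cutoff,
                    short_form_cutoff = short_form_cutoff,
                    max_missing = max_missing)
}

#' Validate a scored instrument on a multi-group cohort
#'
#' The full validation battery on one cohort: per-group score summaries
#' (valid records only), Mann-Whitney comparisons of every control group
#' against the case group with rank effect sizes, ROC curves and AUC of the
#' case group against each control group, operating points at the total and
#' short-form cut-offs, Cronbach's alpha for the full scale and each
#' subscale per group and overall, and a principal-axis factor solution on
#' the cohort excluding the case group (whose uniformly high endorsement
#' otherwise collapses the structure to one factor).
#'
#' @param cohort Response data.frame.
#' @param instrument A `likert_instrument`.
#' @param case_group Case label (default "ASD").
#' @param n_factors Factors to extract in the exclusion factor analysis
#'   (default 3, the scree choice for this instrument; "auto" applies the
#'   mean-eigenvalue rule).
#' @param missing Missing-item scoring rule.
#' @return A list of class `evaluation_report`.
#' @export
evaluate_final <- function(cohort, instrument, case_group = "ASD",
                           n_factors = 3, missing = c("zero", "prorate")) {
  missing <- match.arg(missing)
  if (length(unique(cohort$group)) < 2L) {
    stop("cohort must contain at least two groups", call. = FALSE)
  }
  batch <- batch_score(cohort, instrument, missing = missing)
  sc <- batch$scores[batch$scores$valid, , drop = FALSE]
  valid_rows <- which(batch$scores$valid)
  m <- response_score_matrix(cohort, instrument)[valid_rows, , drop = FALSE]
  m[is.na(m)] <- 0L

  groups <- unique(sc$group)
  controls <- setdiff(groups, case_group)
  if (!case_group %in% groups) {
    warning("case group '", case_group, "' absent; comparisons omitted")
  }
  case_tot <- sc$total[sc$group == case_group]

  comparisons <- NULL
  roc <- list()
  op <- NULL
  for (g in controls) {
    ctl_tot <- sc$total[sc$group == g]
    if (!length(case_tot) || !length(ctl_tot)) {
      warning("group comparison vs '", g, "' omitted (empty group)")
      next
    }
    mw <- mann_whitney(case_tot, ctl_tot)
    comparisons <- rbind(comparisons, data.frame(
      control_group = g, n1 = mw$n1, n2 = mw$n2, u = mw$u, z = mw$z,
      p = mw$p, r = mw$r, stringsAsFactors = FALSE))
    pair <- sc[sc$group %in% c(case_group, g), , drop = FALSE]
    is_case <- pair$group == case_group
    roc[[g]] <- empirical_roc(pair$total, is_case)
    tot_op <- operating_point(pair$total, is_case, instrument$screen_cutoff)
    row <- data.frame(control_group = g, scale = "total",
                      cutoff = instrument$screen_cutoff,
                      sensitivity = tot_op[["sensitivity"]],
                      specificity = tot_op[["specificity"]],
                      auc = roc[[g]]$auc, stringsAsFactors = FALSE)
    if (!is.na(instrument$short_form_cutoff)) {
      sf_op <- operating_point(pair$short_form, is_case,
                               instrument$short_form_cutoff)
      sf_auc <- empirical_roc(pair$short_form, is_case)$auc
      row <- rbind(row, data.frame(control_group = g, scale = "short_form",
                                   cutoff = instrument$short_form_cutoff,
                                   sensitivity = sf_op[["sensitivity"]],
                                   specificity = sf_op[["specificity"]],
                                   auc = sf_auc, stringsAsFactors = FALSE))
    }
    op <- rbind(op, row)
  }

  sub_levels <- unique(instrument$items$subscale[!is.na(instrument$items$subscale)])
  rel_rows <- function(rows, label) {
    mm <- m[rows, , drop = FALSE]
    out <- data.frame(group = label, scale = "full",
                      alpha = tryCatch(cronbach_alpha(mm)$alpha,
                                       error = function(e) NA_real_,
                                       warning = function(w) NA_real_),
                      stringsAsFactors = FALSE)
    for (s in sub_levels) {
      ids <- instrument$items$item_id[!is.na(instrument$items$subscale) &
                                        instrument$items$subscale == s]
      a <- tryCatch(cronbach_alpha(mm[, ids, drop = FALSE])$alpha,
                    error = function(e) NA_real_,
                    warning = function(w) NA_real_)
      out <- rbind(out, data.frame(group = label, scale = s, alpha = a,
                                   stringsAsFactors = FALSE))
    }
    out
  }
  reliability <- rel_rows(seq_len(nrow(sc)), "all")
  for (g in groups) {
    reliability <- rbind(reliability, rel_rows(which(sc$group == g), g))
  }

  factors <- NULL
  excl <- which(sc$group != case_group)
  if (length(excl) > ncol(m) + 1L) {
    factors <- tryCatch(
      principal_factor_analysis(m[excl, , drop = FALSE], n_factors = n_factors),
      error = function(e) {
        warning("factor analysis skipped: ", conditionMessage(e))
        NULL
      })
  }

  structure(
    list(instrument = instrument$name,
         case_group = case_group,
         cutoffs = list(total = instrument$screen_cutoff,
                        short_form = instrument$short_form_cutoff),
         group_summary = batch$summary,
         n_invalid = nrow(batch$invalid),
         comparisons = comparisons,
         roc = roc,
         operating_points = op,
         reliability = reliability,
         factors = factors),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
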