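#' Assign ages to 10-year bands
#'
#' Bands are anchored at 18-29 and then run in decades (30-39, ...,
#' 70-79) with an open-ended top band. The convention is configurable
#' via `breaks`.
#'
#' @param age Integer vector of ages (years, must be >= first break).
#' @param breaks Increasing integer vector of lower band edges; the last
#'   opens an unbounded band.
#' @return Factor of band labels such as `"18-29"`, `"40-49"`, `"80+"`.
#' @export
assign_age_band <- function(age, breaks = c(18L, seq(30L, 80L, 10L))) {
  if (any(age < breaks[1]))
    stop(errorCondition(sprintf("age below %d not in study population",
                                breaks[1]),
                        class = c("dermclaims_domain_error", "error")))
  labels <- c(paste0(head(breaks, -1), "-", breaks[-1] - 1L),
              paste0(breaks[length(breaks)], "+"))
  cut(age, c(breaks, Inf), labels = labels, right = FALSE)
}

match_key <- function(tab, breaks, comorb_cap, with_region = TRUE) {
  parts <- list(as.character(assign_age_band(tab$age, breaks)),
                tab$sex, tab$ses,
                as.character(tab$history_premalignancy),
                pmin(tab$n_comorbidities, comorb_cap))
  if (with_region) parts <- append(parts, list(tab$region), after = 3)
  do.call(paste, c(parts, sep = "|"))
}

#' Tiered 1:3 exact matching of app users to controls
#'
#' Each user is matched without replacement to up to `ratio` controls
#' sharing the full matching key: 10-year age band, sex, SES (missing
#' SES matches only missing SES), residential area, (pre)malignancy
#' history, and exact comorbidity count (capped at `comorb_cap`).
#' Users short of `ratio` full-key controls draw the remaining slots
#' from a fallback tier that drops residential area. Ties among eligible
#' controls are broken uniformly at random under `seed`, independent of
#' input row order (both sides are canonically sorted by `person_id`
#' before any random draw). Users with no eligible controls at either
#' tier are flagged unmatched and excluded from analysis.
#'
#' @param users,pool Insuree tables (disjoint; `pool` must be
#'   `arm == "control-pool"`).
#' @param ratio Controls per user (default 3).
#' @param seed Integer seed for tie-breaking.
#' @param breaks Age-band convention, see [assign_age_band()].
#' @param comorb_cap Ceiling applied to the comorbidity count in the key.
#' @return An object of class `"matched_cohort"`: list with `matches`
#'   (`user_id`, `control_id`, `tier`), `users` (`user_id`, `tier`
#'   = full/no_region/unmatched, `n_controls`), and the call parameters.
#' @export
match_cohort <- function(users, pool, ratio = 3L, seed = 1L,
                         breaks = c(18L, seq(30L, 80L, 10L)),
                         comorb_cap = 5L) {
  if (ratio < 1L)
    config_error("matching ratio must be at least 1")
  if (length(intersect(users$person_id, pool$person_id)) > 0L)
    config_error("users and control pool overlap")
  users <- as.data.table(users)[order(person_id)]
  pool <- as.data.table(pool)[order(person_id)]
  set.seed(seed)

  u_key1 <- match_key(users, breaks, comorb_cap, TRUE)
  u_key2 <- match_key(users, breaks, comorb_cap, FALSE)
  p_key1 <- match_key(pool, breaks, comorb_cap, TRUE)
  p_key2 <- match_key(pool, breaks, comorb_cap, FALSE)

  n_u <- nrow(users)
  got <- vector("list", n_u)
  tier_of <- character(0)

  take <- function(key_u, key_p, avail, need_of) {
    # one tier: for each key group, hand shuffled candidates to users
    # (in canonical order) in chunks of their remaining need
    sel <- vector("list", n_u)
    for (k in unique(key_u[need_of > 0])) {
      uid <- which(key_u == k & need_of > 0)
      cand <- which(key_p == k & avail)
      if (length(cand) > 1L) cand <- cand[sample.int(length(cand))]
      pos <- 0L
      for (i in uid) {
        if (pos >= length(cand)) break
        n_take <- min(need_of[i], length(cand) - pos)
        sel[[i]] <- cand[(pos + 1L):(pos + n_take)]
        pos <- pos + n_take
      }
    }
    sel
  }

  need <- rep(as.integer(ratio), n_u)
  avail <- rep(TRUE, nrow(pool))
  sel1 <- take(u_key1, p_key1, avail, need)
  for (i in seq_len(n_u)) need[i] <- need[i] - length(sel1[[i]])
  avail[unlist(sel1)] <- FALSE
  sel2 <- take(u_key2, p_key2, avail, need)

  matches <- rbindlist(list(
    data.table(user_id = rep(users$person_id, lengths(sel1)),
               control_id = pool$person_id[unlist(sel1)],
               tier = "full"),
    data.table(user_id = rep(users$person_id, lengths(sel2)),
               control_id = pool$person_id[unlist(sel2)],
               tier = "no_region")))
  n1 <- lengths(sel1); n2 <- lengths(sel2)
  user_tier <- ifelse(n1 + n2 == 0L, "unmatched",
                      ifelse(n2 == 0L & n1 == ratio, "full", "no_region"))
  res <- list(matches = matches,
              users = data.table(user_id = users$person_id,
                                 tier = user_tier,
                                 n_controls = n1 + n2),
              ratio = as.integer(ratio), seed = as.integer(seed),
              breaks = breaks, comorb_cap = comorb_cap)
  class(res) <- "matched_cohort"
  res
}

#' Analyzed persons of a matched cohort
#'
#' @param cohort A [match_cohort()] result.
#' @return `data.table` with `person_id` and `arm` (`"user"`/`"control"`)
#'   covering matched users and their controls; unmatched users excluded.
#' @export
analysis_set <- function(cohort) {
  rbind(
    data.table(person_id = cohort$users[tier != "unmatched", user_id],
               arm = "user"),
    data.table(person_id = cohort$matches$control_id, arm = "control"))
}

std_diff <- function(x1, x2) {
  if (is.logical(x1) || is.character(x1) || is.factor(x1)) {
    lev <- unique(c(as.character(x1), as.character(x2)))
    d <- vapply(lev, function(l) {
      p1 <- mean(as.character(x1) == l); p2 <- mean(as.character(x2) == l)
      v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
      if (v == 0) 0 else (p1 - p2) / sqrt(v)
    }, numeric(1))
    max(abs(d))
  } else {
    v <- (stats::var(x1) + stats::var(x2)) / 2
    if (is.na(v) || v == 0) 0 else (mean(x1) - mean(x2)) / sqrt(v)
  }
}

#' Matching diagnostics: tier shares and covariate balance
#'
#' Reports per-tier user counts and fractions, and standardized
#' differences between matched users and their controls on the matching
#' covariates (age band, sex, SES, region, history, capped comorbidity
#' count). With exact full-key matching at the target ratio the
#' standardized differences are identically zero.
#'
#' @param cohort A [match_cohort()] result.
#' @param insurees Insuree table covering all matched persons.
#' @return List with `tiers` (tier, n, fraction) and `balance`
#'   (covariate, std_diff_all, std_diff_tier1) data.tables.
#' @export
matching_report <- function(cohort, insurees) {
  tiers <- cohort$users[, .(n = .N), by = tier]
  tiers[, fraction := if (sum(n) > 0) n / sum(n) else numeric(.N)]
  if (nrow(cohort$matches) == 0L) {
    return(list(tiers = tiers[],
                balance = data.table(covariate = character(0),
                                     std_diff_all = numeric(0),
                                     std_diff_tier1 = numeric(0))))
  }
  ins <- as.data.table(insurees)
  ins[, age_band := as.character(assign_age_band(age, cohort$breaks))]
  ins[, comorb_capped := pmin(n_comorbidities, cohort$comorb_cap)]
  covs <- c("age_band", "sex", "ses", "region",
            "history_premalignancy", "comorb_capped")
  full_users <- cohort$users[tier == "full", user_id]
  bal <- rbindlist(lapply(covs, function(cv) {
    balance_pair <- function(uid, cid) {
      x1 <- ins[match(uid, person_id)][[cv]]
      x2 <- ins[match(cid, person_id)][[cv]]
      std_diff(x1, x2)
    }
    matched_u <- cohort$users[tier != "unmatched", user_id]
    data.table(
      covariate = cv,
      std_diff_all = balance_pair(matched_u, cohort$matches$control_id),
      std_diff_tier1 = if (length(full_users))
        balance_pair(full_users,
                     cohort$matches[user_id %in% full_users, control_id])
      else NA_real_)
  }))
  list(tiers = tiers[], balance = bal)
}
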