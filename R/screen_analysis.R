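#' Classify a thrashing-assay record as long, short or none
#'
#' The primary screen approximates lifespan by survival fractions at four
#' scoring days (days 15, 17, 19 and 21 of adulthood). A gene inactivation is
#' called "long" when the relative change in survival versus control,
#' (treated - control)/control, is at least `+threshold` on at least
#' `min_timepoints` of the scored days *and* no day moves past `-threshold`
#' in the opposite direction; "short" is symmetric; anything else is "none".
#' The consistency clause matters: a record with changes +25, +25, +25, -25
#' is not a consistent phenotype and is called "none".
#'
#' A day with control fraction 0 has no defined relative change: it is
#' flagged indeterminate and excluded from the count. If every day is
#' indeterminate the record is uninformative and classification errors.
#'
#' @param treated numeric survival fractions in `[0, 1]`, one per scored day.
#' @param control matched control fractions, same length.
#' @param threshold relative-change threshold (default 0.10 = 10%).
#' @param min_timepoints minimum number of qualifying days (default 3).
#' @return list with `phenotype` (`"long"`, `"short"` or `"none"`),
#'   `changes` (relative changes, `NA` where indeterminate) and
#'   `n_indeterminate`.
#' @examples
#' classify_thrashing(c(1, .92, .70, .50), c(.90, .80, .60, .40))$phenotype
#' @export
classify_thrashing <- function(treated, control, threshold = 0.10,
                               min_timepoints = 3) {
  stopifnot(is.numeric(treated), is.numeric(control),
            length(treated) == length(control), length(treated) >= 1,
            all(treated >= 0 & treated <= 1), all(control >= 0 & control <= 1),
            threshold > 0, is_count(min_timepoints), min_timepoints >= 1)
  changes <- ifelse(control == 0, NA_real_, (treated - control) / control)
  ok <- !is.na(changes)
  if (!any(ok)) stop("all time points indeterminate (control fraction 0)")
  up <- sum(changes[ok] >= threshold)
  down <- sum(changes[ok] <= -threshold)
  phen <- if (up >= min_timepoints && down == 0) "long"
          else if (down >= min_timepoints && up == 0) "short"
          else "none"
  list(phenotype = phen, changes = changes, n_indeterminate = sum(!ok))
}

#' Per-animal survival datasets
#'
#' @param times positive per-animal event times (days).
#' @param events integer/logical event flags: 1/TRUE = death, 0/FALSE =
#'   right-censored at that time.
#' @param group group label.
#' @return object of class `survival_dataset`.
#' @export
survival_dataset <- function(times, events = rep(1L, length(times)),
                             group = "") {
  stopifnot(is.numeric(times), all(times > 0),
            length(events) == length(times))
  events <- as.integer(as.logical(events))
  structure(list(times = as.numeric(times), events = events, group = group),
            class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat("<survival_dataset> ", if (nzchar(x$group)) paste0(x$group, ": "),
      length(x$times), " animals, ", sum(x$events), " deaths, ",
      sum(1 - x$events), " censored\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier estimate with mean and median lifespan
#'
#' Product-limit estimator with right censoring (via [survival::survfit()]).
#' The mean is the area under the survival curve up to the largest event
#' time; with no censoring it equals the arithmetic mean of the death ages
#' exactly. The median is the first time at which survival drops to 0.5 or
#' below.
#'
#' @param data a [survival_dataset()] with at least one death.
#' @return list with `time`, `surv` (step-curve points after each event
#'   time), `mean`, `median`, `n`, `n_deaths`.
#' @export
km_estimate <- function(data) {
  stopifnot(inherits(data, "survival_dataset"))
  if (sum(data$events) == 0) stop("no death events: all animals censored")
  fit <- survival::survfit(survival::Surv(data$times, data$events) ~ 1)
  tt <- fit$time
  ss <- fit$surv
  # area under the step curve from 0 to the largest event (death or censor) time
  t_grid <- c(0, tt)
  s_grid <- c(1, ss)
  mean_ls <- sum(diff(t_grid) * s_grid[-length(s_grid)])
  med <- if (any(ss <= 0.5)) tt[which(ss <= 0.5)[1L]] else NA_real_
  list(time = tt, surv = ss, mean = mean_ls, median = med,
       n = length(data$times), n_deaths = sum(data$events))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank over pooled risk sets
#' (via [survival::survdiff()]), one degree of freedom.
#'
#' @param a,b [survival_dataset()]s, each with at least one death.
#' @return list with `statistic` (chi-square), `p_value`, `n` per group.
#' @export
logrank_test <- function(a, b) {
  stopifnot(inherits(a, "survival_dataset"), inherits(b, "survival_dataset"))
  if (sum(a$events) == 0 || sum(b$events) == 0)
    stop("both groups need at least one death for the log-rank test")
  times <- c(a$times, b$times)
  events <- c(a$events, b$events)
  grp <- rep(c("a", "b"), c(length(a$times), length(b$times)))
  sd <- survival::survdiff(survival::Surv(times, events) ~ grp)
  stat <- unname(sd$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n = c(a = length(a$times), b = length(b$times)))
}

#' Percent change in mean and maximum lifespan versus control
#'
#' `pct_delta_mean` is the percent change of the Kaplan-Meier mean lifespan
#' relative to control. `pct_delta_max` applies the same formula to maximum
#' lifespan, defined as the mean age at death of the longest-lived quarter
#' (the top `ceiling(n/4)` deaths) of each group. Both use uncensored deaths
#' for the quartile; each group needs at least 4 deaths so the quartile is
#' well defined.
#'
#' @param treated,control [survival_dataset()]s.
#' @return list with `pct_delta_mean`, `pct_delta_max` (percent, unrounded)
#'   and the underlying group means.
#' @export
percent_changes <- function(treated, control) {
  stopifnot(inherits(treated, "survival_dataset"),
            inherits(control, "survival_dataset"))
  if (sum(treated$events) < 4 || sum(control$events) < 4)
    stop("need at least 4 deaths per group for the last-quartile measure")
  km_t <- km_estimate(treated)
  km_c <- km_estimate(control)
  if (km_c$mean <= 0) stop("control mean lifespan is zero")
  last_quartile_mean <- function(d) {
    deaths <- sort(d$times[d$events == 1], decreasing = TRUE)
    mean(deaths[seq_len(ceiling(length(deaths) / 4))])
  }
  lq_t <- last_quartile_mean(treated)
  lq_c <- last_quartile_mean(control)
  list(pct_delta_mean = 100 * (km_t$mean - km_c$mean) / km_c$mean,
       pct_delta_max = 100 * (lq_t - lq_c) / lq_c,
       mean_treated = km_t$mean, mean_control = km_c$mean,
       max_treated = lq_t, max_control = lq_c)
}

#' Screen summary counts
#'
#' Holds the screened / preliminary / retested / verified funnel for one gene
#' set and both phenotype directions. Invariant checked on construction:
#' verified <= retested <= preliminary <= screened per direction.
#'
#' @param genes_screened total genes screened.
#' @param preliminary_long,preliminary_short preliminary candidate counts.
#' @param retested_long,retested_short counts retested longitudinally.
#' @param verified_long,verified_short counts verified longitudinally.
#' @return object of class `screen_summary`.
#' @export
screen_summary <- function(genes_screened, preliminary_long, preliminary_short,
                           retested_long, retested_short,
                           verified_long, verified_short) {
  vals <- c(genes_screened, preliminary_long, preliminary_short,
            retested_long, retested_short, verified_long, verified_short)
  stopifnot(all(vapply(vals, is_count, logical(1))))
  for (dir in c("long", "short")) {
    p <- get(paste0("preliminary_", dir))
    r <- get(paste0("retested_", dir))
    v <- get(paste0("verified_", dir))
    if (!(v <= r && r <= p && p <= genes_screened))
      stop("screen summary violates verified <= retested <= preliminary <= ",
           "screened for the ", dir, " phenotype")
  }
  structure(list(genes_screened = genes_screened,
                 preliminary_long = preliminary_long,
                 preliminary_short = preliminary_short,
                 retested_long = retested_long,
                 retested_short = retested_short,
                 verified_long = verified_long,
                 verified_short = verified_short),
            class = "screen_summary")
}

#' Verification frequency of a screen
#'
#' Verified longevity genes as a percentage of all genes screened, with
#' conventional half-up rounding (19/374 -> 5.1).
#'
#' @param summary a [screen_summary()].
#' @param phenotype `"long"` or `"short"`.
#' @param digits decimal places (1 by default; 2 for finer comparison).
#' @return percent (single numeric).
#' @export
verification_frequency <- function(summary, phenotype = c("long", "short"),
                                   digits = 1) {
  stopifnot(inherits(summary, "screen_summary"))
  phenotype <- match.arg(phenotype)
  if (summary$genes_screened == 0) stop("zero genes screened")
  v <- summary[[paste0("verified_", phenotype)]]
  round_half_up(100 * v / summary$genes_screened, digits)
}

#' Extrapolate verified counts to untested preliminary hits
#'
#' If the longitudinal confirmation rate (verified/retested) held for the
#' untested preliminary hits, the screen would contain
#' `floor(preliminary * verified / retested)` true hits; also returned as a
#' percentage of genes screened (half-up, 1 decimal).
#'
#' @param preliminary preliminary hit count.
#' @param retested number retested (>= 1).
#' @param verified number verified (<= retested).
#' @param screened total genes screened.
#' @return list `(count, percent)`.
#' @export
extrapolate_verified <- function(preliminary, retested, verified, screened) {
  stopifnot(is_count(preliminary), is_count(retested), is_count(verified),
            is_count(screened), screened > 0)
  if (retested < 1) stop("retested count must be at least 1")
  if (!(verified <= retested && retested <= preliminary))
    stop("need verified <= retested <= preliminary")
  count <- floor(preliminary * verified / retested)
  list(count = count, percent = round_half_up(100 * count / screened, 1))
}

#' Fold improvement of a verification frequency over baseline screens
#'
#' @param freq_this this screen's verification frequency (percent).
#' @param baseline_freqs positive baseline frequencies (percent) from other
#'   screens; the comparison is against their mean.
#' @return list with `ratio` (raw) and `fold` (nearest integer).
#' @export
fold_improvement <- function(freq_this, baseline_freqs) {
  stopifnot(is.numeric(freq_this), length(freq_this) == 1,
            is.numeric(baseline_freqs), length(baseline_freqs) >= 1)
  if (any(baseline_freqs <= 0)) stop("baseline frequencies must be positive")
  ratio <- freq_this / mean(baseline_freqs)
  list(ratio = ratio, fold = round_half_up(ratio, 0))
}

#' Summarize verified lifespan effects
#'
#' Mean percent change of mean lifespan across verified genes of one
#' direction, plus how many effects are modest (strictly below the cutoff in
#' magnitude of `pct_delta_mean`). Genes appearing in both the worm- and
#' human-network tables must be deduplicated by id before calling (done here
#' defensively).
#'
#' @param effects data.frame with columns `gene` and `pct_delta_mean`.
#' @param direction `"long"` (positive effects) or `"short"` (negative).
#' @param modest_cutoff percent cutoff for a "modest" effect (default 10).
#' @return list `(n, mean_pct_delta, n_modest)`; the mean is half-up rounded
#'   to 1 decimal.
#' @export
summarize_effects <- function(effects, direction = c("long", "short"),
                              modest_cutoff = 10) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(effects),
            all(c("gene", "pct_delta_mean") %in% names(effects)))
  effects <- effects[!duplicated(effects$gene), , drop = FALSE]
  vals <- effects$pct_delta_mean
  vals <- if (direction == "long") vals[vals > 0] else vals[vals < 0]
  if (!length(vals)) stop("no effects in the requested direction")
  list(n = length(vals),
       mean_pct_delta = round_half_up(mean(vals), 1),
       n_modest = sum(abs(vals) < modest_cutoff))
}

#' Primary-analysis detection rates
#'
#' Percentage of screened genes with any phenotype, a long-lived phenotype,
#' and a short-lived phenotype in the primary (thrashing) analysis, each
#' half-up rounded to an integer.
#'
#' @param screened genes screened in the class.
#' @param n_long preliminary long-lived count.
#' @param n_short preliminary short-lived count.
#' @return list `(any, long, short)` of integer percents.
#' @export
primary_detection_rates <- function(screened, n_long, n_short) {
  stopifnot(is_count(screened), is_count(n_long), is_count(n_short))
  if (screened == 0) stop("zero genes screened")
  list(any = round_half_up(100 * (n_long + n_short) / screened, 0),
       long = round_half_up(100 * n_long / screened, 0),
       short = round_half_up(100 * n_short / screened, 0))
}
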