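#' Configuration for the synthetic longitudinal EHR generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_ehr_cohort()]. The defaults describe a desk-scale cohort used
#' throughout the package's examples and tests: four event domains with
#' frequency-skewed background emission rates, inter-visit gaps drawn from a
#' four-range mixture matching the relative-time tokens, log-normal laboratory
#' values, and a chained conditional cascade (a chronic early marker code
#' leads to a precursor condition, which leads to a target complication)
#' emulating the prodrome -> disease -> complication structure of real
#' disease trajectories.
#'
#' @param n_patients number of patients to simulate.
#' @param code_pools named list with character vectors `diagnosis`,
#'   `medication`, `procedure`, `lab`. Pools must be disjoint.
#' @param visit_count_distribution list with negative-binomial parameters
#'   `size` and `mu` for the number of visits beyond the first, and a hard
#'   `max` cap.
#' @param gap_mixture length-4 numeric mixture weights over the four
#'   inter-visit gap ranges (1-91, 92-182, 183-365, 366-730 days); must sum
#'   to 1.
#' @param lab_value_distributions named list (one entry per lab code) of
#'   lists with `meanlog` and `sdlog` for log-normal lab values.
#' @param background_rates named numeric vector of per-visit emission
#'   probabilities, one entry per code across all pools.
#' @param chronic_codes named numeric vector: codes that, once present,
#'   recur at each subsequent visit with the given probability.
#' @param precursor_rules list of rules, each a list with `precursor`,
#'   `target`, `prob`, `min_lag`, `max_lag` (days). Rules are applied in
#'   order, so the target of one rule may act as the precursor of a later
#'   rule (chained cascades).
#' @param visit_type_probs named probabilities over visit types.
#' @param discharge_type_probs named probabilities over discharge
#'   destinations for inpatient visits.
#' @param age_range age range (years) at first visit.
#' @param epoch character vector of two ISO dates bounding first-visit dates.
#' @param seed integer seed; the same configuration always yields the same
#'   cohort.
#'
#' @return an object of class `ehr_cohort_config`.
#' @export
ehr_cohort_config <- function(n_patients = 2000L,
                              code_pools = NULL,
                              visit_count_distribution = list(size = 4, mu = 11, max = 30),
                              gap_mixture = c(0.55, 0.20, 0.15, 0.10),
                              lab_value_distributions = NULL,
                              background_rates = NULL,
                              chronic_codes = NULL,
                              precursor_rules = NULL,
                              visit_type_probs = c(outpatient = 0.80, inpatient = 0.15, emergency = 0.05),
                              discharge_type_probs = c(home = 0.85, snf = 0.15),
                              age_range = c(30, 85),
                              epoch = c("2008-01-01", "2018-12-31"),
                              seed = 1L) {
  if (is.null(code_pools)) code_pools <- .default_code_pools()
  if (is.null(lab_value_distributions)) lab_value_distributions <- .default_lab_distributions(code_pools$lab)
  if (is.null(background_rates)) background_rates <- .default_background_rates(code_pools)
  if (is.null(chronic_codes)) chronic_codes <- c(E66 = 0.85, E11 = 0.75, N18 = 0.75, I10 = 0.60)
  if (is.null(precursor_rules)) {
    precursor_rules <- list(
      list(precursor = "E66", target = "E11", prob = 0.9, min_lag = 120L, max_lag = 360L),
      list(precursor = "E11", target = "N18", prob = 0.8, min_lag = 1L, max_lag = 89L)
    )
  }

  cfg <- list(
    n_patients = .assert_count(n_patients, "n_patients"),
    code_pools = code_pools,
    visit_count_distribution = visit_count_distribution,
    gap_mixture = as.numeric(gap_mixture),
    gap_ranges = list(c(1L, 91L), c(92L, 182L), c(183L, 365L), c(366L, 730L)),
    lab_value_distributions = lab_value_distributions,
    background_rates = background_rates,
    chronic_codes = chronic_codes,
    precursor_rules = precursor_rules,
    visit_type_probs = visit_type_probs,
    discharge_type_probs = discharge_type_probs,
    age_range = as.numeric(age_range),
    epoch = as.Date(epoch),
    seed = .assert_count(seed, "seed", positive = FALSE)
  )
  class(cfg) <- "ehr_cohort_config"
  .validate_cohort_config(cfg)
  cfg
}

.default_code_pools <- function() {
  list(
    diagnosis = c("A09", "B34", "C25", "C34", "D50", "D64", "E03", "E11", "E66",
                  "E78", "F32", "F41", "G43", "G47", "H25", "H52", "H66", "H92",
                  "I10", "I25", "I48", "I50", "J02", "J06", "J44", "J45", "K21",
                  "K29", "L20", "L30", "M17", "M54", "N18", "N39", "R05", "R10",
                  "R51", "Z00", "Z23", "Z79"),
    medication = as.character(104490 + 1234L * (0:29)),
    procedure = c("99213", "99214", "99203", "99285", "80053", "85025", "93000",
                  "71046", "36415", "90471", "45378", "77067", "93306", "29881",
                  "66984", "12001", "20610", "81001", "94010", "99232"),
    lab = c("2345-7", "2160-0", "718-7", "2093-3", "4548-4", "2823-3",
            "2951-2", "6690-2")
  )
}

.default_lab_distributions <- function(lab_codes) {
  base <- list(
    "2345-7" = list(meanlog = log(100), sdlog = 0.25),
    "2160-0" = list(meanlog = log(0.9), sdlog = 0.30),
    "718-7"  = list(meanlog = log(13.5), sdlog = 0.12),
    "2093-3" = list(meanlog = log(180), sdlog = 0.20),
    "4548-4" = list(meanlog = log(5.8), sdlog = 0.15),
    "2823-3" = list(meanlog = log(4.2), sdlog = 0.08),
    "2951-2" = list(meanlog = log(139), sdlog = 0.02),
    "6690-2" = list(meanlog = log(7.0), sdlog = 0.30)
  )
  out <- lapply(seq_along(lab_codes), function(i) {
    base[[lab_codes[i]]] %||% list(meanlog = log(10), sdlog = 0.3)
  })
  names(out) <- lab_codes
  out
}

.default_background_rates <- function(pools) {
  dx <- pmax(0.10 * 0.90^(seq_along(pools$diagnosis) - 1L), 0.004)
  names(dx) <- pools$diagnosis
  # cascade codes arise (almost) only through the injected rules
  dx["E66"] <- 0.030
  dx["E11"] <- 0.004
  dx["N18"] <- 0.002
  rx <- pmax(0.08 * 0.90^(seq_along(pools$medication) - 1L), 0.004)
  names(rx) <- pools$medication
  px <- pmax(0.08 * 0.85^(seq_along(pools$procedure) - 1L), 0.004)
  names(px) <- pools$procedure
  px["99213"] <- 0.30
  lb <- rep(c(0.35, 0.30, 0.30, 0.15, 0.12, 0.20, 0.20, 0.25),
            length.out = length(pools$lab))
  names(lb) <- pools$lab
  c(dx, rx, px, lb)
}

.validate_cohort_config <- function(cfg) {
  pools <- cfg$code_pools
  need <- c("diagnosis", "medication", "procedure", "lab")
  if (!is.list(pools) || !all(need %in% names(pools))) {
    .stop_cfg("code_pools", "must be a list with diagnosis/medication/procedure/lab")
  }
  all_codes <- unlist(pools[need], use.names = FALSE)
  if (anyDuplicated(all_codes)) .stop_cfg("code_pools", "must be disjoint across domains")
  if (length(cfg$gap_mixture) != 4L || any(cfg$gap_mixture < 0)) {
    .stop_cfg("gap_mixture", "must be 4 non-negative weights")
  }
  if (abs(sum(cfg$gap_mixture) - 1) > 1e-8) .stop_cfg("gap_mixture", "must sum to 1")
  vd <- cfg$visit_count_distribution
  if (!is.list(vd) || is.null(vd$size) || is.null(vd$mu) || vd$size <= 0 || vd$mu < 0) {
    .stop_cfg("visit_count_distribution", "must provide positive size and non-negative mu")
  }
  if (is.null(names(cfg$background_rates)) ||
      !all(all_codes %in% names(cfg$background_rates))) {
    .stop_cfg("background_rates", "must name every code in the pools")
  }
  .assert_prob(cfg$background_rates, "background_rates")
  .assert_prob(unname(cfg$visit_type_probs), "visit_type_probs")
  if (length(cfg$chronic_codes)) .assert_prob(unname(cfg$chronic_codes), "chronic_codes")
  if (!all(pools$lab %in% names(cfg$lab_value_distributions))) {
    .stop_cfg("lab_value_distributions", "must cover every lab code")
  }
  for (ld in cfg$lab_value_distributions) {
    if (!is.finite(ld$meanlog) || !is.finite(ld$sdlog) || ld$sdlog < 0) {
      .stop_cfg("lab_value_distributions", "must have finite meanlog and non-negative sdlog")
    }
  }
  for (i in seq_along(cfg$precursor_rules)) {
    r <- cfg$precursor_rules[[i]]
    if (!all(c("precursor", "target", "prob", "min_lag", "max_lag") %in% names(r))) {
      .stop_cfg("precursor_rules", "entries need precursor/target/prob/min_lag/max_lag")
    }
    .assert_prob(r$prob, "precursor_rules$prob")
    if (r$min_lag < 0 || r$max_lag < r$min_lag) {
      .stop_cfg("precursor_rules", "needs 0 <= min_lag <= max_lag")
    }
    if (!r$precursor %in% all_codes || !r$target %in% all_codes) {
      .stop_cfg("precursor_rules", "references a code absent from the pools")
    }
  }
  invisible(cfg)
}

.code_domain_map <- function(pools) {
  doms <- c("diagnosis", "medication", "procedure", "lab")
  stats::setNames(
    rep(doms, vapply(pools[doms], length, 1L)),
    unlist(pools[doms], use.names = FALSE)
  )
}

#' Simulate a longitudinal OMOP-style cohort with known conditional structure
#'
#' Draws `n_patients` multi-visit records: demographics, inter-visit gaps from
#' the configured four-range mixture, per-visit background code emissions,
#' chronic-code recurrences, continuous lab values, and the configured
#' precursor-to-target rules. Each rule fires at most once per patient: if the
#' patient emits the precursor, then with the configured conditional
#' probability the target code is placed `min_lag`-`max_lag` days after the
#' precursor's first occurrence (a visit is inserted when none falls inside
#' the lag window, as the diagnosis event itself constitutes a visit).
#'
#' @param config an [ehr_cohort_config()] object.
#' @return a list with `records` (class `ehr_cohort`, a list of patient
#'   records) and `ground_truth` (class `ehr_ground_truth`): per patient and
#'   rule the precursor onset, whether the rule fired and the realized target
#'   date, plus per-rule realized conditional frequencies.
#' @examples
#' cohort <- simulate_ehr_cohort(ehr_cohort_config(n_patients = 20, seed = 7))
#' length(cohort$records)
#' cohort$ground_truth$rule_summary
#' @export
simulate_ehr_cohort <- function(config) {
  stopifnot(inherits(config, "ehr_cohort_config"))
  .validate_cohort_config(config)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  pools <- config$code_pools
  domain_of <- .code_domain_map(pools)
  codes <- names(domain_of)
  rates <- config$background_rates[codes]
  n_rules <- length(config$precursor_rules)

  records <- vector("list", config$n_patients)
  gt_rows <- vector("list", config$n_patients)

  for (p in seq_len(config$n_patients)) {
    rec <- .simulate_patient(p, config, pools, domain_of, codes, rates)
    records[[p]] <- rec$record
    gt_rows[[p]] <- rec$gt
  }

  gt <- do.call(rbind, gt_rows)
  rownames(gt) <- NULL
  rule_summary <- NULL
  if (n_rules > 0L) {
    rule_summary <- do.call(rbind, lapply(seq_len(n_rules), function(i) {
      sub <- gt[gt$rule == i & !is.na(gt$precursor_onset), , drop = FALSE]
      data.frame(
        rule = i,
        precursor = config$precursor_rules[[i]]$precursor,
        target = config$precursor_rules[[i]]$target,
        configured_prob = config$precursor_rules[[i]]$prob,
        n_emitting = nrow(sub),
        n_fired = sum(sub$fired),
        realized_frequency = if (nrow(sub)) mean(sub$fired) else NA_real_
      )
    }))
  }
  ground_truth <- structure(list(events = gt, rule_summary = rule_summary),
                            class = "ehr_ground_truth")
  records <- structure(records, class = "ehr_cohort")
  list(records = records, ground_truth = ground_truth)
}

.simulate_patient <- function(person_id, config, pools, domain_of, codes, rates) {
  vd <- config$visit_count_distribution
  n_visits <- 1L + min(stats::rnbinom(1L, size = vd$size, mu = vd$mu),
                       (vd$max %||% 30L) - 1L)

  # visit dates: uniform start over the epoch, then cumulative mixture gaps
  start <- config$epoch[1] + floor(stats::runif(1) *
            as.integer(config$epoch[2] - config$epoch[1] + 1L))
  gaps <- integer(0)
  if (n_visits > 1L) {
    comp <- sample.int(4L, n_visits - 1L, replace = TRUE, prob = config$gap_mixture)
    lo <- vapply(config$gap_ranges, `[`, integer(1), 1L)[comp]
    hi <- vapply(config$gap_ranges, `[`, integer(1), 2L)[comp]
    gaps <- lo + floor(stats::runif(n_visits - 1L) * (hi - lo + 1L))
  }
  dates <- start + cumsum(c(0L, gaps))

  sex <- if (stats::runif(1) < 0.5) "F" else "M"
  age0 <- stats::runif(1, config$age_range[1], config$age_range[2])
  birth_date <- dates[1] - round(age0 * 365.25)

  vt <- names(config$visit_type_probs)[
    sample.int(length(config$visit_type_probs), n_visits, replace = TRUE,
               prob = config$visit_type_probs)]
  dt <- rep(NA_character_, n_visits)
  inpat <- which(vt == "inpatient")
  if (length(inpat)) {
    dt[inpat] <- names(config$discharge_type_probs)[
      sample.int(length(config$discharge_type_probs), length(inpat),
                 replace = TRUE, prob = config$discharge_type_probs)]
  }

  # background emissions: visit x code Bernoulli draws
  emit <- matrix(stats::runif(n_visits * length(codes)), nrow = n_visits) <
    matrix(rates, nrow = n_visits, ncol = length(codes), byrow = TRUE)
  colnames(emit) <- codes

  # chronic recurrence: once present, re-emitted at subsequent visits
  for (code in names(config$chronic_codes)) {
    if (!code %in% codes) next
    first <- which(emit[, code])[1]
    if (!is.na(first) && first < n_visits) {
      later <- (first + 1L):n_visits
      rec_draw <- stats::runif(length(later)) < config$chronic_codes[[code]]
      emit[later, code] <- emit[later, code] | rec_draw
    }
  }

  visits <- lapply(seq_len(n_visits), function(v) {
    present <- codes[emit[v, ]]
    list(date = dates[v], visit_type = vt[v], discharge = dt[v],
         events = present)
  })

  # precursor -> target rules, applied in order so cascades chain
  n_rules <- length(config$precursor_rules)
  gt <- data.frame(person_id = rep(person_id, max(n_rules, 0L)),
                   rule = seq_len(n_rules),
                   precursor_onset = as.Date(rep(NA, n_rules)),
                   fired = rep(FALSE, n_rules),
                   target_date = as.Date(rep(NA, n_rules)))
  if (n_rules > 0L) {
    for (ri in seq_len(n_rules)) {
      rule <- config$precursor_rules[[ri]]
      onset <- NA
      for (v in seq_along(visits)) {
        if (rule$precursor %in% visits[[v]]$events) { onset <- visits[[v]]$date; break }
      }
      if (is.na(onset)) next
      gt$precursor_onset[ri] <- onset
      if (stats::runif(1) >= rule$prob) next
      lag <- rule$min_lag + floor(stats::runif(1) * (rule$max_lag - rule$min_lag + 1L))
      tdate <- onset + lag
      vdates <- vapply(visits, function(v) as.integer(v$date), integer(1))
      # earliest visit inside the lag window at/after the drawn date
      cand <- which(vdates >= as.integer(tdate) &
                    vdates <= as.integer(onset + rule$max_lag))
      if (length(cand)) {
        vi <- cand[1]
        visits[[vi]]$events <- union(visits[[vi]]$events, rule$target)
        gt$target_date[ri] <- visits[[vi]]$date
      } else {
        vtype <- names(config$visit_type_probs)[
          sample.int(length(config$visit_type_probs), 1L,
                     prob = config$visit_type_probs)]
        newv <- list(date = tdate, visit_type = vtype, discharge = NA_character_,
                     events = rule$target)
        pos <- sum(vdates < as.integer(tdate))
        visits <- append(visits, list(newv), after = pos)
        gt$target_date[ri] <- tdate
      }
      gt$fired[ri] <- TRUE
      # chronic recurrence of a rule-introduced code in later visits
      if (rule$target %in% names(config$chronic_codes)) {
        tfirst <- which(vapply(visits, function(v) rule$target %in% v$events, logical(1)))[1]
        if (!is.na(tfirst) && tfirst < length(visits)) {
          for (v in (tfirst + 1L):length(visits)) {
            if (stats::runif(1) < config$chronic_codes[[rule$target]]) {
              visits[[v]]$events <- union(visits[[v]]$events, rule$target)
            }
          }
        }
      }
    }
  }

  # materialize event tables with lab values
  visit_list <- lapply(seq_along(visits), function(v) {
    ev <- visits[[v]]$events
    if (length(ev)) {
      dom <- domain_of[ev]
      ord <- order(match(dom, c("diagnosis", "procedure", "medication", "lab")), ev)
      ev <- ev[ord]; dom <- dom[ord]
      val <- rep(NA_real_, length(ev))
      labs <- which(dom == "lab")
      for (i in labs) {
        ld <- config$lab_value_distributions[[ev[i]]]
        val[i] <- stats::rlnorm(1L, meanlog = ld$meanlog, sdlog = ld$sdlog)
      }
      events <- data.frame(domain = unname(dom), code = ev, value = val,
                           stringsAsFactors = FALSE)
    } else {
      events <- data.frame(domain = character(0), code = character(0),
                           value = numeric(0), stringsAsFactors = FALSE)
    }
    list(date = visits[[v]]$date, visit_type = visits[[v]]$visit_type,
         discharge = visits[[v]]$discharge, events = events)
  })

  record <- structure(
    list(person_id = person_id, sex = sex, birth_date = birth_date,
         visits = visit_list),
    class = "ehr_record")
  list(record = record, gt = gt)
}

#' @export
print.ehr_cohort <- function(x, ...) {
  nv <- vapply(x, function(r) length(r$visits), integer(1))
  ne <- vapply(x, function(r) sum(vapply(r$visits, function(v) nrow(v$events), integer(1))), integer(1))
  cat(sprintf("Synthetic EHR cohort: %d patients, %d visits, %d events\n",
              length(x), sum(nv), sum(ne)))
  cat(sprintf("  visits/patient: median %d, range %d-%d\n",
              as.integer(stats::median(nv)), min(nv), max(nv)))
  invisible(x)
}

#' @export
print.ehr_ground_truth <- function(x, ...) {
  cat("Ground truth for injected precursor->target rules\n")
  if (!is.null(x$rule_summary)) print(x$rule_summary) else cat("  (no rules)\n")
  invisible(x)
}
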