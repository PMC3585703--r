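#' Simulation configuration
#'
#' Loads the packaged default configuration (a versioned YAML file under
#' `extdata`) and merges any overrides, then validates: probabilities in
#' \[0, 1\], SDs non-negative, mixture proportions summing to 1.  The
#' defaults describe a public-sector antenatal cohort: near-universal LMP
#' reporting but only about three quarters certain of the date, ultrasound
#' coverage decreasing with earlier windows, and a Capurro exam for most
#' births.
#'
#' @param ... nested overrides, e.g. `n = 500`,
#'   `lmp = list(month_slip_p = 0)`.  Unknown names are rejected.
#' @param file alternative YAML config file to start from.
#' @return a validated `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(n = 100, us = list(error_sd_days = c(0, 0, 0)))
sim_config <- function(..., file = NULL) {
  if (is.null(file)) {
    file <- system.file(
      "extdata", "sim-config-default.yaml", package = "gestage"
    )
  }
  if (!file.exists(file)) {
    abort(sprintf("config file not found: %s", file))
  }
  cfg <- yaml::read_yaml(file)
  if (!identical(cfg$schema, "gestage-sim-config-v1")) {
    abort("unsupported simulation config schema")
  }
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad) > 0) {
      abort(paste0("unknown config fields: ", paste(bad, collapse = ", ")))
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  problems <- character()
  chk_p <- function(x, what) {
    if (!all(is.finite(x)) || any(x < 0 | x > 1)) {
      problems <<- c(problems, sprintf("%s must be in [0, 1]", what))
    }
  }
  chk_sd <- function(x, what) {
    if (!all(is.finite(x)) || any(x < 0)) {
      problems <<- c(problems, sprintf("%s must be >= 0", what))
    }
  }
  if (!is.numeric(cfg$n) || cfg$n < 0 || cfg$n != round(cfg$n)) {
    problems <- c(problems, "n must be a non-negative integer")
  }
  mix <- c(cfg$true_ga$p_preterm, cfg$true_ga$p_term, cfg$true_ga$p_postterm)
  chk_p(mix, "true_ga mixture proportions")
  if (abs(sum(mix) - 1) > 1e-8) {
    problems <- c(problems, "true_ga mixture proportions must sum to 1")
  }
  for (comp in c("preterm", "term", "postterm")) {
    chk_sd(cfg$true_ga[[comp]]$sd, sprintf("true_ga$%s$sd", comp))
  }
  chk_p(
    c(
      cfg$lmp$available_p, cfg$lmp$certain_p, cfg$lmp$month_slip_p,
      cfg$lmp$month_slip_later_p, cfg$us$window_p, cfg$capurro$available_p,
      cfg$weight$gross_error_p, cfg$sex_male_p
    ),
    "availability/slip probabilities"
  )
  chk_sd(
    c(
      cfg$lmp$sd_sure_days, cfg$lmp$sd_unsure_days, cfg$us$error_sd_days,
      cfg$capurro$noise_sd_days, cfg$weight$noise_sd_multiplier
    ),
    "error SDs"
  )
  if (length(cfg$us$window_p) != 3 || length(cfg$us$error_sd_days) != 3) {
    problems <- c(problems, "us$window_p and us$error_sd_days need 3 entries")
  }
  for (cov in names(cfg$covariates)) {
    p <- unlist(cfg$covariates[[cov]])
    chk_p(p, sprintf("covariates$%s", cov))
    if (abs(sum(p) - 1) > 1e-6) {
      problems <- c(problems, sprintf("covariates$%s must sum to 1", cov))
    }
  }
  if (length(problems) > 0) {
    abort(c("invalid simulation config:", problems))
  }
  invisible(cfg)
}

#' Noise-free simulation configuration
#'
#' The degenerate limit used for closed-form pipeline checks: every source
#' available, every error SD and slip probability zero, birthweight exactly
#' at the reference mean.  In a cohort generated under this config every
#' method's GA estimate equals the true GA for every record.
#'
#' @param n cohort size.
#' @param ... further overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
noiseless_config <- function(n = 500, ...) {
  sim_config(
    n = n,
    lmp = list(
      available_p = 1, certain_p = 1, sd_sure_days = 0,
      sd_unsure_days = 0, month_slip_p = 0
    ),
    us = list(window_p = c(1, 1, 1), error_sd_days = c(0, 0, 0)),
    capurro = list(available_p = 1, shrink = 0, noise_sd_days = 0),
    weight = list(noise_sd_multiplier = 0, gross_error_p = 0),
    ...
  )
}

# Truncated-normal draw by rejection (bounds are a handful of SDs wide, so
# the loop terminates quickly); degenerate sd = 0 returns the clamped mean.
rtrunc_norm <- function(mean, sd, lo, hi) {
  if (sd == 0) {
    return(min(max(mean, lo), hi))
  }
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) {
      return(x)
    }
  }
}

sample_cat <- function(probs) {
  sample(names(probs), 1, prob = unlist(probs))
}

# LMP recall month-slip: move the reported date one calendar month later
# (toward the first missed period, underestimating GA) or earlier, using the
# actual length of the month being slipped across.
slip_month <- function(lmp, later) {
  if (later) {
    lmp + days_in_month(lmp)
  } else {
    lmp - days_in_month(as.Date(format(lmp, "%Y-%m-01")) - 1)
  }
}

#' Generate a synthetic perinatal cohort
#'
#' Draws, per pregnancy: a true GA at birth from a three-component mixture
#' (preterm / term / post-term); a birth date and hence a true LMP; an
#' observed LMP with recall error (small symmetric error when the woman is
#' certain of the date; a wider error plus a possible one-calendar-month
#' slip — asymmetric toward later recall, which underestimates GA — when
#' uncertain); up to one ultrasound per gestational window, scheduled
#' uniformly over the window's feasible days, with the clinician GA at exam
#' equal to the true GA at exam plus window-specific error; a Capurro exam
#' estimate shrunk toward a term target plus noise (so GA is overestimated
#' for preterm and underestimated for post-term newborns); and a birthweight
#' drawn from the scoring growth reference at the true GA and sex, with
#' occasional gross transcription errors.  Draws come from per-record
#' substreams derived from `(seed, record index)`, so cohorts are
#' reproducible and insertion order never changes any record's values.
#'
#' @param config a [sim_config()].
#' @param seed integer master seed.
#' @param growth the [growth_reference()] birthweights are drawn from
#'   (use the same reference when scoring, so the outlier machinery is
#'   self-consistent).
#' @return list with `cohort` (the cohort tibble, see [read_cohort()] for
#'   the schema) and `truth` (tibble `id`, `true_ga_days`, `true_class`).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n = 20), seed = 1)
#' sim$cohort
simulate_cohort <- function(config = sim_config(), seed = 1,
                            growth = default_growth_reference()) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n)
  empty_exams <- tibble::tibble(
    exam_date = as.Date(character()), ga_days = integer()
  )
  records <- vector("list", n)
  truth <- vector("list", n)
  start_date <- as_iso_date(config$start_date, "start_date")
  win_lo <- c(49L, 147L, 203L)
  win_hi <- c(146L, 202L, NA)

  for (i in seq_len(n)) {
    set.seed(as.integer(
      (as.numeric(seed) * 1000003 + i * 7919) %% 2147483647
    ))
    id <- sprintf("p%05d", i)

    comp <- sample_cat(list(
      preterm = config$true_ga$p_preterm,
      term = config$true_ga$p_term,
      postterm = config$true_ga$p_postterm
    ))
    par <- config$true_ga[[comp]]
    true_ga <- as.integer(round(
      rtrunc_norm(par$mean, par$sd, par$min, par$max)
    ))
    birth_date <- start_date +
      sample.int(config$birth_span_days, 1) - 1L
    true_lmp <- birth_date - true_ga
    sex <- if (runif(1) < config$sex_male_p) "male" else "female"

    # observed LMP
    lmp_date <- as.Date(NA)
    lmp_certain <- NA
    if (runif(1) < config$lmp$available_p) {
      lmp_certain <- runif(1) < config$lmp$certain_p
      sd_err <- if (lmp_certain) {
        config$lmp$sd_sure_days
      } else {
        config$lmp$sd_unsure_days
      }
      obs <- true_lmp + round(rnorm(1, 0, sd_err))
      if (!lmp_certain && runif(1) < config$lmp$month_slip_p) {
        obs <- slip_month(obs, runif(1) < config$lmp$month_slip_later_p)
      }
      # keep the implied GA positive; gross negatives are capped, not dropped
      if (obs > birth_date - 7) {
        obs <- birth_date - 7
      }
      lmp_date <- obs
    }

    # ultrasound exams, at most one per window over its feasible days
    exams <- empty_exams
    for (w in 1:3) {
      hi <- min(win_hi[w], true_ga, na.rm = TRUE)
      if (hi < win_lo[w] || runif(1) >= config$us$window_p[w]) {
        next
      }
      exam_true_ga <- win_lo[w] + sample.int(hi - win_lo[w] + 1L, 1) - 1L
      obs_ga <- exam_true_ga +
        as.integer(round(rnorm(1, 0, config$us$error_sd_days[w])))
      obs_ga <- min(max(obs_ga, 0L), 315L)
      exams <- dplyr::bind_rows(exams, tibble::tibble(
        exam_date = birth_date - (true_ga - exam_true_ga),
        ga_days = obs_ga
      ))
    }

    # Capurro neonatal exam: shrunk toward term plus noise
    capurro <- NA_integer_
    if (runif(1) < config$capurro$available_p) {
      capurro <- as.integer(round(
        true_ga +
          config$capurro$shrink * (config$capurro$target_days - true_ga) +
          rnorm(1, 0, config$capurro$noise_sd_days)
      ))
      capurro <- min(max(capurro, 140L), 330L)
    }

    # birthweight from the scoring reference at the true GA
    row <- lookup_reference(growth, sex, min(max(ga_weeks(true_ga), 22), 44))
    weight <- rnorm(
      1, row$mean_g, row$sd_g * config$weight$noise_sd_multiplier
    )
    if (runif(1) < config$weight$gross_error_p) {
      weight <- runif(1, config$weight$gross_min_g, config$weight$gross_max_g)
    }
    weight <- max(round(weight), 250)

    covs <- purrr::map_chr(config$covariates, sample_cat)
    records[[i]] <- tibble::tibble(
      id = id, lmp_date = lmp_date, lmp_certain = lmp_certain,
      capurro_ga_days = capurro, birth_date = birth_date,
      birth_weight_g = weight, infant_sex = sex,
      city = covs[["city"]], age_group = covs[["age_group"]],
      ethnicity = covs[["ethnicity"]], schooling = covs[["schooling"]],
      marital = covs[["marital"]], parity = covs[["parity"]],
      us_exams = list(exams)
    )
    truth[[i]] <- tibble::tibble(
      id = id, true_ga_days = true_ga, true_class = comp
    )
  }
  if (n == 0) {
    cohort <- tibble::tibble(
      id = character(), lmp_date = as.Date(character()),
      lmp_certain = logical(), capurro_ga_days = integer(),
      birth_date = as.Date(character()), birth_weight_g = numeric(),
      infant_sex = character(), city = character(), age_group = character(),
      ethnicity = character(), schooling = character(),
      marital = character(), parity = character(), us_exams = list()
    )
    truth_tbl <- tibble::tibble(
      id = character(), true_ga_days = integer(), true_class = character()
    )
  } else {
    cohort <- dplyr::bind_rows(records)
    truth_tbl <- dplyr::bind_rows(truth)
  }
  list(cohort = cohort, truth = truth_tbl)
}

#' Join simulated truth onto estimates and assignments
#'
#' Produces the evaluation table for a simulated cohort: per record, the
#' true GA and class, each method's estimate error in days (estimate minus
#' truth), and — when assignments are supplied — the assigned method, its
#' error, and whether the assigned maturity class matches the truth.
#'
#' @param cohort a cohort tibble.
#' @param truth the truth tibble from [simulate_cohort()].
#' @param assignments optional output of [assign_ga()].
#' @return tibble, one row per cohort record, with `err_<METHOD>` columns.
#' @export
truth_join <- function(cohort, truth, assignments = NULL) {
  if (!setequal(cohort$id, truth$id) ||
        nrow(truth) != length(unique(truth$id))) {
    abort("id mismatch between cohort and truth table")
  }
  em <- estimate_matrix(cohort)
  out <- tibble::tibble(
    id = cohort$id,
    true_ga_days = truth$true_ga_days[match(cohort$id, truth$id)],
    true_class = truth$true_class[match(cohort$id, truth$id)]
  )
  for (m in GA_METHODS) {
    out[[paste0("err_", m)]] <-
      em[[m]][match(out$id, em$id)] - out$true_ga_days
  }
  if (!is.null(assignments)) {
    if (!setequal(assignments$id, cohort$id)) {
      abort("id mismatch between cohort and assignments")
    }
    pos <- match(out$id, assignments$id)
    out$assigned_method <- assignments$assigned_method[pos]
    out$assigned_ga_days <- assignments$ga_days[pos]
    out$err_assigned <- out$assigned_ga_days - out$true_ga_days
    out$class_correct <- as.character(
      classify_maturity(out$assigned_ga_days)
    ) == out$true_class
  }
  out
}
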