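#' @importFrom Matrix sparseMatrix
NULL

#' Synthetic two-site cohort configuration
#'
#' Both sites share the same latent clinical event processes (conditions
#' occurring as Poisson episode streams with log-linear covariate effects);
#' they differ only in their *coding channels*: which codes an episode of a
#' condition emits, with what probability, and with what per-endorsement
#' multiplicity. This separation is what makes planted differences pure
#' coding heterogeneity rather than clinical heterogeneity, and it gives the
#' two sites a shared co-occurrence geometry for embedding alignment.
#'
#' @param n_patients Patients per site.
#' @param study_years Study length in years; person-time is drawn uniformly
#'   on (0.5, `study_years`].
#' @param covariates List of covariate distribution parameters:
#'   `age_mean`, `age_sd`, `sex_p`, `insulin_p`, `elix_mean`.
#' @param conditions `data.frame(condition, rate, b_age, b_sex, b_ins,
#'   b_elix)`: baseline episode rate per person-year and log-rate
#'   coefficients on standardized covariates.
#' @param channel_a,channel_b Per-site emission channels:
#'   `data.frame(condition, code, code_type, group, prob, mult)`. `prob` is
#'   the probability an episode of `condition` emits `code`; `mult` the
#'   number of endorsements emitted when it does; `group` of `NA` leaves the
#'   code ungrouped. Per condition and site, emission probabilities must sum
#'   to at most 1.
#' @param window Co-emission window in days: all endorsements of an episode
#'   are dated within `window` days after the episode date.
#' @param truth Optional [ground_truth()] describing the planted cross-site
#'   correspondence (scenario constructors fill this in).
#' @param seed Integer seed; [generate_cohort()] is reproducible given it.
#' @return A `synth_config`.
#' @export
synth_config <- function(n_patients = 1000L, study_years = 5,
                         covariates = list(age_mean = 63, age_sd = 10,
                                           sex_p = 0.49, insulin_p = 0.21,
                                           elix_mean = 3.6),
                         conditions, channel_a, channel_b,
                         window = 7L, truth = NULL, seed = 1L) {
  conditions <- as.data.table(conditions)
  channel_a <- as.data.table(channel_a)
  channel_b <- as.data.table(channel_b)
  for (ch in list(channel_a, channel_b)) {
    if (any(ch$prob < 0 | ch$prob > 1))
      stop("emission probabilities must lie in [0, 1]")
    tot <- ch[, .(s = sum(prob)), by = condition]
    if (any(tot$s > 1 + 1e-12))
      stop("emission probabilities exceed 1 for condition(s): ",
           paste(tot$condition[tot$s > 1 + 1e-12], collapse = ", "))
    if (!all(ch$condition %in% conditions$condition))
      stop("channel refers to unknown condition")
  }
  if (any(conditions$rate <= 0)) stop("condition rates must be > 0")
  structure(list(n_patients = as.integer(n_patients),
                 study_years = study_years, covariates = covariates,
                 conditions = conditions, channel_a = channel_a,
                 channel_b = channel_b, window = as.integer(window),
                 truth = truth, seed = as.integer(seed)),
            class = "synth_config")
}

#' Ground-truth cross-site correspondence for a synthetic scenario
#'
#' For each source-site (site A) code, the set of reference-site (site B)
#' codes that carry the same clinical content, weighted by the reference
#' site's emission distribution for the emitting condition (weights sum to
#' one per source code). Null groups are coded identically at both sites;
#' planted codes/groups carry the engineered coding difference.
#'
#' @param map Named list: source code -> `data.frame(ref, weight)`.
#' @param planted_codes,planted_groups Codes/groups carrying planted
#'   heterogeneity.
#' @param null_groups Groups with identical emission tables at both sites.
#' @return A `ground_truth`.
#' @export
ground_truth <- function(map, planted_codes = character(),
                         planted_groups = character(),
                         null_groups = character()) {
  for (m in map) {
    if (abs(sum(m$weight) - 1) > 1e-8)
      stop("ground-truth weights must sum to 1 per source code")
  }
  if (length(intersect(planted_groups, null_groups)))
    stop("planted and null group lists must be disjoint")
  structure(list(map = map, planted_codes = planted_codes,
                 planted_groups = planted_groups, null_groups = null_groups),
            class = "ground_truth")
}

# Standardized covariate design used by the episode intensity model.
synth_design <- function(covars, cv) {
  cbind(z_age = (covars$age - cv$age_mean) / cv$age_sd,
        z_sex = covars$sex - cv$sex_p,
        z_ins = covars$insulin_use - cv$insulin_p,
        z_elix = (covars$elixhauser - cv$elix_mean) / sqrt(cv$elix_mean))
}

draw_covariates <- function(config, site_id) {
  cv <- config$covariates
  n <- config$n_patients
  covariate_table(
    patient_id = sprintf("%s%05d", site_id, seq_len(n)),
    person_time = runif(n, 0.5, config$study_years),
    age = rnorm(n, cv$age_mean, cv$age_sd),
    sex = rbinom(n, 1L, cv$sex_p),
    insulin_use = rbinom(n, 1L, cv$insulin_p),
    elixhauser = rpois(n, cv$elix_mean))
}

# Emit one site's events from its covariates and coding channel.
emit_site <- function(config, covars, channel, site_id) {
  cond <- config$conditions
  Z <- synth_design(covars, config$covariates)
  B <- t(as.matrix(cond[, .(b_age, b_sex, b_ins, b_elix)]))
  lp <- Z %*% B                               # patients x conditions
  lam <- covars$person_time * exp(sweep(lp, 2L, log(cond$rate), "+"))
  m <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
  pt_days <- pmax(1L, floor(covars$person_time * 365))
  pid <- code <- ctype <- list(); day <- list(); k <- 0L
  for (ci in seq_len(ncol(m))) {
    n_ep <- m[, ci]
    tot <- sum(n_ep)
    if (tot == 0L) next
    ep_pat <- rep(seq_along(n_ep), n_ep)
    ep_day <- 1L + floor(runif(tot) * rep(pt_days, n_ep))
    rows <- channel[condition == cond$condition[ci]]
    if (nrow(rows) == 0L) next
    for (ri in seq_len(nrow(rows))) {
      hit <- runif(tot) < rows$prob[ri]
      if (!any(hit)) next
      mult <- rows$mult[ri]
      idx <- rep(which(hit), each = mult)
      k <- k + 1L
      pid[[k]] <- ep_pat[idx]
      day[[k]] <- ep_day[idx] + sample.int(config$window + 1L,
                                           length(idx), replace = TRUE) - 1L
      code[[k]] <- rep(rows$code[ri], length(idx))
      ctype[[k]] <- rep(rows$code_type[ri], length(idx))
    }
  }
  if (k == 0L) {
    return(event_table(site_id, character(), as.Date(character()),
                       character(), character()))
  }
  ev <- data.table(patient_id = covars$patient_id[unlist(pid)],
                   date = as.Date("2015-01-01") + unlist(day),
                   code = unlist(code), code_type = unlist(ctype))
  setorder(ev, patient_id, date, code)
  event_table(site_id, ev$patient_id, ev$date, ev$code, ev$code_type)
}

#' Generate a paired two-site synthetic cohort
#'
#' Draws covariates and person-time per patient, latent condition episodes
#' from a Poisson process with shared log-linear covariate effects, and
#' emits coded events through each site's channel; all endorsements of an
#' episode fall within the co-emission window of the episode date. Byte
#' identical across repeat calls with the same config (seed included).
#'
#' @param config A [synth_config()].
#' @return List with `events_a`, `covars_a`, `events_b`, `covars_b`,
#'   `truth` (a [ground_truth()]), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  covars_a <- draw_covariates(config, "A")
  events_a <- emit_site(config, covars_a, config$channel_a, "A")
  covars_b <- draw_covariates(config, "B")
  events_b <- emit_site(config, covars_b, config$channel_b, "B")
  truth <- config$truth
  if (is.null(truth)) {
    shared <- intersect(config$channel_a$code, config$channel_b$code)
    truth <- ground_truth(setNames(lapply(shared, function(cd)
      data.frame(ref = cd, weight = 1)), shared))
  }
  list(events_a = events_a, covars_a = covars_a,
       events_b = events_b, covars_b = covars_b,
       truth = truth, config = config)
}

#' Group catalog implied by a synthetic configuration
#' @param config A [synth_config()].
#' @return A [group_catalog()] over the grouped codes of both channels.
#' @export
synth_group_catalog <- function(config) {
  ch <- unique(rbind(config$channel_a, config$channel_b)[, .(code, group)])
  ch <- ch[!is.na(group)]
  group_catalog(ch$code, ch$group)
}

#' Expected per-code endorsement rates implied by a configuration
#'
#' Closed-form expectation of each code's endorsements per person-year,
#' marginalized over the covariate distribution: baseline condition rate
#' times the covariate moment generating factor times emission probability
#' times multiplicity. Used to verify planted frequency-ratio structure
#' analytically, without simulation.
#'
#' @param config A [synth_config()].
#' @return `data.table(site, code, group, rate)`.
#' @export
expected_code_rates <- function(config) {
  cv <- config$covariates
  cond <- config$conditions
  mgf <- function(b_age, b_sex, b_ins, b_elix) {
    s <- sqrt(cv$elix_mean)
    exp(b_age^2 / 2) *
      exp(-b_sex * cv$sex_p) * (1 - cv$sex_p + cv$sex_p * exp(b_sex)) *
      exp(-b_ins * cv$insulin_p) * (1 - cv$insulin_p + cv$insulin_p * exp(b_ins)) *
      exp(-b_elix * cv$elix_mean / s + cv$elix_mean * (exp(b_elix / s) - 1))
  }
  cond[, adj := mgf(b_age, b_sex, b_ins, b_elix), by = condition]
  out <- rbindlist(lapply(list(A = config$channel_a, B = config$channel_b),
                          function(ch) {
    x <- merge(ch, cond[, .(condition, rate0 = rate, adj)], by = "condition")
    x[, .(code, group, rate = rate0 * adj * prob * mult)]
  }), idcol = "site")
  cond[, adj := NULL]
  out[, .(rate = sum(rate)), by = .(site, code, group)]
}

# Generative ground truth: a source code's support set is the reference
# channel's emission distribution of its emitting condition, restricted to
# the source code's own clinical category (the candidate scope of the
# mapping stage) and renormalized. Codes of one condition within one group
# are content-equivalent views of the same clinical event, so they share a
# support set; ungrouped codes map to their identically named reference
# code when the reference channel emits it.
generative_truth <- function(channel_a, channel_b, planted_codes = character(),
                             planted_groups = character(),
                             null_groups = character()) {
  map <- list()
  for (i in seq_len(nrow(channel_a))) {
    sc <- channel_a$code[i]
    if (sc %in% names(map)) next
    g <- channel_a$group[i]
    if (is.na(g)) {
      hit <- channel_b[code == sc]
      if (nrow(hit)) map[[sc]] <- data.frame(ref = sc, weight = 1)
      next
    }
    refs <- channel_b[condition == channel_a$condition[i] & !is.na(group) &
                        group == g]
    if (nrow(refs) == 0L) next
    map[[sc]] <- data.frame(ref = refs$code, weight = refs$prob / sum(refs$prob))
  }
  ground_truth(map, planted_codes = planted_codes,
               planted_groups = planted_groups, null_groups = null_groups)
}

# Shared building blocks for the scenario presets -------------------------

null_conditions <- function(ids, rate = 1) {
  data.table(condition = ids, rate = rate,
             b_age = rep_len(c(0.15, -0.1, 0.2, 0.05, -0.15, 0.1), length(ids)),
             b_sex = rep_len(c(-0.1, 0.15, 0, -0.2, 0.1, 0.05), length(ids)),
             b_ins = rep_len(c(0.2, 0, -0.1, 0.15, 0.05, -0.05), length(ids)),
             b_elix = rep_len(c(0.1, 0.2, 0.15, 0, -0.1, 0.25), length(ids)))
}

null_channel <- function(ids) {
  rbindlist(lapply(seq_along(ids), function(k) {
    id <- ids[k]
    data.table(condition = id,
               code = c(sprintf("D%02d.1", k), sprintf("D%02d.2", k),
                        sprintf("P%02d", k)),
               code_type = c("ICD10", "ICD10", "CPT"),
               group = c(sprintf("G%02d", k), sprintf("G%02d", k),
                         sprintf("PG%02d", k)),
               prob = c(0.35, 0.25, 0.40), mult = 1L)
  }))
}

#' Null scenario: identical coding channels at both sites
#'
#' Six conditions, each emitting two diagnosis codes and one procedure code
#' with the same probabilities at both sites. The ground-truth map is the
#' identity on the shared vocabulary; every group is a null group. Serves as
#' the type-I-error and domain-confusion null harness.
#'
#' @param n_patients Patients per site.
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
scenario_null <- function(n_patients = 1000L, seed = 1L) {
  ids <- sprintf("C%d", 1:6)
  ch <- null_channel(ids)
  shared <- ch$code
  truth <- ground_truth(setNames(lapply(shared, function(cd)
    data.frame(ref = cd, weight = 1)), shared),
    null_groups = unique(ch$group[!is.na(ch$group)]))
  synth_config(n_patients = n_patients, conditions = null_conditions(ids),
               channel_a = ch, channel_b = copy(ch), truth = truth,
               seed = seed)
}

#' Code-substitution scenario
#'
#' Three planted conditions are coded in one group `"S"` with a
#' specific/unspecified code pair per condition: site A endorses the
#' specific code with probability 0.55 and the unspecified one with 0.05,
#' site B the reverse, so the group-level emission intensity is identical
#' (expected group frequency ratio 1) while each member code's expected
#' ratio is 11 in one direction. Each planted condition also emits a shared
#' CPT marker at both sites, five null groups are coded identically, and
#' site B additionally uses two local codes site A never emits.
#'
#' @param n_patients Patients per site.
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
scenario_substitution <- function(n_patients = 1000L, seed = 1L) {
  nul <- sprintf("C%d", 1:5)
  sub <- sprintf("S%d", 1:3)
  conditions <- rbind(null_conditions(nul),
                      null_conditions(sub, rate = 1.2),
                      data.table(condition = "ADMIN", rate = 1.5, b_age = 0,
                                 b_sex = 0, b_ins = 0, b_elix = 0.1))
  ch_null <- null_channel(nul)
  mk_sub <- function(p_spec, p_unspec) {
    rbindlist(lapply(seq_along(sub), function(k)
      data.table(condition = sub[k],
                 code = c(sprintf("H%d1.49", k), sprintf("H%d1.40", k),
                          sprintf("Q%d", k)),
                 code_type = c("ICD10", "ICD10", "CPT"),
                 group = c("S", "S", sprintf("QG%d", k)),
                 prob = c(p_spec, p_unspec, 0.40), mult = 1L)))
  }
  ch_a <- rbind(ch_null, mk_sub(0.55, 0.05))
  ch_b <- rbind(ch_null, mk_sub(0.05, 0.55),
                data.table(condition = "ADMIN",
                           code = c("LOC1", "LOC2"),
                           code_type = "LOCAL", group = NA_character_,
                           prob = c(0.3, 0.2), mult = 1L))
  spec_codes <- sprintf("H%d1.49", 1:3)
  unspec_codes <- sprintf("H%d1.40", 1:3)
  truth <- generative_truth(ch_a, ch_b,
                            planted_codes = c(spec_codes, unspec_codes),
                            planted_groups = "S",
                            null_groups = unique(ch_null$group))
  synth_config(n_patients = n_patients, conditions = conditions,
               channel_a = ch_a, channel_b = ch_b, truth = truth, seed = seed)
}

#' Coding-granularity scenario
#'
#' One planted condition that site A codes with three laterality-specific
#' codes (right, left, bilateral) while site B emits a single unspecified
#' code with the same total emission probability; group totals agree in
#' expectation while individual code rates differ. Five null groups and a
#' shared CPT marker as in [scenario_substitution()].
#'
#' @param n_patients Patients per site.
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
scenario_granularity <- function(n_patients = 1000L, seed = 1L) {
  nul <- sprintf("C%d", 1:5)
  conditions <- rbind(null_conditions(nul), null_conditions("T", rate = 1.5))
  lateral <- c("T26.491", "T26.492", "T26.493")
  ch_a <- rbind(null_channel(nul),
                data.table(condition = "T", code = c(lateral, "QT"),
                           code_type = c(rep("ICD10", 3L), "CPT"),
                           group = c(rep("T", 3L), "QGT"),
                           prob = c(0.20, 0.20, 0.15, 0.40), mult = 1L))
  ch_b <- rbind(null_channel(nul),
                data.table(condition = "T", code = c("T26.40", "QT"),
                           code_type = c("ICD10", "CPT"),
                           group = c("T", "QGT"),
                           prob = c(0.55, 0.40), mult = 1L))
  truth <- generative_truth(ch_a, ch_b,
                            planted_codes = c(lateral, "T26.40"),
                            planted_groups = "T",
                            null_groups = unique(null_channel(nul)$group))
  synth_config(n_patients = n_patients, conditions = conditions,
               channel_a = ch_a, channel_b = ch_b, truth = truth, seed = seed)
}
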