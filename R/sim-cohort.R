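#' Configuration for the synthetic cohort generator
#'
#' Produces a per-child cohort table (ages 60-167 months, i.e. 5-13 years,
#' matching the study population) with family structure: a fraction of
#' children are siblings sharing a parent/carer id. Questionnaire item
#' responses for all four disgust-sensitivity instruments are driven by a
#' single latent factor per family dyad, so instrument totals correlate at
#' approximately `latent_correlation`.
#'
#' @param n_participants number of children
#' @param age_range_months inclusive age bracket, months
#' @param sibling_fraction fraction of children who share a parent with
#'   another child
#' @param latent_correlation target Pearson correlation among questionnaire
#'   totals, in `[-1, 1]`
#' @param seed RNG seed
#' @return an object of class `cohort_sim_config`
#' @export
cohort_sim_config <- function(n_participants = 44,
                              age_range_months = c(60, 167),
                              sibling_fraction = 0.2,
                              latent_correlation = 0.3, seed = 1) {
  if (n_participants < 1) abort_input("n_participants must be >= 1")
  if (n_participants < 2 && sibling_fraction > 0)
    abort_input("sibling_fraction > 0 requires at least 2 participants")
  if (abs(latent_correlation) > 1)
    abort_input("latent_correlation must lie in [-1, 1]")
  if (sibling_fraction < 0 || sibling_fraction > 1)
    abort_input("sibling_fraction must lie in [0, 1]")
  structure(list(n_participants = n_participants,
                 age_range_months = age_range_months,
                 sibling_fraction = sibling_fraction,
                 latent_correlation = latent_correlation, seed = seed),
            class = "cohort_sim_config")
}

# discretise a latent score into an integer item response in [0, max]
latent_to_items <- function(s, n_items, max_resp, item_noise_sd = 0.5) {
  z <- s + rnorm(n_items, 0, item_noise_sd)
  pmin(max_resp, pmax(0, round(pnorm(z) * max_resp)))
}

#' Generate a synthetic cohort with correlated questionnaire responses
#'
#' Latent disgust sensitivity is drawn per family; each instrument's
#' continuous scale score loads on it with `sqrt(latent_correlation)`, so
#' any two instrument totals correlate at about `latent_correlation` (minus
#' a few percent of discretisation attenuation). Behavioural avoidance and
#' the gastric index are simulated independent of the questionnaires,
#' mirroring the null relations observed in this population. Parent-report
#' instruments are generated once per parent and shared across siblings.
#'
#' @param cfg a [cohort_sim_config()]
#' @return a list: `cohort` (one row per child: ids, age, sex, avoidance
#'   score in ms, gastric index, questionnaire totals) and `responses`
#'   (item-level response tables per instrument, keyed by participant)
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  n <- cfg$n_participants
  with_seed(cfg$seed, {
    # family assignment: sibling children reattach to an existing parent
    parent <- seq_len(n)
    n_sib <- round(cfg$sibling_fraction * n)
    if (n_sib > 0) {
      sibs <- sample.int(n, n_sib)
      for (i in sibs) {
        others <- setdiff(seq_len(n), i)
        parent[i] <- parent[sample(others, 1)]
      }
    }
    parent_id <- sprintf("f%03d", match(parent, unique(parent)))
    participant_id <- sprintf("p%03d", seq_len(n))
    age <- sample(seq(cfg$age_range_months[1], cfg$age_range_months[2]),
                  n, replace = TRUE)
    sex <- sample(c("F", "M"), n, replace = TRUE)

    rho <- cfg$latent_correlation
    a <- sqrt(abs(rho)) * sign(rho)
    fam_latent <- rnorm(length(unique(parent_id)))
    names(fam_latent) <- unique(parent_id)
    g <- fam_latent[parent_id]

    specs <- lapply(instrument_names(), instrument_spec)
    names(specs) <- instrument_names()
    responses <- list()
    totals <- list()
    for (nm in names(specs)) {
      sp <- specs[[nm]]
      per_parent <- nm != "child_22"   # parents fill the adult instruments
      unit <- if (per_parent) parent_id else participant_id
      uu <- unique(unit)
      scale_score <- a * fam_latent[if (per_parent) uu else parent_id[match(uu, participant_id)]] +
        sqrt(1 - a^2) * rnorm(length(uu))
      names(scale_score) <- uu
      items <- t(vapply(uu, function(u)
        latent_to_items(scale_score[u], sp$n_items, sp$response_range[2]),
        numeric(sp$n_items)))
      resp <- data.frame(participant_id = participant_id,
                         items[match(unit, uu), , drop = FALSE])
      names(resp)[-1] <- paste0("item_", seq_len(sp$n_items))
      rownames(resp) <- NULL
      responses[[nm]] <- resp
      totals[[nm]] <- score_questionnaire(resp, sp)$total
    }

    cohort <- data.frame(participant_id = participant_id,
                         parent_id = parent_id,
                         age_months = age, sex = sex,
                         avoidance_score_ms = rnorm(n, -700, 500),
                         gastric_index = rnorm(n, 0, 0.35))
    for (nm in names(totals)) cohort[[paste0(nm, "_total")]] <- totals[[nm]]
    list(cohort = cohort, responses = responses)
  })
}
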