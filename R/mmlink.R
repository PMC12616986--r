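#' Translate breeding-scheme responses into a mechanistic-model update
#'
#' Step two to three of the coupled pipeline: the correlated annual
#' responses predicted for the acquisition/allocation (AA) input traits (in
#' genetic-SD units per year) are converted to trait units, accumulated over
#' the time horizon, and added to the initial AA means; heritabilities are
#' updated for the Bulmer effect using the observed variance-retention
#' factors with unchanged residual variances. Genetic correlations among AA
#' traits are kept at their initial values.
#'
#' @param result A [run_scheme()] result (or any tibble-like with columns
#'   `trait`, `annual_gain_sd` for the AA traits and an `alpha` table).
#' @param horizon Years of selection (10, 20 or 30 typically).
#' @param means Initial AA means, as [aa_means()].
#' @param h2,cv Base heritability and phenotypic CV of the AA traits.
#' @return A tibble of class `selection_update`: per AA trait the annual
#'   response, `delta_mean` (trait units), `new_mean`, `alpha`, `h2_prime`,
#'   and the updated genetic/residual variances.
#' @export
build_update <- function(result, horizon, means = aa_means(),
                         h2 = 0.35, cv = 0.10) {
  if (horizon <= 0) cfg_error("horizon must be positive")
  aa_panel <- c(bas_acq = "BasAcq", lact_acq = "LactAcq",
                f_prio_gs = "f_prio_GS", lact_all = "LactAll")
  gains <- if (inherits(result, "scheme_result")) result$mean_gains else result
  resp <- setNames(gains$annual_gain_sd[match(aa_panel, gains$trait)],
                   names(aa_panel))
  if (anyNA(resp)) cfg_error("scheme result lacks responses for the AA traits")
  alpha <- if (inherits(result, "scheme_result")) {
    setNames(result$alpha$alpha[match(aa_panel, result$alpha$trait)],
             names(aa_panel))
  } else setNames(rep(1, 4), names(aa_panel))
  alpha <- pmin(pmax(alpha, 1e-6), 1)
  sigma_p <- cv * means[names(aa_panel)]
  sigma_g <- sqrt(h2) * sigma_p
  delta <- resp * sigma_g * horizon
  out <- tibble(
    trait = names(aa_panel),
    annual_response_sd = unname(resp),
    sigma_g = unname(sigma_g),
    delta_mean = unname(delta),
    new_mean = unname(means[names(aa_panel)] + delta),
    alpha = unname(alpha),
    h2_prime = unname(bulmer_update(rep_len(h2, 4), alpha)),
    var_g = unname(alpha * sigma_g^2),
    var_e = unname((1 - h2) * sigma_p^2),
    horizon = horizon
  )
  class(out) <- c("selection_update", class(out))
  out
}

#' Identity update (no selection)
#'
#' @param means,h2,cv As in [build_update()].
#' @return A `selection_update` leaving the baseline configuration unchanged.
#' @export
identity_update <- function(means = aa_means(), h2 = 0.35, cv = 0.10) {
  sigma_p <- cv * means
  out <- tibble(trait = names(means),
                annual_response_sd = 0,
                sigma_g = unname(sqrt(h2) * sigma_p),
                delta_mean = 0, new_mean = unname(means), alpha = 1,
                h2_prime = h2,
                var_g = unname(h2 * sigma_p^2),
                var_e = unname((1 - h2) * sigma_p^2), horizon = 0)
  class(out) <- c("selection_update", class(out))
  out
}

#' Mechanistic prediction of phenotypic selection response
#'
#' Step three of the pipeline: populations of cows are re-simulated with the
#' mechanistic model before and after selection (initial versus updated AA
#' means and Bulmer-updated variances) under the same feed-offer pattern,
#' and the selection response of each derived trait is the difference of
#' population means divided by the horizon, standardized by the baseline
#' genetic standard deviation of the trait. Before/after populations use
#' paired seeds (common random numbers) to reduce Monte-Carlo variance.
#'
#' @param update A [build_update()] result.
#' @param scenario `"HS"` or `"MS"`.
#' @param n_cows Cows per re-simulated population (the reference analysis
#'   uses 2000).
#' @param seed Integer seed shared by the paired populations.
#' @param genetic_sd Named vector of baseline genetic SDs (trait units) for
#'   the derived traits, e.g. from [estimate_variance_components()] on the
#'   baseline population (`sigma_g`); traits without an entry are reported
#'   unstandardized with a flag.
#' @param config Herd-model configuration.
#' @param calendar Optional pre-built feed calendar for `scenario`.
#' @param daughters_per_sire Family size of the re-simulated populations.
#' @return A tibble of class `mm_response`: per derived trait the before and
#'   after means, the annualized response (`annual_response_sd` where a
#'   genetic SD is available), plus the two lifetime summaries as attributes
#'   (`summary_before`, `summary_after`).
#' @export
predict_mm_response <- function(update, scenario = c("HS", "MS"),
                                n_cows = 2000, seed = 1,
                                genetic_sd = NULL,
                                config = herd_config(),
                                calendar = NULL,
                                daughters_per_sire = 20) {
  scenario <- match.arg(scenario)
  horizon <- update$horizon[1]
  if (is.null(calendar)) {
    calendar <- make_feed_calendar(scenario, n_years = config$max_years)
  }
  n_sires <- max(2L, round(n_cows / daughters_per_sire))
  base_pop <- sample_founders(n_sires, daughters_per_sire, seed = seed)
  upd <- setNames(update$new_mean, update$trait)[aa_traits()]
  upd_pop <- sample_founders(
    n_sires, daughters_per_sire, means = upd, seed = seed,
    var_g = setNames(update$var_g, update$trait)[aa_traits()],
    var_e = setNames(update$var_e, update$trait)[aa_traits()])
  sim_b <- simulate_herd(base_pop, calendar, config, seed = seed)
  sim_a <- simulate_herd(upd_pop, calendar, config, seed = seed)
  ph_b <- derive_phenotypes(sim_b)
  ph_a <- derive_phenotypes(sim_a)
  traits <- c(BWcalv1 = "bw_calv1", Milk = "milk_280", DMI = "dmi_mean",
              IFC = "ifc", Lact_Eff = "lact_eff", Life_Eff = "life_eff")
  mb <- vapply(traits, function(v) mean(ph_b[[v]], na.rm = TRUE), numeric(1))
  ma <- vapply(traits, function(v) mean(ph_a[[v]], na.rm = TRUE), numeric(1))
  ann <- if (horizon > 0) (ma - mb) / horizon else ma - mb
  sg <- rep(NA_real_, length(traits))
  if (!is.null(genetic_sd)) {
    sg <- unname(genetic_sd[names(traits)])
  }
  out <- tibble(trait = names(traits), scenario = scenario,
                horizon = horizon,
                mean_before = unname(mb), mean_after = unname(ma),
                annual_response = unname(ann),
                genetic_sd = sg,
                annual_response_sd = unname(ann) / sg)
  attr(out, "summary_before") <- lifetime_summary(ph_b)
  attr(out, "summary_after") <- lifetime_summary(ph_a)
  attr(out, "phenotypes") <- list(before = ph_b, after = ph_a)
  class(out) <- c("mm_response", class(out))
  out
}

#' Baseline genetic standard deviations of the derived traits
#'
#' Simulates a baseline population in the given scenario, derives the
#' complex phenotypes and estimates their genetic SDs with the half-sib
#' estimator; used to standardize mechanistic responses.
#'
#' @param scenario,n_sires,daughters_per_sire,seed,config Simulation set-up.
#' @return Named vector of genetic SDs (trait units) for `BWcalv1`, `Milk`,
#'   `DMI`, `IFC`, `Lact_Eff`, `Life_Eff`.
#' @export
baseline_genetic_sd <- function(scenario = "HS", n_sires = 100,
                                daughters_per_sire = 20, seed = 1,
                                config = herd_config()) {
  pop <- sample_founders(n_sires, daughters_per_sire, seed = seed)
  cal <- make_feed_calendar(scenario, n_years = config$max_years)
  sim <- simulate_herd(pop, cal, config, seed = seed)
  ph <- derive_phenotypes(sim)
  est_tbl <- dplyr::transmute(ph, animal_id = .data$animal_id,
                              BWcalv1 = .data$bw_calv1, Milk = .data$milk_280,
                              DMI = .data$dmi_mean, IFC = .data$ifc,
                              Lact_Eff = .data$lact_eff,
                              Life_Eff = .data$life_eff)
  est <- estimate_variance_components(est_tbl, pop$pedigree)
  est$sigma_g
}

#' Compare mechanistic and conventional response predictions
#'
#' Elementwise differences (mechanistic minus conventional) per trait and
#' goal, the per-trait rank ordering of goals under each method, and flags
#' for rank inversions.
#'
#' @param mm Tibble with columns `goal`, `trait`, `annual_response_sd`
#'   (mechanistic predictions, e.g. stacked [predict_mm_response()] rows
#'   with a `goal` column added).
#' @param conventional Tibble with columns `goal`, `trait`,
#'   `annual_gain_sd` (e.g. stacked `mean_gains` of [run_scheme()] results
#'   mapped to goal-trait names).
#' @return A list of class `method_comparison` with `differences` (tibble:
#'   goal, trait, mm, conventional, difference) and `rankings` (tibble:
#'   trait, goal, rank_mm, rank_conventional, inverted).
#' @export
compare_methods <- function(mm, conventional) {
  if (!setequal(unique(mm$goal), unique(conventional$goal))) {
    cfg_error("mechanistic and conventional tables must cover the same goals")
  }
  diffs <- dplyr::inner_join(
    dplyr::select(mm, "goal", "trait", mm = "annual_response_sd"),
    dplyr::select(conventional, "goal", "trait",
                  conventional = "annual_gain_sd"),
    by = c("goal", "trait")) %>%
    mutate(difference = .data$mm - .data$conventional)
  rankings <- diffs %>%
    group_by(.data$trait) %>%
    mutate(rank_mm = rank(-.data$mm, ties.method = "first"),
           rank_conventional = rank(-.data$conventional,
                                    ties.method = "first"),
           inverted = .data$rank_mm != .data$rank_conventional) %>%
    ungroup() %>%
    select("trait", "goal", "rank_mm", "rank_conventional", "inverted")
  structure(list(differences = diffs, rankings = rankings),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  print(as.data.frame(x$differences), row.names = FALSE)
  invisible(x)
}

#' Full coupled prediction pipeline for one breeding goal
#'
#' Runs the conventional scheme, builds the selection update for each
#' horizon, re-simulates the mechanistic populations in both environments,
#' and returns the stacked response table plus lifetime summaries.
#'
#' @param goal Goal name.
#' @param scheme A precomputed [run_scheme()] result (or `NULL` to run one).
#' @param horizons Selection horizons in years.
#' @param scenarios Environments to re-simulate.
#' @param n_cows Population size of mechanistic re-simulations.
#' @param seed Master seed.
#' @param genetic_sd As in [predict_mm_response()].
#' @param config Herd-model configuration.
#' @param scheme_cfg Scheme configuration (used if `scheme` is `NULL`).
#' @return List of class `link_result` with `responses`, `summaries`,
#'   `scheme`.
#' @export
link_responses <- function(goal = "Base", scheme = NULL,
                           horizons = c(10, 20, 30),
                           scenarios = c("HS", "MS"), n_cows = 2000,
                           seed = 1, genetic_sd = NULL,
                           config = herd_config(),
                           scheme_cfg = scheme_config("desk")) {
  if (is.null(scheme)) {
    scheme <- run_scheme(scheme_cfg, goal = goal, seed = seed)
  }
  cals <- lapply(setNames(scenarios, scenarios), make_feed_calendar,
                 n_years = config$max_years)
  rows <- list(); sums <- list()
  for (h in horizons) {
    upd <- build_update(scheme, horizon = h)
    for (sc in scenarios) {
      r <- predict_mm_response(upd, sc, n_cows = n_cows, seed = seed,
                               genetic_sd = genetic_sd, config = config,
                               calendar = cals[[sc]])
      rows[[length(rows) + 1L]] <- mutate(r, goal = scheme$goal)
      sums[[length(sums) + 1L]] <- cbind(
        tibble(goal = scheme$goal, scenario = sc, horizon = h,
               stage = c("before", "after")),
        bind_rows(attr(r, "summary_before"), attr(r, "summary_after")))
    }
  }
  structure(list(responses = bind_rows(rows), summaries = bind_rows(sums),
                 scheme = scheme),
            class = "link_result")
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("<link_result> goal %s, %d response rows\n",
              x$scheme$goal, nrow(x$responses)))
  invisible(x)
}
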