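#' Configuration of the breeding-scheme simulator
#'
#' Structure of the simulated breeding nucleus: females distributed over
#' herds and mated to young genomically selected sires, with genotyping
#' preselection of calves on parent-average breeding values, within-herd
#' truncation selection of dams aged 1--5 years, multiple ovulation and
#' embryo transfer (MOET) on the top heifers, and random mating. The
#' `"paper"` preset is the full-scale nucleus (20,000 cows in 200 herds, 100
#' sires/year, 4,000 genotyped calves per sex, 400 MOET donors, 30-year
#' horizon with a 20-year burn-in, 30 replicates); the `"desk"` preset is a
#' proportionally reduced configuration for interactive use and testing.
#' Counts scale down; model constants (accuracies, heritabilities, age
#' rules) never change between presets.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param n_cows,n_herds,n_sires Nucleus size, herd count, sires per year.
#' @param n_genotyped Calves genotyped per sex per year.
#' @param n_moet MOET donor heifers per year; each produces
#'   `flushes * offspring_per_mating` offspring replacing natural matings.
#' @param flushes,offspring_per_mating MOET parameters.
#' @param max_dam_age Oldest dam age class (years).
#' @param horizon,burn_in Simulated years and discarded burn-in years.
#' @param replicates Number of replicates.
#' @param dgv_h2 Heritability of the direct-genomic-value pseudo-trait.
#' @param accuracies Named per-trait GEBV accuracies used to construct the
#'   genomic pseudo-traits (correlation between DGV and TBV).
#' @param eval_window Years of birth cohorts included in each yearly BLUP
#'   evaluation (their parents are always added as pedigree links).
#' @param selection `"tmi"` (truncation on the total merit index) or
#'   `"random"` (no selection signal; a null control).
#' @param track_inbreeding Compute pedigree inbreeding on a per-cohort
#'   subsample (`inbreeding_sample` animals per cohort).
#' @param inbreeding_sample Subsample size per cohort.
#' @return A list of class `scheme_config`.
#' @export
scheme_config <- function(preset = c("desk", "paper"),
                          n_cows = NULL, n_herds = NULL, n_sires = NULL,
                          n_genotyped = NULL, n_moet = NULL,
                          flushes = 2, offspring_per_mating = 3,
                          max_dam_age = 5,
                          horizon = NULL, burn_in = NULL, replicates = NULL,
                          dgv_h2 = 0.99,
                          accuracies = c(BWcalv1 = 0.68, Milk = 0.68,
                                         DMI = 0.60, IFC = 0.58,
                                         Lact_Eff = 0.60),
                          eval_window = 7,
                          selection = c("tmi", "random"),
                          track_inbreeding = FALSE,
                          inbreeding_sample = 50) {
  preset <- match.arg(preset)
  def <- switch(preset,
    paper = list(n_cows = 20000, n_herds = 200, n_sires = 100,
                 n_genotyped = 4000, n_moet = 400, horizon = 30,
                 burn_in = 20, replicates = 30),
    desk = list(n_cows = 800, n_herds = 10, n_sires = 8,
                n_genotyped = 160, n_moet = 16, horizon = 16,
                burn_in = 8, replicates = 3))
  cfg <- list(
    preset = preset,
    n_cows = n_cows %||% def$n_cows,
    n_herds = n_herds %||% def$n_herds,
    n_sires = n_sires %||% def$n_sires,
    n_genotyped = n_genotyped %||% def$n_genotyped,
    n_moet = n_moet %||% def$n_moet,
    flushes = flushes, offspring_per_mating = offspring_per_mating,
    max_dam_age = max_dam_age,
    horizon = horizon %||% def$horizon,
    burn_in = burn_in %||% def$burn_in,
    replicates = replicates %||% def$replicates,
    dgv_h2 = dgv_h2, accuracies = accuracies,
    eval_window = eval_window,
    selection = match.arg(selection),
    track_inbreeding = track_inbreeding,
    inbreeding_sample = inbreeding_sample)
  if (cfg$n_cows < cfg$n_herds) cfg_error("need at least one cow per herd")
  if (cfg$burn_in >= cfg$horizon) cfg_error("burn_in must be below horizon")
  class(cfg) <- "scheme_config"
  cfg
}

#' Sample offspring true breeding values under the infinitesimal model
#'
#' Offspring TBV = parent average + Mendelian-sampling deviation with
#' covariance half the additive covariance matrix.
#'
#' @param sire_tbv,dam_tbv Matrices (offspring x traits) of parental TBVs.
#' @param G Additive covariance matrix (must be positive semi-definite; bend
#'   correlation matrices first).
#' @param chol_half Optional precomputed `chol(G / 2)`.
#' @return Matrix of offspring TBVs.
#' @export
sample_offspring_tbv <- function(sire_tbv, dam_tbv, G, chol_half = NULL) {
  n <- nrow(sire_tbv)
  if (is.null(chol_half)) {
    ev <- eigen(G / 2, symmetric = TRUE)
    if (min(ev$values) < -1e-8) {
      cfg_error("G is not positive semi-definite; bend it before sampling")
    }
    chol_half <- diag(sqrt(pmax(ev$values, 0)),
                      nrow = length(ev$values)) %*% t(ev$vectors)
  }
  mend <- matrix(rnorm(n * ncol(sire_tbv)), n) %*% chol_half
  (sire_tbv + dam_tbv) / 2 + mend
}

#' Sample a direct genomic value correlated with the true breeding value
#'
#' The pseudo-genomic device: the DGV is a correlated pseudo-trait with
#' `cor(DGV, TBV) = accuracy`, built as `accuracy * tbv +
#' sqrt(1 - accuracy^2) * deviation` where the deviation is itself an
#' independently inherited polygenic trait, plus a small measurement
#' residual so that the DGV record has heritability `dgv_h2`.
#'
#' @param tbv TBV of the target trait (unit variance scale).
#' @param deviation Independent polygenic deviation (unit variance).
#' @param accuracy GEBV accuracy in \[0, 1\].
#' @param dgv_h2 Heritability of the DGV record.
#' @return List with `genetic` (the heritable DGV) and `record` (the
#'   observed DGV including residual).
#' @export
sample_dgv <- function(tbv, deviation, accuracy, dgv_h2 = 0.99) {
  if (accuracy < 0 || accuracy > 1) cfg_error("accuracy must lie in [0, 1]")
  g <- accuracy * tbv + sqrt(1 - accuracy^2) * deviation
  rec <- g + rnorm(length(g), 0, sqrt((1 - dgv_h2) / dgv_h2))
  list(genetic = g, record = rec)
}

# panel bookkeeping -----------------------------------------------------
scheme_panel <- function(params) {
  gt <- goal_traits()
  idx <- match(unname(goal_trait_panel_index()), params$traits)
  G10 <- bend_correlation_matrix(params$G)
  list(goal_traits = gt, idx = setNames(idx, gt),
       G10 = G10, h2 = params$h2, E = params$E,
       n_panel = length(params$traits))
}

#' Run the stochastic breeding scheme
#'
#' Simulates `config$replicates` replicates of the yearly cycle: calvings
#' and phenotype recording (body weight at first calving; milk and fertility
#' each lactation; no own intake or efficiency records), genotyping
#' preselection of calves on parent-average index, yearly BLUP evaluation
#' (per goal trait, bivariate with its genomic pseudo-trait), truncation
#' selection of young sires and of dams within herds, MOET on the top
#' heifers, and random mating. True breeding values are sampled on the full
#' ten-trait panel (plus genomic deviation traits) so that responses on the
#' acquisition/allocation input traits and on the limiting-environment
#' traits arise as correlated responses to selection on the index.
#'
#' @param config A [scheme_config()].
#' @param params A `genetic_parameters` panel
#'   ([reference_genetic_parameters()] by default); its genetic correlation
#'   matrix is bent to positive definiteness before sampling.
#' @param goal Goal name from [breeding_goals()] or a named weight vector on
#'   the genetic-SD scale.
#' @param seed Integer master seed; replicate r uses `seed + r - 1`.
#' @return An object of class `scheme_result`: per-replicate and mean annual
#'   responses per trait (genetic-SD units per year), variance-retention
#'   factors for the AA traits, generation interval, annual inbreeding rate
#'   (if tracked), and the goal weights used.
#' @export
run_scheme <- function(config = scheme_config(),
                       params = reference_genetic_parameters(),
                       goal = "Base", seed = 1) {
  weights <- resolve_goal_weights(goal)
  reps <- lapply(seq_len(config$replicates), function(r) {
    run_scheme_once(config, params, weights, seed = seed + r - 1)
  })
  gains <- bind_rows(lapply(seq_along(reps), function(r) {
    mutate(reps[[r]]$gains, replicate = r)
  }))
  mean_gains <- gains %>%
    group_by(.data$trait) %>%
    summarise(annual_gain_sd = mean(.data$annual_gain_sd),
              .groups = "drop")
  glance_tbl <- bind_rows(lapply(seq_along(reps), function(r) {
    mutate(reps[[r]]$glance, replicate = r)
  }))
  alpha <- bind_rows(lapply(seq_along(reps), function(r) {
    mutate(reps[[r]]$alpha, replicate = r)
  })) %>%
    group_by(.data$trait) %>%
    summarise(alpha = mean(.data$alpha), .groups = "drop")
  structure(list(goal = if (is.character(goal)) goal else "custom",
                 weights = weights,
                 gains = gains, mean_gains = mean_gains,
                 alpha = alpha, replicate_summary = glance_tbl,
                 config = config, seed = seed),
            class = "scheme_result")
}

resolve_goal_weights <- function(goal) {
  if (is.character(goal)) {
    bg <- breeding_goals()
    if (!goal %in% bg$goal) cfg_error(sprintf("unknown breeding goal '%s'", goal))
    w <- bg[bg$goal == goal, ]
    setNames(w$weight, w$trait)[goal_traits()]
  } else {
    if (is.null(names(goal))) cfg_error("custom goal weights must be named")
    out <- setNames(numeric(5), goal_traits())
    out[names(goal)] <- goal
    out
  }
}

run_scheme_once <- function(config, params, weights, seed) {
  set.seed(seed)
  pan <- scheme_panel(params)
  np <- pan$n_panel; gt <- pan$goal_traits; nt <- length(gt)
  ntot <- np + nt # panel traits + genomic deviation traits
  Gfull <- diag(ntot)
  Gfull[1:np, 1:np] <- pan$G10
  cholG <- chol(Gfull)
  chol_half <- chol(Gfull / 2)
  acc <- config$accuracies[gt]
  sd_dgv_res <- sqrt((1 - config$dgv_h2) / config$dgv_h2)

  rec_traits <- c("BWcalv1", "Milk", "IFC") # recorded complex phenotypes
  rec_idx <- pan$idx[rec_traits]
  e_names <- unname(goal_trait_panel_index()[rec_traits])
  E3 <- pan$E[e_names, e_names]
  sde <- sqrt((1 - pan$h2[e_names]) / pmax(pan$h2[e_names], 0.005))
  Se <- diag(sde) %*% E3 %*% diag(sde)
  cholSe <- chol(Se)

  hsz <- config$n_cows %/% config$n_herds

  cap <- config$n_cows + config$n_sires + config$horizon * (config$n_cows + 10)
  tbv <- matrix(NA_real_, cap, ntot)
  sex <- integer(cap); byear <- integer(cap)
  sire <- integer(cap); dam <- integer(cap); herd <- integer(cap)
  genotyped <- logical(cap)
  dgv_rec <- matrix(NA_real_, cap, nt)
  ebv <- matrix(0, cap, nt)
  is_parent <- logical(cap)

  # founders: unrelated females aged 1..max_dam_age and year-old sires
  n0f <- config$n_cows; n0m <- config$n_sires
  n_anim <- n0f + n0m
  f_id <- seq_len(n0f); m_id <- n0f + seq_len(n0m)
  tbv[1:n_anim, ] <- matrix(rnorm(n_anim * ntot), n_anim) %*% cholG
  sex[f_id] <- 2L; sex[m_id] <- 1L
  age_f <- rep(seq_len(config$max_dam_age), length.out = n0f)
  byear[f_id] <- 1L - age_f
  byear[m_id] <- 0L
  herd[f_id] <- rep(seq_len(config$n_herds), length.out = n0f)
  ever_calved <- logical(cap)

  # record stores (grown per year)
  rec_anim <- list(); rec_trait <- list(); rec_value <- list()
  push_rec <- function(a, tr, v) {
    rec_anim[[length(rec_anim) + 1L]] <<- a
    rec_trait[[length(rec_trait) + 1L]] <<- rep(tr, length.out = length(a))
    rec_value[[length(rec_value) + 1L]] <<- v
  }

  cur_dams <- f_id     # females selected to breed (calve next year)
  cur_sires <- m_id
  cur_donors <- integer(0)

  coh_mean <- matrix(NA_real_, config$horizon, np)
  coh_var <- matrix(NA_real_, config$horizon, np)
  coh_members <- vector("list", config$horizon)

  for (y in seq_len(config$horizon)) {
    ## --- births -------------------------------------------------------
    calvers <- cur_dams
    n_moet_eff <- min(length(cur_donors), config$n_moet)
    moet_per_donor <- config$flushes * config$offspring_per_mating
    n_replaced <- min((moet_per_donor - 1L) * n_moet_eff,
                      max(length(calvers) - n_moet_eff, 0L))
    natural <- setdiff(calvers, cur_donors)
    if (n_replaced > 0) {
      natural <- natural[-sample.int(length(natural), n_replaced)]
    }
    dam_vec <- c(natural, rep(cur_donors[seq_len(n_moet_eff)],
                              each = moet_per_donor))
    nb <- length(dam_vec)
    sire_vec <- cur_sires[sample.int(length(cur_sires), nb, replace = TRUE)]
    ids <- n_anim + seq_len(nb)
    if (max(ids) > cap) cfg_error("internal capacity exceeded")
    tbv[ids, ] <- sample_offspring_tbv(tbv[sire_vec, , drop = FALSE],
                                       tbv[dam_vec, , drop = FALSE],
                                       chol_half = chol_half)
    sex[ids] <- sample(c(1L, 2L), nb, replace = TRUE)
    byear[ids] <- y
    sire[ids] <- sire_vec; dam[ids] <- dam_vec
    herd[ids] <- herd[dam_vec]
    is_parent[unique(c(sire_vec, dam_vec))] <- TRUE
    n_anim <- n_anim + nb
    coh_members[[y]] <- ids
    coh_mean[y, ] <- colMeans(tbv[ids, 1:np, drop = FALSE])
    coh_var[y, ] <- apply(tbv[ids, 1:np, drop = FALSE], 2, var)

    ## --- phenotype recording for this year's calvers ------------------
    eps <- matrix(rnorm(length(calvers) * 3), length(calvers)) %*% cholSe
    first <- !ever_calved[calvers]
    ever_calved[calvers] <- TRUE
    if (any(first)) {
      push_rec(calvers[first], "BWcalv1",
               tbv[calvers[first], rec_idx["BWcalv1"]] + eps[first, 1])
    }
    push_rec(calvers, "Milk", tbv[calvers, rec_idx["Milk"]] + eps[, 2])
    push_rec(calvers, "IFC", tbv[calvers, rec_idx["IFC"]] + eps[, 3])

    ## --- genotyping preselection on parent-average index --------------
    pa <- (ebv_index(ebv[sire_vec, , drop = FALSE], weights) +
             ebv_index(ebv[dam_vec, , drop = FALSE], weights)) / 2
    if (config$selection == "random") pa <- runif(nb)
    for (sx in c(1L, 2L)) {
      cand <- ids[sex[ids] == sx]
      if (!length(cand)) next
      top <- cand[order(pa[match(cand, ids)], decreasing = TRUE)]
      top <- top[seq_len(min(config$n_genotyped, length(top)))]
      genotyped[top] <- TRUE
      for (k in seq_len(nt)) {
        g <- acc[k] * tbv[top, pan$idx[k]] + sqrt(1 - acc[k]^2) * tbv[top, np + k]
        dgv_rec[top, k] <- g + rnorm(length(top), 0, sd_dgv_res)
        push_rec(top, paste0("dgv_", gt[k]), dgv_rec[top, k])
      }
    }

    ## --- evaluation ---------------------------------------------------
    win <- which(byear[1:n_anim] > y - config$eval_window)
    win <- sort(unique(c(win, sire[win], dam[win])))
    win <- win[win > 0]
    win <- win[order(byear[win])]
    ped_win <- tibble(animal_id = win,
                      sire_id = ifelse(sire[win] %in% win, sire[win], 0L),
                      dam_id = ifelse(dam[win] %in% win, dam[win], 0L))
    ra <- unlist(rec_anim); rt <- unlist(rec_trait); rv <- unlist(rec_value)
    keep <- ra %in% win
    ra <- ra[keep]; rt <- rt[keep]; rv <- rv[keep]
    for (k in seq_len(nt)) {
      tr <- gt[k]
      sel <- rt == tr | rt == paste0("dgv_", tr)
      if (!any(sel)) next
      G2 <- matrix(c(1, acc[k], acc[k], 1), 2,
                   dimnames = list(c(tr, paste0("dgv_", tr)),
                                   c(tr, paste0("dgv_", tr))))
      h2k <- max(pan$h2[unname(goal_trait_panel_index()[tr])], 0.005)
      rvars <- setNames(c((1 - h2k) / h2k, sd_dgv_res^2),
                        c(tr, paste0("dgv_", tr)))
      res <- blup_evaluate(ped_win,
                           tibble(animal_id = ra[sel], trait = rt[sel],
                                  value = rv[sel]),
                           G2, rvars)
      ebv[win, k] <- res[[paste0("ebv_", tr)]]
    }

    ## --- selection for next year --------------------------------------
    tmi <- ebv_index(ebv[1:n_anim, , drop = FALSE], weights)
    if (config$selection == "random") tmi <- runif(n_anim)
    age <- y - byear[1:n_anim]
    males1 <- which(sex[1:n_anim] == 1L & age == 1L & genotyped[1:n_anim])
    if (!length(males1)) males1 <- which(sex[1:n_anim] == 1L & age == 1L)
    if (!length(males1)) cfg_error("no male selection candidates available")
    cur_sires <- males1[order(tmi[males1], decreasing = TRUE)]
    cur_sires <- cur_sires[seq_len(min(config$n_sires, length(cur_sires)))]

    fem <- which(sex[1:n_anim] == 2L & age >= 1L & age <= config$max_dam_age)
    if (!length(fem)) cfg_error("no female selection candidates available")
    sel_dams <- integer(0)
    for (h in seq_len(config$n_herds)) {
      fh <- fem[herd[fem] == h]
      fh <- fh[order(tmi[fh], decreasing = TRUE)]
      sel_dams <- c(sel_dams, fh[seq_len(min(hsz, length(fh)))])
    }
    cur_dams <- sel_dams
    heifers <- fem[age[fem] == 1L]
    heifers <- heifers[order(tmi[heifers], decreasing = TRUE)]
    cur_donors <- heifers[seq_len(min(config$n_moet, length(heifers)))]
    cur_donors <- intersect(cur_donors, cur_dams)
  }

  ## --- summaries ------------------------------------------------------
  yrs <- (config$burn_in + 1):config$horizon
  slope <- function(v) unname(coef(lm(v[yrs] ~ yrs))[2])
  gains <- tibble(trait = params$traits,
                  annual_gain_sd = vapply(seq_len(np),
                                          function(j) slope(coh_mean[, j]),
                                          numeric(1)))
  alpha <- tibble(trait = params$traits[1:4],
                  alpha = colMeans(coh_var[yrs, 1:4, drop = FALSE]))

  par_ids <- which(is_parent[1:n_anim] & byear[1:n_anim] %in% yrs)
  gi <- if (length(par_ids)) {
    mean(c(byear[par_ids] - byear[sire[par_ids]],
           byear[par_ids] - byear[dam[par_ids]]))
  } else NA_real_

  dF <- NA_real_
  if (config$track_inbreeding) {
    ord <- order(byear[1:n_anim])
    ped_all <- tibble(animal_id = ord,
                      sire_id = sire[ord], dam_id = dam[ord])
    sub <- unlist(lapply(coh_members[yrs], function(m) {
      m[sample.int(length(m), min(config$inbreeding_sample, length(m)))]
    }))
    fcoef <- inbreeding_coefficients(ped_all, subset = sub)
    fyr <- byear[fcoef$animal_id]
    dF <- 100 * unname(coef(lm(fcoef$inbreeding ~ fyr))[2])
  }

  list(gains = gains,
       alpha = alpha,
       glance = tibble(generation_interval = gi,
                       inbreeding_rate_pct = dF,
                       n_animals = n_anim))
}

ebv_index <- function(ebv, weights) {
  as.numeric(ebv %*% unname(weights[goal_traits()]))
}

#' @export
print.scheme_result <- function(x, ...) {
  cat(sprintf("<scheme_result> goal %s, %d replicates (%s preset)\n",
              x$goal, x$config$replicates, x$config$preset))
  print(as.data.frame(x$mean_gains), row.names = FALSE)
  invisible(x)
}

#' @method tidy scheme_result
#' @export
tidy.scheme_result <- function(x, ...) x$gains

#' @method glance scheme_result
#' @export
glance.scheme_result <- function(x, ...) {
  x$replicate_summary %>%
    summarise(goal = x$goal,
              generation_interval = mean(.data$generation_interval),
              inbreeding_rate_pct = mean(.data$inbreeding_rate_pct),
              min_alpha_aa = min(x$alpha$alpha),
              replicates = dplyr::n())
}

#' @rdname run_scheme
#' @param object A `scheme_result`.
#' @param ... Unused.
#' @method autoplot scheme_result
#' @export
autoplot.scheme_result <- function(object, ...) {
  ggplot2::ggplot(object$gains,
                  ggplot2::aes(x = .data$trait, y = .data$annual_gain_sd)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "annual genetic gain (genetic SD)",
                  title = sprintf("Goal %s", object$goal)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
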