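#' Configuration of the mechanistic cow model
#'
#' All free constants of the reduced-form daily bioenergetic model. Energy is
#' accounted on the metabolizable-energy (ME) scale: `k_net` (default 1)
#' multiplies ME intake to give the energy pool that is partitioned, and the
#' energy-cost constants (MJ per kg of milk, structural growth and labile
#' reserves) are quoted on the same scale. Defaults are calibrated so that
#' the non-limiting baseline population approaches the reference behaviour
#' (around 5.5--6 completed lactations per cow and lifetime efficiency in the
#' mid 30s of percent) with realistic body-weight and reserve trajectories.
#'
#' @param k_net Fraction of ME intake entering the allocation pool.
#' @param maint_mj_per_kg075 Maintenance requirement, MJ per kg metabolic
#'   body weight (BW^0.75) per day.
#' @param ecm_mj_per_kg Energy content of 1 kg energy-corrected milk, MJ.
#' @param growth_mj_per_kg Energy cost of 1 kg structural-mass growth, MJ.
#' @param body_mj_per_kg Energy density of labile body reserves, MJ/kg (same
#'   value for deposition and mobilization).
#' @param mob_cap_mj Maximal daily mobilization of labile reserves, MJ/d.
#' @param mob_reserves_half,mob_reserves_slope Willingness to mobilize
#'   reserves in support of lactation scales with the body-reserve ratio
#'   (logistic with this midpoint and slope): well-conditioned cows buffer
#'   milk against feed restriction, lean cows cut milk instead.
#' @param rho_lact Daily exponential decay rate of the lactation allocation
#'   coefficient after calving (fixed persistency, no genetic variation).
#' @param gamma_growth0 Allocation coefficient to growth at birth; it decays
#'   with age at the genetically driven rate `f_prio_gs`.
#' @param gest_alloc_max,gestation_length Peak gestation allocation
#'   coefficient (reached at term) and gestation length in days; the
#'   gestation trajectory is cubic in day of gestation and has no
#'   inter-individual variability.
#' @param maturity_frac_birth,maturity_tau Maturity curve of basal intake:
#'   fraction of mature basal intake at birth, and exponential time constant
#'   (days).
#' @param dmi_peak_day,dmi_shape Day of peak and shape of the normalized
#'   lactation-intake curve (peak value 1, so the peak intake increment
#'   equals `lact_acq`).
#' @param drive_peak_day,drive_shape Same for the milk-drive curve that sets
#'   the lactation energy demand; milk demand peaks earlier than intake,
#'   which produces the early-lactation energy deficit and body-reserve dip.
#' @param drive_scale Multiplier on the unconstrained acquisition potential
#'   when computing the lactation energy demand; above 1 the udder demands
#'   more than current intake supplies, so milk is supported by reserve
#'   mobilization within the willingness limits.
#' @param dry_off_before_calving,dry_off_before_season Dry-off rule: days
#'   before expected calving, and latest days before the start of the
#'   calving season.
#' @param heifer_first_mating_age Age at first mating of heifers, days.
#' @param mating_season_start,mating_season_length Calendar day on which the
#'   cow mating season opens (day 1 = start of calving season) and its
#'   length in days (10 weeks).
#' @param min_dim_mating Voluntary waiting period: minimal days in milk
#'   before a cow is inseminated.
#' @param oestrus_cycle Days between successive heats.
#' @param conception Named list of the three component conception-probability
#'   curves (each logistic): `milk_half`/`milk_slope` (kg ECM/d, decreasing
#'   in milk yield), `reserves_half`/`reserves_slope` (body-reserve ratio,
#'   increasing), `mob_half`/`mob_slope` (MJ/d mobilized, decreasing).
#' @param conception_feedback If `FALSE` the mechanistic feedback is disabled
#'   and every insemination succeeds with fixed probability `p_const` (used
#'   for consistency checks against the conventional predictions).
#' @param p_const Constant conception probability when feedback is disabled.
#' @param reserves_max_frac Saturation of labile reserves as a fraction of
#'   structural mass; deposition beyond it is dissipated as extra
#'   maintenance (homeostatic appetite/thermogenesis control).
#' @param reserves_floor Body-reserve ratio below which a cow is culled for
#'   depleted reserves.
#' @param max_parity Maximal number of lactations before culling.
#' @param max_conceptions Cap on lifetime conceptions (default unlimited); a
#'   counterfactual lever for controlled comparisons of pregnant versus open
#'   lactations in otherwise identical cows.
#' @param max_years Simulation horizon per cow, years.
#' @param birth_structural_kg,birth_labile_kg Body composition at birth.
#' @return A list of class `herd_config`.
#' @export
herd_config <- function(k_net = 1,
                        maint_mj_per_kg075 = 0.50,
                        ecm_mj_per_kg = 5.06,
                        growth_mj_per_kg = 16,
                        body_mj_per_kg = 26,
                        mob_cap_mj = 25,
                        mob_reserves_half = 0.18,
                        mob_reserves_slope = 0.04,
                        rho_lact = 0.0012,
                        gamma_growth0 = 0.7,
                        gest_alloc_max = 0.14,
                        gestation_length = 282,
                        maturity_frac_birth = 0.10,
                        maturity_tau = 250,
                        dmi_peak_day = 56, dmi_shape = 0.6,
                        drive_peak_day = 28, drive_shape = 0.12,
                        drive_scale = 1.15,
                        dry_off_before_calving = 90,
                        dry_off_before_season = 56,
                        heifer_first_mating_age = 424,
                        mating_season_start = 84,
                        mating_season_length = 70,
                        min_dim_mating = 28,
                        oestrus_cycle = 21,
                        conception = list(milk_half = 26, milk_slope = 7,
                                          reserves_half = 0.08,
                                          reserves_slope = 0.05,
                                          mob_half = 20, mob_slope = 8),
                        conception_feedback = TRUE,
                        p_const = 0.55,
                        reserves_max_frac = 0.40,
                        reserves_floor = 0.01,
                        max_parity = 8,
                        max_conceptions = Inf,
                        max_years = 12,
                        birth_structural_kg = 35,
                        birth_labile_kg = 3) {
  cfg <- as.list(environment())
  class(cfg) <- "herd_config"
  cfg
}

# normalized lactation curve (peak value exactly 1 at t = peak)
wood_curve <- function(t, peak, shape) {
  out <- numeric(length(t))
  pos <- !is.na(t) & t >= 1
  tp <- t[pos] / peak
  out[pos] <- tp^shape * exp(shape * (1 - tp))
  out
}

maturity_curve <- function(age, cfg) {
  1 - (1 - cfg$maturity_frac_birth) * exp(-age / cfg$maturity_tau)
}

#' Expected (unconstrained) dry-matter intake
#'
#' The intake a cow would achieve in a non-limiting environment: a basal
#' component rising monotonically with age toward `bas_acq`, plus, when
#' lactating, a lactation component that peaks at exactly `lact_acq` and
#' then declines with fixed persistency.
#'
#' @param aa Data frame (or named list) of phenotypic AA trait values with
#'   columns/names `bas_acq`, `lact_acq` (either bare or `phen_`-prefixed).
#' @param age Age in days.
#' @param dim Days in milk (`NA` or 0 when dry).
#' @param config A [herd_config()].
#' @return Expected DMI, kg DM/d (vectorized).
#' @export
expected_dmi <- function(aa, age, dim = NA, config = herd_config()) {
  aa <- normalize_aa(aa)
  lact <- !is.na(dim) & dim >= 1
  aa$bas_acq * maturity_curve(age, config) +
    ifelse(lact, aa$lact_acq, 0) *
      wood_curve(ifelse(lact, dim, 1), config$dmi_peak_day, config$dmi_shape)
}

#' Achieved dry-matter intake under a daily feed offer
#'
#' The achieved intake is the minimum of the expected intake and the daily
#' DM offer (which is the unconstrained sentinel `Inf` ad libitum).
#'
#' @param expected,offer kg DM/d, both >= 0.
#' @return kg DM/d.
#' @export
achieved_dmi <- function(expected, offer) {
  if (any(expected < 0, na.rm = TRUE) || any(offer < 0, na.rm = TRUE)) {
    contract_error("expected and offer must be non-negative")
  }
  pmin(expected, offer)
}

# accept bare or phen_-prefixed AA columns; returns tibble with bare names
normalize_aa <- function(aa) {
  aa <- as_tibble(aa)
  for (tr in aa_traits()) {
    if (!tr %in% names(aa) && paste0("phen_", tr) %in% names(aa)) {
      aa[[tr]] <- aa[[paste0("phen_", tr)]]
    }
  }
  missing <- setdiff(aa_traits(), names(aa))
  if (length(missing)) {
    cfg_error(paste("missing AA trait columns:", paste(missing, collapse = ", ")))
  }
  aa[aa_traits()]
}

#' Partition one day's net energy among life functions
#'
#' Maintenance (proportional to metabolic body weight) is served first;
#' remaining energy is split among lactation, gestation and growth by
#' time-varying allocation coefficients, with the residual deposited to (or,
#' under deficit, mobilized from) labile body reserves. The lactation
#' coefficient starts at `lact_all` at calving and decays with the fixed
#' persistency `rho_lact`; the growth coefficient decays with age at the
#' genetic rate `f_prio_gs`; the gestation coefficient follows a fixed cubic
#' trajectory of day of gestation. If the lactation demand (set by
#' `net_drive`, the energy the cow would acquire unconstrained) exceeds the
#' lactation share of intake, reserves are mobilized up to the daily cap.
#' Energy is conserved exactly: the five allocations sum to `net_energy`.
#'
#' @param state Data frame with columns `age`, `dim` (`NA`/0 when dry),
#'   `day_gestation` (`NA` when open), `structural_mass`, `labile_mass`, and
#'   optionally `net_drive` (defaults to `net_energy`).
#' @param net_energy MJ/d available after digestion (>= 0).
#' @param aa AA trait values as in [expected_dmi()].
#' @param config A [herd_config()].
#' @return Tibble with columns `alloc_maintenance`, `alloc_growth`,
#'   `alloc_lactation`, `alloc_gestation`, `alloc_reserves` (negative =
#'   mobilization), `milk_ecm`, `mobilized`.
#' @export
allocate_energy <- function(state, net_energy, aa, config = herd_config()) {
  if (any(net_energy < 0)) contract_error("net_energy must be non-negative")
  aa <- normalize_aa(aa)
  st <- as_tibble(state)
  n <- max(nrow(st), length(net_energy))
  drive <- if ("net_drive" %in% names(st)) st$net_drive else net_energy
  dg <- if ("day_gestation" %in% names(st)) st$day_gestation else rep(NA_real_, n)
  as_tibble(alloc_core(st$age, st$dim, dg, st$structural_mass,
                       st$labile_mass, drive, net_energy,
                       aa$lact_acq, aa$f_prio_gs, aa$lact_all, config))
}

# vectorized allocation on plain vectors (hot path of the daily loop)
alloc_core <- function(age, dim, dg, S, L, drive, net,
                       lacq, fprio, lall, config) {
  lact <- !is.na(dim) & dim >= 1
  e_m <- config$maint_mj_per_kg075 * (S + L)^0.75
  avail <- L * config$body_mj_per_kg
  m1 <- pmin(pmax(e_m - net, 0), config$mob_cap_mj, avail)
  R <- pmax(net - e_m, 0)

  g_l <- ifelse(lact, lall * exp(-config$rho_lact * (dim - 1)), 0)
  g_l[is.na(g_l)] <- 0
  g_p <- ifelse(!is.na(dg) & dg >= 0,
                config$gest_alloc_max * (pmin(dg, config$gestation_length) /
                                           config$gestation_length)^3, 0)
  g_g <- config$gamma_growth0 * exp(-fprio * age)
  over <- g_l + g_g > 1
  if (any(over)) {
    g_g[over] <- pmax(1 - g_l[over], 0)
  }

  # gestation is served out of the post-maintenance pool first, so a failed
  # or absent pregnancy frees energy that flows to lactation and reserves
  a_p <- g_p * R
  R2 <- R - a_p
  d_l <- g_l * pmax(drive - e_m, 0)
  supply_l <- g_l * R2
  short <- pmax(d_l - supply_l, 0)
  willing <- config$mob_cap_mj *
    stats::plogis((L / (S + L) - config$mob_reserves_half) /
                    config$mob_reserves_slope)
  m2 <- pmin(short, pmax(willing - m1, 0), pmax(avail - m1, 0))
  a_l <- pmin(d_l, supply_l) + m2
  leftover <- pmax(supply_l - d_l, 0)
  a_g <- g_g * R2
  a_r <- (1 - g_l - g_g) * R2 + leftover - m1 - m2
  # labile reserves saturate at a fixed fraction of structural mass;
  # deposition beyond the ceiling is dissipated with maintenance
  room <- pmax(config$reserves_max_frac * S - L, 0) * config$body_mj_per_kg
  overflow <- pmax(a_r - room, 0)
  a_r <- a_r - overflow
  a_m <- pmin(net, e_m) + m1 + overflow

  list(alloc_maintenance = a_m, alloc_growth = a_g,
       alloc_lactation = a_l, alloc_gestation = a_p,
       alloc_reserves = a_r,
       milk_ecm = a_l / config$ecm_mj_per_kg,
       mobilized = m1 + m2)
}

#' Daily conception probability
#'
#' The product of three component probabilities: a decreasing logistic in
#' milk yield, an increasing logistic in the body-reserve ratio, and a
#' decreasing logistic in the daily reserve-mobilization rate. Each
#' component lies in (0, 1); if any component is 0 the product is 0.
#'
#' @param milk_ecm kg ECM/d on the day of insemination.
#' @param body_reserves Labile mass / total body mass ratio.
#' @param mobilization MJ/d mobilized from reserves.
#' @param config A [herd_config()].
#' @return Probability in \[0, 1\] (vectorized).
#' @export
conception_probability <- function(milk_ecm, body_reserves, mobilization,
                                   config = herd_config()) {
  if (!config$conception_feedback) {
    return(rep(config$p_const, length(milk_ecm)))
  }
  cc <- config$conception
  p_milk <- stats::plogis((cc$milk_half - milk_ecm) / cc$milk_slope)
  p_level <- stats::plogis((body_reserves - cc$reserves_half) / cc$reserves_slope)
  p_mob <- stats::plogis((cc$mob_half - mobilization) / cc$mob_slope)
  p_milk * p_level * p_mob
}

#' Simulate the lifetime of a herd of cows under a feed calendar
#'
#' Runs the daily bioenergetic model for all cows in lockstep from birth
#' (day 1, the first day of the calving season) to culling: expected intake
#' from the acquisition traits, achieved intake capped by the daily offer,
#' energy partitioning by the allocation coefficients, body-mass updates,
#' oestrus-by-oestrus conception draws inside the seasonal mating windows,
#' and culling for reproductive failure, depleted reserves or parity cap.
#' Heifers are first mated at exactly `heifer_first_mating_age` days; cows
#' are mated within the 10-week seasonal window after a voluntary waiting
#' period. Gestation lasts `gestation_length` days; cows are dried off
#' `dry_off_before_calving` days before expected calving or at latest
#' `dry_off_before_season` days before the start of the calving season.
#' Energy conservation is asserted every simulated day (1e-9 relative).
#'
#' Conception random numbers are indexed per cow and insemination event, so
#' two runs with the same `seed` but different feed calendars share the same
#' underlying random stream (common random numbers across scenarios).
#'
#' @param cows Tibble of phenotypic AA values (`phen_*` or bare columns), or
#'   a [sample_founders()] result.
#' @param calendar A [make_feed_calendar()] covering `max_years` years.
#' @param config A [herd_config()].
#' @param seed Integer seed (fixing it makes the run bit-reproducible).
#' @param keep_daily Store full daily records for every cow (memory-heavy;
#'   intended for small herds).
#' @return An object of class `herd_sim`; see [derive_phenotypes()],
#'   [mean_trajectories()], [lifetime_summary()].
#' @export
simulate_herd <- function(cows, calendar, config = herd_config(),
                          seed = NULL, keep_daily = FALSE) {
  if (inherits(cows, "founder_pop")) cows <- cows$cows
  aa <- normalize_aa(cows)
  n <- nrow(aa)
  id <- if ("animal_id" %in% names(cows)) cows$animal_id else seq_len(n)
  n_days <- 365L * config$max_years
  if (nrow(calendar) < n_days) {
    contract_error(sprintf(
      "calendar (%d days) shorter than the simulation horizon (%d days)",
      nrow(calendar), n_days))
  }
  scenario <- attr(calendar, "scenario") %||% "custom"
  offer_cal <- calendar$dm_offer_kg
  me_cal <- calendar$me_mj_per_kg

  if (!is.null(seed)) set.seed(seed)
  n_seasons <- config$max_years + 1L
  max_heats <- n_seasons * 6L
  heat_offset <- matrix(sample.int(config$oestrus_cycle, n * n_seasons,
                                   replace = TRUE) - 1L, n, n_seasons)
  heat_u <- matrix(runif(n * max_heats), n, max_heats)

  bas <- aa$bas_acq; lacq <- aa$lact_acq
  fprio <- aa$f_prio_gs; lall <- aa$lact_all

  # --- state -----------------------------------------------------------
  alive <- rep(TRUE, n)
  S <- rep(config$birth_structural_kg, n)
  L <- rep(config$birth_labile_kg, n)
  parity <- integer(n)
  lactating <- rep(FALSE, n)
  calv_day <- rep(NA_integer_, n)        # current lactation's calving day
  conc_day <- rep(NA_integer_, n)
  droff_day <- rep(NA_integer_, n)
  open_cull_day <- rep(NA_integer_, n)   # end-of-lactation cull for open cows
  next_heat <- rep(NA_integer_, n)
  window_end <- rep(NA_integer_, n)
  season_idx <- integer(n)
  heat_idx <- integer(n)
  first_insem_cur <- rep(NA_integer_, n)
  cull_day <- rep(NA_integer_, n)
  cull_reason <- rep("none", n)
  lact_count <- integer(n)
  conc_count <- integer(n)

  mp <- config$max_parity
  ins_cap <- n * 60L
  ins_n <- 0L
  ins_cow <- integer(ins_cap); ins_day <- integer(ins_cap)
  ins_parity <- integer(ins_cap); ins_p <- numeric(ins_cap)
  ins_success <- logical(ins_cap)
  calvings <- matrix(NA_integer_, n, mp)
  conceptions <- matrix(NA_integer_, n, mp)
  first_insems <- matrix(NA_integer_, n, mp)
  bw_calv1 <- rep(NA_real_, n)
  bw_calv3 <- rep(NA_real_, n)

  life_alloc_l <- numeric(n); life_me <- numeric(n); life_dmi <- numeric(n)
  p3_alloc_l <- numeric(n); p3_me <- numeric(n); p3_dmi <- numeric(n)
  p3_len <- 450L
  p3_milk <- matrix(NA_real_, n, p3_len)
  p3_dmi_m <- matrix(NA_real_, n, p3_len)
  p3_bw <- matrix(NA_real_, n, p3_len)
  p3_br <- matrix(NA_real_, n, p3_len)

  daily <- NULL
  if (keep_daily) {
    fields <- c("dmi_expected", "dmi_achieved", "me_intake",
                "alloc_maintenance", "alloc_growth", "alloc_lactation",
                "alloc_gestation", "alloc_reserves", "milk_ecm",
                "body_weight", "body_reserves", "parity", "dim", "pregnant")
    daily <- lapply(setNames(fields, fields),
                    function(f) matrix(NA_real_, n_days, n))
  }

  season_start_of <- function(day) {
    # calendar day on which the mating season of the cycle containing `day` opens
    365L * ((day - 1L) %/% 365L) + config$mating_season_start
  }

  for (d in seq_len(n_days)) {
    if (!any(alive)) break
    a <- which(alive)
    cal_row <- ((d - 1L) %% 365L) + 1L
    cyc <- (d - 1L) %/% 365L           # season cycle index (0-based)

    ## -- reproduction-state transitions at day start --------------------
    # calving
    cv <- a[!is.na(conc_day[a]) &
              d == conc_day[a] + config$gestation_length]
    if (length(cv)) {
      parity[cv] <- parity[cv] + 1L
      lactating[cv] <- TRUE
      calv_day[cv] <- d
      calvings[cbind(cv, parity[cv])] <- d
      p1 <- cv[parity[cv] == 1L]
      bw_calv1[p1] <- S[p1] + L[p1]
      p3 <- cv[parity[cv] == 3L]
      bw_calv3[p3] <- S[p3] + L[p3]
      conc_day[cv] <- NA_integer_
      first_insem_cur[cv] <- NA_integer_
      # schedule dry-off is set at conception of the NEXT calf
    }
    # dry-off (pregnant cows at scheduled date; open cows at forced date)
    dr <- a[lactating[a] & ((!is.na(droff_day[a]) & d == droff_day[a]) |
                            (!is.na(open_cull_day[a]) & d == open_cull_day[a]))]
    if (length(dr)) {
      lactating[dr] <- FALSE
      lact_count[dr] <- lact_count[dr] + 1L
      droff_day[dr] <- NA_integer_
      calv_day[dr] <- NA_integer_
      open_cull <- dr[!is.na(open_cull_day[dr]) & d == open_cull_day[dr]]
      if (length(open_cull)) {
        alive[open_cull] <- FALSE
        cull_day[open_cull] <- d
        cull_reason[open_cull] <- "open_at_season_end"
      }
      over <- setdiff(dr, open_cull)
      over <- over[parity[over] >= mp]
      if (length(over)) {
        alive[over] <- FALSE
        cull_day[over] <- d
        cull_reason[over] <- "max_parity"
      }
      a <- which(alive)
    }
    if (!length(a)) break

    ## -- mating-window bookkeeping --------------------------------------
    # heifers: window opens at exactly heifer_first_mating_age
    hf <- a[parity[a] == 0L & d == config$heifer_first_mating_age &
              is.na(conc_day[a]) & conc_count[a] < config$max_conceptions]
    if (length(hf)) {
      next_heat[hf] <- d
      window_end[hf] <- d + config$mating_season_length
      season_idx[hf] <- 1L
      first_insem_cur[hf] <- NA_integer_
    }
    # cows: seasonal window (calendar-anchored), after voluntary wait
    if (cal_row == config$mating_season_start) {
      blocked <- a[parity[a] >= 1L & parity[a] < mp & is.na(conc_day[a]) &
                     lactating[a] & conc_count[a] >= config$max_conceptions]
      if (length(blocked)) {
        nxt_season <- 365L * (((d - 1L) %/% 365L) + 1L) + 1L
        open_cull_day[blocked] <- nxt_season - config$dry_off_before_season
      }
      cw <- a[parity[a] >= 1L & parity[a] < mp & is.na(conc_day[a]) &
                lactating[a] & conc_count[a] < config$max_conceptions]
      if (length(cw)) {
        ws <- pmax(d, calv_day[cw] + config$min_dim_mating)
        we <- d + config$mating_season_length
        ok <- ws < we
        cw <- cw[ok]; ws <- ws[ok]
        if (length(cw)) {
          sidx <- pmin(cyc + 1L, n_seasons)
          next_heat[cw] <- ws + heat_offset[cbind(cw, sidx)]
          window_end[cw] <- we
          season_idx[cw] <- sidx
          first_insem_cur[cw] <- NA_integer_
        }
      }
    }

    ## -- physiology ------------------------------------------------------
    age <- d
    dim_a <- ifelse(lactating[a], d - calv_day[a] + 1L, NA_real_)
    mat <- maturity_curve(age, config)
    lac_on <- lactating[a]
    dmi_exp <- bas[a] * mat + ifelse(lac_on, lacq[a], 0) *
      wood_curve(ifelse(lac_on, dim_a, 1), config$dmi_peak_day, config$dmi_shape)
    offer <- offer_cal[cal_row]
    dmi_ach <- pmin(dmi_exp, offer)
    me <- me_cal[cal_row]
    net <- config$k_net * me * dmi_ach
    drive <- config$drive_scale * config$k_net * me *
      (bas[a] * mat + ifelse(lac_on, lacq[a], 0) *
         wood_curve(ifelse(lac_on, dim_a, 1), config$drive_peak_day,
                    config$drive_shape))
    dg_a <- ifelse(!is.na(conc_day[a]), d - conc_day[a], NA_real_)

    al <- alloc_core(rep(age, length(a)), dim_a, dg_a, S[a], L[a],
                     drive, net, lacq[a], fprio[a], lall[a], config)

    bal <- al$alloc_maintenance + al$alloc_growth + al$alloc_lactation +
      al$alloc_gestation + al$alloc_reserves
    if (any(abs(bal - net) > 1e-9 * pmax(net, 1))) {
      contract_error("energy conservation violated in daily allocation")
    }

    S[a] <- S[a] + al$alloc_growth / config$growth_mj_per_kg
    L[a] <- pmax(L[a] + al$alloc_reserves / config$body_mj_per_kg, 0)
    br <- L[a] / (S[a] + L[a])

    life_alloc_l[a] <- life_alloc_l[a] + al$alloc_lactation
    life_me[a] <- life_me[a] + me * dmi_ach
    life_dmi[a] <- life_dmi[a] + dmi_ach

    in_p3 <- lac_on & parity[a] == 3L
    if (any(in_p3)) {
      i3 <- a[in_p3]; d3 <- dim_a[in_p3]
      keep3 <- d3 <= p3_len
      i3 <- i3[keep3]; d3 <- d3[keep3]
      idx3 <- cbind(i3, d3)
      w3 <- which(in_p3)[keep3]
      p3_milk[idx3] <- al$milk_ecm[w3]
      p3_dmi_m[idx3] <- dmi_ach[w3]
      p3_bw[idx3] <- S[i3] + L[i3]
      p3_br[idx3] <- br[w3]
      p3_alloc_l[i3] <- p3_alloc_l[i3] + al$alloc_lactation[w3]
      p3_me[i3] <- p3_me[i3] + (me * dmi_ach)[w3]
      p3_dmi[i3] <- p3_dmi[i3] + dmi_ach[w3]
    }

    if (keep_daily) {
      daily$dmi_expected[d, a] <- dmi_exp
      daily$dmi_achieved[d, a] <- dmi_ach
      daily$me_intake[d, a] <- me * dmi_ach
      daily$alloc_maintenance[d, a] <- al$alloc_maintenance
      daily$alloc_growth[d, a] <- al$alloc_growth
      daily$alloc_lactation[d, a] <- al$alloc_lactation
      daily$alloc_gestation[d, a] <- al$alloc_gestation
      daily$alloc_reserves[d, a] <- al$alloc_reserves
      daily$milk_ecm[d, a] <- al$milk_ecm
      daily$body_weight[d, a] <- S[a] + L[a]
      daily$body_reserves[d, a] <- br
      daily$parity[d, a] <- parity[a]
      daily$dim[d, a] <- ifelse(is.na(dim_a), 0, dim_a)
      daily$pregnant[d, a] <- as.numeric(!is.na(conc_day[a]))
    }

    ## -- oestrus & conception -------------------------------------------
    ht <- which(alive & !is.na(next_heat) & next_heat == d & is.na(conc_day))
    if (length(ht)) {
      pos <- match(ht, a)
      p <- conception_probability(al$milk_ecm[pos], br[pos], al$mobilized[pos],
                                  config)
      heat_idx[ht] <- heat_idx[ht] + 1L
      u <- heat_u[cbind(ht, pmin(heat_idx[ht], max_heats))]
      if (ins_n + length(ht) <= ins_cap) {
        ii <- ins_n + seq_along(ht)
        ins_cow[ii] <- ht; ins_day[ii] <- d
        ins_parity[ii] <- parity[ht]; ins_p[ii] <- p
        ins_success[ii] <- u < p
        ins_n <- ins_n + length(ht)
      }
      res_par <- pmin(parity[ht] + 1L, mp)
      newf <- is.na(first_insem_cur[ht])
      first_insem_cur[ht[newf]] <- d
      first_insems[cbind(ht[newf], res_par[newf])] <- d
      conc <- u < p
      cc <- ht[conc]
      if (length(cc)) {
        conc_day[cc] <- d
        conc_count[cc] <- conc_count[cc] + 1L
        conceptions[cbind(cc, res_par[conc])] <- d
        next_heat[cc] <- NA_integer_
        # schedule dry-off for currently lactating cows
        lc <- cc[lactating[cc]]
        if (length(lc)) {
          exp_calv <- d + config$gestation_length
          s <- 365L * ((exp_calv - 1L) %/% 365L) + 1L
          droff_day[lc] <- pmin(exp_calv - config$dry_off_before_calving,
                                s - config$dry_off_before_season)
        }
      }
      oc <- ht[!conc]
      if (length(oc)) {
        nh <- next_heat[oc] + config$oestrus_cycle
        done <- nh >= window_end[oc]
        next_heat[oc] <- ifelse(done, NA_integer_, nh)
        fin <- oc[done]
        if (length(fin)) {
          # failed the whole window: heifers culled at window end,
          # cows finish the lactation then leave
          hfail <- fin[parity[fin] == 0L]
          if (length(hfail)) {
            alive[hfail] <- FALSE
            cull_day[hfail] <- d
            cull_reason[hfail] <- "open_at_season_end"
          }
          cfail <- fin[parity[fin] >= 1L]
          if (length(cfail)) {
            nxt_season <- 365L * (((d - 1L) %/% 365L) + 1L) + 1L
            open_cull_day[cfail] <- nxt_season - config$dry_off_before_season
          }
        }
      }
    }

    ## -- reserve-depletion culling ---------------------------------------
    dep <- a[br < config$reserves_floor]
    if (length(dep)) {
      alive[dep] <- FALSE
      cull_day[dep] <- d
      cull_reason[dep] <- "reserves_depleted"
    }
  }

  strag <- which(alive)
  if (length(strag)) {
    cull_day[strag] <- n_days
    cull_reason[strag] <- "end_of_simulation"
  }

  summary <- tibble(
    animal_id = id,
    cull_day = cull_day, cull_reason = cull_reason,
    lactations_completed = lact_count,
    final_parity = parity,
    bw_calv1 = bw_calv1, bw_calv3 = bw_calv3,
    life_alloc_lactation_mj = life_alloc_l,
    life_me_intake_mj = life_me,
    life_dmi_kg = life_dmi,
    p3_alloc_lactation_mj = ifelse(parity >= 3, p3_alloc_l, NA_real_),
    p3_me_intake_mj = ifelse(parity >= 3, p3_me, NA_real_),
    p3_dmi_kg = ifelse(parity >= 3, p3_dmi, NA_real_),
    p3_calving_day = if (mp >= 3L) calvings[, 3L] else rep(NA_integer_, n),
    p3_first_insem = if (mp >= 4L) first_insems[, 4L] else rep(NA_integer_, n),
    p3_conception = if (mp >= 4L) conceptions[, 4L] else rep(NA_integer_, n)
  )
  events <- bind_rows(
    tidyr::drop_na(tibble(animal_id = rep(id, mp),
                          parity = rep(seq_len(mp), each = n),
                          event = "calving", day = as.integer(calvings))),
    tidyr::drop_na(tibble(animal_id = rep(id, mp),
                          parity = rep(seq_len(mp), each = n),
                          event = "conception", day = as.integer(conceptions))),
    tibble(animal_id = id, parity = parity, event = "culling",
           day = cull_day)
  ) %>% arrange(.data$animal_id, .data$day)

  inseminations <- tibble(
    animal_id = id[ins_cow[seq_len(ins_n)]],
    day = ins_day[seq_len(ins_n)],
    parity = ins_parity[seq_len(ins_n)],
    p_conception = ins_p[seq_len(ins_n)],
    success = ins_success[seq_len(ins_n)])
  structure(list(summary = summary, events = events,
                 inseminations = inseminations,
                 p3 = list(milk = p3_milk, dmi = p3_dmi_m,
                           bw = p3_bw, br = p3_br),
                 daily = daily, aa = aa, config = config,
                 scenario = scenario, n_days = n_days, seed = seed),
            class = "herd_sim")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.herd_sim <- function(x, ...) {
  cat(sprintf("<herd_sim> %d cows, scenario %s, %d days\n",
              nrow(x$summary), x$scenario, x$n_days))
  cat(sprintf("  mean lactations completed: %.2f; culling: %s\n",
              mean(x$summary$lactations_completed),
              paste(names(table(x$summary$cull_reason)),
                    table(x$summary$cull_reason), sep = "=", collapse = " ")))
  invisible(x)
}

#' Simulate a single cow's life history
#'
#' Convenience wrapper around [simulate_herd()] for one cow, returning full
#' daily records.
#'
#' @param aa One row of AA phenotypes (named list, 1-row data frame).
#' @param calendar,config,seed As in [simulate_herd()].
#' @return A list of class `life_history` with `daily` (tibble of daily
#'   state and energy records), `events`, `summary`.
#' @export
simulate_lifetime <- function(aa, calendar, config = herd_config(),
                              seed = NULL) {
  sim <- simulate_herd(as_tibble(normalize_aa(aa)), calendar, config,
                       seed = seed, keep_daily = TRUE)
  structure(list(daily = life_history_daily(sim, 1L),
                 events = sim$events, summary = sim$summary,
                 config = config, scenario = sim$scenario),
            class = "life_history")
}

# extract one cow's daily records from a keep_daily herd_sim as a tibble
life_history_daily <- function(sim, cow) {
  if (is.null(sim$daily)) cfg_error("simulation was run without keep_daily")
  days <- which(!is.na(sim$daily$dmi_achieved[, cow]))
  out <- tibble(day = days)
  for (f in names(sim$daily)) out[[f]] <- sim$daily[[f]][days, cow]
  out
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("<life_history> %d days, %d lactations, culled: %s\n",
              nrow(x$daily), x$summary$lactations_completed[1],
              x$summary$cull_reason[1]))
  invisible(x)
}
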