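#' Default mean values of the acquisition/allocation input traits
#'
#' The four genetically driven input traits of the bioenergetic cow model:
#' basal acquisition `bas_acq` (kg DM/d, maximal intake of a non-lactating
#' mature cow), lactation acquisition `lact_acq` (kg DM/d, intake increase
#' during lactation), `f_prio_gs` (1/d, rate of transfer of energy allocation
#' from growth to survival) and `lact_all` (dimensionless, energy allocation
#' to lactation at the start of lactation).
#'
#' @return Named numeric vector of the four trait means.
#' @export
aa_means <- function() {
  c(bas_acq = 7.00, lact_acq = 10.25, f_prio_gs = 0.0035, lact_all = 0.56)
}

#' Names of the acquisition/allocation traits
#' @return Character vector of length 4.
#' @export
aa_traits <- function() names(aa_means())

#' Sample a half-sib founder population of acquisition/allocation traits
#'
#' Draws true breeding values (TBV) and phenotypes for the four
#' acquisition/allocation (AA) input traits for a population of cows
#' structured in paternal half-sib families: `n_sires` unrelated sires, each
#' with `daughters_per_sire` daughters out of unrelated, non-phenotyped dams.
#' Traits are mutually independent (no genetic or residual correlation).
#' Under the infinitesimal model a daughter's TBV is the parent average plus
#' a Mendelian-sampling deviation with variance half the additive variance;
#' phenotype = TBV + residual.
#'
#' Per trait, the phenotypic variance is `(cv * mean)^2` split into additive
#' variance `h2 * (cv * mean)^2` and residual variance; `var_g`/`var_e`
#' override that parameterization (used when re-simulating after selection
#' with Bulmer-reduced additive variance but unchanged residual variance).
#' Draws violating biological support (phenotypes must be positive;
#' `lact_all` in (0, 1)) are resampled.
#'
#' @param n_sires,daughters_per_sire Family structure counts (> 0).
#' @param means Named vector of AA trait means, as [aa_means()].
#' @param h2 Heritability (scalar or per trait), in (0, 1).
#' @param cv Phenotypic coefficient of variation (scalar or per trait), > 0.
#' @param seed Integer seed; fixing it reproduces the population exactly.
#' @param var_g,var_e Optional named vectors of additive and residual
#'   variances per trait, overriding `h2`/`cv`.
#' @return An object of class `founder_pop`: a list with `cows` (one row per
#'   daughter: ids, `tbv_*` and `phen_*` columns) and `pedigree`
#'   (`animal_id`, `sire_id`, `dam_id`, `birth_year`, `sex`; 0 = unknown
#'   parent) tibbles.
#' @examples
#' pop <- sample_founders(5, 10, seed = 1)
#' pop$cows
#' @export
sample_founders <- function(n_sires = 200, daughters_per_sire = 100,
                            means = aa_means(), h2 = 0.35, cv = 0.10,
                            seed = NULL, var_g = NULL, var_e = NULL) {
  if (n_sires < 1 || daughters_per_sire < 1) {
    cfg_error("n_sires and daughters_per_sire must be positive counts")
  }
  traits <- names(means)
  if (is.null(traits)) cfg_error("means must be a named vector")
  h2 <- rep_len(h2, length(traits))
  cv <- rep_len(cv, length(traits))
  if (any(h2 <= 0 | h2 >= 1)) cfg_error("h2 must lie strictly in (0, 1)")
  if (any(cv <= 0)) cfg_error("cv must be positive")
  sigma_p2 <- (cv * means)^2
  vg <- if (is.null(var_g)) h2 * sigma_p2 else var_g[traits]
  ve <- if (is.null(var_e)) (1 - h2) * sigma_p2 else var_e[traits]

  if (!is.null(seed)) set.seed(seed)
  ns <- n_sires; nd <- n_sires * daughters_per_sire
  sire_id <- seq_len(ns)
  dam_id <- ns + seq_len(nd)
  cow_id <- ns + nd + seq_len(nd)
  sire_of <- rep(sire_id, each = daughters_per_sire)

  draw <- function(n, mu, v) rnorm(n, mu, sqrt(v))
  tbv_s <- lapply(seq_along(traits), function(k) draw(ns, means[k], vg[k]))
  tbv_d <- lapply(seq_along(traits), function(k) draw(nd, means[k], vg[k]))
  tbv <- lapply(seq_along(traits), function(k) {
    0.5 * tbv_s[[k]][sire_of] + 0.5 * tbv_d[[k]] + draw(nd, 0, vg[k] / 2)
  })
  phen <- lapply(seq_along(traits), function(k) tbv[[k]] + draw(nd, 0, ve[k]))

  # resample residual + Mendelian parts for draws outside biological support
  lower <- setNames(rep(0, length(traits)), traits)
  upper <- setNames(rep(Inf, length(traits)), traits)
  if ("lact_all" %in% traits) upper["lact_all"] <- 1
  for (k in seq_along(traits)) {
    bad <- which(phen[[k]] <= lower[k] | phen[[k]] >= upper[k] | tbv[[k]] <= lower[k])
    guard <- 0
    while (length(bad) > 0 && guard < 100) {
      tbv[[k]][bad] <- 0.5 * tbv_s[[k]][sire_of[bad]] + 0.5 * tbv_d[[k]][bad] +
        draw(length(bad), 0, vg[k] / 2)
      phen[[k]][bad] <- tbv[[k]][bad] + draw(length(bad), 0, ve[k])
      bad <- bad[phen[[k]][bad] <= lower[k] | phen[[k]][bad] >= upper[k] |
                   tbv[[k]][bad] <= lower[k]]
      guard <- guard + 1
    }
    if (length(bad) > 0) {
      warn(sprintf("truncating %d out-of-support draws for %s", length(bad), traits[k]))
      tbv[[k]][bad] <- pmax(tbv[[k]][bad], lower[k] + 1e-8)
      phen[[k]][bad] <- pmax(phen[[k]][bad], lower[k] + 1e-8)
    }
  }

  cows <- tibble(animal_id = cow_id, sire_id = sire_of, dam_id = dam_id)
  for (k in seq_along(traits)) {
    cows[[paste0("tbv_", traits[k])]] <- tbv[[k]]
    cows[[paste0("phen_", traits[k])]] <- phen[[k]]
  }
  pedigree <- bind_rows(
    tibble(animal_id = sire_id, sire_id = 0L, dam_id = 0L,
           birth_year = 0L, sex = "M"),
    tibble(animal_id = dam_id, sire_id = 0L, dam_id = 0L,
           birth_year = 0L, sex = "F"),
    tibble(animal_id = cow_id, sire_id = sire_of, dam_id = dam_id,
           birth_year = 1L, sex = "F")
  )
  structure(list(cows = cows, pedigree = pedigree,
                 traits = traits, means = means,
                 var_g = setNames(vg, traits), var_e = setNames(ve, traits)),
            class = "founder_pop")
}

#' @export
print.founder_pop <- function(x, ...) {
  cat(sprintf("<founder_pop> %d cows in %d half-sib families; traits: %s\n",
              nrow(x$cows), length(unique(x$cows$sire_id)),
              paste(x$traits, collapse = ", ")))
  invisible(x)
}

#' @method tidy founder_pop
#' @export
tidy.founder_pop <- function(x, ...) x$cows

#' @method glance founder_pop
#' @export
glance.founder_pop <- function(x, ...) {
  tibble(n_cows = nrow(x$cows),
         n_sires = length(unique(x$cows$sire_id)),
         n_traits = length(x$traits))
}

#' Write a pedigree in 3-column whitespace format
#'
#' Columns animal/sire/dam plus birth year and sex; 0 marks an unknown parent.
#'
#' @param pedigree Tibble with `animal_id`, `sire_id`, `dam_id`, and
#'   optionally `birth_year`, `sex`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  cols <- intersect(c("animal_id", "sire_id", "dam_id", "birth_year", "sex"),
                    names(pedigree))
  utils::write.table(as.data.frame(pedigree[cols]), path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a whitespace-separated pedigree file
#' @param path File written by [write_pedigree()].
#' @return A tibble.
#' @export
read_pedigree <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE))
}
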