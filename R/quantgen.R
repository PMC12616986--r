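#' Reference genetic-parameter panel for the ten-trait system
#'
#' The heritabilities, genetic correlations and residual correlations linking
#' the four acquisition/allocation (AA) input traits to the complex traits
#' simulated in the non-limiting (HS) and limiting (MS) environments, as
#' estimated from the baseline mechanistic simulation. Trait aliases: basal
#' acquisition is genetically the same trait as body weight at first calving
#' (`BasAcq/BWcalv1`), and lactation allocation the same as third-lactation
#' efficiency (`LactAll/Lact_Eff`), so the panel has ten entries.
#'
#' @return A `genetic_parameters` object: list with `traits`, `h2`, `G`
#'   (genetic correlation matrix), `E` (residual correlation matrix).
#' @seealso [estimate_variance_components()] to re-estimate such a panel from
#'   simulated data, [bend_correlation_matrix()].
#' @export
reference_genetic_parameters <- function() {
  traits <- c("BasAcq", "LactAcq", "f_prio_GS", "LactAll",
              "Milk_HS", "DMI_HS", "IFC_HS", "Milk_MS", "DMI_MS", "IFC_MS")
  h2 <- setNames(c(0.35, 0.35, 0.35, 0.35, 0.33, 0.34, 0.01, 0.29, 0.26, 0.01),
                 traits)
  G <- diag(10)
  gu <- list( # upper-triangle genetic correlations, row by row
    BasAcq   = c(LactAcq = 0, f_prio_GS = 0, LactAll = 0,
                 Milk_HS = 0.40, DMI_HS = 0.57, IFC_HS = -0.09,
                 Milk_MS = 0.12, DMI_MS = 0.64, IFC_MS = -0.02),
    LactAcq  = c(f_prio_GS = 0, LactAll = 0,
                 Milk_HS = 0.43, DMI_HS = 0.58, IFC_HS = -0.11,
                 Milk_MS = 0.09, DMI_MS = 0.49, IFC_MS = 0.01),
    f_prio_GS = c(LactAll = 0,
                  Milk_HS = 0.05, DMI_HS = -0.06, IFC_HS = -0.44,
                  Milk_MS = 0.20, DMI_MS = -0.02, IFC_MS = -0.49),
    LactAll  = c(Milk_HS = 0.60, DMI_HS = 0.01, IFC_HS = 0.54,
                 Milk_MS = 0.79, DMI_MS = -0.02, IFC_MS = 0.56),
    Milk_HS  = c(DMI_HS = 0.51, IFC_HS = 0.31,
                 Milk_MS = 0.67, DMI_MS = 0.57, IFC_MS = 0.33),
    DMI_HS   = c(IFC_HS = -0.09, Milk_MS = 0.13, DMI_MS = 0.79, IFC_MS = 0.04),
    IFC_HS   = c(Milk_MS = 0.63, DMI_MS = 0.00, IFC_MS = 0.68),
    Milk_MS  = c(DMI_MS = 0.15, IFC_MS = 0.52),
    DMI_MS   = c(IFC_MS = 0.00)
  )
  eu <- list( # lower-triangle residual correlations, read row by row
    LactAcq  = c(BasAcq = 0),
    f_prio_GS = c(BasAcq = 0, LactAcq = 0),
    LactAll  = c(BasAcq = 0, LactAcq = 0, f_prio_GS = 0),
    Milk_HS  = c(BasAcq = 0.45, LactAcq = 0.48, f_prio_GS = 0.06, LactAll = 0.71),
    DMI_HS   = c(BasAcq = 0.66, LactAcq = 0.66, f_prio_GS = -0.03,
                 LactAll = 0.05, Milk_HS = 0.65),
    IFC_HS   = c(BasAcq = -0.01, LactAcq = -0.02, f_prio_GS = -0.10,
                 LactAll = 0.09, Milk_HS = 0.11, DMI_HS = -0.05),
    Milk_MS  = c(BasAcq = 0.15, LactAcq = 0.16, f_prio_GS = 0.17,
                 LactAll = 0.91, Milk_HS = 0.78, DMI_HS = 0.24, IFC_HS = 0.03),
    DMI_MS   = c(BasAcq = 0.59, LactAcq = 0.44, f_prio_GS = -0.01,
                 LactAll = 0.02, Milk_HS = 0.53, DMI_HS = 0.61,
                 IFC_HS = -0.05, Milk_MS = 0.24),
    IFC_MS   = c(BasAcq = 0.02, LactAcq = 0.00, f_prio_GS = -0.13,
                 LactAll = 0.13, Milk_HS = 0.08, DMI_HS = -0.02,
                 IFC_HS = 0.02, Milk_MS = 0.24, DMI_MS = -0.08)
  )
  dimnames(G) <- list(traits, traits)
  E <- G
  for (r in names(gu)) for (c in names(gu[[r]])) {
    G[r, c] <- G[c, r] <- gu[[r]][c]
  }
  for (r in names(eu)) for (c in names(eu[[r]])) {
    E[r, c] <- E[c, r] <- eu[[r]][c]
  }
  new_genetic_parameters(traits, h2, G, E)
}

new_genetic_parameters <- function(traits, h2, G, E, sigma_g = NULL) {
  structure(list(traits = traits, h2 = h2, G = G, E = E, sigma_g = sigma_g),
            class = "genetic_parameters")
}

#' @export
print.genetic_parameters <- function(x, ...) {
  cat(sprintf("<genetic_parameters> %d traits: %s\n", length(x$traits),
              paste(x$traits, collapse = ", ")))
  cat("h2:", paste(sprintf("%s=%.2f", x$traits, x$h2), collapse = " "), "\n")
  invisible(x)
}

#' @method tidy genetic_parameters
#' @export
tidy.genetic_parameters <- function(x, ...) {
  pairs <- which(upper.tri(x$G), arr.ind = TRUE)
  bind_rows(
    tibble(trait1 = x$traits, trait2 = x$traits,
           parameter = "h2", estimate = unname(x$h2)),
    tibble(trait1 = x$traits[pairs[, 1]], trait2 = x$traits[pairs[, 2]],
           parameter = "genetic_correlation", estimate = x$G[pairs]),
    tibble(trait1 = x$traits[pairs[, 1]], trait2 = x$traits[pairs[, 2]],
           parameter = "residual_correlation", estimate = x$E[pairs])
  )
}

#' Breeding-goal weights on the genetic-standard-deviation scale
#'
#' The six selection strategies compared: a production/fertility baseline
#' (`Base`), goals limiting the correlated increase of body weight and/or
#' intake (`LimitBW`, `LimitDMI`, `LimitBoth`, `ReduceBW`), and an extreme
#' goal selecting on lactation efficiency and fertility only (`EFF`).
#' Weights apply to the five goal traits `BWcalv1`, `Milk`, `DMI`, `IFC`,
#' `Lact_Eff` measured in the non-limiting environment.
#'
#' @return A tibble with columns `goal`, `trait`, `weight`.
#' @export
breeding_goals <- function() {
  goals <- c("Base", "LimitBW", "LimitDMI", "LimitBoth", "ReduceBW", "EFF")
  traits <- goal_traits()
  w <- rbind(
    BWcalv1  = c(0, -20, 0, -5, -28, 0),
    Milk     = c(55, 46, 46, 41, 28, 0),
    DMI      = c(0, 0, -22, -25, 0, 0),
    IFC      = c(-45, -34, -32, -29, -34, -50),
    Lact_Eff = c(0, 0, 0, 0, 10, 50)
  )
  colnames(w) <- goals
  tidyr::crossing(goal = goals, trait = traits) %>%
    mutate(weight = purrr::map2_dbl(.data$goal, .data$trait, ~ w[.y, .x])) %>%
    mutate(goal = factor(.data$goal, levels = goals),
           trait = factor(.data$trait, levels = traits)) %>%
    arrange(.data$goal, .data$trait) %>%
    mutate(goal = as.character(.data$goal), trait = as.character(.data$trait))
}

#' Names of the five breeding-goal traits
#' @return Character vector.
#' @export
goal_traits <- function() c("BWcalv1", "Milk", "DMI", "IFC", "Lact_Eff")

# map goal traits onto the ten-trait reference panel (HS recordings)
goal_trait_panel_index <- function() {
  c(BWcalv1 = "BasAcq", Milk = "Milk_HS", DMI = "DMI_HS",
    IFC = "IFC_HS", Lact_Eff = "LactAll")
}

#' Genetic correlation matrix over the five goal traits
#'
#' Extracts the 5x5 genetic correlation matrix of the breeding-goal traits
#' (recorded in the non-limiting environment) from a ten-trait panel, using
#' the trait aliases BasAcq = BWcalv1 and LactAll = Lact_Eff.
#'
#' @param params A `genetic_parameters` panel, default
#'   [reference_genetic_parameters()].
#' @return A 5x5 correlation matrix with goal-trait dimnames.
#' @export
goal_correlations <- function(params = reference_genetic_parameters()) {
  idx <- goal_trait_panel_index()
  G <- params$G[idx, idx]
  dimnames(G) <- list(names(idx), names(idx))
  G
}

#' Correlations between a total merit index and its component traits
#'
#' For index weights `w` on the genetic-standard-deviation scale and a
#' genetic correlation matrix `G` among the traits, the correlation between
#' the total merit index (TMI, the weighted sum of true breeding values) and
#' trait i is \deqn{r_i = (Gw)_i / \sqrt{w'Gw}.}
#'
#' @param weights Named numeric vector of weights (genetic-SD scale); names
#'   must match `colnames(G)`. At least one weight must be nonzero.
#' @param G Positive-definite genetic correlation matrix.
#' @return Tibble with columns `trait`, `weight`, `cor_tmi`.
#' @examples
#' w <- c(BWcalv1 = 0, Milk = 55, DMI = 0, IFC = -45, Lact_Eff = 0)
#' tmi_trait_correlations(w, goal_correlations())
#' @export
tmi_trait_correlations <- function(weights, G = goal_correlations()) {
  if (is.data.frame(weights)) {
    weights <- setNames(weights$weight, weights$trait)
  }
  if (is.null(names(weights))) names(weights) <- colnames(G)
  if (!all(names(weights) %in% colnames(G))) {
    cfg_error("weight names must match the traits in G")
  }
  w <- setNames(numeric(ncol(G)), colnames(G))
  w[names(weights)] <- weights
  weights <- w
  if (all(weights == 0)) cfg_error("all-zero index weights: TMI undefined")
  v <- as.numeric(t(weights) %*% G %*% weights)
  tibble(trait = colnames(G), weight = unname(weights),
         cor_tmi = as.numeric(G %*% weights) / sqrt(v))
}

#' Bend a correlation matrix to positive definiteness
#'
#' Weighted eigenvalue bending: eigenvalues below the floor are raised to the
#' floor, the matrix is reconstructed and its diagonal renormalized to one,
#' iterating until the smallest eigenvalue reaches the floor. An input that
#' is already positive definite is returned unchanged. The operation is
#' idempotent.
#'
#' @param R Symmetric correlation matrix (unit diagonal).
#' @param floor Minimal acceptable eigenvalue (default 1e-4).
#' @param max_iter Iteration cap.
#' @return A positive-definite correlation matrix; attribute `max_change`
#'   reports the largest absolute elementwise change.
#' @export
bend_correlation_matrix <- function(R, floor = 1e-4, max_iter = 200) {
  if (!isSymmetric(unname(R), tol = 1e-8)) {
    contract_error("bend_correlation_matrix() requires a symmetric matrix")
  }
  R0 <- R
  B <- (R + t(R)) / 2
  for (i in seq_len(max_iter)) {
    e <- eigen(B, symmetric = TRUE)
    if (min(e$values) >= floor) break
    vals <- pmax(e$values, floor)
    B <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
    d <- sqrt(diag(B))
    B <- B / tcrossprod(d)
    diag(B) <- 1
  }
  dimnames(B) <- dimnames(R0)
  attr(B, "max_change") <- max(abs(B - R0))
  B
}

#' Effective number of independent chromosome segments
#'
#' \deqn{M_e = 2 N_e L / \ln(4 N_e L)} for effective population size `Ne` and
#' genome length `L` in Morgans.
#'
#' @param Ne Effective population size (> 0).
#' @param L Genome length in Morgans (> 0).
#' @return Numeric.
#' @examples
#' me_segments(350, 30) # about 2000
#' @export
me_segments <- function(Ne, L) {
  if (any(Ne <= 0) || any(L <= 0)) cfg_error("Ne and L must be positive")
  2 * Ne * L / log(4 * Ne * L)
}

#' Deterministic accuracy of genomic breeding values
#'
#' Predicts the accuracy of direct genomic values for selection candidates
#' without own performance, from the effective number of chromosome segments
#' `Me`, the marker-capture proportion `b = n_markers / (n_markers + Me)`,
#' and the effective information content of the reference population. A
#' reference bull with `n` daughter records contributes one record with
#' daughter-mean reliability \eqn{n h^2/4 / (1 + (n-1) h^2/4)}; a reference
#' cow with own performance contributes `h2`. Writing `T` for the summed
#' effective reference information and \eqn{\lambda = M_e / T}:
#' * `variant = "goddard"` (default): \eqn{r^2 = b\,[1 - \lambda \ln(1 + 1/\lambda)]},
#' * `variant = "daetwyler"`: \eqn{r^2 = b\,T / (T + M_e)}.
#'
#' Both variants are 0 with an empty reference, increase monotonically in
#' reference size and heritability, and approach the asymptote
#' \eqn{\sqrt{b}} as the reference grows.
#'
#' @param h2 Trait heritability.
#' @param n_bulls,daughters_per_bull Progeny-tested reference bulls and their
#'   daughter-group size (0 to omit the bull source).
#' @param n_cows Reference cows with own phenotype (0 to omit).
#' @param Ne,L,n_markers Genome/population constants used for `Me` and `b`.
#' @param variant Formula variant, see Details.
#' @return Accuracy in \[0, 1\].
#' @export
genomic_accuracy <- function(h2, n_bulls = 0, daughters_per_bull = 0,
                             n_cows = 0, Ne = 350, L = 30, n_markers = 38000,
                             variant = c("goddard", "daetwyler")) {
  variant <- match.arg(variant)
  if (h2 < 0 || h2 > 1) cfg_error("h2 must lie in [0, 1]")
  Me <- me_segments(Ne, L)
  b <- n_markers / (n_markers + Me)
  rel_daughters <- if (n_bulls > 0 && daughters_per_bull > 0) {
    (daughters_per_bull * h2 / 4) / (1 + (daughters_per_bull - 1) * h2 / 4)
  } else 0
  T_eff <- n_bulls * rel_daughters + n_cows * h2
  if (T_eff <= 0) return(0)
  r2 <- switch(variant,
    goddard = {
      lambda <- Me / T_eff
      b * max(0, 1 - lambda * log(1 + 1 / lambda))
    },
    daetwyler = b * T_eff / (T_eff + Me)
  )
  sqrt(r2)
}

#' Heritability after selection-induced loss of genetic variance
#'
#' Under directional selection, negative gametic-phase disequilibrium (the
#' Bulmer effect) shrinks the additive variance to `alpha` times its base
#' value while residual variance is unchanged. The updated heritability is
#' \deqn{h^{2\prime} = \alpha / (\alpha + (1 - h^2)/h^2),} algebraically
#' identical to \eqn{\alpha\sigma^2_g / (\alpha\sigma^2_g + \sigma^2_e)}.
#'
#' @param h2 Base heritability, in (0, 1).
#' @param alpha Genetic-variance retention factor, in (0, 1].
#' @return Updated heritability; equals `h2` iff `alpha == 1`.
#' @examples
#' bulmer_update(0.35, 0.93)
#' @export
bulmer_update <- function(h2, alpha) {
  if (any(h2 <= 0 | h2 >= 1)) contract_error("h2 must lie strictly in (0, 1)")
  if (any(alpha <= 0 | alpha > 1)) contract_error("alpha must lie in (0, 1]")
  alpha / (alpha + (1 - h2) / h2)
}

#' Estimate variance components from a paternal half-sib design
#'
#' Method-of-moments sire-model estimator for the balanced (or mildly
#' unbalanced) half-sib design: the between-sire variance component estimates
#' one quarter of the additive variance, so \eqn{\hat h^2 = 4\hat\sigma^2_s /
#' (\hat\sigma^2_s + \hat\sigma^2_w)}. Genetic covariances between traits
#' come from the between-sire mean cross-products, residual covariances from
#' the within-sire cross-products after removing three quarters of the
#' genetic covariance. Missing phenotypes are handled pairwise.
#'
#' @param phenotypes Tibble with `animal_id` and one numeric column per
#'   trait. Columns named `phen_<trait>` are accepted and renamed.
#' @param pedigree Tibble with `animal_id` and `sire_id` linking each record
#'   to its sire; at least 2 sires with 2 daughters each.
#' @return A `genetic_parameters` object with estimated `h2`, genetic (`G`)
#'   and residual (`E`) correlation matrices and genetic standard deviations
#'   (`sigma_g`). Negative sire components are clamped to zero with a
#'   warning.
#' @examples
#' pop <- sample_founders(50, 20, seed = 42)
#' estimate_variance_components(pop$cows, pop$pedigree)
#' @export
estimate_variance_components <- function(phenotypes, pedigree) {
  ph <- as_tibble(phenotypes)
  names(ph) <- sub("^phen_", "", names(ph))
  drop <- c("sire_id", "dam_id", grep("^tbv_", names(ph), value = TRUE))
  ph <- ph[setdiff(names(ph), drop)]
  traits <- setdiff(names(ph), "animal_id")
  sires <- pedigree$sire_id[match(ph$animal_id, pedigree$animal_id)]
  if (anyNA(sires)) cfg_error("every phenotyped animal needs a pedigree row")
  keep <- table(sires)
  if (length(keep) < 2 || all(keep < 2)) {
    cfg_error("need >= 2 sires with >= 2 daughters each")
  }
  nt <- length(traits)
  sig_s <- matrix(NA_real_, nt, nt, dimnames = list(traits, traits))
  sig_w <- sig_s
  for (i in seq_len(nt)) for (j in i:nt) {
    comp <- half_sib_components(ph[[traits[i]]], ph[[traits[j]]], sires)
    sig_s[i, j] <- sig_s[j, i] <- comp["sire"]
    sig_w[i, j] <- sig_w[j, i] <- comp["within"]
  }
  neg <- diag(sig_s) < 0
  if (any(neg)) {
    warn(sprintf("negative sire variance clamped to 0 for: %s",
                 paste(traits[neg], collapse = ", ")))
    diag(sig_s)[neg] <- 0
  }
  var_g <- 4 * diag(sig_s)
  h2 <- var_g / (diag(sig_s) + diag(sig_w))
  # correlations only defined for traits with positive variance components
  pos <- diag(sig_s) > 0
  G <- diag(nt)
  if (any(pos)) {
    G[pos, pos] <- stats::cov2cor(sig_s[pos, pos, drop = FALSE])
  }
  G[abs(G) > 1] <- sign(G[abs(G) > 1])
  cov_e <- sig_w - 3 * sig_s # within = 3/4 genetic + residual (sire comp = 1/4 genetic)
  diag(cov_e) <- pmax(diag(cov_e), 1e-12)
  E <- stats::cov2cor(cov_e)
  E[abs(E) > 1] <- sign(E[abs(E) > 1])
  dimnames(G) <- dimnames(E) <- list(traits, traits)
  new_genetic_parameters(traits, setNames(h2, traits), G, E,
                         sigma_g = setNames(sqrt(var_g), traits))
}

# pairwise-complete between-/within-sire (co)variance components
half_sib_components <- function(x, y, sires) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; s <- as.character(sires[ok])
  n_i <- tapply(x, s, length)
  s_levels <- names(n_i)
  N <- length(x); k <- length(s_levels)
  mx <- tapply(x, s, mean); my <- tapply(y, s, mean)
  gx <- mean(x); gy <- mean(y)
  # between-sire mean cross-product
  mcp_b <- sum(n_i * (mx - gx) * (my - gy)) / (k - 1)
  # pooled within-sire cross-product
  mcp_w <- sum((x - mx[s]) * (y - my[s])) / (N - k)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  c(sire = (mcp_b - mcp_w) / n0, within = mcp_w)
}

#' Write and read a genetic-parameter panel as a CSV matrix
#'
#' The file stores heritabilities on the diagonal, genetic correlations in
#' the upper triangle and residual correlations in the lower triangle, with
#' trait names as row/column headers.
#'
#' @param params A `genetic_parameters` object.
#' @param path File path.
#' @return `path` (write) or a `genetic_parameters` object (read).
#' @export
write_genetic_parameters <- function(params, path) {
  M <- params$G
  M[lower.tri(M)] <- params$E[lower.tri(M)]
  diag(M) <- params$h2
  utils::write.csv(as.data.frame(M), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genetic_parameters
#' @export
read_genetic_parameters <- function(path) {
  M <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  traits <- rownames(M)
  h2 <- setNames(diag(M), traits)
  G <- M; G[lower.tri(G)] <- t(G)[lower.tri(G)]; diag(G) <- 1
  E <- M; E[upper.tri(E)] <- t(E)[upper.tri(E)]; diag(E) <- 1
  new_genetic_parameters(traits, h2, G, E)
}
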