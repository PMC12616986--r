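#' Inverse additive-relationship matrix by Henderson's rules
#'
#' Builds the sparse inverse of the pedigree (numerator) relationship matrix
#' directly from the animal/sire/dam lists, ignoring inbreeding in the
#' Mendelian-sampling variances (the classical rules: contribution 2, 4/3 or
#' 1 depending on the number of known parents).
#'
#' @param pedigree Tibble with `animal_id`, `sire_id`, `dam_id` (0 =
#'   unknown); parents must appear as animals before their offspring or be
#'   unknown.
#' @return A sparse symmetric matrix (class `dsCMatrix`) with rows/columns
#'   in pedigree order; attribute `ids` stores the animal ids.
#' @export
a_inverse <- function(pedigree) {
  ids <- pedigree$animal_id
  n <- length(ids)
  s <- match(pedigree$sire_id, ids, nomatch = 0L)
  d <- match(pedigree$dam_id, ids, nomatch = 0L)
  unknown_named <- (pedigree$sire_id != 0 & s == 0L) |
    (pedigree$dam_id != 0 & d == 0L)
  if (any(unknown_named)) {
    cfg_error("pedigree refers to parents that are not listed as animals")
  }
  if (any(s >= seq_len(n)) || any(d >= seq_len(n))) {
    cfg_error("parents must precede their offspring in the pedigree")
  }
  npar <- (s > 0L) + (d > 0L)
  alpha <- c(1, 4 / 3, 2)[npar + 1L]
  i <- seq_len(n)
  ii <- list(); jj <- list(); xx <- list()
  add <- function(a, b, v) {
    ii[[length(ii) + 1L]] <<- a
    jj[[length(jj) + 1L]] <<- b
    xx[[length(xx) + 1L]] <<- v
  }
  add(i, i, alpha)
  ks <- s > 0L
  add(i[ks], s[ks], -alpha[ks] / 2); add(s[ks], i[ks], -alpha[ks] / 2)
  add(s[ks], s[ks], alpha[ks] / 4)
  kd <- d > 0L
  add(i[kd], d[kd], -alpha[kd] / 2); add(d[kd], i[kd], -alpha[kd] / 2)
  add(d[kd], d[kd], alpha[kd] / 4)
  kb <- ks & kd
  add(s[kb], d[kb], alpha[kb] / 4); add(d[kb], s[kb], alpha[kb] / 4)
  A <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n), symmetric = FALSE)
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  attr(A, "ids") <- ids
  A
}

#' Pedigree inbreeding coefficients
#'
#' Exact inbreeding coefficients by the Meuwissen--Luo algorithm (tracing
#' each animal's row of the gene-flow matrix over its ancestors). `subset`
#' restricts the computation to chosen animals; ancestors' coefficients are
#' always computed as needed.
#'
#' @param pedigree As in [a_inverse()].
#' @param subset Optional vector of `animal_id`s for which coefficients are
#'   wanted (all ancestors are processed regardless).
#' @return Tibble `animal_id`, `inbreeding`.
#' @export
inbreeding_coefficients <- function(pedigree, subset = NULL) {
  ids <- pedigree$animal_id
  n <- length(ids)
  s <- match(pedigree$sire_id, ids, nomatch = 0L)
  d <- match(pedigree$dam_id, ids, nomatch = 0L)
  want <- if (is.null(subset)) seq_len(n) else match(subset, ids)
  # every ancestor of a wanted animal is needed for the d_j terms
  need <- rep(FALSE, n)
  need[want] <- TRUE
  for (i in rev(seq_len(n))) {
    if (need[i]) {
      if (s[i] > 0L) need[s[i]] <- TRUE
      if (d[i] > 0L) need[d[i]] <- TRUE
    }
  }
  FF <- rep(0, n)
  Fd <- function(k) if (k > 0L) FF[k] else -1
  L <- numeric(n)
  dd <- numeric(n)
  for (i in seq_len(n)) {
    if (!need[i]) next
    dd[i] <- 0.5 - 0.25 * (Fd(s[i]) + Fd(d[i]))
    if (s[i] == 0L || d[i] == 0L) { FF[i] <- 0; next }
    # accumulate sum of squared gene-flow coefficients times d over ancestors
    L[i] <- 1
    acc <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj == 0) next
      acc <- acc + lj * lj * dd[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      L[j] <- 0
    }
    FF[i] <- acc - 1
  }
  tibble(animal_id = ids[want], inbreeding = FF[want])
}

#' Multi-trait pedigree BLUP via Henderson's mixed-model equations
#'
#' Solves the animal-model mixed-model equations for one or more traits with
#' a trait-wise overall mean as the only fixed effect, additive genetic
#' covariance `G` among traits, and independent residuals with trait-wise
#' variances `resid_var` (records of different traits are treated as
#' separate measurements; repeated records per animal and trait are
#' allowed). The pedigree relationship inverse is built by Henderson's rules
#' and breeding values are returned for every pedigree member, including
#' unrecorded selection candidates. Genomic pseudo-trait records (direct
#' genomic values) enter simply as records of their own correlated trait.
#'
#' @param pedigree As in [a_inverse()].
#' @param records Tibble with `animal_id`, `trait`, `value` (long format).
#' @param G Genetic covariance matrix among the evaluated traits (dimnames
#'   must name the traits); must be positive definite (bend first if not).
#' @param resid_var Named vector of residual variances per trait with
#'   records.
#' @return Tibble `animal_id` plus one `ebv_<trait>` column per trait.
#' @export
blup_evaluate <- function(pedigree, records, G, resid_var) {
  ids <- pedigree$animal_id
  n <- length(ids)
  traits <- colnames(G)
  t <- length(traits)
  rec_tr <- match(records$trait, traits)
  if (anyNA(rec_tr)) cfg_error("record trait not present in G")
  anim <- match(records$animal_id, ids)
  if (anyNA(anim)) cfg_error("record animal not present in pedigree")
  rv <- resid_var[records$trait]
  if (anyNA(rv) || any(rv <= 0)) {
    cfg_error("resid_var must give a positive variance for every recorded trait")
  }
  m <- nrow(records)
  trs_with_rec <- sort(unique(rec_tr))
  X <- Matrix::sparseMatrix(i = seq_len(m),
                            j = match(rec_tr, trs_with_rec),
                            x = 1, dims = c(m, length(trs_with_rec)))
  Z <- Matrix::sparseMatrix(i = seq_len(m), j = (anim - 1L) * t + rec_tr,
                            x = 1, dims = c(m, n * t))
  Rinv <- Matrix::Diagonal(m, 1 / rv)
  Ainv <- a_inverse(pedigree)
  Ginv <- tryCatch(solve(G), error = function(e) {
    cfg_error("G is singular; bend the genetic covariance matrix first")
  })
  K <- Matrix::kronecker(Ainv, as(Ginv, "CsparseMatrix"))
  W <- cbind(X, Z)
  C <- Matrix::forceSymmetric(Matrix::t(W) %*% Rinv %*% W +
    Matrix::bdiag(Matrix::Diagonal(ncol(X), 0), K))
  rhs <- Matrix::t(W) %*% Rinv %*% records$value
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(C, LDL = FALSE, perm = TRUE),
                             rhs)),
    error = function(e) {
      abort(paste("mixed-model equations singular;",
                  "offending block: fixed means or A-inverse x G-inverse",
                  conditionMessage(e)),
            class = "lactgain_blup_error")
    })
  u <- matrix(sol[-seq_len(ncol(X))], nrow = n, ncol = t, byrow = TRUE)
  out <- tibble(animal_id = ids)
  for (k in seq_len(t)) out[[paste0("ebv_", traits[k])]] <- u[, k]
  attr(out, "fixed") <- setNames(sol[seq_len(ncol(X))],
                                 traits[trs_with_rec])
  out
}
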