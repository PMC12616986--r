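# shared fixtures, built once per test run and memoized

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

cal_hs <- function() fixture("cal_hs", function() make_feed_calendar("HS", 12))
cal_ms <- function() fixture("cal_ms", function() make_feed_calendar("MS", 12))

# 60-cow founder population for herd-model tests
tiny_pop <- function() fixture("tiny_pop", function() {
  sample_founders(6, 10, seed = 101)
})

tiny_sim_hs <- function() fixture("tiny_sim_hs", function() {
  simulate_herd(tiny_pop(), cal_hs(), seed = 101)
})

tiny_sim_ms <- function() fixture("tiny_sim_ms", function() {
  simulate_herd(tiny_pop(), cal_ms(), seed = 101)
})

mean_cow <- function() as.data.frame(as.list(aa_means()))

# dense single-trait BLUP oracle: GLS/selection-index solution
dense_blup_oracle <- function(pedigree, y_anim, y, var_g, var_e, A = NULL) {
  ids <- pedigree$animal_id
  n <- length(ids)
  if (is.null(A)) {
    A <- matrix(0, n, n)
    s <- match(pedigree$sire_id, ids, nomatch = 0)
    d <- match(pedigree$dam_id, ids, nomatch = 0)
    for (i in seq_len(n)) {
      A[i, i] <- 1 + if (s[i] > 0 && d[i] > 0) 0.5 * A[s[i], d[i]] else 0
      for (j in seq_len(i - 1)) {
        a <- 0
        if (s[i] > 0) a <- a + 0.5 * A[j, s[i]]
        if (d[i] > 0) a <- a + 0.5 * A[j, d[i]]
        A[i, j] <- A[j, i] <- a
      }
    }
  }
  Z <- matrix(0, length(y), n)
  Z[cbind(seq_along(y), match(y_anim, ids))] <- 1
  V <- var_g * Z %*% A %*% t(Z) + diag(var_e, length(y))
  X <- matrix(1, length(y), 1)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- var_g * A %*% t(Z) %*% Vi %*% (y - X %*% beta)
  as.numeric(u)
}
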