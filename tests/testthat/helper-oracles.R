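# Independent oracles used across the suite. These deliberately avoid the
# package's own solver paths: the LP oracle enumerates basic solutions with
# base solve(), the MDF oracle is an exhaustive grid search, and the
# elimination oracle solves the route system in double precision with
# base qr.solve().

# exhaustive vertex enumeration for max c'x, A x = b, lb <= x <= ub
# (finite bounds, full-row-rank A); returns the optimal objective or -Inf
# when infeasible.
oracle_lp_enum <- function(obj, A, b, lb, ub, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  best <- -Inf
  combos <- utils::combn(n, m)
  # all lower/upper assignments of the n-m nonbasic variables
  k <- n - m
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  for (ci in seq_len(ncol(combos))) {
    basis <- combos[, ci]
    nb <- setdiff(seq_len(n), basis)
    B <- A[, basis, drop = FALSE]
    qrB <- qr(B)
    if (qrB$rank < m) next
    ANB <- A[, nb, drop = FALSE]
    # nonbasic values for every sign pattern: k x 2^k
    XN <- t(grid) * 0
    for (j in seq_len(k)) XN[j, ] <- ifelse(grid[, j] == 0, lb[nb[j]], ub[nb[j]])
    RHS <- b - if (k) ANB %*% XN else matrix(b * 0, m, 1)
    XB <- solve(qrB, RHS)
    feas <- colSums(XB < lb[basis] - tol | XB > ub[basis] + tol) == 0
    if (!any(feas)) next
    vals <- crossprod(XB[, feas, drop = FALSE], obj[basis]) +
      if (k) crossprod(XN[, feas, drop = FALSE], obj[nb]) else 0
    best <- max(best, vals)
  }
  best
}

# random steady-state network LP: S v = 0, finite bounds straddling zero
random_network_lp <- function(m = 8, n = 12) {
  repeat {
    S <- matrix(sample(-2:2, m * n, replace = TRUE,
                       prob = c(1, 2, 3, 2, 1) / 9), m, n)
    if (qr(S)$rank == m) break
  }
  lb <- -sample(0:10, n, replace = TRUE)
  ub <- sample(0:10, n, replace = TRUE)
  obj <- round(stats::rnorm(n), 2)
  list(obj = obj, S = S, lb = lb, ub = ub)
}

# exhaustive grid search MDF oracle: free log-concentrations on a regular
# grid, fixed compounds folded in; returns max over grid of
# min_j -(dG0_j + RT * sum s_ij ln c_i).
oracle_mdf_grid <- function(pathway, constraints, step = 0.01) {
  RT <- formayield::RGAS_KJ * constraints$temperature
  cpds <- sort(unique(unlist(lapply(pathway, function(r)
    names(r$stoichiometry)))))
  cpds <- setdiff(cpds, constraints$exclude)
  fixed <- constraints$fixed_concentrations
  fixed <- fixed[names(fixed) %in% cpds]
  free <- setdiff(cpds, names(fixed))
  rng <- log(constraints$default_range)
  grid_1d <- seq(rng[1], rng[2], by = step)
  grids <- rep(list(grid_1d), length(free))
  names(grids) <- free
  pts <- as.matrix(do.call(expand.grid, grids))
  dfs <- matrix(0, nrow(pts), length(pathway))
  for (j in seq_along(pathway)) {
    r <- pathway[[j]]
    const <- r$dg0_prime
    lin <- numeric(length(free))
    for (cid in names(r$stoichiometry)) {
      s <- r$stoichiometry[[cid]]
      if (cid %in% constraints$exclude) next
      if (cid %in% names(fixed)) const <- const + RT * s * log(fixed[[cid]])
      else lin[match(cid, free)] <- RT * s
    }
    dfs[, j] <- -(const + as.numeric(pts %*% lin))
  }
  max(apply(dfs, 1, min))
}

# double-precision route elimination oracle (independent of the package's
# exact rational path): least-squares solve of the internal+target system.
oracle_route_multipliers <- function(route) {
  rxns <- route$reactions
  cpds <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  S <- matrix(0, length(cpds), length(rxns),
              dimnames = list(cpds, vapply(rxns, `[[`, "", "id")))
  for (j in seq_along(rxns))
    S[names(rxns[[j]]$stoichiometry), j] <- rxns[[j]]$stoichiometry
  M <- S[c(route$internal_compounds, route$target), , drop = FALSE]
  rhs <- c(rep(0, length(route$internal_compounds)), 1)
  qr.solve(M, rhs, tol = 1e-12)
}

# degree of reduction (electron content) of a compound id via compound_db
electrons_of <- function(id) {
  db <- formayield::compound_db()
  row <- db[db$id == id, ]
  if (!nrow(row)) stop("unknown compound ", id)
  f <- formayield::parse_formula(row$formula)
  g <- function(e) if (e %in% names(f)) f[[e]] else 0
  4 * g("C") + g("H") - 2 * g("O") - 3 * g("N") + 5 * g("P") - row$charge
}

core_for_tests <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- formayield::build_core_model()
    cache
  }
})
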