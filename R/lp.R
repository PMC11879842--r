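#' Linear programming by bounded-variable revised simplex
#'
#' Solves `max (or min) c'x  s.t.  A x (dir) rhs,  lb <= x <= ub` where `dir`
#' is one of `"<="`, `"="`, `">="` per row. This dense two-phase primal
#' simplex with explicit variable bounds is the computational core of both
#' the flux balance analysis and the max-min driving force routines: FBA is
#' `max c'v, S v = 0, lb <= v <= ub`, and MDF is a small inequality program
#' over log-concentrations.
#'
#' Determinism: pivoting uses Dantzig pricing with smallest-index tie-breaks
#' and falls back to Bland's rule after prolonged degeneracy, so repeated
#' solves of the same problem give identical objective values.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense numeric.
#' @param rhs right-hand side (length m).
#' @param dir character vector of constraint senses, `"<="`, `"="` or `">="`;
#'   recycled if length 1.
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param maximize logical; `FALSE` minimizes.
#' @param tol feasibility/pricing tolerance (default 1e-9).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective`, and `x` (primal solution, length n).
#' @examples
#' # max x1 + x2 s.t. x1 + x2 <= 4, 0 <= x <= 3
#' lp_solve(c(1, 1), matrix(c(1, 1), 1), 4, "<=", c(0, 0), c(3, 3))$objective
#' @export
lp_solve <- function(obj, A, rhs, dir = "=", lb, ub, maximize = TRUE,
                     tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(lb) == n,
            length(ub) == n)
  dir <- rep_len(dir, m)
  if (!all(dir %in% c("<=", "=", ">="))) stop("dir must be <=, = or >=")
  if (any(!is.finite(lb))) stop("lower bounds must be finite")
  if (any(lb > ub + 1e-12)) stop("lb > ub")

  # slacks convert inequalities to equalities
  nslack <- sum(dir != "=")
  Afull <- cbind(A, matrix(0, m, nslack))
  slb <- sub <- numeric(0)
  j <- n
  for (i in seq_len(m)) {
    if (dir[i] == "=") next
    j <- j + 1
    Afull[i, j] <- if (dir[i] == "<=") 1 else -1
    slb <- c(slb, 0); sub <- c(sub, Inf)
  }
  cfull <- c(if (maximize) obj else -obj, rep(0, nslack))
  res <- .simplex_bounded(cfull, Afull, rhs, c(lb, slb), c(ub, sub), tol)
  if (res$status == "optimal") {
    list(status = "optimal",
         objective = if (maximize) res$objective else -res$objective,
         x = res$x[seq_len(n)])
  } else {
    list(status = res$status, objective = NA_real_, x = rep(NA_real_, n))
  }
}

# Two-phase bounded-variable simplex for max c'x, A x = b, l <= x <= u.
# l finite, u may be Inf. Internal: works on the shifted problem x' = x - l.
.simplex_bounded <- function(cc, A, b, l, u, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  w <- u - l                      # shifted upper bounds, >= 0, may be Inf
  b1 <- as.numeric(b - A %*% l)   # shifted rhs
  # make rhs nonnegative so artificials start feasible
  neg <- b1 < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b1[neg] <- -b1[neg] }

  # artificial columns
  Aall <- cbind(A, diag(m))
  wall <- c(w, rep(Inf, m))
  art <- n + seq_len(m)
  basis <- art
  status <- c(rep(0L, n), rep(1L, m))  # 0 lower, 1 upper, 2 basic
  status[art] <- 2L
  Binv <- diag(m)

  run_phase <- function(cph, basis, status, Binv, wall) {
    degen <- 0L; it <- 0L; maxit <- 20000L
    repeat {
      it <- it + 1L
      if (it > maxit) stop("simplex iteration limit reached")
      if (it %% 60L == 0L) Binv <- solve(Aall[, basis, drop = FALSE])
      upcols <- which(status == 1L & wall > 0)
      beff <- b1
      if (length(upcols))
        beff <- beff - as.numeric(Aall[, upcols, drop = FALSE] %*%
                                    wall[upcols])
      xB <- as.numeric(Binv %*% beff)
      yy <- as.numeric(crossprod(Binv, cph[basis]))
      d <- cph - as.numeric(crossprod(Aall, yy))
      cand_lo <- which(status == 0L & d > tol)
      cand_up <- which(status == 1L & d < -tol)
      cand <- c(cand_lo, cand_up)
      if (!length(cand))
        return(list(basis = basis, status = status, Binv = Binv, xB = xB,
                    opt = TRUE))
      if (degen > 200L) {           # Bland's anti-cycling rule
        jin <- min(cand)
      } else {
        gains <- abs(d[cand])
        jin <- cand[which.max(gains)]
      }
      s <- if (status[jin] == 0L) 1 else -1
      alpha <- s * as.numeric(Binv %*% Aall[, jin])
      # ratio test: xB - t*alpha must stay in [0, wB]
      tmax <- wall[jin]; leave <- 0L; leave_to <- NA_integer_
      wB <- wall[basis]
      pos <- which(alpha > tol)
      if (length(pos)) {
        r1 <- xB[pos] / alpha[pos]
        i1 <- which.min(r1)
        if (r1[i1] < tmax - 1e-12) { tmax <- max(r1[i1], 0); leave <- pos[i1]; leave_to <- 0L }
      }
      neg2 <- which(alpha < -tol & is.finite(wB))
      if (length(neg2)) {
        r2 <- (wB[neg2] - xB[neg2]) / (-alpha[neg2])
        i2 <- which.min(r2)
        if (r2[i2] < tmax - 1e-12) { tmax <- max(r2[i2], 0); leave <- neg2[i2]; leave_to <- 1L }
      }
      if (!is.finite(tmax)) return(list(opt = FALSE, unbounded = TRUE))
      degen <- if (tmax < 1e-11) degen + 1L else 0L
      if (leave == 0L) {            # bound flip, basis unchanged
        status[jin] <- if (status[jin] == 0L) 1L else 0L
        next
      }
      jout <- basis[leave]
      status[jout] <- leave_to
      status[jin] <- 2L
      basis[leave] <- jin
      # eta update of Binv: pivot on row `leave` of alpha (in entering sign s)
      acol <- as.numeric(Binv %*% Aall[, jin])
      piv <- acol[leave]
      E <- diag(m)
      E[, leave] <- -acol / piv
      E[leave, leave] <- 1 / piv
      Binv <- E %*% Binv
    }
  }

  # phase 1: minimize artificial sum
  c1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(c1, basis, status, Binv, wall)
  if (isTRUE(ph1$unbounded)) stop("phase-1 unbounded: internal error")
  basis <- ph1$basis; status <- ph1$status; Binv <- ph1$Binv
  artsum <- sum(ph1$xB[basis > n])
  if (artsum > 1e-7) return(list(status = "infeasible"))
  # freeze artificials at zero for phase 2 (basic-at-zero ones may remain,
  # covering redundant rows)
  wall[art] <- 0
  status[art][status[art] == 1L] <- 0L

  c2 <- c(cc, rep(0, m))
  ph2 <- run_phase(c2, basis, status, Binv, wall)
  if (isTRUE(ph2$unbounded)) return(list(status = "unbounded"))
  basis <- ph2$basis; status <- ph2$status
  xs <- numeric(n + m)
  xs[status == 1L] <- wall[status == 1L]
  xs[basis] <- ph2$xB
  x <- xs[seq_len(n)] + l
  list(status = "optimal", objective = sum(cc * x), x = x)
}
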