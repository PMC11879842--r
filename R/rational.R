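# Exact rational arithmetic on integer numerator/denominator pairs.
# Pathway net-stoichiometry elimination must be exact (a net coefficient of
# an internal intermediate is zero, not 1e-15), so these helpers implement
# vectorised rationals with doubles holding exact integers (safe well below
# 2^53 for the small coefficients of pathway tables).

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

#' Create a vector of exact rationals
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (nonzero).
#' @return object of class `rational` with reduced, sign-normalised terms
#'   (denominator always positive).
#' @examples
#' rational(2, 4)            # 1/2
#' rat_add(rational(1, 3), rational(1, 6))
#' @export
rational <- function(num, den = 1) {
  k <- max(length(num), length(den))
  num <- rep_len(num, k); den <- rep_len(den, k)
  if (any(den == 0)) stop("zero denominator")
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational() needs integer-valued arguments")
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- .gcd(num, den); g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

.as_rat <- function(x) {
  if (inherits(x, "rational")) return(x)
  rational(x, 1)
}

#' @export
print.rational <- function(x, ...) {
  cat(ifelse(x$den == 1, as.character(x$num),
             paste0(x$num, "/", x$den)), "\n")
  invisible(x)
}

#' @rdname rational
#' @param x,y rational vectors (plain integer vectors are promoted).
#' @export
rat_add <- function(x, y) {
  x <- .as_rat(x); y <- .as_rat(y)
  rational(x$num * y$den + y$num * x$den, x$den * y$den)
}

#' @rdname rational
#' @export
rat_sub <- function(x, y) rat_add(x, rat_neg(y))

#' @rdname rational
#' @export
rat_neg <- function(x) { x <- .as_rat(x); rational(-x$num, x$den) }

#' @rdname rational
#' @export
rat_mul <- function(x, y) {
  x <- .as_rat(x); y <- .as_rat(y)
  rational(x$num * y$num, x$den * y$den)
}

#' @rdname rational
#' @export
rat_div <- function(x, y) {
  y <- .as_rat(y)
  if (any(y$num == 0)) stop("division by zero")
  rat_mul(x, rational(y$den, y$num))
}

#' @rdname rational
#' @export
rat_num <- function(x) .as_rat(x)$num

#' @rdname rational
#' @export
rat_den <- function(x) .as_rat(x)$den

#' Convert rationals to double
#' @param x rational vector.
#' @export
rat_dbl <- function(x) { x <- .as_rat(x); x$num / x$den }

rat_elt <- function(x, i) rational(x$num[i], x$den[i])
rat_is_zero <- function(x) .as_rat(x)$num == 0

# Gauss-Jordan elimination of M y = rhs over the rationals.
# M, rhs: plain numeric with integer-valued entries scaled by `den` (single
# common denominator per matrix not needed: entries converted elementwise).
# Returns list(solution = rational vector with free variables set to zero,
# pivots, consistent).
rat_solve_gj <- function(Mnum, Mden, rnum, rden) {
  m <- nrow(Mnum); n <- ncol(Mnum)
  # augmented rational matrix held as numerator/denominator matrices
  An <- cbind(Mnum, rnum); Ad <- cbind(Mden, rden)
  red <- function(i, j) {                 # reduce one cell
    g <- .gcd(An[i, j], Ad[i, j]); if (g == 0) g <- 1
    s <- if (Ad[i, j] < 0) -1 else 1
    An[i, j] <<- s * An[i, j] / g; Ad[i, j] <<- s * Ad[i, j] / g
  }
  piv_rows <- integer(0); piv_cols <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    pr <- which(An[row:m, col] != 0)
    if (!length(pr)) next
    pr <- pr[1] + row - 1L
    if (pr != row) { An[c(pr, row), ] <- An[c(row, pr), ]; Ad[c(pr, row), ] <- Ad[c(row, pr), ] }
    # scale pivot row to 1
    pn <- An[row, col]; pd <- Ad[row, col]
    for (j in seq_len(n + 1L)) {
      An[row, j] <- An[row, j] * pd; Ad[row, j] <- Ad[row, j] * pn
      red(row, j)
    }
    for (i in seq_len(m)) {
      if (i == row || An[i, col] == 0) next
      fn <- An[i, col]; fd <- Ad[i, col]
      for (j in seq_len(n + 1L)) {
        # A[i,j] <- A[i,j] - f * A[row,j]
        num <- An[i, j] * fd * Ad[row, j] - fn * An[row, j] * Ad[i, j]
        den <- Ad[i, j] * fd * Ad[row, j]
        An[i, j] <- num; Ad[i, j] <- den
        red(i, j)
      }
    }
    piv_rows <- c(piv_rows, row); piv_cols <- c(piv_cols, col)
    row <- row + 1L
  }
  # consistency: zero rows must have zero rhs
  consistent <- TRUE
  for (i in seq_len(m)) {
    if (all(An[i, seq_len(n)] == 0) && An[i, n + 1L] != 0) consistent <- FALSE
  }
  sol_n <- numeric(n); sol_d <- rep(1, n)
  if (consistent) {
    sol_n[piv_cols] <- An[piv_rows, n + 1L]
    sol_d[piv_cols] <- Ad[piv_rows, n + 1L]
  }
  list(solution = rational(sol_n, sol_d), consistent = consistent,
       pivot_cols = piv_cols, n_free = n - length(piv_cols))
}
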