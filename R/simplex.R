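# Exact rational phase-1 simplex for small feasibility problems.
#
# Decides whether { x >= 0 : A x >= b } is nonempty for integer A, b and
# returns a rational witness.  All tableau entries are kept as reduced
# numerator/denominator pairs stored in doubles; with the integer data
# and desk-scale problems handled here (tens of rows/columns) the
# intermediate integers stay far below 2^53, which is asserted.
# Bland's rule guarantees termination.

RAT_LIMIT <- 2^52

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  repeat {
    nz <- which(b > 0)
    if (!length(nz)) return(a)
    t <- b[nz]
    b[nz] <- a[nz] %% b[nz]
    a[nz] <- t
  }
}

rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("rational with zero denominator")
  s <- sign(den)
  num <- num * s; den <- den * s
  g <- rat_gcd(num, den)
  g[g == 0] <- 1
  num <- num / g; den <- den / g
  if (any(abs(num) > RAT_LIMIT) || any(den > RAT_LIMIT))
    stop("exact rational arithmetic overflow (problem too large)")
  list(num = num, den = den)
}

# elementwise a/b - f * c/d for rational vectors, f a rational scalar
rat_submul <- function(an, ad, fn, fd, cn, cd) {
  rat_reduce(an * fd * cd - fn * cn * ad, ad * fd * cd)
}

# Solve: does x >= 0 with A x >= b exist?  A: p x q integer matrix.
# Returns list(feasible =, x_num =, x_den =) with x of length q.
lp_feasible <- function(A, b) {
  p <- nrow(A); q <- ncol(A)
  stopifnot(length(b) == p)
  if (p == 0L)
    return(list(feasible = TRUE, x_num = rep(0, q), x_den = rep(1, q)))
  A <- matrix(as.numeric(A), p, q); b <- as.numeric(b)
  stopifnot(all(A == round(A)), all(b == round(b)))

  # standard form A x - s = b, s >= 0; flip rows to make rhs >= 0,
  # then add one artificial per row to obtain a starting basis.
  slack <- -diag(p)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  slack[flip, ] <- -slack[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  ncol_t <- q + p + p + 1L                # x | s | artificials | rhs
  Tn <- cbind(A, slack, diag(p), b)       # numerators
  Td <- matrix(1, p, ncol_t)              # denominators
  basis <- q + p + seq_len(p)             # artificial basis
  art <- q + p + seq_len(p)

  # phase-1 objective row: w_j = sum_i T[i, j] - c_j (c = 1 on artificials)
  wn <- colSums(Tn); wd <- rep(1, ncol_t)
  wn[art] <- wn[art] - 1
  w <- rat_reduce(wn, wd); wn <- w$num; wd <- w$den

  repeat {
    # Bland: smallest column (excluding rhs) with positive reduced value
    enter <- 0L
    for (j in seq_len(ncol_t - 1L)) {
      if (wn[j] > 0) { enter <- j; break }
    }
    if (enter == 0L) break

    # ratio test over rows with positive pivot column entry
    leave <- 0L; best_n <- NA_real_; best_d <- NA_real_
    for (i in seq_len(p)) {
      if (Tn[i, enter] > 0) {
        # ratio rhs_i / T[i, enter]
        rn <- Tn[i, ncol_t] * Td[i, enter]
        rd <- Td[i, ncol_t] * Tn[i, enter]
        if (leave == 0L || rn * best_d < best_n * rd ||
            (rn * best_d == best_n * rd && basis[i] < basis[leave])) {
          leave <- i; best_n <- rn; best_d <- rd
        }
      }
    }
    if (leave == 0L) stop("phase-1 LP unbounded; cannot happen")

    # pivot on (leave, enter): normalize row, eliminate elsewhere
    pn <- Tn[leave, enter]; pd <- Td[leave, enter]
    row <- rat_reduce(Tn[leave, ] * pd, Td[leave, ] * pn)
    Tn[leave, ] <- row$num; Td[leave, ] <- row$den
    for (i in seq_len(p)) {
      if (i != leave && Tn[i, enter] != 0) {
        fn <- Tn[i, enter]; fd <- Td[i, enter]
        upd <- rat_submul(Tn[i, ], Td[i, ], fn, fd, Tn[leave, ], Td[leave, ])
        Tn[i, ] <- upd$num; Td[i, ] <- upd$den
      }
    }
    if (wn[enter] != 0) {
      fn <- wn[enter]; fd <- wd[enter]
      upd <- rat_submul(wn, wd, fn, fd, Tn[leave, ], Td[leave, ])
      wn <- upd$num; wd <- upd$den
    }
    basis[leave] <- enter
  }

  if (wn[ncol_t] != 0)                    # residual artificial mass
    return(list(feasible = FALSE, x_num = NULL, x_den = NULL))
  # basic artificials can only remain at value zero here
  x_num <- rep(0, q); x_den <- rep(1, q)
  for (i in seq_len(p)) {
    if (basis[i] <= q) {
      x_num[basis[i]] <- Tn[i, ncol_t]
      x_den[basis[i]] <- Td[i, ncol_t]
    }
  }
  list(feasible = TRUE, x_num = x_num, x_den = x_den)
}

# exact check that x (rational) satisfies A x >= b with integer A, b
lp_check_exact <- function(A, b, x_num, x_den) {
  p <- nrow(A)
  if (p == 0L) return(TRUE)
  D <- Reduce(function(a, d) a / rat_gcd(a, d) * d, unique(x_den), 1)
  if (abs(D) > RAT_LIMIT) stop("rational overflow in exact check")
  xs <- x_num * (D / x_den)           # integer scaled solution
  all(A %*% xs - b * D >= 0) && all(xs >= 0)
}
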